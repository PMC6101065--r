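# independent oracles and fixture builders, used across the suite

r_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")

r_revcomp <- function(s) {
  chartr("ACGT", "TGCA", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

# naive sliding-window k-mer counting (the brute-force oracle)
oracle_count_kmers <- function(reads, k, canonical) {
  words <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    i <- seq_len(n - k + 1)
    substring(r, i, i + k - 1)
  }))
  words <- words[!grepl("[^ACGT]", words)]
  if (canonical && length(words)) words <- pmin(words, r_revcomp(words))
  if (length(words) == 0) return(NULL)
  tab <- table(words)
  tab[order(names(tab))]
}

# textbook LCS dynamic programming
oracle_lcs <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  if (na == 0 || nb == 0) return(0L)
  dp <- matrix(0L, na + 1, nb + 1)
  for (i in seq_len(na))
    for (j in seq_len(nb))
      dp[i + 1, j + 1] <- if (av[i] == bv[j]) dp[i, j] + 1L else
        max(dp[i, j + 1], dp[i + 1, j])
  dp[na + 1, nb + 1]
}

# substitute the bases at `pos` (1-based), each advanced cyclically A->C->G->T->A
substitute_at <- function(word, pos, offset = 1) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(word, "")[[1]]
  for (p in pos)
    chars[p] <- bases[((match(chars[p], bases) - 1 + offset) %% 4) + 1]
  paste(chars, collapse = "")
}

# brute-force maximum non-overlapping interval coverage over all subsets
oracle_best_cover <- function(start, end) {
  n <- length(start)
  if (n == 0) return(0)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > 1) {
      ord <- order(start[idx])
      s <- start[idx][ord]; e <- end[idx][ord]
      if (any(utils::head(e, -1) > utils::tail(s, -1))) next
    }
    best <- max(best, sum(end[idx] - start[idx]))
  }
  best
}

# connected components of an explicit adjacency predicate, by BFS
oracle_components <- function(n, linked) {
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in seq_len(n)) {
        if (is.na(comp[u]) && linked(v, u)) {
          comp[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

# a kmer_table from explicit words/counts without canonicality checks
as_table <- function(words, counts, canonical = FALSE) {
  kmer_table(words, counts, k = nchar(words[1]), canonical = canonical,
             validate = FALSE)
}
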