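#' Clustering parameters
#'
#' @param sim_threshold pairwise similarity above which two repeats are
#'   linked (default 0.85).
#' @return An object of class \code{cluster_params}.
#' @export
cluster_params <- function(sim_threshold = 0.85) {
  stopifnot_scalar(sim_threshold, "sim_threshold", min = 1e-12, max = 1)
  structure(list(sim_threshold = sim_threshold), class = "cluster_params")
}

#' Pairwise similarity of two repeat sequences
#'
#' The maximum number of aligned identical bases over all gapped alignments
#' (the longest common subsequence, taking the better of the two relative
#' orientations) divided by the length of the shorter sequence. Normalizing
#' by the shorter sequence lets a fragment reach similarity 1 with its
#' full-length parent, which is the point: many assembled repeats are partial
#' copies of the same consensus.
#'
#' @param a,b nonempty DNA strings.
#' @param both_strands also try the reverse complement of \code{b}
#'   (default \code{TRUE}).
#' @return Similarity in [0, 1]; symmetric; \code{pairwise_similarity(x, x)}
#'   is 1.
#' @export
pairwise_similarity <- function(a, b, both_strands = TRUE) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  s <- .lcs_cpp(a, b)
  if (both_strands) s <- max(s, .lcs_cpp(a, reverse_complement(b)))
  s / min(nchar(a), nchar(b))
}

#' Cluster assembled repeats that are copies of one consensus
#'
#' Links every pair of repeats whose \code{\link{pairwise_similarity}}
#' exceeds \code{sim_threshold} and forms clusters as the connected
#' components of the link graph (union-find). The longest member of each
#' cluster is its representative. The partition does not depend on record
#' order; cluster ids are numbered by each cluster's lexicographically
#' smallest member id.
#'
#' @param repeats named character vector of sequences, a \code{contig_set},
#'   or a FASTA file path.
#' @param params a \code{\link{cluster_params}}.
#' @return A data frame with columns \code{repeat_id}, \code{cluster_id},
#'   \code{is_representative}.
#' @export
cluster_repeats <- function(repeats, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  seqs <- as_named_seqs(repeats)
  n <- length(seqs)
  if (n == 0) stop("repeats must be nonempty")
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (find(i) == find(j)) next
        if (pairwise_similarity(seqs[i], seqs[j]) > params$sim_threshold) {
          ri <- find(i); rj <- find(j)
          parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # order-independent labels: number clusters by smallest member id
  min_id <- vapply(split(names(seqs), roots), min, character(1))
  cluster_id <- match(min_id[as.character(roots)],
                      sort(unique(unname(min_id))))
  rep_flag <- logical(n)
  for (cl in unique(cluster_id)) {
    mem <- which(cluster_id == cl)
    lens <- nchar(seqs[mem])
    cand <- mem[lens == max(lens)]
    rep_flag[cand[order(names(seqs)[cand])[1]]] <- TRUE
  }
  data.frame(repeat_id = names(seqs), cluster_id = cluster_id,
             is_representative = rep_flag, stringsAsFactors = FALSE,
             row.names = NULL)
}

# coerce contig_set / FASTA path / character to a named character vector
as_named_seqs <- function(x) {
  if (inherits(x, "contig_set")) {
    seqs <- x$sequence
    names(seqs) <- x$id
    return(seqs)
  }
  if (is.character(x) && length(x) == 1 &&
      grepl("\\.(fa|fasta)(\\.gz)?$", x, ignore.case = TRUE) && file.exists(x))
    x <- read_fasta(x)
  if (!is.character(x)) x <- as.character(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- sprintf("rep%d", seq_along(x))
  toupper(x)
}
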