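#' Contig merging parameters
#'
#' @param min_overlap minimum suffix-prefix overlap length (default 10).
#' @param max_overlap_mismatch maximum mismatches tolerated inside the
#'   overlap (default 1).
#' @param allow_revcomp consider the reverse complement of the second contig
#'   (default \code{TRUE}).
#' @param min_output_len minimum length of reported merged repeats; the
#'   conventional default is twice the counting k (60 for k = 30).
#' @return An object of class \code{merge_params}.
#' @export
merge_params <- function(min_overlap = 10, max_overlap_mismatch = 1,
                         allow_revcomp = TRUE, min_output_len = 60) {
  stopifnot_scalar(min_overlap, "min_overlap", min = 1, integer = TRUE)
  stopifnot_scalar(max_overlap_mismatch, "max_overlap_mismatch", min = 0,
                   integer = TRUE)
  stopifnot_scalar(min_output_len, "min_output_len", min = 1, integer = TRUE)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_overlap_mismatch = as.integer(max_overlap_mismatch),
                 allow_revcomp = isTRUE(allow_revcomp),
                 min_output_len = as.integer(min_output_len)),
            class = "merge_params")
}

# contig container: data frame with id / sequence / mean_support
contig_set <- function(sequence, mean_support, id = NULL) {
  if (is.null(id)) id <- sprintf("rep%d", seq_along(sequence))
  structure(data.frame(id = id, sequence = as.character(sequence),
                       mean_support = as.numeric(mean_support),
                       stringsAsFactors = FALSE),
            class = c("contig_set", "data.frame"))
}

#' Assemble k-mers into unitig contigs
#'
#' Builds the de Bruijn graph whose nodes are the (assembly_k - 1)-mers and
#' whose edges are the assembly_k-mers occurring in the input k-mers (both
#' orientations for canonical tables), then reports maximal non-branching
#' paths (unitigs) as contigs. Choosing \code{assembly_k} a little below the
#' counting k lets k-mers that still carry a stray variant base co-assemble.
#' Dead-end branches shorter than \code{assembly_k} whose edges are each
#' supported by a single input k-mer occurrence are pruned first (minimal
#' tip cleanup; disable with \code{prune_tips = FALSE}).
#'
#' @param kmers a \code{\link{kmer_table}}.
#' @param assembly_k de Bruijn word length; must be smaller than the table's
#'   k (default \code{k - 5}).
#' @param min_edge_support discard edges seen in fewer input k-mer
#'   occurrences (default 1: discard none).
#' @param prune_tips prune low-support dead-end branches (default TRUE).
#' @param tip_max_support maximum per-edge occurrence support of a prunable
#'   tip (default 1).
#' @return A \code{contig_set} data frame with columns \code{id},
#'   \code{sequence}, \code{mean_support} (mean per-occurrence count of the
#'   k-mers supporting the contig's edges), sorted by decreasing length.
#' @export
assemble_contigs <- function(kmers, assembly_k = kmers$k - 5,
                             min_edge_support = 1, prune_tips = TRUE,
                             tip_max_support = 1) {
  stopifnot(inherits(kmers, "kmer_table"))
  stopifnot_scalar(assembly_k, "assembly_k", min = 2, integer = TRUE)
  if (assembly_k > kmers$k)
    stop("assembly_k must not exceed the table's k = ", kmers$k)
  if (length(kmers) == 0) stop("kmers must be nonempty")
  res <- .assemble_unitigs_cpp(kmers$kmer, kmers$count,
                               as.integer(assembly_k), kmers$canonical,
                               as.integer(min_edge_support),
                               isTRUE(prune_tips), as.integer(assembly_k),
                               as.integer(tip_max_support))
  seqs <- as.character(res$sequence)
  supp <- as.numeric(res$mean_support)
  if (kmers$canonical && length(seqs)) {
    canon <- pmin(seqs, reverse_complement(seqs))
    keep <- !duplicated(canon)
    seqs <- canon[keep]
    supp <- supp[keep]
  }
  ord <- order(-nchar(seqs), seqs, method = "radix")
  contig_set(seqs[ord], supp[ord])
}

#' Best suffix-prefix overlap between two contigs
#'
#' Finds the longest overlap of a suffix of \code{a} with a prefix of
#' \code{b} (considering the reverse complement of \code{b} when allowed)
#' with length at least \code{min_overlap} and at most
#' \code{max_overlap_mismatch} mismatches. Length ties break toward fewer
#' mismatches, then toward the forward orientation.
#'
#' @param a,b DNA strings (or single rows of a \code{contig_set}).
#' @param params a \code{\link{merge_params}}.
#' @return \code{NULL} when no qualifying overlap exists, else a list with
#'   \code{orientation} ("forward" or "revcomp"), \code{overlap_len} and
#'   \code{mismatches}.
#' @export
best_overlap <- function(a, b, params = merge_params()) {
  if (is.data.frame(a)) a <- a$sequence
  if (is.data.frame(b)) b <- b$sequence
  stopifnot(inherits(params, "merge_params"))
  fw <- .suffix_prefix_cpp(a, b, params$min_overlap,
                           params$max_overlap_mismatch)
  best <- NULL
  if (fw[1] > 0)
    best <- list(orientation = "forward", overlap_len = fw[1],
                 mismatches = fw[2])
  if (params$allow_revcomp) {
    rv <- .suffix_prefix_cpp(a, reverse_complement(b), params$min_overlap,
                             params$max_overlap_mismatch)
    if (rv[1] > 0) {
      better <- is.null(best) || rv[1] > best$overlap_len ||
        (rv[1] == best$overlap_len && rv[2] < best$mismatches)
      if (better)
        best <- list(orientation = "revcomp", overlap_len = rv[1],
                     mismatches = rv[2])
    }
  }
  best
}

#' Merge contigs on reliable suffix-prefix overlaps
#'
#' Greedy second-round assembly: repeatedly merge the contig pair with the
#' longest qualifying overlap (ties to fewer mismatches, then forward
#' orientation, then input order) until no pair qualifies. At mismatching
#' overlap positions the base of the contig with higher mean k-mer support
#' wins, mirroring frequency-weighted consensus voting. The result is
#' filtered to \code{min_output_len}.
#'
#' @param contigs a \code{contig_set} from \code{\link{assemble_contigs}}, or
#'   a character vector of sequences.
#' @param params a \code{\link{merge_params}}.
#' @return A \code{contig_set} of merged consensus repeats.
#' @export
merge_contigs <- function(contigs, params = merge_params()) {
  stopifnot(inherits(params, "merge_params"))
  if (is.character(contigs)) contigs <- contig_set(contigs, rep(1, length(contigs)))
  seqs <- contigs$sequence
  supp <- contigs$mean_support
  repeat {
    n <- length(seqs)
    if (n < 2) break
    best <- NULL
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        ov <- best_overlap(seqs[i], seqs[j], params)
        if (is.null(ov)) next
        cand <- list(i = i, j = j, ov = ov)
        if (is.null(best) ||
            ov$overlap_len > best$ov$overlap_len ||
            (ov$overlap_len == best$ov$overlap_len &&
               ov$mismatches < best$ov$mismatches) ||
            (ov$overlap_len == best$ov$overlap_len &&
               ov$mismatches == best$ov$mismatches &&
               best$ov$orientation == "revcomp" &&
               ov$orientation == "forward"))
          best <- cand
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    b_seq <- if (best$ov$orientation == "revcomp")
      reverse_complement(seqs[j]) else seqs[j]
    L <- best$ov$overlap_len
    na <- nchar(seqs[i]); nb <- nchar(b_seq)
    junction <- if (supp[i] >= supp[j])
      substr(seqs[i], na - L + 1, na) else substr(b_seq, 1, L)
    merged <- paste0(substr(seqs[i], 1, na - L), junction,
                     substr(b_seq, L + 1, nb))
    new_supp <- (na * supp[i] + (nb - L) * supp[j]) / (na + nb - L)
    keep <- setdiff(seq_len(n), c(i, j))
    seqs <- c(seqs[keep], merged)
    supp <- c(supp[keep], new_supp)
  }
  keep <- nchar(seqs) >= params$min_output_len
  seqs <- seqs[keep]; supp <- supp[keep]
  ord <- order(-nchar(seqs), seqs, method = "radix")
  contig_set(seqs[ord], supp[ord])
}
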