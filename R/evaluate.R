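#' Align assembled repeats to a reference repeat library
#'
#' Local alignment (via \code{Biostrings::pairwiseAlignment}, match 1,
#' mismatch -1, gap open 2, gap extend 1) of every assembled repeat against
#' every library entry, in both orientations. An alignment is reported as a
#' hit interval on the library sequence when its identity (matches divided by
#' alignment columns) reaches \code{min_local_identity} and it spans at least
#' \code{min_hit_len} library bases; the length floor suppresses the short
#' spurious local matches any two random sequences share.
#'
#' @param repeats,library named character vectors of DNA sequences, a
#'   \code{contig_set}, or FASTA file paths.
#' @param min_local_identity minimum alignment identity of a reported hit
#'   (default 0.85).
#' @param min_hit_len minimum library bases spanned by a reported hit
#'   (default 50).
#' @return A data frame of intervals: \code{library_id}, \code{start},
#'   \code{end} (0-based, half-open, on the library sequence),
#'   \code{identity}, \code{query_id}, \code{query_len}, \code{orientation},
#'   \code{nmatch}.
#' @export
align_to_library <- function(repeats, library, min_local_identity = 0.85,
                             min_hit_len = 50) {
  hits <- align_all(repeats, library)
  hits[hits$identity >= min_local_identity &
         (hits$end - hits$start) >= min_hit_len, , drop = FALSE]
}

# all best local alignments, unfiltered
align_all <- function(repeats, library) {
  reps <- as_named_seqs(repeats)
  lib <- as_named_seqs(library)
  if (length(reps) == 0 || length(lib) == 0)
    stop("repeats and library must be nonempty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  out <- vector("list", length(reps) * length(lib) * 2L)
  slot <- 0L
  for (li in seq_along(lib)) {
    subj <- lib[[li]]
    for (ri in seq_along(reps)) {
      for (orient in c("forward", "revcomp")) {
        q <- if (orient == "forward") reps[[ri]] else
          reverse_complement(reps[[ri]])
        aln <- Biostrings::pairwiseAlignment(
          pattern = q, subject = subj, type = "local",
          substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
        ncols <- Biostrings::nchar(aln)
        if (ncols == 0) next
        nm <- Biostrings::nmatch(aln)
        s <- Biostrings::start(Biostrings::subject(aln))
        e <- Biostrings::end(Biostrings::subject(aln))
        slot <- slot + 1L
        out[[slot]] <- data.frame(
          library_id = names(lib)[li], start = s - 1L, end = e,
          identity = nm / ncols, query_id = names(reps)[ri],
          query_len = nchar(reps[[ri]]), orientation = orient,
          nmatch = nm, stringsAsFactors = FALSE)
      }
    }
  }
  if (slot == 0L)
    return(data.frame(library_id = character(0), start = integer(0),
                      end = integer(0), identity = numeric(0),
                      query_id = character(0), query_len = integer(0),
                      orientation = character(0), nmatch = integer(0)))
  do.call(rbind, out[seq_len(slot)])
}

#' Maximum non-overlapping coverage of a library entry
#'
#' Among the hit intervals on one library sequence, selects the pairwise
#' non-overlapping subset with the largest total length (weighted interval
#' scheduling, weight = interval length, solved by dynamic programming over
#' end-sorted intervals). Abutting half-open intervals do not overlap.
#'
#' @param intervals a data frame with columns \code{start} and \code{end}
#'   (0-based, half-open), all on one library sequence.
#' @return Total covered length of the optimal subset.
#' @export
max_nonoverlapping_coverage <- function(intervals) {
  n <- nrow(intervals)
  if (is.null(n) || n == 0) return(0L)
  ord <- order(intervals$end, intervals$start)
  s <- intervals$start[ord]
  e <- intervals$end[ord]
  w <- e - s
  # p[i]: rightmost j < i with e[j] <= s[i]
  p <- vapply(seq_len(n), function(i) {
    cand <- which(e[seq_len(i - 1)] <= s[i])
    if (length(cand)) max(cand) else 0L
  }, integer(1))
  dp <- numeric(n + 1)
  for (i in seq_len(n))
    dp[i + 1] <- max(dp[i], w[i] + dp[p[i] + 1])
  dp[n + 1]
}

#' Score assembled repeats against a reference repeat library
#'
#' Computes the standard library-evaluation summary:
#' \describe{
#'   \item{N}{total number of assembled repeats.}
#'   \item{N_0}{library entries with at least one hit
#'     (\code{\link{align_to_library}}).}
#'   \item{N_h}{library entries fully reconstructed by a single assembled
#'     repeat: some repeat's aligned matches, divided by the \emph{entire}
#'     library entry length (uncovered positions count as mismatches),
#'     exceed \code{identity_threshold}.}
#'   \item{C_avg}{mean, over hit entries, of the maximum non-overlapping
#'     covered fraction (\code{\link{max_nonoverlapping_coverage}}).}
#'   \item{C_m}{mean, over hit entries, of the covered fraction using only
#'     the longest assembled repeat hitting that entry.}
#' }
#'
#' @inheritParams align_to_library
#' @param identity_threshold full-length identity for N_h and local identity
#'   for hits (default 0.85).
#' @return An object of class \code{library_metrics}: a list with the five
#'   summary values and a \code{per_entry} data frame.
#' @export
compute_metrics <- function(repeats, library, identity_threshold = 0.85,
                            min_hit_len = 50) {
  reps <- as_named_seqs(repeats)
  lib <- as_named_seqs(library)
  all_hits <- align_all(reps, lib)
  hits <- all_hits[all_hits$identity >= identity_threshold &
                     (all_hits$end - all_hits$start) >= min_hit_len, ,
                   drop = FALSE]
  per <- lapply(names(lib), function(lid) {
    L <- nchar(lib[[lid]])
    h <- hits[hits$library_id == lid, , drop = FALSE]
    a <- all_hits[all_hits$library_id == lid, , drop = FALSE]
    # best single-repeat identity across the full entry length
    full_ident <- if (nrow(a)) {
      best <- tapply(a$nmatch, a$query_id, max)
      max(best) / L
    } else 0
    hit <- nrow(h) > 0
    cov <- if (hit) max_nonoverlapping_coverage(h) / L else NA_real_
    cov_longest <- if (hit) {
      longest <- h$query_id[which.max(h$query_len)]
      max_nonoverlapping_coverage(h[h$query_id == longest, , drop = FALSE]) / L
    } else NA_real_
    data.frame(library_id = lid, length = L, hit = hit,
               best_full_identity = full_ident, coverage = cov,
               coverage_longest = cov_longest, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  hit_rows <- per[per$hit, , drop = FALSE]
  metrics <- list(
    N = length(reps),
    N_h = sum(per$best_full_identity > identity_threshold),
    N_0 = nrow(hit_rows),
    C_avg = if (nrow(hit_rows)) mean(hit_rows$coverage) else 0,
    C_m = if (nrow(hit_rows)) mean(hit_rows$coverage_longest) else 0,
    per_entry = per)
  class(metrics) <- "library_metrics"
  metrics
}

#' @export
print.library_metrics <- function(x, ...) {
  cat("library evaluation:\n")
  cat(sprintf("  N     = %d assembled repeats\n", x$N))
  cat(sprintf("  N_h   = %d library entries fully reconstructed\n", x$N_h))
  cat(sprintf("  N_0   = %d library entries hit\n", x$N_0))
  cat(sprintf("  C_avg = %.3f mean covered fraction (optimal hit set)\n",
              x$C_avg))
  cat(sprintf("  C_m   = %.3f mean covered fraction (longest hit only)\n",
              x$C_m))
  invisible(x)
}
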