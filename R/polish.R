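#' Polishing parameters
#'
#' Parameters for the randomized end-to-end matching scheme. In each of
#' \code{n_trials} trials, \code{h} positions of the k-mer are sampled
#' without replacement; two k-mers whose extracted h-mers agree in at least
#' one trial are grouped. For a pair of k-mers within edit distance \code{e}
#' the probability of being grouped is given by
#' \code{\link{grouping_probability}}.
#'
#' @param k word length.
#' @param h sampled positions per trial, \code{1 <= h <= k} (default 15).
#' @param n_trials number of trials; the default is the smallest n for which
#'   the grouping probability at \code{(k, h, e)} reaches 0.99.
#' @param e tolerated edit distance between grouped k-mers (default 1: one
#'   mismatch, insertion or deletion, reasonable for k below 100).
#' @param seed RNG seed for the position draws.
#' @param n_partitions number of partitions for partitioned (map-reduce
#'   style) execution; the result is identical for any value (default 1).
#' @return An object of class \code{polish_params}.
#' @export
polish_params <- function(k, h = min(15L, k), n_trials = NULL, e = 1,
                          seed = 1, n_partitions = 1) {
  stopifnot_scalar(k, "k", min = 2, integer = TRUE)
  stopifnot_scalar(h, "h", min = 1, max = k, integer = TRUE)
  stopifnot_scalar(e, "e", min = 0, max = k - 1, integer = TRUE)
  stopifnot_scalar(seed, "seed", integer = TRUE)
  stopifnot_scalar(n_partitions, "n_partitions", min = 1, integer = TRUE)
  if (is.null(n_trials)) {
    ratio <- match_fraction(k, h, e)
    if (ratio <= 0)
      stop("grouping probability cannot reach 0.99 at these (k, h, e); ",
           "supply n_trials explicitly")
    n_trials <- if (ratio >= 1) 1L else as.integer(ceiling(log(0.01) / log(1 - ratio)))
  }
  stopifnot_scalar(n_trials, "n_trials", min = 1, integer = TRUE)
  structure(list(k = as.integer(k), h = as.integer(h),
                 n_trials = as.integer(n_trials), e = as.integer(e),
                 seed = as.integer(seed),
                 n_partitions = as.integer(n_partitions)),
            class = "polish_params")
}

# C(k-e, h) / C(k, h) as an exact product of small-integer ratios
match_fraction <- function(k, h, e) {
  if (h > k - e) return(0)
  if (e == 0) return(1)
  i <- seq_len(e) - 1
  prod((k - h - i) / (k - i))
}

#' Probability that two similar k-mers are grouped
#'
#' For two k-mers within edit distance \code{e}, the probability that the h
#' sampled positions all avoid the differing positions in a single trial is
#' \code{choose(k - e, h) / choose(k, h)}; over n independent trials the
#' probability of at least one agreeing trial is
#' \deqn{p = 1 - \left(1 - \binom{k-e}{h} / \binom{k}{h}\right)^n.}
#' The binomial ratio is evaluated exactly (as a product of integer ratios);
#' \code{choose(k - e, h)} is 0 when \code{h > k - e}.
#'
#' @param k word length.
#' @param h sampled positions per trial.
#' @param e edit distance between the pair.
#' @param n number of trials.
#' @return Probability in [0, 1].
#' @examples
#' grouping_probability(30, 15, e = 0, n = 1)   # 1
#' grouping_probability(30, 30, e = 1, n = 5)   # 0
#' grouping_probability(30, 15, e = 1, n = 10)  # 1 - 0.5^10
#' @export
grouping_probability <- function(k, h, e, n) {
  stopifnot_scalar(k, "k", min = 1, integer = TRUE)
  stopifnot_scalar(h, "h", min = 1, max = k, integer = TRUE)
  stopifnot_scalar(e, "e", min = 0, integer = TRUE)
  stopifnot_scalar(n, "n", min = 1, integer = TRUE)
  1 - (1 - match_fraction(k, h, e))^n
}

#' Draw the per-trial position subsets
#'
#' Samples \code{n_trials} subsets of \code{h} positions from \code{1..k},
#' without replacement within a trial and independently across trials,
#' deterministically for a given seed. The same subsets are applied to every
#' k-mer in a trial, which realizes the pairwise end-to-end matching
#' probability while allowing exact h-mer bucketing.
#'
#' @param params a \code{\link{polish_params}}.
#' @return List of \code{n_trials} sorted integer vectors of length \code{h}.
#' @export
draw_position_sets <- function(params) {
  stopifnot(inherits(params, "polish_params"))
  with_seed(params$seed, {
    lapply(seq_len(params$n_trials), function(i)
      sort(sample.int(params$k, params$h)))
  })
}

#' Group end-to-end matched k-mers
#'
#' Per trial, k-mers are bucketed by the h-mer extracted at that trial's
#' positions; any two k-mers sharing a bucket in at least one trial are
#' linked, and groups are the connected components of the link graph. For a
#' pair at Hamming distance \code{d <= e} the probability of being grouped
#' equals \code{grouping_probability(k, h, d, n_trials)}.
#'
#' @param kmers a \code{\link{kmer_table}}.
#' @param params a \code{\link{polish_params}} with \code{params$k} equal to
#'   the table's word length.
#' @param position_sets optional pre-drawn position subsets (from
#'   \code{\link{draw_position_sets}}).
#' @return An integer vector of group ids (1-based, dense), one per key of
#'   \code{kmers}, named by k-mer.
#' @export
find_groups <- function(kmers, params, position_sets = NULL) {
  stopifnot(inherits(kmers, "kmer_table"), inherits(params, "polish_params"))
  if (kmers$k != params$k) stop("params$k does not match the table's k")
  if (is.null(position_sets)) position_sets <- draw_position_sets(params)
  ids <- .group_kmers_cpp(kmers$kmer, position_sets, params$n_partitions)
  names(ids) <- kmers$kmer
  ids
}

#' Weighted-vote consensus of a k-mer group
#'
#' Position-wise, each member votes for its base with weight equal to its
#' count; the consensus base is the maximum-vote base (ties break to the
#' alphabetically smallest base). The consensus count is the maximum winning
#' vote over all positions.
#'
#' @param group a data frame (or list) with elements \code{kmer} and
#'   \code{count}; all words must share one length.
#' @return A list with elements \code{kmer} and \code{count}.
#' @examples
#' consensus_vote(data.frame(kmer = c("AAA", "AAC"), count = c(10, 3)))
#' @export
consensus_vote <- function(group) {
  kmer <- as.character(group$kmer)
  count <- as.numeric(group$count)
  if (length(kmer) == 0) stop("empty group")
  if (length(unique(nchar(kmer))) != 1) stop("group mixes word lengths")
  res <- .consensus_vote_cpp(kmer, count, rep(1L, length(kmer)))
  list(kmer = as.character(res$kmer[1]), count = as.numeric(res$count[1]))
}

#' Polish a k-mer table by grouped consensus voting
#'
#' Groups end-to-end matched k-mers (\code{\link{find_groups}}) and replaces
#' each group by its weighted-vote consensus k-mer
#' (\code{\link{consensus_vote}}). Consensus words from different groups that
#' collide pool by summing counts; for canonical input tables the consensus
#' keys are re-canonicalized. Partitioned execution
#' (\code{params$n_partitions > 1}) assigns trial buckets to partitions but
#' feeds one global link structure, so the output is identical for any
#' partition count.
#'
#' @param kmers a \code{\link{kmer_table}}.
#' @param params a \code{\link{polish_params}}.
#' @return A polished \code{\link{kmer_table}} with at most as many distinct
#'   keys as the input.
#' @export
polish_kmers <- function(kmers, params) {
  stopifnot(inherits(kmers, "kmer_table"), inherits(params, "polish_params"))
  if (length(kmers) == 0) return(kmers)
  ids <- find_groups(kmers, params)
  res <- .consensus_vote_cpp(kmers$kmer, kmers$count, ids)
  words <- as.character(res$kmer)
  counts <- as.numeric(res$count)
  if (kmers$canonical) words <- .canonicalize_cpp(words)
  pooled <- rowsum(counts, group = words)
  ord <- order(rownames(pooled), method = "radix")
  kmer_table(rownames(pooled)[ord], pooled[ord, 1], kmers$k,
             kmers$canonical, validate = FALSE)
}
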