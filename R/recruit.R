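#' Recruitment parameters
#'
#' Controls recovery of intermediate-frequency k-mers by similarity to the
#' highly frequent tier. A candidate must share at least one exact seed of
#' length \code{seed_len} with some highly frequent k-mer and reach a
#' match-only alignment score (longest common subsequence, see
#' \code{\link{match_score}}) of at least \code{min_score} against it.
#'
#' @param k word length of the tables to be recruited.
#' @param min_score minimum alignment score; default \code{k - 5}, i.e. up to
#'   5 unmatched bases are tolerated.
#' @param seed_len exact-seed length for the candidate filter (default 12).
#'   With at most one edit, a shared seed always exists when
#'   \code{seed_len <= floor((k - 1) / 2)} (pigeonhole).
#' @param max_rounds number of recruitment rounds for
#'   \code{\link{iterative_recruit}} (default 1).
#' @return An object of class \code{recruitment_params}.
#' @export
recruitment_params <- function(k, min_score = k - 5, seed_len = 12,
                               max_rounds = 1) {
  stopifnot_scalar(k, "k", min = 2, integer = TRUE)
  stopifnot_scalar(min_score, "min_score", min = 1, max = k, integer = TRUE)
  stopifnot_scalar(seed_len, "seed_len", min = 1, max = min_score,
                   integer = TRUE)
  stopifnot_scalar(max_rounds, "max_rounds", min = 1, integer = TRUE)
  structure(list(k = as.integer(k), min_score = as.integer(min_score),
                 seed_len = as.integer(seed_len),
                 max_rounds = as.integer(max_rounds)),
            class = "recruitment_params")
}

#' Match-only alignment score (longest common subsequence)
#'
#' The optimal gapped alignment score when a match rewards 1 and mismatches,
#' gap opens and gap extensions cost nothing equals the length of the longest
#' common subsequence: the maximum number of aligned identical bases.
#'
#' @param a,b DNA words (vectorized; recycled if one has length 1).
#' @return Integer vector of LCS lengths.
#' @examples
#' match_score("ACGTACGT", "ACGTACGT")  # 8
#' match_score("AAAA", "CCCC")          # 0
#' @export
match_score <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("words must be nonempty")
  .lcs_cpp(as.character(a), as.character(b))
}

#' Seed index over highly frequent k-mers
#'
#' @param high a \code{\link{kmer_table}} of highly frequent k-mers.
#' @param seed_len seed length.
#' @return An object of class \code{seed_index}.
#' @export
seed_index <- function(high, seed_len = 12) {
  stopifnot(inherits(high, "kmer_table"))
  structure(list(kmers = high$kmer, seed_len = as.integer(seed_len),
                 both_strands = high$canonical),
            class = "seed_index")
}

#' Does a word share an exact seed with an indexed k-mer?
#'
#' True iff some length-\code{seed_len} window of the query (in either
#' orientation when the index was built from a canonical table) occurs in
#' some indexed k-mer. An empty index matches nothing.
#'
#' @param a character vector of query words.
#' @param high_index a \code{\link{seed_index}}.
#' @return Logical vector.
#' @export
shares_seed <- function(a, high_index) {
  stopifnot(inherits(high_index, "seed_index"))
  if (length(high_index$kmers) == 0) return(rep(FALSE, length(a)))
  .shares_seed_cpp(as.character(a), high_index$kmers,
                   high_index$seed_len, high_index$both_strands)
}

#' Recruit intermediate-frequency k-mers similar to highly frequent ones
#'
#' K-mers from highly divergent repeat regions tend to have intermediate
#' frequency and high sequence identity to some highly frequent repeat k-mer.
#' This filter keeps every intermediate k-mer that shares an exact seed with
#' a highly frequent k-mer and attains \code{match_score >= min_score}
#' against it. Alignment is per k-mer, never across a concatenation of
#' k-mers, and queries from canonical tables are checked in both
#' orientations. Counts are preserved from the intermediate table.
#'
#' @param intermediate,high \code{\link{kmer_table}}s with the same \code{k}.
#' @param params a \code{\link{recruitment_params}}.
#' @return The recruited sub-table of \code{intermediate}.
#' @export
recruit_kmers <- function(intermediate, high, params) {
  stopifnot(inherits(intermediate, "kmer_table"),
            inherits(high, "kmer_table"),
            inherits(params, "recruitment_params"))
  if (intermediate$k != high$k)
    stop("intermediate and high tables disagree on k")
  if (params$k != intermediate$k)
    stop("params$k does not match the tables' k")
  if (length(intermediate) == 0 || length(high) == 0)
    return(kt_subset(intermediate, logical(0)))
  keep <- .recruit_cpp(intermediate$kmer, high$kmer, params$seed_len,
                       params$min_score,
                       intermediate$canonical || high$canonical)
  kt_subset(intermediate, keep)
}

#' Iterative recruitment
#'
#' Round 1 recruits against the highly frequent tier; each later round
#' recruits the remaining intermediate k-mers against the union of the high
#' tier and everything recruited so far, so chains of similar k-mers can be
#' pulled in. More rounds recover more diverged k-mers at the cost of more
#' false positives. The result is the recruited k-mers merged with the highly
#' frequent k-mers, ready for polishing and assembly.
#'
#' @inheritParams recruit_kmers
#' @return A \code{\link{kmer_table}}: \code{high} plus all recruited
#'   intermediate k-mers, keys sorted.
#' @export
iterative_recruit <- function(intermediate, high, params) {
  stopifnot(inherits(params, "recruitment_params"))
  remaining <- intermediate
  targets <- high
  recruited_idx <- character(0)
  for (round in seq_len(params$max_rounds)) {
    if (length(remaining) == 0) break
    got <- recruit_kmers(remaining, targets, params)
    if (length(got) == 0) break
    recruited_idx <- c(recruited_idx, got$kmer)
    remaining <- kt_subset(remaining, !(remaining$kmer %in% got$kmer))
    targets <- merge_kmer_tables(targets, got)
  }
  merge_kmer_tables(high, kt_subset(intermediate,
                                    intermediate$kmer %in% recruited_idx))
}

# union of two tables with disjoint key sets (counts kept as-is; a key
# present in both keeps the first table's count)
merge_kmer_tables <- function(a, b) {
  stopifnot(a$k == b$k)
  dup <- b$kmer %in% a$kmer
  kmer <- c(a$kmer, b$kmer[!dup])
  count <- c(a$count, b$count[!dup])
  ord <- order(kmer, method = "radix")
  kmer_table(kmer[ord], count[ord], a$k, a$canonical && b$canonical,
             validate = FALSE)
}
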