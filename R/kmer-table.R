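#' K-mer count table
#'
#' Lightweight container for a set of fixed-length DNA words and their
#' positive counts. When \code{canonical} is \code{TRUE} every key is the
#' lexicographically smaller of the word and its reverse complement, and
#' counts pool both strands.
#'
#' @param kmer character vector of DNA words, all of length \code{k}.
#' @param count numeric vector of positive counts, same length as \code{kmer}.
#' @param k word length.
#' @param canonical logical; are keys canonicalized?
#' @param validate check invariants (alphabet, lengths, positivity,
#'   canonicality). Disable only for internally constructed tables.
#' @return An object of class \code{kmer_table}: a list with elements
#'   \code{kmer}, \code{count}, \code{k}, \code{canonical}.
#' @export
kmer_table <- function(kmer, count, k, canonical = TRUE, validate = TRUE) {
  stopifnot_scalar(k, "k", min = 2, integer = TRUE)
  count <- as.numeric(count)
  if (length(kmer) != length(count))
    stop("kmer and count must have the same length")
  if (validate && length(kmer)) {
    if (any(nchar(kmer) != k)) stop("all k-mers must have length k = ", k)
    check_dna(kmer, "kmer")
    if (any(count < 1)) stop("all counts must be >= 1")
    if (anyDuplicated(kmer)) stop("duplicate k-mer keys")
    if (canonical && any(kmer != .canonicalize_cpp(kmer)))
      stop("table is declared canonical but a key exceeds its reverse complement")
  }
  structure(list(kmer = as.character(kmer), count = count,
                 k = as.integer(k), canonical = isTRUE(canonical)),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: %d distinct %d-mers (%s), total count %s\n",
              length(x$kmer), x$k,
              if (x$canonical) "canonical" else "forward-only",
              format(sum(x$count), big.mark = ",")))
  if (length(x$kmer)) {
    n <- min(6L, length(x$kmer))
    for (i in seq_len(n)) cat(sprintf("  %s  %g\n", x$kmer[i], x$count[i]))
    if (length(x$kmer) > n) cat(sprintf("  ... %d more\n", length(x$kmer) - n))
  }
  invisible(x)
}

#' @export
length.kmer_table <- function(x) length(x$kmer)

# subset by logical/integer index, preserving metadata
kt_subset <- function(x, idx) {
  kmer_table(x$kmer[idx], x$count[idx], x$k, x$canonical, validate = FALSE)
}

#' Reverse complement of DNA words
#'
#' Watson-Crick reverse complement. Vectorized; errors on non-ACGT input.
#'
#' @param seq character vector of DNA words over A/C/G/T.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")  # "ACGT"
#' reverse_complement("AAAA")  # "TTTT"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("seq must be character")
  .revcomp_cpp(seq)
}

#' Count k-mers in a set of reads
#'
#' Slides a window of length \code{k} over every read and tallies each word.
#' Windows containing a non-ACGT character (e.g. N) contribute nothing. With
#' \code{canonical = TRUE} (the default; reads come from both strands) a word
#' and its reverse complement pool under the lexicographically smaller key.
#'
#' @param reads character vector of read sequences, or a file path to a
#'   FASTA/FASTQ file (see \code{\link{read_reads}}).
#' @param k word length (default 30).
#' @param canonical pool reverse-complement words (default \code{TRUE}).
#' @return A \code{\link{kmer_table}} with keys sorted lexicographically.
#' @examples
#' count_kmers("ACGT", k = 2, canonical = FALSE)  # AC:1 CG:1 GT:1
#' count_kmers("ACGT", k = 2, canonical = TRUE)   # AC:2 CG:1
#' @export
count_kmers <- function(reads, k = 30, canonical = TRUE) {
  stopifnot_scalar(k, "k", min = 2, integer = TRUE)
  if (is.character(reads) && length(reads) >= 1 && !is.na(reads[1]) &&
      grepl("\\.(fa|fasta|fq|fastq)(\\.gz)?$", reads[1], ignore.case = TRUE))
    reads <- unlist(lapply(reads, read_reads), use.names = FALSE)
  if (!is.character(reads)) reads <- as.character(reads)
  if (length(reads) == 0) stop("reads must be nonempty")
  res <- .count_kmers_cpp(toupper(reads), as.integer(k), isTRUE(canonical))
  kmer_table(res$kmer, res$count, k, canonical, validate = FALSE)
}

#' K-mer frequency histogram
#'
#' Tallies, for each observed count value, the number of distinct k-mers with
#' that count. The histogram is the input to
#' \code{\link{estimate_base_freq}}.
#'
#' @param table a \code{\link{kmer_table}}.
#' @return A data frame with columns \code{count} (ascending) and
#'   \code{n_kmers}; \code{sum(n_kmers)} equals the number of distinct keys.
#' @export
frequency_histogram <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  if (length(table$kmer) == 0) stop("table must be nonempty")
  tab <- table(table$count)
  data.frame(count = as.numeric(names(tab)), n_kmers = as.integer(tab),
             row.names = NULL)
}

#' Estimate the base (per-copy) k-mer frequency
#'
#' The classification cutoffs are multiples of the k-mer depth of a
#' single-copy locus. For reasonably uniform coverage this depth is the mode
#' of the k-mer frequency histogram once the sequencing-error peak at very low
#' counts is excluded: bins with count below \code{min_count} are ignored and
#' the modal count among the remaining bins is returned. Supply a known read
#' depth directly to \code{\link{selection_params}} to override.
#'
#' @param hist histogram data frame from \code{\link{frequency_histogram}}.
#' @param min_count smallest count bin eligible as the mode (default 2,
#'   excluding the singleton error peak).
#' @return The modal count (ties break toward the smaller count).
#' @export
estimate_base_freq <- function(hist, min_count = 2) {
  stopifnot(is.data.frame(hist), all(c("count", "n_kmers") %in% names(hist)))
  keep <- hist[hist$count >= min_count, , drop = FALSE]
  if (nrow(keep) == 0)
    stop("no histogram bin with count >= ", min_count,
         "; supply base_freq manually")
  keep <- keep[order(keep$count), , drop = FALSE]
  keep$count[which.max(keep$n_kmers)]
}

#' Tier-selection parameters
#'
#' @param base_freq expected k-mer depth of a single-copy locus (positive).
#' @param high_multiplier highly-frequent cutoff as a multiple of
#'   \code{base_freq} (default 10): a k-mer is highly frequent when its count
#'   is at least \code{high_multiplier * base_freq}.
#' @param mid_multiplier intermediate cutoff multiple (default 3); must be
#'   smaller than \code{high_multiplier}.
#' @return An object of class \code{selection_params}.
#' @export
selection_params <- function(base_freq, high_multiplier = 10,
                             mid_multiplier = 3) {
  stopifnot_scalar(base_freq, "base_freq", min = 1e-12)
  stopifnot_scalar(high_multiplier, "high_multiplier", min = 1e-12)
  stopifnot_scalar(mid_multiplier, "mid_multiplier", min = 1e-12)
  if (mid_multiplier >= high_multiplier)
    stop("mid_multiplier must be < high_multiplier")
  structure(list(base_freq = base_freq, high_multiplier = high_multiplier,
                 mid_multiplier = mid_multiplier),
            class = "selection_params")
}

#' Classify k-mers into highly frequent and intermediate tiers
#'
#' A k-mer is \emph{highly frequent} when its count is at least
#' \code{high_multiplier * base_freq}, and of \emph{intermediate} frequency
#' when its count is at least \code{mid_multiplier * base_freq} but below the
#' high cutoff. Both lower bounds are inclusive. Remaining k-mers are
#' discarded: they are unlikely to come from repeats.
#'
#' @param table a \code{\link{kmer_table}}.
#' @param params a \code{\link{selection_params}}.
#' @return A list with \code{kmer_table} elements \code{high} and
#'   \code{intermediate} (disjoint sub-tables of \code{table}).
#' @export
classify_kmers <- function(table, params) {
  stopifnot(inherits(table, "kmer_table"), inherits(params, "selection_params"))
  hi_cut <- params$high_multiplier * params$base_freq
  mid_cut <- params$mid_multiplier * params$base_freq
  list(high = kt_subset(table, table$count >= hi_cut),
       intermediate = kt_subset(table, table$count >= mid_cut &
                                         table$count < hi_cut))
}

#' Read / write a k-mer table as TSV
#'
#' Headerless two-column TSV \code{kmer<TAB>count}, rows sorted
#' lexicographically by k-mer for reproducible diffs.
#'
#' @param table a \code{\link{kmer_table}}.
#' @param path file path.
#' @param canonical declared canonicality when reading (not re-derivable from
#'   the file).
#' @return \code{write_kmer_table} returns \code{path} invisibly;
#'   \code{read_kmer_table} returns a \code{\link{kmer_table}}.
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_table"))
  ord <- order(table$kmer, method = "radix")
  lines <- paste0(table$kmer[ord], "\t",
                  format(table$count[ord], scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_kmer_table
#' @export
read_kmer_table <- function(path, canonical = TRUE) {
  dat <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric"),
                           col.names = c("kmer", "count"))
  if (nrow(dat) == 0) stop("empty k-mer table: ", path)
  kmer_table(dat$kmer, dat$count, k = nchar(dat$kmer[1]),
             canonical = canonical, validate = FALSE)
}
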