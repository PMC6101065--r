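#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is chosen by extension (\code{.fq}/\code{.fastq} vs
#' \code{.fa}/\code{.fasta}, optionally gzipped); parsing is done by
#' \code{Biostrings::readDNAStringSet}.
#'
#' @param path file path.
#' @return Named character vector of sequences.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  x <- Biostrings::readDNAStringSet(path, format = if (fastq) "fastq" else "fasta")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_reads
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' \code{contig_set} objects get headers of the form
#' \code{rep<i> len=<L> support=<mean_support>}; named character vectors use
#' their names.
#'
#' @param x a \code{contig_set} or (named) character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "contig_set")) {
    headers <- sprintf("%s len=%d support=%.2f", x$id, nchar(x$sequence),
                       x$mean_support)
    seqs <- x$sequence
  } else {
    seqs <- as.character(x)
    headers <- if (is.null(names(x))) sprintf("seq%d", seq_along(seqs))
      else names(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", headers, "\n", seqs), con)
  invisible(path)
}

# read a contig FASTA written by write_fasta, restoring mean_support
read_contig_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  supp <- suppressWarnings(as.numeric(sub(".*support=([0-9.eE+-]+).*", "\\1", hdr)))
  supp[is.na(supp)] <- 1
  contig_set(as.character(x), supp, id = id)
}

#' Write simulated reads as FASTQ
#'
#' Plain four-line records with uniform quality 'I'; bit-identical output
#' for identical input.
#'
#' @param reads named character vector (e.g. from
#'   \code{\link{simulate_reads}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  nm <- names(reads)
  if (is.null(nm)) nm <- sprintf("read%d", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", nm, "\n", as.character(reads), "\n+\n", qual), con)
  invisible(path)
}
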