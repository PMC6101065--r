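#' Planted repeat family specification
#'
#' Describes one repeat family to plant in a simulated genome: a random
#' consensus of \code{consensus_len} bases with \code{copy_number}
#' independently mutated copies. Each copy diverges from the consensus by
#' i.i.d. per-base substitutions (rate \code{sub_rate}) and indels (rate
#' \code{indel_rate}, length uniform on 1..\code{indel_max_len}, insertions
#' and deletions equally likely).
#'
#' @param consensus_len consensus length in bp (>= 50).
#' @param copy_number number of planted copies (>= 1).
#' @param sub_rate per-base substitution probability.
#' @param indel_rate per-base indel probability.
#' @param indel_max_len maximum indel length (default 3).
#' @return An object of class \code{repeat_sim_spec}.
#' @export
repeat_sim_spec <- function(consensus_len, copy_number, sub_rate = 0,
                            indel_rate = 0, indel_max_len = 3) {
  stopifnot_scalar(consensus_len, "consensus_len", min = 50, integer = TRUE)
  stopifnot_scalar(copy_number, "copy_number", min = 1, integer = TRUE)
  stopifnot_scalar(sub_rate, "sub_rate", min = 0, max = 0.5)
  stopifnot_scalar(indel_rate, "indel_rate", min = 0, max = 0.5)
  stopifnot_scalar(indel_max_len, "indel_max_len", min = 1, integer = TRUE)
  if (sub_rate + indel_rate >= 0.5)
    stop("sub_rate + indel_rate must be < 0.5")
  structure(list(consensus_len = as.integer(consensus_len),
                 copy_number = as.integer(copy_number),
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_max_len = as.integer(indel_max_len)),
            class = "repeat_sim_spec")
}

#' Read simulation specification
#'
#' @param read_len read length in bp.
#' @param depth mean genome coverage.
#' @param error_rate per-base substitution sequencing error (< 0.1).
#' @param seed RNG seed.
#' @return An object of class \code{read_sim_spec}.
#' @export
read_sim_spec <- function(read_len, depth, error_rate = 0, seed = 1) {
  stopifnot_scalar(read_len, "read_len", min = 1, integer = TRUE)
  stopifnot_scalar(depth, "depth", min = 1e-9)
  stopifnot_scalar(error_rate, "error_rate", min = 0, max = 0.1 - 1e-12)
  stopifnot_scalar(seed, "seed", integer = TRUE)
  structure(list(read_len = as.integer(read_len), depth = depth,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "read_sim_spec")
}

# mutate one copy of a consensus: i.i.d. substitutions then indels
mutate_copy <- function(consensus, sub_rate, indel_rate, indel_max_len) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  n <- length(chars)
  subs <- which(runif(n) < sub_rate)
  if (length(subs)) {
    for (i in subs)
      chars[i] <- sample(setdiff(bases, chars[i]), 1)
  }
  ind <- which(runif(n) < indel_rate)
  if (length(ind)) {
    pieces <- as.list(chars)
    for (i in ind) {
      len <- sample.int(indel_max_len, 1)
      if (runif(1) < 0.5) {
        pieces[[i]] <- c(chars[i],
                         sample(bases, len, replace = TRUE))  # insertion after i
      } else {
        drop <- seq(i, min(n, i + len - 1))
        for (d in drop) pieces[[d]] <- character(0)
      }
    }
    chars <- unlist(pieces)
  }
  paste(chars, collapse = "")
}

#' Simulate a genome with planted repeat families
#'
#' Generates a uniform-random background sequence and plants each family's
#' mutated copies at non-overlapping, non-nested uniform positions (the copy
#' replaces the background bases in place). Each copy lands on a random
#' strand. The returned truth records the consensus sequences and the
#' 0-based half-open interval of every placed copy.
#'
#' @param bg_len background genome length in bp; must exceed the total
#'   planted length.
#' @param specs a \code{\link{repeat_sim_spec}} or list of them.
#' @param seed RNG seed; fixed seed gives a bit-identical genome.
#' @return A list of class \code{sim_genome}: \code{genome} (DNA string),
#'   \code{consensus} (named character vector, one per family), and
#'   \code{copies} (data frame \code{family}, \code{copy}, \code{start},
#'   \code{end}, \code{strand}).
#' @export
simulate_genome <- function(bg_len, specs, seed = 1) {
  stopifnot_scalar(bg_len, "bg_len", min = 1, integer = TRUE)
  if (inherits(specs, "repeat_sim_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "repeat_sim_spec")))
  with_seed(seed, {
    genome <- random_dna_string(bg_len)
    consensus <- character(0)
    rows <- list()
    taken_start <- integer(0)
    taken_end <- integer(0)
    for (fi in seq_along(specs)) {
      sp <- specs[[fi]]
      fam <- sprintf("family%d", fi)
      cons <- random_dna_string(sp$consensus_len)
      consensus[fam] <- cons
      for (ci in seq_len(sp$copy_number)) {
        copy <- mutate_copy(cons, sp$sub_rate, sp$indel_rate, sp$indel_max_len)
        clen <- nchar(copy)
        if (clen > bg_len)
          stop("background too short for a planted copy")
        placed <- FALSE
        for (try in seq_len(1000L)) {
          s <- sample.int(bg_len - clen + 1L, 1L)   # 1-based start
          e <- s + clen - 1L
          if (any(s <= taken_end & e >= taken_start)) next
          strand <- if (runif(1) < 0.5) "+" else "-"
          ins <- if (strand == "+") copy else reverse_complement(copy)
          substr(genome, s, e) <- ins
          taken_start <- c(taken_start, s)
          taken_end <- c(taken_end, e)
          rows[[length(rows) + 1L]] <-
            data.frame(family = fam, copy = ci, start = s - 1L, end = e,
                       strand = strand, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place a repeat copy without overlap; ",
               "background too short for the planted families")
      }
    }
    copies <- if (length(rows)) do.call(rbind, rows) else
      data.frame(family = character(0), copy = integer(0),
                 start = integer(0), end = integer(0),
                 strand = character(0))
    structure(list(genome = genome, consensus = consensus, copies = copies),
              class = "sim_genome")
  })
}

#' Simulate uniform-coverage short reads
#'
#' Draws \code{round(depth * genome_length / read_len)} reads with uniform
#' start positions and random strand, then applies i.i.d. per-base
#' substitution errors at \code{error_rate}. Deterministic for a fixed seed.
#'
#' @param genome a DNA string or a \code{sim_genome}.
#' @param spec a \code{\link{read_sim_spec}}.
#' @return Named character vector of read sequences (class \code{sim_reads}).
#' @export
simulate_reads <- function(genome, spec) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  stopifnot(inherits(spec, "read_sim_spec"))
  glen <- nchar(genome)
  if (glen < spec$read_len) stop("genome shorter than read_len")
  n_reads <- round(spec$depth * glen / spec$read_len)
  with_seed(spec$seed, {
    starts <- sample.int(glen - spec$read_len + 1L, n_reads, replace = TRUE)
    reads <- substring(genome, starts, starts + spec$read_len - 1L)
    rc <- runif(n_reads) < 0.5
    if (any(rc)) reads[rc] <- reverse_complement(reads[rc])
    if (spec$error_rate > 0) {
      bases <- c("A", "C", "G", "T")
      flat <- which(runif(n_reads * spec$read_len) < spec$error_rate)
      if (length(flat)) {
        ri <- (flat - 1L) %/% spec$read_len + 1L
        pos <- (flat - 1L) %% spec$read_len + 1L
        subs <- sample(bases, length(flat), replace = TRUE)
        for (idx in seq_along(flat)) {
          old <- substr(reads[ri[idx]], pos[idx], pos[idx])
          new <- subs[idx]
          if (new == old) new <- bases[(match(old, bases) %% 4L) + 1L]
          substr(reads[ri[idx]], pos[idx], pos[idx]) <- new
        }
      }
    }
    names(reads) <- sprintf("read%d", seq_len(n_reads))
    class(reads) <- c("sim_reads", "character")
    reads
  })
}
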