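all_kmers_of <- function(s, k) {
  vapply(seq_len(nchar(s) - k + 1), function(i) substr(s, i, i + k - 1),
         character(1))
}

test_that("a linear path of k-mers assembles into the original string", {
  words <- all_kmers_of("ACGGTCAT", 5)
  kt <- as_table(words, rep(3, length(words)))
  out <- assemble_contigs(kt, assembly_k = 5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, "ACGGTCAT")
  expect_equal(out$mean_support, 3)
})

test_that("disconnected k-mer sets give one contig per component", {
  s1 <- "ACGGTCATAA"
  s2 <- "TTCTCCTCTT"   # shares no 4-mer with s1
  w1 <- all_kmers_of(s1, 5)
  w2 <- all_kmers_of(s2, 5)
  expect_length(intersect(all_kmers_of(s1, 4), all_kmers_of(s2, 4)), 0)
  kt <- as_table(c(w1, w2), rep(2, length(c(w1, w2))))
  out <- assemble_contigs(kt, assembly_k = 5)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$sequence, c(s1, s2))
})

test_that("unique internal words guarantee full-length unitig recovery", {
  set.seed(77)
  for (rep in 1:6) {
    repeat {
      s <- r_dna(300)
      internal <- all_kmers_of(s, 24)
      both <- c(internal, r_revcomp(internal))
      if (!anyDuplicated(both)) break
    }
    words <- all_kmers_of(s, 25)
    canon <- pmin(words, r_revcomp(words))
    kt <- as_table(unique(canon), rep(2, length(unique(canon))),
                   canonical = TRUE)
    out <- assemble_contigs(kt, assembly_k = 25)
    expect_true(s %in% out$sequence | r_revcomp(s) %in% out$sequence)
  }
})

test_that("contig set does not depend on k-mer input order", {
  set.seed(88)
  s <- r_dna(200)
  words <- unique(all_kmers_of(s, 21))
  kt1 <- as_table(words, rep(2, length(words)))
  shuffled <- sample(seq_along(words))
  kt2 <- as_table(words[shuffled], rep(2, length(words)))
  o1 <- assemble_contigs(kt1, 20)
  o2 <- assemble_contigs(kt2, 20)
  expect_equal(o1$sequence, o2$sequence)
})

test_that("best_overlap finds the longest qualifying suffix-prefix match", {
  p <- merge_params(min_overlap = 4, max_overlap_mismatch = 0,
                    allow_revcomp = FALSE, min_output_len = 1)
  ov <- best_overlap("AAAACCCC", "CCCCGGGG", p)
  expect_equal(ov$orientation, "forward")
  expect_equal(ov$overlap_len, 4L)
  expect_equal(ov$mismatches, 0L)
  expect_null(best_overlap("AAAA", "GGGG", p))
  # reverse-complement orientation is found when allowed
  p2 <- merge_params(min_overlap = 4, max_overlap_mismatch = 0,
                     min_output_len = 1)
  ov2 <- best_overlap("AAAACCCC", "CCCCGGGG", p2)   # rc(b) = CCCCGGGG
  expect_equal(ov2$orientation, "forward")
  ov3 <- best_overlap("AAAACCCC", "TTTTGGGG", p2)   # rc = CCCCAAAA
  expect_equal(ov3$orientation, "revcomp")
  expect_equal(ov3$overlap_len, 4L)
  expect_null(best_overlap("AAAACCCC", "GTGTGTGT", p2))
  ov4 <- best_overlap("AAAACCCC", "GGGGTTTT", p2)   # rc = AAAACCCC: contained
  expect_equal(ov4$orientation, "revcomp")
  expect_equal(ov4$overlap_len, 8L)
})

test_that("best_overlap agrees with an exhaustive scan", {
  set.seed(99)
  brute <- function(a, b, minov, maxmm, allow_rc) {
    best <- NULL
    cands <- list(c("forward", b))
    if (allow_rc) cands <- c(cands, list(c("revcomp", r_revcomp(b))))
    for (cand in cands) {
      lmax <- min(nchar(a), nchar(cand[2]))
      if (lmax < minov) next
      for (L in seq(lmax, minov)) {
        sa <- strsplit(substr(a, nchar(a) - L + 1, nchar(a)), "")[[1]]
        sb <- strsplit(substr(cand[2], 1, L), "")[[1]]
        mm <- sum(sa != sb)
        if (mm <= maxmm) {
          if (is.null(best) || L > best$overlap_len ||
              (L == best$overlap_len && mm < best$mismatches))
            best <- list(orientation = cand[1], overlap_len = L,
                         mismatches = mm)
          break
        }
      }
    }
    best
  }
  for (i in 1:40) {
    a <- r_dna(sample(15:40, 1))
    b <- if (i %% 2 == 0) r_dna(sample(15:40, 1)) else
      paste0(substr(a, nchar(a) - 12, nchar(a)), r_dna(10))
    p <- merge_params(min_overlap = 5, max_overlap_mismatch = 1,
                      min_output_len = 1)
    got <- best_overlap(a, b, p)
    want <- brute(a, b, 5, 1, TRUE)
    if (is.null(want)) expect_null(got)
    else expect_equal(got[c("orientation", "overlap_len", "mismatches")],
                      want)
  }
})

test_that("merge_contigs chains overlapping fragments back together", {
  set.seed(111)
  s <- r_dna(300)
  cuts <- c(1, 80, 160, 230)
  frags <- vapply(cuts, function(c0) substr(s, c0, min(300, c0 + 95)),
                  character(1))
  p <- merge_params(min_overlap = 10, max_overlap_mismatch = 0,
                    min_output_len = 50)
  out <- merge_contigs(frags, p)
  expect_equal(nrow(out), 1L)
  expect_true(out$sequence %in% c(s, r_revcomp(s)))
  # mutually non-overlapping contigs are a fixed point
  p_short <- merge_params(min_overlap = 10, max_overlap_mismatch = 0,
                          min_output_len = 30)
  a <- "AAAAAAAAAAAAAAAAAAAACCCCCCCCCCCCCCCCCCCC"
  b <- "GTGTGTGTGTGTGTGTGTGTGTGTGTGTGTGTGTGTGTGT"
  out2 <- merge_contigs(c(a, b), p_short)
  expect_setequal(out2$sequence, c(a, b))
  # idempotence on own output
  out3 <- merge_contigs(out2$sequence, p_short)
  expect_setequal(out3$sequence, out2$sequence)
})

test_that("five fragments with 15-30 bp overlaps reconstruct a 600 bp string", {
  set.seed(222)
  for (rep in 1:3) {
    s <- r_dna(600)
    # cut points spaced far apart so only adjacent fragments overlap
    bounds <- c(140, 250, 360, 470) + sample(-20:20, 4, replace = TRUE)
    ovl <- sample(15:30, 4, replace = TRUE)
    starts <- c(1, bounds - ovl + 1)
    ends <- c(bounds, 600)
    frags <- vapply(seq_len(5), function(i) substr(s, starts[i], ends[i]),
                    character(1))
    p <- merge_params(min_overlap = 10, max_overlap_mismatch = 0,
                      min_output_len = 100)
    out <- merge_contigs(frags, p)
    expect_equal(nrow(out), 1L)
    expect_true(out$sequence %in% c(s, r_revcomp(s)))
  }
})
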