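test_that("reverse_complement matches Watson-Crick pairing and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAA"), "TTTT")
  expect_equal(reverse_complement(c("AC", "GT")), c("GT", "AC"))
  expect_error(reverse_complement("ACGN"), "alphabet")
  set.seed(11)
  for (i in 1:20) {
    x <- r_dna(30)
    expect_equal(reverse_complement(reverse_complement(x)), x)
    expect_equal(reverse_complement(x), r_revcomp(x))
  }
})

test_that("count_kmers enumerates windows and pools canonical pairs", {
  kt <- count_kmers("ACGT", k = 2, canonical = FALSE)
  expect_equal(kt$kmer, c("AC", "CG", "GT"))
  expect_equal(kt$count, c(1, 1, 1))
  kt <- count_kmers("ACGT", k = 2, canonical = TRUE)
  expect_equal(kt$kmer, c("AC", "CG"))
  expect_equal(kt$count, c(2, 1))
  expect_error(count_kmers(c("ACG", "GTA"), k = 5), "larger than every read")
})

test_that("count_kmers equals the naive sliding-window oracle", {
  set.seed(42)
  for (rep in 1:12) {
    len <- sample(50:400, 1)
    reads <- replicate(sample(1:4, 1), r_dna(len))
    for (canonical in c(FALSE, TRUE)) {
      kt <- count_kmers(reads, k = 21, canonical = canonical)
      oracle <- oracle_count_kmers(reads, 21, canonical)
      expect_equal(kt$kmer, names(oracle))
      expect_equal(kt$count, as.numeric(oracle))
    }
  }
  # a full-length check on a 1 kb string
  s <- r_dna(1000)
  kt <- count_kmers(s, k = 21, canonical = TRUE)
  oracle <- oracle_count_kmers(s, 21, TRUE)
  expect_equal(kt$kmer, names(oracle))
  expect_equal(kt$count, as.numeric(oracle))
})

test_that("windows spanning non-ACGT characters are skipped", {
  kt <- count_kmers("ACGNTGCA", k = 3, canonical = FALSE)
  expect_equal(kt$kmer, c("ACG", "GCA", "TGC"))  # CGN, GNT, NTG skipped
  expect_equal(sum(kt$count), 3)
  # read of only Ns contributes nothing but other reads still count
  kt2 <- count_kmers(c("NNNNN", "ACGTA"), k = 4, canonical = FALSE)
  expect_equal(sum(kt2$count), 2)
})

test_that("canonical counts are the pooled forward counts of both strands", {
  set.seed(7)
  reads <- replicate(5, r_dna(200))
  fwd <- count_kmers(reads, k = 9, canonical = FALSE)
  can <- count_kmers(reads, k = 9, canonical = TRUE)
  fwd_counts <- stats::setNames(fwd$count, fwd$kmer)
  for (i in seq_along(can$kmer)) {
    w <- can$kmer[i]
    rc <- r_revcomp(w)
    expected <- sum(fwd_counts[w], fwd_counts[rc], na.rm = TRUE)
    if (w == rc) expected <- unname(fwd_counts[w])
    expect_equal(can$count[i], unname(expected))
  }
})

test_that("frequency_histogram tallies distinct k-mers per count", {
  kt <- as_table(c("AC", "CG"), c(2, 1))
  h <- frequency_histogram(kt)
  expect_equal(h$count, c(1, 2))
  expect_equal(h$n_kmers, c(1, 1))
  set.seed(5)
  kt2 <- count_kmers(replicate(4, r_dna(150)), k = 7)
  h2 <- frequency_histogram(kt2)
  expect_equal(sum(h2$n_kmers), length(kt2$kmer))
  for (i in seq_len(nrow(h2)))
    expect_equal(h2$n_kmers[i], sum(kt2$count == h2$count[i]))
})

test_that("estimate_base_freq returns the modal count above the error bin", {
  h <- data.frame(count = c(1, 20, 21), n_kmers = c(10000, 500, 480))
  expect_equal(estimate_base_freq(h), 20)
  expect_equal(estimate_base_freq(data.frame(count = 7, n_kmers = 42)), 7)
  expect_error(estimate_base_freq(data.frame(count = 1, n_kmers = 10)),
               "base_freq")
})

test_that("base-frequency estimate tracks known simulated depth", {
  # repeat-free genome at uniform depth 20: k-mer depth for k = 21 and
  # 100 bp reads is 20 * 80 / 100 = 16; the estimate must land near it
  g <- simulate_genome(100000, list(), seed = 3)
  rd <- simulate_reads(g, read_sim_spec(read_len = 100, depth = 20,
                                        error_rate = 0, seed = 4))
  kt <- count_kmers(as.character(rd), k = 21)
  est <- estimate_base_freq(frequency_histogram(kt))
  expect_gte(est, 15)
  expect_lte(est, 25)
})

test_that("classify_kmers applies inclusive lower bounds and partitions", {
  p <- selection_params(base_freq = 10)
  kt <- as_table(c("AAAA", "CCCC", "GGGG", "TTTT"), c(100, 30, 29, 5))
  tiers <- classify_kmers(kt, p)
  expect_equal(tiers$high$kmer, "AAAA")          # 100 >= 10 * 10, inclusive
  expect_equal(tiers$intermediate$kmer, "CCCC")  # 30 >= 3 * 10; 29 discarded
  set.seed(9)
  kt2 <- count_kmers(replicate(6, r_dna(120)), k = 5)
  kt2$count <- kt2$count * sample(1:40, length(kt2$kmer), replace = TRUE)
  tiers2 <- classify_kmers(kt2, selection_params(2, 10, 3))
  expect_equal(tiers2$high$kmer, kt2$kmer[kt2$count >= 20])
  expect_equal(tiers2$intermediate$kmer,
               kt2$kmer[kt2$count >= 6 & kt2$count < 20])
  expect_length(intersect(tiers2$high$kmer, tiers2$intermediate$kmer), 0)
})

test_that("k-mer tables round-trip through sorted TSV", {
  set.seed(13)
  kt <- count_kmers(replicate(3, r_dna(100)), k = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kmer_table(kt, path)
  back <- read_kmer_table(path)
  expect_equal(back$kmer, kt$kmer)
  expect_equal(back$count, kt$count)
  expect_equal(back$k, kt$k)
})
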