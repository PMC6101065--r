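test_that("grouping_probability evaluates the closed form exactly", {
  expect_equal(grouping_probability(30, 15, e = 0, n = 1), 1.0)
  expect_equal(grouping_probability(25, 10, e = 0, n = 7), 1.0)
  expect_equal(grouping_probability(30, 30, e = 1, n = 5), 0.0)
  # C(29,15)/C(30,15) = 15/30 = 1/2
  expect_equal(grouping_probability(30, 15, e = 1, n = 10), 1 - 0.5^10)
  # independent evaluation through R's choose()
  for (k in c(20, 30, 40)) for (h in c(5, 15)) for (e in 0:3) for (n in c(1, 8)) {
    ratio <- if (h > k - e) 0 else choose(k - e, h) / choose(k, h)
    expect_equal(grouping_probability(k, h, e, n), 1 - (1 - ratio)^n)
  }
  expect_error(grouping_probability(30, 31, 1, 5), "h")
  expect_error(grouping_probability(30, 15, -1, 5), "e")
  expect_error(grouping_probability(30, 15, 1, 0), "n")
})

test_that("grouping_probability is monotone in n and decreasing in e", {
  grid_n <- vapply(1:12, function(n) grouping_probability(30, 15, 1, n),
                   numeric(1))
  expect_true(all(diff(grid_n) >= 0))
  grid_e <- vapply(0:5, function(e) grouping_probability(30, 15, e, 6),
                   numeric(1))
  expect_true(all(diff(grid_e) <= 0))
})

test_that("position draws are deterministic, sized h, and uniform", {
  p <- polish_params(k = 30, h = 15, n_trials = 10, seed = 99)
  sets1 <- draw_position_sets(p)
  sets2 <- draw_position_sets(p)
  expect_identical(sets1, sets2)
  expect_length(sets1, 10)
  for (s in sets1) {
    expect_length(s, 15)
    expect_length(unique(s), 15)
    expect_true(all(s >= 1 & s <= 30))
  }
  full <- draw_position_sets(polish_params(k = 12, h = 12, n_trials = 3))
  for (s in full) expect_equal(s, 1:12)
  # uniformity: 10,000 single-position draws, k = 10
  k <- 10
  draws <- unlist(draw_position_sets(
    polish_params(k = k, h = 1, n_trials = 10000, seed = 5)))
  freq <- tabulate(draws, k) / 10000
  tol <- 3 * sqrt((1 / k) * (1 - 1 / k) / 10000)
  expect_true(all(abs(freq - 1 / k) <= tol))
})

test_that("find_groups links bucket-sharing k-mers into components", {
  # words differing at every position can never share an h-mer
  w <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG")
  p <- polish_params(k = 8, h = 3, n_trials = 20, seed = 1)
  ids <- find_groups(as_table(w, c(5, 5, 5)), p)
  expect_length(unique(ids), 3)
  # identical at all but one position: grouped whenever a trial avoids it
  pair <- c("AAAAAAAA", "AAAACAAA")
  p2 <- polish_params(k = 8, h = 2, n_trials = 50, seed = 2)
  ids2 <- find_groups(as_table(pair, c(5, 5)), p2)
  expect_equal(unname(ids2[1]), unname(ids2[2]))
})

test_that("pair grouping frequency matches the closed form (Monte Carlo)", {
  k <- 30; h <- 15; n <- 10
  n_rep <- 2000
  set.seed(123)
  grouped <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    a <- r_dna(k)
    b <- substitute_at(a, sample(k, 1))
    p <- polish_params(k, h, n_trials = n, seed = r)
    ids <- find_groups(as_table(c(a, b), c(1, 1)), p)
    grouped[r] <- ids[1] == ids[2]
  }
  p_expected <- grouping_probability(k, h, 1, n)
  tol <- 3 * sqrt(p_expected * (1 - p_expected) / n_rep)
  expect_lt(abs(mean(grouped) - p_expected), max(tol, 0.005))
})

test_that("consensus_vote applies weighted voting with lexicographic ties", {
  expect_equal(consensus_vote(data.frame(kmer = "ACG", count = 5)),
               list(kmer = "ACG", count = 5))
  # per-position winning votes (13, 13, 10); final count is the max, 13
  expect_equal(consensus_vote(data.frame(kmer = c("AAA", "AAC"),
                                         count = c(10, 3))),
               list(kmer = "AAA", count = 13))
  expect_equal(consensus_vote(data.frame(kmer = c("AT", "TA"),
                                         count = c(2, 2))),
               list(kmer = "AA", count = 2))
  expect_error(consensus_vote(data.frame(kmer = character(0),
                                         count = numeric(0))), "empty")
})

test_that("polish leaves mutually dissimilar k-mers untouched", {
  w <- c("AAAAAAAAAA", "CCCCCCCCCC", "GTGTGTGTGT")
  kt <- as_table(w, c(7, 8, 9))
  out <- polish_kmers(kt, polish_params(k = 10, h = 4, n_trials = 30, seed = 3))
  expect_setequal(out$kmer, w)
  expect_equal(out$count[match(w, out$kmer)], c(7, 8, 9))
})

test_that("polish collapses single-base perturbations onto the backbone", {
  set.seed(17)
  k <- 30
  center <- r_dna(k)
  perturbed <- vapply(sample(k, 10), function(p) substitute_at(center, p),
                      character(1))
  perturbed <- setdiff(unique(perturbed), center)
  kt <- as_table(c(center, perturbed), c(300, rep(3, length(perturbed))))
  out <- polish_kmers(kt, polish_params(k, h = 15, n_trials = 20, seed = 8))
  expect_equal(out$kmer, center)
  expect_equal(length(out$kmer), 1L)
})

test_that("polish output is invariant to partitioning and never grows", {
  set.seed(29)
  k <- 24
  base <- replicate(12, r_dna(k))
  words <- unique(c(base, vapply(base, function(b)
    substitute_at(b, sample(k, 1)), character(1))))
  counts <- sample(1:100, length(words), replace = TRUE)
  ref <- NULL
  for (np in c(1, 2, 8)) {
    kt <- as_table(words, counts)
    out <- polish_kmers(kt, polish_params(k, h = 12, n_trials = 15, seed = 4,
                                          n_partitions = np))
    if (is.null(ref)) ref <- out else expect_identical(out, ref)
  }
  expect_lte(length(ref$kmer), length(words))
  # repeated runs with one seed are identical
  kt <- as_table(words, counts)
  again <- polish_kmers(kt, polish_params(k, h = 12, n_trials = 15, seed = 4))
  expect_identical(again, ref)
})
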