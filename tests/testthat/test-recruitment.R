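test_that("match_score equals the LCS dynamic-programming oracle", {
  x <- r_dna(30)
  expect_equal(match_score(x, x), 30L)
  expect_equal(match_score("AAAA", "CCCC"), 0L)
  set.seed(21)
  for (i in 1:30) {
    a <- r_dna(30); b <- r_dna(30)
    expect_equal(match_score(a, b), oracle_lcs(a, b))
  }
})

test_that("shares_seed agrees with a brute-force window scan", {
  high <- as_table(c("ACGTACGTACGTACG", "TTTTTTTTTTTTTTT"), c(5, 5))
  idx <- seed_index(high, seed_len = 6)
  expect_true(shares_seed("ACGTACGTACGTACG", idx))        # indexed word itself
  expect_false(shares_seed("AAAAAAAAAAAAAAA", idx))
  empty <- seed_index(kmer_table(character(0), numeric(0), k = 15,
                                 validate = FALSE), 6)
  expect_false(any(shares_seed(c("ACGTAC"), empty)))
  set.seed(31)
  targets <- replicate(8, r_dna(15))
  idx2 <- seed_index(as_table(targets, rep(1, 8), canonical = FALSE), 5)
  for (i in 1:25) {
    q <- r_dna(15)
    brute <- any(vapply(targets, function(t) {
      any(vapply(1:(15 - 5 + 1), function(s)
        grepl(substr(q, s, s + 4), t, fixed = TRUE), logical(1)))
    }, logical(1)))
    expect_equal(unname(shares_seed(q, idx2)), brute)
  }
})

test_that("recruitment keeps similar k-mers and drops diverged ones", {
  set.seed(41)
  k <- 30
  params <- recruitment_params(k)      # min_score = 25, seed_len = 12
  # search for a word whose 6-substitution variant regains nothing via gaps
  repeat {
    high_word <- r_dna(k)
    six_sub <- substitute_at(high_word, c(2, 7, 12, 17, 22, 27))
    if (oracle_lcs(six_sub, high_word) == 24L) break
  }
  high <- as_table(high_word, 300)
  one_sub <- substitute_at(high_word, 15)
  expect_equal(oracle_lcs(one_sub, high_word), 29L)
  inter <- as_table(c(high_word, one_sub, six_sub), c(50, 50, 50))
  got <- recruit_kmers(inter, high, params)
  expect_true(high_word %in% got$kmer)          # identical: score k
  expect_true(one_sub %in% got$kmer)            # score 29 >= 25
  expect_false(six_sub %in% got$kmer)           # score 24 < 25
  expect_equal(got$count, rep(50, 2))           # counts preserved
})

test_that("recruited set equals the seed-restricted all-pairs LCS brute force", {
  set.seed(51)
  k <- 20
  for (rep in 1:5) {
    high_words <- unique(replicate(6, r_dna(k)))
    base <- sample(high_words, 10, replace = TRUE)
    inter_words <- unique(vapply(seq_along(base), function(i)
      substitute_at(base[i], sample(k, sample(0:8, 1))), character(1)))
    inter_words <- setdiff(inter_words, high_words)
    high <- as_table(high_words, rep(100, length(high_words)),
                     canonical = FALSE)
    inter <- as_table(inter_words, seq_along(inter_words) + 10,
                      canonical = FALSE)
    params <- recruitment_params(k, min_score = k - 4, seed_len = 6)
    got <- recruit_kmers(inter, high, params)
    brute <- vapply(inter_words, function(w) {
      any(vapply(high_words, function(t) {
        seeded <- any(vapply(1:(k - 6 + 1), function(s)
          grepl(substr(w, s, s + 5), t, fixed = TRUE), logical(1)))
        seeded && oracle_lcs(w, t) >= k - 4
      }, logical(1)))
    }, logical(1))
    expect_equal(got$kmer, inter_words[brute])
    # filter contract: recruited is a sub-table with unchanged counts
    expect_true(all(got$kmer %in% inter$kmer))
    expect_equal(got$count, inter$count[match(got$kmer, inter$kmer)])
  }
})

test_that("iterative recruitment pulls in chains and is monotone in rounds", {
  set.seed(61)
  k <- 30
  # w1 near the high k-mer; w2 near w1 but too diverged from high directly.
  # substitutions are clustered at the ends so a shared 12-mer seed survives
  repeat {
    h <- r_dna(k)
    w1 <- substitute_at(h, 1:4)
    w2 <- substitute_at(w1, 27:30)
    if (oracle_lcs(w1, h) >= k - 5 && oracle_lcs(w2, w1) >= k - 5 &&
        oracle_lcs(w2, h) < k - 5) break
  }
  high <- as_table(h, 300)
  inter <- as_table(c(w1, w2), c(40, 40))
  one <- iterative_recruit(inter, high, recruitment_params(k, max_rounds = 1))
  two <- iterative_recruit(inter, high, recruitment_params(k, max_rounds = 2))
  expect_true(w1 %in% one$kmer)
  expect_false(w2 %in% one$kmer)
  expect_true(all(c(w1, w2) %in% two$kmer))
  expect_true(all(one$kmer %in% two$kmer))      # monotone in rounds
  # one round is recruit_kmers merged with high
  direct <- recruit_kmers(inter, high, recruitment_params(k))
  expect_setequal(one$kmer, c(high$kmer, direct$kmer))
})

test_that("lowering min_score never shrinks the recruited set", {
  set.seed(71)
  k <- 20
  high <- as_table(unique(replicate(5, r_dna(k))), rep(100, 5))
  words <- unique(replicate(30, substitute_at(r_dna(k), sample(k, 2))))
  inter <- as_table(words, rep(10, length(words)))
  prev <- character(0)
  for (ms in c(k, k - 3, k - 6, k - 9)) {
    got <- recruit_kmers(inter, high,
                         recruitment_params(k, min_score = ms, seed_len = 5))
    expect_true(all(prev %in% got$kmer))
    prev <- got$kmer
  }
})
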