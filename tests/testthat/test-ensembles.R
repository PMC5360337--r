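test_that("random sequences are uniform i.i.d. draws", {
  expect_error(random_sequence(17, 1), "alphabet_size")
  expect_error(random_sequence(0, 4), "length")
  s1 <- random_sequence(17, 4, rng_seed = 1)
  s2 <- random_sequence(17, 4, rng_seed = 2)
  expect_false(identical(s1, s2))
  expect_identical(s1, random_sequence(17, 4, rng_seed = 1))
  expect_true(all(random_sequence(17, 2, rng_seed = 5) %in% 1:2))
  # accidental match probability of independent draws ~ 1/4 (binomial check)
  set.seed(99)
  n <- 1e5
  hits <- sum(random_sequence(n, 4) == random_sequence(n, 4))
  se <- sqrt(n * 0.25 * 0.75)
  expect_lt(abs(hits - n / 4), 3 * se)
})

test_that("off-target construction yields exactly N central matches (round trip)", {
  target <- random_sequence(17, 4, rng_seed = 10)
  for (N in 0:17) {
    for (seed in 1:40) {
      pp <- offtarget_with_N_matches(target, N, rng_seed = seed)
      expect_identical(central_run_length(pp), as.integer(N))
      expect_identical(brute_central_run(pp), as.integer(N))
    }
  }
  expect_error(offtarget_with_N_matches(target, 18), "N must")
  expect_identical(offtarget_with_N_matches(target, 17)$seq_b, target)
  # N = 0 forces the central mismatch
  pp0 <- offtarget_with_N_matches(target, 0, rng_seed = 1)
  expect_false(pp0$seq_b[9] == target[9])
})

test_that("accidental matches outside the run occur at rate q", {
  target <- random_sequence(17, 4, rng_seed = 20)
  # N = 6 run spans sites 7..12; sites 6 and 13 are forced mismatches;
  # the 9 remaining sites match independently with probability q
  n_free <- 9
  q <- 1 / 4
  set.seed(21)
  hits <- vapply(1:2000, function(i) {
    pp <- offtarget_with_N_matches(target, 6)
    free <- setdiff(1:17, 6:13)
    sum(pp$seq_b[free] == target[free])
  }, numeric(1))
  se <- sqrt(n_free * q * (1 - q) / 2000)
  expect_lt(abs(mean(hits) - n_free * q), 3 * se)
})

test_that("forced central mismatches reduce the contact energy by ~ M*epsilon", {
  target <- random_sequence(17, 4, rng_seed = 30)
  expect_identical(target_with_M_central_mismatches(target, 0)$seq_b, target)
  p1 <- target_with_M_central_mismatches(target, 1, rng_seed = 1)
  expect_identical(sum(p1$seq_b != target), 1L)
  expect_false(p1$seq_b[9] == target[9])
  # short-range limit: losing the central 3 matches costs exactly 3 epsilon
  p <- model_params(decay_length_lambda = 1e-4, alphabet_size = 1000L)
  tgt <- seq_len(17)   # all-distinct symbols: no accidental off-diagonal matches
  u_full <- energy_profile(site_pairing(tgt, tgt), p)[1]
  p3 <- target_with_M_central_mismatches(tgt, 3, rng_seed = 2,
                                         alphabet_size = 1000L)
  expect_equal(energy_profile(p3, p)[1] - u_full, 3 * p$epsilon,
               tolerance = 1e-9)
})

test_that("closed-form run frequencies match exhaustive enumeration", {
  p5 <- model_params(n_sites = 5L)
  q <- 1 / 4
  G <- 1
  st <- fN_random(p5, G, q)
  # oracle: enumerate all 2^5 facing match/mismatch patterns
  expected <- numeric(6)
  for (bits in 0:31) {
    m <- as.logical(bitwAnd(bits, 2^(0:4)) > 0)
    prob <- prod(ifelse(m, q, 1 - q))
    cc <- 3L
    N <- if (!m[cc]) 0L else {
      lo <- cc; while (lo > 1 && m[lo - 1]) lo <- lo - 1
      hi <- cc; while (hi < 5 && m[hi + 1]) hi <- hi + 1
      hi - lo + 1L
    }
    expected[N + 1L] <- expected[N + 1L] + prob
  }
  expect_equal(unname(st$f), expected, tolerance = 1e-12)
})

test_that("run-frequency spectrum has the expected structure", {
  p <- model_params()
  G <- 4641652
  st <- fN_random(p, G)
  expect_equal(sum(st$f), G, tolerance = 1e-9)
  expect_equal(st$f[["0"]] / G, 1 - 1 / 4)
  expect_true(all(diff(st$f[2:18]) < 0))      # decreasing for N >= 1, q < 1/2
  st2 <- fN_random(p, G, q = 1 / 2)
  expect_equal(st2$f[["17"]] / G, 2^-17)
})

test_that("genome windows reproduce the random ensemble statistics", {
  tmp <- withr::local_tempdir()
  fa <- make_fixture("toy_genome", seed = 4, size = 1e5, dir = tmp)
  p <- model_params()
  searcher <- random_sequence(17, 4, rng_seed = 40)
  st <- fN_genome(fa, searcher, p)
  W <- 1e5 - 16
  expect_equal(sum(st$f), W)
  # agreement with the closed form within Monte-Carlo error (multinomial SE)
  ref <- fN_random(p, W)
  for (N in 0:8) {
    pN <- ref$f[[as.character(N)]] / W
    se <- sqrt(W * pN * (1 - pN))
    expect_lt(abs(st$f[[as.character(N)]] - ref$f[[as.character(N)]]),
              4 * se + 1e-9)
  }
  # reverse complement doubles the classified windows
  st2 <- fN_genome(fa, searcher, p, include_revcomp = TRUE)
  expect_equal(sum(st2$f), 2 * W)
})

test_that("genome edge cases: self-window, ambiguity codes, short genome", {
  tmp <- withr::local_tempdir()
  p <- model_params()
  searcher <- random_sequence(17, 4, rng_seed = 50)
  self <- file.path(tmp, "self.fasta")
  writeLines(c(">searcher_itself",
               paste(c("A", "C", "G", "T")[searcher], collapse = "")), self)
  st <- fN_genome(self, searcher, p)
  expect_equal(unname(st$f[["17"]]), 1)
  expect_equal(sum(st$f), 1)
  amb <- file.path(tmp, "amb.fasta")
  writeLines(c(">with_ambiguity",
               paste(c(rep("A", 20), "N", rep("C", 20)), collapse = "")), amb)
  stam <- fN_genome(amb, searcher, p)
  expect_identical(attr(stam, "n_skipped"), 17L)
  expect_equal(sum(stam$f), (41 - 16) - 17)
  short <- file.path(tmp, "short.fasta")
  writeLines(c(">too_short", "ACGT"), short)
  expect_error(fN_genome(short, searcher, p), "shorter")
  expect_error(fN_genome(file.path(tmp, "nope.fasta"), searcher, p), "nope")
})
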