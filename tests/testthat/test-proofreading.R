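# Minimal hand-built kinetics cache: every class N decays as a single
# exponential exp(-rates[N+1] * t); the target decays at rate_target.
fake_kinetics <- function(params, rate_target, rates) {
  mix <- function(r) list(lambda = -r, A = 1)
  structure(list(
    params = params, q = 0.25, n_replicates = 1L, master_seed = 1L,
    rotation_enabled = FALSE,
    target_kin = list(mix_avg = mix(rate_target), mix_zero = mix(rate_target),
                      mfpt = 1 / rate_target),
    classes = lapply(rates, function(r)
      list(mixes = list(mix(r)), mfpt_mean = 1 / r)),
    weights = theta_weights(params)), class = "search_kinetics")
}

ens_with_f <- function(params, f_named) {
  f <- setNames(numeric(params$n_sites + 1), 0:params$n_sites)
  f[names(f_named)] <- f_named
  rodsearch:::new_ensemble_stats(0.25, f, f_T = 1, genome_length = sum(f))
}

test_that("sin-weighted angle averages reproduce closed-form integrals", {
  p <- model_params()
  thetas <- angle_grid(p)
  expect_equal(sum(theta_weights(p)), 1, tolerance = 1e-12)
  expect_equal(angle_average(rep(3.7, 90), p), 3.7, tolerance = 1e-12)
  # int sin cos / int sin over [0, pi/2] = 1/2
  expect_equal(angle_average(cos(thetas), p), 0.5, tolerance = 1e-3)
  # concentrating the weights at small angles raises the average of a
  # decreasing function
  avgs <- vapply(c(pi / 2, pi / 3, pi / 6), function(tm) {
    pm <- model_params(theta_max = tm)
    angle_average(cos(angle_grid(pm)), pm)
  }, numeric(1))
  expect_true(all(diff(avgs) > 0))
})

test_that("specificity implements the proofreading ratio exactly", {
  p <- model_params()
  # hand ensemble: f_1 = 10, P_1(t*) = 0.01, P_T(t*) = 0.5 at t* = 1
  kin <- fake_kinetics(p, rate_target = -log(0.5), rates = c(1, -log(0.01),
                                                             rep(1, 16)))
  ens <- ens_with_f(p, c("1" = 10))
  sp <- specificity(1, ens, kin)
  expect_equal(sp$sigma, 0.5 / (0.5 + 10 * 0.01), tolerance = 1e-10)
  expect_equal(sp$sigma + sp$eta, 1)
  # no off-targets: sigma = 1 at every delay, and the chosen delay is 0
  ens0 <- ens_with_f(p, c())
  expect_equal(specificity(c(0, 5, 50), ens0, kin)$sigma, rep(1, 3))
  expect_equal(choose_delay(0.99, ens0, kin)$T_D, 0)
})

test_that("delay selection matches the hand-solved two-exponential crossing", {
  p <- model_params()
  a <- 0.01   # target decay rate
  b <- 0.2    # off-target decay rate
  f1 <- 50
  kin <- fake_kinetics(p, a, c(1, b, rep(1e3, 16)))
  ens <- ens_with_f(p, c("1" = f1))
  # sigma(t) = 1 / (1 + f1 e^{-(b-a)t}); sigma_max = 1;
  # sigma(t) >= 0.99 <=> t >= ln(99 f1) / (b - a)
  hand <- log(99 * f1) / (b - a)
  cd <- choose_delay(0.99, ens, kin)
  expect_equal(cd$sigma_max, 1, tolerance = 1e-6)
  expect_equal(cd$T_D, hand, tolerance = 0.02)
  # stricter fractions never shorten the delay
  tds <- vapply(c(0.9, 0.99, 0.999), function(fr)
    choose_delay(fr, ens, kin)$T_D, numeric(1))
  expect_true(all(diff(tds) > 0))
})

test_that("off-target dwell time is the f-weighted angle-averaged unbinding time", {
  p <- model_params()
  kin <- fake_kinetics(p, 0.01, c(1, 1 / 5, rep(1, 16)))  # tau_1 = 5
  ens <- ens_with_f(p, c("1" = 1))
  expect_equal(off_target_time(ens, kin), 5, tolerance = 1e-12)
  ens2 <- ens_with_f(p, c("1" = 2))
  expect_equal(off_target_time(ens2, kin), 10, tolerance = 1e-12)
  # N = 0 enters only on request
  ens3 <- ens_with_f(p, c("0" = 100, "1" = 1))
  expect_equal(off_target_time(ens3, kin), 5, tolerance = 1e-12)
  expect_equal(off_target_time(ens3, kin, include_N0 = TRUE), 105,
               tolerance = 1e-12)
})

test_that("search time and parallel success follow their defining formulas", {
  expect_equal(search_time(1, 7, 3), 10)
  expect_equal(search_time(0.2, 10), 50)
  expect_equal(search_time(0.1, 10), 2 * search_time(0.2, 10))
  expect_error(search_time(0, 1), "P_T")
  expect_equal(parallel_success(0.2, 1), 0.2)
  expect_equal(parallel_success(1, 7), 1)
  expect_equal(parallel_success(0.2, 20), 1 - 0.8^20)
  # composition identity over split collision counts
  P <- 0.13
  expect_equal(parallel_success(P, 12),
               1 - (1 - parallel_success(P, 5)) * (1 - parallel_success(P, 7)),
               tolerance = 1e-12)
  expect_error(parallel_success(1.2, 3), "P_T")
})

test_that("class survival orderings and limits hold on a real ensemble", {
  p <- model_params()
  kin <- search_kinetics(p, n_replicates = 15, master_seed = 7)
  expect_equal(class_survival(0, kin, 0), 1, tolerance = 1e-9)
  expect_equal(class_survival("target", kin, 0), 1, tolerance = 1e-9)
  td <- 100
  expect_lt(class_survival(0, kin, td), class_survival(17, kin, td))
  # every finite chain eventually unbinds
  expect_lt(class_survival("target", kin, 1e18, log = TRUE), log(1e-6))
  # P_T non-increasing, sigma non-decreasing in the delay
  ens <- fN_random(p, 4641652)
  tds <- 10^seq(0, 10, length.out = 12)
  PT <- class_survival("target", kin, tds)
  expect_true(all(diff(PT) <= 1e-12))
  sig <- specificity(tds, ens, kin)$sigma
  expect_true(all(diff(sig) >= -1e-10))
})

test_that("sweeps reuse kinetics coherently and degrade gracefully", {
  p <- model_params()
  ens <- fN_random(p, 4641652)
  kin <- search_kinetics(p, n_replicates = 10, master_seed = 3)
  direct <- search_pipeline(p, ens, kinetics = kin)
  sw <- sweep_search("k", c(1, 5, 20), p, ens, n_replicates = 10,
                     master_seed = 3, variants = "rotating")
  expect_equal(sw$T_search[1], direct$T_search, tolerance = 1e-9)
  # parallel collisions never slow the search
  expect_true(all(diff(sw$T_search) <= 1e-9))
  expect_identical(attr(sw, "n_failed"), 0L)
  # a failing point is recorded, the sweep continues
  swbad <- sweep_search("theta_max", c(pi / 2, 99), p, ens, n_replicates = 5,
                        master_seed = 3, variants = "rotating")
  expect_identical(attr(swbad, "n_failed"), 1L)
  expect_false(is.na(swbad$T_search[1]))
  expect_true(is.na(swbad$T_search[2]))
})
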