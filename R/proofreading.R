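#' Collision-angle weights on the truncated grid
#'
#' Collisions uniformly distributed over a half sphere have angle density
#' proportional to `sin(theta0)`, truncated at `theta_max` (crowding) and
#' renormalized.  Discrete weights use trapezoid end-corrections on the
#' uniform grid.
#'
#' @param params A [model_params()] object.
#' @param thetas Grid angles; defaults to [angle_grid()].
#' @return Numeric weights summing to 1.
#' @export
theta_weights <- function(params, thetas = angle_grid(params)) {
  w <- sin(thetas)
  m <- length(w)
  w[c(1, m)] <- w[c(1, m)] / 2
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("cannot normalize collision-angle weights", call. = FALSE)
  w / s
}

#' Average a per-angle quantity over the collision-angle distribution
#'
#' @param values One value per grid angle.
#' @param params A [model_params()] object (defines grid and `theta_max`).
#' @param weights Optional weights; default [theta_weights()].
#' @return Weighted scalar average.
#' @export
angle_average <- function(values, params, weights = theta_weights(params)) {
  if (length(values) != length(weights))
    stop("values and angle weights differ in length", call. = FALSE)
  sum(weights * values)
}

# ---- per-class kinetics cache --------------------------------------------

# Kinetic summaries of one pairing: angle-averaged survival mixture,
# theta0 = 0 survival mixture, and the MFPT from every grid angle.
pairing_kinetics <- function(U, params, rotation_enabled, w) {
  chain <- chain_from_energies(U, params, rotation_enabled)
  if (!rotation_enabled) {
    r <- chain$unbind[1]
    return(list(mix_avg = list(lambda = -r, A = 1),
                mix_zero = list(lambda = -r, A = 1),
                mfpt = 1 / r))
  }
  sp <- chain_spectrum(chain)
  Aavg <- as.numeric(crossprod(w, sp$Vi)) * sp$B
  list(mix_avg = list(lambda = sp$lambda, A = Aavg),
       mix_zero = list(lambda = sp$lambda, A = sp$Vi[1, ] * sp$B),
       mfpt = mfpt_all(chain, sp))
}

#' Precompute ensemble kinetics for every off-target class and the target
#'
#' For each class `N` in `0:n_sites`, draws `n_replicates` off-target
#' sequences, builds their chains, and stores exact spectral survival
#' mixtures (angle-averaged and from `theta0 = 0`) together with mean
#' unbinding times from every collision angle.  The true target (perfect
#' match) is deterministic and stored once.  Every downstream proofreading
#' quantity -- `P_N(T_D)`, `P_T(T_D)`, `sigma`, `tau_off`, delay selection,
#' sweeps -- evaluates against this cache, so the expensive eigensolves are
#' done exactly once per sequence.
#'
#' @param params A [model_params()] object.
#' @param n_replicates Sequences drawn per class (the headline study
#'   condition is 2000; tests use fewer).
#' @param master_seed Integer master seed; per-(class, replicate) seeds are
#'   derived by the counter scheme of [ensemble_estimate()].
#' @param rotation_enabled `FALSE` gives the rotationally constrained
#'   reference model.
#' @param q Accidental match probability used when drawing off-targets;
#'   defaults to `1/alphabet_size`.
#' @param target Optional target sequence; defaults to a random sequence
#'   drawn from the master seed.
#' @return Object of class `"search_kinetics"`.
#' @export
search_kinetics <- function(params, n_replicates = 2000L, master_seed = 1L,
                            rotation_enabled = TRUE,
                            q = 1 / params$alphabet_size, target = NULL) {
  n <- params$n_sites
  w <- theta_weights(params)
  thetas <- angle_grid(params)
  ktab <- kernel_table(params, thetas)
  if (is.null(target)) {
    set.seed(master_seed)
    target <- random_sequence(n, max(params$alphabet_size, 2L))
  }
  tg <- pairing_kinetics(energy_from_match(as.vector(outer(target, target, "==")),
                                           ktab, params$epsilon),
                         params, rotation_enabled, w)
  classes <- vector("list", n + 1L)
  seeds <- replicate_seeds(master_seed, (n + 1L) * n_replicates)
  for (N in 0:n) {
    mixes <- vector("list", n_replicates)
    mfpt <- matrix(0, n_replicates, if (rotation_enabled) length(thetas) else 1L)
    for (r in seq_len(n_replicates)) {
      set.seed(seeds[N * n_replicates + r])
      pp <- offtarget_with_N_matches(target, N, q = q,
                                     alphabet_size = max(params$alphabet_size, 2L))
      pk <- pairing_kinetics(energy_from_match(as.vector(pp$match), ktab,
                                               params$epsilon),
                             params, rotation_enabled, w)
      mixes[[r]] <- pk$mix_avg
      mfpt[r, ] <- pk$mfpt
    }
    classes[[N + 1L]] <- list(mixes = mixes, mfpt_mean = colMeans(mfpt))
  }
  structure(list(params = params, target = target, q = q,
                 n_replicates = n_replicates, master_seed = master_seed,
                 rotation_enabled = rotation_enabled,
                 target_kin = tg, classes = classes, weights = w),
            class = "search_kinetics")
}

#' @export
print.search_kinetics <- function(x, ...) {
  cat(sprintf("search_kinetics: %d classes x %d replicates, rotation %s, q = %.4g\n",
              length(x$classes), x$n_replicates,
              if (x$rotation_enabled) "on" else "off", x$q))
  invisible(x)
}

# Mean log-survival of a class at time t (log of the ensemble-mean
# survival), stable for arbitrarily large t.
class_log_survival <- function(mixes, t) {
  ls <- vapply(mixes, mix_eval_log, numeric(1), t = t)
  M <- max(ls)
  if (!is.finite(M)) return(-Inf)
  M + log(mean(exp(ls - M)))
}

#' Ensemble survival probability of an off-target class or the target
#'
#' `P_N(T_D)`: the probability that a pairing from class `N`, collided at
#' an angle drawn from the sin-weighted distribution, is still bound at
#' `T_D`, averaged over the class ensemble.  `class = "target"` gives
#' `P_T(T_D)` for the perfect match (deterministic).
#'
#' @param class Integer class `N` in `0:n_sites`, or `"target"`.
#' @param kinetics A [search_kinetics()] cache.
#' @param T_D Delay time(s), `>= 0`.
#' @param log If `TRUE` return the log survival (stable at huge `T_D`).
#' @return Survival probability (or its log), vectorized over `T_D`.
#' @export
class_survival <- function(class, kinetics, T_D, log = FALSE) {
  if (any(T_D < 0)) stop("T_D must be >= 0", call. = FALSE)
  mixes <- if (identical(class, "target")) list(kinetics$target_kin$mix_avg)
           else kinetics$classes[[as.integer(class) + 1L]]$mixes
  ls <- vapply(T_D, function(t) class_log_survival(mixes, t), numeric(1))
  if (log) ls else exp(ls)
}

#' Specificity of the proofread search
#'
#' The probability that the irreversible product forms with the true
#' target rather than an off-target:
#' \deqn{\sigma(T_D) = \frac{f_T P_T(T_D)}{f_T P_T(T_D) + \sum_{N=1}^{n} f_N P_N(T_D)},}
#' with the off-target sum running over `N = 1..n_sites`.  The error rate
#' is `eta = 1 - sigma`.
#'
#' @param T_D Delay time(s).
#' @param ensemble An `"ensemble_stats"` object supplying `f_N` and `f_T`.
#' @param kinetics A [search_kinetics()] cache.
#' @param include_N0 Also count the `N = 0` class in the off-target sum
#'   (default `FALSE`: the printed formula starts at `N = 1`).
#' @return List with `sigma` and `eta`, each vectorized over `T_D`.
#' @export
specificity <- function(T_D, ensemble, kinetics, include_N0 = FALSE) {
  if (ensemble$f_T < 1) stop("ensemble must have f_T >= 1", call. = FALSE)
  n <- kinetics$params$n_sites
  Ns <- if (include_N0) 0:n else 1:n
  sig <- vapply(T_D, function(t) {
    lt <- log(ensemble$f_T) + class_log_survival(list(kinetics$target_kin$mix_avg), t)
    lo <- vapply(Ns, function(N) {
      fN <- ensemble$f[[as.character(N)]]
      if (fN <= 0) return(-Inf)
      log(fN) + class_log_survival(kinetics$classes[[N + 1L]]$mixes, t)
    }, numeric(1))
    terms <- c(lt, lo)
    M <- max(terms)
    if (!is.finite(M)) stop("all survival terms vanished", call. = FALSE)
    exp(lt - (M + log(sum(exp(terms - M)))))
  }, numeric(1))
  list(sigma = sig, eta = 1 - sig)
}

# Slowest survival decay time over all classes and the target: the scale
# on which every survival ratio has reached its long-delay limit.
slowest_decay_time <- function(kinetics) {
  mix_tau <- function(mix) max(-1 / mix$lambda)
  cl <- vapply(kinetics$classes,
               function(x) max(vapply(x$mixes, mix_tau, numeric(1))),
               numeric(1))
  max(c(mix_tau(kinetics$target_kin$mix_avg), cl))
}

#' Maximum attainable specificity
#'
#' `sigma(T_D)` in the long-delay limit, evaluated at the horizon
#' `10^3 x` the slowest class survival decay time, with a convergence
#' check (relative change below `tol` over the last decade of `T_D`).
#' When full-length accidental matches exist (`f_n > 0`) the limit is
#' `f_T / (f_T + f_n)`: those sequences are indistinguishable from the
#' true target.
#'
#' @param ensemble An `"ensemble_stats"` object.
#' @param kinetics A [search_kinetics()] cache.
#' @param tol Convergence tolerance on the relative change.
#' @return List with `sigma_max`, `horizon`, and the convergence estimate.
#' @export
sigma_max <- function(ensemble, kinetics, tol = 1e-4) {
  horizon <- 1e3 * slowest_decay_time(kinetics)
  s1 <- specificity(horizon / 10, ensemble, kinetics)$sigma
  s2 <- specificity(horizon, ensemble, kinetics)$sigma
  rel <- abs(s2 - s1) / max(s2, .Machine$double.eps)
  if (rel > tol)
    warning(sprintf("sigma(T_D) not converged at horizon (rel change %.3g)", rel),
            call. = FALSE)
  list(sigma_max = s2, horizon = horizon, rel_change = rel)
}

#' Minimal delay achieving a fraction of the maximum specificity
#'
#' Finds the smallest `T_D` with
#' `sigma(T_D) >= target_fraction * sigma_max` by bisection on `log T_D`
#' (relative tolerance 1% in `T_D`).  `sigma` is expected to be
#' non-decreasing in `T_D`; a violated bracket is an error, not a silent
#' answer.
#'
#' @param target_fraction Required fraction of `sigma_max`, in `(0, 1]`.
#' @param ensemble An `"ensemble_stats"` object.
#' @param kinetics A [search_kinetics()] cache.
#' @return List with `T_D`, `sigma_at_T_D`, `sigma_max`, `horizon`.
#' @export
choose_delay <- function(target_fraction, ensemble, kinetics) {
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must lie in (0, 1]", call. = FALSE)
  sm <- sigma_max(ensemble, kinetics)
  thr <- target_fraction * sm$sigma_max
  s0 <- specificity(0, ensemble, kinetics)$sigma
  if (s0 >= thr)
    return(list(T_D = 0, sigma_at_T_D = s0, sigma_max = sm$sigma_max,
                horizon = sm$horizon))
  hi <- sm$horizon
  s_hi <- specificity(hi, ensemble, kinetics)$sigma
  if (s_hi < thr)
    stop(sprintf("sigma never reaches %.6g on [0, %.3g] (sigma(horizon) = %.6g)",
                 thr, hi, s_hi), call. = FALSE)
  lo <- hi * 1e-18
  s_lo <- specificity(lo, ensemble, kinetics)$sigma
  if (s_lo >= thr) lo <- 0
  if (lo == 0) {        # threshold crossed below the log bracket; linear bisect
    lo2 <- 0
    while (hi / max(lo2, hi * 1e-30) > 1.01) {
      mid <- if (lo2 == 0) hi * 1e-30 else sqrt(lo2 * hi)
      if (specificity(mid, ensemble, kinetics)$sigma >= thr) hi <- mid else lo2 <- mid
    }
    td <- hi
  } else {
    while (hi / lo > 1.01) {
      mid <- sqrt(lo * hi)
      if (specificity(mid, ensemble, kinetics)$sigma >= thr) hi <- mid else lo <- mid
    }
    td <- hi
  }
  list(T_D = td, sigma_at_T_D = specificity(td, ensemble, kinetics)$sigma,
       sigma_max = sm$sigma_max, horizon = sm$horizon)
}

#' Expected off-target dwell time per search round
#'
#' \deqn{\tau_{off} = \int_0^{\theta_{max}} d\theta_0\, p(\theta_0) \sum_{N=1}^{n} f_N \tau_N(\theta_0),}
#' with `tau_N(theta0)` the ensemble-mean unbinding time of class `N` from
#' collision angle `theta0` and `p(theta0)` the sin-weighted collision
#' density.  Erroneous irreversible captures of off-targets are accounted
#' in the specificity, not here.
#'
#' @param ensemble An `"ensemble_stats"` object.
#' @param kinetics A [search_kinetics()] cache.
#' @param include_N0 Add the `N = 0` class to the sum (default `FALSE`:
#'   the sum starts at `N = 1`).
#' @return `tau_off` in units of `1/k_off0`.
#' @export
off_target_time <- function(ensemble, kinetics, include_N0 = FALSE) {
  n <- kinetics$params$n_sites
  w <- kinetics$weights
  Ns <- if (include_N0) 0:n else 1:n
  tot <- 0
  for (N in Ns) {
    fN <- ensemble$f[[as.character(N)]]
    if (fN <= 0) next
    tauN <- kinetics$classes[[N + 1L]]$mfpt_mean
    tauN_avg <- if (length(tauN) == 1L) tauN else sum(w * tauN)
    tot <- tot + fN * tauN_avg
  }
  tot
}

#' Expected total search time
#'
#' The searcher needs on average `1/P_T` encounters with the true target
#' before one is irreversibly captured; each search round costs the
#' off-target dwell plus free diffusion (target interaction time is
#' neglected):
#' \deqn{\langle T_{search} \rangle = (\tau_{off} + \tau_{diff} + \tau_{target}) / P_T.}
#'
#' @param P_T Probability that a true-target collision is bound at `T_D`.
#' @param tau_off Off-target dwell per round.
#' @param tau_diff Free-diffusion time per round (default 0).
#' @param tau_target Target interaction time per round (fixed 0 by default).
#' @return Expected search time.
#' @export
search_time <- function(P_T, tau_off, tau_diff = 0, tau_target = 0) {
  if (any(P_T <= 0)) stop("P_T must be > 0: search never completes", call. = FALSE)
  (tau_off + tau_diff + tau_target) / P_T
}

#' Success probability of k correlated parallel collisions
#'
#' Probability that at least one of `k` simultaneous collision points with
#' the true target forms the irreversible product:
#' \deqn{P_T'(k) = 1 - (1 - P_T)^k.}
#'
#' @param P_T Per-collision success probability in `[0, 1]`.
#' @param k Number of collision points, integer `>= 1`.
#' @return `P_T'`, vectorized over `P_T` and `k`.
#' @export
parallel_success <- function(P_T, k) {
  if (any(P_T < 0 | P_T > 1)) stop("P_T must lie in [0, 1]", call. = FALSE)
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  1 - (1 - P_T)^k
}

#' Run the full proofreading search pipeline once
#'
#' Chooses the delay `T_D` for the requested specificity fraction, then
#' assembles `P_T`, `sigma`, `tau_off`, the parallel success probability
#' and the total search time into one object.
#'
#' @param params A [model_params()] object.
#' @param ensemble An `"ensemble_stats"` object.
#' @param kinetics Optional precomputed [search_kinetics()] cache (built on
#'   the fly otherwise).
#' @param n_replicates,master_seed Ensemble controls when `kinetics` is
#'   built here.
#' @param rotation_enabled Rotating or constrained variant.
#' @param target_fraction Fraction of `sigma_max` that `T_D` must achieve.
#' @param tau_diff Free-diffusion time per round.
#' @param k Number of correlated parallel collision points.
#' @param include_N0 Include the `N = 0` class in `tau_off`.
#' @return Object of class `"search_model"` with fields `T_D`, `P_T`,
#'   `sigma`, `eta`, `sigma_max`, `tau_off`, `tau_diff`, `tau_target`,
#'   `k`, `P_T_prime`, `T_search`.
#' @export
search_pipeline <- function(params, ensemble, kinetics = NULL,
                            n_replicates = 200L, master_seed = 1L,
                            rotation_enabled = TRUE, target_fraction = 0.99,
                            tau_diff = 0, k = 1L, include_N0 = FALSE) {
  if (is.null(kinetics))
    kinetics <- search_kinetics(params, n_replicates, master_seed,
                                rotation_enabled, q = ensemble$q)
  cd <- choose_delay(target_fraction, ensemble, kinetics)
  P_T <- class_survival("target", kinetics, cd$T_D)
  sp <- specificity(cd$T_D, ensemble, kinetics)
  tau_off <- off_target_time(ensemble, kinetics, include_N0 = include_N0)
  P_Tk <- parallel_success(P_T, k)
  structure(list(T_D = cd$T_D, P_T = P_T, sigma = sp$sigma, eta = sp$eta,
                 sigma_max = cd$sigma_max, tau_off = tau_off,
                 tau_diff = tau_diff, tau_target = 0, k = as.integer(k),
                 P_T_prime = P_Tk,
                 T_search = search_time(P_Tk, tau_off, tau_diff),
                 rotation_enabled = rotation_enabled,
                 params = params),
            class = "search_model")
}

#' @export
print.search_model <- function(x, ...) {
  cat(sprintf("search_model (%s):\n",
              if (x$rotation_enabled) "rotating" else "constrained"))
  cat(sprintf("  T_D = %.4g, P_T = %.4g, sigma = %.6g (max %.6g)\n",
              x$T_D, x$P_T, x$sigma, x$sigma_max))
  cat(sprintf("  tau_off = %.4g, tau_diff = %.4g, k = %d, P_T' = %.4g\n",
              x$tau_off, x$tau_diff, x$k, x$P_T_prime))
  cat(sprintf("  T_search = %.4g (units of 1/k_off0)\n", x$T_search))
  invisible(x)
}

#' Sweep one search parameter across values
#'
#' Runs the full pipeline at every value of `epsilon`, `theta_max`,
#' `tau_diff`, or `k` for both the rotating and the constrained variant,
#' returning a tidy table.  The expensive class kinetics are cached and
#' reused across `tau_diff` and `k` sweep points, where they stay valid.
#' Per-point failures are recorded in the `error` column and the sweep
#' continues; any failure is flagged in the `"n_failed"` attribute.
#'
#' @param parameter One of `"epsilon"`, `"theta_max"`, `"tau_diff"`, `"k"`.
#' @param values Non-empty numeric vector of parameter values.
#' @param params Baseline [model_params()] object.
#' @param ensemble An `"ensemble_stats"` object (its `q` also seeds random
#'   ensembles rebuilt at each point).
#' @param n_replicates,master_seed Ensemble controls.
#' @param target_fraction,tau_diff,k,include_N0 Pipeline settings held
#'   fixed while another parameter is swept.
#' @param variants Which model variants to run.
#' @return Data frame with one row per (value, variant):
#'   `value, variant, T_D, P_T, sigma, tau_off, T_search, error`.
#' @export
sweep_search <- function(parameter = c("epsilon", "theta_max", "tau_diff", "k"),
                         values, params, ensemble,
                         n_replicates = 200L, master_seed = 1L,
                         target_fraction = 0.99, tau_diff = 0, k = 1L,
                         include_N0 = FALSE,
                         variants = c("rotating", "constrained")) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  variants <- match.arg(variants, several.ok = TRUE)
  rows <- list()
  kin_cache <- list()   # per-variant cache, valid across tau_diff/k points
  for (variant in variants) {
    rot <- variant == "rotating"
    for (v in values) {
      p_v <- params
      td_v <- tau_diff
      k_v <- k
      reuse <- parameter %in% c("tau_diff", "k")
      if (parameter == "epsilon") p_v$epsilon <- v
      if (parameter == "theta_max") p_v$theta_max <- v
      if (parameter == "tau_diff") td_v <- v
      if (parameter == "k") k_v <- as.integer(v)
      res <- tryCatch({
        validate_params(p_v)
        kin <- if (reuse && !is.null(kin_cache[[variant]])) kin_cache[[variant]]
               else search_kinetics(p_v, n_replicates, master_seed, rot,
                                    q = ensemble$q)
        if (reuse) kin_cache[[variant]] <- kin
        sm <- search_pipeline(p_v, ensemble, kinetics = kin,
                              rotation_enabled = rot,
                              target_fraction = target_fraction,
                              tau_diff = td_v, k = k_v,
                              include_N0 = include_N0)
        data.frame(value = v, variant = variant, T_D = sm$T_D, P_T = sm$P_T,
                   sigma = sm$sigma, tau_off = sm$tau_off,
                   T_search = sm$T_search, error = NA_character_)
      }, error = function(e) {
        data.frame(value = v, variant = variant, T_D = NA_real_,
                   P_T = NA_real_, sigma = NA_real_, tau_off = NA_real_,
                   T_search = NA_real_, error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- sum(!is.na(out$error))
  out
}

#' Ensemble-mean probability of reaching parallel alignment per angle
#'
#' Mean over `n_replicates` class-`N` sequences of the exact reach
#' probability from every grid angle (`class = "target"` for the perfect
#' match, a single deterministic profile).
#'
#' @param class Integer class `N`, or `"target"`, or `"M"` combined with
#'   the `M` argument for near-target pairings with forced central
#'   mismatches.
#' @param params A [model_params()] object.
#' @param n_replicates Sequences drawn for random classes.
#' @param master_seed Integer master seed.
#' @param q Accidental match probability.
#' @param M Number of forced central mismatches when `class = "M"`.
#' @param target Optional fixed target sequence.
#' @return List with `thetas`, `p` (mean reach probability per angle) and
#'   `p_avg` (sin-weighted angle average).
#' @export
ensemble_reach <- function(class, params, n_replicates = 200L,
                           master_seed = 1L, q = 1 / params$alphabet_size,
                           M = 0L, target = NULL) {
  thetas <- angle_grid(params)
  ktab <- kernel_table(params, thetas)
  ab <- max(params$alphabet_size, 2L)
  if (is.null(target)) {
    set.seed(master_seed)
    target <- random_sequence(params$n_sites, ab)
  }
  reach_of <- function(match_vec) {
    ch <- chain_from_energies(energy_from_match(match_vec, ktab, params$epsilon),
                              params, TRUE)
    reach_probabilities(ch)
  }
  if (identical(class, "target")) {
    p <- reach_of(as.vector(outer(target, target, "==")))
  } else {
    seeds <- replicate_seeds(master_seed, n_replicates)
    acc <- 0
    for (r in seq_len(n_replicates)) {
      set.seed(seeds[r])
      pp <- if (identical(class, "M"))
        target_with_M_central_mismatches(target, M, alphabet_size = ab)
      else offtarget_with_N_matches(target, as.integer(class), q = q,
                                    alphabet_size = ab)
      acc <- acc + reach_of(as.vector(pp$match))
    }
    p <- acc / n_replicates
  }
  list(thetas = thetas, p = p,
       p_avg = angle_average(p, params))
}

#' Characteristic rotation time of a perfectly matched pair
#'
#' Mean time for a perfect-match pairing to rotate from a sin-distributed
#' collision angle into parallel alignment (`theta = 0`), computed for the
#' rotational dynamics alone (unbinding switched off, so this is a pure
#' timescale of the angular motion on the matched energy landscape, not a
#' survival-biased quantity).  The default `k_rot` is calibrated so this is
#' about 100 time units -- the characteristic rotation timescale separating
#' the ~1 rejection time of full mismatches from the > 1e6 x longer
#' unbinding times of trapped near-matches.
#'
#' @param params A [model_params()] object.
#' @param target Optional explicit target sequence (default: all-distinct
#'   symbols, so exactly the facing sites match).
#' @param conditional If `TRUE`, return instead the mean time to reach
#'   `theta = 0` conditioned on doing so before unbinding (survival-biased;
#'   dominated by near-parallel collisions).
#' @return Mean rotation time, units of `1/k_off0`.
#' @export
rotation_time <- function(params, target = NULL, conditional = FALSE) {
  # all-distinct symbols: exactly the facing sites match (pure diagonal)
  if (is.null(target)) target <- seq_len(params$n_sites)
  ch <- build_chain(site_pairing(target, target), params, TRUE)
  w <- theta_weights(params)
  if (conditional) {
    cr <- conditional_reach_times(ch)
    num <- sum(w * cr$p * ifelse(is.na(cr$t_cond), 0, cr$t_cond))
    return(num / sum(w * cr$p))
  }
  m <- length(ch$thetas)
  rot <- ch$Qbb
  diag(rot) <- diag(rot) + ch$unbind      # remove the unbinding leak
  Qtt <- rot[-1, -1, drop = FALSE]        # absorb at theta = 0
  tau <- c(0, solve(-Qtt, rep(1, m - 1L)))
  sum(w * tau)
}
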