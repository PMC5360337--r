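#' Simulate one trajectory of the bound chain (Gillespie)
#'
#' Exact kinetic Monte Carlo realization of the chain: exponential waiting
#' times at the total exit rate, categorical next-state draws.  The
#' trajectory ends at UNBOUND, at parallel alignment (`theta = 0`) if
#' `stop_at_parallel`, or is censored at `t_max`.  Reproducible per seed.
#'
#' @param chain A [build_chain()] object.
#' @param theta0 Initial angle; must be a grid angle.
#' @param rng_seed Integer seed (required: trajectories are reproducible by
#'   contract).
#' @param t_max Censoring time (default `Inf`).
#' @param stop_at_parallel Absorb at `theta = 0` instead of treating it as
#'   a regular state.
#' @param max_events Safety cap on the number of simulated events.
#' @return An object of class `"trajectory"`: `events` (data frame with
#'   `time`, `state` index and `theta`; state 0 is UNBOUND), `terminal`
#'   (`"UNBOUND"`, `"REACHED_PARALLEL"` or `"CENSORED"`), `rng_seed`.
#' @export
simulate_chain <- function(chain, theta0, rng_seed, t_max = Inf,
                           stop_at_parallel = FALSE, max_events = 1e7) {
  if (t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  i <- theta_index(chain, theta0)
  set.seed(rng_seed)
  m <- length(chain$thetas)
  rot <- chain$Qbb
  diag(rot) <- 0
  res <- .gillespie_path(rot, chain$unbind, i - 1L, t_max,
                         stop_at_parallel, max_events)
  theta_of <- function(s) ifelse(s == 0L, NA_real_, chain$thetas[pmax(s, 1L)])
  ev <- data.frame(time = res$time, state = res$state,
                   theta = theta_of(res$state))
  structure(list(events = ev,
                 terminal = c("UNBOUND", "REACHED_PARALLEL", "CENSORED")[res$terminal + 1L],
                 t_end = res$t_end, rng_seed = rng_seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d events, terminal %s at t = %.4g (seed %d)\n",
              nrow(x$events) - 1L, x$terminal, x$t_end, x$rng_seed))
  invisible(x)
}

#' Export a trajectory as TSV
#'
#' @param traj A [simulate_chain()] trajectory.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_tsv_commented(traj$events[, c("time", "state")], path,
                      extra = c(sprintf("terminal = %s", traj$terminal),
                                sprintf("rng_seed = %d", traj$rng_seed)))
}

# Batch terminal statistics for n_rep trajectories from one chain; relies
# on the caller having set the RNG state.
gillespie_terminals <- function(chain, i, n_rep, t_max = Inf,
                                stop_at_parallel = FALSE) {
  rot <- chain$Qbb
  diag(rot) <- 0
  .gillespie_batch(rot, chain$unbind, i - 1L, t_max, n_rep, stop_at_parallel)
}

#' Monte-Carlo ensemble estimate of a chain statistic
#'
#' Draws a fresh chain per replicate from `chain_factory` (typically one
#' off-target sequence per replicate), simulates one trajectory, and
#' averages the requested statistic.  Per-replicate seeds are derived from
#' the master seed by a fixed counter scheme: `set.seed(master_seed)` then
#' one `sample.int(2^31 - 1)` draw per replicate, so replicate `i` always
#' sees the same seed regardless of `n_replicates` consumed elsewhere.
#'
#' @param chain_factory Function of one argument (the replicate seed)
#'   returning a [build_chain()] object.  The RNG is already seeded with
#'   the replicate seed when the factory is called, so factories that draw
#'   random sequences are reproducible.
#' @param theta0 Initial angle (grid angle of every factory chain).
#' @param n_replicates Number of replicates, at least 2.
#' @param statistic One of `"reach_parallel"` (indicator of hitting
#'   `theta = 0` before unbinding), `"unbinding_time"`, or `"survival"`
#'   (indicator of still being bound at time `t`).
#' @param master_seed Integer master seed.
#' @param t Time at which survival is evaluated (required for
#'   `statistic = "survival"`).
#' @param t_max Censoring time for the simulations.
#' @return List with `mean`, `se` (standard error of the mean), `n`, and
#'   the per-replicate `values`.
#' @export
ensemble_estimate <- function(chain_factory, theta0, n_replicates,
                              statistic = c("reach_parallel",
                                            "unbinding_time", "survival"),
                              master_seed = 1L, t = NULL, t_max = Inf) {
  statistic <- match.arg(statistic)
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (statistic == "survival") {
    if (is.null(t)) stop("statistic 'survival' needs t", call. = FALSE)
    t_max <- t
  }
  seeds <- replicate_seeds(master_seed, n_replicates)
  vals <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seeds[r])
    chain <- chain_factory(seeds[r])
    i <- theta_index(chain, theta0)
    res <- gillespie_terminals(chain, i, 1L, t_max = t_max,
                               stop_at_parallel = statistic == "reach_parallel")
    vals[r] <- switch(statistic,
                      reach_parallel = as.numeric(res$terminal[1] == 1L),
                      unbinding_time = res$time[1],
                      survival = as.numeric(res$terminal[1] == 2L))
  }
  list(mean = mean(vals), se = sd(vals) / sqrt(n_replicates),
       n = n_replicates, values = vals)
}

# Deterministic replicate seeds from a master seed.
replicate_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2147483646L, n)
}
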