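#' Build the discrete-state bound chain for a pairing
#'
#' Constructs the continuous-time Markov chain of the bound pair.  Bound
#' states are the angles of [angle_grid()]; an absorbing UNBOUND state is
#' appended.  Rotation between adjacent angle states uses Metropolis rates
#' `k_hop * min(1, pi'/pi)` (reflecting at both grid ends), where the
#' stationary weight `pi` of a state is its Boltzmann factor `exp(-U)`
#' times its cell width (the two end cells are half-width).  The
#' rotation-only dynamics thus satisfy detailed balance with respect to
#' the Boltzmann density and form a finite-volume approximation of
#' reflected rotational diffusion, so refining the grid leaves
#' first-passage quantities essentially unchanged.  The hop attempt rate
#' `k_hop` equals
#' `k_rot * (delta_theta_ref / delta_theta)^2`, which keeps the rotational
#' diffusion coefficient independent of the grid resolution.  Unbinding
#' from a bound state at energy `U` is an Arrhenius escape over the binding
#' energy, `k_off0 * exp(U)`: exactly 1 (the time unit) for a zero-energy
#' contact and exponentially slow for deeply bound states.
#'
#' With `rotation_enabled = FALSE` the chain has the single state
#' `theta = 0` with unbinding rate `exp(U(0))` -- the rotationally
#' constrained ("frozen parallel") reference model.
#'
#' @param pairing A [site_pairing()].
#' @param params A [model_params()] object.
#' @param rotation_enabled Logical; `FALSE` builds the constrained-parallel
#'   one-state chain.
#' @return An object of class `"bound_chain"`: `thetas`, `energies`, the
#'   full generator `Q` (bound states plus UNBOUND, rows sum to zero),
#'   its bound-bound block `Qbb`, `unbind` rates, and flags.
#' @export
build_chain <- function(pairing, params, rotation_enabled = TRUE) {
  thetas <- angle_grid(params)
  U <- energy_profile(pairing, params, thetas)
  chain_from_energies(U, params, rotation_enabled, thetas)
}

# Core constructor from an energy vector; also used for hand-built test
# chains and ensemble drivers that compute U themselves.
chain_from_energies <- function(U, params, rotation_enabled = TRUE,
                                thetas = angle_grid(params)) {
  if (any(!is.finite(U))) stop("non-finite energies", call. = FALSE)
  if (!rotation_enabled) {
    thetas <- thetas[1]
    U <- U[1]
  }
  m <- length(thetas)
  if (rotation_enabled && m < 2L)
    stop("rotating chain needs at least 2 angle states", call. = FALSE)
  unbind <- params$k_off0 * exp(U)
  # stationary log-weights: Boltzmann factor times the cell size (the two
  # boundary cells are half-width), so the chain is a finite-volume
  # approximation of reflected rotational diffusion in the potential U
  log_pi <- -U
  if (m > 1L) log_pi[c(1L, m)] <- log_pi[c(1L, m)] + log(0.5)
  up <- down <- numeric(m)
  if (m > 1L) {
    delta <- thetas[2] - thetas[1]
    k_hop <- params$k_rot * (DELTA_THETA_REF / delta)^2
    dlp <- diff(log_pi)
    up[1:(m - 1)] <- k_hop * pmin(1, exp(dlp))    # theta_i -> theta_{i+1}
    down[2:m] <- k_hop * pmin(1, exp(-dlp))       # theta_i -> theta_{i-1}
  }
  Q <- matrix(0, m + 1L, m + 1L)
  for (i in seq_len(m)) {
    if (i < m) Q[i, i + 1L] <- up[i]
    if (i > 1L) Q[i, i - 1L] <- down[i]
    Q[i, m + 1L] <- unbind[i]
  }
  diag(Q) <- -rowSums(Q)
  lab <- c(sprintf("theta_%d", seq_len(m) - 1L), "UNBOUND")
  dimnames(Q) <- list(lab, lab)
  structure(list(thetas = thetas, energies = U, log_pi = log_pi, Q = Q,
                 Qbb = Q[seq_len(m), seq_len(m), drop = FALSE],
                 unbind = unbind, rotation_enabled = rotation_enabled,
                 params = params),
            class = "bound_chain")
}

#' @export
print.bound_chain <- function(x, ...) {
  cat(sprintf("bound_chain: %d bound state(s) + UNBOUND, rotation %s\n",
              length(x$thetas), if (x$rotation_enabled) "on" else "off"))
  cat(sprintf("  U(0) = %.4g kBT, min U = %.4g kBT\n",
              x$energies[1], min(x$energies)))
  invisible(x)
}

# Index of theta0 on the chain grid; errors rather than snapping.
theta_index <- function(chain, theta0) {
  i <- which(abs(chain$thetas - theta0) <= 1e-9 * max(1, abs(theta0)))
  if (length(i) != 1L)
    stop("theta0 is not a grid angle of this chain", call. = FALSE)
  i
}

# Symmetric spectral decomposition of the bound-bound generator.  The
# rotation rates obey detailed balance wrt the cell-weighted Boltzmann
# measure pi, so D^{1/2} Qbb D^{-1/2} is symmetric (D = diag(pi)) and
# exp(Qbb t) = D^{-1/2} V exp(Lambda t) V' D^{1/2}.
chain_spectrum <- function(chain) {
  if (!is.null(chain$spectrum)) return(chain$spectrum)
  shalf <- exp(chain$log_pi / 2)
  S <- sweep(sweep(chain$Qbb, 1, shalf, "*"), 2, shalf, "/")
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  Vi <- e$vectors / shalf                          # D^{-1/2} V, rows = states
  lambda <- rq_eigenvalues(chain, Vi, e$vectors)
  list(lambda = lambda, Vi = Vi,
       B = as.numeric(crossprod(e$vectors, shalf)))  # V' D^{1/2} 1
}

# Refine eigenvalues as Rayleigh quotients in Dirichlet form.  The dense
# eigensolver only resolves eigenvalues down to ~eps * ||S||, far above the
# exponentially slow decay rates of deep energy wells.  For a reversible
# chain with killing the quotient is a ratio of sums of nonnegative terms
#   -lambda = [sum_edges pi_i q_i (w_{i+1} - w_i)^2 + sum_i pi_i k_u w_i^2]
#             / sum_i pi_i w_i^2,     w = D^{-1/2} v,
# which is free of cancellation and accurate at any magnitude.
rq_eigenvalues <- function(chain, Vi, V) {
  m <- nrow(Vi)
  up <- chain$Qbb[cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)]
  # sqrt(pi_i) * (w_{i+1} - w_i) = v_{i+1} sqrt(pi_i/pi_{i+1}) - v_i
  g <- exp(-diff(chain$log_pi) / 2)
  dnum <- (V[-1, , drop = FALSE] * g - V[-m, , drop = FALSE])^2 * up
  knum <- V^2 * chain$unbind
  den <- colSums(V^2)
  -(colSums(dnum) + colSums(knum)) / den
}

# Survival-from-state-i mixture coefficients: s_i(t) = sum_k c_k e^{lambda_k t}.
start_mixture <- function(chain, i, spectrum = chain_spectrum(chain)) {
  list(lambda = spectrum$lambda, A = spectrum$Vi[i, ] * spectrum$B)
}

# Evaluate an exponential mixture sum_k A_k e^{lambda_k t} (vectorized in t).
mix_eval <- function(mix, t) {
  vapply(t, function(tt) sum(mix$A * exp(mix$lambda * tt)), numeric(1))
}

# log of a mixture value, stable at times where the direct sum underflows:
# beyond underflow only the slowest (Perron) mode matters and its
# coefficient is positive.
mix_eval_log <- function(mix, t) {
  vapply(t, function(tt) {
    v <- sum(mix$A * exp(mix$lambda * tt))
    if (is.finite(v) && v > 1e-250) return(log(v))
    pos <- mix$A > 0
    if (!any(pos)) return(-Inf)
    x <- log(mix$A[pos]) + mix$lambda[pos] * tt
    M <- max(x)
    M + log(sum(exp(x - M)))
  }, numeric(1))
}

# Mean time to absorption from every bound state: tau = integral of the
# survival, sum_k -c_k / lambda_k (spectral), which is stable for deep wells.
mfpt_all <- function(chain, spectrum = chain_spectrum(chain)) {
  as.numeric((spectrum$Vi %*% (spectrum$B / (-spectrum$lambda))))
}

#' Probability of reaching parallel alignment before unbinding
#'
#' First-passage probability that the chain started at `theta0` hits the
#' parallel state `theta = 0` before the absorbing UNBOUND state, from the
#' exact linear first-passage system (no sampling).
#'
#' @param chain A rotating [build_chain()] object.
#' @param theta0 Initial collision angle; must be a grid angle (no silent
#'   snapping).
#' @return Probability in `[0, 1]`.
#' @export
prob_reach_parallel <- function(chain, theta0) {
  if (!chain$rotation_enabled)
    stop("prob_reach_parallel requires a rotating chain", call. = FALSE)
  reach_probabilities(chain)[theta_index(chain, theta0)]
}

# Reach probability from every grid angle at once (one linear solve).
reach_probabilities <- function(chain) {
  m <- length(chain$thetas)
  Qtt <- chain$Qbb[-1, -1, drop = FALSE]
  h <- solve(-Qtt, chain$Qbb[-1, 1])
  unname(c(1, h))
}

# Conditional mean time to reach theta = 0, given that it is reached,
# from every grid angle (NA where the reach probability is 0).
conditional_reach_times <- function(chain) {
  p <- reach_probabilities(chain)
  Qtt <- chain$Qbb[-1, -1, drop = FALSE]
  w <- solve(-Qtt, p[-1])
  tc <- unname(c(0, ifelse(p[-1] > 0, w / p[-1], NA_real_)))
  list(p = p, t_cond = tc)
}

#' Mean unbinding time
#'
#' Expected hitting time of the absorbing UNBOUND state from `theta0`, by
#' an exact solve; `theta = 0` is a regular (non-absorbing) state here.
#' For the one-state constrained chain this is the closed form
#' `exp(-U(0))`.
#'
#' @param chain A [build_chain()] object.
#' @param theta0 Initial angle; must be a grid angle.
#' @return Mean first-passage time in units of `1/k_off0`.
#' @export
mean_unbinding_time <- function(chain, theta0) {
  i <- theta_index(chain, theta0)
  if (length(chain$thetas) == 1L) return(1 / chain$unbind[1])
  tau <- mfpt_all(chain)
  if (any(!is.finite(tau))) stop("singular first-passage system", call. = FALSE)
  tau[i]
}

#' Survival probability of the bound pair
#'
#' Probability that the pair is still bound at each requested time, started
#' from `theta0`, from the exact spectral solution of the master equation.
#'
#' @param chain A [build_chain()] object.
#' @param theta0 Initial angle; must be a grid angle.
#' @param times Non-negative, non-decreasing times.
#' @return Vector of probabilities, non-increasing in `t`, `P(0) = 1`.
#' @export
survival_probability <- function(chain, theta0, times) {
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (is.unsorted(times)) stop("times must be ascending", call. = FALSE)
  i <- theta_index(chain, theta0)
  if (length(chain$thetas) == 1L) return(exp(-chain$unbind[1] * times))
  s <- mix_eval(start_mixture(chain, i), times)
  pmin(pmax(s, 0), 1)   # strip eigensolver noise at the 1e-14 level
}

#' Time-dependent angle distribution versus the Boltzmann reference
#'
#' Conditional distribution over bound angle states at each time
#' (normalized among surviving pairs), the Boltzmann reference
#' `exp(-U)/Z`, and their total-variation distance.  For deep energy wells
#' the surviving pairs reach a quasi-equilibrium close to Boltzmann.
#'
#' @param chain A rotating [build_chain()] object.
#' @param theta0 Initial angle; must be a grid angle.
#' @param times Non-negative times.
#' @return List with `times`, `distributions` (length(times) x n_states
#'   matrix), `boltzmann`, `survival`, and `tv` (total-variation distance
#'   per time; `NA` with a warning where essentially all mass has unbound).
#' @export
boltzmann_comparison <- function(chain, theta0, times) {
  if (!chain$rotation_enabled)
    stop("boltzmann_comparison requires a rotating chain", call. = FALSE)
  i <- theta_index(chain, theta0)
  sp <- chain_spectrum(chain)
  pi_w <- exp(chain$log_pi)
  boltz <- pi_w / sum(pi_w)
  m <- length(chain$thetas)
  dist <- matrix(NA_real_, length(times), m)
  surv <- numeric(length(times))
  tv <- rep(NA_real_, length(times))
  for (t in seq_along(times)) {
    w <- exp(sp$lambda * times[t])
    # p_j(t) = [e^{Qbb t}]_{ij} = sum_k Vi[i,k] e^{lambda_k t} Vi[j,k] pi_j
    p <- as.numeric(sp$Vi %*% (w * sp$Vi[i, ])) * pi_w
    p <- pmax(p, 0)
    s <- sum(p)
    surv[t] <- s
    if (s < 1e-12) {
      warning("survival below 1e-12 at t = ", times[t],
              "; conditional distribution undefined", call. = FALSE)
      next
    }
    dist[t, ] <- p / s
    tv[t] <- 0.5 * sum(abs(dist[t, ] - boltz))
  }
  list(times = times, distributions = dist, boltzmann = boltz,
       survival = surv, tv = tv)
}

#' Export a chain as a TSV edge list
#'
#' One row per nonzero transition rate (`state_from`, `state_to`, `rate`),
#' for inspection or as a solver fixture.
#'
#' @param chain A [build_chain()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_chain_edges <- function(chain, path) {
  Q <- chain$Q
  idx <- which(Q > 0 & row(Q) != col(Q), arr.ind = TRUE)
  df <- data.frame(state_from = rownames(Q)[idx[, 1]],
                   state_to = colnames(Q)[idx[, 2]],
                   rate = Q[idx])
  df <- df[order(idx[, 1], idx[, 2]), ]
  write_tsv_commented(df, path, params = chain$params)
}
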