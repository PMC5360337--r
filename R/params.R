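#' Model parameters for the rigid-rod pairing model
#'
#' Collects every physical and numerical constant of the model.  Energies
#' are measured in units of \eqn{k_B T}; times in units of the bare
#' unbinding rate `k_off0`, which is fixed to 1 and defines the time unit
#' (the unbinding rate of a fully mismatched, zero-energy contact).
#'
#' @param n_sites Number of binding sites per rod (one per helical turn).
#' @param spacing_a Distance between adjacent sites along a rod, nm.
#' @param epsilon Attractive energy per matched site pair at contact,
#'   \eqn{k_B T}, stored as a positive magnitude.
#' @param decay_length_lambda Decay length of the site-site interaction, nm.
#'   The default `spacing_a / 10` keeps the interaction much shorter-ranged
#'   than the site spacing, so only sites near the collision point interact
#'   at finite angles.
#' @param contact_r0 Closest-approach distance between two facing sites, nm
#'   (of the order of the dsDNA diameter).  The out-of-plane separation of
#'   the rods is folded into this constant, added in quadrature to the
#'   in-plane distance.
#' @param kernel Radial form of the site-site attraction: exponential decay
#'   (default) or a softened inverse-cube power law.  Both are normalized to
#'   1 at contact so a matched facing pair contributes exactly `-epsilon`.
#' @param alphabet_size Number of distinct site types; two random sites
#'   match accidentally with probability `q = 1/alphabet_size`.
#' @param theta_max Largest collision angle, radians, at most `pi/2`.
#'   Values below `pi/2` emulate molecular crowding that biases collisions
#'   towards small angles.
#' @param n_angle_bins Number of grid points of the discrete angle grid
#'   spanning `[0, theta_max]`.
#' @param k_rot Rotational attempt rate between adjacent angle states on the
#'   reference grid (90 bins over `[0, pi/2]`), in units of `k_off0`.  On
#'   other grids the hop rate is rescaled by `1/delta_theta^2` so that the
#'   rotational diffusion coefficient `D = k_rot * delta_theta_ref^2` is a
#'   grid-independent physical quantity.  The default is calibrated so that
#'   the mean conditional time for a perfectly matched pair to rotate into
#'   parallel alignment is about 100 time units.
#' @param k_off0 Bare unbinding rate; fixed to 1 (defines the time unit).
#'
#' @return An object of class `"rod_params"` (a validated list).
#' @examples
#' p <- model_params()
#' p$n_sites * p$spacing_a   # total rod length, 57.8 nm
#' @export
model_params <- function(n_sites = 17L,
                         spacing_a = 3.4,
                         epsilon = 1.5,
                         decay_length_lambda = spacing_a / 10,
                         contact_r0 = 2.0,
                         kernel = c("exponential", "power_law_3"),
                         alphabet_size = 4L,
                         theta_max = pi / 2,
                         n_angle_bins = 90L,
                         k_rot = 14.632,
                         k_off0 = 1) {
  kernel <- match.arg(kernel)
  p <- list(
    n_sites = as.integer(n_sites),
    spacing_a = as.numeric(spacing_a),
    epsilon = as.numeric(epsilon),
    decay_length_lambda = as.numeric(decay_length_lambda),
    contact_r0 = as.numeric(contact_r0),
    kernel = kernel,
    alphabet_size = as.integer(alphabet_size),
    theta_max = as.numeric(theta_max),
    n_angle_bins = as.integer(n_angle_bins),
    k_rot = as.numeric(k_rot),
    k_off0 = as.numeric(k_off0)
  )
  class(p) <- "rod_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(length(p$n_sites) == 1 && !is.na(p$n_sites) && p$n_sites >= 1L,
      "n_sites must be an integer >= 1")
  chk(is.finite(p$spacing_a) && p$spacing_a > 0, "spacing_a must be > 0")
  chk(is.finite(p$epsilon) && p$epsilon >= 0, "epsilon must be >= 0")
  chk(is.finite(p$decay_length_lambda) && p$decay_length_lambda > 0,
      "decay_length_lambda must be > 0")
  chk(is.finite(p$contact_r0) && p$contact_r0 > 0, "contact_r0 must be > 0")
  chk(p$kernel %in% c("exponential", "power_law_3"),
      "kernel must be 'exponential' or 'power_law_3'")
  chk(!is.na(p$alphabet_size) && p$alphabet_size >= 1L,
      "alphabet_size must be an integer >= 1")
  chk(is.finite(p$theta_max) && p$theta_max > 0 && p$theta_max <= pi / 2 + 1e-12,
      "theta_max must lie in (0, pi/2]")
  chk(!is.na(p$n_angle_bins) && p$n_angle_bins >= 2L,
      "n_angle_bins must be an integer >= 2")
  chk(is.finite(p$k_rot) && p$k_rot > 0, "k_rot must be > 0")
  chk(identical(p$k_off0, 1) || isTRUE(all.equal(p$k_off0, 1)),
      "k_off0 is the time unit and must equal 1")
  invisible(p)
}

#' @export
print.rod_params <- function(x, ...) {
  cat("Rigid-rod pairing model parameters\n")
  cat(sprintf("  %d sites per rod, spacing %.3g nm (rod length %.3g nm)\n",
              x$n_sites, x$spacing_a, x$n_sites * x$spacing_a))
  cat(sprintf("  epsilon = %.3g kBT per matched site, kernel = %s, lambda = %.3g nm, r0 = %.3g nm\n",
              x$epsilon, x$kernel, x$decay_length_lambda, x$contact_r0))
  cat(sprintf("  alphabet size %d (q = %.3g)\n", x$alphabet_size, 1 / x$alphabet_size))
  cat(sprintf("  angle grid: %d bins on [0, %.4g rad]; k_rot = %.3g, k_off0 = %g\n",
              x$n_angle_bins, x$theta_max, x$k_rot, x$k_off0))
  invisible(x)
}

#' Discrete angle grid
#'
#' Uniform grid of collision/rotation angles from 0 (parallel alignment) to
#' `theta_max`.  The bound states of the Markov chain live on this grid; an
#' additional absorbing UNBOUND state is appended by [build_chain()].
#'
#' @param params A [model_params()] object.
#' @return Numeric vector of strictly increasing, uniformly spaced angles
#'   (radians), starting at 0 and ending at `theta_max`.
#' @export
angle_grid <- function(params) {
  seq(0, params$theta_max, length.out = params$n_angle_bins)
}

# 0-based central index; (n-1)/2 for odd n, n/2 - 0.5 for even n.
central_offset <- function(n_sites) (n_sites - 1) / 2

# 1-based central site index; only defined for odd n_sites.
central_site <- function(n_sites) {
  if (n_sites %% 2L == 0L)
    stop("central-site operations require an odd n_sites", call. = FALSE)
  (n_sites + 1L) %/% 2L
}

# Reference grid spacing used to express k_rot (90 bins on [0, pi/2]).
DELTA_THETA_REF <- (pi / 2) / 89
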