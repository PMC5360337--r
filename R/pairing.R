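#' Pair two site sequences
#'
#' A `site_pairing` holds the two sequences and their Boolean match matrix
#' `match[i, j] = (seq_a[i] == seq_b[j])`.  Matched site pairs are the only
#' ones that contribute to the inter-rod attraction.
#'
#' @param seq_a,seq_b Vectors of site symbols (integer or character), equal
#'   length.
#' @return An object of class `"site_pairing"` with elements `seq_a`,
#'   `seq_b`, `match` and `n_sites`.
#' @examples
#' s <- random_sequence(17, 4, rng_seed = 1)
#' pp <- site_pairing(s, s)   # perfect match: diagonal all TRUE
#' all(diag(pp$match))
#' @export
site_pairing <- function(seq_a, seq_b) {
  if (length(seq_a) != length(seq_b))
    stop("seq_a and seq_b must have the same length", call. = FALSE)
  if (length(seq_a) < 1L) stop("sequences must have length >= 1", call. = FALSE)
  structure(
    list(seq_a = seq_a, seq_b = seq_b,
         match = outer(seq_a, seq_b, "=="),
         n_sites = length(seq_a)),
    class = "site_pairing")
}

#' @export
print.site_pairing <- function(x, ...) {
  cat(sprintf("site_pairing: %d sites, %d matched pairs (%d facing)\n",
              x$n_sites, sum(x$match), sum(diag(x$match))))
  invisible(x)
}

#' In-plane coordinates of the binding sites of both rods
#'
#' Rod A lies along the x axis; rod B is rotated by `theta` about the shared
#' collision point at the origin (the rod centers coincide in-plane; the
#' constant out-of-plane offset is folded into `contact_r0`).
#'
#' @param params A [model_params()] object.
#' @param theta Angle between the rods, radians, in `[0, pi]`.
#' @return List with `a` and `b`, each an `n_sites x 2` matrix of (x, y)
#'   coordinates in nm.
#' @export
site_positions <- function(params, theta) {
  if (!is.finite(theta)) stop("theta must be finite", call. = FALSE)
  if (theta < 0 || theta > pi) stop("theta must lie in [0, pi]", call. = FALSE)
  n <- params$n_sites
  s <- (seq_len(n) - 1 - central_offset(n)) * params$spacing_a
  list(a = cbind(x = s, y = rep(0, n)),
       b = cbind(x = s * cos(theta), y = s * sin(theta)))
}

#' Distance between a site on rod A and a site on rod B
#'
#' The in-plane Euclidean distance is combined in quadrature with the
#' closest-approach offset `contact_r0`, so facing sites at the collision
#' point are at distance exactly `contact_r0`.
#'
#' @param params A [model_params()] object.
#' @param i,j Site indices (1-based) on rod A and rod B; may be vectors of
#'   equal length.
#' @param theta Angle between the rods, radians, in `[0, pi]`.
#' @return Distance(s) in nm, always `>= contact_r0`.
#' @export
pair_distance <- function(params, i, j, theta) {
  n <- params$n_sites
  if (any(i < 1L | i > n) || any(j < 1L | j > n))
    stop("site indices out of range", call. = FALSE)
  if (!is.finite(theta) || theta < 0 || theta > pi)
    stop("theta must be finite and in [0, pi]", call. = FALSE)
  a <- params$spacing_a
  c0 <- central_offset(n)
  si <- (i - 1 - c0) * a
  sj <- (j - 1 - c0) * a
  d2 <- (si - sj * cos(theta))^2 + (sj * sin(theta))^2
  sqrt(d2 + params$contact_r0^2)
}

# Radial kernel, normalized so K(contact_r0) = 1.  The inverse-cube form
# diverges at contact, so it is softened by w = decay_length_lambda.
kernel_value <- function(params, r) {
  x <- pmax(r - params$contact_r0, 0)
  switch(params$kernel,
         exponential = exp(-x / params$decay_length_lambda),
         power_law_3 = (params$decay_length_lambda / (x + params$decay_length_lambda))^3)
}

# n^2 x n_theta matrix of kernel values for all site pairs at all grid
# angles; row index runs over (i, j) pairs in column-major order of the
# match matrix.  This is the hot inner object of ensemble computations.
kernel_table <- function(params, thetas = angle_grid(params)) {
  key <- paste(params$n_sites, params$spacing_a, params$contact_r0,
               params$decay_length_lambda, params$kernel,
               length(thetas), thetas[1], thetas[length(thetas)], sep = "|")
  cached <- .rodsearch_cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- params$n_sites
  c0 <- central_offset(n)
  s <- (seq_len(n) - 1 - c0) * params$spacing_a
  si <- rep(s, times = n)       # i varies fastest (column-major (i, j))
  sj <- rep(s, each = n)
  K <- matrix(0, n * n, length(thetas))
  for (t in seq_along(thetas)) {
    th <- thetas[t]
    d2 <- (si - sj * cos(th))^2 + (sj * sin(th))^2
    K[, t] <- kernel_value(params, sqrt(d2 + params$contact_r0^2))
  }
  .rodsearch_cache[[key]] <- K
  K
}

.rodsearch_cache <- new.env(parent = emptyenv())

#' Inter-rod interaction energy at a given angle
#'
#' The energy is the sum over matched site pairs of the attractive kernel,
#' \eqn{U(\theta) = -\epsilon \sum_{(i,j): match} K(r_{ij}(\theta))}, with
#' `K` normalized so that a matched facing pair at contact contributes
#' exactly `-epsilon`.  A pairing with no matched sites has zero energy at
#' every angle.
#'
#' @param pairing A [site_pairing()].
#' @param params A [model_params()] object.
#' @param theta Angle(s) between the rods, radians, in `[0, theta_max]`.
#' @return Energy in \eqn{k_B T}, `<= 0`; vectorized over `theta`.
#' @export
interaction_energy <- function(pairing, params, theta) {
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  if (any(theta < 0 | theta > params$theta_max + 1e-12))
    stop("theta must lie in [0, theta_max]", call. = FALSE)
  if (pairing$n_sites != params$n_sites)
    stop("pairing and params disagree on n_sites", call. = FALSE)
  m <- which(pairing$match)
  if (length(m) == 0L) return(rep(0, length(theta)))
  vapply(theta, function(th) {
    r <- pair_distance(params,
                       i = (m - 1L) %% params$n_sites + 1L,
                       j = (m - 1L) %/% params$n_sites + 1L,
                       theta = th)
    -params$epsilon * sum(kernel_value(params, r))
  }, numeric(1))
}

#' Energy profile over the whole angle grid
#'
#' @param pairing A [site_pairing()].
#' @param params A [model_params()] object.
#' @param thetas Angles to evaluate; defaults to [angle_grid()].
#' @return Numeric vector `U(theta)` in \eqn{k_B T}, one value per angle.
#' @export
energy_profile <- function(pairing, params, thetas = angle_grid(params)) {
  if (pairing$n_sites != params$n_sites)
    stop("pairing and params disagree on n_sites", call. = FALSE)
  energy_from_match(as.vector(pairing$match), kernel_table(params, thetas),
                    params$epsilon)
}

# U over the grid from a logical match vector (column-major) and a kernel
# table; the vectorized path used by all ensemble loops.
energy_from_match <- function(match_vec, ktab, epsilon) {
  if (!any(match_vec)) return(rep(0, ncol(ktab)))
  -epsilon * as.numeric(colSums(ktab[match_vec, , drop = FALSE]))
}

#' Export an energy profile as two-column TSV
#'
#' Writes `theta_rad` and `energy_kBT` columns, with the full parameter set
#' recorded in '#'-prefixed header lines.
#'
#' @param pairing A [site_pairing()].
#' @param params A [model_params()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_energy_profile <- function(pairing, params, path) {
  thetas <- angle_grid(params)
  df <- data.frame(theta_rad = thetas,
                   energy_kBT = energy_profile(pairing, params, thetas))
  write_tsv_commented(df, path, params = params)
}
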