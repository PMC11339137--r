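# Stick-zeppelin-ball forward model.
#
# Three compartments per voxel:
#   * intra-axonal "stick": diffusion along the fiber orientation only,
#     axial diffusivity d_ax_intra, zero radial diffusivity;
#   * extra-axonal "zeppelin": axially symmetric tensor with axial
#     diffusivity d_ax_extra and radial diffusivity d_rad_extra;
#   * free fluid "ball": isotropic diffusion fixed at 3 um^2/ms.
#
# Volume fractions v_intra + v_csf + v_extra = 1. All diffusivities in
# um^2/ms, all b-values here in ms/um^2.

#' Fixed free-fluid diffusivity (um^2/ms)
#'
#' The isotropic diffusivity of the free-water compartment, fixed at
#' 3 um^2/ms (body-temperature free water).
#' @export
D_CSF <- 3

# Spherical mean attenuation factor of exp(-x * cos^2 theta) over the
# sphere: F(x) = sqrt(pi/(4x)) * erf(sqrt(x)), with the series limit
# F(0) = 1. Vectorized in x; x >= 0.
sphere_mean_factor <- function(x) {
  out <- x
  small <- x < 1e-6
  # second-order series around 0: 1 - x/3 + x^2/10
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 10
  xl <- x[!small]
  out[!small] <- sqrt(pi / (4 * xl)) * (2 * stats::pnorm(sqrt(2 * xl)) - 1)
  out
}

# Tortuosity closure for the zeppelin radial diffusivity:
# d_rad = d_ax_extra * (1 - v_intra / (v_intra + v_extra)).
# When the anisotropic fractions vanish the value is immaterial; return
# d_ax_extra (isotropic zeppelin).
tortuosity_drad <- function(v_intra, v_extra, d_ax_extra) {
  tot <- v_intra + v_extra
  frac <- ifelse(tot > 0, v_intra / tot, 0)
  d_ax_extra * (1 - frac)
}

# Compartment decomposition at diffusion weighting b (ms/um^2):
# S(g) = sum_j V_j * a_j * exp(-b * delta_j * (g . n)^2)
# with a_j = exp(-b * dperp_j), delta_j = dpar_j - dperp_j.
# Arguments are equal-length vectors (voxels); returns list of 3-column
# matrices a, delta, v.
compartment_terms <- function(v_intra, v_csf, d_ax_intra, d_ax_extra,
                              d_rad_extra, b) {
  v_extra <- 1 - v_intra - v_csf
  a <- cbind(exp(-b * D_CSF), rep(1, length(v_intra)), exp(-b * d_rad_extra))
  delta <- cbind(rep(0, length(v_intra)), d_ax_intra,
                 d_ax_extra - d_rad_extra)
  v <- cbind(v_csf, v_intra, v_extra)
  list(a = a, delta = delta, v = v)
}

#' Directional stick-zeppelin-ball signal
#'
#' Noise-free normalized signal S/S0 of the three-compartment model for
#' each gradient direction.
#'
#' @param params A list or one-row data.frame with `v_intra`, `v_csf`,
#'   `d_ax_intra`, `d_ax_extra`, `d_rad_extra` (um^2/ms).
#' @param b Diffusion weighting in ms/um^2 (scalar).
#' @param dirs 3 x m matrix of unit gradient directions.
#' @param orient Unit fiber orientation 3-vector.
#' @return Numeric vector of length m with S/S0 in (0, 1].
#' @export
szb_signal <- function(params, b, dirs, orient) {
  stopifnot(b >= 0)
  c2 <- as.vector(crossprod(dirs, orient))^2
  v_extra <- 1 - params$v_intra - params$v_csf
  params$v_csf * exp(-b * D_CSF) +
    params$v_intra * exp(-b * params$d_ax_intra * c2) +
    v_extra * exp(-b * (params$d_rad_extra +
                          (params$d_ax_extra - params$d_rad_extra) * c2))
}

#' Powder-averaged (spherical mean) signal
#'
#' Closed-form mean of the stick-zeppelin-ball signal over uniformly
#' distributed gradient directions at fixed b. This is a rotation-invariant
#' quantity: it depends on compartment fractions and diffusivities only,
#' not on the fiber orientation.
#'
#' @param v_intra,v_csf Volume fractions (vectors allowed).
#' @param d_ax_intra,d_ax_extra,d_rad_extra Diffusivities, um^2/ms.
#' @param b Diffusion weighting, ms/um^2 (scalar, >= 0).
#' @return Mean normalized signal(s) in (0, 1].
#' @export
powder_forward <- function(v_intra, v_csf, d_ax_intra, d_ax_extra,
                           d_rad_extra, b) {
  if (b < 0) stop("b must be non-negative")
  ct <- compartment_terms(v_intra, v_csf, d_ax_intra, d_ax_extra,
                          d_rad_extra, b)
  unname(rowSums(ct$v * ct$a *
                   cbind(sphere_mean_factor(b * ct$delta[, 1]),
                         sphere_mean_factor(b * ct$delta[, 2]),
                         sphere_mean_factor(b * ct$delta[, 3]))))
}

#' Spherical second moment of the signal
#'
#' Closed-form mean of (S/S0)^2 over uniformly distributed directions at
#' fixed b. Together with the spherical mean this captures the directional
#' spread (anisotropy) of the signal as a rotation-invariant feature. The
#' product of two compartment attenuations is again of the form
#' a * exp(-b * delta * cos^2), so the second moment is a sum over
#' compartment pairs of the same spherical factor.
#'
#' @inheritParams powder_forward
#' @return Mean squared normalized signal(s).
#' @export
powder_moment2 <- function(v_intra, v_csf, d_ax_intra, d_ax_extra,
                           d_rad_extra, b) {
  if (b < 0) stop("b must be non-negative")
  ct <- compartment_terms(v_intra, v_csf, d_ax_intra, d_ax_extra,
                          d_rad_extra, b)
  out <- 0
  for (j in 1:3) {
    for (k in 1:3) {
      out <- out + ct$v[, j] * ct$v[, k] * ct$a[, j] * ct$a[, k] *
        sphere_mean_factor(b * (ct$delta[, j] + ct$delta[, k]))
    }
  }
  unname(out)
}

#' Spherical fourth moment of the signal
#'
#' Closed-form mean of (S/S0)^4 over uniformly distributed directions at
#' fixed b: a sum over multisets of four compartments of the same
#' spherical factor as [powder_forward()]. The fourth moment separates
#' parameter combinations that share the spherical mean and second moment
#' (the well-known two-shell degeneracy of the standard model), which is
#' why the microstructure fitter includes it.
#'
#' @inheritParams powder_forward
#' @return Mean fourth power of the normalized signal(s).
#' @export
powder_moment4 <- function(v_intra, v_csf, d_ax_intra, d_ax_extra,
                           d_rad_extra, b) {
  if (b < 0) stop("b must be non-negative")
  ct <- compartment_terms(v_intra, v_csf, d_ax_intra, d_ax_extra,
                          d_rad_extra, b)
  out <- 0
  for (col in seq_len(ncol(MOMENT4_COUNTS))) {
    counts <- MOMENT4_COUNTS[, col]
    term <- MOMENT4_COEFS[col] *
      sphere_mean_factor(b * as.vector(ct$delta %*% counts))
    for (j in 1:3) {
      if (counts[j] > 0) term <- term * (ct$v[, j] * ct$a[, j])^counts[j]
    }
    out <- out + term
  }
  unname(out)
}

# Multisets of size 4 over the 3 compartments (stars-and-bars) and their
# multinomial coefficients, tabulated once.
MOMENT4_COUNTS <- local({
  combos <- utils::combn(3 + 4 - 1, 4)
  apply(combos, 2, function(cc) tabulate(cc - 0:3, 3))
})
MOMENT4_COEFS <- apply(MOMENT4_COUNTS, 2,
                       function(cc) factorial(4) / prod(factorial(cc)))

# Mean of a Rician variate with underlying amplitude S and noise sd
# sigma, via the scaled Bessel representation (numerically stable at
# high SNR). Vectorized in S.
rice_mean <- function(S, sigma) {
  if (sigma <= 0) return(S)
  x <- S^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
       x * besselI(x / 2, 1, expon.scaled = TRUE))
}

# Validate a microstructure parameter set (vectors allowed); used by the
# phantom generator and profile tables.
check_microstructure <- function(v_intra, v_csf, d_ax_intra, d_ax_extra,
                                 d_rad_extra, tol = 1e-9) {
  v_extra <- 1 - v_intra - v_csf
  if (any(v_intra < -tol | v_intra > 1 + tol) ||
      any(v_csf < -tol | v_csf > 1 + tol) || any(v_extra < -tol)) {
    stop("invalid profile: volume fractions must lie in [0, 1] with v_intra + v_csf <= 1")
  }
  if (any(d_ax_intra <= 0 | d_ax_intra > D_CSF) ||
      any(d_ax_extra <= 0 | d_ax_extra > D_CSF)) {
    stop("invalid profile: axial diffusivities must lie in (0, 3] um^2/ms")
  }
  if (any(d_rad_extra <= 0 | d_rad_extra > d_ax_extra + tol)) {
    stop("invalid profile: radial diffusivity must lie in (0, d_ax_extra]")
  }
  invisible(TRUE)
}
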