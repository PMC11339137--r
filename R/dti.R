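# Ordinary log-linear diffusion tensor estimation from the b = 0 and
# b = 1000 s/mm^2 volumes.

# Design matrix rows for ln S = ln S0 - b g' D g:
# [1, -b gx^2, -b gy^2, -b gz^2, -2b gxgy, -2b gxgz, -2b gygz]
tensor_design <- function(bvals_model, bvecs) {
  g <- t(bvecs)
  cbind(1,
        -bvals_model * g[, 1]^2,
        -bvals_model * g[, 2]^2,
        -bvals_model * g[, 3]^2,
        -2 * bvals_model * g[, 1] * g[, 2],
        -2 * bvals_model * g[, 1] * g[, 3],
        -2 * bvals_model * g[, 2] * g[, 3])
}

#' Ordinary log-linear diffusion tensor fit
#'
#' Fits ln S(g, b) = ln S0 - b g'Dg per voxel by ordinary least squares
#' over the b = 0 and b = 1000 s/mm^2 volumes. Volumes at higher shells
#' (b = 2000) are ignored. Voxels with any non-positive signal among the
#' used volumes are flagged invalid rather than failing globally.
#'
#' @param dwi 4D signal array (a `dwi_volume`, or any array with a
#'   `scheme` attribute).
#' @param mask Logical 3D array of voxels to fit; default all voxels with
#'   positive b = 0 signal.
#' @param scheme Acquisition scheme; taken from `attr(dwi, "scheme")` if
#'   missing.
#' @param max_b Largest shell used for the tensor fit, s/mm^2
#'   (default 1000).
#' @return An object of class `tensor_map`: list with `eig` (n_voxels x 3
#'   matrix of eigenvalues, descending, um^2/ms), `tensor` (n_voxels x 6
#'   matrix: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `valid` (logical vector),
#'   `idx` (voxel indices into the 3D grid), `dim`.
#' @export
fit_tensor <- function(dwi, mask = NULL, scheme = attr(dwi, "scheme"),
                       max_b = 1000) {
  if (is.null(scheme)) stop("no acquisition scheme available")
  use <- scheme$bvals <= max_b
  if (sum(scheme$bvals[use] > 0) < 6) {
    stop("at least 6 diffusion-weighted directions are required")
  }
  if (!any(scheme$bvals[use] == 0)) stop("a b = 0 volume is required")

  dims <- dim(dwi)[1:3]
  if (is.null(mask)) {
    mask <- array(dwi[, , , which(scheme$bvals == 0)[1]] > 0, dim = dims)
  }
  idx <- which(mask)
  nvol <- dim(dwi)[4]
  flat <- matrix(dwi, prod(dims), nvol)[idx, use, drop = FALSE]

  valid <- rowSums(flat <= 0) == 0
  X <- tensor_design(b_to_model_units(scheme$bvals[use]), scheme$bvecs[, use])
  coefs <- matrix(NA_real_, length(idx), 7)
  if (any(valid)) {
    lnS <- t(log(flat[valid, , drop = FALSE]))
    coefs[valid, ] <- t(qr.coef(qr(X), lnS))
  }

  eig <- matrix(NA_real_, length(idx), 3)
  for (v in which(valid)) {
    D <- matrix(c(coefs[v, 2], coefs[v, 5], coefs[v, 6],
                  coefs[v, 5], coefs[v, 3], coefs[v, 7],
                  coefs[v, 6], coefs[v, 7], coefs[v, 4]), 3, 3)
    eig[v, ] <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE)
  }
  structure(list(eig = eig, tensor = coefs[, 2:7, drop = FALSE],
                 ln_s0 = coefs[, 1], valid = valid, idx = idx, dim = dims),
            class = "tensor_map")
}

#' Fractional anisotropy and mean diffusivity from a tensor map
#'
#' MD is the eigenvalue mean (raw, negative eigenvalues included); for FA
#' negative eigenvalues are clipped to zero first, and the number of
#' clipped voxels is reported as an attribute. An all-zero tensor has
#' FA 0 by convention.
#'
#' @param tensor A `tensor_map` from [fit_tensor()].
#' @return List with 3D arrays `fa` (unitless, in [0, 1]) and `md`
#'   (um^2/ms); `NA` at invalid/unfitted voxels. The `fa` array carries
#'   attribute `n_clipped`.
#' @export
fa_md <- function(tensor) {
  eig <- tensor$eig
  md_v <- rowMeans(eig)
  clipped <- eig
  neg <- !is.na(eig) & eig < 0
  clipped[neg] <- 0
  mdc <- rowMeans(clipped)
  num <- sqrt(rowSums((clipped - mdc)^2))
  den <- sqrt(rowSums(clipped^2))
  fa_v <- ifelse(den > 0, sqrt(1.5) * num / den, 0)

  fa <- array(NA_real_, dim = tensor$dim)
  md <- array(NA_real_, dim = tensor$dim)
  fa[tensor$idx] <- fa_v
  md[tensor$idx] <- md_v
  attr(fa, "n_clipped") <- sum(rowSums(neg) > 0)
  list(fa = fa, md = md)
}

# FA of an eigenvalue triple (vector of length 3); convenience for
# calibration and tests.
fa_of_eigenvalues <- function(lambda) {
  lambda <- pmax(lambda, 0)
  m <- mean(lambda)
  den <- sqrt(sum(lambda^2))
  if (den == 0) return(0)
  sqrt(1.5) * sqrt(sum((lambda - m)^2)) / den
}

#' Mono-exponential diffusivity fit across shells
#'
#' Ordinary least-squares slope of -ln(S/S0) against b over all shells,
#' for signals from a single voxel. Used e.g. to verify that a pure
#' free-water voxel decays with D = 3 um^2/ms.
#'
#' @param signals Per-volume signals of one voxel.
#' @param scheme Acquisition scheme.
#' @return Fitted diffusivity D in um^2/ms.
#' @export
fit_adc <- function(signals, scheme) {
  b <- b_to_model_units(scheme$bvals)
  keep <- signals > 0
  fit <- stats::lm.fit(cbind(1, -b[keep]), log(signals[keep]))
  unname(fit$coefficients[2])
}

# Noise-free DTI eigenvalues of a single stick-zeppelin-ball parameter
# set under a given scheme (used for FA calibration of phantom profiles).
szb_dti_eigenvalues <- function(params, scheme, orient = c(0, 0, 1),
                                max_b = 1000) {
  use <- scheme$bvals <= max_b
  b_model <- b_to_model_units(scheme$bvals[use])
  s <- vapply(seq_along(b_model), function(j) {
    if (b_model[j] == 0) return(1)
    szb_signal(params, b_model[j], scheme$bvecs[, use][, j, drop = FALSE],
               orient)
  }, numeric(1))
  X <- tensor_design(b_model, scheme$bvecs[, use])
  cf <- qr.coef(qr(X), log(s))
  D <- matrix(c(cf[2], cf[5], cf[6], cf[5], cf[3], cf[7],
                cf[6], cf[7], cf[4]), 3, 3)
  sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# Solve the zeppelin radial diffusivity so that the noise-free log-linear
# DTI fit of a zone's parameters reaches a target FA. FA is monotone
# decreasing in d_rad_extra; returns the solved d_rad (um^2/ms).
solve_drad_for_fa <- function(row, fa_target, scheme, lo = 0.05) {
  hi <- row$d_ax_extra
  f <- function(dr) {
    p <- list(v_intra = row$v_intra, v_csf = row$v_csf,
              d_ax_intra = row$d_ax_intra, d_ax_extra = row$d_ax_extra,
              d_rad_extra = dr)
    fa_of_eigenvalues(szb_dti_eigenvalues(p, scheme)) - fa_target
  }
  if (f(lo) < 0) return(lo)   # target above the achievable maximum
  if (f(hi) > 0) return(hi)   # target below the achievable minimum
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

# Calibrate a subject's per-zone profile so the noise-free DTI FA matches
# the fa_target column, preserving inter-zone FA differences where the
# targets leave the achievable window (the whole FA level is shifted, the
# gradients are not).
calibrate_profile_fa <- function(profile, scheme) {
  zones <- c("IZ", "MZ", "OZ")
  lims <- vapply(zones, function(z) {
    row <- profile[z, ]
    make_p <- function(dr) list(v_intra = row$v_intra, v_csf = row$v_csf,
                                d_ax_intra = row$d_ax_intra,
                                d_ax_extra = row$d_ax_extra, d_rad_extra = dr)
    c(fa_of_eigenvalues(szb_dti_eigenvalues(make_p(row$d_ax_extra), scheme)),
      fa_of_eigenvalues(szb_dti_eigenvalues(make_p(0.05), scheme)))
  }, numeric(2))
  eps <- 0.005
  shift_lo <- max(lims[1, ] + eps - profile[zones, "fa_target"])
  shift_hi <- min(lims[2, ] - eps - profile[zones, "fa_target"])
  shift <- min(max(0, shift_lo), shift_hi)
  profile$fa_target <- profile$fa_target + shift
  for (z in zones) {
    profile[z, "d_rad_extra"] <- solve_drad_for_fa(profile[z, ],
                                                   profile[z, "fa_target"],
                                                   scheme)
  }
  profile
}
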