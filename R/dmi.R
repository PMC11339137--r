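# Three-compartment microstructure estimation from rotation-invariant
# spherical signal features.
#
# Per shell the fitter uses three features of the normalized signal: the
# spherical mean, the spherical second moment and the spherical fourth
# moment over gradient directions. All three depend only on compartment
# fractions and diffusivities (not fiber orientation) and have closed
# forms under the stick-zeppelin-ball model (powder_forward,
# powder_moment2, powder_moment4). The even moments admit exact
# method-of-moments debiasing under magnitude (Rician) noise:
#   E[M^2] = S^2 + 2 s^2
#   E[M^4] = S^4 + 8 s^2 S^2 + 8 s^4          (s = noise sd)
# and the debiased mean follows from the second moment minus the
# directional variance. The fourth moment is essential: two-shell mean +
# second moment alone leave a continuous parameter degeneracy (the
# standard-model two-shell degeneracy). Estimates are posterior means
# over a bounded uniform parameter grid under a Gaussian likelihood on
# the features.

#' Per-shell spherical means of a DWI volume
#'
#' Arithmetic mean over gradient directions within each nonzero shell of
#' S/S0, where S0 is the mean of the b = 0 volumes. No noise debiasing is
#' applied here; see [shell_features()] for the debiased fit features.
#'
#' @param dwi 4D signal array with a `scheme` attribute (or pass `scheme`).
#' @param mask Logical 3D array of voxels to include.
#' @param scheme Acquisition scheme.
#' @return List with `means` (n_voxels x n_shells matrix), `shells`
#'   (b-values, s/mm^2), `n_dirs`, `s0`, `valid` (S0 > 0), `idx`.
#' @export
spherical_mean <- function(dwi, mask = NULL, scheme = attr(dwi, "scheme")) {
  if (is.null(scheme)) stop("no acquisition scheme available")
  if (length(scheme$shells) < 2) stop("at least two nonzero shells are required")
  dims <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  idx <- which(mask)
  flat <- matrix(dwi, prod(dims), dim(dwi)[4])[idx, , drop = FALSE]

  s0 <- rowMeans(flat[, scheme$bvals == 0, drop = FALSE])
  valid <- s0 > 0
  s0[!valid] <- 1
  means <- vapply(scheme$shells, function(b) {
    rowMeans(flat[, scheme$bvals == b, drop = FALSE]) / s0
  }, numeric(length(idx)))
  means <- matrix(means, ncol = length(scheme$shells))
  means[!valid, ] <- NA_real_
  list(means = means, shells = scheme$shells, n_dirs = scheme$dirs_per_shell,
       s0 = s0, valid = valid, idx = idx, dim = dims)
}

#' Debiased rotation-invariant fit features
#'
#' For each nonzero shell, computes the spherical mean, second moment and
#' fourth moment of the normalized magnitude signal, debiased for
#' magnitude (Rician) noise using the exact even-moment relations; with
#' `sigma = 0` the plain sample moments are returned. Per-feature
#' sampling variances (used as likelihood weights) are also derived.
#'
#' @inheritParams spherical_mean
#' @param sigma Noise standard deviation relative to S0. `NULL` estimates
#'   it from the spread of the b = 0 volumes.
#' @return List with `m`, `q`, `r` (n_voxels x n_shells matrices: debiased
#'   mean, second and fourth moment), `sd_m`, `sd_q`, `sd_r` (sampling
#'   standard deviations), `shells_b` (ms/um^2), `n_dirs`, `sigma`,
#'   `valid`, `idx`, `dim`.
#' @export
shell_features <- function(dwi, mask = NULL, scheme = attr(dwi, "scheme"),
                           sigma = NULL) {
  if (is.null(scheme)) stop("no acquisition scheme available")
  dims <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  idx <- which(mask)
  flat <- matrix(dwi, prod(dims), dim(dwi)[4])[idx, , drop = FALSE]

  b0 <- flat[, scheme$bvals == 0, drop = FALSE]
  s0 <- rowMeans(b0)
  valid <- s0 > 0
  s0[!valid] <- 1
  if (is.null(sigma)) {
    # pooled b = 0 repeat variability; at high SNR the magnitude-noise
    # standard deviation is close to the Gaussian one
    sigma <- if (ncol(b0) > 1) {
      sqrt(mean(apply(b0 / s0, 1, stats::var)))
    } else 0
  }
  N <- scheme$dirs_per_shell

  ns <- length(scheme$shells)
  m <- q <- r <- sd_m <- sd_q <- sd_r <- matrix(NA_real_, length(idx), ns)
  for (k in seq_len(ns)) {
    sh <- flat[, scheme$bvals == scheme$shells[k], drop = FALSE] / s0
    raw_m <- rowMeans(sh)
    m2 <- sh^2
    raw_q <- rowMeans(m2)
    raw_r <- rowMeans(m2^2)
    qd <- pmax(raw_q - 2 * sigma^2, 0)
    rd <- pmax(raw_r - 8 * sigma^2 * raw_q + 8 * sigma^4, 0)
    s2 <- pmax(m2 - 2 * sigma^2, 0)        # per-direction S^2 plug-in
    s4 <- rowMeans(s2^2)
    s6 <- rowMeans(s2^3)
    # directional variance of S: total spread of M minus the exact
    # Rician noise variance at the plug-in signal level per direction
    vnoise <- 2 * sigma^2 + s2 - rice_mean(sqrt(s2), sigma)^2
    vd <- pmax(raw_q - raw_m^2 - rowMeans(vnoise), 0)
    m[, k] <- sqrt(pmax(qd - vd, pmax(raw_m - 2 * sigma, 0)^2))
    q[, k] <- qd
    r[, k] <- rd
    sd_m[, k] <- rep(sqrt(sigma^2 / N), length(raw_m))
    sd_q[, k] <- sqrt((4 * sigma^2 * qd + 4 * sigma^4) / N)
    sd_r[, k] <- sqrt((16 * sigma^2 * s6 + 80 * sigma^4 * s4 +
                         128 * sigma^6 * qd + 64 * sigma^8) / N)
  }
  m[!valid, ] <- q[!valid, ] <- r[!valid, ] <- NA_real_
  list(m = m, q = q, r = r, sd_m = sd_m, sd_q = sd_q, sd_r = sd_r,
       shells_b = b_to_model_units(scheme$shells),
       n_dirs = N, sigma = sigma, valid = valid, idx = idx, dim = dims)
}

# Cache of precomputed grids for the current session.
.grid_cache <- new.env(parent = emptyenv())

#' Bounded parameter grid with precomputed forward features
#'
#' Enumerates (v_intra, v_csf) on the unit simplex with step `frac_step`
#' and the axial diffusivities on (0, `d_max`] with step `d_step`; the
#' zeppelin radial diffusivity follows the tortuosity closure. By default
#' the grid carries the standard branch assumption
#' `d_ax_intra >= d_ax_extra` (intra-axonal axial diffusivity at least as
#' large as extra-axonal), which resolves the well-known two-shell branch
#' ambiguity of the model. For every grid point the noise-free spherical
#' mean, second and fourth moments at the shells are precomputed, sorted
#' by the first-shell mean to support windowed likelihood evaluation.
#'
#' @param resolution `"coarse"` (fraction step 0.02, diffusivity step 0.1,
#'   default for cohort work) or `"fine"` (0.02 / 0.05).
#' @param frac_step,d_step Override the named resolutions.
#' @param d_max Upper diffusivity bound, um^2/ms (default 3, the free-water
#'   value).
#' @param shells_b Shell b-values in ms/um^2 (default `c(1, 2)`).
#' @param constrain_branch Keep only `d_ax_intra >= d_ax_extra` points
#'   (default TRUE).
#' @return An object of class `dmi_grid`.
#' @export
dmi_grid <- function(resolution = c("coarse", "fine"), frac_step = NULL,
                     d_step = NULL, d_max = 3, shells_b = c(1, 2),
                     constrain_branch = TRUE) {
  resolution <- match.arg(resolution)
  if (is.null(frac_step)) frac_step <- 0.02
  if (is.null(d_step)) d_step <- if (resolution == "fine") 0.05 else 0.1
  key <- paste(frac_step, d_step, d_max, paste(shells_b, collapse = "_"),
               constrain_branch, sep = "|")
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])

  fr <- seq(0, 1, by = frac_step)
  fpairs <- expand.grid(v_intra = fr, v_csf = fr)
  fpairs <- fpairs[fpairs$v_intra + fpairs$v_csf <= 1 + 1e-12, ]
  dv <- seq(d_step, d_max, by = d_step)
  dd <- expand.grid(d_ax_intra = dv, d_ax_extra = dv)
  if (constrain_branch) dd <- dd[dd$d_ax_intra >= dd$d_ax_extra, ]

  nf <- nrow(fpairs)
  nd <- nrow(dd)
  params <- cbind(v_intra = rep(fpairs$v_intra, times = nd),
                  v_csf = rep(fpairs$v_csf, times = nd),
                  d_ax_intra = rep(dd$d_ax_intra, each = nf),
                  d_ax_extra = rep(dd$d_ax_extra, each = nf))
  v_extra <- 1 - params[, 1] - params[, 2]
  d_rad <- tortuosity_drad(params[, 1], v_extra, params[, 4])

  feat <- matrix(NA_real_, nrow(params), 3 * length(shells_b))
  for (k in seq_along(shells_b)) {
    feat[, 3 * k - 2] <- powder_forward(params[, 1], params[, 2],
                                        params[, 3], params[, 4], d_rad,
                                        shells_b[k])
    feat[, 3 * k - 1] <- powder_moment2(params[, 1], params[, 2],
                                        params[, 3], params[, 4], d_rad,
                                        shells_b[k])
    feat[, 3 * k] <- powder_moment4(params[, 1], params[, 2],
                                    params[, 3], params[, 4], d_rad,
                                    shells_b[k])
  }
  ord <- order(feat[, 1])
  g <- structure(list(params = params[ord, , drop = FALSE],
                      d_rad = d_rad[ord],
                      feat = feat[ord, , drop = FALSE],
                      m1_sorted = feat[ord, 1],
                      shells_b = shells_b, frac_step = frac_step,
                      d_step = d_step, d_max = d_max),
                 class = "dmi_grid")
  .grid_cache[[key]] <- g
  g
}

#' @export
print.dmi_grid <- function(x, ...) {
  cat("DMI parameter grid:", nrow(x$params), "points",
      sprintf("(fraction step %.3g, diffusivity step %.3g, shells %s ms/um^2)\n",
              x$frac_step, x$d_step, paste(x$shells_b, collapse = ", ")))
  invisible(x)
}

# Forward feature vector (m, q, r per shell) for a single parameter set
# theta = (v_intra, v_csf, d_ax_intra, d_ax_extra) under the tortuosity
# closure.
szb_features <- function(theta, shells_b) {
  dr <- tortuosity_drad(theta[1], 1 - theta[1] - theta[2], theta[4])
  out <- numeric(3 * length(shells_b))
  for (k in seq_along(shells_b)) {
    b <- shells_b[k]
    out[3 * k - 2] <- powder_forward(theta[1], theta[2], theta[3],
                                     theta[4], dr, b)
    out[3 * k - 1] <- powder_moment2(theta[1], theta[2], theta[3],
                                     theta[4], dr, b)
    out[3 * k] <- powder_moment4(theta[1], theta[2], theta[3],
                                 theta[4], dr, b)
  }
  out
}

# Grid stage for one feature vector x with per-feature standard
# deviations sds: windowed on the first-shell mean for speed, falling
# back to the full grid if the best match inside the window is poor.
# Returns the posterior mean, basin representatives among the lowest
# deviance points (candidate starts for refinement), and the posterior
# spread.
grid_posterior_voxel <- function(grid, x, sds, window_k = 8) {
  n <- nrow(grid$feat)
  nf <- length(x)
  # plain binary search; findInterval revalidates the sorted vector on
  # every call, which dominates at this grid size
  bsearch <- function(v) {
    lo <- 0L
    hi <- n + 1L
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (grid$m1_sorted[mid] <= v) lo <- mid else hi <- mid
    }
    lo
  }
  w <- window_k * max(sds[1], 2e-3 * x[1])
  lo <- bsearch(x[1] - w) + 1L
  hi <- bsearch(x[1] + w)
  if (hi - lo < 200L) {  # make sure the slice is not degenerate
    mid <- bsearch(x[1])
    lo <- max(1L, mid - 100L)
    hi <- min(n, mid + 100L)
  }
  repeat {
    sl <- lo:hi
    # cheap second-feature prefilter before the full deviance
    keep <- abs(grid$feat[sl, 2] - x[2]) <=
      max(window_k * sds[2], 2e-2 * x[2])
    if (sum(keep) >= 50L) sl <- sl[keep]
    dev <- 0
    for (f in seq_len(nf)) {
      dev <- dev + ((grid$feat[sl, f] - x[f]) / sds[f])^2
    }
    best <- which.min(dev)
    if (dev[best] < 50 * nf || (lo == 1L && hi == n)) break
    lo <- 1L
    hi <- n
  }
  wts <- exp(-0.5 * (dev - dev[best]))
  s <- sum(wts)
  est <- as.vector(crossprod(wts, grid$params[sl, , drop = FALSE])) / s
  post_var <- sum(wts * (grid$params[sl, 1] - est[1])^2) / s
  # basin representatives: lowest-deviance points, deduplicated on a
  # coarse parameter rounding so distinct likelihood basins each appear
  top <- sl[order(dev)[seq_len(min(200L, length(sl)))]]
  key <- paste(round(grid$params[top, 1] * 10),
               round(grid$params[top, 2] * 10),
               round(grid$params[top, 3] * 2),
               round(grid$params[top, 4] * 2))
  reps <- top[!duplicated(key)][seq_len(min(3L, sum(!duplicated(key))))]
  list(post_mean = est, starts = grid$params[reps, , drop = FALSE],
       best_dev = dev[best], post_sd_vintra = sqrt(post_var))
}

# Internal fit coordinates: (v_intra, f_csf, d_ax_intra, g) with
# v_csf = f_csf * (1 - v_intra) and d_ax_extra = g * d_ax_intra, so the
# fraction simplex and the branch constraint d_ax_extra <= d_ax_intra
# become box bounds.
theta_to_internal <- function(theta) {
  c(theta[1], theta[2] / max(1 - theta[1], 1e-9), theta[3],
    theta[4] / theta[3])
}
internal_to_theta <- function(u) {
  c(u[1], u[2] * (1 - u[1]), u[3], u[4] * u[3])
}

# Continuous refinement: bounded Levenberg-Marquardt on the weighted
# feature residuals in internal coordinates, seeded from a grid-stage
# basin. Returns c(theta, deviance).
refine_voxel <- function(x, sds, start, grid) {
  resid_fun <- function(u) {
    th <- internal_to_theta(u)
    (szb_features(th, grid$shells_b) - x) / sds
  }
  u0 <- pmin(pmax(theta_to_internal(start), c(0, 0, 0.02, 0.01)),
             c(1, 1, grid$d_max, 1))
  fit <- tryCatch(
    minpack.lm::nls.lm(u0, lower = c(0, 0, 0.02, 0.01),
                       upper = c(1, 1, grid$d_max, 1),
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(c(start, sum(((szb_features(start, grid$shells_b) - x) / sds)^2)))
  }
  c(internal_to_theta(fit$par), sum(fit$fvec^2))
}

# Full single-voxel estimate. With refine = FALSE (the default for noisy
# data) the noise-matched grid posterior mean is returned — the
# minimum-mean-square estimate under the uniform grid prior. With
# refine = TRUE (default for noise-free features) the lowest-deviance
# likelihood basins are additionally polished by lattice zoom, which
# drives exact features to near-exact parameter recovery.
# Returns c(params(4), resid, post_sd_vintra).
posterior_mean_voxel <- function(grid, x, sds, refine = FALSE) {
  gp <- grid_posterior_voxel(grid, x, sds)
  nf <- length(x)
  if (!refine) {
    return(c(gp$post_mean, sqrt(gp$best_dev / nf), gp$post_sd_vintra))
  }
  best <- NULL
  for (i in seq_len(nrow(gp$starts))) {
    r <- refine_voxel(x, sds, gp$starts[i, ], grid)
    if (is.null(best) || r[5] < best[5]) best <- r
  }
  c(best[1:4], sqrt(max(best[5], 0) / nf), gp$post_sd_vintra)
}

#' Fit three-compartment microstructure from shell features
#'
#' Posterior-mean estimates of (v_intra, v_csf, d_ax_intra, d_ax_extra)
#' over a bounded uniform grid, per voxel. The Gaussian feature
#' likelihood uses the per-voxel feature variances computed by
#' [shell_features()]; for noise-free input a small relative floor keeps
#' the posterior proper. Voxels with identical features (to 5 significant
#' digits) are fitted once.
#'
#' @param features Output of [shell_features()].
#' @param grid A [dmi_grid()] (default coarse).
#' @param refine Polish each estimate by a constrained Levenberg-
#'   Marquardt least-squares refinement seeded from the likelihood
#'   basins of the grid stage. Default `NULL`: refine only noise-free
#'   features (`sigma == 0`), where the refinement recovers parameters
#'   to well below one grid step; noisy voxels use the tempered grid
#'   posterior mean.
#' @param temper Likelihood tempering factor applied to the feature
#'   standard deviations of noisy voxels (default 0.25). Sharpening the
#'   likelihood moves the posterior mean from the prior-shrunk Bayes
#'   estimate toward the maximum-likelihood solution, trading a little
#'   per-voxel variance (absorbed by zone averaging) for a much smaller
#'   systematic bias.
#' @return A data.frame with one row per voxel of `features`: `v_intra`,
#'   `v_csf`, `v_extra`, `d_ax_intra`, `d_ax_extra`, `resid` (root mean
#'   squared standardized feature residual), `post_sd_vintra`, `valid`.
#' @export
fit_dmi <- function(features, grid = dmi_grid("coarse"), refine = NULL,
                    temper = 0.25) {
  stopifnot(length(features$shells_b) == length(grid$shells_b),
            all(features$shells_b == grid$shells_b))
  if (is.null(refine)) refine <- features$sigma == 0
  ns <- length(grid$shells_b)
  nvox <- nrow(features$m)
  X <- SD <- matrix(NA_real_, nvox, 3 * ns)
  for (k in seq_len(ns)) {
    X[, 3 * k - 2] <- features$m[, k]
    X[, 3 * k - 1] <- features$q[, k]
    X[, 3 * k] <- features$r[, k]
    SD[, 3 * k - 2] <- features$sd_m[, k]
    SD[, 3 * k - 1] <- features$sd_q[, k]
    SD[, 3 * k] <- features$sd_r[, k]
  }
  # tempering, then a relative floor guarding the noise-free case and
  # direction-sampling error
  SD <- pmax(SD * temper, 2e-3 * abs(X), 1e-9)
  ok <- features$valid & rowSums(is.na(X)) == 0 &
    X[, 1] <= 1.2 & X[, 1] >= 0 & X[, 3 * ns - 2] <= 1.2

  out <- matrix(NA_real_, nvox, 6)
  if (any(ok)) {
    keydf <- cbind(signif(X[ok, , drop = FALSE], 5),
                   signif(SD[ok, , drop = FALSE], 3))
    key <- do.call(paste, c(as.data.frame(keydf), sep = "|"))
    first <- !duplicated(key)
    fit1 <- t(apply(keydf[first, , drop = FALSE], 1, function(row) {
      posterior_mean_voxel(grid, row[seq_len(3 * ns)],
                           row[3 * ns + seq_len(3 * ns)], refine = refine)
    }))
    out[which(ok), ] <- fit1[match(key, key[first]), , drop = FALSE]
  }
  # boundary canonicalization: a stick-free zeppelin whose axial
  # diffusivity reaches the free-water value is isotropic at 3 um^2/ms
  # under the tortuosity closure and therefore indistinguishable from
  # free water; report such volume as V-CSF
  iso_fw <- !is.na(out[, 1]) & out[, 1] < 0.02 & out[, 4] > 2.9
  out[iso_fw, 2] <- 1 - out[iso_fw, 1]
  data.frame(v_intra = out[, 1], v_csf = out[, 2],
             v_extra = 1 - out[, 1] - out[, 2],
             d_ax_intra = out[, 3], d_ax_extra = out[, 4],
             resid = out[, 5], post_sd_vintra = out[, 6],
             valid = ok & !is.na(out[, 1]))
}

#' Fit a single voxel from its spherical moments
#'
#' Convenience wrapper around [fit_dmi()] for one voxel.
#'
#' @param m,q,r Spherical mean, second and fourth moment per shell
#'   (length 2, for shells at 1 and 2 ms/um^2).
#' @param sigma Noise level relative to S0 (0 for noise-free features).
#' @param n_dirs Directions per shell the features were averaged over.
#' @param grid A [dmi_grid()].
#' @return One-row data.frame (see [fit_dmi()]).
#' @export
fit_voxel <- function(m, q, r, sigma = 0, n_dirs = 58,
                      grid = dmi_grid("fine"), refine = NULL) {
  ns <- length(grid$shells_b)
  stopifnot(length(m) == ns, length(q) == ns, length(r) == ns)
  s6 <- q * r / pmax(m^2, 1e-12)  # rough plug-in for the 6th moment scale
  features <- list(m = matrix(m, 1), q = matrix(q, 1), r = matrix(r, 1),
                   sd_m = matrix(sqrt(sigma^2 / n_dirs), 1, ns),
                   sd_q = matrix(sqrt((4 * sigma^2 * q + 4 * sigma^4) /
                                        n_dirs), 1),
                   sd_r = matrix(sqrt((16 * sigma^2 * s6 +
                                         80 * sigma^4 * r) / n_dirs), 1),
                   shells_b = grid$shells_b, n_dirs = n_dirs,
                   sigma = sigma, valid = TRUE, idx = 1L,
                   dim = c(1L, 1L, 1L))
  fit_dmi(features, grid = grid, refine = refine)
}

#' Fit microstructure maps for a masked DWI volume
#'
#' Full wrapper: computes debiased shell features and fits every voxel in
#' the mask.
#'
#' @param dwi 4D `dwi_volume`.
#' @param mask Logical 3D array.
#' @param grid A [dmi_grid()].
#' @param sigma Noise level relative to S0 (`NULL` to estimate from the
#'   b = 0 volumes).
#' @return List of 3D arrays `v_intra`, `v_csf`, `v_extra`, `d_ax_intra`,
#'   `d_ax_extra`, `resid` (`NA` outside the mask / invalid voxels).
#' @export
fit_dmi_volume <- function(dwi, mask, grid = dmi_grid("coarse"),
                           sigma = NULL, refine = NULL) {
  features <- shell_features(dwi, mask, sigma = sigma)
  fits <- fit_dmi(features, grid = grid, refine = refine)
  maps <- lapply(c("v_intra", "v_csf", "v_extra", "d_ax_intra",
                   "d_ax_extra", "resid"), function(p) {
    a <- array(NA_real_, dim = features$dim)
    a[features$idx] <- fits[[p]]
    a
  })
  names(maps) <- c("v_intra", "v_csf", "v_extra", "d_ax_intra",
                   "d_ax_extra", "resid")
  maps
}
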