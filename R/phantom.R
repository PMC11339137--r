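#' Phantom specification
#'
#' Describes a single synthetic subject: a spherical contrast-enhancing
#' core surrounded by an edema shell on a regular voxel grid, with a
#' per-zone microstructure profile and an acquisition noise level.
#'
#' @param dim Grid shape in voxels (length 3, default `c(20, 20, 20)`).
#' @param spacing Voxel spacing in mm (length 3, default 1.5 mm isotropic;
#'   use `c(1.5, 1.5, 3)` for acquisition-resolution phantoms).
#' @param r_core Core radius in mm.
#' @param r_edema Outer edema radius in mm (must exceed `r_core`).
#' @param profile A per-zone parameter table (see [zone_profile_table()]),
#'   or a group profile name (`"gbm-like"` or `"met-like"`) whose printed
#'   central values are used for all subjects.
#' @param snr Signal-to-noise ratio at b = 0 (default 30).
#' @param noise Noise model: `"rician"` (magnitude MRI, default),
#'   `"gaussian"` (for analytic checks), or `"none"`.
#' @param orient Unit fiber orientation (length 3), `"curved"` for a
#'   tangential orientation field around the lesion, or `NULL` to draw a
#'   random orientation from the seed.
#' @param gm_plane_mm If numeric, voxels with x-coordinate (mm, from grid
#'   center) beyond this value and outside the lesion are labeled gray
#'   matter, to exercise the gray-matter exclusion logic. `NULL` for none.
#' @param smooth Logical; `TRUE` interpolates zone values radially across
#'   the edema, `FALSE` (default) assigns hard per-tertile constants.
#' @param seed Integer random seed for noise and any profile draws.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(20, 20, 20), spacing = c(1.5, 1.5, 1.5),
                         r_core = 4.5, r_edema = 10.5,
                         profile = "gbm-like", snr = 30,
                         noise = c("rician", "gaussian", "none"),
                         orient = NULL, gm_plane_mm = NULL,
                         smooth = FALSE, seed = 1L) {
  noise <- match.arg(noise)
  if (r_core <= 0 || r_edema <= 0) stop("radii must be positive")
  if (r_core >= r_edema) stop("core radius must be smaller than edema outer radius")
  if (snr <= 0) stop("invalid noise level: snr must be positive")
  half_extent <- min(dim * spacing) / 2
  if (r_edema > half_extent) stop("edema radius does not fit within the grid")
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 r_core = r_core, r_edema = r_edema, profile = profile,
                 snr = snr, noise = noise, orient = orient,
                 gm_plane_mm = gm_plane_mm, smooth = smooth,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Tissue label codes shared across the package.
LABELS <- c(background = 0L, core = 1L, edema = 2L, gray_matter = 3L,
            white_matter = 4L)

# Voxel-center coordinates (mm) relative to the grid center, as an
# n_voxels x 3 matrix in array (column-major) order.
voxel_centers <- function(dim, spacing) {
  ax <- lapply(1:3, function(k) (seq_len(dim[k]) - (dim[k] + 1) / 2) * spacing[k])
  cbind(rep(ax[[1]], times = dim[2] * dim[3]),
        rep(rep(ax[[2]], each = dim[1]), times = dim[3]),
        rep(ax[[3]], each = dim[1] * dim[2]))
}

#' Synthesize the tissue label volume
#'
#' Voxels whose centers lie within `r_core` of the grid center become
#' enhancing core; voxels within `r_edema` (excluding core) become edema;
#' optionally a gray-matter half-space is placed beyond `gm_plane_mm`;
#' everything else is normal white matter.
#'
#' @param spec A [phantom_spec()].
#' @return A 3D integer array of labels (0 background, 1 core, 2 edema,
#'   3 gray matter, 4 white matter) with attributes `spacing` and
#'   `label_codes`.
#' @export
make_labels <- function(spec) {
  ctr <- voxel_centers(spec$dim, spec$spacing)
  r <- sqrt(rowSums(ctr^2))
  lab <- rep(LABELS[["white_matter"]], nrow(ctr))
  lab[r <= spec$r_edema] <- LABELS[["edema"]]
  lab[r <= spec$r_core] <- LABELS[["core"]]
  if (!is.null(spec$gm_plane_mm)) {
    gm <- ctr[, 1] > spec$gm_plane_mm & lab == LABELS[["white_matter"]]
    lab[gm] <- LABELS[["gray_matter"]]
  }
  if (!any(lab == LABELS[["core"]])) stop("degenerate geometry: core contains no voxels")
  if (!any(lab == LABELS[["edema"]])) {
    stop("degenerate geometry: edema shell contains no voxels")
  }
  lab <- array(as.integer(lab), dim = spec$dim)
  attr(lab, "spacing") <- spec$spacing
  attr(lab, "label_codes") <- LABELS
  lab
}

# Reference microstructure for non-edema tissue. Values are plausible
# healthy/tumor settings; they surround the edema but carry no
# calibration targets.
TISSUE_DEFAULTS <- list(
  white_matter = list(v_intra = 0.40, v_csf = 0.03, d_ax_intra = 2.30,
                      d_ax_extra = 2.00, d_rad_extra = NA),
  gray_matter  = list(v_intra = 0.15, v_csf = 0.10, d_ax_intra = 2.00,
                      d_ax_extra = 1.20, d_rad_extra = NA),
  core         = list(v_intra = 0.05, v_csf = 0.20, d_ax_intra = 2.00,
                      d_ax_extra = 1.50, d_rad_extra = NA)
)

#' Per-zone microstructure table for a named tissue profile
#'
#' Central per-zone values for the edema of each tumor entity. Inner-zone
#' values and outer-minus-inner gradients follow the published group
#' summaries for glioblastoma-like and metastasis-like edema; the middle
#' zone is the midpoint. `d_rad_extra = NA` requests the tortuosity
#' closure `d_ax_extra * (1 - v_intra / (v_intra + v_extra))`.
#'
#' @param profile `"gbm-like"` or `"met-like"`.
#' @return A data.frame with rows IZ, MZ, OZ and columns `v_intra`,
#'   `v_csf`, `d_ax_intra`, `d_ax_extra`, `d_rad_extra`, `fa_target`.
#' @export
zone_profile_table <- function(profile = c("gbm-like", "met-like")) {
  profile <- match.arg(profile)
  p <- group_profile(profile)
  zones_from_draw(vapply(p, function(m) m$mean, numeric(1)),
                  vapply(p, function(m) m$grad_mean, numeric(1)))
}

# Group-level calibration: inner-zone mean/SD and OZ-IZ gradient mean/SD
# per parameter. Central values and dispersions are taken from the
# published group summaries (SD of median[IQR] entries via IQR/1.349);
# entries without a printed counterpart are documented choices.
group_profile <- function(profile) {
  switch(profile,
    "gbm-like" = list(
      v_intra    = list(mean = 0.08, sd = 0.030, grad_mean =  0.010, grad_sd = 0.0200),
      v_csf      = list(mean = 0.48, sd = 0.120, grad_mean = -0.010, grad_sd = 0.0400),
      d_ax_intra = list(mean = 2.29, sd = 0.022, grad_mean = -0.008, grad_sd = 0.0114),
      d_ax_extra = list(mean = 1.22, sd = 0.030, grad_mean = -0.010, grad_sd = 0.0237),
      fa         = list(mean = 0.19, sd = 0.040, grad_mean =  0.003, grad_sd = 0.0400)),
    "met-like" = list(
      v_intra    = list(mean = 0.09, sd = 0.030, grad_mean =  0.005, grad_sd = 0.0200),
      v_csf      = list(mean = 0.55, sd = 0.120, grad_mean = -0.005, grad_sd = 0.0400),
      d_ax_intra = list(mean = 2.28, sd = 0.022, grad_mean =  0.002, grad_sd = 0.0096),
      d_ax_extra = list(mean = 1.24, sd = 0.030, grad_mean =  0.010, grad_sd = 0.0200),
      fa         = list(mean = 0.18, sd = 0.040, grad_mean =  0.030, grad_sd = 0.0500)),
    stop("unknown profile: ", profile)
  )
}

# Build an IZ/MZ/OZ table from per-parameter inner-zone values and
# OZ-IZ gradients (MZ at the midpoint).
zones_from_draw <- function(base, grad) {
  zone_of <- function(t) {
    v_intra <- base[["v_intra"]] + t * grad[["v_intra"]]
    v_csf <- base[["v_csf"]] + t * grad[["v_csf"]]
    data.frame(v_intra = v_intra, v_csf = v_csf,
               d_ax_intra = base[["d_ax_intra"]] + t * grad[["d_ax_intra"]],
               d_ax_extra = base[["d_ax_extra"]] + t * grad[["d_ax_extra"]],
               d_rad_extra = NA_real_,
               fa_target = base[["fa"]] + t * grad[["fa"]])
  }
  tab <- rbind(zone_of(0), zone_of(0.5), zone_of(1))
  rownames(tab) <- c("IZ", "MZ", "OZ")
  tab
}

# Shift a (base, base + grad) pair into [lo, hi] preserving the gradient;
# the gradient itself is clipped only if it exceeds the feasible span.
shift_into_bounds <- function(base, grad, lo, hi) {
  grad <- max(min(grad, hi - lo), lo - hi)
  base <- min(max(base, lo, lo - min(grad, 0)), hi - max(grad, 0))
  c(base, base + grad)
}

# Draw one subject's per-zone table from a group profile. Gradients are
# preserved exactly under the feasibility clamps so that cohort gradient
# distributions match the calibration. `z` supplies the standard-normal
# scores (named base/grad per parameter), enabling antithetic cohort
# draws; NULL draws fresh scores.
draw_subject_profile <- function(profile_name, z = NULL) {
  p <- group_profile(profile_name)
  if (is.null(z)) z <- stats::rnorm(2 * length(p))
  z <- matrix(z, nrow = 2)
  lims <- list(v_intra = c(0.01, 0.60), v_csf = c(0.02, 0.90),
               d_ax_intra = c(0.50, 2.99), d_ax_extra = c(0.30, 2.80),
               fa = c(0.02, 0.60))
  base <- grad <- numeric(0)
  for (j in seq_along(p)) {
    nm <- names(p)[j]
    b <- p[[nm]]$mean + p[[nm]]$sd * z[1, j]
    g <- p[[nm]]$grad_mean + p[[nm]]$grad_sd * z[2, j]
    izoz <- shift_into_bounds(b, g, lims[[nm]][1], lims[[nm]][2])
    base[nm] <- izoz[1]
    grad[nm] <- izoz[2] - izoz[1]
  }
  # keep the fraction simplex valid in every zone, preserving v_intra
  for (t in c(0, 1)) {
    tot <- (base[["v_intra"]] + t * grad[["v_intra"]]) +
      (base[["v_csf"]] + t * grad[["v_csf"]])
    if (tot > 0.95) {
      base[["v_csf"]] <- base[["v_csf"]] - (tot - 0.95)
    }
  }
  zones_from_draw(base, grad)
}

#' Assign ground-truth microstructure from a per-zone profile
#'
#' Edema voxels receive parameter values from the zone table: either hard
#' per-tertile constants (`smooth = FALSE`; tertiles of the Euclidean
#' distance from the core outline, matching the zonation rule) or radial
#' interpolation between the IZ value at the core boundary and the OZ
#' value at the outer edema boundary (`smooth = TRUE`). Core, gray- and
#' white-matter voxels receive fixed reference values.
#'
#' @param labels Label volume from [make_labels()].
#' @param profile Per-zone table as returned by [zone_profile_table()].
#' @param smooth Interpolate radially instead of hard tertile constants.
#' @param orient Unit fiber orientation 3-vector, or `"curved"` for a
#'   tangential field around the grid center.
#' @return An object of class `microstructure_truth`: a list of 3D arrays
#'   `v_intra`, `v_csf`, `v_extra`, `d_ax_intra`, `d_ax_extra`,
#'   `d_rad_extra`, plus `orient` (3-vector or 3-column matrix per voxel)
#'   and `spacing`.
#' @export
assign_microstructure <- function(labels, profile, smooth = FALSE,
                                  orient = c(0, 0, 1)) {
  spacing <- attr(labels, "spacing")
  if (is.null(spacing)) stop("labels must carry a 'spacing' attribute")
  for (z in c("IZ", "MZ", "OZ")) {
    row <- profile[z, ]
    if (row$v_intra + row$v_csf > 1) {
      stop("invalid profile: v_intra + v_csf exceeds 1 in zone ", z)
    }
  }
  params <- c("v_intra", "v_csf", "d_ax_intra", "d_ax_extra", "d_rad_extra")
  maps <- lapply(params, function(p) array(NA_real_, dim = dim(labels)))
  names(maps) <- params

  fill <- function(mask, values) {
    for (p in params) maps[[p]][mask] <<- values[[p]]
  }
  for (tissue in names(TISSUE_DEFAULTS)) {
    td <- TISSUE_DEFAULTS[[tissue]]
    if (is.na(td$d_rad_extra)) {
      td$d_rad_extra <- tortuosity_drad(td$v_intra, 1 - td$v_intra - td$v_csf,
                                        td$d_ax_extra)
    }
    fill(labels == LABELS[[tissue]], td)
  }

  edema <- labels == LABELS[["edema"]]
  core <- labels == LABELS[["core"]]
  d <- distance_from_core(core, edema, spacing)
  zrows <- lapply(c("IZ", "MZ", "OZ"), function(z) {
    row <- as.list(profile[z, params])
    if (is.na(row$d_rad_extra)) {
      row$d_rad_extra <- tortuosity_drad(row$v_intra,
                                         1 - row$v_intra - row$v_csf,
                                         row$d_ax_extra)
    }
    row
  })
  names(zrows) <- c("IZ", "MZ", "OZ")
  if (smooth) {
    # t = 0 at the core boundary, 1 at the outer edema boundary
    dmin <- min(d)
    t <- if (max(d) > dmin) (d - dmin) / (max(d) - dmin) else rep(0, length(d))
    for (p in params) {
      maps[[p]][edema] <- zrows$IZ[[p]] + t * (zrows$OZ[[p]] - zrows$IZ[[p]])
    }
  } else {
    zone <- tertile_bands(d)
    for (k in 1:3) {
      sel <- which(edema)[zone == k]
      for (p in params) maps[[p]][sel] <- zrows[[k]][[p]]
    }
  }

  check_microstructure(maps$v_intra[labels > 0], maps$v_csf[labels > 0],
                       maps$d_ax_intra[labels > 0], maps$d_ax_extra[labels > 0],
                       maps$d_rad_extra[labels > 0])
  maps$v_extra <- 1 - maps$v_intra - maps$v_csf
  if (identical(orient, "curved")) {
    orient <- tangential_field(dim(labels), spacing)
  } else {
    orient <- orient / sqrt(sum(orient^2))
  }
  structure(c(maps, list(orient = orient, spacing = spacing,
                         profile = profile)),
            class = "microstructure_truth")
}

# Tangential orientation field: unit vectors perpendicular to the radial
# direction (circling the z-axis); degenerate on-axis voxels fall back to x.
tangential_field <- function(dim, spacing) {
  ctr <- voxel_centers(dim, spacing)
  tang <- cbind(-ctr[, 2], ctr[, 1], 0)
  nrm <- sqrt(rowSums(tang^2))
  bad <- nrm < 1e-9
  tang[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE)
  nrm[bad] <- 1
  tang / nrm
}

#' Synthesize a noisy two-shell DWI volume
#'
#' Evaluates the stick-zeppelin-ball signal for every voxel with complete
#' ground-truth parameters at every scheme volume, then applies magnitude
#' (Rician) noise with sigma = S0 / snr. The b = 0 intensity is 1.
#'
#' @param truth A `microstructure_truth` from [assign_microstructure()].
#' @param scheme A [make_scheme()] acquisition scheme.
#' @param snr Signal-to-noise ratio at b = 0; must be positive.
#' @param seed Integer seed; identical seeds give identical output.
#' @param noise `"rician"`, `"gaussian"`, or `"none"`.
#' @return A 4D array (x, y, z, volume) of class `dwi_volume` with
#'   attributes `scheme`, `spacing`, and `S0`.
#' @export
synthesize_signal <- function(truth, scheme, snr = 30, seed = 1L,
                              noise = c("rician", "gaussian", "none")) {
  noise <- match.arg(noise)
  if (snr <= 0) stop("invalid noise level: snr must be positive")
  dims <- dim(truth$v_intra)
  nvox <- prod(dims)
  mask <- !is.na(truth$v_intra)
  idx <- which(mask)

  p <- list(v_intra = truth$v_intra[idx], v_csf = truth$v_csf[idx],
            d_ax_intra = truth$d_ax_intra[idx],
            d_ax_extra = truth$d_ax_extra[idx],
            d_rad_extra = truth$d_rad_extra[idx])
  v_extra <- 1 - p$v_intra - p$v_csf
  if (is.matrix(truth$orient)) {
    orient <- truth$orient[idx, , drop = FALSE]
  } else {
    orient <- matrix(truth$orient, nrow = length(idx), ncol = 3, byrow = TRUE)
  }

  nvol <- n_volumes(scheme)
  sig <- matrix(0, length(idx), nvol)
  b_model <- b_to_model_units(scheme$bvals)
  for (j in seq_len(nvol)) {
    b <- b_model[j]
    if (b == 0) {
      sig[, j] <- 1
      next
    }
    g <- scheme$bvecs[, j]
    c2 <- (orient %*% g)^2
    sig[, j] <- p$v_csf * exp(-b * D_CSF) +
      p$v_intra * exp(-b * p$d_ax_intra * c2) +
      v_extra * exp(-b * (p$d_rad_extra +
                            (p$d_ax_extra - p$d_rad_extra) * c2))
  }

  if (noise != "none") {
    set.seed(seed)
    sigma <- 1 / snr
    n1 <- matrix(stats::rnorm(length(sig), 0, sigma), nrow(sig))
    if (noise == "rician") {
      n2 <- matrix(stats::rnorm(length(sig), 0, sigma), nrow(sig))
      sig <- sqrt((sig + n1)^2 + n2^2)
    } else {
      sig <- pmax(sig + n1, 0)
    }
  }

  out <- array(0, dim = c(dims, nvol))
  flat <- matrix(out, nvox, nvol)
  flat[idx, ] <- sig
  out <- array(flat, dim = c(dims, nvol))
  structure(out, scheme = scheme, spacing = truth$spacing, S0 = 1,
            class = "dwi_volume")
}

#' Simulate one synthetic subject
#'
#' Draws the subject's geometry and per-zone microstructure from the group
#' profile, builds labels and ground truth, optionally calibrates the
#' zeppelin radial diffusivity so that the noise-free DTI fit reproduces
#' the subject's per-zone FA targets, and synthesizes the noisy DWI.
#'
#' @param group `"gbm-like"` or `"met-like"`.
#' @param scheme Acquisition scheme.
#' @param seed Integer seed controlling all random draws for this subject.
#' @param dim,spacing Grid geometry (see [phantom_spec()]).
#' @param snr Signal-to-noise ratio at b = 0.
#' @param noise Noise model.
#' @param calibrate_fa Solve the per-zone radial diffusivity so the
#'   noise-free tensor fit matches the drawn FA targets (default FALSE;
#'   the tortuosity closure is used otherwise).
#' @param profile_z Optional standard-normal scores for the profile draw
#'   (see [draw_subject_profile()] internals); used by [simulate_cohort()]
#'   for antithetic pairing.
#' @return A list with `labels`, `truth`, `dwi`, `profile`, `geometry`.
#' @export
simulate_subject <- function(group, scheme, seed,
                             dim = c(20, 20, 20),
                             spacing = c(1.5, 1.5, 1.5),
                             snr = 30, noise = "rician",
                             calibrate_fa = FALSE, profile_z = NULL) {
  set.seed(seed)
  r_core <- min(max(stats::rnorm(1, 5.0, 0.5), 4.0), 6.0)
  r_edema <- min(max(stats::rnorm(1, 12.0, 1.0), 10.0), 13.8)
  profile <- draw_subject_profile(group, z = profile_z)
  orient <- stats::rnorm(3)
  orient <- orient / sqrt(sum(orient^2))

  spec <- phantom_spec(dim = dim, spacing = spacing, r_core = r_core,
                       r_edema = r_edema, profile = profile, snr = snr,
                       noise = noise, seed = seed)
  labels <- make_labels(spec)
  if (calibrate_fa) {
    profile <- calibrate_profile_fa(profile, scheme)
  }
  truth <- assign_microstructure(labels, profile, smooth = FALSE,
                                 orient = orient)
  dwi <- synthesize_signal(truth, scheme, snr = snr, seed = seed + 1L,
                           noise = noise)
  list(labels = labels, truth = truth, dwi = dwi, profile = profile,
       geometry = list(r_core = r_core, r_edema = r_edema, orient = orient))
}

#' Simulate a cohort of synthetic subjects
#'
#' Per-subject microstructure profiles are drawn antithetically: subjects
#' are paired and the second member of each pair uses the sign-flipped
#' standard-normal scores of the first. Each profile still follows the
#' calibrated normal distribution marginally, but the cohort mean of
#' every drawn quantity is centered on its calibration target — standard
#' variance reduction for simulation studies.
#'
#' @param n Number of subjects.
#' @param group `"gbm-like"` or `"met-like"`.
#' @param scheme Acquisition scheme.
#' @param seed Global seed; subject s uses derived seed `seed + 1000 * s`.
#' @param antithetic Use antithetic profile pairing (default TRUE).
#' @param ... Passed to [simulate_subject()].
#' @return A list of subject bundles (see [simulate_subject()]).
#' @export
simulate_cohort <- function(n, group, scheme, seed, antithetic = TRUE, ...) {
  Z <- cohort_profile_scores(n, group, seed, antithetic)
  lapply(seq_len(n), function(s) {
    simulate_subject(group, scheme, seed = as.integer(seed + 1000 * s),
                     profile_z = Z[[s]], ...)
  })
}

# Antithetically paired standard-normal score vectors for a cohort's
# profile draws (list of length n; NULL entries mean "draw fresh").
cohort_profile_scores <- function(n, group, seed, antithetic = TRUE) {
  if (!antithetic) return(vector("list", n))
  set.seed(as.integer(seed))
  nz <- 2 * length(group_profile(group))
  Z <- matrix(stats::rnorm(ceiling(n / 2) * nz), ncol = nz)
  lapply(seq_len(n), function(s) {
    Z[(s + 1) %/% 2, ] * if (s %% 2 == 0) -1 else 1
  })
}
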