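# Shared fixtures and oracles, built in code at test time.

# Dense deterministic direction set for brute-force sphere quadrature
# (oracle for the closed-form powder expressions).
dense_sphere <- function(n = 20000) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

# Complete a parameter list with the tortuosity radial diffusivity
# (isotropic zeppelin when the anisotropic fractions vanish).
with_tortuosity <- function(p) {
  aniso <- p$v_intra + (1 - p$v_intra - p$v_csf)
  frac <- if (aniso > 0) p$v_intra / aniso else 0
  p$d_rad_extra <- p$d_ax_extra * (1 - frac)
  p
}

# Edema-like operating point (inner-zone glioblastoma values).
edema_params <- function() {
  with_tortuosity(list(v_intra = 0.08, v_csf = 0.48,
                       d_ax_intra = 2.29, d_ax_extra = 1.22))
}

# Closed-form feature vector (m, q, r at shells b = 1, 2 ms/um^2).
true_features <- function(p) {
  unlist(lapply(c(1, 2), function(b) {
    c(powder_forward(p$v_intra, p$v_csf, p$d_ax_intra, p$d_ax_extra,
                     p$d_rad_extra, b),
      powder_moment2(p$v_intra, p$v_csf, p$d_ax_intra, p$d_ax_extra,
                     p$d_rad_extra, b),
      powder_moment4(p$v_intra, p$v_csf, p$d_ax_intra, p$d_ax_extra,
                     p$d_rad_extra, b))
  }))
}

# Single-voxel (or n-voxel constant) ground-truth block for signal
# synthesis, bypassing the geometric phantom.
uniform_truth <- function(p, n = 1, orient = c(0, 0, 1)) {
  arr <- function(v) array(v, dim = c(n, 1, 1))
  structure(list(v_intra = arr(p$v_intra), v_csf = arr(p$v_csf),
                 v_extra = arr(1 - p$v_intra - p$v_csf),
                 d_ax_intra = arr(p$d_ax_intra),
                 d_ax_extra = arr(p$d_ax_extra),
                 d_rad_extra = arr(p$d_rad_extra),
                 orient = orient, spacing = c(1.5, 1.5, 1.5)),
            class = "microstructure_truth")
}

# Minimal zone-summary objects from explicit per-subject IZ/MZ/OZ values
# for one metric (for the statistics battery).
fake_summaries <- function(iz, mz, oz, metric = "FA", group = "A",
                           volumes = NULL) {
  lapply(seq_along(iz), function(i) {
    s <- data.frame(subject = sprintf("s%02d", i), group = group,
                    metric = metric, IZ = iz[i], MZ = mz[i], OZ = oz[i],
                    stringsAsFactors = FALSE)
    attr(s, "edema_volume_ml") <- if (is.null(volumes)) 20 else volumes[i]
    attr(s, "incomplete") <- FALSE
    class(s) <- c("subject_zone_summary", class(s))
    s
  })
}

# Small default-protocol scheme reused across tests.
test_scheme <- function() make_scheme(15, 58, c(0, 1000, 2000))

# Memoized synthetic cohorts for the acceptance checks (several criteria
# draw on the same cohort; simulate and fit once per session).
.cohort_cache <- new.env(parent = emptyenv())
acceptance_summaries <- function(group, n, seed, fit = "dmi",
                                 calibrate_fa = FALSE) {
  key <- paste(group, n, seed, fit, calibrate_fa, sep = "|")
  if (is.null(.cohort_cache[[key]])) {
    sch <- make_scheme()
    grid <- dmi_grid("coarse")
    subs <- simulate_cohort(n, group, sch, seed = seed,
                            calibrate_fa = calibrate_fa)
    .cohort_cache[[key]] <- lapply(seq_len(n), function(i) {
      process_subject(subs[[i]], grid = grid,
                      subject = sprintf("%s_%02d", group, i),
                      group = group, fit = fit)
    })
  }
  .cohort_cache[[key]]
}

ACCEPT_SEED <- 20260924

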