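# Three-compartment microstructure estimation from spherical features.

test_that("spherical means follow analytic limits", {
  sch <- test_scheme()
  # isotropic voxel: mean equals exp(-b d) at every shell
  iso <- uniform_truth(list(v_intra = 0, v_csf = 0, d_ax_intra = 1,
                            d_ax_extra = 0.9, d_rad_extra = 0.9))
  s <- synthesize_signal(iso, sch, noise = "none")
  sm <- spherical_mean(s)
  expect_equal(sm$means[1, ], c(exp(-0.9), exp(-1.8)), tolerance = 1e-9)
  # pure stick with Da = 2 at b = 1: closed form ~ 0.598, 58-direction
  # sampling within 1%
  stick <- uniform_truth(list(v_intra = 1, v_csf = 0, d_ax_intra = 2,
                              d_ax_extra = 1, d_rad_extra = 0.5),
                         orient = c(1, 2, -1) / sqrt(6))
  ss <- synthesize_signal(stick, sch, noise = "none")
  sms <- spherical_mean(ss)
  expect_lt(abs(sms$means[1, 1] / 0.59814 - 1), 0.01)
  # S0 <= 0 flags the voxel
  bad <- s
  bad[1, 1, 1, sch$bvals == 0] <- 0
  smb <- spherical_mean(bad)
  expect_false(smb$valid[1])
  expect_true(is.na(smb$means[1, 1]))
})

test_that("noise-free shell features equal the plain sample moments", {
  sch <- test_scheme()
  p <- edema_params()
  tr <- uniform_truth(p, orient = c(0, 1, 0))
  s <- synthesize_signal(tr, sch, noise = "none")
  ft <- shell_features(s)
  expect_equal(ft$sigma, 0)
  for (k in 1:2) {
    dirsig <- s[1, 1, 1, sch$bvals == sch$shells[k]]
    expect_equal(ft$m[1, k], mean(dirsig), tolerance = 1e-9)
    expect_equal(ft$q[1, k], mean(dirsig^2), tolerance = 1e-9)
    expect_equal(ft$r[1, k], mean(dirsig^4), tolerance = 1e-9)
  }
})

test_that("Rician debiasing recovers the noise-free moments", {
  sch <- test_scheme()
  p <- edema_params()
  tr <- uniform_truth(p, n = 3000)
  noisy <- synthesize_signal(tr, sch, snr = 30, seed = 9, noise = "rician")
  clean <- synthesize_signal(uniform_truth(p), sch, noise = "none")
  ft <- shell_features(noisy, sigma = 1 / 30)
  fc <- shell_features(clean)
  for (k in 1:2) {
    expect_lt(abs(mean(ft$m[, k]) / fc$m[1, k] - 1), 0.015)
    expect_lt(abs(mean(ft$q[, k]) / fc$q[1, k] - 1), 0.01)
    expect_lt(abs(mean(ft$r[, k]) / fc$r[1, k] - 1), 0.02)
  }
  # sigma estimated from the b = 0 repeats is close to the truth
  ft2 <- shell_features(noisy)
  expect_lt(abs(ft2$sigma / (1 / 30) - 1), 0.05)
})

test_that("grid respects parameter bounds and the branch constraint", {
  g <- dmi_grid("coarse")
  expect_true(all(g$params[, "v_intra"] + g$params[, "v_csf"] <= 1 + 1e-12))
  expect_true(all(g$params[, "d_ax_intra"] >= g$params[, "d_ax_extra"]))
  expect_true(all(g$params[, c("d_ax_intra", "d_ax_extra")] > 0))
  expect_true(all(g$params[, c("d_ax_intra", "d_ax_extra")] <= 3))
  expect_true(!is.unsorted(g$m1_sorted))
})

test_that("a pure free-water voxel is identified from noise-free features", {
  p <- with_tortuosity(list(v_intra = 0, v_csf = 1, d_ax_intra = 2,
                            d_ax_extra = 1))
  x <- true_features(p)
  f <- fit_voxel(m = x[c(1, 4)], q = x[c(2, 5)], r = x[c(3, 6)],
                 grid = dmi_grid("fine"))
  expect_gte(f$v_csf, 0.99)
})

test_that("noise-free recovery at the printed inner-zone operating point", {
  p <- edema_params()   # V-intra 0.08, V-CSF 0.48, Da 2.29, De 1.22
  x <- true_features(p)
  f <- fit_voxel(m = x[c(1, 4)], q = x[c(2, 5)], r = x[c(3, 6)],
                 grid = dmi_grid("fine"))
  expect_lt(abs(f$v_intra - 0.08), 0.02)
  expect_lt(abs(f$v_csf - 0.48), 0.02)
  expect_lt(abs(f$d_ax_intra - 2.29), 0.05)
  expect_lt(abs(f$d_ax_extra - 1.22), 0.05)
  expect_lt(f$resid, 1)
})

test_that("noise-free identifiability across the reported parameter ranges", {
  g <- dmi_grid("fine")
  set.seed(42)
  n <- 100
  tru <- data.frame(v_intra = runif(n, 0.05, 0.15),
                    v_csf = runif(n, 0.35, 0.65),
                    d_ax_intra = runif(n, 2.1, 2.5),
                    d_ax_extra = runif(n, 1.1, 1.4))
  err <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    p <- with_tortuosity(as.list(tru[i, ]))
    x <- true_features(p)
    f <- fit_voxel(m = x[c(1, 4)], q = x[c(2, 5)], r = x[c(3, 6)], grid = g)
    err[i, ] <- unlist(f[1, c("v_intra", "v_csf", "d_ax_intra",
                              "d_ax_extra")]) - unlist(tru[i, ])
  }
  # within two grid steps for every parameter (fractions 2 x 0.02,
  # diffusivities 2 x 0.05)
  expect_lt(max(abs(err[, 1])), 0.04)
  expect_lt(max(abs(err[, 2])), 0.04)
  expect_lt(max(abs(err[, 3])), 0.10)
  expect_lt(max(abs(err[, 4])), 0.10)
})

test_that("estimates respect output constraints at every voxel", {
  sch <- test_scheme()
  spec <- phantom_spec(r_core = 4.5, r_edema = 9)
  lab <- make_labels(spec)
  truth <- assign_microstructure(lab, zone_profile_table("gbm-like"))
  dwi <- synthesize_signal(truth, sch, snr = 30, seed = 21)
  maps <- fit_dmi_volume(dwi, lab == 2)
  vi <- maps$v_intra[lab == 2]
  vc <- maps$v_csf[lab == 2]
  di <- maps$d_ax_intra[lab == 2]
  de <- maps$d_ax_extra[lab == 2]
  ok <- !is.na(vi)
  expect_gt(mean(ok), 0.99)
  expect_true(all(vi[ok] >= 0 & vi[ok] <= 1))
  expect_true(all(vc[ok] >= 0 & vc[ok] <= 1))
  expect_true(all(vi[ok] + vc[ok] <= 1 + 1e-9))
  expect_true(all(di[ok] > 0 & di[ok] <= 3))
  expect_true(all(de[ok] > 0 & de[ok] <= 3))
})

test_that("estimated V-CSF is monotone in true V-CSF (noise-free)", {
  g <- dmi_grid("fine")
  vc_grid <- seq(0.30, 0.70, by = 0.1)
  est <- vapply(vc_grid, function(vc) {
    p <- with_tortuosity(list(v_intra = 0.09, v_csf = vc,
                              d_ax_intra = 2.28, d_ax_extra = 1.24))
    x <- true_features(p)
    fit_voxel(m = x[c(1, 4)], q = x[c(2, 5)], r = x[c(3, 6)],
              grid = g)$v_csf
  }, numeric(1))
  expect_true(all(diff(est) > -0.02))  # grid-resolution tolerance
})

test_that("estimates are rotation invariant", {
  sch <- test_scheme()
  p <- edema_params()
  orients <- list(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3))
  fits <- lapply(orients, function(o) {
    s <- synthesize_signal(uniform_truth(p, orient = o), sch, noise = "none")
    ft <- shell_features(s)
    fit_dmi(ft, grid = dmi_grid("fine"))
  })
  # feature quadrature error across orientations maps to small estimate
  # differences
  for (i in 2:3) {
    expect_equal(fits[[1]]$v_intra, fits[[i]]$v_intra, tolerance = 0.02)
    expect_equal(fits[[1]]$v_csf, fits[[i]]$v_csf, tolerance = 0.03)
    expect_equal(fits[[1]]$d_ax_extra, fits[[i]]$d_ax_extra,
                 tolerance = 0.06)
  }
})

test_that("repeated noisy measurements center on the noise-free estimate", {
  sch <- test_scheme()
  p <- edema_params()
  nrep <- 200
  noisy <- synthesize_signal(uniform_truth(p, n = nrep), sch, snr = 30,
                             seed = 31, noise = "rician")
  fits <- fit_dmi(shell_features(noisy, sigma = 1 / 30),
                  grid = dmi_grid("coarse"))
  clean <- synthesize_signal(uniform_truth(p), sch, noise = "none")
  f0 <- fit_dmi(shell_features(clean), grid = dmi_grid("coarse"))
  # median over repetitions within one coarse grid step of the noise-free
  # estimate
  expect_lt(abs(median(fits$v_intra) - f0$v_intra), 0.02)
  expect_lt(abs(median(fits$v_csf) - f0$v_csf), 0.04)
  expect_lt(abs(median(fits$d_ax_extra) - f0$d_ax_extra), 0.10)
})

test_that("out-of-range features flag the voxel invalid", {
  f <- fit_voxel(m = c(1.5, 0.8), q = c(2.4, 0.7), r = c(5.5, 0.5),
                 grid = dmi_grid("coarse"))
  expect_false(f$valid)
  expect_true(is.na(f$v_intra))
})
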