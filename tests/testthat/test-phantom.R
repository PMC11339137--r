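# Synthetic phantom generation: geometry, ground truth, signals.

test_that("label geometry matches brute-force voxel-center enumeration", {
  spec <- phantom_spec(dim = c(40, 40, 40), r_core = 6, r_edema = 15,
                      spacing = c(1.5, 1.5, 1.5))
  lab <- make_labels(spec)
  expect_true(all(lab %in% 0:4))
  expect_equal(sum(lab == 1 & lab == 2), 0)  # disjoint by construction
  # exhaustive enumeration of grid centers within the core radius
  ax <- (seq_len(40) - 20.5) * 1.5
  cc <- expand.grid(x = ax, y = ax, z = ax)
  expect_equal(sum(lab == 1), sum(sqrt(rowSums(cc^2)) <= 6))
  expect_equal(sum(lab == 2),
               sum(sqrt(rowSums(cc^2)) <= 15) - sum(sqrt(rowSums(cc^2)) <= 6))
  expect_gt(sum(lab == 1), 0)
  expect_gt(sum(lab == 2), 0)
})

test_that("degenerate or inconsistent geometry is rejected", {
  expect_error(make_labels(phantom_spec(dim = c(10, 10, 10), r_core = 6,
                                        r_edema = 6.1)),
               "degenerate")
  expect_error(phantom_spec(r_core = 8, r_edema = 6), "smaller")
  expect_error(phantom_spec(r_core = -1, r_edema = 6), "positive")
  expect_error(phantom_spec(dim = c(10, 10, 10), r_core = 4, r_edema = 14),
               "fit within")
  expect_error(phantom_spec(snr = 0), "snr")
})

test_that("hard zones give per-tertile constants, smooth mode interpolates", {
  spec <- phantom_spec(r_core = 4.5, r_edema = 10.5)
  lab <- make_labels(spec)
  prof <- zone_profile_table("gbm-like")

  hard <- assign_microstructure(lab, prof, smooth = FALSE)
  expect_equal(sort(unique(hard$v_intra[lab == 2])),
               sort(unique(prof$v_intra)))
  expect_length(unique(hard$v_intra[lab == 2]), 3)

  sm <- assign_microstructure(lab, prof, smooth = TRUE)
  d <- distance_from_core(lab == 1, lab == 2, c(1.5, 1.5, 1.5))
  # boundary condition: nearest-to-core edema voxel carries the IZ value
  expect_equal(sm$v_csf[lab == 2][which.min(d)], prof["IZ", "v_csf"],
               tolerance = 1e-6)
  # monotone nondecreasing v_intra outward along the +x ray (IZ < OZ in
  # the profile)
  ctr <- dim(lab)[1] %/% 2 + 1
  ray <- sm$v_intra[ctr:dim(lab)[1], ctr, ctr]
  ray <- ray[lab[ctr:dim(lab)[1], ctr, ctr] == 2]
  expect_true(all(diff(ray) >= -1e-9))
  # compartment conservation everywhere
  tot <- sm$v_intra + sm$v_csf + sm$v_extra
  expect_true(all(abs(tot[!is.na(tot)] - 1) < 1e-9))
})

test_that("invalid zone profiles are rejected", {
  spec <- phantom_spec()
  lab <- make_labels(spec)
  bad <- zone_profile_table("gbm-like")
  bad["MZ", "v_intra"] <- 0.7
  bad["MZ", "v_csf"] <- 0.5
  expect_error(assign_microstructure(lab, bad), "invalid profile")
})

test_that("synthesized signal is normalized, bounded and deterministic", {
  sch <- test_scheme()
  spec <- phantom_spec(r_core = 4.5, r_edema = 9)
  lab <- make_labels(spec)
  truth <- assign_microstructure(lab, zone_profile_table("met-like"))

  clean <- synthesize_signal(truth, sch, seed = 3, noise = "none")
  expect_equal(dim(clean)[4], n_volumes(sch))
  b0 <- clean[, , , 1][lab > 0]
  expect_true(all(abs(b0 - 1) < 1e-12))
  dw <- clean[, , , n_volumes(sch)][lab > 0]
  expect_true(all(dw > 0 & dw <= 1))

  n1 <- synthesize_signal(truth, sch, snr = 30, seed = 11)
  n2 <- synthesize_signal(truth, sch, snr = 30, seed = 11)
  n3 <- synthesize_signal(truth, sch, snr = 30, seed = 12)
  expect_identical(as.vector(n1), as.vector(n2))
  expect_false(identical(as.vector(n1), as.vector(n3)))
  expect_true(all(n1 >= 0))
  expect_error(synthesize_signal(truth, sch, snr = -2), "snr")
})

test_that("pure-compartment signals hit their analytic values", {
  sch <- test_scheme()
  csf <- uniform_truth(list(v_intra = 0, v_csf = 1, d_ax_intra = 2,
                            d_ax_extra = 1, d_rad_extra = 0.5))
  s <- synthesize_signal(csf, sch, noise = "none")
  b1000 <- which(sch$bvals == 1000)
  expect_equal(unique(round(s[1, 1, 1, b1000], 10)), round(exp(-3), 10))

  stick <- uniform_truth(list(v_intra = 1, v_csf = 0, d_ax_intra = 2.29,
                              d_ax_extra = 1, d_rad_extra = 0.5))
  sb <- synthesize_signal(stick, sch, noise = "none")
  c2 <- as.vector(crossprod(sch$directions, c(0, 0, 1)))^2
  expect_equal(as.vector(sb[1, 1, 1, b1000]), exp(-2.29 * c2),
               tolerance = 1e-12)
})

test_that("58-direction spherical mean tracks the closed-form powder average", {
  sch <- test_scheme()
  p <- edema_params()
  for (orient in list(c(0, 0, 1), c(1, 1, 1) / sqrt(3))) {
    tr <- uniform_truth(p, orient = orient)
    s <- synthesize_signal(tr, sch, noise = "none")
    sm <- spherical_mean(s, array(TRUE, dim = c(1, 1, 1)))
    for (k in 1:2) {
      cf <- powder_forward(p$v_intra, p$v_csf, p$d_ax_intra,
                           p$d_ax_extra, p$d_rad_extra, k)
      expect_lt(abs(sm$means[1, k] / cf - 1), 0.01)
    }
  }
})

test_that("cohort profile draws are antithetically centered", {
  sch <- make_scheme(1, 6, c(0, 1000))  # scheme unused by the draw itself
  Z <- perizone:::cohort_profile_scores(28, "met-like", seed = 5)
  expect_length(Z, 28)
  expect_equal(Z[[1]], -Z[[2]])
  expect_equal(Z[[27]], -Z[[28]])
  # marginal distribution preserved: pooled scores are standard normal-ish
  pooled <- unlist(Z)
  expect_lt(abs(mean(pooled)), 1e-9)
})

test_that("curved orientation fields keep rotation-invariant features", {
  sch <- test_scheme()
  spec <- phantom_spec(r_core = 4.5, r_edema = 9)
  lab <- make_labels(spec)
  prof <- zone_profile_table("gbm-like")
  straight <- assign_microstructure(lab, prof, orient = c(0, 0, 1))
  curved <- assign_microstructure(lab, prof, orient = "curved")
  s1 <- synthesize_signal(straight, sch, noise = "none")
  s2 <- synthesize_signal(curved, sch, noise = "none")
  m1 <- spherical_mean(s1, lab == 2)
  m2 <- spherical_mean(s2, lab == 2)
  # spherical means agree across orientation fields (direction-sampling
  # error only)
  expect_equal(m1$means, m2$means, tolerance = 0.01)
})
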