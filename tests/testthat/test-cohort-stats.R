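# The normality-gated statistical battery.

test_that("Shapiro-Wilk gate has correct size and power", {
  set.seed(100)
  # size: normal samples pass the gate almost always
  normal_rate <- mean(vapply(1:100, function(i) {
    normality_gate(rnorm(30)) == "normal"
  }, logical(1)))
  expect_gte(normal_rate, 0.90)
  # power: a heavily skewed exponential sample is flagged
  nonnormal_rate <- mean(vapply(1:100, function(i) {
    normality_gate(rexp(30)) == "non-normal"
  }, logical(1)))
  expect_gt(nonnormal_rate, 0.9)
  # degenerate input
  expect_equal(as.character(normality_gate(rep(1, 10))), "non-normal")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("Pratt signed rank matches the library test when zero-free", {
  set.seed(5)
  for (i in 1:20) {
    d <- round(rnorm(25), 2)
    d <- d[d != 0]
    ours <- perizone:::wilcoxon_signed_rank_pratt(d)
    ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
  # zeros: all-zero differences are a null result
  expect_equal(perizone:::wilcoxon_signed_rank_pratt(rep(0, 10))$p.value, 1)
})

test_that("within-group comparison handles identity, symmetry and gating", {
  set.seed(6)
  iz <- rnorm(20, 0.18, 0.04)
  same <- fake_summaries(iz, iz, iz)
  r <- within_group_compare(same, "FA")
  expect_equal(r$p, 1)

  oz <- iz + rnorm(20, 0.03, 0.05)
  s1 <- fake_summaries(iz, (iz + oz) / 2, oz)
  s2 <- fake_summaries(-iz, -(iz + oz) / 2, -oz)
  r1 <- within_group_compare(s1, "FA")
  r2 <- within_group_compare(s2, "FA")
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)
  expect_error(within_group_compare(s1[1:2], "FA"), "insufficient")
})

test_that("calibrated paired alternative is detected with high power", {
  # metastasis-like FA zone contrast: OZ - IZ differences ~ N(0.03, 0.05),
  # n = 28
  set.seed(7)
  rejections <- vapply(1:500, function(i) {
    iz <- rnorm(28, 0.18, 0.04)
    oz <- iz + rnorm(28, 0.03, 0.05)
    within_group_compare(fake_summaries(iz, (iz + oz) / 2, oz), "FA")$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.5)  # far above the 5% null rate
})

test_that("between-group comparison is calibrated under the null", {
  set.seed(8)
  mk_grad <- function(x) data.frame(subject = seq_along(x), group = "g",
                                    metric = "FA", MZ_IZ = x / 2, OZ_IZ = x)
  rejections <- vapply(1:1000, function(i) {
    a <- rnorm(30, 0, 0.04)
    b <- rnorm(28, 0, 0.04)
    between_group_compare(mk_grad(a), mk_grad(b), "FA")$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)

  # separation limit and label symmetry
  a <- rnorm(30, 0, 0.04)
  b <- rnorm(28, 5, 0.04)
  expect_lt(between_group_compare(mk_grad(a), mk_grad(b), "FA")$p, 0.001)
  r_ab <- between_group_compare(mk_grad(a), mk_grad(b), "FA")
  r_ba <- between_group_compare(mk_grad(b), mk_grad(a), "FA")
  expect_equal(r_ab$p, r_ba$p, tolerance = 1e-12)
  expect_equal(r_ab$statistic, -r_ba$statistic, tolerance = 1e-9)
})

test_that("p-values agree with the library implementations", {
  set.seed(9)
  mk_grad <- function(x) data.frame(subject = seq_along(x), group = "g",
                                    metric = "FA", MZ_IZ = x / 2, OZ_IZ = x)
  a <- rnorm(30, 0.003, 0.04)
  b <- rnorm(28, 0.03, 0.05)
  r <- between_group_compare(mk_grad(a), mk_grad(b), "FA")
  if (r$test == "Welch t") {
    expect_equal(r$p, t.test(a, b)$p.value, tolerance = 1e-6)
  } else {
    expect_equal(r$p, wilcox.test(a, b, exact = FALSE)$p.value,
                 tolerance = 1e-6)
  }
  # skewed data drops to Mann-Whitney U
  a2 <- rexp(30)
  b2 <- rexp(28) + 1
  r2 <- between_group_compare(mk_grad(a2), mk_grad(b2), "FA")
  expect_equal(r2$test, "Mann-Whitney U")
  expect_equal(r2$p, wilcox.test(a2, b2, exact = FALSE)$p.value,
               tolerance = 1e-6)
})

test_that("ANCOVA separates group effects from the volume covariate", {
  set.seed(10)
  mk_grad <- function(x) data.frame(subject = seq_along(x), group = "g",
                                    metric = "FA", MZ_IZ = x / 2, OZ_IZ = x)
  # volume unrelated, large group shift: group significant
  va <- runif(30, 10, 40)
  vb <- runif(28, 10, 40)
  a <- rnorm(30, 0, 0.01)
  b <- rnorm(28, 0.05, 0.01)
  r <- ancova_gradient(mk_grad(a), mk_grad(b), va, vb, "FA")
  expect_lt(r$p, 0.001)
  # recovery of a known covariate slope with no group effect: group-effect
  # rejections stay near the nominal rate
  rejections <- vapply(1:200, function(i) {
    va <- runif(30, 10, 40)
    vb <- runif(28, 10, 40)
    a <- 0.002 * va + rnorm(30, 0, 0.005)
    b <- 0.002 * vb + rnorm(28, 0, 0.005)
    ancova_gradient(mk_grad(a), mk_grad(b), va, vb, "FA")$p < 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.12)
  # degenerate covariate reduces to a two-sample comparison with warning
  expect_warning(
    r0 <- ancova_gradient(mk_grad(a), mk_grad(b), rep(20, 30), rep(20, 28),
                          "FA"),
    "constant")
  expect_lt(r0$p, 0.001)
})

test_that("demographics reproduce the printed-style tests", {
  # sex counts 18/12 vs 18/10: chi-square without continuity correction
  counts <- matrix(c(18, 12, 18, 10), nrow = 2, byrow = TRUE,
                   dimnames = list(c("GBM", "met"), c("m", "f")))
  r <- sex_chisq(counts)
  expect_equal(round(r$p, 2), 0.74)
  # identical age vectors
  set.seed(11)
  age <- round(rnorm(29, 64, 10))
  demo <- data.frame(group = rep(c("GBM", "met"), each = 29),
                     age = c(age, age),
                     sex = sample(c("m", "f"), 58, replace = TRUE),
                     volume_ml = runif(58, 5, 45))
  res <- demographics(demo)
  expect_equal(res$p[res$metric == "age"], 1, tolerance = 1e-9)
  expect_true(all(res$p >= 0 & res$p <= 1))
  # zero-cell 2x2 table stays close to the exact-test oracle
  z <- matrix(c(12, 0, 6, 6), nrow = 2, byrow = TRUE)
  pz <- sex_chisq(z)$p
  pf <- fisher.test(z)$p.value
  expect_true(is.finite(pz))
  expect_equal(pz < 0.05, pf < 0.05)
})

test_that("the full gated battery keeps its type-I error near nominal", {
  set.seed(12)
  rejections <- vapply(1:1000, function(i) {
    iz_a <- rnorm(30, 1.22, 0.03)
    oz_a <- iz_a + rnorm(30, 0, 0.02)
    iz_b <- rnorm(28, 1.22, 0.03)
    oz_b <- iz_b + rnorm(28, 0, 0.02)
    ga <- data.frame(subject = 1:30, group = "a", metric = "Dax_extra",
                     MZ_IZ = (oz_a - iz_a) / 2, OZ_IZ = oz_a - iz_a)
    gb <- data.frame(subject = 1:28, group = "b", metric = "Dax_extra",
                     MZ_IZ = (oz_b - iz_b) / 2, OZ_IZ = oz_b - iz_b)
    between_group_compare(ga, gb, "Dax_extra")$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})
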