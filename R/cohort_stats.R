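# The cohort statistical battery: normality-gated within-group paired
# comparisons (inner vs outer zone), between-group comparisons of the
# outer-minus-inner gradients, demographics tests, and ANCOVA
# controlling for edema volume. Alpha 0.05 throughout; no
# multiple-testing correction by default, mirroring the single-test
# reporting convention of the study design this package emulates.

#' Shapiro-Wilk normality gate
#'
#' Classifies a sample as `"normal"` or `"non-normal"` at the given
#' alpha. Constant input is non-normal by convention.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Significance level of the gate (default 0.05).
#' @return `"normal"` or `"non-normal"`, with attribute `p` (the
#'   Shapiro-Wilk p-value, `NA` for constant input).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("normality gate requires at least 3 values")
  if (stats::sd(values) == 0) {
    return(structure("non-normal", p = NA_real_))
  }
  p <- stats::shapiro.test(values)$p.value
  structure(if (p >= alpha) "normal" else "non-normal", p = p)
}

# Wilcoxon signed rank with Pratt handling of zero differences: zeros
# participate in the ranking of |d| but their ranks are dropped from the
# statistic; normal approximation with tie and zero corrections and
# continuity correction. With no zeros this matches
# wilcox.test(..., exact = FALSE, correct = TRUE).
wilcoxon_signed_rank_pratt <- function(d) {
  d <- d[!is.na(d)]
  n <- length(d)
  r <- rank(abs(d))
  nonzero <- d != 0
  V <- sum(r[nonzero][d[nonzero] > 0])
  # null moments with zero (Pratt) and tie corrections
  n0 <- sum(!nonzero)
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(r)
  sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (sig2 <= 0) {
    return(list(statistic = V, p.value = 1))
  }
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
  list(statistic = V, p.value = 2 * stats::pnorm(-abs(z)))
}

# Printed-style group summary: mean +/- SD or median [IQR].
format_group_summary <- function(values, style) {
  if (style == "normal") {
    sprintf("%.3g ± %.2g", mean(values), stats::sd(values))
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.3g [%.3g-%.3g]", q[2], q[1], q[3])
  }
}

test_result <- function(metric, contrast, test, statistic, p, estimates,
                        gate, n) {
  data.frame(metric = metric, contrast = contrast, test = test,
             statistic = statistic, p = p, estimates = estimates,
             gate = gate, n = n, stringsAsFactors = FALSE)
}

#' Within-group inner-vs-outer zone comparison
#'
#' Paired comparison of a metric between two zones within one group:
#' paired t-test if the paired differences pass the Shapiro-Wilk gate,
#' Wilcoxon signed-rank (Pratt zero handling) otherwise.
#'
#' @param summaries List of `subject_zone_summary` objects for one group.
#' @param metric Metric name to compare.
#' @param zones Character pair of zones (default `c("IZ", "OZ")`).
#' @param alpha Gate significance level.
#' @return One-row data.frame (`TestResult`): metric, contrast, test,
#'   statistic, p, printed-style estimates, gate decision, n.
#' @export
within_group_compare <- function(summaries, metric, zones = c("IZ", "OZ"),
                                 alpha = 0.05) {
  vals <- vapply(summaries, function(s) {
    row <- s[s$metric == metric, ]
    c(row[[zones[1]]], row[[zones[2]]])
  }, numeric(2))
  keep <- colSums(is.na(vals)) == 0
  vals <- vals[, keep, drop = FALSE]
  n <- ncol(vals)
  if (n < 3) stop("insufficient data: fewer than 3 complete pairs")
  d <- vals[2, ] - vals[1, ]
  gate <- normality_gate(d, alpha)
  if (gate == "normal") {
    tt <- stats::t.test(vals[2, ], vals[1, ], paired = TRUE)
    test <- "paired t"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- wilcoxon_signed_rank_pratt(d)
    test <- "Wilcoxon signed-rank"
    statistic <- wt$statistic
    p <- wt$p.value
  }
  est <- paste0(zones[1], " ", format_group_summary(vals[1, ], gate),
                " vs. ", zones[2], " ", format_group_summary(vals[2, ], gate))
  test_result(metric, paste(zones[1], "vs", zones[2], "within group"),
              test, statistic, p, est, as.character(gate), n)
}

#' Between-group comparison of zone gradients
#'
#' Compares one metric's OZ - IZ (or MZ - IZ) gradient between two
#' groups: Welch t-test when both groups pass the normality gate,
#' Mann-Whitney U otherwise.
#'
#' @param grad_a,grad_b Data.frames from [zone_gradients()] (stacked per
#'   group).
#' @param metric Metric name.
#' @param column Gradient column, `"OZ_IZ"` (default) or `"MZ_IZ"`.
#' @param alpha Gate significance level.
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return One-row `TestResult` data.frame.
#' @export
between_group_compare <- function(grad_a, grad_b, metric,
                                  column = "OZ_IZ", alpha = 0.05,
                                  var_equal = FALSE) {
  a <- grad_a[grad_a$metric == metric, column]
  b <- grad_b[grad_b$metric == metric, column]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("insufficient data: each group needs at least 3 subjects")
  }
  gate_a <- normality_gate(a, alpha)
  gate_b <- normality_gate(b, alpha)
  both_normal <- gate_a == "normal" && gate_b == "normal"
  if (both_normal) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    test <- if (var_equal) "Student t" else "Welch t"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    test <- "Mann-Whitney U"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  }
  style <- if (both_normal) "normal" else "non-normal"
  est <- paste0(format_group_summary(a, style), " vs. ",
                format_group_summary(b, style))
  test_result(metric, paste(column, "between groups"), test, statistic, p,
              est, if (both_normal) "normal" else "non-normal",
              length(a) + length(b))
}

#' ANCOVA on zone gradients controlling for edema volume
#'
#' Linear model `gradient ~ group + edema_volume`; reports the group
#' effect. A constant covariate is dropped with a warning, reducing the
#' model to a two-sample comparison.
#'
#' @param grad_a,grad_b Gradient data.frames for the two groups.
#' @param vol_a,vol_b Edema volumes (ml), one per subject, aligned with
#'   the gradient tables' subject order.
#' @param metric Metric name.
#' @param column Gradient column (default `"OZ_IZ"`).
#' @return One-row `TestResult` data.frame (group-effect t statistic and
#'   p-value).
#' @export
ancova_gradient <- function(grad_a, grad_b, vol_a, vol_b, metric,
                            column = "OZ_IZ") {
  ga <- grad_a[grad_a$metric == metric, ]
  gb <- grad_b[grad_b$metric == metric, ]
  df <- data.frame(y = c(ga[[column]], gb[[column]]),
                   group = factor(c(rep("A", nrow(ga)), rep("B", nrow(gb)))),
                   vol = c(vol_a, vol_b))
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 4) stop("insufficient data for ANCOVA")
  if (stats::sd(df$vol) == 0) {
    warning("edema-volume covariate is constant; dropping it")
    fit <- stats::lm(y ~ group, data = df)
  } else {
    fit <- stats::lm(y ~ group + vol, data = df)
  }
  co <- summary(fit)$coefficients
  test_result(metric, paste(column, "between groups | edema volume"),
              "ANCOVA", co["groupB", "t value"], co["groupB", "Pr(>|t|)"],
              sprintf("adjusted group difference %.3g", -co["groupB", "Estimate"]),
              "covariate-adjusted", nrow(df))
}

#' Demographic comparisons between groups
#'
#' Age via gated t-test / Mann-Whitney U, sex via chi-square on the 2x2
#' count table (without continuity correction), edema volume via
#' Mann-Whitney U with median [IQR] reporting.
#'
#' @param demo Data.frame with columns `group`, `age`, `sex` (factor or
#'   character), and optionally `volume_ml`.
#' @param alpha Gate significance level.
#' @return A `TestResult` data.frame with one row per comparison.
#' @export
demographics <- function(demo, alpha = 0.05) {
  groups <- unique(demo$group)
  if (length(groups) != 2) stop("exactly two groups are required")
  a <- demo[demo$group == groups[1], ]
  b <- demo[demo$group == groups[2], ]
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty group")
  out <- list()

  gate_a <- normality_gate(a$age, alpha)
  gate_b <- normality_gate(b$age, alpha)
  if (gate_a == "normal" && gate_b == "normal") {
    if (stats::sd(c(a$age, b$age)) == 0) {
      out$age <- test_result("age", "between groups", "t", 0, 1,
                             "identical", "normal", nrow(demo))
    } else {
      tt <- stats::t.test(a$age, b$age)
      out$age <- test_result("age", "between groups", "Welch t",
                             unname(tt$statistic), tt$p.value,
                             paste0(format_group_summary(a$age, "normal"),
                                    " vs. ",
                                    format_group_summary(b$age, "normal")),
                             "normal", nrow(demo))
    }
  } else {
    wt <- stats::wilcox.test(a$age, b$age, exact = FALSE)
    out$age <- test_result("age", "between groups", "Mann-Whitney U",
                           unname(wt$statistic), wt$p.value,
                           paste0(format_group_summary(a$age, "non-normal"),
                                  " vs. ",
                                  format_group_summary(b$age, "non-normal")),
                           "non-normal", nrow(demo))
  }

  out$sex <- sex_chisq(table(demo$group, demo$sex))

  if (!is.null(demo$volume_ml)) {
    wt <- stats::wilcox.test(a$volume_ml, b$volume_ml, exact = FALSE)
    out$volume <- test_result("edema volume", "between groups",
                              "Mann-Whitney U", unname(wt$statistic),
                              wt$p.value,
                              paste0(format_group_summary(a$volume_ml,
                                                          "non-normal"),
                                     " vs. ",
                                     format_group_summary(b$volume_ml,
                                                          "non-normal")),
                              "non-normal", nrow(demo))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chi-square test on a 2x2 sex-by-group table
#'
#' Pearson chi-square without continuity correction (the convention that
#' reproduces the study's printed demographics p-value from its counts).
#'
#' @param counts 2x2 contingency table or matrix.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return One-row `TestResult` data.frame.
#' @export
sex_chisq <- function(counts, correct = FALSE) {
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  test_result("sex", "between groups",
              if (correct) "chi-square (Yates)" else "chi-square",
              unname(ct$statistic), ct$p.value,
              paste(apply(counts, 1, paste, collapse = "/"),
                    collapse = " vs. "),
              "count data", sum(counts))
}

#' Run the full gated statistical battery on a two-group cohort
#'
#' For every metric: the within-group IZ-vs-OZ paired comparison in each
#' group, the between-group comparison of the OZ - IZ gradient, and the
#' ANCOVA controlling for edema volume.
#'
#' @param summaries_a,summaries_b Lists of `subject_zone_summary` objects
#'   (group A and B).
#' @param metrics Metric names (default the six diffusion metrics).
#' @param alpha Gate significance level.
#' @return A `TestResult` data.frame, one row per test.
#' @export
analyze_cohort <- function(summaries_a, summaries_b, metrics = METRICS,
                           alpha = 0.05) {
  grads_a <- do.call(rbind, lapply(summaries_a, zone_gradients))
  grads_b <- do.call(rbind, lapply(summaries_b, zone_gradients))
  vols_a <- vapply(summaries_a, attr, numeric(1), "edema_volume_ml")
  vols_b <- vapply(summaries_b, attr, numeric(1), "edema_volume_ml")
  metrics <- intersect(metrics, unique(grads_a$metric))
  out <- list()
  # a failed test (e.g. too few subjects) yields an NA row rather than
  # aborting the battery: partial results are preserved
  safely <- function(metric, contrast, expr) {
    tryCatch(expr, error = function(e) {
      test_result(metric, contrast, paste("failed:", conditionMessage(e)),
                  NA_real_, NA_real_, NA_character_, NA_character_,
                  NA_integer_)
    })
  }
  for (m in metrics) {
    out[[paste0(m, "_within_A")]] <- cbind(
      group = "A", safely(m, "IZ vs OZ within group",
                          within_group_compare(summaries_a, m,
                                               alpha = alpha)))
    out[[paste0(m, "_within_B")]] <- cbind(
      group = "B", safely(m, "IZ vs OZ within group",
                          within_group_compare(summaries_b, m,
                                               alpha = alpha)))
    out[[paste0(m, "_between")]] <- cbind(
      group = "A vs B", safely(m, "OZ_IZ between groups",
                               between_group_compare(grads_a, grads_b, m,
                                                     alpha = alpha)))
    out[[paste0(m, "_ancova")]] <- cbind(
      group = "A vs B",
      safely(m, "OZ_IZ between groups | edema volume",
             ancova_gradient(grads_a, grads_b, vols_a, vols_b, m)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
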