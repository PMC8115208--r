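test_that("FWHM estimator: white-noise limit and known-smoothness recovery", {
  set.seed(31)
  # white noise: estimator converges to sqrt(4 log 2 / 2) ~ 1.18 nodes
  est_white <- replicate(40, estimate_fwhm(matrix(rnorm(25 * 51), 25, 51)))
  expect_lt(abs(mean(est_white) - sqrt(2 * log(2))) / sqrt(2 * log(2)), 0.2)

  # fields smoothed with a FWHM-10 kernel: estimate within 15%
  est10 <- replicate(40, estimate_fwhm(gen_fields_oracle(25, 51, 10)))
  expect_lt(abs(mean(est10) - 10) / 10, 0.15)
})

test_that("constant-in-space fields are flagged maximally smooth", {
  R <- matrix(rep(rnorm(10), 51), 10, 51)
  out <- estimate_fwhm(R)
  expect_equal(as.numeric(out), 51)
  expect_true(attr(out, "maximal"))
  expect_error(estimate_fwhm(matrix(0, 5, 51)), "zero-variance")
})

test_that("thresholds approach pointwise critical values as FWHM grows", {
  # one-resel limit: no multiple-comparison penalty left
  expect_equal(rft_threshold("f", c(2, 40), 51, fwhm_nodes = 1e9,
                             alpha = 0.05),
               qf(0.95, 2, 40), tolerance = 1e-4)
  expect_equal(rft_threshold("t", 20, 51, fwhm_nodes = 1e9, alpha = 0.05,
                             two_tailed = TRUE),
               qt(0.975, 20), tolerance = 1e-4)

  # monotone: decreasing in FWHM, increasing in field length
  th <- vapply(c(5, 10, 20, 40), function(w)
    rft_threshold("f", c(2, 40), 51, w, 0.05), numeric(1))
  expect_true(all(diff(th) < 0))
  th2 <- vapply(c(21, 51, 101), function(nn)
    rft_threshold("f", c(2, 40), nn, 10, 0.05), numeric(1))
  expect_true(all(diff(th2) > 0))
})

test_that("per-node ANOVA F matches aov on every node", {
  set.seed(32)
  limb <- rep(c("control", "paretic", "non_paretic"), each = 6)
  field <- rep(rep(c("null", "damping"), each = 3), times = 3)
  Y <- matrix(rnorm(18 * 51), 18, 51) +
    outer(as.numeric(factor(limb)), seq(0, 1, length.out = 51))
  an <- stridefield:::anova2_fields_ss(Y, limb, field)
  for (j in c(1, 17, 34, 51)) {
    fit <- summary(stats::aov(Y[, j] ~ factor(limb) * factor(field)))[[1]]
    expect_equal(an$F_A[j], fit[["F value"]][1], tolerance = 1e-8)
    expect_equal(an$F_B[j], fit[["F value"]][2], tolerance = 1e-8)
    expect_equal(an$F_AB[j], fit[["F value"]][3], tolerance = 1e-8)
  }
  expect_equal(unname(an$df), c(2, 1, 2, 12))
})

test_that("anova2_field names an empty design cell", {
  limb <- rep(c("control", "paretic"), each = 4)
  field <- rep(c("null", "damping"), times = 4)
  keep <- !(limb == "paretic" & field == "damping")
  expect_error(
    anova2_field(matrix(rnorm(sum(keep) * 51), sum(keep), 51),
                 limb[keep], field[keep]),
    "empty design cell.*paretic")
})

test_that("post-hoc t fields: antisymmetry, pairing, Bonferroni alpha", {
  set.seed(33)
  Y <- gen_fields_oracle(24, 51, 10)
  limb <- rep(c("control", "paretic", "non_paretic"), each = 8)
  subj <- c(sprintf("c%d", 1:8), rep(sprintf("s%d", 1:8), 2))
  out <- posthoc_tfields(Y, limb, subject = subj, alpha_family = 0.05)
  expect_length(out, 3)
  # per-pair level is alpha_family / 3 (prints as 0.0167)
  expect_equal(out[[1]]$alpha, 0.05 / 3, tolerance = 1e-12)

  # swapping groups negates the t field exactly
  swap <- posthoc_tfields(Y, limb, subject = subj, alpha_family = 0.05,
                          pairs = list(c("paretic", "control"),
                                       c("control", "paretic")))
  expect_equal(swap[[1]]$field_values, -swap[[2]]$field_values,
               tolerance = 1e-12)

  # paretic vs non-paretic shares subjects: paired df = n - 1
  pnp <- out[["paretic_vs_non_paretic"]]
  if (is.null(pnp)) pnp <- out[["non_paretic_vs_paretic"]]
  expect_equal(pnp$df, 7)
  # control comparisons are two-sample: df = n1 + n2 - 2
  cvp <- out[[grep("control", names(out))[1]]]
  expect_equal(cvp$df, 14)
})

test_that("identical groups rarely show suprathreshold post-hoc clusters", {
  set.seed(34)
  hits <- 0
  nrep <- 200
  limb <- rep(c("a", "b"), each = 8)
  for (r in seq_len(nrep)) {
    Y <- gen_fields_oracle(16, 51, 10)
    out <- posthoc_tfields(Y, limb, alpha_family = 0.05,
                           pairs = list(c("a", "b")))
    hits <- hits + (nrow(out[[1]]$clusters) > 0)
  }
  expect_lte(hits / nrep, 0.05 + 2 * sqrt(0.05 * 0.95 / nrep))
})

test_that("cluster extraction reports maximal suprathreshold runs in %", {
  f <- rep(0, 51); f[c(5:10, 30:35)] <- 10
  cl <- stridefield:::field_clusters(f, threshold = 5)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start_pct, c(8, 58))
  expect_equal(cl$end_pct, c(18, 68))
})

test_that("an injected limb effect is localized where it was injected", {
  set.seed(35)
  found <- 0
  nrep <- 100
  limb <- rep(c("control", "paretic", "non_paretic"), each = 6)
  field <- rep(rep(c("null", "damping"), each = 3), 3)
  bump <- c(rep(0, 15), seq(0, 4, length.out = 36))  # nodes 30%-100%
  for (r in seq_len(nrep)) {
    Y <- gen_fields_oracle(18, 51, 10)
    Y[limb == "control", ] <- Y[limb == "control", ] +
      matrix(bump, 6, 51, byrow = TRUE)
    res <- anova2_field(Y, limb, field)
    cl <- res$limb$clusters
    if (nrow(cl) && any(cl$end_pct >= 30)) found <- found + 1
  }
  expect_gte(found / nrep, 0.95)
})
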