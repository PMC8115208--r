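#' Estimate 1D residual-field smoothness (FWHM)
#'
#' Standard gradient-based estimator: residual fields are variance-
#' normalized per node, node-to-node forward differences are pooled across
#' fields, and the smoothness follows from the identity
#' `FWHM = sqrt(4 log 2 / E[grad^2])` for a Gaussian-autocorrelation field
#' with unit node spacing.
#'
#' @param R Matrix of residual fields (fields x nodes), >= 2 rows.
#' @return Estimated FWHM in nodes. Fields constant in space (no gradient)
#'   return the field length, flagged with attribute `maximal = TRUE`.
#' @export
estimate_fwhm <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) < 2) stopf("need at least 2 residual fields")
  n <- ncol(R)
  ssq <- colSums(R^2)
  if (any(ssq == 0)) stopf("zero-variance residuals at one or more nodes")
  D <- R[, -1, drop = FALSE] - R[, -n, drop = FALSE]
  v <- colSums(D^2) / ((ssq[-1] + ssq[-n]) / 2)
  resels_per_node <- sqrt(v / (4 * log(2)))
  m <- mean(resels_per_node)
  if (m < sqrt(.Machine$double.eps))
    return(structure(n, maximal = TRUE))
  1 / m
}

# 1D Euler-characteristic densities (Worsley); returns c(EC0, EC1) where
# EC0 is the tail probability and EC1 the per-resel density at height u
ec_density <- function(stat = c("t", "f"), u, df) {
  stat <- match.arg(stat)
  if (stat == "t") {
    nu <- df[length(df)]
    ec0 <- pt(u, nu, lower.tail = FALSE)
    ec1 <- sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / nu)^(-(nu - 1) / 2)
  } else {
    k <- df[1]; nu <- df[2]
    ec0 <- pf(u, k, nu, lower.tail = FALSE)
    lg <- lgamma((nu + k - 1) / 2) - lgamma(nu / 2) - lgamma(k / 2)
    z <- k * u / nu
    ec1 <- sqrt(4 * log(2) / pi) * exp(lg) *
      z^((k - 1) / 2) * (1 + z)^(-(nu + k - 2) / 2)
  }
  c(ec0, ec1)
}

#' Random-field-theory critical threshold for a 1D statistic field
#'
#' Smallest height u whose expected Euler characteristic over the field
#' (pointwise tail probability plus resel count times the 1D EC density)
#' equals `alpha`. For t fields the default is two-sided, i.e. the
#' threshold controls `max |t|`.
#'
#' @param stat `"t"` or `"f"`.
#' @param df Degrees of freedom: `nu` for t, `c(k, nu)` for F.
#' @param n_nodes Number of grid nodes in the field.
#' @param fwhm_nodes Field smoothness in nodes (> 0).
#' @param alpha Family-wise error level in (0, 1). Default 0.05.
#' @param two_tailed For t fields, control `max |t|` (default `TRUE`).
#' @return The critical threshold (numeric scalar).
#' @export
rft_threshold <- function(stat = c("t", "f"), df, n_nodes = 51, fwhm_nodes,
                          alpha = 0.05, two_tailed = TRUE) {
  stat <- match.arg(stat)
  if (fwhm_nodes <= 0) stopf("fwhm_nodes must be positive")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  resels <- (n_nodes - 1) / fwhm_nodes
  expected_ec <- function(u) {
    d <- ec_density(stat, u, df)
    e <- d[1] + resels * d[2]
    if (stat == "t" && two_tailed) 2 * e else e
  }
  lower <- if (stat == "t") {
    qt(1 - alpha / if (two_tailed) 2 else 1, df[length(df)])
  } else {
    qf(1 - alpha, df[1], df[2])
  }
  f <- function(u) expected_ec(u) - alpha
  # expected EC >= pointwise tail prob, so the root lies above `lower`
  upper <- lower + 1
  while (f(upper) > 0 && upper < 1e6) upper <- upper * 2
  stats::uniroot(f, c(lower * 0.999999, upper), tol = 1e-10)$root
}

# maximal runs of field > threshold, reported as % of swing intervals
field_clusters <- function(field_values, threshold, node_pct = sf_grid()) {
  up <- field_values > threshold
  if (!any(up)) {
    return(data.frame(start_pct = numeric(), end_pct = numeric()))
  }
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start_pct = node_pct[starts[keep]],
             end_pct = node_pct[ends[keep]])
}

new_spm_result <- function(statistic, field_values, df, fwhm, alpha,
                           threshold, node_pct, effect = NULL) {
  structure(list(statistic = statistic, effect = effect,
                 field_values = field_values, df = df,
                 fwhm_nodes = fwhm, alpha = alpha, threshold = threshold,
                 clusters = field_clusters(abs_if_t(statistic, field_values),
                                           threshold, node_pct),
                 node_pct = node_pct),
            class = "spm_result")
}

abs_if_t <- function(statistic, v) if (statistic == "t") abs(v) else v

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> %s field%s, df = (%s), FWHM = %.2f nodes\n",
              toupper(x$statistic),
              if (!is.null(x$effect)) paste0(" [", x$effect, "]") else "",
              paste(signif(x$df, 4), collapse = ", "), x$fwhm_nodes))
  cat(sprintf("  alpha = %g, critical threshold = %.3f\n",
              x$alpha, x$threshold))
  if (nrow(x$clusters)) {
    cat("  suprathreshold clusters (% of swing):\n")
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("    %g%% - %g%%\n", x$clusters$start_pct[i],
                  x$clusters$end_pct[i]))
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}

# per-node two-way fixed-effects ANOVA on a (samples x nodes) matrix;
# vectorized over nodes. Cell-means formulation; balanced designs match
# classical Type I/II/III identically.
anova2_fields_ss <- function(Y, A, B) {
  Y <- as.matrix(Y)
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B)
  N <- nrow(Y)
  cells <- interaction(A, B, drop = FALSE)
  if (any(table(A, B) == 0)) stopf("empty design cell: %s",
      paste(levels(cells)[table(cells) == 0], collapse = ", "))
  grand <- colMeans(Y)
  mean_by <- function(f) {
    t(vapply(levels(f),
             function(l) colMeans(Y[f == l, , drop = FALSE]),
             numeric(ncol(Y))))
  }
  mA <- mean_by(A); mB <- mean_by(B); mC <- mean_by(cells)
  nA <- as.vector(table(A)); nB <- as.vector(table(B))
  nC <- as.vector(table(cells))
  ssA <- colSums(nA * (sweep(mA, 2, grand))^2)
  ssB <- colSums(nB * (sweep(mB, 2, grand))^2)
  # interaction from cell means vs additive means; interaction() levels
  # vary the first factor fastest
  cellA <- rep(levels(A), times = b)
  cellB <- rep(levels(B), each = a)
  addfit <- mA[match(cellA, levels(A)), , drop = FALSE] +
    mB[match(cellB, levels(B)), , drop = FALSE] -
    matrix(grand, length(nC), ncol(Y), byrow = TRUE)
  ssAB <- colSums(nC * (mC - addfit)^2)
  resid <- Y - mC[match(as.character(cells), levels(cells)), , drop = FALSE]
  ssE <- colSums(resid^2)
  df <- c(A = a - 1, B = b - 1, AB = (a - 1) * (b - 1), E = N - a * b)
  list(F_A = (ssA / df["A"]) / (ssE / df["E"]),
       F_B = (ssB / df["B"]) / (ssE / df["E"]),
       F_AB = (ssAB / df["AB"]) / (ssE / df["E"]),
       df = df, residuals = resid)
}

#' SPM two-way ANOVA over 1D fields
#'
#' Per-node fixed-effects two-way ANOVA (limb x field) F statistics for
#' each effect, residual-based smoothness estimation, random-field-theory
#' critical thresholds at `alpha`, and suprathreshold clusters in % of
#' swing.
#'
#' @param Y Matrix of field samples (samples x nodes), e.g. per-subject
#'   R-squared curves.
#' @param limb,field Factors (length `nrow(Y)`) giving each sample's cell.
#' @param alpha Family-wise error level. Default 0.05.
#' @param node_pct Grid node percentages.
#' @return A named list of three `spm_result` objects: `limb`, `field`,
#'   `interaction`.
#' @export
anova2_field <- function(Y, limb, field, alpha = 0.05,
                         node_pct = sf_grid()) {
  an <- anova2_fields_ss(Y, limb, field)
  fwhm <- estimate_fwhm(an$residuals)
  mk <- function(Fv, dfn, eff)
    new_spm_result("f", Fv, c(dfn, an$df[["E"]]), fwhm, alpha,
                   rft_threshold("f", c(dfn, an$df[["E"]]), ncol(Y), fwhm,
                                 alpha),
                   node_pct, effect = eff)
  list(limb = mk(an$F_A, an$df[["A"]], "limb"),
       field = mk(an$F_B, an$df[["B"]], "field"),
       interaction = mk(an$F_AB, an$df[["AB"]], "limb x field"))
}

# per-node two-sample (pooled variance) t field
t_field_two_sample <- function(Y1, Y2) {
  n1 <- nrow(Y1); n2 <- nrow(Y2)
  m1 <- colMeans(Y1); m2 <- colMeans(Y2)
  s2 <- (colSums(sweep(Y1, 2, m1)^2) + colSums(sweep(Y2, 2, m2)^2)) /
    (n1 + n2 - 2)
  list(t = (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2)), df = n1 + n2 - 2,
       residuals = rbind(sweep(Y1, 2, m1), sweep(Y2, 2, m2)))
}

# per-node paired t field
t_field_paired <- function(Y1, Y2) {
  D <- Y1 - Y2
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  list(t = m / (s / sqrt(n)), df = n - 1,
       residuals = sweep(D, 2, m))
}

#' Bonferroni-corrected pairwise SPM t fields between limbs
#'
#' Post-hoc pairwise comparisons after a significant limb effect. The
#' paretic vs non-paretic comparison is paired within subject; comparisons
#' against control are two-sample. Each t field is thresholded (two-sided)
#' at `alpha_family / n_pairs`.
#'
#' @param Y Matrix of field samples (samples x nodes).
#' @param limb Factor of limb labels per sample.
#' @param subject Subject identifiers per sample (required for the paired
#'   comparison; pairs are matched by subject).
#' @param alpha_family Family-wise level split across pairs. Default 0.05
#'   (3 pairs, per-pair alpha 0.0167).
#' @param pairs List of 2-vectors of limb levels to compare; defaults to
#'   all unordered pairs present.
#' @param node_pct Grid node percentages.
#' @return Named list of `spm_result` objects, one per pair.
#' @export
posthoc_tfields <- function(Y, limb, subject = NULL, alpha_family = 0.05,
                            pairs = NULL, node_pct = sf_grid()) {
  limb <- factor(limb)
  if (is.null(pairs)) {
    lv <- levels(limb)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  }
  alpha <- alpha_family / length(pairs)
  out <- list()
  for (pr in pairs) {
    i1 <- limb == pr[1]; i2 <- limb == pr[2]
    paired <- !is.null(subject) &&
      setequal(subject[i1], subject[i2]) &&
      !anyDuplicated(subject[i1]) && !anyDuplicated(subject[i2])
    if (paired) {
      Y1 <- Y[i1, , drop = FALSE][order(subject[i1]), , drop = FALSE]
      Y2 <- Y[i2, , drop = FALSE][order(subject[i2]), , drop = FALSE]
      tf <- t_field_paired(Y1, Y2)
    } else {
      tf <- t_field_two_sample(Y[i1, , drop = FALSE], Y[i2, , drop = FALSE])
    }
    fwhm <- estimate_fwhm(tf$residuals)
    thr <- rft_threshold("t", tf$df, ncol(Y), fwhm, alpha, two_tailed = TRUE)
    out[[paste(pr, collapse = "_vs_")]] <-
      new_spm_result("t", tf$t, tf$df, fwhm, alpha, thr, node_pct,
                     effect = paste(pr, collapse = " vs "))
  }
  out
}

#' Generate smooth Gaussian null fields
#'
#' White Gaussian noise convolved with a Gaussian kernel of the requested
#' FWHM (in nodes) and scaled to unit pointwise variance; used for
#' Monte-Carlo validation of the random-field-theory thresholds and as the
#' null-cohort generator in the family-wise error-rate checks.
#'
#' @param n Number of fields.
#' @param n_nodes Nodes per field. Default 51.
#' @param fwhm Kernel full width at half maximum in nodes; 0 gives white
#'   noise.
#' @param pad Padding (nodes) on each side before convolution. Default
#'   `3 * fwhm`.
#' @return An `n` x `n_nodes` matrix of unit-variance smooth Gaussian
#'   fields.
#' @export
gen_smooth_fields <- function(n, n_nodes = 51, fwhm = 10,
                              pad = ceiling(3 * fwhm)) {
  if (fwhm <= 0) return(matrix(rnorm(n * n_nodes), n, n_nodes))
  sigma <- fwhm / sqrt(8 * log(2))
  half <- pad
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sqrt(sum(kern^2))  # unit output variance
  wide <- n_nodes + 2 * half
  Z <- matrix(rnorm(n * wide), n, wide)
  W <- matrix(0, n_nodes, wide)
  for (i in seq_len(n_nodes)) W[i, i:(i + 2 * half)] <- kern
  Z %*% t(W)
}
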