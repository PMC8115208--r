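#' Remove the mean of a numeric vector
#'
#' The COM-state predictors (and, to keep the intercept-free model
#' well-posed, the foot placements) are centered before fitting.
#'
#' @param x Numeric vector, length >= 1.
#' @return `x - mean(x)`.
#' @export
demean <- function(x) x - mean(x)

#' Fit the foot-placement regression at one swing-phase node
#'
#' Least-squares fit of centered foot placement on centered lateral COM
#' position and velocity, without intercept:
#' `FP_x = beta1 * COM_x + beta2 * COM_v + eps`.
#' R-squared is the regression sum of squares over the total (centered) sum
#' of squares. Coefficient significance uses normal-theory t statistics on
#' `n - 3` degrees of freedom (two slopes plus the centering).
#'
#' @param com_x,com_v,fp Per-step predictor and response values (equal
#'   lengths, n >= 3).
#' @return A one-row data.frame: `beta1`, `beta2`, `r2`, `resid_var`
#'   (residual variance, RSS/n), `n_steps`, `se_beta1`, `se_beta2`,
#'   `p_beta1`, `p_beta2`. Collinear predictors yield a flagged row with
#'   `NA` estimates (missing, not zero).
#' @export
fit_point <- function(com_x, com_v, fp) {
  n <- length(fp)
  if (length(com_x) != n || length(com_v) != n)
    stopf("com_x, com_v and fp must have equal lengths")
  if (n < 3)
    stopf("at least 3 steps are needed for the two-predictor fit")
  flagged <- data.frame(beta1 = NA_real_, beta2 = NA_real_, r2 = NA_real_,
                        resid_var = NA_real_, n_steps = n,
                        se_beta1 = NA_real_, se_beta2 = NA_real_,
                        p_beta1 = NA_real_, p_beta2 = NA_real_)
  X <- cbind(demean(com_x), demean(com_v))
  y <- demean(fp)
  xtx <- crossprod(X)
  # collinear (or constant) predictors: rank-deficient normal equations
  if (min(svd(xtx, nu = 0, nv = 0)$d) <=
      max(svd(xtx, nu = 0, nv = 0)$d) * 1e-12)
    return(flagged)
  beta <- solve(xtx, crossprod(X, y))
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum(y^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  df <- n - 3
  sigma2 <- if (df > 0) rss / df else NA_real_
  se <- sqrt(diag(solve(xtx)) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  data.frame(beta1 = beta[1], beta2 = beta[2], r2 = r2,
             resid_var = rss / n, n_steps = n,
             se_beta1 = se[1], se_beta2 = se[2],
             p_beta1 = pval[1], p_beta2 = pval[2])
}

#' Fit the regression at every swing-phase node
#'
#' Repeats [fit_point()] at each node of the swing grid using that node's
#' COM state across steps and the node-independent foot placements. Steps
#' with any missing node are dropped listwise so all nodes fit on the same
#' step set.
#'
#' @param com_x,com_v Matrices (steps x nodes) from [swing_design()].
#' @param fp Foot placements, one per step.
#' @param limb Cell label: `"paretic"`, `"non_paretic"` or `"control"`.
#' @param field Cell label: `"null"` or `"damping"`.
#' @param node_pct Grid node percentages (defaults to the 2% grid).
#' @param min_steps Minimum steps required; fewer returns `NULL` with a
#'   warning.
#' @return A `regression_series` data.frame with one row per node:
#'   `limb`, `field`, `node_pct`, `beta1`, `beta2`, `r2`, `resid_var`,
#'   `n_steps`, `se_beta1`, `se_beta2`, `p_beta1`, `p_beta2`.
#' @export
fit_series <- function(com_x, com_v, fp, limb = "control", field = "null",
                       node_pct = sf_grid(), min_steps = 10) {
  com_x <- as.matrix(com_x)
  com_v <- as.matrix(com_v)
  if (ncol(com_x) != length(node_pct) || ncol(com_v) != length(node_pct))
    stopf("predictor matrices must have one column per grid node")
  complete <- stats::complete.cases(com_x) & stats::complete.cases(com_v) &
    !is.na(fp)
  com_x <- com_x[complete, , drop = FALSE]
  com_v <- com_v[complete, , drop = FALSE]
  fp <- fp[complete]
  if (length(fp) < min_steps) {
    warnf("cell %s/%s skipped: only %d usable steps (minimum %d)",
          limb, field, length(fp), min_steps)
    return(NULL)
  }
  pts <- lapply(seq_along(node_pct), function(j)
    fit_point(com_x[, j], com_v[, j], fp))
  out <- do.call(rbind, pts)
  out <- cbind(data.frame(limb = limb, field = field, node_pct = node_pct),
               out)
  structure(out, class = c("regression_series", "data.frame"))
}
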