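#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef lm median pf pt qf qt quantile rnorm sd spline var
#' @importFrom utils read.csv write.csv head tail
NULL

# Default marker labels consumed by the pipeline.  Pelvis markers follow the
# usual mocap shorthand (anterior/posterior superior iliac spines, greater
# trochanters); foot markers are the calcaneus and 5th metatarsal head.
SF_FOOT_MARKERS <- c("LCAL", "RCAL", "LMT5", "RMT5")
SF_PELVIS_MARKERS <- c("LASIS", "RASIS", "LPSIS", "RPSIS", "LGT", "RGT")
SF_COM_MARKERS <- c("LASIS", "RASIS", "LGT", "RGT")

#' Marker labels required by the analysis pipeline
#'
#' @return Character vector of marker labels that [read_markers()] validates
#'   against: bilateral calcaneus and 5th-metatarsal markers plus the pelvis
#'   markers used for the COM estimate.
#' @export
sf_required_markers <- function() {
  c(SF_FOOT_MARKERS, SF_COM_MARKERS)
}

# grid of swing-phase percentages: 0, 2, ..., 100 (51 nodes)
sf_grid <- function(step_pct = 2) seq(0L, 100L, by = step_pct)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# smoothstep ramp on [0, 1]: C1, monotone, endpoints exact
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}
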