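#' Gate dual-reporter events on both channels
#'
#' Retains events strictly above both thresholds — the "upper right
#' quadrant" used to quantify reporter expression, which excludes
#' untransduced cells sitting at the autofluorescence floor.
#'
#' @param events A tibble with `egfp` and `mcherry` columns.
#' @param threshold_gfp,threshold_mcherry Positive gate thresholds.
#' @return The gated subset of `events`.
#' @export
gate_double_positive <- function(events, threshold_gfp, threshold_mcherry) {
  if (!all(c("egfp", "mcherry") %in% names(events))) {
    abort("`events` needs `egfp` and `mcherry` columns.")
  }
  if (threshold_gfp <= 0 || threshold_mcherry <= 0) {
    abort("gate thresholds must be positive.")
  }
  keep <- events$egfp > threshold_gfp & events$mcherry > threshold_mcherry
  if (!any(keep)) {
    abort(sprintf(
      "empty gate: no events with eGFP > %g and mCherry > %g.",
      threshold_gfp, threshold_mcherry))
  }
  events[keep, , drop = FALSE]
}

#' Orthogonal (total least squares) regression of eGFP on mCherry
#'
#' Fits the line minimising perpendicular distances — the principal axis of
#' the 2x2 covariance of `(mcherry, gfp)` through the centroid — and
#' reports its slope as the relative level of eGFP per mCherry. Unlike
#' ordinary regression, the fit treats both channels as noisy, and swapping
#' the channels inverts the slope exactly. No variance standardisation is
#' applied: both channels are in common fluorescence-intensity units, and
#' the TLS slope is not invariant to per-axis rescaling. `log_space = TRUE`
#' fits on log10 intensities instead (the slope is then the log-log
#' exponent, not an expression ratio).
#'
#' @param gfp,mcherry Gated per-cell intensities; at least 10 events, each
#'   channel with non-zero variance.
#' @param log_space Fit on log10-transformed intensities.
#' @return An `orthogonal_fit` with `slope`, `intercept`, `n`, `space` and
#'   `resid_var` (the minor-axis, i.e. residual orthogonal, variance).
#'   Summarise with [tidy()]/[glance()]; plot with [autoplot()].
#' @examples
#' ev <- generate_dual_reporter(2000, true_slope = 0.5, seed = 1)
#' orthogonal_fit(ev$egfp, ev$mcherry)
#' @export
orthogonal_fit <- function(gfp, mcherry, log_space = FALSE) {
  if (length(gfp) != length(mcherry)) {
    abort("`gfp` and `mcherry` must be paired per cell.")
  }
  if (length(gfp) < 10L) {
    abort("at least 10 gated events are required for a stable fit.")
  }
  x <- if (log_space) log10(mcherry) else mcherry
  y <- if (log_space) log10(gfp) else gfp
  S <- stats::cov(cbind(x, y))
  if (S[1, 1] == 0 || S[2, 2] == 0) {
    abort("degenerate covariance: a channel has zero variance.")
  }
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[1] == 0) abort("principal axis is vertical; slope undefined.")
  slope <- v[2] / v[1]
  structure(
    list(slope = slope,
         intercept = mean(y) - slope * mean(x),
         n = length(gfp),
         space = if (log_space) "log10" else "linear",
         resid_var = e$values[2],
         mcherry = mcherry, gfp = gfp),
    class = "orthogonal_fit")
}

#' @export
print.orthogonal_fit <- function(x, ...) {
  cat(sprintf(
    "<orthogonal_fit> slope %.4f (%s space), n = %d, residual orthogonal variance %.4g\n",
    x$slope, x$space, x$n, x$resid_var))
  invisible(x)
}

#' @export
tidy.orthogonal_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' @export
glance.orthogonal_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, n = x$n, space = x$space,
                 resid_var = x$resid_var)
}

#' @export
autoplot.orthogonal_fit <- function(object, alpha = 0.2, ...) {
  df <- tibble::tibble(mcherry = object$mcherry, gfp = object$gfp)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mcherry, y = .data$gfp)) +
    ggplot2::geom_point(alpha = alpha, size = 0.6) +
    ggplot2::labs(x = "mCherry", y = "eGFP")
  if (object$space == "linear") {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  colour = "red") +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Normalise a construct's slope to the empty-vector slope
#'
#' The empty vector carries no candidate 3'UTR, so its eGFP/mCherry slope
#' defines the unrepressed reference; a construct's relative eGFP
#' expression is its slope divided by the empty-vector slope (the empty
#' vector itself normalises to exactly 1). The ratio is invariant to
#' rescaling both channels' units by a common factor.
#'
#' @param fit_construct,fit_empty [orthogonal_fit()] results from the same
#'   fit space.
#' @param construct,genotype Optional labels carried into the output.
#' @return A one-row tibble with `construct`, `genotype`, `slope`,
#'   `slope_empty` and `relative_expression`.
#' @export
normalize_to_empty <- function(fit_construct, fit_empty, construct = NA,
                               genotype = NA) {
  stopifnot(inherits(fit_construct, "orthogonal_fit"),
            inherits(fit_empty, "orthogonal_fit"))
  if (fit_construct$space != fit_empty$space) {
    abort("both fits must use the same fit space.")
  }
  if (!is.finite(fit_empty$slope) || fit_empty$slope <= 0) {
    abort("empty-vector slope must be positive.")
  }
  tibble::tibble(construct = construct, genotype = genotype,
                 slope = fit_construct$slope, slope_empty = fit_empty$slope,
                 relative_expression = fit_construct$slope / fit_empty$slope)
}

#' microRNA-dependent de-repression between genotypes
#'
#' Ratio of normalised reporter expression in microRNA-deficient
#' (Dicer-deficient) cells over control cells; values above 1 indicate that
#' the construct's 3'UTR is repressed by microRNAs in control cells.
#'
#' @param norm_control,norm_deficient Normalised expression values:
#'   numbers, or [normalize_to_empty()] rows.
#' @return The de-repression ratio (deficient / control).
#' @export
derepression_ratio <- function(norm_control, norm_deficient) {
  pull_val <- function(x) {
    if (is.data.frame(x)) x <- x$relative_expression
    as.numeric(x)
  }
  ctrl <- pull_val(norm_control)
  defi <- pull_val(norm_deficient)
  if (any(ctrl <= 0)) abort("control normalised expression must be positive.")
  defi / ctrl
}
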