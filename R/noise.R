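#' Coefficient of variation of a set of intensities
#'
#' `cv()` returns the sample CV in percent, `100 * sd / mean` with the
#' (n-1)-denominator SD; `cv_summary()` returns the mean, SD, CV and event
#' count as a one-row tibble. The CV is scale-free: rescaling all
#' intensities by a positive factor leaves it unchanged, which is what makes
#' it comparable across stains of different brightness.
#'
#' @param values Numeric intensities; at least 2 values with positive mean.
#' @return `cv()`: the CV in percent. `cv_summary()`: a tibble with
#'   `mean`, `sd`, `cv`, `n`.
#' @examples
#' cv(c(90, 100, 110))  # 10
#' @export
cv <- function(values) {
  if (length(values) < 2L) abort("`values` must contain at least 2 events.")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) abort("mean intensity must be positive.")
  100 * sd(values) / m
}

#' @rdname cv
#' @export
cv_summary <- function(values) {
  tibble::tibble(mean = mean(values), sd = sd(values), cv = cv(values),
                 n = length(values))
}

#' Technical-noise bound from a co-regulated channel pair
#'
#' For two channels reporting an obligate heterodimer, the per-cell ratio
#' `a/b` cancels the shared biological signal; the CV of these ratios is an
#' upper bound on the technical noise of the measurement.
#'
#' @param channel_a,channel_b Paired per-cell intensities of equal length;
#'   `channel_b` must be strictly positive.
#' @return A one-row tibble ([cv_summary()] of the per-cell ratios).
#' @examples
#' ev <- generate_paired_channels(5000, 100, 80, biological_cv = 30,
#'                                technical_cv = 5, seed = 1)
#' technical_noise_bound(ev$a, ev$b)$cv  # ~ sqrt(2) * 5%
#' @export
technical_noise_bound <- function(channel_a, channel_b) {
  if (length(channel_a) != length(channel_b)) {
    abort("channels must be paired per cell (equal lengths).")
  }
  if (any(channel_b <= 0)) abort("`channel_b` must be strictly positive.")
  cv_summary(channel_a / channel_b)
}

# log-spaced histogram over the pooled positive range
log_hist_counts <- function(values, breaks) {
  idx <- findInterval(log10(values), breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1L)
}

log_breaks <- function(values, n_bins) {
  rng <- range(log10(values))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = n_bins + 1L)
}

#' Fractions of events below and above the peak channel
#'
#' Histograms the intensities on log-spaced bins (cytometer channels are
#' log-spaced), finds the modal ("peak") bin and returns the fraction of
#' events strictly below and strictly above it; events inside the peak bin
#' count in neither tail. A population skewed towards dim cells has
#' `fraction_below > fraction_above`, and vice versa. Modal ties resolve to
#' the dimmest tied bin.
#'
#' @param values Positive intensities; at least 100 events.
#' @param n_bins Number of log-spaced bins.
#' @param log_binning If `FALSE`, use linear bins instead.
#' @return A tibble with `fraction_below`, `fraction_above` and the peak
#'   bin's intensity midpoint `peak_mid`.
#' @export
peak_channel_skew <- function(values, n_bins = 256, log_binning = TRUE) {
  if (length(values) == 0L) abort("`values` is empty.")
  if (length(values) < 100L) {
    abort("`values` must contain at least 100 events for a stable peak.")
  }
  if (any(values <= 0) && log_binning) {
    abort("log binning requires strictly positive intensities.")
  }
  x <- if (log_binning) log10(values) else values
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  peak <- which.max(counts)
  mid <- (breaks[peak] + breaks[peak + 1L]) / 2
  tibble::tibble(
    fraction_below = mean(idx < peak),
    fraction_above = mean(idx > peak),
    peak_mid = if (log_binning) 10^mid else mid
  )
}

#' Analytic CV of a mixture of populations
#'
#' Law of total variance: with component fractions \eqn{f_i}, means
#' \eqn{\mu_i} and SDs \eqn{\sigma_i}, the composite has mean
#' \eqn{\bar\mu = \sum f_i \mu_i} and variance
#' \eqn{\sum f_i (\sigma_i^2 + (\mu_i - \bar\mu)^2)}. Mixing components
#' with equal CVs but different means therefore always inflates the CV
#' above the shared component CV.
#'
#' @param components A data frame with columns `fraction`, `mean`, `cv`
#'   (percent), or a list of such per-component lists.
#' @return Composite CV in percent.
#' @examples
#' mixture_cv_analytic(data.frame(fraction = c(0.2, 0.8),
#'                                mean = c(1, 2), cv = 20))
#' @export
mixture_cv_analytic <- function(components) {
  if (!is.data.frame(components)) {
    components <- dplyr::bind_rows(lapply(components, tibble::as_tibble))
  }
  if (!all(c("fraction", "mean", "cv") %in% names(components))) {
    abort("`components` needs columns fraction, mean, cv.")
  }
  f <- components$fraction
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
    abort("fractions must be >= 0 and sum to 1.")
  }
  if (any(components$mean <= 0)) abort("component means must be positive.")
  mu <- components$mean
  sig2 <- (components$cv / 100 * mu)^2
  mbar <- sum(f * mu)
  v <- sum(f * (sig2 + (mu - mbar)^2))
  100 * sqrt(v) / mbar
}

#' CV after computational removal of a reference subpopulation
#'
#' Emulates "unmixing": for each removal fraction `f`, a density
#' proportional to the reference sample — scaled to `f` of the mixture's
#' events — is subtracted from the mixture's histogram on shared log-spaced
#' bins (subtraction clipped at zero where the reference overshoots), and
#' the CV of the remaining distribution is computed. The subtraction is
#' applied as per-event weights (each mixture event is down-weighted by its
#' bin's removal fraction), so at `f = 0` the curve reproduces the plain
#' sample [cv()] of the mixture exactly rather than a binned approximation.
#'
#' @param mixture Positive intensities of the observed (mixed) population.
#' @param retaining_reference Positive intensities distributed like the
#'   subpopulation to be removed.
#' @param fraction_grid Removal fractions in `[0, 1)`.
#' @param n_bins Number of shared log-spaced bins.
#' @return An `unmix_curve` tibble with `fraction`, `cv_remainder` and
#'   `mass_remaining` (fraction of mixture events left); the grid is
#'   truncated with a warning if the remaining mass vanishes. Plot with
#'   [autoplot()]; interpolate with [unmix_fraction_for_reduction()].
#' @export
unmix_cv_curve <- function(mixture, retaining_reference,
                           fraction_grid = seq(0, 0.5, by = 0.02),
                           n_bins = 256) {
  if (!length(mixture) || !length(retaining_reference)) {
    abort("both samples must be non-empty.")
  }
  if (any(mixture <= 0) || any(retaining_reference <= 0)) {
    abort("intensities must be strictly positive for log binning.")
  }
  if (any(fraction_grid < 0) || any(fraction_grid >= 1)) {
    abort("`fraction_grid` values must lie in [0, 1).")
  }
  fraction_grid <- sort(fraction_grid)
  breaks <- log_breaks(c(mixture, retaining_reference), n_bins)
  idx <- findInterval(log10(mixture), breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  h_mix <- tabulate(idx, nbins = n_bins)
  h_ref <- log_hist_counts(retaining_reference, breaks)
  n_mix <- length(mixture)
  n_ref <- length(retaining_reference)
  rows <- vector("list", length(fraction_grid))
  for (i in seq_along(fraction_grid)) {
    f <- fraction_grid[i]
    # events to remove per bin, capped at the bin's own content
    remove_bin <- pmin(h_mix, f * n_mix * h_ref / n_ref)
    w_bin <- ifelse(h_mix > 0, 1 - remove_bin / h_mix, 0)
    w <- w_bin[idx]
    sw <- sum(w)
    # reliability-weight variance denominator; reduces to n - 1 at f = 0 and
    # keeps the CV exactly invariant under removal proportional to the
    # mixture itself
    denom <- sw - sum(w^2) / sw
    if (sw <= 1 || denom <= 0) {
      warn(sprintf(
        "remaining mass vanished at removal fraction %.3g; curve truncated.",
        f))
      rows <- rows[seq_len(i - 1L)]
      break
    }
    m <- sum(w * mixture) / sw
    v <- sum(w * (mixture - m)^2) / denom
    rows[[i]] <- tibble::tibble(fraction = f,
                                cv_remainder = 100 * sqrt(v) / m,
                                mass_remaining = sw / n_mix)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("unmix_curve", class(out)), n_bins = n_bins)
}

#' Removal fraction needed for a requested CV reduction
#'
#' Linear interpolation on an [unmix_cv_curve()].
#'
#' @param curve An `unmix_curve`.
#' @param reduction Requested CV reduction in percentage points (> 0).
#' @return The interpolated removal fraction, or `NA` if the curve never
#'   reaches the requested reduction.
#' @export
unmix_fraction_for_reduction <- function(curve, reduction) {
  stopifnot(inherits(curve, "unmix_curve"), reduction > 0)
  drop <- curve$cv_remainder[1] - curve$cv_remainder
  if (max(drop) < reduction) return(NA_real_)
  approx(drop, curve$fraction, xout = reduction, ties = "ordered")$y
}

#' @export
autoplot.unmix_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction,
                                       y = .data$cv_remainder)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of events removed", y = "CV of remainder (%)")
}

#' Compare replicate CVs between two groups
#'
#' Two-sided Welch (unequal-variance) t-test on per-replicate CV values,
#' the comparison used for genotype or condition contrasts of cytometry
#' CVs.
#'
#' @param group_a,group_b Per-replicate CVs: numeric vectors, or data
#'   frames with a `cv` column (e.g. [cv_summary()] rows bound together);
#'   at least 2 replicates per group.
#' @return A one-row tibble with `difference` (mean a - mean b), `t`, `df`
#'   and `p_value`.
#' @export
compare_cv <- function(group_a, group_b) {
  pull_cv <- function(g) {
    if (is.data.frame(g)) {
      if (!"cv" %in% names(g)) abort("data-frame input needs a `cv` column.")
      g <- g$cv
    }
    as.numeric(g)
  }
  a <- pull_cv(group_a)
  b <- pull_cv(group_b)
  if (length(a) < 2L || length(b) < 2L) {
    abort("at least 2 replicates per group are required.")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble::tibble(difference = mean(a) - mean(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 n_a = length(a), n_b = length(b))
}
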