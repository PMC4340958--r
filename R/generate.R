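#' Specify a log-normal fluorescence population
#'
#' Flow-cytometry intensity distributions are right-skewed and conventionally
#' viewed on log axes; populations are therefore modelled as log-normal and
#' parameterised directly by their true arithmetic mean and CV:
#' \eqn{\sigma^2 = \ln(1 + (cv/100)^2)}, \eqn{\mu = \ln(mean) - \sigma^2/2}.
#'
#' @param mean Target mean intensity (arbitrary fluorescence units, > 0).
#' @param cv Target coefficient of variation in percent (>= 0).
#' @param n Default number of events when the spec is generated standalone.
#' @return A `population_spec` list.
#' @export
population_spec <- function(mean, cv, n = NULL) {
  if (!is.numeric(mean) || mean <= 0) abort("`mean` must be positive.")
  if (!is.numeric(cv) || cv < 0) abort("`cv` must be >= 0 (percent).")
  structure(list(mean = mean, cv = cv, n = n), class = "population_spec")
}

# meanlog/sdlog of a log-normal with given arithmetic mean and CV (%).
lnorm_params <- function(mean, cv) {
  s2 <- log(1 + (cv / 100)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# log-normal draws with true arithmetic mean `mean` and CV `cv` (%).
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  p <- lnorm_params(mean, cv)
  rlnorm(n, p$meanlog, p$sdlog)
}

#' Generate a single log-normal fluorescence population
#'
#' @param spec A [population_spec()] (its `n` may be overridden).
#' @param seed Integer seed; fixed seed gives an identical table.
#' @param n Number of events (defaults to `spec$n`).
#' @param channel Column name for the intensity.
#' @return A tibble of `n` events with one intensity column.
#' @examples
#' ev <- generate_population(population_spec(100, 20), seed = 1, n = 1000)
#' cv(ev$intensity)
#' @export
generate_population <- function(spec, seed = NULL, n = spec$n,
                                channel = "intensity") {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(n) || n < 1) abort("`n` must be a positive event count.")
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(!!channel := rlnorm_mean_cv(n, spec$mean, spec$cv))
}

#' Generate a co-regulated channel pair with shared biological signal
#'
#' Emulates two stains reporting an obligate heterodimer (as CD8a/CD8b do):
#' each cell draws one shared log-normal biological factor (CV
#' `biological_cv`) that scales both channels, then each channel is
#' multiplied by an independent log-normal technical factor (CV
#' `technical_cv`). All factors have mean 1, so the channel means are
#' `mean_a` and `mean_b`. The per-cell ratio `a/b` cancels the biological
#' factor, leaving purely technical variation — the basis of the
#' ratio-based technical-noise bound.
#'
#' @param n Number of events.
#' @param mean_a,mean_b Channel mean intensities (> 0).
#' @param biological_cv Shared biological CV in percent.
#' @param technical_cv Per-channel technical CV in percent.
#' @param seed Integer seed.
#' @return A tibble with columns `a` and `b`.
#' @export
generate_paired_channels <- function(n, mean_a, mean_b, biological_cv,
                                     technical_cv, seed = NULL) {
  if (mean_a <= 0 || mean_b <= 0) abort("channel means must be positive.")
  if (biological_cv < 0 || technical_cv < 0) abort("CVs must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  bio <- rlnorm_mean_cv(n, 1, biological_cv)
  tibble::tibble(
    a = mean_a * bio * rlnorm_mean_cv(n, 1, technical_cv),
    b = mean_b * bio * rlnorm_mean_cv(n, 1, technical_cv)
  )
}

#' Generate a labelled mixture of log-normal populations
#'
#' Events are allocated to components by a single multinomial draw on the
#' component fractions; each event keeps its component label.
#'
#' @param components A list of `list(fraction =, spec = population_spec())`
#'   entries; fractions must be >= 0 and sum to 1 (tolerance 1e-9).
#' @param n Total number of events.
#' @param seed Integer seed.
#' @param channel Intensity column name.
#' @return A tibble with the intensity column and an integer
#'   `component` label (1-based, in input order).
#' @examples
#' mix <- generate_mixture(
#'   list(list(fraction = 0.2, spec = population_spec(100, 20)),
#'        list(fraction = 0.8, spec = population_spec(200, 20))),
#'   n = 5000, seed = 1)
#' table(mix$component)
#' @export
generate_mixture <- function(components, n, seed = NULL,
                             channel = "intensity") {
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  if (any(fr < 0)) abort("component fractions must be >= 0.")
  if (abs(sum(fr) - 1) > 1e-9) {
    abort(sprintf("component fractions must sum to 1 (got %.12g).", sum(fr)))
  }
  specs <- lapply(components, `[[`, "spec")
  if (!all(vapply(specs, inherits, logical(1), "population_spec"))) {
    abort("each component needs a population_spec().")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- as.integer(rmultinom(1, n, fr))
  parts <- purrr::map2(seq_along(specs), counts, function(i, k) {
    tibble::tibble(
      !!channel := rlnorm_mean_cv(k, specs[[i]]$mean, specs[[i]]$cv),
      component = i
    )
  })
  out <- dplyr::bind_rows(parts)
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Generate dual-fluorescence reporter events with known slope
#'
#' Emulates a two-promoter reporter: mCherry (the internal control) is drawn
#' from `mcherry_spec`; for transduced cells
#' `eGFP = true_slope * mCherry * residual`, with a mean-1 log-normal
#' residual of CV `residual_cv` capturing promoter-to-promoter noise. An
#' `untransduced_fraction` of events sits near a dim autofluorescence floor
#' in both channels, so that double-positive gating has something to remove.
#'
#' @param n Number of events.
#' @param true_slope Ground-truth eGFP-per-mCherry ratio (> 0).
#' @param mcherry_spec A [population_spec()] for the control channel. The
#'   default (mean 300, CV 250%) spans roughly two and a half decades, as
#'   LTR-driven retroviral reporter expression does.
#' @param residual_cv Multiplicative residual CV in percent.
#' @param untransduced_fraction Fraction of floor events in `[0, 1)`.
#' @param seed Integer seed.
#' @param floor_mean,floor_cv Autofluorescence floor population (both
#'   channels), dim relative to the reporter signal.
#' @return A tibble with columns `egfp`, `mcherry` and logical
#'   `transduced`.
#' @export
generate_dual_reporter <- function(n, true_slope,
                                   mcherry_spec = population_spec(300, 250),
                                   residual_cv = 20,
                                   untransduced_fraction = 0, seed = NULL,
                                   floor_mean = 3, floor_cv = 50) {
  if (true_slope <= 0) abort("`true_slope` must be positive.")
  if (untransduced_fraction < 0 || untransduced_fraction >= 1) {
    abort("`untransduced_fraction` must be in [0, 1).")
  }
  stopifnot(inherits(mcherry_spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_un <- as.integer(rmultinom(1, n, c(untransduced_fraction,
                                       1 - untransduced_fraction))[1])
  n_tr <- n - n_un
  mch <- rlnorm_mean_cv(n_tr, mcherry_spec$mean, mcherry_spec$cv)
  gfp <- true_slope * mch * rlnorm_mean_cv(n_tr, 1, residual_cv)
  out <- dplyr::bind_rows(
    tibble::tibble(egfp = gfp, mcherry = mch, transduced = TRUE),
    tibble::tibble(egfp = rlnorm_mean_cv(n_un, floor_mean, floor_cv),
                   mcherry = rlnorm_mean_cv(n_un, floor_mean, floor_cv),
                   transduced = FALSE)
  )
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Read and write event tables as delimited text
#'
#' Event tables are plain tibbles of per-cell intensities; they round-trip
#' through tab-separated text with a header.
#'
#' @param events An event tibble.
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` a
#'   tibble.
#' @export
write_events <- function(events, path) {
  write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t", check.names = FALSE))
}
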