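#' Exact stochastic simulation of a reaction network
#'
#' Runs the direct-method Gillespie algorithm: waiting times are drawn from
#' an exponential with rate equal to the total propensity and the firing
#' reaction is chosen with probability proportional to its propensity, until
#' the simulated time passes `t_end`. Counts stay non-negative integers
#' throughout. A network whose propensities are all zero is frozen and its
#' current state is returned at `t_end` (not an error).
#'
#' @param network A [reaction_network()].
#' @param t_end Simulation horizon (> 0, arbitrary time units).
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   results.
#' @param trajectory If `TRUE`, record every event and return the full
#'   trajectory instead of only the endpoint.
#' @param max_steps Safety cap on recorded events when `trajectory = TRUE`.
#' @return With `trajectory = FALSE` (default), a named integer vector of
#'   copy numbers at `t_end`. Otherwise a tibble with a `time` column and
#'   one column per species, carrying the endpoint as attribute
#'   `"endpoint"`.
#' @examples
#' net <- reaction_network(
#'   list(species("X", 0)),
#'   list(reaction("birth", 10, c(X = 1)), reaction("death", 1, c(X = -1)))
#' )
#' simulate_ssa(net, t_end = 50, seed = 42)
#' @export
simulate_ssa <- function(network, t_end, seed = NULL, trajectory = FALSE,
                         max_steps = 1e6) {
  stopifnot(inherits(network, "reaction_network"))
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    abort("`t_end` must be a single positive time.")
  }
  cm <- compile_network(network)
  if (!is.null(seed)) set.seed(seed)
  if (!trajectory) {
    out <- ssa_endpoint_cpp(cm$init, cm$stoich, cm$rate, cm$order, cm$hill,
                            t_end)
    return(setNames(out, colnames(cm$stoich)))
  }
  tr <- ssa_trajectory_cpp(cm$init, cm$stoich, cm$rate, cm$order, cm$hill,
                           t_end, as.integer(max_steps))
  if (isTRUE(tr$truncated)) {
    warn(sprintf("trajectory truncated at %d recorded events (max_steps).",
                 max_steps))
  }
  st <- tr$state
  colnames(st) <- colnames(cm$stoich)
  out <- dplyr::bind_cols(tibble::tibble(time = tr$time),
                          tibble::as_tibble(st))
  attr(out, "endpoint") <- setNames(tr$endpoint, colnames(cm$stoich))
  out
}

#' Per-run child seeds for an ensemble
#'
#' Seeds are derived by seeding R's generator with `base_seed` and drawing
#' `n_runs` integers without replacement from `1:(2^31 - 1)`; run `i` then
#' reseeds the generator with the i-th child seed, so runs are independent
#' and the whole ensemble is reproducible from `base_seed` alone.
#'
#' @param base_seed Integer master seed.
#' @param n_runs Number of child seeds.
#' @return Integer vector of length `n_runs`.
#' @export
derive_run_seeds <- function(base_seed, n_runs) {
  set.seed(base_seed)
  sample.int(2147483647L, n_runs)
}

#' Ensemble of independent SSA endpoint states
#'
#' Runs `n_runs` independent Gillespie simulations of the same network
#' (per-run seeds from [derive_run_seeds()]) and collects the copy numbers
#' at `t_end` — the across-cell distribution at a snapshot in time, one row
#' per simulated cell.
#'
#' @inheritParams simulate_ssa
#' @param n_runs Ensemble size (>= 1).
#' @param base_seed Master seed for the ensemble.
#' @return An `endpoint_ensemble`: a tibble with `run_id`, `seed` and one
#'   column per species, plus attributes `t_end` and `base_seed`. Summarise
#'   with [tidy()] (per-species mean, SD, CV) and [glance()].
#' @examples
#' net <- reaction_network(
#'   list(species("X", 0)),
#'   list(reaction("birth", 10, c(X = 1)), reaction("death", 1, c(X = -1)))
#' )
#' ens <- simulate_endpoint_ensemble(net, t_end = 30, n_runs = 200,
#'                                   base_seed = 1)
#' tidy(ens)
#' @export
simulate_endpoint_ensemble <- function(network, t_end, n_runs, base_seed) {
  stopifnot(inherits(network, "reaction_network"))
  if (n_runs < 1) abort("`n_runs` must be >= 1.")
  cm <- compile_network(network)
  seeds <- derive_run_seeds(base_seed, n_runs)
  nm <- colnames(cm$stoich)
  counts <- matrix(0L, n_runs, length(nm), dimnames = list(NULL, nm))
  for (i in seq_len(n_runs)) {
    set.seed(seeds[i])
    counts[i, ] <- ssa_endpoint_cpp(cm$init, cm$stoich, cm$rate, cm$order,
                                    cm$hill, t_end)
  }
  out <- dplyr::bind_cols(
    tibble::tibble(run_id = seq_len(n_runs), seed = seeds),
    tibble::as_tibble(counts)
  )
  structure(out,
            class = c("endpoint_ensemble", class(out)),
            t_end = t_end, base_seed = base_seed, species = nm)
}

#' @export
tidy.endpoint_ensemble <- function(x, ...) {
  nm <- attr(x, "species")
  if (nrow(x) < 2L) {
    warn("ensemble of one run: SD and CV are undefined (reported as NaN).")
  }
  purrr::map_dfr(nm, function(s) {
    v <- x[[s]]
    m <- mean(v)
    sdev <- if (length(v) < 2L) NaN else sd(v)
    tibble::tibble(
      species = s, mean = m, sd = sdev,
      cv = if (is.nan(sdev)) NaN else if (m > 0) 100 * sdev / m else NaN,
      n_runs = length(v)
    )
  })
}

#' @export
glance.endpoint_ensemble <- function(x, ...) {
  tibble::tibble(n_runs = nrow(x), t_end = attr(x, "t_end"),
                 base_seed = attr(x, "base_seed"),
                 n_species = length(attr(x, "species")))
}

#' @export
autoplot.endpoint_ensemble <- function(object, bins = 50, ...) {
  nm <- attr(object, "species")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(nm),
                              names_to = "species", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(~species, scales = "free") +
    ggplot2::labs(x = "copies per cell at t_end", y = "cells")
}

#' Write an endpoint ensemble to delimited text with a JSON sidecar
#'
#' Writes `<prefix>.tsv` (run_id, seed, one column per species) and
#' `<prefix>.json` recording `t_end`, the master seed and species names, so
#' a run is reproducible from its outputs.
#'
#' @param ensemble An [simulate_endpoint_ensemble()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_ensemble <- function(ensemble, prefix) {
  stopifnot(inherits(ensemble, "endpoint_ensemble"))
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  write.table(as.data.frame(ensemble), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(t_end = attr(ensemble, "t_end"),
         base_seed = attr(ensemble, "base_seed"),
         n_runs = nrow(ensemble),
         species = attr(ensemble, "species")),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
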