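#' Declare a species of a reaction network
#'
#' @param name Species identifier (unique within a network).
#' @param initial_count Non-negative integer number of molecules at time 0.
#' @return A `species` list.
#' @seealso [reaction()], [reaction_network()]
#' @export
species <- function(name, initial_count = 0L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  if (length(initial_count) != 1L || is.na(initial_count) ||
      initial_count < 0 || initial_count != round(initial_count)) {
    abort("`initial_count` must be a single non-negative integer.")
  }
  structure(list(name = name, initial_count = as.integer(initial_count)),
            class = "mirffl_species")
}

#' Hill modulation term for a reaction propensity
#'
#' @param species Name of the regulating species.
#' @param K Dissociation constant (> 0).
#' @param n Hill coefficient (> 0).
#' @param type `"activation"` for \eqn{x^n/(K^n+x^n)} or `"repression"`
#'   for \eqn{1/(1+(x/K)^n)}.
#' @return A `hill_term` list.
#' @export
hill_term <- function(species, K, n = 2, type = c("activation", "repression")) {
  type <- match.arg(type)
  if (K <= 0 || n <= 0) abort("`K` and `n` must be positive.")
  structure(list(species = species, K = K, n = n, type = type),
            class = "mirffl_hill_term")
}

#' Declare a reaction
#'
#' A reaction carries a stoichiometric state change and a propensity
#' specification: a base rate constant, optional mass-action dependence on
#' reactant counts, and optional Hill factors. The propensity is
#' `rate * prod(falling_factorial(count, order)) * prod(hill factors)`;
#' zero-order (constitutive) reactions have an empty `order` and carry no
#' count factor.
#'
#' @param name Reaction identifier.
#' @param rate Base rate constant per unit time (>= 0; time units arbitrary).
#' @param stoich Named integer vector of species changes when the reaction
#'   fires (e.g. `c(protein = 1)`).
#' @param order Named integer vector of count-factor multiplicities. Defaults
#'   to the consumed multiplicities (`pmax(-stoich, 0)`), so plain mass
#'   action needs no explicit `order`; catalytic dependencies (a species that
#'   modulates the rate without being consumed, e.g. an mRNA template for
#'   translation) must be listed explicitly.
#' @param hill A [hill_term()] or list of them, or `NULL`.
#' @return A `reaction` list.
#' @export
reaction <- function(name, rate, stoich, order = NULL, hill = NULL) {
  if (!is.character(name) || length(name) != 1L) {
    abort("`name` must be a string.")
  }
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0) {
    abort(sprintf("reaction '%s': `rate` must be a single finite value >= 0.",
                  name))
  }
  if (length(stoich) == 0L || is.null(names(stoich)) ||
      any(!nzchar(names(stoich)))) {
    abort(sprintf("reaction '%s': `stoich` must be a named vector.", name))
  }
  if (any(stoich != round(stoich))) {
    abort(sprintf("reaction '%s': stoichiometry must be integer.", name))
  }
  stoich <- vapply(stoich, as.integer, integer(1))
  if (is.null(order)) {
    order <- pmax(-stoich, 0L)
    order <- order[order > 0L]
  } else {
    if (length(order) > 0L && is.null(names(order))) {
      abort(sprintf("reaction '%s': `order` must be named.", name))
    }
    order <- vapply(order, as.integer, integer(1))
    if (any(order < 0L)) {
      abort(sprintf("reaction '%s': `order` must be non-negative.", name))
    }
  }
  # consumed species must appear in the count factor so the propensity
  # vanishes before any count can go negative
  consumed <- -pmin(stoich, 0L)
  consumed <- consumed[consumed > 0L]
  for (s in names(consumed)) {
    if (is.na(order[s]) || order[s] < consumed[[s]]) {
      abort(sprintf(
        "reaction '%s': consumed species '%s' needs order >= %d so its propensity vanishes at low counts.",
        name, s, consumed[[s]]))
    }
  }
  if (inherits(hill, "mirffl_hill_term")) hill <- list(hill)
  if (!is.null(hill) &&
      !all(vapply(hill, inherits, logical(1), "mirffl_hill_term"))) {
    abort(sprintf("reaction '%s': `hill` must be hill_term() objects.", name))
  }
  structure(list(name = name, rate = rate, stoich = stoich,
                 order = order, hill = hill %||% list()),
            class = "mirffl_reaction")
}

#' Assemble a reaction network
#'
#' @param species List of [species()] declarations; names must be unique.
#' @param reactions List of [reaction()] declarations; every species a
#'   reaction references (stoichiometry, order, Hill terms) must be declared.
#' @return A `reaction_network` object.
#' @examples
#' net <- reaction_network(
#'   species = list(species("X", 0)),
#'   reactions = list(
#'     reaction("birth", 10, c(X = 1)),
#'     reaction("death", 1, c(X = -1))
#'   )
#' )
#' simulate_ssa(net, t_end = 20, seed = 1)
#' @export
reaction_network <- function(species, reactions) {
  if (inherits(species, "mirffl_species")) species <- list(species)
  if (inherits(reactions, "mirffl_reaction")) reactions <- list(reactions)
  if (!all(vapply(species, inherits, logical(1), "mirffl_species"))) {
    abort("`species` must be a list of species() declarations.")
  }
  if (!all(vapply(reactions, inherits, logical(1), "mirffl_reaction"))) {
    abort("`reactions` must be a list of reaction() declarations.")
  }
  nm <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("species names must be unique.")
  for (r in reactions) {
    refs <- unique(c(names(r$stoich), names(r$order),
                     vapply(r$hill, `[[`, character(1), "species")))
    missing <- setdiff(refs, nm)
    if (length(missing)) {
      abort(sprintf("reaction '%s' references undeclared species: %s",
                    r$name, paste(missing, collapse = ", ")))
    }
  }
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  cat("species: ", paste(species_names(x), collapse = ", "), "\n", sep = "")
  for (r in x$reactions) {
    chg <- paste(sprintf("%s%+d", names(r$stoich), r$stoich), collapse = ", ")
    cat(sprintf("  %-18s rate %-8g  %s\n", r$name, r$rate, chg))
  }
  invisible(x)
}

#' Species names of a network
#' @param network A [reaction_network()].
#' @return Character vector of declared species names.
#' @export
species_names <- function(network) {
  vapply(network$species, `[[`, character(1), "name")
}

# Compile a network into the matrix form consumed by the C++ kernel.
compile_network <- function(network) {
  nm <- species_names(network)
  n_s <- length(nm)
  n_r <- length(network$reactions)
  init <- vapply(network$species, `[[`, integer(1), "initial_count")
  stoich <- matrix(0L, n_r, n_s, dimnames = list(NULL, nm))
  order <- matrix(0L, n_r, n_s, dimnames = list(NULL, nm))
  rate <- numeric(n_r)
  hill_rows <- list()
  for (i in seq_len(n_r)) {
    r <- network$reactions[[i]]
    rate[i] <- r$rate
    stoich[i, names(r$stoich)] <- r$stoich
    if (length(r$order)) order[i, names(r$order)] <- r$order
    for (h in r$hill) {
      hill_rows[[length(hill_rows) + 1L]] <-
        c(i, match(h$species, nm), h$K, h$n,
          as.numeric(h$type == "repression"))
    }
  }
  hill <- if (length(hill_rows)) do.call(rbind, hill_rows) else
    matrix(numeric(0), 0, 5)
  list(init = init, stoich = stoich, rate = rate, order = order, hill = hill)
}

#' Evaluate reaction propensities at a state
#'
#' Mostly a diagnostic/verification aid; the stochastic simulator evaluates
#' the same composition in compiled code. With `deterministic = TRUE`,
#' count factors use plain powers `x^m` instead of falling factorials, the
#' convention for continuous mean-field states.
#'
#' @param network A [reaction_network()].
#' @param state Named (or positionally matched) numeric state vector.
#' @param deterministic Use continuous mean-field count factors.
#' @return Named numeric vector of propensities, one per reaction.
#' @export
propensities <- function(network, state, deterministic = FALSE) {
  nm <- species_names(network)
  if (!is.null(names(state))) state <- state[nm]
  if (length(state) != length(nm) || any(is.na(state))) {
    abort("`state` must supply one value per declared species.")
  }
  state <- as.numeric(state)
  names(state) <- nm
  out <- vapply(network$reactions, function(r) {
    a <- r$rate
    for (s in names(r$order)) {
      m <- r$order[[s]]
      a <- a * if (deterministic) state[[s]]^m else
        prod(pmax(state[[s]] - seq_len(m) + 1, 0))
    }
    for (h in r$hill) {
      a <- a * if (h$type == "repression") {
        hill_repression(state[[h$species]], h$K, h$n)
      } else {
        hill_activation(state[[h$species]], h$K, h$n)
      }
    }
    a
  }, numeric(1))
  setNames(out, vapply(network$reactions, `[[`, character(1), "name"))
}

#' Deterministic mean-field steady state of a network
#'
#' Integrates the mean-field rate equations \eqn{dx/dt = S^T a(x)} (Hill
#' factors evaluated at the continuous state) until the state stops moving,
#' giving the ODE fixed point that the stochastic ensemble mean approximates
#' when fluctuations are small.
#'
#' @param network A [reaction_network()].
#' @param t_max Integration horizon (default generous; integration stops
#'   early once the relative derivative norm falls below `tol`).
#' @param tol Convergence tolerance on `max |dx/dt| / (1 + |x|)`.
#' @return Named numeric vector of steady-state copy numbers.
#' @export
meanfield_steady_state <- function(network, t_max = 1e5, tol = 1e-10) {
  nm <- species_names(network)
  init <- vapply(network$species, `[[`, integer(1), "initial_count")
  cm <- compile_network(network)
  deriv <- function(t, y, parms) {
    a <- propensities(network, setNames(y, nm), deterministic = TRUE)
    list(as.numeric(crossprod(cm$stoich, a)))
  }
  rootfun <- function(t, y, parms) {
    dy <- deriv(t, y, parms)[[1]]
    max(abs(dy) / (1 + abs(y))) - tol
  }
  out <- deSolve::lsodar(y = as.numeric(init), times = c(0, t_max),
                         func = deriv, rootfunc = rootfun)
  setNames(as.numeric(out[nrow(out), -1]), nm)
}

#' Load a reaction network from a YAML or JSON config file
#'
#' The schema mirrors the constructors: a `species` list of
#' `{name, initial_count}` entries and a `reactions` list of
#' `{name, rate, stoich, order, hill}` entries, where `stoich`/`order` are
#' name-to-integer maps and each `hill` entry is
#' `{species, K, n, type}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a pre-parsed
#'   list with the same structure.
#' @return A [reaction_network()].
#' @export
network_from_config <- function(path) {
  cfg <- read_config(path)
  if (is.null(cfg$species) || is.null(cfg$reactions)) {
    abort("config must contain `species` and `reactions` blocks.")
  }
  sp <- lapply(cfg$species, function(s) {
    species(s$name, s$initial_count %||% 0L)
  })
  rx <- lapply(cfg$reactions, function(r) {
    if (is.null(r$rate) || is.null(r$stoich)) {
      abort(sprintf("reaction '%s': `rate` and `stoich` are required.",
                    r$name %||% "?"))
    }
    hill <- lapply(r$hill %||% list(), function(h) {
      hill_term(h$species, h$K, h$n %||% 2, h$type %||% "activation")
    })
    reaction(r$name, r$rate, unlist(r$stoich),
             order = if (!is.null(r$order)) unlist(r$order),
             hill = if (length(hill)) hill)
  })
  reaction_network(sp, rx)
}

read_config <- function(path) {
  if (is.list(path)) return(path)
  if (!is.character(path) || !file.exists(path)) {
    abort("config must be a list or a path to an existing file.")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}
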