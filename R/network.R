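# Mass-action reaction networks and exact stochastic simulation
# (Gillespie's direct method), providing white-box sample sources for the
# verification algorithms.

#' Load a reaction network (or Bernoulli surrogate) from JSON
#'
#' Schema: top-level keys \code{species} (map name -> initial count),
#' \code{reactions} (list of \code{{reactants: map, products: map,
#' rate: number}}) and \code{horizon} (simulation end time, model time
#' units). A surrogate model \code{{"type": "bernoulli", "p": number}} is
#' accepted wherever a network is, for experiments against a known
#' satisfaction probability.
#'
#' @param document path to a JSON file, a JSON string, or an equivalent R
#'   list.
#' @return an object of class \code{"reaction_network"} or
#'   \code{"bernoulli_model"}.
#' @export
load_network <- function(document) {
  doc <- if (is.character(document) && length(document) == 1L) {
    jsonlite::fromJSON(document, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else if (is.list(document)) {
    document
  } else stop("document must be a path, JSON string, or list")

  if (!is.null(doc$type)) {
    if (doc$type != "bernoulli") stop("unknown model type: ", doc$type)
    p <- doc$p
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
      stop("bernoulli model: p must be a probability in [0, 1]")
    return(structure(list(p = as.numeric(p)), class = "bernoulli_model"))
  }

  if (is.null(doc$species) || is.null(doc$reactions) || is.null(doc$horizon))
    stop("network document must have 'species', 'reactions' and 'horizon'")
  counts <- unlist(doc$species)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("species must be a named map of initial counts")
  if (any(counts < 0) || any(counts != trunc(counts)))
    stop("species counts must be nonnegative integers")
  horizon <- doc$horizon
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("horizon must be a positive number")
  sp <- names(counts)
  nr <- length(doc$reactions)
  if (nr == 0L) stop("network must declare at least one reaction")
  R <- P <- matrix(0L, nrow = nr, ncol = length(sp), dimnames = list(NULL, sp))
  rates <- numeric(nr)
  stoich <- function(mp, what, j) {
    v <- unlist(mp)
    if (is.null(v)) return(integer(0))
    unknown <- setdiff(names(v), sp)
    if (length(unknown))
      stop(sprintf("reaction %d %s reference undeclared species: %s",
                   j, what, paste(unknown, collapse = ", ")))
    if (any(v < 0) || any(v != trunc(v)))
      stop(sprintf("reaction %d: stoichiometries must be nonnegative integers", j))
    v
  }
  for (j in seq_len(nr)) {
    rx <- doc$reactions[[j]]
    r <- stoich(rx$reactants, "reactants", j)
    p <- stoich(rx$products, "products", j)
    R[j, names(r)] <- as.integer(r)
    P[j, names(p)] <- as.integer(p)
    if (!is.numeric(rx$rate) || length(rx$rate) != 1L || rx$rate <= 0)
      stop(sprintf("reaction %d: rate must be a positive number", j))
    rates[j] <- rx$rate
  }
  structure(
    list(species = as.numeric(counts), species_names = sp,
         reactants = R, products = P, net = P - R,
         rates = rates, horizon = as.numeric(horizon)),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction network> %d species, %d reactions, horizon %g\n",
              length(x$species), nrow(x$reactants), x$horizon))
  invisible(x)
}

#' @export
print.bernoulli_model <- function(x, ...) {
  cat(sprintf("<bernoulli surrogate model> p = %g\n", x$p))
  invisible(x)
}

# Mass-action propensities with combinatorial (falling-factorial) counting:
# a_j = k_j * prod_i x_i * (x_i - 1) * ... * (x_i - r_ij + 1).
propensities <- function(net, x) {
  a <- net$rates
  for (j in seq_along(a)) {
    r <- net$reactants[j, ]
    idx <- which(r > 0L)
    for (i in idx) {
      ri <- r[[i]]
      xi <- x[[i]]
      if (xi < ri) { a[j] <- 0; break }
      a[j] <- a[j] * prod(xi - seq_len(ri) + 1)
    }
  }
  a
}

# One SSA trajectory under the *current* RNG stream. Every event is
# recorded; the trace ends at the first event time >= horizon or when all
# propensities vanish.
ssa_run <- function(net) {
  x <- net$species
  t <- 0
  cap <- 64L
  times <- numeric(cap)
  states <- matrix(0, nrow = cap, ncol = length(x))
  times[1L] <- 0; states[1L, ] <- x
  k <- 1L
  repeat {
    a <- propensities(net, x)
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1L, a0)
    j <- sample.int(length(a), 1L, prob = a)
    x <- x + net$net[j, ]
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      times <- c(times, numeric(cap - length(times)))
      states <- rbind(states, matrix(0, nrow = cap - nrow(states), ncol = ncol(states)))
    }
    times[k] <- t
    states[k, ] <- x
    if (t >= net$horizon) break
  }
  tr <- data.frame(time = times[seq_len(k)])
  st <- states[seq_len(k), , drop = FALSE]
  colnames(st) <- net$species_names
  cbind(tr, as.data.frame(st))
}

#' Simulate one exact SSA trajectory
#'
#' Gillespie's direct method: exponential waiting times at the total
#' propensity, reaction choice proportional to individual propensities,
#' mass-action propensities with falling-factorial counting. The trace
#' starts at t = 0 and ends at the first event time at or beyond the
#' network horizon, or when the total propensity reaches zero. Identical
#' seeds give identical traces.
#'
#' @param net a \code{reaction_network} from [load_network()].
#' @param seed integer seed.
#' @return data frame with a \code{time} column and one column per species.
#' @export
simulate_trace <- function(net, seed = 1L) {
  stopifnot(inherits(net, "reaction_network"))
  src <- new_sample_source(generate = NULL, kind = "ssa", seed = seed)
  with_source_rng(src, ssa_run(net))
}

#' Sample source judging a temporal property on fresh trajectories
#'
#' Each draw simulates one fresh SSA trajectory of the network and returns
#' the verdict of [evaluate_formula()] on it. For a Bernoulli surrogate
#' model the formula is ignored and draws come from [bernoulli_source()].
#'
#' @param net a \code{reaction_network} or \code{bernoulli_model}.
#' @param formula a \code{temporal_formula} or property string.
#' @param seed integer seed.
#' @return an object of class \code{"sample_source"}.
#' @export
property_source <- function(net, formula, seed = 1L) {
  if (inherits(net, "bernoulli_model")) return(bernoulli_source(net$p, seed))
  stopifnot(inherits(net, "reaction_network"))
  if (is.character(formula)) formula <- parse_formula(formula)
  core <- if (formula$kind == "timed") formula$sub else formula
  missing <- setdiff(formula_species(core), net$species_names)
  if (length(missing))
    stop("formula references species absent from the network: ",
         paste(missing, collapse = ", "))
  new_sample_source(
    generate = function(src, k) {
      with_source_rng(src, vapply(seq_len(k), function(i)
        evaluate_formula(src$formula, ssa_run(src$net)), logical(1)))
    },
    kind = "ssa-property", seed = seed,
    fields = list(net = net, formula = formula)
  )
}
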