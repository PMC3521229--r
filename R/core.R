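#' Verification problem: the claim Pr{psi} rel theta
#'
#' A verification problem asks whether a stochastic system satisfies a path
#' property \code{psi} with probability related to a threshold \code{theta}.
#' Only \code{theta} strictly inside (0, 1) is accepted: at 0 or 1 the
#' underlying hypothesis tests are degenerate.
#'
#' @param relation one of \code{"GE"}, \code{"GT"}, \code{"LE"}, \code{"LT"}
#'   (at least / strictly more / at most / strictly less).
#' @param theta probability threshold, strictly in (0, 1).
#' @param property_id opaque handle naming the property or sample source;
#'   informational only.
#' @return an object of class \code{"verification_problem"}.
#' @seealso [normalize_problem()]
#' @export
verification_problem <- function(relation = c("GE", "GT", "LE", "LT"),
                                 theta, property_id = "psi") {
  relation <- match.arg(relation)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta >= 1) {
    stop("invalid problem: theta must be a single probability strictly in (0, 1)")
  }
  structure(
    list(relation = relation, theta = as.numeric(theta),
         property_id = as.character(property_id)),
    class = "verification_problem"
  )
}

#' @export
print.verification_problem <- function(x, ...) {
  op <- c(GE = ">=", GT = ">", LE = "<=", LT = "<")[[x$relation]]
  cat(sprintf("<verification problem> P %s %g { %s }\n", op, x$theta, x$property_id))
  invisible(x)
}

#' Test parameters for the sequential algorithms
#'
#' Bundles the error bounds and auxiliary knobs consumed by the tests:
#' \code{alpha} (probability of wrongly answering FALSE when the claim holds,
#' Type-1), \code{beta} (probability of wrongly answering TRUE, Type-2),
#' \code{gamma} (bound on the undecided rate of the two-test procedure),
#' \code{delta} (indifference half-width, baselines only) and
#' \code{max_samples} (global cap, capped algorithm only).
#'
#' @param alpha,beta error bounds, each strictly in (0, 1).
#' @param gamma undecided-rate bound strictly in (0, 1), or \code{"auto"}
#'   meaning \code{min(alpha, beta)}.
#' @param delta indifference half-width in (0, 1]; \code{NA} when the
#'   algorithm chooses it itself.
#' @param max_samples positive sample cap, or \code{Inf} for unbounded.
#' @return an object of class \code{"test_parameters"}.
#' @export
test_parameters <- function(alpha = 0.01, beta = 0.01, gamma = "auto",
                            delta = NA_real_, max_samples = Inf) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
      stop(sprintf("invalid parameters: %s must be strictly in (0, 1)", nm))
  }
  chk_prob(alpha, "alpha")
  chk_prob(beta, "beta")
  if (identical(gamma, "auto")) gamma <- min(alpha, beta) else chk_prob(gamma, "gamma")
  if (!is.na(delta)) {
    if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1)
      stop("invalid parameters: delta must be in (0, 1]")
  }
  if (!(is.numeric(max_samples) && length(max_samples) == 1L &&
        (is.infinite(max_samples) || (max_samples >= 1 && max_samples == trunc(max_samples)))))
    stop("invalid parameters: max_samples must be a positive count or Inf")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         delta = as.numeric(delta), max_samples = max_samples),
    class = "test_parameters"
  )
}

#' Normalize a verification problem to the relation ">="
#'
#' All algorithms operate on claims of the form \code{P >= theta}. Strict
#' relations are not statistically distinguishable from their non-strict
#' counterparts, so \code{GT} maps to \code{GE} unchanged. \code{LE}/\code{LT}
#' are handled by the complement identity
#' \code{P<=theta\{psi\} == P>=1-theta\{!psi\}}: the threshold becomes
#' \code{1 - theta} and every sample outcome is negated before tallying
#' (\code{outcome_flip = TRUE}). The decision (TRUE/FALSE) of the normalized
#' problem is the decision of the original claim; it is never re-flipped.
#'
#' Idempotent on \code{GE} problems.
#'
#' @param problem a [verification_problem()].
#' @return a list with elements \code{problem} (relation \code{GE}) and
#'   \code{outcome_flip} (logical).
#' @export
normalize_problem <- function(problem) {
  stopifnot(inherits(problem, "verification_problem"))
  flip <- problem$relation %in% c("LE", "LT")
  theta <- if (flip) 1 - problem$theta else problem$theta
  norm <- verification_problem("GE", theta, problem$property_id)
  list(problem = norm, outcome_flip = flip)
}

relation_holds <- function(p, relation, theta) {
  switch(relation,
    GE = p >= theta,
    GT = p > theta,
    LE = p <= theta,
    LT = p < theta,
    stop("unknown relation: ", relation)
  )
}

#' Construct a verification result
#'
#' Container for the outcome of one verification run. \code{p_value} is
#' present exactly when the decision is definite but not error-bounded
#' (the capped algorithm's fallback and the fixed-sample black-box test).
#'
#' @param decision \code{"TRUE"}, \code{"FALSE"} or \code{"UNDECIDED"}.
#' @param guaranteed logical; do the requested error bounds hold?
#' @param samples_used total samples consumed.
#' @param successes number of satisfying samples among them (after any
#'   outcome flip from [normalize_problem()]).
#' @param algorithm algorithm identifier string.
#' @param problem the original [verification_problem()].
#' @param p_value p-value of the accepted hypothesis, or \code{NA}.
#' @param p_value_other p-value of the rejected hypothesis, or \code{NA}.
#' @param final_delta indifference half-width in force at termination, or
#'   \code{NA}.
#' @param record optional algorithm-specific run record (e.g. the
#'   delta-halving schedule).
#' @return object of class \code{"verification_result"}.
#' @export
verification_result <- function(decision, guaranteed, samples_used, successes,
                                algorithm, problem,
                                p_value = NA_real_, p_value_other = NA_real_,
                                final_delta = NA_real_, record = NULL) {
  stopifnot(decision %in% c("TRUE", "FALSE", "UNDECIDED"),
            samples_used >= successes, successes >= 0)
  if (!is.na(p_value) && (!isFALSE(guaranteed) || decision == "UNDECIDED"))
    stop("p_value may only accompany a definite, non-guaranteed decision")
  structure(
    list(decision = decision, guaranteed = isTRUE(guaranteed),
         p_value = p_value, p_value_other = p_value_other,
         samples_used = as.numeric(samples_used),
         successes = as.numeric(successes),
         final_delta = final_delta, algorithm = algorithm,
         problem = problem, record = record),
    class = "verification_result"
  )
}

#' @export
print.verification_result <- function(x, ...) {
  cat(sprintf("<verification result> [%s]\n", x$algorithm))
  print(x$problem)
  cat(sprintf("  decision:   %s (%s)\n", x$decision,
              if (x$guaranteed) "error-bounded" else "p-value based"))
  cat(sprintf("  samples:    %g (successes %g)\n", x$samples_used, x$successes))
  if (!is.na(x$final_delta))
    cat(sprintf("  final delta: %g\n", x$final_delta))
  if (!is.na(x$p_value))
    cat(sprintf("  p-value:    %.6g (other hypothesis: %.6g)\n",
                x$p_value, x$p_value_other))
  invisible(x)
}
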