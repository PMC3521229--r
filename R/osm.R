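# Optimized sequential model checking: delta-halving with sample reuse,
# optionally under a global sample cap with a binomial p-value fallback.

#' Sequential verification with automatic indifference-region halving
#'
#' Removes the user-chosen indifference half-width: delta starts at 1 (the
#' widest possible region, needing the fewest samples) with
#' \code{gamma = min(alpha, beta)}, and the two-acceptance-test procedure is
#' run incrementally. Whenever it returns UNDECIDED, delta is halved and the
#' procedure re-enters with the accumulated tally (n, d) -- no sample is ever
#' drawn twice, so the total draw count equals the n at which the last
#' incremental call decided. The answer is always definite (TRUE or FALSE)
#' and error-bounded by \code{<alpha, beta>}.
#'
#' If the true probability equals theta exactly the procedure need not
#' terminate; use [osm_b()] with a sample cap in that regime.
#'
#' @param problem a [verification_problem()].
#' @param alpha,beta error bounds, each strictly in (0, 0.5).
#' @param source a sample source.
#' @return a [verification_result()] with \code{guaranteed = TRUE}; its
#'   \code{record} holds the delta schedule (1, 1/2, 1/4, ...) and the tally
#'   size at the end of each level.
#' @export
osm_a <- function(problem, alpha, beta, source) {
  r <- osm_run(problem, alpha, beta, Inf, source)
  stopifnot(r$decision %in% c("TRUE", "FALSE"))  # cap is infinite
  verification_result(
    decision = r$decision, guaranteed = TRUE,
    samples_used = r$n, successes = r$d,
    final_delta = r$delta, algorithm = "osm-a", problem = problem,
    record = r$record
  )
}

#' Capped sequential verification with p-value fallback
#'
#' Identical to [osm_a()] while fewer than \code{max_samples} outcomes have
#' been drawn; the cap is a global budget across all delta levels. If a
#' boundary is crossed at or before the capped sample, that error-bounded
#' decision wins. Otherwise the run falls back to the fixed-sample rule:
#' accept whichever of H0: p >= theta, H1: p < theta has the lower binomial
#' p-value (\code{1 - F(d; n, theta)} vs \code{F(d; n, theta)}), report that
#' p-value, and flag the result as not guaranteed. Never UNDECIDED, and
#' always terminates, even when p = theta exactly.
#'
#' @inheritParams osm_a
#' @param max_samples positive global sample cap.
#' @return a [verification_result()]; \code{guaranteed = FALSE} with a
#'   p-value iff the cap forced the fallback.
#' @export
osm_b <- function(problem, alpha, beta, max_samples, source) {
  stopifnot(is.numeric(max_samples), max_samples >= 1)
  r <- osm_run(problem, alpha, beta, max_samples, source)
  if (r$decision %in% c("TRUE", "FALSE")) {
    return(verification_result(
      decision = r$decision, guaranteed = TRUE,
      samples_used = r$n, successes = r$d,
      final_delta = r$delta, algorithm = "osm-b", problem = problem,
      record = r$record
    ))
  }
  # Budget exhausted (or undecided exactly at the cap): lower-p-value rule
  # on the normalized claim.
  theta <- if (r$flip) 1 - problem$theta else problem$theta
  pv <- lower_pvalue_decision(r$d, r$n, theta)
  verification_result(
    decision = pv$decision, guaranteed = FALSE,
    samples_used = r$n, successes = r$d,
    p_value = pv$p_value, p_value_other = pv$p_value_other,
    final_delta = r$delta, algorithm = "osm-b", problem = problem,
    record = c(r$record, list(pvalue_tie = pv$tie))
  )
}

# Shared delta-halving loop. Returns the raw outcome: decision is TRUE/FALSE
# (error-bounded) or BUDGET_EXHAUSTED/UNDECIDED-at-cap.
osm_run <- function(problem, alpha, beta, max_samples, source) {
  stopifnot(alpha > 0, alpha < 0.5, beta > 0, beta < 0.5)
  np <- normalize_problem(problem)
  theta <- np$problem$theta
  gamma <- min(alpha, beta)
  delta <- 1
  n <- 0; d <- 0
  schedule <- numeric(0)
  n_levels <- numeric(0)
  repeat {
    state <- two_test_state(theta, delta, alpha, beta, gamma, n = n, d = d)
    r <- younes_b_incremental(state, source, max_samples, np$outcome_flip)
    n <- r$state$n; d <- r$state$d
    schedule <- c(schedule, delta)
    n_levels <- c(n_levels, n)
    record <- list(delta_schedule = schedule, n_at_each_level = n_levels)
    if (r$decision %in% c("TRUE", "FALSE")) {
      return(list(decision = r$decision, n = n, d = d, delta = delta,
                  record = record, flip = np$outcome_flip))
    }
    if (r$decision == "BUDGET_EXHAUSTED" ||
        (r$decision == "UNDECIDED" && n >= max_samples)) {
      # An UNDECIDED stop exactly at the cap cannot become definite by
      # halving delta at the same n (prefix property of the two tests), so
      # both cases fall through to the caller's fallback.
      return(list(decision = "BUDGET_EXHAUSTED", n = n, d = d, delta = delta,
                  record = record, flip = np$outcome_flip))
    }
    delta <- delta / 2
  }
}
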