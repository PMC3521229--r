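# Baseline sequential tests.
#
# Both tests observe i.i.d. Bernoulli outcomes x_1, x_2, ... and accumulate
# log-likelihood ratios. The loops below draw outcomes in growing batches,
# evaluate the stopping rule vectorially over the batch, and push unused
# outcomes back to the source, which is draw-for-draw equivalent to the
# one-sample-at-a-time formulation.

CHUNK_MIN <- 64L
CHUNK_MAX <- 65536L

#' Wald SPRT with indifference region
#'
#' Tests H0: p >= theta + delta against H1: p < theta - delta with Wald's
#' sequential probability ratio test. After n samples with d successes the
#' log ratio is
#' \code{d*log((theta-delta)/(theta+delta)) +
#'       (n-d)*log((1-theta+delta)/(1-theta-delta))};
#' H0 is accepted (decision TRUE) when it drops to \code{log(beta/(1-alpha))},
#' H1 (decision FALSE) when it reaches \code{log((1-beta)/alpha)}. The result
#' is always definite and flagged as guaranteed, but the bounds
#' \code{<alpha, beta>} only hold when the true probability lies outside the
#' indifference region \code{[theta-delta, theta+delta]} -- the test itself
#' cannot tell the caller whether that is the case.
#'
#' @param problem a [verification_problem()]; any relation (normalized
#'   internally).
#' @param params a [test_parameters()] with a finite \code{delta} satisfying
#'   \code{delta < min(theta, 1-theta)} after normalization.
#' @param source a sample source such as [bernoulli_source()].
#' @return a [verification_result()]; never UNDECIDED.
#' @export
younes_a <- function(problem, params, source) {
  np <- normalize_problem(problem)
  theta <- np$problem$theta
  flip <- np$outcome_flip
  delta <- params$delta
  alpha <- params$alpha
  beta <- params$beta
  if (is.na(delta) || delta >= min(theta, 1 - theta))
    stop("invalid parameters: need 0 < delta < min(theta, 1 - theta)")
  logA <- log((1 - beta) / alpha)
  logB <- log(beta / (1 - alpha))
  inc_s <- log((theta - delta) / (theta + delta))
  inc_f <- log((1 - theta + delta) / (1 - theta - delta))

  n <- 0; d <- 0; chunk <- CHUNK_MIN
  repeat {
    raw <- draw_samples(source, chunk)
    x <- if (flip) !raw else raw
    dc <- d + cumsum(x)
    nv <- n + seq_along(x)
    f <- dc * inc_s + (nv - dc) * inc_f
    hit <- which(f <= logB | f >= logA)
    if (length(hit)) {
      i <- hit[[1L]]
      if (i < length(raw)) pushback_samples(source, raw[(i + 1L):length(raw)])
      return(verification_result(
        decision = if (f[[i]] <= logB) "TRUE" else "FALSE",
        guaranteed = TRUE, samples_used = nv[[i]], successes = dc[[i]],
        final_delta = delta, algorithm = "younes-a", problem = problem
      ))
    }
    n <- nv[[length(x)]]; d <- dc[[length(x)]]
    chunk <- min(chunk * 2L, CHUNK_MAX)
  }
}

#' State of the two-acceptance-test procedure
#'
#' Sets up the two simultaneous one-sided tests
#' \itemize{
#'   \item test 1: H0: p >= theta vs H1: p < theta - delta, strength
#'     (alpha, gamma);
#'   \item test 2: H0': p >= theta + delta vs H1': p < theta, strength
#'     (gamma, beta);
#' }
#' with log-space boundaries \code{A1 = log((1-gamma)/alpha)},
#' \code{B1 = log(gamma/(1-alpha))}, \code{A2 = log((1-beta)/gamma)},
#' \code{B2 = log(beta/(1-gamma))}. The hypothesis points are clamped into
#' [0, 1]: \code{p0 = max(theta-delta, 0)}, \code{p1 = min(theta+delta, 1)},
#' which makes \code{delta = 1} legal; at the clamped endpoints the
#' log-ratios take their limit values (a single success forces the first
#' ratio to -Inf when p0 = 0; a single failure forces the second to +Inf
#' when p1 = 1). The log-ratios are a function of (n, d) only and are
#' recomputed exactly, never accumulated.
#'
#' @param theta threshold in (0, 1).
#' @param delta indifference half-width in (0, 1].
#' @param alpha,beta,gamma strictly in (0, 1).
#' @param n,d tally carried in from a previous run at a different
#'   \code{delta} (sample reuse); default fresh.
#' @return object of class \code{"two_test_state"}.
#' @export
two_test_state <- function(theta, delta, alpha, beta, gamma, n = 0, d = 0) {
  stopifnot(theta > 0, theta < 1, delta > 0, delta <= 1,
            alpha > 0, alpha < 1, beta > 0, beta < 1,
            gamma > 0, gamma < 1, d >= 0, n >= d)
  p0 <- max(theta - delta, 0)
  p1 <- min(theta + delta, 1)
  structure(list(
    theta = theta, delta = delta, alpha = alpha, beta = beta, gamma = gamma,
    p0 = p0, p1 = p1,
    A1 = log((1 - gamma) / alpha), B1 = log(gamma / (1 - alpha)),
    A2 = log((1 - beta) / gamma),  B2 = log(beta / (1 - gamma)),
    l1s = if (p0 > 0) log(p0 / theta) else -Inf,
    l1f = log((1 - p0) / (1 - theta)),
    l2s = log(theta / p1),
    l2f = if (p1 < 1) log((1 - theta) / (1 - p1)) else Inf,
    n = n, d = d
  ), class = "two_test_state")
}

# Vectorized log-ratios f (test 1) and f' (test 2) at tallies (nvec, dvec),
# with limit semantics at the clamped endpoints.
two_test_log_ratios <- function(state, nvec, dvec) {
  f <- if (state$p0 == 0) {
    ifelse(dvec == 0, nvec * state$l1f, -Inf)
  } else {
    dvec * state$l1s + (nvec - dvec) * state$l1f
  }
  fp <- if (state$p1 == 1) {
    ifelse(dvec == nvec, dvec * state$l2s, Inf)
  } else {
    dvec * state$l2s + (nvec - dvec) * state$l2f
  }
  list(f = f, fp = fp)
}

# Stopping rule: continue while either test is strictly inside its
# boundaries; on stop, TRUE iff both accept their null, FALSE iff both
# accept their alternative, otherwise UNDECIDED.
two_test_stopped <- function(state, lr) {
  (lr$f <= state$B1 | lr$f >= state$A1) &
    (lr$fp <= state$B2 | lr$fp >= state$A2)
}

two_test_verdict <- function(state, f, fp) {
  if (f < state$B1 && fp < state$B2) "TRUE"
  else if (f > state$A1 && fp > state$A2) "FALSE"
  else "UNDECIDED"
}

#' Incremental two-acceptance-test run
#'
#' Entry point for sample reuse: the state may carry a tally (n, d) already
#' drawn at a wider half-width. The stop condition is evaluated on the
#' carried-in tally first, without drawing -- a re-entry may immediately
#' yield a definite result or another UNDECIDED (requiring a further
#' reduction of delta). Otherwise outcomes are drawn until both tests decide
#' or the global budget \code{stop_at} is reached.
#'
#' @param state a [two_test_state()].
#' @param source a sample source.
#' @param stop_at global sample budget (total n, including the carried-in
#'   tally); \code{Inf} for unbounded.
#' @param outcome_flip negate outcomes before tallying (complement-transform
#'   plumbing; see [normalize_problem()]).
#' @return list with the updated \code{state} and \code{decision}, one of
#'   \code{"TRUE"}, \code{"FALSE"}, \code{"UNDECIDED"},
#'   \code{"BUDGET_EXHAUSTED"}.
#' @export
younes_b_incremental <- function(state, source, stop_at = Inf,
                                 outcome_flip = FALSE) {
  lr <- two_test_log_ratios(state, state$n, state$d)
  if (two_test_stopped(state, lr)) {
    return(list(state = state,
                decision = two_test_verdict(state, lr$f, lr$fp)))
  }
  chunk <- CHUNK_MIN
  while (state$n < stop_at) {
    m <- as.integer(min(chunk, stop_at - state$n))
    raw <- draw_samples(source, m)
    x <- if (outcome_flip) !raw else raw
    dc <- state$d + cumsum(x)
    nv <- state$n + seq_along(x)
    lr <- two_test_log_ratios(state, nv, dc)
    hit <- which(two_test_stopped(state, lr))
    if (length(hit)) {
      i <- hit[[1L]]
      if (i < length(raw)) pushback_samples(source, raw[(i + 1L):length(raw)])
      state$n <- nv[[i]]; state$d <- dc[[i]]
      return(list(state = state,
                  decision = two_test_verdict(state, lr$f[[i]], lr$fp[[i]])))
    }
    state$n <- nv[[m]]; state$d <- dc[[m]]
    chunk <- min(chunk * 2L, CHUNK_MAX)
  }
  list(state = state, decision = "BUDGET_EXHAUSTED")
}

#' Two-acceptance-test procedure (fixed indifference region)
#'
#' Runs the two simultaneous one-sided tests from a fresh tally with an
#' unbounded budget. Reports TRUE when both tests accept p >= theta, FALSE
#' when both accept the alternative, and UNDECIDED otherwise; definite
#' answers respect the error bounds \code{<alpha, beta>} for any true p, and
#' the UNDECIDED rate is bounded by \code{gamma} when p lies outside the
#' indifference region.
#'
#' @inheritParams younes_a
#' @param params a [test_parameters()] with finite \code{delta}; pass
#'   \code{gamma = "auto"} for \code{min(alpha, beta)}.
#' @return a [verification_result()]; may be UNDECIDED.
#' @export
younes_b <- function(problem, params, source) {
  np <- normalize_problem(problem)
  state <- two_test_state(np$problem$theta, params$delta,
                          params$alpha, params$beta, params$gamma)
  r <- younes_b_incremental(state, source, Inf, np$outcome_flip)
  verification_result(
    decision = r$decision, guaranteed = TRUE,
    samples_used = r$state$n, successes = r$state$d,
    final_delta = params$delta, algorithm = "younes-b", problem = problem
  )
}
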