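# Binomial tail statistics and the fixed-sample black-box decision rule.

#' Binomial cumulative distribution function
#'
#' \code{F(d; n, theta) = sum_{i=0}^{d} C(n,i) theta^i (1-theta)^(n-i)},
#' computed through the regularized incomplete beta function
#' (\code{stats::pbinom}), stable up to n ~ 1e6.
#'
#' @param d number of successes, \code{0 <= d <= n} (vectorized).
#' @param n number of trials, \code{n >= 1}.
#' @param theta success probability, strictly in (0, 1).
#' @return \code{F(d; n, theta)}.
#' @export
binom_cdf <- function(d, n, theta) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != trunc(n))
    stop("n must be a positive count")
  if (!is.numeric(d) || any(d < 0) || any(d > n) || any(d != trunc(d)))
    stop("d must be a count with 0 <= d <= n")
  if (!is.numeric(theta) || theta <= 0 || theta >= 1)
    stop("theta must be strictly in (0, 1)")
  stats::pbinom(d, n, theta)
}

#' p-values for the two one-sided binomial hypotheses
#'
#' For the hypotheses H0: p >= theta and H1: p < theta, given d successes in
#' n samples, the p-value for H0 is \code{1 - F(d; n, theta)} and the p-value
#' for H1 is \code{F(d; n, theta)}; they sum to one by construction.
#'
#' @inheritParams binom_cdf
#' @return list of class \code{"p_value_pair"} with elements \code{pval_H0}
#'   and \code{pval_H1}.
#' @export
p_values <- function(d, n, theta) {
  F <- binom_cdf(d, n, theta)
  structure(list(pval_H0 = 1 - F, pval_H1 = F), class = "p_value_pair")
}

#' Fixed-sample black-box decision
#'
#' The claim P >= theta is declared to hold iff the observed satisfaction
#' fraction \code{d/n} is at least \code{theta}; the reported p-value is that
#' of the accepted hypothesis (H0: p >= theta if TRUE, H1: p < theta
#' otherwise). The smaller the p-value, the greater the confidence; no
#' error-rate guarantee is attached.
#'
#' @inheritParams binom_cdf
#' @return list with \code{decision} ("TRUE"/"FALSE"), \code{p_value}, and
#'   the full \code{p_values} pair.
#' @export
blackbox_decide <- function(d, n, theta) {
  pv <- p_values(d, n, theta)
  holds <- (d / n) >= theta
  list(
    decision = if (holds) "TRUE" else "FALSE",
    p_value = if (holds) pv$pval_H0 else pv$pval_H1,
    p_values = pv
  )
}

# Lower-p-value rule used by the capped algorithm's fallback: TRUE iff
# pval_H0 < pval_H1, i.e. F(d; n, theta) > 1/2. The knife-edge tie
# F == 1/2 is resolved by the black-box rule (TRUE iff d/n >= theta) and
# flagged.
lower_pvalue_decision <- function(d, n, theta) {
  pv <- p_values(d, n, theta)
  tie <- pv$pval_H0 == pv$pval_H1
  holds <- if (tie) (d / n) >= theta else pv$pval_H0 < pv$pval_H1
  list(
    decision = if (holds) "TRUE" else "FALSE",
    p_value = if (holds) pv$pval_H0 else pv$pval_H1,
    p_value_other = if (holds) pv$pval_H1 else pv$pval_H0,
    tie = tie
  )
}
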