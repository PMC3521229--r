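# Independent reference implementations used as oracles. These follow the
# one-sample-at-a-time definitions directly (scalar loops, explicit
# case analysis) and share no code with the package's chunk-vectorized
# paths.

naive_binom_cdf <- function(d, n, theta) {
  sum(choose(n, 0:d) * theta^(0:d) * (1 - theta)^(n - (0:d)))
}

# Wald SPRT, one sample at a time. `stream` is a logical vector of
# outcomes; indexing is absolute.
ref_younes_a <- function(stream, theta, delta, alpha, beta) {
  A <- log((1 - beta) / alpha)
  B <- log(beta / (1 - alpha))
  n <- 0; d <- 0
  repeat {
    n <- n + 1
    if (stream[n]) d <- d + 1
    f <- d * log((theta - delta) / (theta + delta)) +
      (n - d) * log((1 - theta + delta) / (1 - theta - delta))
    if (f <= B) return(list(decision = "TRUE", n = n, d = d))
    if (f >= A) return(list(decision = "FALSE", n = n, d = d))
  }
}

ref_log_ratios <- function(theta, delta, n, d) {
  p0 <- max(theta - delta, 0)
  p1 <- min(theta + delta, 1)
  f <- if (p0 == 0) {
    if (d > 0) -Inf else n * log((1 - p0) / (1 - theta))
  } else {
    d * log(p0 / theta) + (n - d) * log((1 - p0) / (1 - theta))
  }
  fp <- if (p1 == 1) {
    if (d < n) Inf else d * log(theta / p1)
  } else {
    d * log(theta / p1) + (n - d) * log((1 - theta) / (1 - p1))
  }
  c(f, fp)
}

# Two simultaneous acceptance tests, one sample at a time, with the
# stop-condition re-check on entry (sample-reuse entry point).
ref_two_test <- function(stream, theta, delta, alpha, beta, gamma,
                         n = 0, d = 0, stop_at = Inf) {
  A1 <- log((1 - gamma) / alpha); B1 <- log(gamma / (1 - alpha))
  A2 <- log((1 - beta) / gamma);  B2 <- log(beta / (1 - gamma))
  stopped <- function(f, fp) !((B1 < f && f < A1) || (B2 < fp && fp < A2))
  verdict <- function(f, fp) {
    if (f < B1 && fp < B2) "TRUE"
    else if (f > A1 && fp > A2) "FALSE"
    else "UNDECIDED"
  }
  lr <- ref_log_ratios(theta, delta, n, d)
  if (stopped(lr[1], lr[2]))
    return(list(decision = verdict(lr[1], lr[2]), n = n, d = d))
  repeat {
    if (n >= stop_at) return(list(decision = "BUDGET_EXHAUSTED", n = n, d = d))
    n <- n + 1
    if (stream[n]) d <- d + 1
    lr <- ref_log_ratios(theta, delta, n, d)
    if (stopped(lr[1], lr[2]))
      return(list(decision = verdict(lr[1], lr[2]), n = n, d = d))
  }
}

ref_osm_a <- function(stream, theta, alpha, beta) {
  gamma <- min(alpha, beta)
  delta <- 1; n <- 0; d <- 0
  repeat {
    r <- ref_two_test(stream, theta, delta, alpha, beta, gamma, n, d)
    if (r$decision %in% c("TRUE", "FALSE"))
      return(list(decision = r$decision, n = r$n, d = r$d, delta = delta))
    n <- r$n; d <- r$d
    delta <- delta / 2
  }
}

# Brute-force recursive finite-trace evaluator (position-by-position
# definitions; derivative atoms are undefined at the final position).
ref_eval_at <- function(f, tr, i, m) {
  val <- function(o, j) {
    switch(o$type,
      const = o$value,
      species = tr[[o$name]][j],
      diff = if (j < m) tr[[o$name]][j + 1] - tr[[o$name]][j] else NA_real_)
  }
  switch(f$kind,
    atom = {
      a <- val(f$lhs, i); b <- val(f$rhs, i)
      if (is.na(a) || is.na(b)) return(NA)
      switch(f$op, "<" = a < b, "<=" = a <= b, ">" = a > b,
             ">=" = a >= b, "==" = a == b)
    },
    G = all(vapply(i:m, function(j)
      !isFALSE(ref_eval_at(f$sub, tr, j, m)), logical(1))),
    F = any(vapply(i:m, function(j)
      isTRUE(ref_eval_at(f$sub, tr, j, m)), logical(1))),
    U = any(vapply(i:m, function(j) {
      isTRUE(ref_eval_at(f$rhs, tr, j, m)) &&
        (j == i || all(vapply(i:(j - 1), function(k)
          isTRUE(ref_eval_at(f$lhs, tr, k, m)), logical(1))))
    }, logical(1)))
  )
}

ref_eval <- function(formula, trace) {
  if (formula$kind == "timed") {
    keep <- if (formula$op == ">") trace$time > formula$t
            else trace$time >= formula$t
    trace <- trace[keep, , drop = FALSE]
    formula <- formula$sub
  }
  m <- nrow(trace)
  if (m == 0) return(formula$kind == "G")
  isTRUE(ref_eval_at(formula, trace, 1, m))
}

# AST constructors for property tests (internal node helper).
f_node <- function(kind, ...) osmcheck:::node(kind, ...)

random_operand <- function() {
  r <- runif(1)
  if (r < 0.4) list(type = "species", name = sample(c("x", "y"), 1))
  else if (r < 0.7) list(type = "diff", name = sample(c("x", "y"), 1))
  else list(type = "const", value = sample(0:3, 1))
}

random_atom <- function() {
  f_node("atom", op = sample(c("<", "<=", ">", ">=", "=="), 1),
         lhs = random_operand(), rhs = random_operand())
}

random_formula <- function(depth = 2) {
  if (depth <= 0 || runif(1) < 0.3) return(random_atom())
  k <- sample(c("G", "F", "U"), 1)
  if (k == "U") f_node("U", lhs = random_formula(depth - 1),
                       rhs = random_formula(depth - 1))
  else f_node(k, sub = random_formula(depth - 1))
}

random_trace <- function(len) {
  data.frame(time = cumsum(rexp(len)),
             x = cumsum(sample(c(-1L, 0L, 1L), len, replace = TRUE)),
             y = sample(0:3, len, replace = TRUE))
}

# Negate a comparison atom (used by the G/F duality property; == excluded
# there since its negation is not a single comparison).
negate_atom <- function(a) {
  stopifnot(a$kind == "atom", a$op != "==")
  nop <- c("<" = ">=", "<=" = ">", ">" = "<=", ">=" = "<")[[a$op]]
  f_node("atom", op = nop, lhs = a$lhs, rhs = a$rhs)
}

table_row_params <- function(delta = NA, gamma = 0.01, max_samples = Inf) {
  test_parameters(alpha = 0.01, beta = 0.01, gamma = gamma, delta = delta,
                  max_samples = max_samples)
}

run_table_cell <- function(algorithm, theta, p, delta = NA, max_samples = Inf,
                           relation = "GE", reps = 1000, base_seed = 1) {
  run_benchmark(benchmark_config(
    algorithm, theta, p, relation = relation,
    params = table_row_params(delta = delta, max_samples = max_samples),
    replications = reps, base_seed = base_seed
  ))
}

expect_mean_close <- function(row, printed) {
  tol <- 3 * row$sd_n / sqrt(row$reps)
  expect_lt(abs(row$mean_n - printed), tol,
            label = sprintf("|mean %.1f - printed %.1f|", row$mean_n, printed))
}

expect_count_close <- function(observed, printed) {
  tol <- max(5, 3 * sqrt(printed))
  expect_lte(abs(observed - printed), tol,
             label = sprintf("|count %d - printed %d|", observed, printed))
}
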