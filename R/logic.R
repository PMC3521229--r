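# Finite-trace temporal logic: parsing and evaluation of properties over
# species trajectories.
#
# Grammar (square brackets around species names optional):
#   formula  := expr timequal?
#   timequal := '{' time ('>'|'>=') number '}'
#   expr     := unary ('U' expr)?          (right-associative until)
#   unary    := 'G' unary | 'F' unary | '(' expr ')' | atom
#   atom     := operand cmp operand        cmp in < <= > >= = ==
#   operand  := 'd' '(' ref ')' | ref | number
#   ref      := '[' name ']' | name
#
# Semantics are over the finite observation sequence s_0..s_m retained by
# the time qualifier: G phi at i means phi at all j >= i (the last recorded
# state persists), F the dual, phi U psi the usual bounded until. d(X) at
# position i is X(s_{i+1}) - X(s_i); the final position has no forward
# difference, so derivative atoms are *undefined* there: they can neither
# witness an F/U nor refute a G (this keeps G phi == !F(!phi)); an
# undefined verdict at the top level is reported as FALSE.

TOKEN_RE <- paste0(
  "^(?:",
  "(?<ws>\\s+)|",
  "(?<bref>\\[[^]]+\\])|",
  "(?<cmp><=|>=|==|≤|≥|<|>|=)|",
  "(?<punct>[(){}])|",
  "(?<num>[0-9]+\\.?[0-9]*(?:[eE][+-]?[0-9]+)?)|",
  "(?<id>[A-Za-z_][A-Za-z0-9_.\\-]*)",
  ")"
)

tokenize_formula <- function(text) {
  toks <- list()
  pos <- 1L
  rest <- text
  while (nchar(rest) > 0L) {
    m <- regexpr(TOKEN_RE, rest, perl = TRUE)
    if (m == -1L)
      stop(sprintf("syntax error at position %d: unexpected '%s'",
                   pos, substr(rest, 1, 1)))
    len <- attr(m, "match.length")
    lens <- attr(m, "capture.length")[1, ]
    kind <- names(lens)[which(lens > 0)][1]
    val <- substr(rest, 1, len)
    if (kind != "ws") {
      if (kind == "bref") val <- substr(val, 2, nchar(val) - 1)
      if (kind == "cmp" && val %in% c("≤", "≥", "="))
        val <- c("≤" = "<=", "≥" = ">=", "=" = "==")[[val]]
      toks[[length(toks) + 1L]] <- list(kind = if (kind == "bref") "name" else kind,
                                        value = val, pos = pos)
    }
    pos <- pos + len
    rest <- substr(rest, len + 1L, nchar(rest))
  }
  toks
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

new_parser <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$i <- 1L
  env
}
p_peek <- function(p) if (p$i <= length(p$toks)) p$toks[[p$i]] else NULL
p_next <- function(p) { t <- p_peek(p); p$i <- p$i + 1L; t }
p_expect <- function(p, kind, value = NULL) {
  t <- p_peek(p)
  if (is.null(t) || t$kind != kind || (!is.null(value) && t$value != value))
    stop(sprintf("syntax error at position %d: expected %s",
                 if (is.null(t)) -1L else t$pos, value %||% kind))
  p_next(p)
}

node <- function(kind, ...) structure(list(kind = kind, ...),
                                      class = "temporal_formula")

#' Parse a finite-trace temporal property
#'
#' Accepts properties such as \code{"G([gcy5] > [gcy6]) \{[time] > 300\}"}
#' and \code{"(d([lsy2N]) > 0) U (G(d([lsy2N]) <= 0))"}. Atoms compare
#' species values, one-step forward differences \code{d(X)}, or numeric
#' constants; \code{G}/\code{F}/\code{U} are the usual temporal operators;
#' an optional trailing \code{\{time > T\}} (or \code{>=}) restricts
#' evaluation to observations later than T.
#'
#' @param text property string (the probabilistic head, if any, must already
#'   be stripped; see [parse_claim()]).
#' @return an abstract syntax tree of class \code{"temporal_formula"}.
#' @export
parse_formula <- function(text) {
  p <- new_parser(tokenize_formula(text))
  e <- parse_expr(p)
  t <- p_peek(p)
  if (!is.null(t) && t$kind == "punct" && t$value == "{") {
    p_next(p)
    ref <- p_peek(p)
    if (is.null(ref) || !(ref$kind %in% c("name", "id")) || ref$value != "time")
      stop(sprintf("syntax error at position %d: expected time qualifier",
                   if (is.null(ref)) -1L else ref$pos))
    p_next(p)
    op <- p_expect(p, "cmp")
    if (!op$value %in% c(">", ">="))
      stop(sprintf("syntax error at position %d: time bound must use > or >=", op$pos))
    num <- p_expect(p, "num")
    tv <- as.numeric(num$value)
    if (tv < 0) stop("time bound must be nonnegative")
    p_expect(p, "punct", "}")
    e <- node("timed", op = op$value, t = tv, sub = e)
  }
  t <- p_peek(p)
  if (!is.null(t))
    stop(sprintf("syntax error at position %d: unexpected '%s'", t$pos, t$value))
  e
}

parse_expr <- function(p) {
  left <- parse_unary(p)
  t <- p_peek(p)
  if (!is.null(t) && t$kind == "id" && t$value == "U") {
    p_next(p)
    right <- parse_expr(p)
    return(node("U", lhs = left, rhs = right))
  }
  left
}

parse_unary <- function(p) {
  t <- p_peek(p)
  if (is.null(t)) stop("syntax error: unexpected end of property")
  if (t$kind == "id" && t$value %in% c("G", "F")) {
    p_next(p)
    return(node(t$value, sub = parse_unary(p)))
  }
  if (t$kind == "punct" && t$value == "(") {
    p_next(p)
    e <- parse_expr(p)
    p_expect(p, "punct", ")")
    return(e)
  }
  parse_atom(p)
}

parse_atom <- function(p) {
  lhs <- parse_operand(p)
  op <- p_expect(p, "cmp")
  rhs <- parse_operand(p)
  node("atom", op = op$value, lhs = lhs, rhs = rhs)
}

parse_operand <- function(p) {
  t <- p_peek(p)
  if (is.null(t)) stop("syntax error: unexpected end of property")
  if (t$kind == "num") {
    p_next(p)
    return(list(type = "const", value = as.numeric(t$value)))
  }
  if (t$kind == "id" && t$value == "d") {
    nxt <- if (p$i + 1L <= length(p$toks)) p$toks[[p$i + 1L]] else NULL
    if (!is.null(nxt) && nxt$kind == "punct" && nxt$value == "(") {
      p_next(p); p_next(p)
      ref <- p_peek(p)
      if (is.null(ref) || !(ref$kind %in% c("name", "id")))
        stop(sprintf("syntax error at position %d: expected species name",
                     if (is.null(ref)) -1L else ref$pos))
      p_next(p)
      p_expect(p, "punct", ")")
      return(list(type = "diff", name = ref$value))
    }
  }
  if (t$kind %in% c("name", "id")) {
    p_next(p)
    return(list(type = "species", name = t$value))
  }
  stop(sprintf("syntax error at position %d: unexpected '%s'", t$pos, t$value))
}

format_operand <- function(o) {
  switch(o$type,
    const = format(o$value),
    species = sprintf("[%s]", o$name),
    diff = sprintf("d([%s])", o$name)
  )
}

#' Serialize a temporal formula back to its textual form
#'
#' Round-trips with [parse_formula()]: parsing the output yields an
#' identical syntax tree.
#'
#' @param x a \code{temporal_formula}.
#' @param ... unused.
#' @return a property string.
#' @export
format.temporal_formula <- function(x, ...) {
  switch(x$kind,
    atom = sprintf("%s %s %s", format_operand(x$lhs), x$op, format_operand(x$rhs)),
    G = sprintf("G(%s)", format(x$sub)),
    F = sprintf("F(%s)", format(x$sub)),
    U = sprintf("(%s) U (%s)", format(x$lhs), format(x$rhs)),
    timed = sprintf("%s {[time] %s %g}", format(x$sub), x$op, x$t)
  )
}

#' @export
print.temporal_formula <- function(x, ...) {
  cat("<temporal formula>", format(x), "\n")
  invisible(x)
}

formula_species <- function(f) {
  if (is.null(f)) return(character(0))
  switch(f$kind,
    atom = {
      nm <- c(if (f$lhs$type != "const") f$lhs$name,
              if (f$rhs$type != "const") f$rhs$name)
      unique(nm)
    },
    U = unique(c(formula_species(f$lhs), formula_species(f$rhs))),
    timed = ,
    G = ,
    F = formula_species(f$sub %||% f$lhs)
  )
}

#' Evaluate a temporal formula on a finite trace
#'
#' The trace is a data frame with a \code{time} column and one column per
#' species (as produced by [simulate_trace()]). The time qualifier, if any,
#' first restricts the rows; the verdict is satisfaction at the first
#' retained observation. If no observation survives the restriction, a
#' top-level \code{G} is vacuously true and everything else is false.
#'
#' @param formula a parsed \code{temporal_formula} (or a string, parsed on
#'   the fly).
#' @param trace data frame of timed state observations.
#' @return a single logical verdict.
#' @export
evaluate_formula <- function(formula, trace) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "temporal_formula"), is.data.frame(trace))
  core <- formula
  if (formula$kind == "timed") {
    keep <- if (formula$op == ">") trace$time > formula$t else trace$time >= formula$t
    trace <- trace[keep, , drop = FALSE]
    core <- formula$sub
  }
  missing <- setdiff(formula_species(core), names(trace))
  if (length(missing))
    stop("unknown species in formula: ", paste(missing, collapse = ", "))
  m <- nrow(trace)
  if (m == 0L) return(core$kind == "G")
  isTRUE(eval_positions(core, trace, m)[[1L]])
}

# Satisfaction of `f` at every position 1..m. NA marks "undefined"
# (a derivative atom at the final position); temporal operators resolve it.
eval_positions <- function(f, trace, m) {
  switch(f$kind,
    atom = {
      a <- operand_values(f$lhs, trace, m)
      b <- operand_values(f$rhs, trace, m)
      switch(f$op,
        "<" = a < b, "<=" = a <= b, ">" = a > b, ">=" = a >= b,
        "==" = a == b)
    },
    G = {
      s <- eval_positions(f$sub, trace, m)
      refuted <- !s & !is.na(s)              # undefined cannot refute
      rev(cumsum(rev(refuted)) == 0)
    },
    F = {
      s <- eval_positions(f$sub, trace, m)
      witnessed <- s & !is.na(s)             # undefined cannot witness
      rev(cumsum(rev(witnessed)) > 0)
    },
    U = {
      a <- eval_positions(f$lhs, trace, m)
      b <- eval_positions(f$rhs, trace, m)
      u <- logical(m)
      u[m] <- isTRUE(b[m])
      if (m > 1L) for (i in (m - 1L):1L)
        u[i] <- isTRUE(b[i]) || (isTRUE(a[i]) && u[i + 1L])
      u
    },
    timed = stop("time qualifier is only allowed at the top level")
  )
}

operand_values <- function(o, trace, m) {
  switch(o$type,
    const = rep(o$value, m),
    species = trace[[o$name]],
    diff = c(diff(trace[[o$name]]), NA_real_)
  )
}

#' Split a probabilistic claim into threshold and path property
#'
#' Parses strings of the form \code{"P>=0.45 G([gcy5] > [gcy6]) \{[time] > 300\}"}
#' into a [verification_problem()] plus the path-formula text.
#'
#' @param text claim string beginning with \code{P} and a relation.
#' @return list with \code{problem} and \code{formula_text}.
#' @export
parse_claim <- function(text) {
  m <- regmatches(text, regexec(
    "^\\s*P\\s*(>=|<=|>|<|≥|≤)\\s*([0-9]*\\.?[0-9]+)\\s*(.*)$", text))[[1]]
  if (length(m) == 0L)
    stop("syntax error: expected a probabilistic head like 'P>=0.45 ...'")
  rel <- c(">=" = "GE", ">" = "GT", "<=" = "LE", "<" = "LT",
           "≥" = "GE", "≤" = "LE")[[m[2]]]
  theta <- as.numeric(m[3])
  list(problem = verification_problem(rel, theta, property_id = trimws(m[4])),
       formula_text = trimws(m[4]))
}
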