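# Replication harness: repeated seeded verification runs against a source
# with known ground truth, tallying errors, undecided outcomes and sample
# sizes in the shape of the error-rate / sample-size tables.

ALGORITHMS <- c("younes-a", "younes-b", "osm-a", "osm-b", "blackbox")

#' Benchmark configuration
#'
#' @param algorithm one of \code{"younes-a"}, \code{"younes-b"},
#'   \code{"osm-a"}, \code{"osm-b"}, \code{"blackbox"}.
#' @param theta vector of thresholds (the problem grid), each in (0, 1).
#' @param p_true true satisfaction probability of the Bernoulli surrogate,
#'   or a list \code{list(net =, formula =)} for a white-box source.
#' @param relation claim relation, default \code{"GE"}.
#' @param params a [test_parameters()].
#' @param replications number of repetitions per grid point.
#' @param base_seed replication r uses seed \code{base_seed + r}.
#' @return list of class \code{"benchmark_config"}.
#' @export
benchmark_config <- function(algorithm, theta, p_true, relation = "GE",
                             params = test_parameters(), replications = 1000L,
                             base_seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  stopifnot(all(theta > 0), all(theta < 1), replications >= 1)
  structure(
    list(algorithm = algorithm, theta = theta, p_true = p_true,
         relation = relation, params = params,
         replications = as.integer(replications),
         base_seed = as.integer(base_seed)),
    class = "benchmark_config"
  )
}

make_bench_source <- function(p_true, seed) {
  if (is.numeric(p_true)) bernoulli_source(p_true, seed)
  else property_source(p_true$net, p_true$formula, seed)
}

run_algorithm <- function(algorithm, problem, params, source) {
  switch(algorithm,
    "younes-a" = younes_a(problem, params, source),
    "younes-b" = younes_b(problem, params, source),
    "osm-a" = osm_a(problem, params$alpha, params$beta, source),
    "osm-b" = osm_b(problem, params$alpha, params$beta, params$max_samples, source),
    "blackbox" = blackbox_verify(problem, params$max_samples, source),
    stop("unknown algorithm id: ", algorithm)
  )
}

# Fixed-sample black-box verification: draw n outcomes, decide by the
# observed fraction, report the accepted hypothesis's p-value. Not
# error-bounded.
blackbox_verify <- function(problem, n, source) {
  stopifnot(is.finite(n), n >= 1)
  np <- normalize_problem(problem)
  raw <- draw_samples(source, n)
  x <- if (np$outcome_flip) !raw else raw
  d <- sum(x)
  bd <- blackbox_decide(d, n, np$problem$theta)
  pv <- bd$p_values
  other <- if (bd$decision == "TRUE") pv$pval_H1 else pv$pval_H0
  verification_result(
    decision = bd$decision, guaranteed = FALSE,
    samples_used = n, successes = d,
    p_value = bd$p_value, p_value_other = other,
    algorithm = "blackbox", problem = problem
  )
}

#' Run a replicated benchmark
#'
#' For each threshold in the grid, runs \code{replications} independent
#' seeded verifications (replication r uses seed \code{base_seed + r}) and
#' tallies outcomes against the ground truth \code{p_true rel theta}.
#' Guaranteed (error-bounded) wrong decisions and p-value-based wrong
#' decisions are tallied separately, mirroring the "k (m)" notation of the
#' result tables. Deterministic given the configuration.
#'
#' @param config a [benchmark_config()]. \code{p_true} must be numeric for
#'   ground-truth checking unless \code{truth} is supplied.
#' @param truth optional logical: does the claim hold? Required for
#'   white-box sources.
#' @return a data frame of class \code{"benchmark_summary"}, one row per
#'   theta, columns \code{theta, delta, algorithm, reps, mean_n, sd_n,
#'   correct, errors, undecided, pvalue_decisions, pvalue_errors,
#'   mean_pvalue_correct, mean_pvalue_incorrect, seed}.
#' @export
run_benchmark <- function(config, truth = NULL) {
  stopifnot(inherits(config, "benchmark_config"))
  params <- config$params
  rows <- lapply(config$theta, function(theta) {
    problem <- verification_problem(config$relation, theta)
    want <- if (!is.null(truth)) {
      if (truth) "TRUE" else "FALSE"
    } else {
      if (!is.numeric(config$p_true))
        stop("ground truth undecidable: supply `truth` for white-box sources")
      if (isTRUE(all.equal(config$p_true, theta)) && config$p_true == theta)
        stop("ground truth undecidable: p_true equals theta")
      if (relation_holds(config$p_true, config$relation, theta)) "TRUE" else "FALSE"
    }
    reps <- config$replications
    n_used <- numeric(reps)
    decision <- character(reps)
    guaranteed <- logical(reps)
    pval <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      source <- make_bench_source(config$p_true, config$base_seed + r)
      res <- run_algorithm(config$algorithm, problem, params, source)
      n_used[r] <- res$samples_used
      decision[r] <- res$decision
      guaranteed[r] <- res$guaranteed
      pval[r] <- res$p_value
    }
    wrong <- decision != want & decision != "UNDECIDED"
    pv_dec <- !guaranteed & decision != "UNDECIDED"
    pv_correct <- pval[pv_dec & !wrong]
    pv_wrong <- pval[pv_dec & wrong]
    data.frame(
      theta = theta,
      delta = if (config$algorithm %in% c("younes-a", "younes-b"))
        params$delta else NA_real_,
      algorithm = config$algorithm,
      reps = reps,
      mean_n = mean(n_used),
      sd_n = stats::sd(n_used),
      correct = sum(decision == want),
      errors = sum(wrong & guaranteed),
      undecided = sum(decision == "UNDECIDED"),
      pvalue_decisions = if (any(pv_dec)) sum(pv_dec) else NA_integer_,
      pvalue_errors = if (any(pv_dec)) length(pv_wrong) else NA_integer_,
      mean_pvalue_correct = if (length(pv_correct)) mean(pv_correct) else NA_real_,
      mean_pvalue_incorrect = if (length(pv_wrong)) mean(pv_wrong) else NA_real_,
      seed = config$base_seed,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_summary", "data.frame")
  out
}

#' Combine benchmark summaries into one table
#'
#' Stacks summaries with a stable column order, one row per
#' (theta, delta, algorithm). Empty p-value tallies stay missing (not zero).
#'
#' @param summaries a \code{benchmark_summary} or list of them.
#' @return a \code{benchmark_summary} data frame.
#' @export
summarize_to_table <- function(summaries) {
  if (inherits(summaries, "data.frame")) summaries <- list(summaries)
  stopifnot(length(summaries) > 0)
  cols <- c("theta", "delta", "algorithm", "reps", "mean_n", "sd_n",
            "correct", "errors", "undecided", "pvalue_decisions",
            "pvalue_errors", "mean_pvalue_correct", "mean_pvalue_incorrect",
            "seed")
  out <- do.call(rbind, lapply(summaries, function(s) s[, cols]))
  rownames(out) <- NULL
  class(out) <- c("benchmark_summary", "data.frame")
  out
}

#' Write a benchmark table as CSV with a manifest header
#'
#' The manifest (tool version, seed, timestamp, any extra fields) is echoed
#' as \code{# key: value} comment lines before the CSV header, so every
#' output file records how to reproduce it.
#'
#' @param table a \code{benchmark_summary}.
#' @param path output file.
#' @param manifest named list of manifest fields.
#' @export
write_benchmark_csv <- function(table, path, manifest = list()) {
  manifest <- c(list(tool = paste0("osmcheck ",
                                   as.character(utils::packageVersion("osmcheck"))),
                     written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                manifest)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(manifest))
    writeLines(sprintf("# %s: %s", nm, paste(manifest[[nm]], collapse = " ")), con)
  utils::write.table(table, con, sep = ",", row.names = FALSE,
                     qmethod = "double", na = "")
  invisible(path)
}

#' Read a benchmark CSV written by [write_benchmark_csv()]
#'
#' @param path CSV file.
#' @return a \code{benchmark_summary} data frame (manifest lines attached as
#'   the \code{"manifest"} attribute).
#' @export
read_benchmark_csv <- function(path) {
  lines <- readLines(path)
  manifest <- grep("^#", lines, value = TRUE)
  out <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  attr(out, "manifest") <- sub("^#\\s*", "", manifest)
  class(out) <- c("benchmark_summary", "data.frame")
  out
}
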