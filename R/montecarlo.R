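#' Summary statistics of a sample of total query counts
#'
#' Query-count distributions are heavily right-skewed at high loss rates
#' (the support is semi-infinite), so the mean, median and mode are all
#' reported, together with a unit-width histogram and the empirical CDF at
#' the observed support points. The mode is the smallest count attaining the
#' maximal histogram frequency (smallest-value tie-break); the median of an
#' even-length sample is the mean of the central pair. The standard error of
#' the mean accompanies every mean so sampling tolerances are
#' self-documenting.
#'
#' @param counts Nonempty vector of positive integer query counts.
#' @return An object of class `halflie_summary`: list with `n_trials`,
#'   `mean`, `se_mean`, `median`, `mode`, `histogram` (tibble: `count`, `n`),
#'   `cdf` (tibble: `count`, `cum_frac`).
#' @examples
#' summarize_counts(c(1, 2, 3)) # mean 2, median 2, mode 1
#' @export
summarize_counts <- function(counts) {
  if (length(counts) == 0) {
    abort("`counts` must be nonempty.")
  }
  if (any(counts < 1)) {
    abort("`counts` must be positive integers.")
  }
  tab <- table(counts)
  support <- as.numeric(names(tab))
  freq <- as.vector(tab)
  structure(
    list(
      n_trials = length(counts),
      mean = mean(counts),
      se_mean = stats::sd(counts) / sqrt(length(counts)),
      median = median(counts),
      mode = support[which.max(freq)], # table() is sorted: smallest tie wins
      histogram = tibble(count = support, n = freq),
      cdf = tibble(count = support, cum_frac = cumsum(freq) / length(counts))
    ),
    class = "halflie_summary"
  )
}

#' @export
print.halflie_summary <- function(x, ...) {
  cat("<halflie_summary>\n")
  cat(sprintf("  trials : %d\n", x$n_trials))
  cat(sprintf("  mean   : %.4g  (SE %.3g)\n", x$mean, x$se_mean))
  cat(sprintf("  median : %g\n", x$median))
  cat(sprintf("  mode   : %g\n", x$mode))
  invisible(x)
}

#' @export
tidy.halflie_summary <- function(x, ...) {
  dplyr::left_join(x$histogram, x$cdf, by = "count")
}

#' @export
glance.halflie_summary <- function(x, ...) {
  tibble(
    n_trials = x$n_trials, mean = x$mean, se_mean = x$se_mean,
    median = x$median, mode = x$mode
  )
}

#' Monte Carlo batch of q-sectioning searches
#'
#' Runs `n_trials` independent searches over uniformly placed targets and
#' summarizes the total query counts. Two engines produce distributionally
#' identical counts:
#' \describe{
#'   \item{`"fast"`}{[sample_query_count_fast()]: per-level geometric/uniform
#'     sampling; the performance path.}
#'   \item{`"naive"`}{[run_qsectioning()] on a freshly drawn uniform target
#'     per trial, simulating every individual query; the reference path.
#'     Trial `i` uses seed `seed + i`, so any single trial is replayable
#'     in isolation via `run_qsectioning(config, target, seed = seed + i)`
#'     after redrawing its target.}
#' }
#' Identical `(config, n_trials, seed, engine)` give bit-identical results.
#'
#' @param config A [game_config()].
#' @param n_trials Number of independent trials, `>= 1`.
#' @param seed Integer master seed.
#' @param engine `"fast"` (default) or `"naive"`.
#' @return An object of class `halflie_mc`: list with `config`, `n_trials`,
#'   `seed`, `engine`, `counts` (numeric vector), `summary`
#'   (a [summarize_counts()] result).
#' @examples
#' cfg <- game_config(precision = 1e-3, loss_rate = 0.5, sectioning_order = 3)
#' run_trials(cfg, n_trials = 500, seed = 1)
#' @export
run_trials <- function(config, n_trials, seed = 1,
                       engine = c("fast", "naive")) {
  stopifnot(inherits(config, "game_config"))
  engine <- match.arg(engine)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1) {
    abort("`n_trials` must be a single integer >= 1.")
  }
  n_trials <- as.integer(n_trials)
  if (engine == "fast") {
    set.seed(seed)
    counts <- sample_query_count_fast(config, n_trials)
  } else {
    counts <- vapply(seq_len(n_trials), function(i) {
      set.seed(seed + i)
      target <- runif(1, 0, config$domain_length)
      run_qsectioning(config, target)$total_queries
    }, numeric(1))
  }
  structure(
    list(
      config = config, n_trials = n_trials, seed = seed, engine = engine,
      counts = counts, summary = summarize_counts(counts)
    ),
    class = "halflie_mc"
  )
}

#' @export
print.halflie_mc <- function(x, ...) {
  cat(sprintf(
    "<halflie_mc> %d trials (%s engine), q = %d, eps^-1 = %g, alpha0 = %g\n",
    x$n_trials, x$engine, x$config$sectioning_order,
    1 / x$config$precision, x$config$loss_rate
  ))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.halflie_mc <- function(x, ...) {
  tidy(x$summary)
}

#' @export
glance.halflie_mc <- function(x, ...) {
  tibble::add_column(
    glance(x$summary),
    q = x$config$sectioning_order,
    epsilon_inverse = 1 / x$config$precision,
    loss_rate = x$config$loss_rate,
    engine = x$engine,
    seed = x$seed,
    mean_predicted = mean_queries(
      x$config$sectioning_order, 1 / x$config$precision, x$config$loss_rate
    )
  )
}
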