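#' Number of sectioning levels needed to reach a target precision
#'
#' The recursion of a q-sectioning search narrows the surviving interval by a
#' factor `q` per level, so reaching a precision of `1/epsilon_inverse` of the
#' domain requires the smallest integer `t` with `q^t >= epsilon_inverse`,
#' i.e. `ceiling(log(epsilon_inverse, q))`.
#'
#' The ceiling is evaluated robustly: when `epsilon_inverse` is an integer the
#' level count is found by exact integer power accumulation, and otherwise the
#' floating-point logarithm is guarded by checking the adjacent integer
#' exponents. A naive `ceiling(log(n)/log(q))` misfires at exact powers of `q`
#' for some `(q, n)` pairs, which would silently shift every downstream cost.
#'
#' @param sectioning_order Integer `q >= 2`, the number of subdomains per level.
#' @param epsilon_inverse Reciprocal precision (`>= 1`), the number of
#'   resolvable subdomains. May be non-integer. Vectorized.
#' @return Integer vector of level counts.
#' @examples
#' sectioning_levels(3, 1e10) # 21
#' sectioning_levels(2, 8)    # exactly 3
#' @export
sectioning_levels <- function(sectioning_order, epsilon_inverse) {
  q <- sectioning_order
  if (length(q) != 1L || q < 2 || q != as.integer(q)) {
    abort("`sectioning_order` must be a single integer >= 2.")
  }
  if (any(epsilon_inverse < 1)) {
    abort("`epsilon_inverse` must be >= 1.")
  }
  vapply(epsilon_inverse, .levels_one, numeric(1), q = q)
}

.levels_one <- function(n, q) {
  if (abs(n - round(n)) < 1e-9) {
    # exact integer path: smallest t with q^t >= n
    n <- round(n)
    t <- 0
    p <- 1
    while (p < n) {
      p <- p * q
      t <- t + 1
    }
    return(t)
  }
  t <- ceiling(log(n) / log(q))
  while (t > 0 && q^(t - 1) >= n) t <- t - 1
  while (q^t < n) t <- t + 1
  t
}

#' Parameterization of one half-lie search game
#'
#' Bundles the four quantities that define a game: the domain length `L`, the
#' target precision `epsilon` (as a fraction of `L`), the photon loss rate
#' `alpha0` (the probability that an illuminated emitter yields no detected
#' photon), and the sectioning order `q`. The derived number of recursion
#' levels, `ceiling(log(1/epsilon, q))`, is computed at construction.
#'
#' A game with `loss_rate = 1` never terminates (no photon is ever detected)
#' and is rejected; likewise `precision = 1` needs zero levels and is
#' degenerate.
#'
#' @param precision Target precision `epsilon` in (0, 1), as a fraction of the
#'   domain length.
#' @param loss_rate Photon loss probability `alpha0` in \[0, 1).
#' @param sectioning_order Integer `q >= 2`.
#' @param domain_length Positive domain length `L` (default 1).
#' @return An object of class `game_config`: a list with fields
#'   `domain_length`, `precision`, `loss_rate`, `sectioning_order`, `levels`.
#' @examples
#' game_config(precision = 1e-10, loss_rate = 0.99, sectioning_order = 3)
#' @export
game_config <- function(precision, loss_rate = 0, sectioning_order = 2,
                        domain_length = 1) {
  if (!is.numeric(domain_length) || length(domain_length) != 1L ||
      domain_length <= 0) {
    abort("`domain_length` must be a single positive number.")
  }
  if (!is.numeric(precision) || length(precision) != 1L ||
      precision <= 0 || precision > 1) {
    abort("`precision` must be a single number in (0, 1].")
  }
  if (!is.numeric(loss_rate) || length(loss_rate) != 1L ||
      loss_rate < 0 || loss_rate >= 1) {
    abort(paste0(
      "`loss_rate` must be in [0, 1): at loss_rate = 1 no photon is ever ",
      "detected, the optimal boundary is undefined and a verification-based ",
      "search never terminates."
    ))
  }
  if (!is.numeric(sectioning_order) || length(sectioning_order) != 1L ||
      sectioning_order < 2 || sectioning_order != round(sectioning_order)) {
    abort("`sectioning_order` must be a single integer >= 2.")
  }
  levels <- sectioning_levels(sectioning_order, 1 / precision)
  if (levels < 1) {
    abort("`precision` = 1 needs no search; it must be < 1.")
  }
  structure(
    list(
      domain_length = domain_length,
      precision = precision,
      loss_rate = loss_rate,
      sectioning_order = as.integer(sectioning_order),
      levels = as.integer(levels)
    ),
    class = "game_config"
  )
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config>\n")
  cat(sprintf("  domain length L : %g\n", x$domain_length))
  cat(sprintf("  precision eps   : %g  (eps^-1 = %g)\n",
              x$precision, 1 / x$precision))
  cat(sprintf("  loss rate alpha0: %g\n", x$loss_rate))
  cat(sprintf("  sectioning q    : %d\n", x$sectioning_order))
  cat(sprintf("  levels          : %d\n", x$levels))
  invisible(x)
}

#' Construct a top-hat illumination query interval
#'
#' A query illuminates the half-open interval `[lower, upper)` of the domain:
#' a target exactly at `upper` is not illuminated. Half-open intervals let the
#' `q` equal subdomains at every level of a sectioning search partition the
#' current interval without ambiguity at shared boundaries, so a target
#' belongs to exactly one subdomain. The choice is statistically irrelevant
#' (boundary hits have measure zero under the uniform prior) but must be
#' fixed for reproducibility.
#'
#' @param lower,upper Interval endpoints, `0 <= lower < upper <= domain_length`.
#' @param domain_length Domain length `L` (default 1).
#' @return An object of class `query_interval` (named numeric of length 2).
#' @examples
#' query_interval(0, 0.5)
#' @export
query_interval <- function(lower, upper, domain_length = 1) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      length(lower) != 1L || length(upper) != 1L) {
    abort("`lower` and `upper` must be single numbers.")
  }
  if (lower >= upper) {
    abort("Malformed interval: `lower` must be strictly less than `upper`.")
  }
  if (lower < 0 || upper > domain_length) {
    abort("Interval must lie within [0, domain_length].")
  }
  structure(c(lower = lower, upper = upper), class = "query_interval")
}

#' @export
print.query_interval <- function(x, ...) {
  cat(sprintf("<query_interval> [%g, %g)\n", x[["lower"]], x[["upper"]]))
  invisible(x)
}
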