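#' Mutual information of a single boundary query under half-lies
#'
#' For a uniform prior on `[0, L]`, a query illuminating `[0, v)` with photon
#' loss rate `alpha` has joint distribution
#' `P(x, r = 1) = (1 - alpha)/L` for `x < v` and
#' `P(x, r = 0) = alpha/L` for `x < v`, `1/L` for `x >= v`.
#' The mutual information between position and result reduces to the closed
#' form (natural log, `L = 1` fractional boundary `w = v/L`):
#' \deqn{I = -[(1-\alpha) w \log w + (1 - w + \alpha w)\log(1 - w + \alpha w)
#'       - \alpha w \log \alpha].}
#' Terms of the form `p log p` are taken as 0 in the limit `p -> 0`, with
#' explicit guards rather than floating-point conventions. Information
#' depends only on the fractional boundary, so
#' `mutual_information(a, v, L) == mutual_information(a, v/L, 1)`.
#'
#' @param loss_rate Photon loss rate(s) `alpha` in `[0, 1]`.
#' @param boundary Turn-off boundary `v` in `[0, L]` (0 and `L` are handled
#'   as limits and return 0).
#' @param domain_length Domain length `L` (default 1).
#' @param units `"nats"` (default; natural log) or `"bits"`.
#' @return Numeric vector of information per query. At most `log(2)` nats
#'   (1 bit): a binary-outcome query cannot yield more.
#' @examples
#' mutual_information(0, 0.5)            # log(2) nats: lossless bisection
#' mutual_information(0.99, 0.368, units = "bits")
#' @export
mutual_information <- function(loss_rate, boundary, domain_length = 1,
                               units = c("nats", "bits")) {
  units <- match.arg(units)
  if (any(loss_rate < 0 | loss_rate > 1)) {
    abort("`loss_rate` must be in [0, 1].")
  }
  if (any(boundary < 0 | boundary > domain_length)) {
    abort("`boundary` must be in [0, domain_length].")
  }
  n <- max(length(loss_rate), length(boundary))
  a <- rep_len(loss_rate, n)
  w <- rep_len(boundary / domain_length, n)

  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  miss <- 1 - w + a * w # probability of r = 0
  # a*w*log(a) guarded: zero when a = 0 or w = 0
  alog <- ifelse(a > 0 & w > 0, a * w * log(a), 0)
  info <- -((1 - a) * xlogx(w) + xlogx(miss) - alog)
  info <- pmax(info, 0) # clip -0/eps noise at the v -> 0, L limits
  if (units == "bits") info / log(2) else info
}

#' Information-optimal query boundary
#'
#' The boundary `v0` maximizing [mutual_information()] over `v` for a given
#' loss rate has the closed form
#' \deqn{v_0 = \frac{L\,\alpha_0^{\alpha_0/(1-\alpha_0)}}
#'   {1 + (1-\alpha_0)\,\alpha_0^{\alpha_0/(1-\alpha_0)}}.}
#' At `alpha0 = 0` the analytic limit `L/2` is returned exactly (lossless
#' bisection) rather than evaluating the `0^0`-style expression; as
#' `alpha0 -> 1` the boundary tends to `L/e`. The optimum is strictly
#' decreasing in the loss rate and always lies in `(L/e, L/2]`: under loss, a
#' smaller measured region is interrogated so that a positive result, when it
#' survives, carries more information.
#'
#' @param loss_rate Loss rate(s) in `[0, 1)`. The boundary is undefined at
#'   `loss_rate = 1` (no photon is ever seen) and such input is an error.
#' @param domain_length Domain length `L` (default 1).
#' @return Numeric vector of optimal boundaries, in length units.
#' @examples
#' optimal_boundary(0)    # 0.5
#' optimal_boundary(0.5)  # 0.4
#' @export
optimal_boundary <- function(loss_rate, domain_length = 1) {
  if (any(loss_rate < 0 | loss_rate >= 1)) {
    abort("`loss_rate` must be in [0, 1): the optimal boundary is undefined at loss_rate = 1.")
  }
  a <- loss_rate
  g <- ifelse(a > 0, a^(a / (1 - a)), 1) # a^(a/(1-a)) -> 1 as a -> 0
  out <- domain_length * g / (1 + (1 - a) * g)
  ifelse(a == 0, domain_length / 2, out)
}

#' Information map over loss rate and boundary position
#'
#' Evaluates [mutual_information()] on the Cartesian grid of loss rates and
#' boundaries, in long (tidy) format. Use [information_optima()] for the
#' per-loss-rate maximum and argmax (the ridge of the map).
#'
#' Default grids: 101 loss rates on `[0, 0.99]` and 1001 interior boundaries
#' on `(0, L)`.
#'
#' @param loss_grid Numeric vector of loss rates in `[0, 1]`.
#' @param boundary_grid Numeric vector of boundaries in `[0, L]`.
#' @param domain_length Domain length `L` (default 1).
#' @return A tibble of class `halflie_infomap` with columns `loss_rate`,
#'   `boundary`, `info_nats`, `info_bits`.
#' @examples
#' information_map(loss_grid = c(0, 0.5), boundary_grid = c(0.25, 0.5))
#' @export
information_map <- function(loss_grid = seq(0, 0.99, length.out = 101),
                            boundary_grid = seq(0, 1, length.out = 1003)[2:1002] *
                              domain_length,
                            domain_length = 1) {
  if (length(loss_grid) == 0 || length(boundary_grid) == 0) {
    abort("Grids must be nonempty.")
  }
  cells <- tidyr::expand_grid(loss_rate = loss_grid, boundary = boundary_grid)
  info <- mutual_information(cells$loss_rate, cells$boundary, domain_length)
  out <- tibble::add_column(cells, info_nats = info, info_bits = info / log(2))
  attr(out, "domain_length") <- domain_length
  class(out) <- c("halflie_infomap", class(out))
  out
}

#' Per-loss-rate optimum of an information map
#'
#' For each loss rate in an [information_map()], the boundary attaining the
#' maximal information and that maximum. On a fine boundary grid the argmax
#' matches [optimal_boundary()] to within one grid step, and the maxima are
#' non-increasing in the loss rate.
#'
#' @param map A `halflie_infomap` tibble.
#' @return A tibble with columns `loss_rate`, `boundary_opt`,
#'   `info_max_nats`, `info_max_bits`.
#' @export
information_optima <- function(map) {
  if (!inherits(map, "halflie_infomap")) {
    abort("`map` must come from information_map().")
  }
  map |>
    as_tibble() |>
    group_by(.data$loss_rate) |>
    slice_max(.data$info_nats, n = 1, with_ties = FALSE) |>
    ungroup() |>
    dplyr::rename(
      boundary_opt = "boundary",
      info_max_nats = "info_nats",
      info_max_bits = "info_bits"
    )
}

#' Estimated optimal number of queries for a target precision
#'
#' Localizing to precision `eps` acquires `log2(1/eps)` bits. A hypothetical
#' scheme extracting the per-query maximum `I(X:R)` at the optimal boundary
#' for every query would need an estimated
#' `ceiling(log2(1/eps) / I_bits(alpha0, v0))` queries. This is an
#' information-accounting estimate, not an achievable strategy: it assumes
#' every query is as informative as the first.
#'
#' @param precision Target precision in (0, 1].
#' @param loss_rate Loss rate in `[0, 1)`.
#' @return Integer estimated query count.
#' @examples
#' estimated_optimal_queries(1e-10, 0)    # 34
#' estimated_optimal_queries(1e-10, 0.99) # 6240
#' @export
estimated_optimal_queries <- function(precision, loss_rate) {
  if (any(precision <= 0 | precision > 1)) {
    abort("`precision` must be in (0, 1].")
  }
  if (any(loss_rate < 0 | loss_rate >= 1)) {
    abort("`loss_rate` must be in [0, 1).")
  }
  n <- max(length(precision), length(loss_rate))
  precision <- rep_len(precision, n)
  loss_rate <- rep_len(loss_rate, n)
  bits_needed <- log2(1 / precision)
  info_bits <- mutual_information(loss_rate, optimal_boundary(loss_rate),
    units = "bits"
  )
  # guard the ceiling against float noise when the ratio is an exact integer
  as.integer(ceiling(bits_needed / info_bits - 1e-9))
}
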