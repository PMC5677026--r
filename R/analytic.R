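#' Expected q-sectioning cost without photon loss
#'
#' With no loss, verification succeeds on the first illuminated query, so a
#' level over a uniformly placed target costs on average `(q + 1)/2` queries
#' (the target's subdomain index is uniform on `1..q`), and the whole search
#' \deqn{\bar m_{q,\varepsilon,0} = \frac{q+1}{2}
#'   \lceil \log_q \varepsilon^{-1} \rceil.}
#'
#' @param q Sectioning order, integer `>= 2`.
#' @param epsilon_inverse Reciprocal precision (`>= 1`). Vectorized.
#' @return Expected number of queries.
#' @examples
#' mean_zero_lie(3, 1e10) # 42
#' mean_zero_lie(2, 8)    # 4.5
#' @export
mean_zero_lie <- function(q, epsilon_inverse) {
  (q + 1) / 2 * sectioning_levels(q, epsilon_inverse)
}

#' Expected q-sectioning cost under photon loss
#'
#' In the long run `1/(1 - alpha0)` passes must hit the correct subdomain
#' before a photon survives; each wasted pass also pays for the other
#' `q - 1` subdomains, and the final (successful) pass costs `(q + 1)/2` on
#' average as in the lossless case:
#' \deqn{\bar m_{q,\varepsilon^{-1},\alpha_0} =
#'   \left[q\Big(\frac{1}{1-\alpha_0} - 1\Big) + \frac{q+1}{2}\right]
#'   \lceil \log_q \varepsilon^{-1} \rceil.}
#' Reduces exactly to [mean_zero_lie()] at `loss_rate = 0`.
#'
#' @param q Sectioning order, integer `>= 2`.
#' @param epsilon_inverse Reciprocal precision (`>= 1`). Vectorized.
#' @param loss_rate Loss rate in `[0, 1)`.
#' @return Expected number of queries.
#' @examples
#' mean_queries(3, 1e6, 0.99) # 3887
#' mean_queries(4, 1e3, 0.99) # 1992.5
#' @export
mean_queries <- function(q, epsilon_inverse, loss_rate = 0) {
  if (any(loss_rate < 0 | loss_rate >= 1)) {
    abort("`loss_rate` must be in [0, 1): the expected cost diverges at 1.")
  }
  prefactor <- q * loss_rate / (1 - loss_rate) + (q + 1) / 2
  prefactor * sectioning_levels(q, epsilon_inverse)
}

#' Nearness of a precision to a power of the sectioning order
#'
#' Distance of `log_q(1/eps)` from the nearest integer:
#' \deqn{F(q,\varepsilon) = 0.5 - \left\|0.5 -
#'   [\log_q \varepsilon^{-1} - \lfloor \log_q \varepsilon^{-1}\rfloor]\right\|.}
#' `F = 0` when `1/eps` is an exact power of `q` (the last level lands exactly
#' on the precision); `F = 0.5` is the farthest possible mismatch. Nearness
#' alone does not decide which heuristic is cheapest.
#'
#' @param q Sectioning order, integer `>= 2`.
#' @param epsilon_inverse Reciprocal precision (`> 1`). Vectorized.
#' @return Value in `[0, 0.5]`.
#' @examples
#' nearness_metric(4, 1e6) # ~0.034
#' nearness_metric(3, 3^7) # exactly 0
#' @export
nearness_metric <- function(q, epsilon_inverse) {
  if (length(q) != 1L || q < 2 || q != round(q)) {
    abort("`q` must be a single integer >= 2.")
  }
  if (any(epsilon_inverse <= 1)) {
    abort("`epsilon_inverse` must be > 1.")
  }
  lg <- log(epsilon_inverse) / log(q)
  # snap to integer before flooring: exact powers must give F = 0
  lg <- ifelse(abs(lg - round(lg)) < 1e-9, round(lg), lg)
  frac <- lg - floor(lg)
  0.5 - abs(0.5 - frac)
}

#' Expected cost of rastering with verification
#'
#' The limiting member of the q-sectioning family with `q = 1/eps`: all
#' `1/eps` subdomains of final size are rastered until positive verification,
#' in a single level, costing `0.5 (1/eps + 1)` queries on average (the
#' `log_{1/eps}(1/eps)` level factor is identically 1). Prohibitive for any
#' appreciable `1/eps`; it coincides with [mean_zero_lie()] at
#' `q = 1/eps`.
#'
#' @param epsilon_inverse Reciprocal precision (`> 1`). Vectorized.
#' @return Expected number of queries.
#' @examples
#' rastering_verification_mean(1e6) # 500000.5
#' @export
rastering_verification_mean <- function(epsilon_inverse) {
  if (any(epsilon_inverse <= 1)) {
    abort("`epsilon_inverse` must be > 1.")
  }
  0.5 * (epsilon_inverse + 1)
}

#' Cost of a conventional dwell raster scan
#'
#' Conventional microscopy scans the domain with a spot of width `eps`,
#' dwelling for `dwell` (gamma) queries per subdomain: `gamma / eps`
#' measurements, or `0.5 gamma / eps` on average if the scan stops adaptively
#' after locating the target.
#'
#' @param epsilon_inverse Reciprocal precision. Vectorized.
#' @param dwell Queries per subdomain (gamma), integer `>= 1`.
#' @param adaptive Stop after locating the target?
#' @return Number of measurements.
#' @examples
#' conventional_raster_queries(10, dwell = 1)                  # 10
#' conventional_raster_queries(10, dwell = 1, adaptive = TRUE) # 5
#' @export
conventional_raster_queries <- function(epsilon_inverse, dwell = 1,
                                        adaptive = FALSE) {
  if (any(dwell < 1)) {
    abort("`dwell` must be at least 1.")
  }
  dwell * epsilon_inverse * (if (isTRUE(adaptive)) 0.5 else 1)
}

#' Lower bound on comparison queries with bounded one-sided errors
#'
#' For a target among `k` discrete cells when up to `E` answers to
#' comparison questions may be erroneous in one specified direction, any
#' strategy needs at least
#' `ceiling(log2(k) + E log2 log2(k) + E log2(E))` queries
#' (Rivest-Meyer-Kleitman-Winklmann bound), with the `E log2 E` term taken
#' as 0 for `E <= 1`.
#'
#' @param k Number of cells, `>= 2`.
#' @param num_errors Maximum number of erroneous answers `E >= 0`.
#' @return Integer lower bound on the number of queries.
#' @examples
#' rivest_lower_bound(1e10, 1) # 39
#' rivest_lower_bound(1e10, 0) # 34
#' @export
rivest_lower_bound <- function(k, num_errors) {
  if (any(k < 2)) abort("`k` must be >= 2.")
  if (any(num_errors < 0 | num_errors != round(num_errors))) {
    abort("`num_errors` must be a nonnegative integer.")
  }
  n <- max(length(k), length(num_errors))
  k <- rep_len(k, n)
  e <- rep_len(num_errors, n)
  extra <- ifelse(e > 1, e * log2(e), 0)
  as.integer(ceiling(log2(k) + e * log2(log2(k)) + extra - 1e-9))
}
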