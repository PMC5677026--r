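#' Simulate one top-hat query with half-lie photon loss
#'
#' One query asks "is the target inside `[lower, upper)`?". A target outside
#' the illuminated interval generates no photon, so the result is `r = 0` with
#' certainty. A target inside generates one photon, which is lost with
#' probability `loss_rate`: the result is `r = 1` with probability
#' `1 - loss_rate` and `r = 0` otherwise. The error is therefore asymmetric
#' (a "half-lie"): `r = 1` is always truthful, `r = 0` is ambiguous.
#'
#' Exactly one uniform random draw is consumed when, and only when, the
#' target is illuminated, so a simulated search trace is exactly reproducible
#' from its seed.
#'
#' @param target_position Position of the emitter in `[0, L]`.
#' @param query A [query_interval()], or a numeric `c(lower, upper)`.
#' @param loss_rate Photon loss probability in `[0, 1]`.
#' @param domain_length Domain length `L` (default 1).
#' @return Integer `0` or `1`.
#' @examples
#' simulate_measurement(0.9, query_interval(0, 0.5), loss_rate = 0.7) # always 0
#' set.seed(1)
#' simulate_measurement(0.2, query_interval(0, 0.5), loss_rate = 0)   # always 1
#' @export
simulate_measurement <- function(target_position, query, loss_rate,
                                 domain_length = 1) {
  if (!inherits(query, "query_interval")) {
    query <- query_interval(query[[1]], query[[2]], domain_length)
  }
  if (!is.numeric(target_position) || length(target_position) != 1L ||
      target_position < 0 || target_position > domain_length) {
    abort("`target_position` must be a single number in [0, domain_length].")
  }
  if (loss_rate < 0 || loss_rate > 1) {
    abort("`loss_rate` must be in [0, 1].")
  }
  .measure(target_position, query[[1]], query[[2]], loss_rate)
}

# hot-path kernel, no validation: half-open [lower, upper)
.measure <- function(x, lower, upper, loss_rate) {
  if (x < lower || x >= upper) {
    return(0L)
  }
  u <- runif(1) # the one draw per illuminated query; consumed even at loss 0
  if (u < loss_rate) 0L else 1L
}
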