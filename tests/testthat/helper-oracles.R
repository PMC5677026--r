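# Independent oracles, kept deliberately brute-force and separate from the
# closed-form code paths they check.

# Mutual information by direct summation of the discretized joint
# distribution on a fine x-grid.
mi_grid_oracle <- function(loss_rate, boundary, domain_length = 1, m = 4e5) {
  L <- domain_length
  dx <- L / m
  x <- (seq_len(m) - 0.5) * dx
  p_x <- 1 / L
  joint <- list(
    r0 = ifelse(x < boundary, loss_rate / L, 1 / L),
    r1 = ifelse(x < boundary, (1 - loss_rate) / L, 0)
  )
  info <- 0
  for (p_xr in joint) {
    p_r <- sum(p_xr) * dx
    nz <- p_xr > 0
    if (p_r > 0) {
      info <- info + sum(p_xr[nz] * log(p_xr[nz] / (p_x * p_r))) * dx
    }
  }
  info
}

# Exact pmf of the total query count of a q-sectioning search over a uniform
# random target, by exhaustive enumeration of the per-level (k, l) pairs:
# level cost = (k - 1) q + l, P = (1/q) * alpha^(k-1) (1 - alpha).
# Levels are convolved; mass beyond the k-truncation is < 1e-12.
qsection_count_pmf_oracle <- function(q, levels, loss_rate) {
  k_max <- if (loss_rate == 0) 1 else ceiling(log(1e-14) / log(loss_rate)) + 1
  cost <- as.vector(outer(1:q, (seq_len(k_max) - 1) * q, `+`))
  prob <- as.vector(outer(
    rep(1 / q, q),
    loss_rate^(seq_len(k_max) - 1) * (1 - loss_rate)
  ))
  one <- rep(0, max(cost))
  for (i in seq_along(cost)) one[cost[i]] <- one[cost[i]] + prob[i]
  pmf <- 1 # pmf[i] = P(total = i - 1); starts as a point mass at 0
  for (lev in seq_len(levels)) {
    new <- rep(0, length(pmf) + length(one))
    for (c1 in which(one > 0)) {
      new[seq_along(pmf) + c1] <- new[seq_along(pmf) + c1] + pmf * one[c1]
    }
    pmf <- new
  }
  tibble::tibble(count = seq_along(pmf) - 1, prob = pmf)[-1, ]
}

# Brute-force zero-loss argmin over candidate q for one epsilon_inverse,
# evaluating the expected cost from first principles (per-level average
# (q+1)/2, integer level count by repeated multiplication).
zero_lie_argmin_oracle <- function(epsilon_inverse, q_candidates) {
  costs <- vapply(q_candidates, function(q) {
    t <- 0
    p <- 1
    while (p < epsilon_inverse) {
      p <- p * q
      t <- t + 1
    }
    (q + 1) / 2 * t
  }, numeric(1))
  q_candidates[abs(costs - min(costs)) < 1e-9]
}
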