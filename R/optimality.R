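# Vectorized level counts for a dense integer scan: levels(n) = number of
# powers of q strictly below n, via findInterval on the exact power table.
# Powers of q are exact doubles up to 2^53, covering scans to eps^-1 = 2^48.
.levels_vec <- function(q, n) {
  t_max <- .levels_one(max(n), q)
  pw <- q^(0:max(t_max, 1))
  findInterval(n - 0.5, pw)
}

#' Which sectioning orders minimize the expected cost, cell by cell
#'
#' Evaluates [mean_queries()] for every candidate `q` at every
#' `(epsilon_inverse, loss_rate)` cell and flags the argmin set. Every `q`
#' attaining the minimum is marked optimal; a cell's solution is unique when
#' exactly one `q` does. Costs are level counts (exact integers) times
#' half-integer-plus-odds prefactors; minima are compared with a guarded
#' relative tolerance of `1e-9`, far below the smallest genuine cost gap, so
#' ties are classified exactly.
#'
#' @param epsilon_inverse Integer vector of reciprocal precisions (`>= 2`),
#'   e.g. `2:1000` or [fig6_epsilon_grid()].
#' @param loss_rates Numeric vector of loss rates in `[0, 1)`.
#' @param q_candidates Integer vector of candidate sectioning orders
#'   (`>= 2`). The census depends on this universe: a wider universe can
#'   only take cells away from a given `q`.
#' @return A tibble of class `halflie_optmap`, long format: `epsilon_inverse`,
#'   `loss_rate`, `q`, `mean_queries`, `is_optimal`, `is_unique`.
#' @seealso [optimality_counts()] for the per-q census;
#'   [count_optimal_q()] for censuses over ranges too large to materialize.
#' @examples
#' optimality_map(2:20, loss_rates = 0, q_candidates = 2:5)
#' @export
optimality_map <- function(epsilon_inverse, loss_rates = 0,
                           q_candidates = 2:8) {
  .check_scan_args(epsilon_inverse, loss_rates, q_candidates)
  n <- sort(unique(epsilon_inverse))
  grids <- purrr::map(loss_rates, function(a) {
    cost <- vapply(
      q_candidates,
      function(q) (q * a / (1 - a) + (q + 1) / 2) * .levels_vec(q, n),
      numeric(length(n))
    )
    cost <- matrix(cost, nrow = length(n))
    mn <- do.call(pmin, as.data.frame(cost))
    isopt <- cost <= mn * (1 + 1e-9)
    uniq <- rowSums(isopt) == 1L
    tibble(
      epsilon_inverse = rep(n, times = length(q_candidates)),
      loss_rate = a,
      q = rep(as.integer(q_candidates), each = length(n)),
      mean_queries = as.vector(cost),
      is_optimal = as.vector(isopt),
      is_unique = as.vector(isopt) & rep(uniq, times = length(q_candidates))
    )
  })
  out <- dplyr::bind_rows(grids)
  class(out) <- c("halflie_optmap", class(out))
  out
}

#' Per-q census of an optimality map
#'
#' Counts, for each loss rate and candidate `q`, in how many
#' `epsilon_inverse` cells that `q` attains the minimal expected cost
#' (`n_optimal`) and in how many it is the sole minimizer (`n_unique`).
#'
#' @param map A `halflie_optmap` from [optimality_map()].
#' @return A tibble with columns `loss_rate`, `q`, `n_optimal`, `n_unique`.
#' @export
optimality_counts <- function(map) {
  if (!inherits(map, "halflie_optmap")) {
    abort("`map` must come from optimality_map().")
  }
  map |>
    as_tibble() |>
    group_by(.data$loss_rate, .data$q) |>
    summarise(
      n_optimal = sum(.data$is_optimal),
      n_unique = sum(.data$is_unique),
      .groups = "drop"
    )
}

#' Census of optimal sectioning orders over a dense precision range
#'
#' Streams over every integer `epsilon_inverse` in `range` in chunks
#' (nothing is materialized per cell), counting per candidate `q` the cells
#' where it attains the minimal expected cost and where it does so uniquely.
#' Optionally also counts the cells whose argmin set intersects `joint_q`.
#' Identical tie handling to [optimality_map()]. Correct for ranges up to
#' `2^48` (beyond which double-precision level arithmetic would fail).
#'
#' @param range Length-2 integer vector, inclusive `c(min, max)` with
#'   `min >= 2`.
#' @param loss_rate Single loss rate in `[0, 1)`.
#' @param q_candidates Integer vector of candidate sectioning orders.
#' @param joint_q Optional integer subset of `q_candidates`: additionally
#'   count cells where some member of `joint_q` is optimal.
#' @param chunk_size Cells per chunk (default `2^20`).
#' @return A tibble with columns `q`, `n_optimal`, `n_unique`; attributes
#'   `n_cells` (number of scanned cells) and, if requested, `n_joint`.
#' @examples
#' count_optimal_q(c(2, 1e4), loss_rate = 0, q_candidates = 2:8)
#' @export
count_optimal_q <- function(range, loss_rate = 0, q_candidates = 2:8,
                            joint_q = NULL, chunk_size = 2^20) {
  if (length(range) != 2L || range[1] < 2 || range[2] < range[1]) {
    abort("`range` must be c(min, max) with 2 <= min <= max.")
  }
  if (range[2] > 2^48) {
    abort("Ranges beyond 2^48 exceed exact double-precision level arithmetic.")
  }
  .check_scan_args(range, loss_rate, q_candidates)
  if (length(loss_rate) != 1L) abort("`loss_rate` must be a single value.")
  qs <- as.integer(sort(q_candidates))
  pref <- qs * loss_rate / (1 - loss_rate) + (qs + 1) / 2
  n_opt <- n_uni <- setNames(numeric(length(qs)), qs)
  n_joint <- 0
  lo <- range[1]
  while (lo <= range[2]) {
    hi <- min(lo + chunk_size - 1, range[2])
    n <- lo:hi
    cost <- vapply(seq_along(qs),
      function(i) pref[i] * .levels_vec(qs[i], n),
      numeric(length(n))
    )
    cost <- matrix(cost, nrow = length(n))
    mn <- do.call(pmin, as.data.frame(cost))
    isopt <- cost <= mn * (1 + 1e-9)
    uniq <- rowSums(isopt) == 1L
    n_opt <- n_opt + colSums(isopt)
    n_uni <- n_uni + colSums(isopt & uniq)
    if (!is.null(joint_q)) {
      n_joint <- n_joint +
        sum(rowSums(isopt[, qs %in% joint_q, drop = FALSE]) > 0)
    }
    lo <- hi + 1
  }
  out <- tibble(q = qs, n_optimal = unname(n_opt), n_unique = unname(n_uni))
  attr(out, "n_cells") <- range[2] - range[1] + 1
  if (!is.null(joint_q)) attr(out, "n_joint") <- n_joint
  out
}

#' Compressed epsilon-inverse grid straddling every cost step
#'
#' The expected cost of a q-sectioning search is a step function of
#' `epsilon_inverse`, constant between consecutive powers of `q`. A grid made
#' of `q^i - 1`, `q^i`, `q^i + 1` for every candidate `q` and every power in
#' range therefore samples each side of every step: the optimal-q
#' classification at a grid point is valid for all `epsilon_inverse` across
#' the step interval it represents.
#'
#' @param q_candidates Integer vector of sectioning orders.
#' @param max_epsilon_inverse Upper end of the range (inclusive).
#' @param min_epsilon_inverse Lower end (default 2).
#' @return Sorted unique numeric vector of grid points.
#' @examples
#' fig6_epsilon_grid(2:5, 1e3)
#' @export
fig6_epsilon_grid <- function(q_candidates = 2:5, max_epsilon_inverse = 1e10,
                              min_epsilon_inverse = 2) {
  pts <- unlist(lapply(q_candidates, function(q) {
    i <- seq_len(.levels_one(max_epsilon_inverse, q) + 1)
    c(q^i - 1, q^i, q^i + 1)
  }))
  sort(unique(pts[pts >= min_epsilon_inverse & pts <= max_epsilon_inverse]))
}

.check_scan_args <- function(epsilon_inverse, loss_rates, q_candidates) {
  if (any(epsilon_inverse < 2)) {
    abort("All `epsilon_inverse` values must be >= 2.")
  }
  if (any(loss_rates < 0 | loss_rates >= 1)) {
    abort("Loss rates must be in [0, 1): costs are undefined at 1.")
  }
  if (length(q_candidates) == 0 || any(q_candidates < 2)) {
    abort("`q_candidates` must all be >= 2.")
  }
  invisible(NULL)
}
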