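#' Plot an information map
#'
#' False-colour map of information per query (bits) over loss rate and
#' boundary position, with the closed-form optimal boundary overlaid in
#' white.
#'
#' @param object A `halflie_infomap` from [information_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.halflie_infomap <- function(object, ...) {
  L <- attr(object, "domain_length") %||% 1
  ridge <- tibble(
    loss_rate = sort(unique(object$loss_rate)),
    boundary = optimal_boundary(sort(unique(object$loss_rate)), L)
  )
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$loss_rate, y = .data$boundary)
  ) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$info_bits)) +
    ggplot2::geom_line(data = ridge, colour = "white", linewidth = 0.7) +
    ggplot2::scale_fill_viridis_c(name = "bits/query") +
    ggplot2::labs(
      x = "loss rate α", y = "boundary v",
      title = "Information per query and optimal boundary"
    )
}

#' Plot a Monte Carlo query-count distribution
#'
#' @param object A `halflie_mc` from [run_trials()].
#' @param type `"histogram"` (default) or `"cdf"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.halflie_mc <- function(object, type = c("histogram", "cdf"), ...) {
  type <- match.arg(type)
  s <- object$summary
  if (type == "histogram") {
    ggplot2::ggplot(s$histogram, ggplot2::aes(x = .data$count, y = .data$n)) +
      ggplot2::geom_col(width = 1) +
      ggplot2::geom_vline(xintercept = s$mode, linetype = "dashed") +
      ggplot2::labs(
        x = "total queries", y = "trials",
        title = sprintf(
          "q = %d, ε⁻¹ = %g, α₀ = %g (mode dashed)",
          object$config$sectioning_order, 1 / object$config$precision,
          object$config$loss_rate
        )
      )
  } else {
    ggplot2::ggplot(s$cdf, ggplot2::aes(x = .data$count, y = .data$cum_frac)) +
      ggplot2::geom_step() +
      ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
      ggplot2::labs(
        x = "total queries", y = "cumulative fraction",
        title = "Empirical CDF of total queries (median at dotted line)"
      )
  }
}

#' Plot an optimality map
#'
#' Tiles of the minimal-cost sectioning order(s) over precision and loss
#' rate; tied cells are labelled with the full argmin set.
#'
#' @param object A `halflie_optmap` from [optimality_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.halflie_optmap <- function(object, ...) {
  cells <- object |>
    as_tibble() |>
    filter(.data$is_optimal) |>
    group_by(.data$epsilon_inverse, .data$loss_rate) |>
    summarise(
      optimal_q = paste(sort(.data$q), collapse = ","),
      .groups = "drop"
    )
  ggplot2::ggplot(
    cells,
    ggplot2::aes(
      x = .data$epsilon_inverse, y = .data$loss_rate,
      fill = .data$optimal_q
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(epsilon^-1), y = expression(alpha[0]),
      fill = "optimal q",
      title = "Minimal-cost sectioning order"
    )
}

#' @importFrom rlang %||%
NULL
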