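#' Plot a Tajima's D scan
#'
#' D per window along the genome, with optional horizontal tail thresholds.
#' Windows with undefined D are dropped from the panel.
#'
#' @param object A `tajima_scan` tibble.
#' @param thresholds Optional `c(low =, high =)` from
#'   [empirical_thresholds()], drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tajima_scan
#' @export
autoplot.tajima_scan <- function(object, thresholds = NULL, ...) {
  df <- dplyr::filter(object, is.finite(.data$D))
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$D)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "window midpoint (bp)", y = "Tajima's D") +
    ggplot2::theme_minimal()
  if ("population" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~population)
  }
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_hline(
      yintercept = unname(thresholds), linetype = "dashed"
    )
  }
  p
}

#' Plot a TE age distribution
#'
#' Per-family histogram of Jukes-Cantor distances to the consensus — the
#' proxy for insertion age. The saturated overflow bin is dropped from the
#' panel.
#'
#' @param object A `te_age_hist` tibble from [te_age_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_age_hist
#' @export
autoplot.te_age_hist <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$bin_low))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = (.data$bin_low + .data$bin_high) / 2, y = .data$count
    )
  ) +
    ggplot2::geom_col(
      width = attr(object, "bin_width") %||% 0.01, fill = "grey30"
    ) +
    ggplot2::facet_wrap(~family_id) +
    ggplot2::labs(
      x = "substitutions per site (Jukes-Cantor)", y = "copies"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-branch Dollo gains and losses
#'
#' @param object A `dollo_map` from [dollo_reconstruct()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dollo_map
#' @export
autoplot.dollo_map <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(
      c("n_gained", "n_lost"), names_to = "event", values_to = "n"
    ) |>
    mutate(event = ifelse(.data$event == "n_gained", "gained", "lost"))
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$label, y = .data$n, fill = .data$event)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "branch (child node)", y = "gene families") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)
    )
}

#' @method glance tajima_scan
#' @export
glance.tajima_scan <- function(x, ...) {
  tibble(
    n_windows = nrow(x),
    n_defined = sum(is.finite(x$D)),
    mean_pi = mean(x$pi, na.rm = TRUE),
    mean_theta_w = mean(x$theta_w, na.rm = TRUE),
    mean_D = mean(x$D[is.finite(x$D)])
  )
}
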