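#' Plot a dose-response fit
#'
#' Observed responses and the fitted four-parameter logistic curve on a
#' log-dose axis.
#'
#' @param object A `four_pl_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.four_pl_fit <- function(object, ...) {
  df <- object$data[object$data$d > 0, , drop = FALSE]
  curve <- tibble(d = exp(seq(log(min(df$d)), log(max(df$d)),
                              length.out = 200)))
  curve$r <- predict(object, curve$d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$r)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$estimates[["ic50"]],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response",
                  title = sprintf("4PL fit: IC50 = %.0f",
                                  object$estimates[["ic50"]]))
}

#' Plot a cleavage report as a fragment map
#'
#' Horizontal segments for the parent sequence and each single-cut
#' fragment, positioned along the parent coordinates.
#'
#' @param object A `cleavage_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cleavage_report <- function(object, ...) {
  frags <- object$fragments
  df <- dplyr::bind_rows(
    tibble(label = object$id, start = 1L, end = nchar(object$sequence),
           what = "parent"),
    tibble(label = frags$fragment, start = frags$start, end = frags$end,
           what = paste("cut at bond", frags$bond))
  )
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start - 0.5,
                                       xend = .data$end + 0.5,
                                       yend = .data$label,
                                       colour = .data$what),
                          linewidth = 3) +
    ggplot2::geom_vline(xintercept = unique(frags$bond) + 0.5,
                        linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "residue position", y = NULL, colour = NULL,
                  title = sprintf("Single-cut fragments of %s", object$id))
}

#' Plot normalized activity against surface charge
#'
#' Scatter of the points with the OLS line and per-bin mean +/- SD.
#'
#' @param object A `charge_activity_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.charge_activity_summary <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pz_mV,
                               y = .data$normalized_activity)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = object$ols$slope,
                         intercept = object$ols$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "zeta potential (mV)",
                  y = "normalized activity (AU)",
                  title = sprintf("Y = %.4f X + %.1f; r^2 = %.4f",
                                  object$ols$slope, object$ols$intercept,
                                  object$ols$r_squared))
}
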