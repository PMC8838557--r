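# ggplot2 displays for the result types.

#' Bar chart of aggregated algorithm performance
#'
#' Mean with an SD error bar per metric and algorithm, mirroring the usual
#' comparison layout for wear-detection studies.
#'
#' @param object A `wear_comparison` from [run_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wear_comparison <- function(object, ...) {
  s <- object$summary
  s <- s[is.finite(s$mean), ]  # metrics absent on every recording: no bar
  s$metric <- factor(toupper(s$metric), c("SEN", "SPE", "ACC", "NPV"))
  ggplot2::ggplot(
    s,
    ggplot2::aes(x = .data$metric, y = .data$mean, fill = .data$algorithm)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$mean - dplyr::coalesce(.data$sd, 0), 0),
        ymax = pmin(.data$mean + dplyr::coalesce(.data$sd, 0), 1)
      ),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25,
      na.rm = TRUE
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "mean across recordings",
                  fill = "algorithm") +
    ggplot2::theme_minimal()
}

#' Wear/non-wear timeline of an epoch label vector
#'
#' @param object A `wear_epochs` tibble.
#' @param ... Unused.
#' @return A ggplot object (step trace; 1 = non-wear).
#' @export
autoplot.wear_epochs <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s / 3600, y = .data$label)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("wear", "non-wear")) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Candidate audit display for an event-based detection run
#'
#' Plots each candidate's temperature-level change against time, marking
#' retained events and the retention threshold; detected non-wear intervals
#' are shaded.
#'
#' @param object A `wear_events` from [detect_event()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wear_events <- function(object, ...) {
  a <- object$audit
  p <- ggplot2::ggplot()
  if (nrow(object$intervals)) {
    p <- p + ggplot2::geom_rect(
      data = object$intervals,
      ggplot2::aes(xmin = .data$start_s / 3600, xmax = .data$end_s / 3600,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85"
    )
  }
  p +
    ggplot2::geom_hline(yintercept = object$params$retain_thr_c,
                        linetype = "dashed") +
    ggplot2::geom_point(
      data = a,
      ggplot2::aes(x = .data$time_s / 3600, y = .data$t_diff,
                   colour = .data$retained,
                   shape = factor(.data$sign, c(-1, 1),
                                  c("removal", "reattach")))
    ) +
    ggplot2::labs(x = "time (h)", y = "temperature change (degC)",
                  colour = "retained", shape = "candidate") +
    ggplot2::theme_minimal()
}
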