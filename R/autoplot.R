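#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated filament trace
#'
#' Terminus positions (and optionally the free-monomer concentration for
#' closed-mode traces) against time.
#'
#' @param object A `"sim_trace"` from [simulate_filament()].
#' @param what `"positions"` (both termini), `"length"`, or
#'   `"concentration"` (closed mode).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_trace
#' @export
autoplot.sim_trace <- function(object,
                               what = c("positions", "length", "concentration"),
                               ...) {
  what <- match.arg(what)
  if (what == "positions") {
    df <- tidyr::pivot_longer(
      tibble::as_tibble(object)[, c("time_min", "pos_A_um", "pos_B_um")],
      cols = c("pos_A_um", "pos_B_um"),
      names_to = "terminus", values_to = "position_um"
    )
    df$terminus <- ifelse(df$terminus == "pos_A_um", "A (N face)", "B (O face)")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$position_um,
                                     colour = .data$terminus)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "time (min)", y = "terminus position (µm)",
                    colour = NULL)
  } else if (what == "length") {
    ggplot2::ggplot(trace_length(object),
                    ggplot2::aes(x = .data$time_min, y = .data$length_um)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "time (min)", y = "filament length (µm)")
  } else {
    ggplot2::ggplot(tibble::as_tibble(object),
                    ggplot2::aes(x = .data$time_min, y = .data$conc_mM)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "time (min)", y = "free monomer (mM)")
  }
}

#' Plot a growth-law fit
#'
#' The (concentration, rate) points with the fitted line
#' `R = k_on c - k_off`; the x-intercept is the critical concentration.
#'
#' @param object A `"growth_law_fit"` from [fit_growth_law()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_law_fit
#' @export
autoplot.growth_law_fit <- function(object, ...) {
  df <- object$lm$model
  names(df)[names(df) == "rate_um_min"] <- "rate"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_mM, y = .data$rate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_abline(intercept = -object$k_off, slope = object$k_on,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "monomer concentration (mM)",
                  y = "net growth rate (µm/min)")
}

#' Plot a recovery report
#'
#' Per-condition mean rates with standard-error bars, the fitted growth
#' law, and the estimated critical concentration (vertical line).
#'
#' @param object A `"recovery_report"` from [run_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  cr <- object$condition_rates
  ggplot2::ggplot(cr, ggplot2::aes(x = .data$conc_mM, y = .data$rate_um_min)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = object$critical$estimate,
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_abline(intercept = -object$fit$k_off,
                         slope = object$fit$k_on, colour = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate_um_min - .data$se,
                                        ymax = .data$rate_um_min + .data$se),
                           width = 0.02) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "monomer concentration (mM)",
                  y = "net growth rate (µm/min)")
}
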