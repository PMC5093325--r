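#' Per-terminus and per-tube growth rates from a trace table
#'
#' `terminus_rates()` fits each (tube, terminus) position series by OLS
#' ([estimate_terminus_rate()]), with the outward-positive orientation
#' convention (-1 for terminus A, +1 for B). `tube_rates()` sums the two
#' termini of each tube: since length is `pos_B - pos_A`, the summed outward
#' rates equal the tube's net elongation rate `dL/dt`, which is what the
#' linear growth law describes.
#'
#' @param data A trace table with the standard columns (see
#'   [write_traces()]), e.g. from [generate_experiment()] or
#'   [read_traces()].
#' @return `terminus_rates()`: a tibble with one row per (tube, terminus):
#'   `tube_id`, `terminus`, `conc_mM`, `rate_um_min`, `se`, `n_frames`.
#'   `tube_rates()`: one row per tube: `tube_id`, `conc_mM`, `rate_um_min`
#'   (sum of the termini), `se` (quadrature sum).
#' @export
terminus_rates <- function(data) {
  validate_trace_table(data)
  data |>
    dplyr::group_by(.data$tube_id, .data$terminus) |>
    dplyr::group_modify(function(df, key) {
      orientation <- if (key$terminus == "A") -1 else 1
      est <- estimate_terminus_rate(df, orientation = orientation)
      est$conc_mM <- df$conc_mM[[1]]
      est
    }) |>
    dplyr::ungroup() |>
    dplyr::select("tube_id", "terminus", "conc_mM", "rate_um_min", "se",
                  "n_frames")
}

#' @rdname terminus_rates
#' @export
tube_rates <- function(data) {
  terminus_rates(data) |>
    dplyr::group_by(.data$tube_id, .data$conc_mM) |>
    dplyr::summarise(rate_um_min = sum(.data$rate_um_min),
                     se = sqrt(sum(.data$se^2)),
                     .groups = "drop")
}

#' Per-condition mean growth rates
#'
#' Averages per-tube net rates within each concentration (unweighted mean
#' over tubes, mirroring "average growth rate of ten individual termini"
#' data points) and reports the standard error over tubes, whose inverse
#' square is the default weight for [fit_growth_law()].
#'
#' @param data A trace table (see [terminus_rates()]).
#' @return A tibble with one row per concentration: `conc_mM`,
#'   `rate_um_min`, `se`, `n_tubes`, `weight` (`1/se^2`).
#' @export
condition_rates <- function(data) {
  tube_rates(data) |>
    dplyr::group_by(.data$conc_mM) |>
    dplyr::summarise(
      rate = mean(.data$rate_um_min),
      se = stats::sd(.data$rate_um_min) / sqrt(dplyr::n()),
      n_tubes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::rename(rate_um_min = "rate") |>
    dplyr::mutate(weight = 1 / .data$se^2)
}

#' Delta-method confidence interval for the critical concentration
#'
#' First-order (delta-method) interval for `c_s = k_off / k_on` using the
#' fit's parameter covariance: with `g = (dc_s/dk_off, dc_s/dk_on) =
#' (1/k_on, -k_off/k_on^2)`, `var(c_s) ~ g' V g`. The interval is symmetric
#' and approximate (quantiles use the fit's residual t distribution, since
#' the parameter covariance rests on few degrees of freedom); when `k_on`
#' is within 2 standard errors of zero the
#' linearisation is unreliable and the interval is returned with a warning.
#'
#' @param fit A [fit_growth_law()] object with `k_on > 0`.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `estimate`, `low`, `high`, `se`, `level`.
#' @export
delta_ci_critical_concentration <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "growth_law_fit"),
            is.numeric(level), length(level) == 1, level > 0, level < 1)
  if (!is.finite(fit$k_on) || fit$k_on <= 0) {
    stop("critical concentration CI requires fitted k_on > 0", call. = FALSE)
  }
  if (fit$k_on <= 2 * fit$se_k_on) {
    warning("fitted k_on is within 2 SE of zero; the delta-method interval ",
            "for c_s is unreliable", call. = FALSE)
  }
  cs <- fit$k_off / fit$k_on
  g <- c(1 / fit$k_on, -fit$k_off / fit$k_on^2) # d c_s / d (k_off, k_on)
  V <- fit$vcov
  se <- sqrt(drop(t(g) %*% V %*% g))
  z <- stats::qt(1 - (1 - level) / 2, df = fit$df_residual)
  tibble::tibble(estimate = cs, low = cs - z * se, high = cs + z * se,
                 se = se, level = level)
}

#' Run the full parameter-recovery experiment
#'
#' The end-to-end synthetic pipeline mirroring a growth-rate-versus-
#' concentration study: generate the dataset from the design, estimate a
#' rate per terminus, sum termini into per-tube net rates, average tubes
#' into per-condition points, fit the linear growth law (inverse-variance
#' weighted by default), derive the critical concentration with a
#' delta-method CI, and classify each tube's directionality. Deterministic
#' under the design's master seed.
#'
#' @param design An [experiment_design()].
#' @param weighted Use `1/se^2` weights for the growth-law fit (default
#'   TRUE); set FALSE for an unweighted fit.
#' @param alpha Per-end activity level for the directionality
#'   classification. Default 0.01: an experiment tests two termini on each
#'   of dozens of tubes, and 0.01 keeps the expected number of truly silent
#'   termini flagged active to about one per experiment (at the
#'   single-comparison default of 0.05 it would be about five).
#' @param ci_level Confidence level for parameter and c_s intervals.
#' @return A `"recovery_report"` list: `design`, `data` (the generated
#'   trace table), `terminus_rates`, `tube_rates`, `condition_rates`, `fit`
#'   (a [fit_growth_law()] object), `params_ci` (tibble of k_on/k_off
#'   estimates with CIs), `critical` (c_s with delta CI), `directionality`
#'   (per-tube calls) and `tally` (label counts).
#' @examples
#' \donttest{
#' rep <- run_recovery(experiment_design(n_tubes = 3, seed = 2))
#' glance(rep)
#' }
#' @export
run_recovery <- function(design, weighted = TRUE, alpha = 0.01,
                         ci_level = 0.95) {
  stopifnot(inherits(design, "experiment_design"))
  data <- generate_experiment(design)
  term <- terminus_rates(data)
  tubes <- tube_rates(data)
  conds <- condition_rates(data)
  fit_data <- conds[, c("conc_mM", "rate_um_min", "weight")]
  if (!weighted) fit_data$weight <- NULL
  fit <- fit_growth_law(fit_data)
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = fit$df_residual)
  params_ci <- tibble::tibble(
    term = c("k_on", "k_off"),
    estimate = c(fit$k_on, fit$k_off),
    std.error = c(fit$se_k_on, fit$se_k_off),
    low = c(fit$k_on - tq * fit$se_k_on, fit$k_off - tq * fit$se_k_off),
    high = c(fit$k_on + tq * fit$se_k_on, fit$k_off + tq * fit$se_k_off),
    level = ci_level
  )
  critical <- delta_ci_critical_concentration(fit, level = ci_level)
  directionality <- term |>
    tidyr::pivot_wider(id_cols = c("tube_id", "conc_mM"),
                       names_from = "terminus",
                       values_from = c("rate_um_min", "se")) |>
    dplyr::rowwise() |>
    dplyr::mutate(classify_directionality(
      list(rate_um_min = .data$rate_um_min_A, se = .data$se_A),
      list(rate_um_min = .data$rate_um_min_B, se = .data$se_B),
      alpha = alpha
    )) |>
    dplyr::ungroup()
  tally <- directionality |>
    dplyr::count(.data$label, .drop = FALSE, name = "n_tubes")
  structure(list(
    design = design,
    data = data,
    terminus_rates = term,
    tube_rates = tubes,
    condition_rates = conds,
    fit = fit,
    params_ci = params_ci,
    critical = critical,
    directionality = directionality,
    tally = tally,
    alpha = alpha,
    weighted = weighted
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$design)
  cat("\nPer-condition net growth rates (um/min):\n")
  print(as.data.frame(x$condition_rates), row.names = FALSE, digits = 4)
  cat("\n")
  print(x$fit)
  cat(sprintf("\nCritical concentration: %.3f mM (%.0f%% CI %.3f-%.3f)\n",
              x$critical$estimate, 100 * x$critical$level,
              x$critical$low, x$critical$high))
  cat("\nDirectionality tally (alpha =", x$alpha, "):\n")
  print(as.data.frame(x$tally), row.names = FALSE)
  invisible(x)
}

#' Tidy a recovery report
#'
#' @param x A `"recovery_report"`.
#' @param ... Unused.
#' @return The parameter table with estimates, standard errors and CIs
#'   (rows `k_on`, `k_off`, `c_s`).
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) {
  dplyr::bind_rows(
    x$params_ci,
    tibble::tibble(term = "c_s", estimate = x$critical$estimate,
                   std.error = x$critical$se, low = x$critical$low,
                   high = x$critical$high, level = x$critical$level)
  )
}

#' Glance at a recovery report
#'
#' @param x A `"recovery_report"`.
#' @param ... Unused.
#' @return A one-row tibble: fitted parameters, `critical_conc_mM`,
#'   `r.squared`, tube counts and the modal directionality label.
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tal <- x$tally
  tibble::tibble(
    k_on = x$fit$k_on,
    k_off = x$fit$k_off,
    critical_conc_mM = x$critical$estimate,
    r.squared = x$fit$r_squared,
    n_conditions = nrow(x$condition_rates),
    n_tubes = nrow(x$tube_rates),
    modal_label = as.character(tal$label[[which.max(tal$n_tubes)]])
  )
}
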