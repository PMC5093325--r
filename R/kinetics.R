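#' Kinetic parameters of the linear growth law
#'
#' A filament terminus gains length at rate `k_on * c` (monomer attachment,
#' proportional to the local free-monomer concentration `c`) and loses length
#' at a concentration-independent rate `k_off` (detachment). The net growth
#' rate is the linear law `R = k_on * c - k_off`, which crosses zero at the
#' critical concentration `c_s = k_off / k_on`: above `c_s` the filament
#' elongates, below it the filament shortens.
#'
#' @param k_on Elongation rate constant, um min^-1 mM^-1, >= 0.
#' @param k_off Dissociation rate, um min^-1, >= 0.
#' @return An object of class `"kinetic_params"`.
#' @examples
#' ff <- kinetic_params(k_on = 3.36, k_off = 7.4)
#' critical_concentration(ff)
#' @export
kinetic_params <- function(k_on, k_off) {
  stopifnot(is.numeric(k_on), is.numeric(k_off),
            length(k_on) == 1, length(k_off) == 1)
  if (!is.finite(k_on) || k_on < 0) stop("k_on must be finite and >= 0", call. = FALSE)
  if (!is.finite(k_off) || k_off < 0) stop("k_off must be finite and >= 0", call. = FALSE)
  structure(list(k_on = as.numeric(k_on), k_off = as.numeric(k_off)),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> k_on = %g um/min/mM, k_off = %g um/min", x$k_on, x$k_off))
  if (x$k_on > 0) cat(sprintf(" (c_s = %g mM)", x$k_off / x$k_on))
  cat("\n")
  invisible(x)
}

#' Net growth rate at a given monomer concentration
#'
#' Evaluates `R = k_on * c - k_off`. Negative values mean net shortening.
#'
#' @param conc_mM Free-monomer concentration(s) in mM, >= 0.
#' @param params A [kinetic_params()] object.
#' @return Numeric vector of net growth rates in um/min.
#' @examples
#' net_growth_rate(3.20, kinetic_params(3.36, 7.4)) # supercritical: grows
#' net_growth_rate(1.60, kinetic_params(3.36, 7.4)) # subcritical: shrinks
#' @export
net_growth_rate <- function(conc_mM, params) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(conc_mM))
  if (any(!is.finite(conc_mM)) || any(conc_mM < 0)) {
    stop("concentration must be finite and >= 0", call. = FALSE)
  }
  params$k_on * conc_mM - params$k_off
}

#' Critical concentration of the growth law
#'
#' The concentration at which attachment and detachment balance,
#' `c_s = k_off / k_on`. Net growth is zero at `c_s` by construction.
#'
#' @param params A [kinetic_params()] object or a [fit_growth_law()] fit,
#'   with `k_on > 0`.
#' @return Critical concentration in mM (unrounded).
#' @examples
#' round_half_up(critical_concentration(kinetic_params(3.36, 7.4)), 1) # 2.2
#' @export
critical_concentration <- function(params) {
  UseMethod("critical_concentration")
}

#' @export
critical_concentration.kinetic_params <- function(params) {
  if (params$k_on <= 0) {
    stop("critical concentration is undefined for k_on = 0", call. = FALSE)
  }
  params$k_off / params$k_on
}

#' @export
critical_concentration.growth_law_fit <- function(params) {
  if (!is.finite(params$k_on) || params$k_on <= 0) {
    stop("critical concentration is undefined for fitted k_on <= 0",
         call. = FALSE)
  }
  params$k_off / params$k_on
}

#' Fit the linear growth law to (concentration, rate) points
#'
#' Ordinary (optionally weighted) least squares of net growth rate on
#' monomer concentration. The slope estimates `k_on`, the negated intercept
#' estimates `k_off`. Weights, when supplied, are inverse variances of the
#' rate points (the usual choice is `1/se^2` of per-condition mean rates).
#'
#' @param data Data frame with columns `conc_mM` and `rate_um_min`, and
#'   optionally `weight` (inverse-variance, non-negative).
#' @return An object of class `"growth_law_fit"`: a list with elements
#'   `k_on`, `k_off`, `se_k_on`, `se_k_off`, `r_squared`, `n_points`, the
#'   parameter covariance matrix `vcov` (order `k_off`, `k_on`), residual
#'   degrees of freedom `df_residual`, and the underlying `lm` fit. Raw
#'   estimates are kept even if noise pushes one below zero.
#' @seealso [critical_concentration()], [delta_ci_critical_concentration()],
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' pts <- tibble::tibble(conc_mM = c(1.6, 2.4, 3.2), rate_um_min = c(-2.024, 0.664, 3.352))
#' fit <- fit_growth_law(pts)
#' tidy(fit)
#' @export
fit_growth_law <- function(data) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(c("conc_mM", "rate_um_min"), names(data))
  if (length(missing) > 0) {
    stop("data is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(data$conc_mM)) < 2) {
    stop("need >= 2 distinct concentrations to fit the growth law",
         call. = FALSE)
  }
  w <- if ("weight" %in% names(data)) data$weight else NULL
  if (!is.null(w)) {
    if (any(!is.finite(w)) || any(w < 0)) {
      stop("weights must be finite and >= 0", call. = FALSE)
    }
  }
  fit <- stats::lm(rate_um_min ~ conc_mM, data = data, weights = w)
  cf <- stats::coef(fit)
  # noiseless interpolation is a supported use (oracle checks, two-point
  # fits); muffle lm's perfect-fit warning for that case only
  quiet_perfect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  V <- quiet_perfect(stats::vcov(fit))
  # reparameterise (intercept, slope) -> (k_off, k_on): k_off = -intercept
  vc <- matrix(c(V[1, 1], -V[1, 2], -V[2, 1], V[2, 2]), 2, 2,
               dimnames = list(c("k_off", "k_on"), c("k_off", "k_on")))
  se <- sqrt(diag(V))
  # kinetic_params() enforces non-negativity, but a noisy fit can legitimately
  # cross zero; store the raw estimates and let accessors wrap them
  k_on_hat <- unname(cf[2])
  k_off_hat <- -unname(cf[1])
  r2 <- quiet_perfect(summary(fit)$r.squared)
  structure(list(
    k_on = k_on_hat,
    k_off = k_off_hat,
    se_k_on = unname(se[2]),
    se_k_off = unname(se[1]),
    r_squared = r2,
    n_points = nrow(data),
    vcov = vc,
    df_residual = fit$df.residual,
    lm = fit
  ), class = "growth_law_fit")
}

#' @export
print.growth_law_fit <- function(x, ...) {
  cat("<growth_law_fit> R = k_on * c - k_off\n")
  cat(sprintf("  k_on  = %.4g +/- %.3g um/min/mM\n", x$k_on, x$se_k_on))
  cat(sprintf("  k_off = %.4g +/- %.3g um/min\n", x$k_off, x$se_k_off))
  if (x$k_on > 0) {
    cat(sprintf("  c_s   = %.4g mM\n", x$k_off / x$k_on))
  }
  cat(sprintf("  r^2 = %.4f on %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a growth-law fit
#'
#' @param x A `"growth_law_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`k_on`, `k_off`):
#'   `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy growth_law_fit
#' @export
tidy.growth_law_fit <- function(x, ...) {
  est <- c(k_on = x$k_on, k_off = x$k_off)
  se <- c(k_on = x$se_k_on, k_off = x$se_k_off)
  stat <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pt(-abs(unname(stat)), df = x$df_residual)
  )
}

#' Glance at a growth-law fit
#'
#' @param x A `"growth_law_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `critical_conc_mM`, `n_points`,
#'   `df.residual`.
#' @method glance growth_law_fit
#' @export
glance.growth_law_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    critical_conc_mM = if (x$k_on > 0) x$k_off / x$k_on else NA_real_,
    n_points = x$n_points,
    df.residual = x$df_residual
  )
}

#' Estimate a terminus growth rate from a position time series
#'
#' Fits position against time by ordinary least squares over the whole
#' trace and reports the slope in the outward-positive convention: the
#' filament lies on an axis with terminus A at the lower coordinate and
#' terminus B at the higher, so orientation is -1 for A and +1 for B and
#' outward growth is positive for either terminus. OLS over the trace (not
#' frame-to-frame differencing) is the minimum-variance linear estimator for
#' a constant-rate segment.
#'
#' @param data Data frame with columns `time_min` (strictly increasing) and
#'   `position_um`; at least 2 frames.
#' @param orientation `+1` (terminus B) or `-1` (terminus A).
#' @return A one-row tibble: `rate_um_min` (outward-positive), `se`,
#'   `n_frames`.
#' @examples
#' tr <- tibble::tibble(time_min = 0:5, position_um = 10 + 0.5 * (0:5))
#' estimate_terminus_rate(tr, orientation = +1)
#' @export
estimate_terminus_rate <- function(data, orientation = c(1, -1)) {
  if (length(orientation) > 1) orientation <- orientation[[1]]
  stopifnot(is.data.frame(data), orientation %in% c(-1, 1))
  missing <- setdiff(c("time_min", "position_um"), names(data))
  if (length(missing) > 0) {
    stop("data is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  t <- data$time_min
  x <- data$position_um
  n <- length(t)
  if (n < 2) stop("need >= 2 frames", call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("times must be strictly increasing (duplicate or unsorted time stamps)",
         call. = FALSE)
  }
  # closed-form simple OLS: called thousands of times per experiment, so
  # avoid lm() overhead (equivalence with lm checked in the test suite)
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- sum(tc * x) / sxx
  intercept <- mean(x) - slope * mean(t)
  resid <- x - intercept - slope * t
  se <- if (n > 2) sqrt(sum(resid^2) / (n - 2) / sxx) else 0
  tibble::tibble(
    rate_um_min = orientation * slope,
    se = se,
    n_frames = n
  )
}

#' Classify filament growth directionality from two terminus rates
#'
#' A terminus is called "active" when its outward rate differs from zero
#' beyond measurement error: `|rate| > z_(1-alpha/2) * se` (an `se` of zero
#' is treated as exact, so any nonzero rate is active). The filament is
#' `unidirectional` when exactly one terminus is active (growth or
#' shortening confined to one end), `bidirectional` when both are, and
#' `stalled` when neither is. `indeterminate` is reserved for non-finite
#' inputs and is returned with a warning rather than an error. Alongside the
#' label, the two-sample z statistic for equality of the two rates,
#' `(rate_a - rate_b) / sqrt(se_a^2 + se_b^2)`, is reported.
#'
#' @param end_a,end_b One-row data frames as returned by
#'   [estimate_terminus_rate()] (columns `rate_um_min`, `se`), or named lists
#'   with those elements.
#' @param alpha Two-sided significance level for the per-end activity test.
#' @return A one-row tibble: `label` (factor with levels unidirectional,
#'   bidirectional, stalled, indeterminate), `active_ends` (0-2),
#'   `z_statistic`, `alpha`.
#' @examples
#' a <- tibble::tibble(rate_um_min = 5.0, se = 0.1)
#' b <- tibble::tibble(rate_um_min = 0.02, se = 0.1)
#' classify_directionality(a, b) # unidirectional
#' @export
classify_directionality <- function(end_a, end_b, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  pick <- function(e) {
    r <- e[["rate_um_min"]]
    s <- e[["se"]]
    if (is.null(r) || is.null(s)) {
      stop("each end needs elements rate_um_min and se", call. = FALSE)
    }
    c(rate = as.numeric(r[[1]]), se = as.numeric(s[[1]]))
  }
  a <- pick(end_a)
  b <- pick(end_b)
  levels <- c("unidirectional", "bidirectional", "stalled", "indeterminate")
  z_eq <- (a[["rate"]] - b[["rate"]]) / sqrt(a[["se"]]^2 + b[["se"]]^2)
  if (any(!is.finite(c(a, b))) || any(c(a[["se"]], b[["se"]]) < 0)) {
    warning("non-finite rate or se; classification is indeterminate",
            call. = FALSE)
    return(tibble::tibble(
      label = factor("indeterminate", levels = levels),
      active_ends = NA_integer_,
      z_statistic = NA_real_,
      alpha = alpha
    ))
  }
  zcrit <- stats::qnorm(1 - alpha / 2)
  active <- function(e) {
    if (e[["se"]] == 0) e[["rate"]] != 0 else abs(e[["rate"]]) > zcrit * e[["se"]]
  }
  n_active <- active(a) + active(b)
  label <- c("stalled", "unidirectional", "bidirectional")[n_active + 1]
  tibble::tibble(
    label = factor(label, levels = levels),
    active_ends = as.integer(n_active),
    z_statistic = if (a[["se"]] == 0 && b[["se"]] == 0) NA_real_ else z_eq,
    alpha = alpha
  )
}
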