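#' Build a co-flow mixing specification
#'
#' In a laminar co-flow device, two (or more) inlet solutions merge in a
#' narrow mixing channel; diffusion across the channel completes mixing well
#' before the observation region, so the in-channel concentration is the
#' flow-weighted average of the inlet concentrations. A mixing spec is a
#' tibble with one row per inlet stream.
#'
#' All streams must share one concentration unit; mixing mg/ml with mM is an
#' error rather than a silent conversion, because both units are in routine
#' use for the same solutions.
#'
#' @param conc Numeric vector of inlet concentrations (one per stream),
#'   non-negative.
#' @param flow_ul_h Numeric vector of inlet flow rates in ul/h, non-negative;
#'   at least one must be positive.
#' @param unit Concentration unit shared by all streams: `"mM"` or `"mg/ml"`.
#' @return A tibble with columns `conc`, `flow_ul_h`, `unit`.
#' @examples
#' mixing_spec(conc = c(3.20, 1.60), flow_ul_h = c(2.2, 1.7), unit = "mM")
#' @export
mixing_spec <- function(conc, flow_ul_h, unit = c("mM", "mg/ml")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(conc), is.numeric(flow_ul_h),
            length(conc) == length(flow_ul_h), length(conc) >= 1)
  tibble::tibble(conc = as.numeric(conc),
                 flow_ul_h = as.numeric(flow_ul_h),
                 unit = unit)
}

validate_streams <- function(streams) {
  stopifnot(is.data.frame(streams))
  required <- c("conc", "flow_ul_h", "unit")
  missing <- setdiff(required, names(streams))
  if (length(missing) > 0) {
    stop("mixing spec is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(streams) == 0) stop("mixing spec has no streams", call. = FALSE)
  if (length(unique(streams$unit)) != 1) {
    stop("streams use mixed concentration units (",
         paste(unique(streams$unit), collapse = ", "),
         "); convert explicitly before mixing", call. = FALSE)
  }
  if (any(!is.finite(streams$conc)) || any(streams$conc < 0)) {
    stop("stream concentrations must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(streams$flow_ul_h)) || any(streams$flow_ul_h < 0)) {
    stop("flow rates must be finite and >= 0", call. = FALSE)
  }
  if (sum(streams$flow_ul_h) <= 0) {
    stop("total flow must be > 0 (all flow rates are zero)", call. = FALSE)
  }
  invisible(streams)
}

#' In-channel concentration of a co-flow mixture
#'
#' Computes the flow-weighted mean concentration
#' \eqn{\sum_i c_i q_i / \sum_i q_i} over the inlet streams. This is the
#' concentration the filament experiences once the streams are fully mixed;
#' it is bounded by the extreme inlet concentrations, invariant under stream
#' permutation, and invariant under uniform scaling of all flow rates.
#'
#' @param streams A data frame from [mixing_spec()] (columns `conc`,
#'   `flow_ul_h`, `unit`).
#' @return A one-row tibble with columns `conc` (the mixed concentration,
#'   unrounded), `unit`, and `total_flow_ul_h`.
#' @examples
#' # programming the cycloFF critical concentration:
#' mixing_spec(c(0.5, 4.0), c(1.9, 2.1), unit = "mg/ml") |>
#'   mixed_concentration()
#' @export
mixed_concentration <- function(streams) {
  validate_streams(streams)
  q <- streams$flow_ul_h
  tibble::tibble(
    conc = sum(streams$conc * q) / sum(q),
    unit = streams$unit[[1]],
    total_flow_ul_h = sum(q)
  )
}

#' Flow split that realises a target mixed concentration
#'
#' Solves the inverse co-flow problem: given a low- and a high-concentration
#' inlet solution and a total flow rate, find the unique pair of flow rates
#' whose flow-weighted mean equals the target concentration. This is the
#' calculation used to hold a filament exactly at its critical concentration.
#'
#' @param c_low,c_high Inlet concentrations, `c_low < c_high` (any shared
#'   unit).
#' @param c_target Target in-channel concentration; must lie in
#'   `[c_low, c_high]`.
#' @param q_total Total flow rate in ul/h, > 0.
#' @return A one-row tibble with columns `q_low_ul_h`, `q_high_ul_h`.
#' @examples
#' flow_rates_for_target(1.60, 3.20, 2.43, q_total = 3.9)
#' @export
flow_rates_for_target <- function(c_low, c_high, c_target, q_total) {
  stopifnot(is.numeric(c_low), is.numeric(c_high), is.numeric(c_target),
            is.numeric(q_total),
            length(c_low) == 1, length(c_high) == 1,
            length(c_target) == 1, length(q_total) == 1)
  if (!(c_low < c_high)) stop("require c_low < c_high", call. = FALSE)
  if (q_total <= 0) stop("q_total must be > 0", call. = FALSE)
  if (c_target < c_low || c_target > c_high) {
    stop("target concentration ", c_target, " is unreachable from inlets [",
         c_low, ", ", c_high, "]", call. = FALSE)
  }
  frac_high <- (c_target - c_low) / (c_high - c_low)
  tibble::tibble(
    q_low_ul_h = (1 - frac_high) * q_total,
    q_high_ul_h = frac_high * q_total
  )
}
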