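trace_columns <- c("tube_id", "terminus", "time_min", "position_um",
                   "replicate_sd_um", "conc_mM")

validate_trace_table <- function(data) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(trace_columns, names(data))
  if (length(missing) > 0) {
    stop("trace table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) stop("trace table is empty", call. = FALSE)
  if (!all(data$terminus %in% c("A", "B"))) {
    stop("terminus must be 'A' or 'B'", call. = FALSE)
  }
  if (any(data$replicate_sd_um < 0, na.rm = TRUE)) {
    stop("replicate_sd_um must be >= 0", call. = FALSE)
  }
  keyed <- paste(data$tube_id, data$terminus, data$time_min, sep = "\r")
  if (anyDuplicated(keyed) > 0) {
    stop("duplicated (tube_id, terminus, time_min) rows", call. = FALSE)
  }
  ok <- vapply(
    split(data$time_min, paste(data$tube_id, data$terminus, sep = "\r")),
    function(t) all(diff(t) > 0),
    logical(1)
  )
  if (!all(ok)) {
    stop("times must be strictly increasing within each (tube, terminus)",
         call. = FALSE)
  }
  invisible(data)
}

#' Read and write filament trace tables
#'
#' One fixed CSV dialect is used for every trace table in the package:
#' comma-separated, UTF-8, `.` decimal separator, header row required, with
#' columns `tube_id`, `terminus` (A|B), `time_min`, `position_um`,
#' `replicate_sd_um`, `conc_mM` (times in minutes, positions in um).
#' `read_traces()` validates the schema (a missing column is reported by
#' name), monotone times, and duplicate rows; `write_traces()` writes with
#' full precision so a write/read round trip is lossless.
#'
#' @param data A trace table (e.g. from [generate_experiment()] or
#'   [observe_trace()]).
#' @param path File path.
#' @return `read_traces()` returns a validated tibble with the columns
#'   above; `write_traces()` returns `path` invisibly.
#' @export
write_traces <- function(data, path) {
  validate_trace_table(data)
  readr::write_csv(data[trace_columns], path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # a missing column is reported by the schema check below, by name;
  # silence readr's own parser-mismatch chatter
  data <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      tube_id = readr::col_character(),
      terminus = readr::col_character(),
      time_min = readr::col_double(),
      position_um = readr::col_double(),
      replicate_sd_um = readr::col_double(),
      conc_mM = readr::col_double()
    ),
    progress = FALSE
  ))
  validate_trace_table(data)
  data
}

#' Read an experiment design from a YAML file
#'
#' The YAML schema mirrors [experiment_design()]:
#' ```yaml
#' concentrations_mM: [1.6, 2.4, 2.8, 3.2, 3.6]
#' n_tubes: 10
#' duration_min: 10
#' seed: 1
#' filament:
#'   preset: ff          # or cycloff; omit to give ends explicitly
#'   layer_um: 0.01
#'   initial_length_um: 30
#'   end_O: {k_on: 3.36, k_off: 7.4, cap_rate: 0}   # overrides preset
#'   end_N: {k_on: 0, k_off: 0, cap_rate: 0}
#' measurement:
#'   sigma_um: 0.25
#'   n_repeats: 5
#'   frame_interval_min: 0.5
#' ```
#'
#' @param path Path to a YAML file.
#' @return An [experiment_design()].
#' @export
read_experiment_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  fil <- y$filament
  base <- if (!is.null(fil$preset)) {
    switch(tolower(fil$preset),
           ff = ff_filament(),
           cycloff = cycloff_filament(),
           stop("unknown filament preset '", fil$preset, "'", call. = FALSE))
  } else {
    NULL
  }
  mk_end <- function(spec, fallback) {
    if (is.null(spec)) return(fallback)
    end_kinetics(k_on = spec$k_on %||% fallback$k_on,
                 k_off = spec$k_off %||% fallback$k_off,
                 cap_rate = spec$cap_rate %||% fallback$cap_rate %||% 0)
  }
  zero <- end_kinetics(0, 0)
  filament <- filament_config(
    end_O = mk_end(fil$end_O, base$end_O %||% zero),
    end_N = mk_end(fil$end_N, base$end_N %||% zero),
    layer_um = fil$layer_um %||% base$layer_um %||% 0.01,
    initial_length_um = fil$initial_length_um %||% base$initial_length_um %||% 20
  )
  meas <- y$measurement
  measurement <- measurement_model(
    sigma_um = meas$sigma_um %||% 0.25,
    n_repeats = meas$n_repeats %||% 5,
    frame_interval_min = meas$frame_interval_min %||% 0.5
  )
  experiment_design(
    concentrations = unlist(y$concentrations_mM),
    n_tubes = y$n_tubes %||% 10,
    duration_min = y$duration_min %||% 10,
    filament = filament,
    measurement = measurement,
    seed = y$seed %||% 1
  )
}

#' Read a co-flow mixing spec from a YAML file
#'
#' Schema: `streams: [{conc: 3.2, unit: mM, flow_ul_per_h: 2.2}, ...]`.
#'
#' @param path Path to a YAML file.
#' @return A [mixing_spec()] tibble.
#' @export
read_mixing_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$streams) || length(y$streams) == 0) {
    stop("YAML must contain a non-empty 'streams' list", call. = FALSE)
  }
  units <- vapply(y$streams, function(s) s$unit %||% "mM", character(1))
  if (length(unique(units)) != 1) {
    stop("streams use mixed concentration units (",
         paste(unique(units), collapse = ", "), ")", call. = FALSE)
  }
  mixing_spec(
    conc = vapply(y$streams, function(s) as.numeric(s$conc), numeric(1)),
    flow_ul_h = vapply(y$streams, function(s) as.numeric(s$flow_ul_per_h),
                       numeric(1)),
    unit = units[[1]]
  )
}

#' @importFrom rlang %||%
NULL
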