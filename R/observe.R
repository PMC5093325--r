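#' Microscopy measurement model
#'
#' Emulates the manual image-analysis protocol: filament end positions are
#' read off frames captured at a fixed interval, and each position is
#' measured several times and averaged per time point. Single reads carry
#' iid Gaussian error with standard deviation `sigma_um`; the reported
#' (averaged) position therefore has SD `sigma_um / sqrt(n_repeats)`.
#'
#' @param sigma_um Per-single-measurement Gaussian noise SD, um, >= 0
#'   (default 0.25, small against the 5-10 um scale of the structures).
#' @param n_repeats Independent reads averaged per time point (default 5).
#' @param frame_interval_min Time between frames, min, > 0.
#' @return An object of class `"measurement_model"`.
#' @export
measurement_model <- function(sigma_um = 0.25, n_repeats = 5,
                              frame_interval_min = 0.5) {
  if (!is.finite(sigma_um) || sigma_um < 0) {
    stop("sigma_um must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(n_repeats) || n_repeats < 1 || n_repeats != round(n_repeats)) {
    stop("n_repeats must be a positive integer", call. = FALSE)
  }
  if (!is.finite(frame_interval_min) || frame_interval_min <= 0) {
    stop("frame_interval_min must be > 0", call. = FALSE)
  }
  structure(list(sigma_um = as.numeric(sigma_um),
                 n_repeats = as.integer(n_repeats),
                 frame_interval_min = as.numeric(frame_interval_min)),
            class = "measurement_model")
}

#' Observe a simulated trace through the measurement model
#'
#' Samples terminus positions at frame times `0, dt, 2dt, ...` up to the
#' trace's end time by zero-order hold on the event trace (the position is
#' constant between discrete events; a frame falling exactly on an event
#' time reports the post-event position — the left-closed convention). Each
#' frame position is then reported as the mean of `n_repeats` independent
#' Gaussian reads, together with the replicate standard deviation.
#'
#' @param trace A `"sim_trace"` from [simulate_filament()].
#' @param model A [measurement_model()].
#' @param seed Integer seed for the measurement noise.
#' @param tube_id Label carried into the output (default `"tube_1"`).
#' @return An `"observed_trace"` tibble with columns `tube_id`, `terminus`
#'   (`"A"`/`"B"`), `time_min`, `position_um`, `replicate_sd_um`, `conc_mM`
#'   (the bath concentration at t = 0). Frame times are strictly increasing
#'   and equally spaced within each terminus.
#' @export
observe_trace <- function(trace, model, seed, tube_id = "tube_1") {
  stopifnot(inherits(trace, "sim_trace"), inherits(model, "measurement_model"))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (nrow(trace) == 0) stop("trace is empty", call. = FALSE)
  t_end <- attr(trace, "t_end_min")
  frames <- seq(0, t_end, by = model$frame_interval_min)
  # zero-order hold, left-closed: state at frame t is the last event row
  # with time <= t
  idx <- findInterval(frames, trace$time_min)
  true_pos <- list(A = trace$pos_A_um[idx], B = trace$pos_B_um[idx])
  nf <- length(frames)
  k <- model$n_repeats
  withr::with_seed(
    as.integer(seed),
    {
      out <- purrr::map_dfr(c("A", "B"), function(term) {
        reads <- matrix(stats::rnorm(nf * k, mean = 0, sd = model$sigma_um),
                        nrow = nf, ncol = k) + true_pos[[term]]
        tibble::tibble(
          tube_id = tube_id,
          terminus = term,
          time_min = frames,
          position_um = rowMeans(reads),
          replicate_sd_um = apply(reads, 1, stats::sd),
          conc_mM = attr(trace, "bath")$c0_mM
        )
      })
      out
    },
    .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion"
  ) -> obs
  structure(obs, class = c("observed_trace", class(obs)),
            measurement = model, seed = as.integer(seed))
}

# deterministic sub-seed stream: repeated Lehmer steps keep every product
# below 2^53 so the arithmetic is exact in doubles; the same (master,
# indices) always maps to the same sub-seed regardless of iteration order
derive_seed <- function(master, ...) {
  m <- 2147483647
  a <- 48271
  s <- abs(as.numeric(master)) %% m
  for (ix in c(...)) {
    s <- (s * a + abs(as.numeric(ix)) + 1) %% m
  }
  as.integer(s %% 2147483646) + 1L
}

#' Design a synthetic concentration-series experiment
#'
#' Describes a growth-rate-versus-concentration experiment of the kind used
#' to fit the linear growth law: at each concentration, several filaments
#' are simulated in an open bath (continuous flow) for a fixed duration and
#' observed through the measurement model. Each condition and tube receives
#' a deterministic sub-seed derived from the master seed, so the whole
#' dataset is reproducible and independent of iteration order.
#'
#' @param concentrations Numeric vector of bath concentrations, mM
#'   (non-empty). Default: an FF-style grid spanning subcritical to
#'   supercritical around c_s = 2.2 mM.
#' @param n_tubes Filaments simulated per concentration (default 10,
#'   matching ten analysed termini per condition).
#' @param duration_min Simulated/observed duration per filament, min.
#' @param filament A [filament_config()] shared by all tubes (default
#'   [ff_filament()]).
#' @param measurement A [measurement_model()].
#' @param seed Master seed.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(concentrations = c(1.60, 2.40, 2.80, 3.20, 3.60),
                              n_tubes = 10,
                              duration_min = 10,
                              filament = ff_filament(),
                              measurement = measurement_model(),
                              seed = 1) {
  stopifnot(is.numeric(concentrations), is.numeric(n_tubes),
            is.numeric(duration_min), is.numeric(seed))
  if (length(concentrations) == 0) {
    stop("concentrations must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  if (n_tubes < 1 || n_tubes != round(n_tubes)) {
    stop("n_tubes must be a positive integer", call. = FALSE)
  }
  if (duration_min <= 0) stop("duration_min must be > 0", call. = FALSE)
  stopifnot(inherits(filament, "filament_config"),
            inherits(measurement, "measurement_model"))
  structure(list(concentrations = as.numeric(concentrations),
                 n_tubes = as.integer(n_tubes),
                 duration_min = as.numeric(duration_min),
                 filament = filament,
                 measurement = measurement,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  p <- filament_params(x$filament)
  cat("<experiment_design>\n")
  cat(sprintf("  %d concentrations (mM): %s\n", length(x$concentrations),
              paste(x$concentrations, collapse = ", ")))
  cat(sprintf("  %d tubes/condition, %g min at %g min/frame\n",
              x$n_tubes, x$duration_min, x$measurement$frame_interval_min))
  cat(sprintf("  truth: k_on = %g, k_off = %g (c_s = %g mM); seed %d\n",
              p$k_on, p$k_off,
              if (p$k_on > 0) p$k_off / p$k_on else NA, x$seed))
  invisible(x)
}

#' Generate an observed dataset from an experiment design
#'
#' For each concentration, simulates `n_tubes` filaments in an open bath
#' and observes each through the measurement model. Deterministic under the
#' design's master seed: the same design yields a byte-identical dataset.
#'
#' @param design An [experiment_design()].
#' @return A `"filament_dataset"` tibble in the long trace format (columns
#'   `tube_id`, `terminus`, `time_min`, `position_um`, `replicate_sd_um`,
#'   `conc_mM`), with the design attached as attribute `design`.
#' @examples
#' d <- experiment_design(concentrations = c(1.6, 3.2), n_tubes = 2,
#'                        duration_min = 2, seed = 7)
#' generate_experiment(d)
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  grid <- tidyr::expand_grid(
    cond = seq_along(design$concentrations),
    tube = seq_len(design$n_tubes)
  )
  out <- purrr::pmap_dfr(grid, function(cond, tube) {
    conc <- design$concentrations[[cond]]
    bath <- bath_config("open", c0_mM = conc, t_max_min = design$duration_min)
    tr <- simulate_filament(design$filament, bath,
                            seed = derive_seed(design$seed, cond, tube, 0))
    observe_trace(tr, design$measurement,
                  seed = derive_seed(design$seed, cond, tube, 1),
                  tube_id = sprintf("c%02d_t%02d", cond, tube))
  })
  out <- tibble::as_tibble(out)
  structure(out, class = c("filament_dataset", class(out)), design = design)
}
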