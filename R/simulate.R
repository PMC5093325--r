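#' Per-terminus kinetics for the stochastic simulator
#'
#' Each axial face of a filament carries its own attachment and detachment
#' kinetics, plus an optional Poisson capping rate modelling the irreversible
#' growth arrest attributed to crystal-packing defects. A capped end has zero
#' attach and detach propensity thereafter.
#'
#' @param k_on Elongation rate constant at this end, um min^-1 mM^-1, >= 0.
#' @param k_off Dissociation rate at this end, um min^-1, >= 0.
#' @param cap_rate Poisson rate of irreversible capping, min^-1, >= 0
#'   (default 0 = capping off).
#' @return An object of class `"end_kinetics"`.
#' @export
end_kinetics <- function(k_on, k_off, cap_rate = 0) {
  vals <- c(k_on = as.numeric(k_on), k_off = as.numeric(k_off),
            cap_rate = as.numeric(cap_rate))
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("k_on, k_off and cap_rate must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(vals), class = "end_kinetics")
}

#' Two-ended filament configuration
#'
#' A filament is one-dimensional: two termini on an axis, terminus A at the
#' lower coordinate and terminus B at the higher. The two crystallographic
#' faces are named O (fast exchange, carboxylate-exposed; mapped to terminus
#' B) and N (slow exchange, amino-exposed; mapped to terminus A). Length is
#' quantised in layers of `layer_um`; each attach/detach event moves one
#' terminus outward/inward by one layer. `layer_um` is a pure discretisation
#' knob — ensemble rates are insensitive to it (halving it doubles event
#' rates but leaves um/min rates unchanged).
#'
#' @param end_O [end_kinetics()] of the O (fast) face.
#' @param end_N [end_kinetics()] of the N (slow) face.
#' @param layer_um Length added or removed per event, um, > 0 (default 0.01,
#'   small against the um-scale measurements).
#' @param initial_length_um Initial filament length, um, >= 0; snapped to the
#'   nearest whole number of layers.
#' @return An object of class `"filament_config"`.
#' @seealso [ff_filament()], [cycloff_filament()] for stylised presets.
#' @export
filament_config <- function(end_O, end_N, layer_um = 0.01,
                            initial_length_um = 20) {
  stopifnot(inherits(end_O, "end_kinetics"), inherits(end_N, "end_kinetics"))
  if (!is.finite(layer_um) || layer_um <= 0) {
    stop("layer_um must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(initial_length_um) || initial_length_um < 0) {
    stop("initial_length_um must be finite and >= 0", call. = FALSE)
  }
  structure(list(end_O = end_O, end_N = end_N,
                 layer_um = as.numeric(layer_um),
                 initial_length_um = as.numeric(initial_length_um)),
            class = "filament_config")
}

#' Stylised filament presets
#'
#' `ff_filament()` models the strongly asymmetric diphenylalanine (FF)
#' nanotube: the fitted growth-law parameters (k_on = 3.36 um/min/mM,
#' k_off = 7.4 um/min) are assigned entirely to the fast O face and the N
#' face is silent — the strong-asymmetry limit consistent with the observed
#' unidirectional growth and shortening. `cycloff_filament()` models the
#' symmetric cyclo-(Phe-Phe) needle: the fitted (0.15, 1.2) is split equally
#' between the two faces, consistent with per-terminus rates that are
#' indistinguishable within error. Both are stylised: length measurements
#' constrain only the summed two-end law, so the per-face split is a
#' modelling choice, and every rate is overridable.
#'
#' @param initial_length_um Initial length in um.
#' @param layer_um Discretisation layer in um.
#' @param cap_rate Per-end capping rate, min^-1 (default 0).
#' @return A [filament_config()].
#' @export
ff_filament <- function(initial_length_um = 30, layer_um = 0.01,
                        cap_rate = 0) {
  filament_config(
    end_O = end_kinetics(k_on = 3.36, k_off = 7.4, cap_rate = cap_rate),
    end_N = end_kinetics(k_on = 0, k_off = 0, cap_rate = cap_rate),
    layer_um = layer_um,
    initial_length_um = initial_length_um
  )
}

#' @rdname ff_filament
#' @export
cycloff_filament <- function(initial_length_um = 80, layer_um = 0.01,
                             cap_rate = 0) {
  filament_config(
    end_O = end_kinetics(k_on = 0.075, k_off = 0.6, cap_rate = cap_rate),
    end_N = end_kinetics(k_on = 0.075, k_off = 0.6, cap_rate = cap_rate),
    layer_um = layer_um,
    initial_length_um = initial_length_um
  )
}

#' Summed growth-law parameters of a filament configuration
#'
#' The net length rate of the whole filament is governed by the sums of the
#' two faces' rate constants: `dL/dt = (k_on_O + k_on_N) c - (k_off_O +
#' k_off_N)`. These summed parameters are what a length-versus-time
#' experiment estimates.
#'
#' @param filament A [filament_config()].
#' @return A [kinetic_params()] with the summed rates.
#' @export
filament_params <- function(filament) {
  stopifnot(inherits(filament, "filament_config"))
  kinetic_params(
    k_on = filament$end_O$k_on + filament$end_N$k_on,
    k_off = filament$end_O$k_off + filament$end_N$k_off
  )
}

#' Monomer bath configuration
#'
#' Open mode holds the free-monomer concentration constant for all time,
#' emulating continuous microfluidic flow (the system never equilibrates;
#' sustained subcritical flow dissolves the filament completely). Closed
#' mode is a finite reservoir: each attach/detach event moves the free
#' concentration down/up by the depletion quantum `gamma_mM`, so
#' `c(t) + gamma_mM * (net layers added) = c0` exactly, and filament and
#' solution relax to equilibrium at the critical concentration. `gamma_mM`
#' is the single coarse-graining parameter of the closed system and sets the
#' fluctuation scale around equilibrium.
#'
#' @param mode `"open"` or `"closed"`.
#' @param c0_mM Constant concentration (open) or initial free concentration
#'   (closed), mM, >= 0.
#' @param t_max_min Simulated time horizon, min, > 0.
#' @param gamma_mM Closed-mode depletion quantum, mM per event, > 0
#'   (default 1e-4).
#' @return An object of class `"bath_config"`.
#' @export
bath_config <- function(mode = c("open", "closed"), c0_mM, t_max_min,
                        gamma_mM = 1e-4) {
  mode <- match.arg(mode)
  if (!is.finite(c0_mM) || c0_mM < 0) stop("c0_mM must be >= 0", call. = FALSE)
  if (!is.finite(t_max_min) || t_max_min <= 0) {
    stop("t_max_min must be > 0", call. = FALSE)
  }
  if (mode == "closed" && (!is.finite(gamma_mM) || gamma_mM <= 0)) {
    stop("gamma_mM must be > 0 in closed mode", call. = FALSE)
  }
  structure(list(mode = mode, c0_mM = c0_mM, t_max_min = t_max_min,
                 gamma_mM = gamma_mM),
            class = "bath_config")
}

#' Simulate a two-ended filament by exact Gillespie kinetic Monte Carlo
#'
#' Elementary events per uncapped end `e`: attachment with propensity
#' `k_on(e) * c / layer_um` per minute, detachment with propensity
#' `k_off(e) / layer_um`, and capping with propensity `cap_rate(e)`.
#' Waiting times are exponential in the total propensity and the event is
#' chosen proportionally to its propensity (the stochastic simulation
#' algorithm, exact for this continuous-time Markov jump process). Positions
#' move outward by one layer on attach and inward on detach; detachment is
#' impossible at zero length, and a detach event that reaches zero length
#' terminates the trace as full dissolution. The trace also terminates at
#' `t_max_min` or when both ends are capped.
#'
#' The same `(filament, bath, seed)` always yields the identical trace: the
#' simulation draws from R's Mersenne-Twister stream seeded locally with
#' `seed`, without touching the global RNG state.
#'
#' @param filament A [filament_config()].
#' @param bath A [bath_config()].
#' @param seed Integer seed governing the whole trace.
#' @return A `"sim_trace"` tibble with one initial row (`event = "init"`) at
#'   time 0 followed by one row per event: `time_min`, `end` (`"O"`/`"N"`),
#'   `event` (`attach`/`detach`/`cap`), `pos_A_um`, `pos_B_um`, `conc_mM`.
#'   Attributes: `filament`, `bath`, `seed`, `status` (one of
#'   `t_max_reached`, `fully_dissolved`, `both_capped`), `t_end_min`.
#' @examples
#' tr <- simulate_filament(ff_filament(), bath_config("open", 3.2, 2), seed = 1)
#' trace_length(tr) |> head()
#' @export
simulate_filament <- function(filament, bath, seed) {
  stopifnot(inherits(filament, "filament_config"),
            inherits(bath, "bath_config"))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  raw <- withr::with_seed(
    as.integer(seed),
    gillespie_core(
      kOnO = filament$end_O$k_on, kOffO = filament$end_O$k_off,
      capO = filament$end_O$cap_rate,
      kOnN = filament$end_N$k_on, kOffN = filament$end_N$k_off,
      capN = filament$end_N$cap_rate,
      layer = filament$layer_um, L0 = filament$initial_length_um,
      open_mode = bath$mode == "open",
      c0 = bath$c0_mM, gamma = bath$gamma_mM, tmax = bath$t_max_min
    ),
    .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion"
  )
  status <- c("t_max_reached", "fully_dissolved", "both_capped")[raw$status]
  tr <- tibble::tibble(
    time_min = c(0, raw$time_min),
    end = c(NA_character_, c("O", "N")[raw$end]),
    event = c("init", c("attach", "detach", "cap")[raw$type]),
    pos_A_um = c(raw$init_pos_A, raw$pos_A_um),
    pos_B_um = c(raw$init_pos_B, raw$pos_B_um),
    conc_mM = c(bath$c0_mM, raw$conc_mM)
  )
  structure(tr,
            class = c("sim_trace", class(tr)),
            filament = filament, bath = bath, seed = as.integer(seed),
            status = status, t_end_min = raw$t_end)
}

#' Filament length along a simulated trace
#'
#' @param trace A `"sim_trace"` from [simulate_filament()].
#' @return A tibble with `time_min` and `length_um` (= `pos_B_um -
#'   pos_A_um`) per recorded state.
#' @export
trace_length <- function(trace) {
  stopifnot(inherits(trace, "sim_trace"))
  tibble::tibble(time_min = trace$time_min,
                 length_um = trace$pos_B_um - trace$pos_A_um)
}

#' Realised net growth rate of a simulated trace
#'
#' The end-to-end length change divided by the elapsed simulated time
#' (through `t_end`, so a trace that dissolved or capped early is averaged
#' over its actual lifetime).
#'
#' @param trace A `"sim_trace"`.
#' @return Net growth rate in um/min (scalar).
#' @export
trace_growth_rate <- function(trace) {
  stopifnot(inherits(trace, "sim_trace"))
  n <- nrow(trace)
  t_end <- attr(trace, "t_end_min")
  L0 <- trace$pos_B_um[[1]] - trace$pos_A_um[[1]]
  L1 <- trace$pos_B_um[[n]] - trace$pos_A_um[[n]]
  (L1 - L0) / t_end
}

#' Equilibrium free-monomer concentration of a closed-pool trace
#'
#' Time-weighted mean of the free-concentration trajectory over the final
#' `tail_fraction` of simulated time. In a closed pool with a persistent
#' filament the free concentration relaxes to the critical concentration
#' `k_off/k_on` — the fixed point where attach and detach propensities
#' balance — independent of the (supercritical) starting concentration.
#'
#' @param trace A closed-mode `"sim_trace"`.
#' @param tail_fraction Fraction of simulated time to average over, in
#'   (0, 1].
#' @return Mean free concentration in mM.
#' @export
equilibrium_concentration <- function(trace, tail_fraction = 0.5) {
  stopifnot(inherits(trace, "sim_trace"))
  if (attr(trace, "bath")$mode != "closed") {
    stop("equilibrium_concentration requires a closed-mode trace",
         call. = FALSE)
  }
  stopifnot(is.numeric(tail_fraction), length(tail_fraction) == 1,
            tail_fraction > 0, tail_fraction <= 1)
  t_end <- attr(trace, "t_end_min")
  t0 <- t_end * (1 - tail_fraction)
  tt <- trace$time_min
  cc <- trace$conc_mM
  # piecewise-constant concentration: value on [t_i, t_{i+1}) is c_i
  knots <- c(tt, t_end)
  i0 <- findInterval(t0, knots, left.open = FALSE)
  seg_start <- pmax(knots[i0:(length(knots) - 1)], t0)
  seg_end <- knots[(i0 + 1):length(knots)]
  w <- seg_end - seg_start
  sum(cc[i0:length(cc)] * w) / sum(w)
}

#' Per-end monomer turnover over a time window
#'
#' Counts attach and detach events per end over `[t_start, t_end]` and
#' reports binding and unbinding event rates (events/min), plus the net
#' length rate `(attach - detach) * layer_um / window`. Turnover (total
#' binding-plus-unbinding traffic) distinguishes a fast face from a slow
#' one even at equilibrium, where the *net* rate of both faces is zero.
#'
#' @param trace A `"sim_trace"`.
#' @param t_start,t_end Window bounds in minutes, within the trace span,
#'   `t_start < t_end`.
#' @return A tibble with one row per end (`"O"`, `"N"`): `n_attach`,
#'   `n_detach`, `binding_rate_per_min`, `unbinding_rate_per_min`,
#'   `net_rate_um_min`, `t_start`, `t_end`.
#' @export
turnover_summary <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "sim_trace"),
            is.numeric(t_start), is.numeric(t_end),
            length(t_start) == 1, length(t_end) == 1)
  span_end <- attr(trace, "t_end_min")
  if (!(t_start >= 0 && t_end <= span_end && t_start < t_end)) {
    stop("window [", t_start, ", ", t_end, "] must be non-empty and within ",
         "the trace span [0, ", span_end, "]", call. = FALSE)
  }
  layer <- attr(trace, "filament")$layer_um
  window <- t_end - t_start
  in_win <- trace$time_min >= t_start & trace$time_min <= t_end &
    trace$event %in% c("attach", "detach")
  ev <- trace[in_win, c("end", "event")]
  purrr::map_dfr(c("O", "N"), function(e) {
    na <- sum(ev$end == e & ev$event == "attach")
    nd <- sum(ev$end == e & ev$event == "detach")
    tibble::tibble(
      end = e, n_attach = na, n_detach = nd,
      binding_rate_per_min = na / window,
      unbinding_rate_per_min = nd / window,
      net_rate_um_min = (na - nd) * layer / window,
      t_start = t_start, t_end = t_end
    )
  })
}
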