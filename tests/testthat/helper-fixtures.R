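# shared builders for small test objects

ff_params <- function() kinetic_params(k_on = 3.36, k_off = 7.4)
cycloff_params <- function() kinetic_params(k_on = 0.15, k_off = 1.2)

# symmetric filament with overall (k_on, k_off) split across both faces
symmetric_filament <- function(k_on, k_off, initial_length_um = 30,
                               layer_um = 0.01) {
  filament_config(
    end_O = end_kinetics(k_on / 2, k_off / 2),
    end_N = end_kinetics(k_on / 2, k_off / 2),
    layer_um = layer_um,
    initial_length_um = initial_length_um
  )
}

# noiseless linear position series
linear_trace <- function(slope, intercept = 0, times = seq(0, 10, by = 0.5)) {
  tibble::tibble(time_min = times, position_um = intercept + slope * times)
}

# small valid observed-trace table for IO tests
small_trace_table <- function() {
  tr <- simulate_filament(ff_filament(initial_length_um = 10),
                          bath_config("open", 3.2, t_max_min = 1), seed = 42)
  observe_trace(tr, measurement_model(frame_interval_min = 0.25), seed = 43,
                tube_id = "t1")
}

# cycloFF-style experiment: slower symmetric dynamics, longer frames,
# concentrations bracketing c_s = 8 mM on both sides
cycloff_design <- function(seed = 1, n_tubes = 10) {
  experiment_design(
    concentrations = c(1.70, 5.0, 9.5, 11.5, 13.59),
    n_tubes = n_tubes,
    duration_min = 60,
    filament = cycloff_filament(initial_length_um = 80),
    measurement = measurement_model(frame_interval_min = 4),
    seed = seed
  )
}
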