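test_that("traces are deterministic, well-formed and length-positive", {
  fil <- ff_filament(initial_length_um = 20)
  bath <- bath_config("open", 3.2, t_max_min = 2)
  tr1 <- simulate_filament(fil, bath, seed = 123)
  tr2 <- simulate_filament(fil, bath, seed = 123)
  expect_identical(tibble::as_tibble(tr1), tibble::as_tibble(tr2))
  tr3 <- simulate_filament(fil, bath, seed = 124)
  expect_false(identical(tibble::as_tibble(tr1), tibble::as_tibble(tr3)))

  expect_true(all(diff(tr1$time_min) > 0))
  expect_true(all(tr1$pos_B_um - tr1$pos_A_um >= 0))
  expect_equal(tr1$event[1], "init")
  expect_equal(attr(tr1, "status"), "t_max_reached")

  # event steps are exactly one layer, outward on attach, inward on detach
  dA <- diff(tr1$pos_A_um)
  dB <- diff(tr1$pos_B_um)
  step <- abs(dA) + abs(dB)
  expect_true(all(abs(step - fil$layer_um) < 1e-12))
})

test_that("pure-growth ensemble rate matches the Poisson-process oracle", {
  # k_off = 0 at both ends: total growth is a Poisson process with rate
  # (k_on_O + k_on_N) * c / layer events/min, each adding one layer
  fil <- filament_config(end_kinetics(k_on = 1.2, k_off = 0),
                         end_kinetics(k_on = 0.6, k_off = 0),
                         layer_um = 0.01, initial_length_um = 5)
  conc <- 2.5
  bath <- bath_config("open", conc, t_max_min = 2)
  rates <- vapply(1:100, function(s)
    trace_growth_rate(simulate_filament(fil, bath, seed = s)), numeric(1))
  expected <- (1.2 + 0.6) * conc
  sem <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - expected), 3 * sem)
})

test_that("waiting times of a single-event process are exponential", {
  # detachment only: a single event type with constant propensity k_off/layer
  fil <- filament_config(end_kinetics(k_on = 0, k_off = 3),
                         end_kinetics(k_on = 0, k_off = 0),
                         layer_um = 0.01, initial_length_um = 50)
  tr <- simulate_filament(fil, bath_config("open", 1, t_max_min = 8), seed = 31)
  waits <- diff(tr$time_min)
  expect_gt(length(waits), 500)
  ks <- suppressWarnings(stats::ks.test(waits, "pexp", rate = 3 / 0.01))
  expect_gt(ks$p.value, 0.01)
})

test_that("balanced ends at the critical concentration neither grow nor shrink", {
  p <- ff_params()
  fil <- symmetric_filament(p$k_on, p$k_off, initial_length_um = 40)
  cs <- critical_concentration(p)
  bath <- bath_config("open", cs, t_max_min = 2)
  rates <- vapply(1:100, function(s)
    trace_growth_rate(simulate_filament(fil, bath, seed = 200 + s)), numeric(1))
  sem <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates)), 3 * sem)
})

test_that("sustained subcritical flow dissolves the filament completely", {
  fil <- ff_filament(initial_length_um = 5)
  bath <- bath_config("open", 1.60, t_max_min = 60)
  tr <- simulate_filament(fil, bath, seed = 55)
  expect_equal(attr(tr, "status"), "fully_dissolved")
  n <- nrow(tr)
  expect_equal(tr$pos_B_um[n] - tr$pos_A_um[n], 0, tolerance = 1e-12)
  expect_lt(attr(tr, "t_end_min"), 60)
  # no events after dissolution: the trace simply ends
  expect_equal(tr$time_min[n], attr(tr, "t_end_min"))
})

test_that("capping silences ends and both-capped traces terminate", {
  fil <- filament_config(end_kinetics(2, 1, cap_rate = 5),
                         end_kinetics(2, 1, cap_rate = 5),
                         initial_length_um = 10)
  bath <- bath_config("open", 2, t_max_min = 50)
  tr <- simulate_filament(fil, bath, seed = 61)
  expect_equal(attr(tr, "status"), "both_capped")
  caps <- which(tr$event == "cap")
  expect_equal(length(caps), 2)
  # no attach/detach events at an end after its cap
  for (i in caps) {
    e <- tr$end[i]
    later <- tr[-seq_len(i), ]
    expect_equal(sum(later$end == e & later$event != "cap", na.rm = TRUE), 0)
  }
  # an end with zero rates produces zero events
  quiet <- filament_config(end_kinetics(3, 2), end_kinetics(0, 0),
                           initial_length_um = 10)
  tq <- simulate_filament(quiet, bath_config("open", 2, 2), seed = 62)
  expect_equal(sum(tq$end == "N", na.rm = TRUE), 0)
  tv <- turnover_summary(tq, 0, attr(tq, "t_end_min"))
  expect_equal(tv$n_attach[tv$end == "N"], 0L)
  expect_equal(tv$n_detach[tv$end == "N"], 0L)
})

test_that("closed mode conserves mass exactly at every event", {
  fil <- symmetric_filament(3.36, 7.4, initial_length_um = 20)
  bath <- bath_config("closed", 3.0, t_max_min = 10, gamma_mM = 1e-4)
  tr <- simulate_filament(fil, bath, seed = 71)
  L0 <- tr$pos_B_um[1] - tr$pos_A_um[1]
  net_layers <- ((tr$pos_B_um - tr$pos_A_um) - L0) / fil$layer_um
  expect_true(all(abs(tr$conc_mM + bath$gamma_mM * net_layers - bath$c0_mM)
                  < 1e-9))
})

test_that("a subcritical closed pool with a small seed dissolves and returns all mass", {
  fil <- symmetric_filament(3.36, 7.4, initial_length_um = 2)
  bath <- bath_config("closed", 1.0, t_max_min = 200, gamma_mM = 1e-4)
  tr <- simulate_filament(fil, bath, seed = 81)
  expect_equal(attr(tr, "status"), "fully_dissolved")
  n <- nrow(tr)
  L0 <- tr$pos_B_um[1] - tr$pos_A_um[1]
  expect_equal(tr$conc_mM[n], 1.0 + 1e-4 * (L0 / fil$layer_um),
               tolerance = 1e-9)
})

test_that("closed-pool equilibrium sits at k_off/k_on, independent of start and split", {
  cs <- critical_concentration(ff_params())
  gamma <- 5e-4
  run <- function(fil, c0, seed) {
    tr <- simulate_filament(fil, bath_config("closed", c0, t_max_min = 60,
                                             gamma_mM = gamma), seed = seed)
    equilibrium_concentration(tr, tail_fraction = 0.3)
  }
  sym <- symmetric_filament(3.36, 7.4, initial_length_um = 40)
  eq1 <- run(sym, 3.2, 91)
  expect_lt(abs(eq1 - cs), 0.1)
  # same k_off/k_on per face at 10x different magnitudes: same fixed point
  asym <- filament_config(end_kinetics(3.0, 3.0 * cs), end_kinetics(0.3, 0.3 * cs),
                          initial_length_um = 40)
  eq2 <- run(asym, 3.2, 92)
  expect_lt(abs(eq2 - cs), 0.1)
  expect_error(
    equilibrium_concentration(
      simulate_filament(sym, bath_config("open", 3.2, 1), seed = 1)),
    "closed-mode"
  )
})

test_that("open-mode ensemble mean growth follows the deterministic law", {
  # law-of-large-numbers agreement: mean over seeds of the realised net rate
  # equals (sum k_on) c - (sum k_off) within 3 SEM
  fil <- symmetric_filament(3.36, 7.4, initial_length_um = 40)
  p <- filament_params(fil)
  for (conc in c(1.8, 3.0)) {
    rates <- vapply(1:100, function(s)
      trace_growth_rate(simulate_filament(fil, bath_config("open", conc, 2),
                                          seed = 300 + s)), numeric(1))
    sem <- sd(rates) / sqrt(length(rates))
    expect_lt(abs(mean(rates) - net_growth_rate(conc, p)), 3 * sem)
  }
})

test_that("ensemble rates are insensitive to the layer discretisation", {
  conc <- 3.0
  p <- ff_params()
  mean_rate <- function(layer) {
    fil <- symmetric_filament(p$k_on, p$k_off, initial_length_um = 40,
                              layer_um = layer)
    rates <- vapply(1:80, function(s)
      trace_growth_rate(simulate_filament(fil, bath_config("open", conc, 2),
                                          seed = 400 + s)), numeric(1))
    c(mean(rates), sd(rates) / sqrt(length(rates)))
  }
  a <- mean_rate(0.01)
  b <- mean_rate(0.005)
  expect_lt(abs(a[1] - b[1]), 3 * sqrt(a[2]^2 + b[2]^2))
})

test_that("turnover summary counts events and scales with face kinetics", {
  cs <- 2.2
  asym <- filament_config(end_kinetics(3.0, 3.0 * cs), end_kinetics(0.3, 0.3 * cs),
                          initial_length_um = 40)
  tr <- simulate_filament(asym, bath_config("closed", 3.0, t_max_min = 60,
                                            gamma_mM = 5e-4), seed = 95)
  t_end <- attr(tr, "t_end_min")
  tv <- turnover_summary(tr, t_end / 2, t_end)
  o <- tv[tv$end == "O", ]
  n <- tv[tv$end == "N", ]
  # event counts are consistent with the recorded trace
  win <- tr$time_min >= t_end / 2 & tr$event == "attach" & tr$end == "O"
  expect_equal(o$n_attach, sum(win, na.rm = TRUE))
  # the 10x-faster face shows ~10x binding turnover
  ratio <- o$binding_rate_per_min / n$binding_rate_per_min
  expect_gt(ratio, 8)
  expect_lt(ratio, 12)
  expect_error(turnover_summary(tr, 10, 5), "window")
})
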