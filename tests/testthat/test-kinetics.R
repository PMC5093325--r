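test_that("growth law and critical concentration follow the linear model", {
  ff <- ff_params()
  expect_equal(net_growth_rate(3.20, ff), 3.36 * 3.20 - 7.4)
  expect_equal(net_growth_rate(1.60, ff), 3.36 * 1.60 - 7.4) # negative: shortening
  expect_lt(net_growth_rate(1.60, ff), 0)

  expect_equal(round_half_up(critical_concentration(ff), 1), 2.2)
  expect_equal(critical_concentration(cycloff_params()), 8.0) # ratio of printed rates
  expect_equal(critical_concentration(kinetic_params(5, 0)), 0)

  # R(c_s) = 0 exactly for random parameter draws
  set.seed(3)
  for (i in 1:20) {
    p <- kinetic_params(runif(1, 0.01, 10), runif(1, 0, 20))
    expect_equal(net_growth_rate(critical_concentration(p), p), 0,
                 tolerance = 1e-12)
  }

  expect_error(net_growth_rate(-0.1, ff), ">= 0")
  expect_error(critical_concentration(kinetic_params(0, 1)), "undefined")
  expect_error(kinetic_params(-1, 2), ">= 0")
})

test_that("fit_growth_law recovers generating parameters from noiseless data", {
  set.seed(11)
  for (i in 1:10) {
    p <- kinetic_params(runif(1, 0.05, 5), runif(1, 0, 10))
    conc <- sort(runif(sample(2:6, 1), 0, 12))
    if (length(unique(conc)) < 2) next
    pts <- tibble::tibble(conc_mM = conc, rate_um_min = net_growth_rate(conc, p))
    fit <- fit_growth_law(pts)
    expect_equal(fit$k_on, p$k_on, tolerance = 1e-9)
    expect_equal(fit$k_off, p$k_off, tolerance = 1e-9)
    if (p$k_on > 0) {
      expect_equal(critical_concentration(fit), critical_concentration(p),
                   tolerance = 1e-9)
    }
  }
  # two points define the unique line through them
  fit2 <- fit_growth_law(tibble::tibble(conc_mM = c(1, 3), rate_um_min = c(-1, 5)))
  expect_equal(fit2$k_on, 3)
  expect_equal(fit2$k_off, 4)

  expect_error(fit_growth_law(tibble::tibble(conc_mM = c(2, 2),
                                             rate_um_min = c(1, 2))),
               "distinct")
  expect_error(fit_growth_law(tibble::tibble(conc_mM = c(1, 2),
                                             rate_um_min = c(1, 2),
                                             weight = c(-1, 1))),
               "weights")
})

test_that("fit_growth_law agrees with lm and exposes broom-style accessors", {
  set.seed(21)
  pts <- tibble::tibble(
    conc_mM = c(1.6, 2.0, 2.4, 2.8, 3.2, 3.6),
    rate_um_min = net_growth_rate(c(1.6, 2.0, 2.4, 2.8, 3.2, 3.6), ff_params()) +
      rnorm(6, 0, 0.3),
    weight = runif(6, 0.5, 2)
  )
  fit <- fit_growth_law(pts)
  ref <- lm(rate_um_min ~ conc_mM, data = pts, weights = pts$weight)
  expect_equal(fit$k_on, unname(coef(ref)[2]))
  expect_equal(fit$k_off, -unname(coef(ref)[1]))
  expect_equal(fit$se_k_on, unname(sqrt(diag(vcov(ref)))[2]))
  expect_equal(fit$se_k_off, unname(sqrt(diag(vcov(ref)))[1]))
  expect_equal(fit$r_squared, summary(ref)$r.squared)

  td <- tidy(fit)
  expect_equal(td$term, c("k_on", "k_off"))
  expect_equal(td$estimate, c(fit$k_on, fit$k_off))
  gl <- glance(fit)
  expect_equal(gl$critical_conc_mM, fit$k_off / fit$k_on)
  expect_equal(gl$n_points, 6)
})

test_that("terminus rate estimation is exact on linear data and equivariant", {
  tr <- linear_trace(slope = 0.5, intercept = 10)
  est <- estimate_terminus_rate(tr, orientation = +1)
  expect_equal(est$rate_um_min, 0.5, tolerance = 1e-12)
  expect_equal(est$se, 0, tolerance = 1e-9)
  expect_equal(est$n_frames, nrow(tr))

  # constant positions: zero rate
  flat <- estimate_terminus_rate(linear_trace(0, 5), orientation = -1)
  expect_equal(flat$rate_um_min, 0, tolerance = 1e-12)

  # orientation equivariance on noisy data
  set.seed(5)
  noisy <- linear_trace(-0.8, 3)
  noisy$position_um <- noisy$position_um + rnorm(nrow(noisy), 0, 0.2)
  up <- estimate_terminus_rate(noisy, +1)
  dn <- estimate_terminus_rate(noisy, -1)
  expect_equal(up$rate_um_min, -dn$rate_um_min, tolerance = 1e-12)
  expect_equal(up$se, dn$se, tolerance = 1e-12)

  # closed-form OLS matches lm's slope and standard error
  ref <- summary(lm(position_um ~ time_min, data = noisy))$coefficients
  expect_equal(up$rate_um_min, ref["time_min", "Estimate"], tolerance = 1e-10)
  expect_equal(up$se, ref["time_min", "Std. Error"], tolerance = 1e-10)

  expect_error(estimate_terminus_rate(
    tibble::tibble(time_min = c(0, 1, 1), position_um = c(1, 2, 3)), +1
  ), "strictly increasing")
  expect_error(estimate_terminus_rate(
    tibble::tibble(time_min = 1, position_um = 1), +1
  ), ">= 2 frames")
})

test_that("terminus rate from a simulated noisy trace is within 3 se of truth", {
  fil <- ff_filament(initial_length_um = 30)
  bath <- bath_config("open", 3.2, t_max_min = 10)
  truth <- net_growth_rate(3.2, ff_params()) # all activity on the O face (terminus B)
  tr <- simulate_filament(fil, bath, seed = 77)
  obs <- observe_trace(tr, measurement_model(frame_interval_min = 0.5), seed = 78)
  b <- dplyr::filter(obs, terminus == "B")
  est <- estimate_terminus_rate(b[, c("time_min", "position_um")], +1)
  expect_lt(abs(est$rate_um_min - truth), 3 * est$se + 0.2)
})

test_that("directionality classification matches the per-end activity test", {
  uni <- classify_directionality(list(rate_um_min = 5.0, se = 0.1),
                                 list(rate_um_min = 0.02, se = 0.1))
  expect_equal(as.character(uni$label), "unidirectional")
  expect_equal(uni$active_ends, 1L)

  bi <- classify_directionality(list(rate_um_min = 2.5, se = 0.3),
                                list(rate_um_min = 2.4, se = 0.3))
  expect_equal(as.character(bi$label), "bidirectional")
  expect_lt(abs(bi$z_statistic), 1.96)

  st <- classify_directionality(list(rate_um_min = 0, se = 0.5),
                                list(rate_um_min = 0, se = 0.5))
  expect_equal(as.character(st$label), "stalled")
  expect_equal(st$active_ends, 0L)

  # se = 0 is exact: any nonzero rate is active
  ex <- classify_directionality(list(rate_um_min = 1e-6, se = 0),
                                list(rate_um_min = 0, se = 0))
  expect_equal(as.character(ex$label), "unidirectional")

  # symmetric in its ends up to labelling
  set.seed(9)
  for (i in 1:20) {
    a <- list(rate_um_min = rnorm(1, 0, 2), se = runif(1, 0, 0.5))
    b <- list(rate_um_min = rnorm(1, 0, 2), se = runif(1, 0, 0.5))
    ab <- classify_directionality(a, b)
    ba <- classify_directionality(b, a)
    expect_equal(as.character(ab$label), as.character(ba$label))
    expect_equal(ab$z_statistic, -ba$z_statistic, tolerance = 1e-12)
  }

  expect_warning(
    ind <- classify_directionality(list(rate_um_min = NaN, se = 0.1),
                                   list(rate_um_min = 1, se = 0.1)),
    "indeterminate"
  )
  expect_equal(as.character(ind$label), "indeterminate")
})

test_that("an asymmetric filament converges to unidirectional as noise vanishes", {
  # one silent end, one growing end; shrink measurement noise and watch the
  # unidirectional call rate approach 1
  fil <- ff_filament(initial_length_um = 20)
  bath <- bath_config("open", 3.2, t_max_min = 5)
  call_rate <- function(sigma, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- simulate_filament(fil, bath, seed = s)
      obs <- observe_trace(tr, measurement_model(sigma_um = sigma,
                                                 frame_interval_min = 0.5),
                           seed = s + 5000)
      a <- estimate_terminus_rate(
        dplyr::filter(obs, terminus == "A")[, c("time_min", "position_um")], -1)
      b <- estimate_terminus_rate(
        dplyr::filter(obs, terminus == "B")[, c("time_min", "position_um")], +1)
      as.character(classify_directionality(a, b)$label) == "unidirectional"
    }, logical(1)))
  }
  # in the noiseless limit the call is deterministic: the silent terminus has
  # exactly zero slope and zero se, the growing terminus is clearly active
  expect_equal(call_rate(0, 1:15), 1)
  expect_gte(call_rate(0.25, 1:25), 0.8)
})
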