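capsaicin_series <- c(0.03, 0.1, 0.3, 1, 5, 10)

test_that("dose-response normalization pins the 5 uM reference to 1", {
  pts <- tibble::tibble(conc_uM = c(0.3, 5), current_pA = c(200, 400))
  out <- normalize_dose_response(pts)
  expect_equal(out$norm_current, c(0.5, 1.0))
  expect_error(normalize_dose_response(pts, reference_conc = 7),
               class = "ardscan_missing_reference")
  expect_error(
    normalize_dose_response(tibble::tibble(conc_uM = 5, current_pA = 0)),
    class = "ardscan_zero_reference"
  )
})

test_that("Hill fitting inverts its own forward model exactly when noiseless", {
  truths <- list(c(1, 0.3, 2), c(0.8, 1.2, 1.5), c(1.1, 0.05, 3.2))
  for (th in truths) {
    pts <- tibble::tibble(
      conc_uM = capsaicin_series,
      norm_current = hill_curve(capsaicin_series, th[1], th[2], th[3])
    )
    fit <- hill_fit(pts)
    expect_true(fit$converged)
    expect_lt(max(abs(coef(fit) - th) / th), 1e-6)
    # definitional: response at EC50 is half of Imax
    expect_equal(predict(fit, tibble::tibble(conc_uM = fit$EC50)),
                 fit$Imax / 2)
  }
  expect_error(hill_fit(tibble::tibble(conc_uM = c(1, 5), norm_current = c(0.5, 1))),
               class = "ardscan_too_few_concentrations")
})

test_that("Hill tidiers expose estimates and diagnostics", {
  pts <- tibble::tibble(
    conc_uM = capsaicin_series,
    norm_current = hill_curve(capsaicin_series, 1, 0.3, 2)
  )
  fit <- hill_fit(pts)
  td <- tidy(fit)
  expect_equal(td$term, c("Imax", "EC50", "n"))
  gl <- glance(fit)
  expect_equal(gl$n_points, 6L)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("tagged sweep segments concatenate in order with labels carried", {
  fs <- 1000
  trace <- tibble::tibble(time_s = (0:1999) / fs,
                          current_pA = rep(c(1, 2), each = 1000))
  segs <- tibble::tibble(
    sweep_id = c("s1", "s1", "s2", "s2"),
    segment = c("-80mV", "+80mV", "-80mV", "+80mV"),
    start_s = c(0, 0.4, 1.0, 1.4),
    end_s = c(0.4, 0.8, 1.4, 1.8),
    voltage_mV = c(-80, 80, -80, 80),
    ligand_uM = 0.1, pH = 7.2
  )
  out <- concatenate_segments(trace, segs)
  expect_equal(nrow(out), 800L)
  expect_equal(unique(out$voltage_mV), 80)
  expect_equal(unique(out$pH), 7.2)
  # sweep order is preserved, not sorted away
  expect_equal(out$current_pA, rep(c(1, 2), each = 400))
  expect_equal(out$time_s, (0:799) / fs)

  expect_error(concatenate_segments(trace, segs[segs$segment == "-80mV", ]),
               class = "ardscan_missing_segment")
  expect_error(concatenate_segments(trace, segs[0, ]), class = "ardscan_empty_input")
})

test_that("baseline subtraction recovers traces under offset and drift", {
  clean <- simulate_two_state_channel(30, 70, 1, 20000, 30, noise_sd = 0.05,
                                      drift = 0, seed = 7)
  offset <- dplyr::mutate(clean$trace, current_pA = current_pA + 3.3)
  rec <- subtract_baseline(offset, window_s = 1)
  rel_rms <- sqrt(mean((rec$current_pA - clean$trace$current_pA)^2)) /
    sqrt(mean(clean$trace$current_pA^2))
  expect_lt(rel_rms, 0.01)

  zero <- tibble::tibble(time_s = (0:9999) / 1000, current_pA = 0)
  expect_equal(subtract_baseline(zero, 1)$current_pA, rep(0, 10000))

  drifting <- simulate_two_state_channel(30, 70, 1, 20000, 30, noise_sd = 0.1,
                                         drift = 0.05, seed = 8)
  bs <- subtract_baseline(drifting$trace, window_s = 1)
  closed_bias <- mean(bs$current_pA[drifting$occupancy == 0])
  expect_lt(abs(closed_bias), 0.05 * 1)

  expect_error(subtract_baseline(zero, window_s = 60),
               class = "ardscan_window_too_long")
})

test_that("half-amplitude idealization is exact on square waves", {
  sq <- square_wave_trace(i = 2.4)
  id <- idealize_half_amplitude(sq, unitary_current = 2.4)
  expect_identical(id$po, 0.5)
  expect_equal(id$trace$state, rep(c(0L, 1L), 500))

  flat <- tibble::tibble(time_s = (0:999) / 1000, current_pA = 0)
  expect_identical(idealize_half_amplitude(flat, 1)$po, 0)
  expect_error(idealize_half_amplitude(sq, unitary_current = -1),
               class = "ardscan_bad_unitary_current")
})

test_that("idealized Po is invariant to joint scaling and polarity", {
  sim <- simulate_two_state_channel(30, 70, 1, 20000, 10, noise_sd = 0.1, seed = 4)
  po1 <- idealize_half_amplitude(sim$trace, 1)$po
  scaled <- dplyr::mutate(sim$trace, current_pA = current_pA * 7)
  expect_identical(idealize_half_amplitude(scaled, 7)$po, po1)
  flipped <- dplyr::mutate(sim$trace, current_pA = -current_pA)
  expect_identical(idealize_half_amplitude(flipped, 1, polarity = "negative")$po, po1)
})

test_that("idealized Po agrees with the true Markov state path", {
  sim <- simulate_two_state_channel(30, 70, 1, 20000, 60, noise_sd = 0.1, seed = 42)
  id <- idealize_half_amplitude(sim$trace, 1)
  # idealization error (noise misclassification) is negligible at sigma = 0.1 i
  expect_lt(abs(id$po - sim$po_true), 1e-3)
  # time-averaged Po within 3 SE of the stationary value 0.3
  se <- sqrt(2 * 0.3^2 * 0.7^2 * (1 / 30 + 1 / 70) / 60)
  expect_lt(abs(id$po - 0.3), 3 * se)
})

test_that("macroscopic open probability is a guarded ratio", {
  expect_equal(macro_open_probability(2, 4)$po, 0.5)
  expect_equal(macro_open_probability(4, 4)$po, 1.0)
  over <- macro_open_probability(5, 4)
  expect_equal(over$po, 1.25)
  expect_true(over$over_unity)
  expect_error(macro_open_probability(1, 0), class = "ardscan_bad_reference")
})

test_that("temperature relations normalize per cell to the room window", {
  const <- tibble::tibble(cell_id = "c1", temp_C = c(22, 24, 30, 40),
                          current_pA = 100)
  rel <- temperature_relation(const)
  expect_equal(rel$median_norm, rep(1, nrow(rel)))

  single <- temperature_relation(
    tibble::tibble(cell_id = "c1", temp_C = c(20.5, 21.5), current_pA = c(90, 110))
  )
  expect_equal(nrow(single), 1L)
  expect_equal(single$median_norm, 1)

  expect_error(
    temperature_relation(tibble::tibble(cell_id = "c1", temp_C = 40, current_pA = 1)),
    class = "ardscan_no_reference"
  )
})

test_that("synthetic heat activation yields rising binned medians above 35 degC", {
  sweeps <- simulate_temperature_currents(delta_H = 100, T_half = 45, seed = 21)
  rel <- temperature_relation(sweeps)
  # room-window bins sit at ~1 by construction
  room_bins <- rel$median_norm[rel$temp_bin > 20 & rel$temp_bin < 25]
  expect_true(all(abs(room_bins - 1) < 0.1))
  rising <- rel[rel$temp_bin > 35 & rel$temp_bin < 56, ]
  expect_true(!is.unsorted(rising$median_norm))
  expect_s3_class(plot_temperature_relation(rel), "ggplot")
})
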