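test_that("Savitzky-Golay derivatives behave on known shapes", {
  wl <- 190:500
  flat <- titration_series(wl, c(2, 7, 14), matrix(0.4, length(wl), 3))
  expect_lt(max(abs(derivative_spectra(flat, 1)$absorbance)), 1e-12)

  lin <- titration_series(wl, c(2, 7, 14),
                          matrix(rep(0.002 * wl, 3), ncol = 3))
  expect_lt(max(abs(derivative_spectra(lin, 2)$absorbance)), 1e-10)

  band <- titration_series(wl, c(2, 7, 14), matrix(rep(
    0.8 * exp(-0.5 * ((wl - 300) / 15)^2), 3), ncol = 3))
  d1 <- derivative_spectra(band, 1)
  zero_at <- wl[which.min(abs(d1$absorbance[wl > 250 & wl < 350, 1]))
                + sum(wl <= 250)]
  expect_lt(abs(zero_at - 300), 1.5)

  expect_error(derivative_spectra(band, 1, window = 6), "odd")
  expect_error(derivative_spectra(band, 1, window = 3, polyorder = 3),
               "exceed")
  expect_error(derivative_spectra(band, 3), "order")
  short <- titration_series(1:5 + 200, c(2, 7, 14), matrix(0.1, 5, 3))
  expect_error(derivative_spectra(short, 1, window = 7), "grid")
})

test_that("isosbestic points are found where species spectra intersect", {
  # mirror bands intersect halfway between the centers: 265 nm
  ts <- mirror_monoprotic(9, center_acid = 250, center_base = 280)
  iso <- find_isosbestic_points(ts)
  expect_gt(nrow(iso), 0)
  expect_equal(iso$wavelength_nm[1], 265, tolerance = 1)
  expect_lt(iso$spread[1], 1e-10)
  expect_false(attr(iso, "degenerate"))

  # single species: zero spread everywhere, degenerate
  one <- simulate_titration(acid_system(7),
                            rep(generic_spectra(1), 2), noise_sd = 0)
  iso1 <- find_isosbestic_points(one)
  expect_true(attr(iso1, "degenerate"))
  expect_equal(nrow(iso1), 0)

  # pure noise: no crossing, empty candidate list
  noise <- titration_series(190:500, default_ph_grid(), {
    set.seed(99); matrix(rnorm(311 * 49, 0, 0.002), 311, 49)
  })
  expect_equal(nrow(find_isosbestic_points(noise)), 0)
})

test_that("trace intersection recovers the pKa of a mirror monoprotic", {
  ts <- mirror_monoprotic(9)
  est <- intersection_pka(ts, 255, 275)
  expect_s3_class(est, "pka_estimate")
  expect_equal(est$pka, 9, tolerance = 0.01)
  expect_error(intersection_pka(ts, 255, 255), "differ")
  expect_error(intersection_pka(ts, 250.5, 275), "on the grid")
  # traces on the same side of the isosbestic never cross
  expect_error(intersection_pka(ts, 246, 254), "no crossing")
})

test_that("zero-crossing on derivative spectra recovers a monoprotic pKa", {
  ts <- mirror_monoprotic(8.4, center_acid = 250, center_base = 280)
  d1 <- derivative_spectra(ts, 1)
  est <- zero_crossing_pka(d1, ph_acid = 2, ph_base = 14)
  expect_identical(est$method, "zero_crossing")
  expect_equal(est$pka, 8.4, tolerance = 0.05)

  flat <- titration_series(190:500, default_ph_grid(),
                           matrix(0, 311, 49))
  expect_error(zero_crossing_pka(flat, 2, 14), "identically zero")
})

test_that("baseline-to-peak fits the exact log-ratio line on ideal data", {
  ph <- default_ph_grid()
  wl <- 240:320
  tr <- hh_trace(ph, 8, 0.05, 0.92)
  a <- outer(exp(-0.5 * ((wl - 280) / 20)^2), tr)
  ts <- titration_series(wl, ph, a)
  est <- baseline_to_peak_pka(ts, 280)
  expect_equal(est$pka, 8, tolerance = 1e-4)
  expect_equal(est$diagnostics$slope, 1, tolerance = 1e-4)

  # no transition amplitude
  flat <- titration_series(wl, ph, matrix(0.3, length(wl), length(ph)))
  expect_error(baseline_to_peak_pka(flat, 280), "amplitude")
  expect_error(baseline_to_peak_pka(ts, 280, ph_fit_range = c(2, 2.4)),
               "3 pH points")
})

test_that("baseline-to-peak recovers pKa1 of a catechol-like simulation", {
  ts <- catechol_series()
  # wavelength with rising absorbance across the first transition
  cols <- which(ts$ph_values <= 11)
  delta <- ts$absorbance[, max(cols)] - ts$absorbance[, 1]
  wl <- ts$wavelengths_nm[which.max(delta)]
  est <- baseline_to_peak_pka(ts, wl, ph_fit_range = c(2, 11))
  expect_equal(est$pka, 8.83, tolerance = 0.05)
})

test_that("the Seok closed form matches the numeric three-point oracle", {
  # worked examples
  ph <- c(6, 7, 8)
  est <- seok_pka(seok_inputs(ph, hh_trace(ph, 7, 0.1, 0.9)))
  expect_equal(est$pka, 7, tolerance = 1e-10)
  ph2 <- c(10.8, 11.75, 12.7)
  est2 <- seok_pka(seok_inputs(ph2, hh_trace(ph2, 11.75, 0.15, 0.8)))
  expect_equal(est2$pka, 11.75, tolerance = 1e-6)
  expect_error(seok_pka(seok_inputs(c(6, 7, 8), c(0.5, 0.5, 0.5))),
               "no transition")
  expect_error(seok_inputs(c(7, 6, 8), c(0.1, 0.2, 0.3)), "increasing")

  # 1000 random valid inputs against the independent numeric solver
  set.seed(2024)
  for (i in 1:1000) {
    pka <- runif(1, 3, 12)
    p <- sort(pka + runif(3, -1.5, 1.5))
    while (min(diff(p)) < 0.2) p <- sort(pka + runif(3, -1.5, 1.5))
    lim <- sort(runif(2, 0.05, 1.2))
    A <- hh_trace(p, pka, lim[1], lim[2])
    est <- seok_pka(seok_inputs(p, A))
    expect_equal(est$pka, seok_oracle(p, A), tolerance = 1e-8)
    expect_equal(est$pka, pka, tolerance = 1e-8)
  }
})

test_that("all estimators are invariant to uniform absorbance scaling", {
  ts <- mirror_monoprotic(9)
  scaled <- titration_series(ts$wavelengths_nm, ts$ph_values,
                             3.7 * ts$absorbance)
  expect_equal(intersection_pka(scaled, 255, 275)$pka,
               intersection_pka(ts, 255, 275)$pka, tolerance = 1e-12)
  d1 <- derivative_spectra(ts, 1); d1s <- derivative_spectra(scaled, 1)
  expect_equal(zero_crossing_pka(d1s, 2, 14)$pka,
               zero_crossing_pka(d1, 2, 14)$pka, tolerance = 1e-12)
  iso <- find_isosbestic_points(ts); isos <- find_isosbestic_points(scaled)
  expect_equal(isos$wavelength_nm[1], iso$wavelength_nm[1])
  ph <- c(8, 9, 10); A <- hh_trace(ph, 9, 0.2, 0.9)
  expect_equal(seok_pka(seok_inputs(ph, 5 * A))$pka,
               seok_pka(seok_inputs(ph, A))$pka, tolerance = 1e-12)
  wl <- match(270, ts$wavelengths_nm)
  expect_equal(baseline_to_peak_pka(scaled, 270)$pka,
               baseline_to_peak_pka(ts, 270)$pka, tolerance = 1e-10)
})

test_that("isosbestic + intersection methods agree on ideal monoprotic data", {
  ts <- mirror_monoprotic(7.5)
  a <- intersection_pka(ts, 255, 275)$pka
  b <- baseline_to_peak_pka(ts, 280)$pka
  ph <- c(6.5, 7.5, 8.5)
  i <- match(280, ts$wavelengths_nm)
  j <- vapply(ph, function(p) which.min(abs(ts$ph_values - p)), 1L)
  s <- seok_pka(seok_inputs(ts$ph_values[j], ts$absorbance[i, j]))$pka
  expect_lt(max(abs(c(a - b, a - s, b - s))), 0.01)
})
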