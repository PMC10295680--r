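# Synthetic-data generators: determinism, closed-form structure, and the
# spectral features they are required to emulate.

test_that("generators are bit-reproducible from their seed", {
  expect_identical(gen_formation_trace(trace_recipe(seed = 5)),
                   gen_formation_trace(trace_recipe(seed = 5)))
  expect_false(identical(gen_formation_trace(trace_recipe(seed = 5)),
                         gen_formation_trace(trace_recipe(seed = 6))))
  r <- spectrum_recipe(seed = 8)
  expect_identical(gen_dose_series(r), gen_dose_series(r))
  lr <- linelist_recipe(seed = 12, contamination_fraction = 0.2)
  expect_identical(gen_linelist(lr), gen_linelist(lr))
})

test_that("formation traces have the closed-form pseudo-first-order shape", {
  rec <- trace_recipe(noise_fraction = 0, bump_amplitude = 0)
  tr <- gen_formation_trace(rec)
  k_obs <- rec$k2 * rec$scavenger_conc
  expected <- rec$path_cm * rec$eps_radical * rec$c_radical0 *
    (1 - exp(-k_obs * tr$time_s))
  expect_equal(tr$absorbance, expected)

  # no radical pool: pure bump
  rec0 <- trace_recipe(noise_fraction = 0, c_radical0 = 0,
                       bump_amplitude = 0.02)
  tr0 <- gen_formation_trace(rec0)
  expect_equal(tr0$absorbance, 0.02 * exp(-tr0$time_s / 5e-8))

  # isosbestic wavelength: equal coefficients give a flat post-bump trace
  iso <- gen_formation_trace(trace_recipe(noise_fraction = 0,
                                          bump_amplitude = 0,
                                          eps_radical = 5e4,
                                          eps_parent = 5e4,
                                          wavelength_nm = 375))
  expect_lt(diff(range(iso$absorbance)) / max(iso$absorbance), 1e-9)
})

test_that("decay traces are exactly linear in reciprocal absorbance", {
  rec <- trace_recipe(mechanism = "second_order_decay", noise_fraction = 0)
  tr <- gen_decay_trace(rec)
  inv <- 1 / tr$absorbance
  slopes <- diff(inv) / diff(tr$time_s)
  expect_lt(diff(range(slopes)) / mean(slopes), 1e-9)
  expect_equal(mean(slopes), rec$two_k / (rec$eps_radical * 1), tolerance = 1e-9)
  # t = 0 gives A0 exactly; absorbance halves at (slope * A0)^-1
  a0 <- rec$eps_radical * rec$c_radical0 * rec$conversion_path_cm
  expect_equal(tr$absorbance[1], a0)
  t_half <- 1 / (mean(slopes) * a0)
  a_half <- a0 / (1 + mean(slopes) * a0 * t_half)
  expect_equal(a_half, a0 / 2)
})

test_that("crocin-like spectrum has the required band structure", {
  sp <- gen_crocin_like_spectrum()
  expect_equal(spectrum_at(sp, 441), 1.35e5)
  # no absorbance beyond 550 nm (under 1% of the peak)
  expect_lt(spectrum_at(sp, 600) / spectrum_at(sp, 441), 0.01)
  expect_lt(max(sp$value[sp$wavelength_nm >= 560]) / 1.35e5, 0.01)
  # weak UV bands present as local maxima near 333 and 250 nm
  expect_gt(spectrum_at(sp, 333), spectrum_at(sp, 300))
  expect_gt(spectrum_at(sp, 250), spectrum_at(sp, 290))
  # all-zero amplitudes give the zero spectrum
  z <- gen_crocin_like_spectrum(amplitudes = c(main = 0, shoulder = 0,
                                               uv333 = 0, uv250 = 0))
  expect_true(all(z$value == 0))
})

test_that("product-like spectrum satisfies its anchor constraints", {
  croc <- gen_crocin_like_spectrum()
  prod <- gen_product_like_spectrum(croc)
  expect_equal(spectrum_at(prod, 330), 0.25e5, tolerance = 1e-9)
  expect_equal(spectrum_at(prod, 441), 0.11e5, tolerance = 1e-9)
  expect_equal(spectrum_at(prod, 375), spectrum_at(croc, 375),
               tolerance = 1e-9)
  expect_true(all(prod$value >= 0))
})

test_that("dose series respects mass balance and its worked example", {
  rec <- spectrum_recipe(noise_fraction = 0)
  ser <- gen_dose_series(rec)
  with(ser$concentrations,
       expect_equal(c_known + c_product, rep(rec$c0, length(dose_gy))))
  # zero dose is the pure parent spectrum
  i0 <- which(ser$doses == 0)
  expect_equal(ser$spectra[[i0]]$value,
               rec$path_cm * rec$eps_known$value * rec$c0)
  # bleaching amplitude at 441 nm and 97 Gy: delta A = G D delta_eps l ~ 0.49
  i97 <- which(ser$doses == 97)
  da441 <- spectrum_at(ser$spectra[[i0]], 441) -
    spectrum_at(ser$spectra[[i97]], 441)
  d_eps <- spectrum_at(rec$eps_known, 441) - spectrum_at(rec$eps_product, 441)
  expect_equal(da441, rec$g * 97 * d_eps * rec$path_cm, tolerance = 1e-9)
  expect_equal(signif(da441, 2), 0.48)   # 4e-7 * 97 * 1.24e5 * 0.1
})

test_that("line lists carry the configured contamination fraction", {
  rec <- linelist_recipe(n_config = 500, contamination_fraction = 0.3,
                         contamination_excess = 0.5, seed = 4)
  ens <- gen_linelist(rec)
  n <- nrow(ens$lines)
  scr <- spin_screen(ens, 0.2)
  removed <- 1 - nrow(scr$lines) / n
  expect_lt(abs(removed - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # no contamination: screening is the identity
  pure <- gen_linelist(linelist_recipe(contamination_fraction = 0, seed = 4))
  expect_identical(spin_screen(pure, 0.2)$lines, pure$lines)
  # single configuration, single line: convolution peaks there
  one <- line_ensemble(data.frame(config = 1L, energy_ev = nm_to_ev(500),
                                  osc_strength = 1, s2 = 0.75), 0.75)
  sp <- convolve_lines(one, 0.5)
  expect_lte(abs(sp$wavelength_nm[which.max(sp$value)] - 500), 1)
})
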