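# Molar-absorptivity calibration algebra and isosbestic-point location.

test_that("ratio calibration gives the radical coefficient at 678 nm", {
  expect_equal(calibrate_by_ratio(1.35e5, 0.52, 0.024), 6230, tolerance = 1e-3)
  expect_equal(calibrate_by_ratio(1.35e5, 0.52, 0.52), 1.35e5)
  expect_equal(calibrate_by_ratio(2e5, 0.5, 0.25), 1e5)
  expect_error(calibrate_by_ratio(1e5, 0, 0.1), "> 0")
})

test_that("differential-to-absolute reconstruction matches the worked values", {
  grid <- 300:500
  ref <- spectrum(grid, rep(1.35e5, length(grid)), "molar_absorptivity")
  d <- spectrum(grid, rep(-18200, length(grid)), "differential")
  out <- differential_to_absolute(d, ref)
  expect_equal(out$value[1], 1.168e5)
  expect_equal(signif(out$value[1], 3), 1.17e5)

  ref333 <- spectrum(grid, rep(7000, length(grid)), "molar_absorptivity")
  d333 <- spectrum(grid, rep(3000, length(grid)), "differential")
  expect_equal(differential_to_absolute(d333, ref333)$value[1], 1.0e4)

  zero <- spectrum(grid, rep(0, length(grid)), "differential")
  expect_equal(differential_to_absolute(zero, ref)$value, ref$value)
})

test_that("differential reconstruction is the exact inverse of subtraction", {
  sp <- gen_crocin_like_spectrum()
  target <- spectrum(sp$wavelength_nm, pmax(sp$value * 0.8 + 500, 0),
                     "molar_absorptivity")
  d <- spectrum(sp$wavelength_nm, target$value - sp$value, "differential")
  expect_equal(differential_to_absolute(d, sp)$value, target$value)
})

test_that("negative reconstructed absorptivity is clipped with a warning", {
  grid <- 300:310
  ref <- spectrum(grid, rep(100, length(grid)), "molar_absorptivity")
  d <- spectrum(grid, rep(-200, length(grid)), "differential")
  expect_warning(out <- differential_to_absolute(d, ref), "clipped")
  expect_true(all(out$value == 0))
})

test_that("disjoint wavelength ranges are rejected", {
  ref <- spectrum(400:500, rep(1, 101), "molar_absorptivity")
  d <- spectrum(200:300, rep(1, 101), "differential")
  expect_error(differential_to_absolute(d, ref), "disjoint")
})

test_that("dimer coefficient inverts the bleaching-ratio equation", {
  expect_equal(signif(dimer_epsilon(1.35e5, 1.17e5, 0.43 / 0.18), 3), 1.84e5)
  # ratio 1 means the late bleach equals the early one: eps_d = 2 eps_r
  expect_equal(dimer_epsilon(1e5, 0.7e5, 1), 1.4e5)
  expect_equal(dimer_epsilon(1e5, 0.5e5, 0.5), 1.5e5)
  expect_error(dimer_epsilon(1e5, 1.2e5, 1), "bleaching")
})

test_that("dimer equation and its ratio form are mutual inverses", {
  set.seed(7)
  for (i in 1:50) {
    ec <- runif(1, 0.5e5, 2e5)
    er <- runif(1, 0, 0.99) * ec
    ratio <- runif(1, 0.01, 3)
    ed <- suppressWarnings(dimer_epsilon(ec, er, ratio))
    expect_equal((ec - ed / 2) / (ec - er), ratio, tolerance = 1e-12)
  }
})

test_that("isosbestic points are located at constructed crossings", {
  fam <- crossing_family(x0 = 375)
  iso <- find_isosbestic(fam, tolerance = 0.01)
  expect_true(any(abs(iso - 375) <= 1))

  # identical spectra: degenerate report
  same <- list(fam[[2]], fam[[2]])
  out <- find_isosbestic(same)
  expect_length(out, 0)
  expect_true(isTRUE(attr(out, "degenerate")))

  # parallel lines never cross
  grid <- 300:500
  par1 <- spectrum(grid, grid * 1.0, "differential")
  par2 <- spectrum(grid, grid + 50, "differential")
  expect_length(find_isosbestic(list(par1, par2), tolerance = 0.01), 0)
})

test_that("synthesized dose families preserve their isosbestic point", {
  rec <- spectrum_recipe(noise_fraction = 0)
  ser <- gen_dose_series(rec)
  # all spectra agree at the construction anchor where the components cross
  i375 <- which(rec$eps_known$wavelength_nm == 375)
  vals <- sapply(ser$spectra, function(s) s$value)
  expect_lt(max(vals[i375, ]) - min(vals[i375, ]),
            1e-9 * max(vals[i375, ]))
  iso <- find_isosbestic(ser$spectra, tolerance = 0.02)
  expect_true(any(abs(iso - 375) <= 1))
})

test_that("bleach-to-yield conversion reproduces the gamma yield", {
  g <- g_exp_from_bleach(0.49, 1.24e5, 0.1, 97)
  expect_equal(signif(g, 2), 4.1e-7)   # unrounded 4.074e-7
  expect_lt(abs(g / 4.0e-7 - 1), 0.02)
  expect_equal(g_exp_from_bleach(0, 1.24e5, 0.1, 97), 0)
  # inverse identity with dose_to_concentration
  for (gg in c(1e-7, 4e-7, 6.2e-7)) {
    da <- dose_to_concentration(97, gg) * 1.24e5 * 0.1
    expect_equal(g_exp_from_bleach(da, 1.24e5, 0.1, 97), gg)
  }
  expect_error(g_exp_from_bleach(0.1, 0, 0.1, 97), "> 0")
})

test_that("spectrum container enforces grid and sign invariants", {
  expect_error(spectrum(c(300, 300, 301), 1:3, "absorbance"),
               "strictly increasing")
  expect_error(spectrum(300:302, c(1, -1, 1), "molar_absorptivity"), ">= 0")
  expect_silent(spectrum(300:302, c(1, -1, 1), "differential"))
  sp <- spectrum(300:400, seq(0, 1, length.out = 101), "absorbance")
  expect_equal(spectrum_at(sp, 350), 0.5)
  expect_error(spectrum_at(sp, 250), "outside")
  rs <- resample_spectrum(sp, seq(310, 390, by = 5))
  expect_equal(rs$value, seq(0.1, 0.9, length.out = 17))
})
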