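# Line-list handling: subsampling, spin screening, Gaussian convolution and
# probability-weighted mixing.

test_that("uniform subsampling keeps the expected configurations", {
  lines <- data.frame(config = 1:60000, energy_ev = 2.8,
                      osc_strength = 1, s2 = 0.75)
  ens <- line_ensemble(lines, ground_s2 = 0.75, total_steps = 60000)
  sub <- subsample(ens, burn_in = 20000, stride = 100)
  kept <- unique(sub$lines$config)
  expect_length(kept, 400)
  expect_true(all(kept > 20000))
  expect_true(all((kept - 20000) %% 100 == 0))

  # stride 1, no burn-in: identity
  id <- subsample(ens, burn_in = 0, stride = 1)
  expect_equal(nrow(id$lines), nrow(lines))

  expect_error(subsample(line_ensemble(lines[1:20000, ], 0.75,
                                       total_steps = 20000),
                         burn_in = 20000), "smaller than")
})

test_that("spin screening discards lines above the relative cutoff", {
  lines <- data.frame(config = 1L, energy_ev = 2:4,
                      osc_strength = 1, s2 = c(0.76, 0.88, 1.20))
  ens <- line_ensemble(lines, ground_s2 = 0.75)
  kept <- spin_screen(ens, 0.20)$lines
  expect_equal(sort(kept$s2), c(0.76, 0.88))   # cutoff 0.90

  # parameter 0, uncontaminated lines: all kept
  pure <- line_ensemble(data.frame(config = 1L, energy_ev = 2:4,
                                   osc_strength = 1, s2 = 0.75), 0.75)
  expect_equal(nrow(spin_screen(pure, 0)$lines), 3L)

  # closed shell: only exactly uncontaminated lines survive
  cs <- line_ensemble(data.frame(config = 1L, energy_ev = 2:4,
                                 osc_strength = 1, s2 = c(0, 0, 0.5)), 0)
  expect_equal(nrow(spin_screen(cs, 0.2)$lines), 2L)
})

test_that("spin screening is idempotent and monotone in the parameter", {
  ens <- gen_linelist(linelist_recipe(contamination_fraction = 0.4,
                                      contamination_excess = 0.5, seed = 3))
  once <- spin_screen(ens, 0.2)
  twice <- spin_screen(once, 0.2)
  expect_identical(once$lines, twice$lines)
  n_prev <- -1
  for (p in c(0, 0.1, 0.3, 0.5, 1)) {
    n <- nrow(spin_screen(ens, p)$lines)
    expect_gte(n, n_prev)   # larger parameter never removes more lines
    n_prev <- n
  }
})

test_that("a single line convolves to a Gaussian peaking at its wavelength", {
  ens <- line_ensemble(data.frame(config = 1L, energy_ev = nm_to_ev(441),
                                  osc_strength = 3.22, s2 = 0),
                       ground_s2 = 0)
  for (fwhm in c(0.2, 0.5, 0.7)) {
    sp <- convolve_lines(ens, fwhm = fwhm)
    peak <- sp$wavelength_nm[which.max(sp$value)]
    expect_lte(abs(peak - 441), 1)
  }
})

test_that("convolution conserves oscillator-strength area in energy", {
  rec <- linelist_recipe(n_config = 5, seed = 9)
  ens <- gen_linelist(rec)
  grid <- seq(120, 4000, by = 2)
  for (fwhm in c(0.2, 0.5, 0.7)) {
    sp <- convolve_lines(ens, fwhm, grid_nm = grid)
    expected <- sum(ens$lines$osc_strength) / length(unique(ens$lines$config))
    expect_equal(energy_domain_area(sp), expected, tolerance = 1e-3)
  }
})

test_that("convolution is linear and the empty ensemble warns", {
  ens <- gen_linelist(linelist_recipe(n_config = 3, seed = 2))
  doubled <- ens
  doubled$lines <- rbind(ens$lines, ens$lines)
  s1 <- convolve_lines(ens, 0.5)
  s2 <- convolve_lines(doubled, 0.5)
  expect_equal(s2$value, 2 * s1$value)

  empty <- line_ensemble(data.frame(config = integer(), energy_ev = numeric(),
                                    osc_strength = numeric(), s2 = numeric()),
                         ground_s2 = 0.75)
  expect_warning(z <- convolve_lines(empty, 0.5), "empty")
  expect_true(all(z$value == 0))
})

test_that("mixing is a weighted pointwise sum with simplex weights", {
  grid <- 300:500
  sa <- spectrum(grid, dnorm(grid, 420, 20), "absorbance")
  sb <- spectrum(grid, dnorm(grid, 460, 25), "absorbance")
  half <- mix_spectra(list(a = sa, b = sb), c(a = 0.5, b = 0.5))
  expect_equal(half$value, 0.5 * sa$value + 0.5 * sb$value)
  # weight 1 on a single species is the identity
  expect_equal(mix_spectra(list(a = sa), c(a = 1))$value, sa$value)
  # permutation safety
  p1 <- mix_spectra(list(a = sa, b = sb), c(a = 0.3, b = 0.7))
  p2 <- mix_spectra(list(b = sb, a = sa), c(b = 0.7, a = 0.3))
  expect_equal(p1$value, p2$value)
  # mixing identical spectra returns that spectrum for any valid weights
  same <- mix_spectra(list(a = sa, b = sa), c(a = 0.21, b = 0.79))
  expect_equal(same$value, sa$value)
  # the disproportionation-product combination pattern 0, 1/2, 1/4, 1/4
  cyc <- mix_spectra(list(CaCap = sa, CaCbp = sb, CaCapcyc = sa,
                          CbCbpcyc = sb),
                     c(CaCap = 0, CaCbp = 0.5, CaCapcyc = 0.25,
                       CbCbpcyc = 0.25))
  expect_equal(cyc$value, 0.5 * sb$value + 0.25 * sa$value + 0.25 * sb$value)
  expect_error(mix_spectra(list(a = sa), c(a = 0.5, b = 0.5)), "no spectrum")
  expect_error(mix_spectra(list(a = sa, b = sb), c(a = 0.6, b = 0.6)),
               "sum to 1")
})

test_that("dimer weights follow the binomial closure", {
  expect_equal(monomer_to_dimer_weights(0.5, 0.5),
               c(aa = 0.25, ab = 0.5, bb = 0.25))
  w <- monomer_to_dimer_weights(5 / 6, 1 / 6)
  expect_equal(round(unname(w), 2), c(0.69, 0.28, 0.03))
  expect_equal(monomer_to_dimer_weights(1, 0), c(aa = 1, ab = 0, bb = 0))
  set.seed(5)
  for (p in runif(20)) {
    expect_equal(sum(monomer_to_dimer_weights(p, 1 - p)), 1)
  }
  expect_error(monomer_to_dimer_weights(0.7, 0.7), "sum to 1")
})

test_that("sugar-driven probabilities interpolate between the two limits", {
  expect_equal(sugar_driven_weights(1 / 3), c(a = 5 / 6, b = 1 / 6))
  expect_equal(sugar_driven_weights(1), c(a = 0.5, b = 0.5))
  expect_equal(sugar_driven_weights(0), c(a = 1, b = 0))
  expect_error(sugar_driven_weights(1.2), "in \\[0, 1\\]")
})
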