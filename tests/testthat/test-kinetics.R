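# Pseudo-first-order and second-order transient-absorbance fitting.

test_that("exact exponential growth is fitted to machine precision", {
  tr <- exact_formation_trace(1e6)
  fit <- fit_pseudo_first_order(tr, scavenger_conc = 1e-4,
                                window = c(0, max(tr$time_s)), plateau = 0.2)
  expect_equal(fit$k_obs, 1e6, tolerance = 1e-10)
  expect_equal(fit$k2, 1e10, tolerance = 1e-10)
  expect_identical(fit$flag, "ok")
})

test_that("noiseless fitters recover rates below 0.1% across the k range", {
  for (k in c(1e4, 1e5, 1e6, 1e7, 1e8)) {
    tr <- exact_formation_trace(k)
    fit <- fit_pseudo_first_order(tr, 1e-4, window = c(0, max(tr$time_s)),
                                  plateau = 0.2)
    expect_lt(abs(fit$k_obs / k - 1), 1e-3)

    trd <- exact_decay_trace(k, t_max = 8 / (k * 0.3))
    fitd <- fit_second_order(trd, epsilon = 6230)
    expect_lt(abs(fitd$k_obs / k - 1), 1e-3)
  }
})

test_that("second-order conversion multiplies slope, epsilon and path", {
  tr <- exact_decay_trace(0.6e6)
  fit <- fit_second_order(tr, epsilon = 6.23e3, conversion_path = 1)
  expect_equal(fit$k_obs, 0.6e6, tolerance = 1e-8)
  expect_equal(signif(fit$two_k, 2), 3.7e9)
  # the cell path enters linearly if folded in explicitly
  fit05 <- fit_second_order(tr, epsilon = 6.23e3, conversion_path = 0.5)
  expect_equal(fit05$two_k, fit$two_k / 2)
})

test_that("second-order fit is consistent under time/absorbance rescaling", {
  tr <- exact_decay_trace(5e5)
  fit_s <- fit_second_order(tr, epsilon = 6230)
  # same data in microseconds: slope in us^-1, rate per us
  tr_us <- kinetic_trace(tr$time_s * 1e6, tr$absorbance, 678, 0.5)
  fit_us <- fit_second_order(tr_us, epsilon = 6230)
  expect_equal(fit_us$two_k * 1e6, fit_s$two_k, tolerance = 1e-8)
})

test_that("synthetic round trips recover the generating constants", {
  # formation: k2 = 3.4e10 at 0.13 mM, noiseless with bump excluded
  tr <- gen_formation_trace(trace_recipe(noise_fraction = 0))
  fit <- fit_pseudo_first_order(tr, scavenger_conc = 1.3e-4)
  expect_lt(abs(fit$k2 / 3.4e10 - 1), 0.01)
  # the generating pseudo-first-order constant is k2 * c = 4.42e6 s^-1
  expect_lt(abs(fit$k_obs / 4.42e6 - 1), 0.01)
  # decay: 2k = 3.7e9 with eps = 6230
  trd <- gen_decay_trace(trace_recipe(mechanism = "second_order_decay",
                                      noise_fraction = 0))
  fitd <- fit_second_order(trd, epsilon = 6230)
  expect_lt(abs(fitd$two_k / 3.7e9 - 1), 0.01)
})

test_that("noisy recovery has small bias and bounded spread over seeds", {
  k2s <- vapply(1:100, function(s) {
    tr <- gen_formation_trace(trace_recipe(seed = s))
    fit_pseudo_first_order(tr, 1.3e-4)$k2
  }, numeric(1))
  expect_lt(abs(mean(k2s) / 3.4e10 - 1), 0.02)     # relative bias < 2%
  expect_lt(sd(k2s) / mean(k2s), 0.10)             # relative spread < 10%

  tks <- vapply(1:100, function(s) {
    tr <- gen_decay_trace(trace_recipe(mechanism = "second_order_decay",
                                       seed = s))
    fit_second_order(tr, 6230)$two_k
  }, numeric(1))
  expect_lt(abs(mean(tks) / 3.7e9 - 1), 0.02)
  expect_lt(sd(tks) / mean(tks), 0.10)
})

test_that("constant traces are flagged instead of fitted", {
  t <- seq(0, 1e-6, length.out = 100)
  flat <- kinetic_trace(t, rep(0.25, 100), 375, 0.5)
  expect_identical(fit_pseudo_first_order(flat, 1e-4)$flag, "no_kinetics")
  expect_identical(fit_second_order(flat, 6230)$flag, "no_kinetics")
})

test_that("nonpositive absorbances are rejected by the reciprocal test", {
  t <- seq(0, 1e-5, length.out = 50)
  tr <- kinetic_trace(t, seq(0.2, -0.01, length.out = 50), 678, 0.5)
  expect_error(fit_second_order(tr, 6230), "must be > 0")
})

test_that("order discrimination identifies the generating mechanism", {
  trd <- gen_decay_trace(trace_recipe(mechanism = "second_order_decay",
                                      noise_fraction = 0))
  expect_identical(order_discrimination(trd)$verdict, "second")

  t <- seq(0, 8e-6, length.out = 300)
  tr1 <- kinetic_trace(t, 0.3 * exp(-1e6 * t), 678, 0.5)
  expect_identical(order_discrimination(tr1)$verdict, "first")

  flat <- kinetic_trace(t, rep(0.2, length(t)), 678, 0.5)
  expect_identical(order_discrimination(flat)$verdict, "neither")
  expect_error(order_discrimination(kinetic_trace(1:5 * 1e-9, rep(1, 5),
                                                  678, 0.5)),
               "at least 10")
})

test_that("the nonlinear refinement agrees with the linearization", {
  tr <- gen_formation_trace(trace_recipe(noise_fraction = 0.05, seed = 11))
  lin <- fit_pseudo_first_order(tr, 1.3e-4)
  nl <- fit_pseudo_first_order(tr, 1.3e-4, nonlinear = TRUE)
  expect_lt(abs(nl$k2 / lin$k2 - 1), 0.15)
  expect_lt(abs(nl$k2 / 3.4e10 - 1), 0.15)
})

test_that("trace constructor validates its invariants", {
  expect_error(kinetic_trace(c(1, 1, 2) * 1e-9, 1:3, 678, 0.5),
               "strictly increasing")
  expect_error(kinetic_trace(1:3 * 1e-9, 1:2, 678, 0.5), "same length")
  expect_error(kinetic_trace(1:3 * 1e-9, 1:3, 678, 0), "> 0")
})
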