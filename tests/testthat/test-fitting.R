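test_that("nernst_model evaluates the multi-couple closed form", {
  expect_equal(nernst_model(-118, -118), 0.5, tolerance = 1e-12)
  expect_equal(nernst_model(-118 - 59.16, -118), 10 / 11, tolerance = 1e-6)
  f <- nernst_model(c(-300, -100), c(-105, -168), c(0.3, 0.7))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(nernst_model(0, c(-1, -2), c(0.5)), "one per couple")
  expect_error(nernst_model(0, -1, -0.5), "non-negative")
})

test_that("fit_redox recovers noiseless truth essentially exactly", {
  E <- seq(-400, 100, by = 5)
  d1 <- data.frame(potential_mV = E, fraction = nernst_model(E, -118))
  f1 <- fit_redox(d1)
  expect_equal(f1$midpoints, -118, tolerance = 1e-6)
  expect_lt(f1$residual_rms, 1e-8)

  d2 <- data.frame(potential_mV = E,
                   fraction = nernst_model(E, c(-105, -168), c(0.55, 0.45)))
  f2 <- fit_redox(d2, n_couples = 2)
  expect_equal(f2$midpoints, c(-105, -168), tolerance = 1e-4)
  expect_equal(f2$weights, c(0.55, 0.45), tolerance = 1e-4)
  expect_equal(f2$delta_em, 63, tolerance = 1e-3)

  d3 <- data.frame(potential_mV = E,
                   fraction = nernst_model(E, c(-92, -156), c(0.5, 0.5)))
  f3 <- fit_redox(d3, n_couples = 2, pairs = TRUE)
  expect_equal(f3$midpoints, c(-92, -156), tolerance = 1e-4)
  expect_identical(f3$weights, c(0.5, 0.5))
})

test_that("fit_redox output satisfies its invariants on noisy data", {
  sim <- gen_redox_titration(c(-105, -168), seed = 21)
  f <- fit_redox(sim$data, n_couples = 2)
  expect_true(all(diff(f$midpoints) < 0))       # sorted descending
  expect_equal(sum(f$weights), 1, tolerance = 1e-9)
  expect_identical(length(f$midpoint_se), 2L)   # replicate-spread SEs
  expect_true(all(f$midpoint_se > 0))
  expect_lt(abs(f$residual_rms - 0.02), 0.005)
  # accepts the E column alias, without replicates
  alias <- data.frame(E = sim$data$potential_mV, fraction = sim$data$fraction)
  expect_lt(max(abs(fit_redox(alias, n_couples = 2)$midpoints -
                      f$midpoints)), 1e-3)
})

test_that("fit_redox validates input and warns on truncated titrations", {
  expect_error(fit_redox(data.frame(potential_mV = 1:4, fraction = 0.5)),
               "at least 8")
  expect_error(fit_redox(data.frame(potential_mV = 1:10, fraction = 0.5),
                         n_couples = 3), "1 or 2")
  expect_error(fit_redox(data.frame(potential_mV = 1:10, fraction = 0.5),
                         n_couples = 1, pairs = TRUE), "pairs mode")
  E <- seq(-150, 100, by = 10)  # never reaches the reduced asymptote
  expect_warning(fit_redox(data.frame(potential_mV = E,
                                      fraction = nernst_model(E, -200))),
                 "asymptote")
})

test_that("adding a second couple never increases the residual", {
  sim <- gen_redox_titration(c(-105, -168), seed = 31)
  r1 <- fit_redox(sim$data, n_couples = 1)$residual_rms
  r2 <- fit_redox(sim$data, n_couples = 2)$residual_rms
  expect_lte(r2, r1 + 1e-9)
  expect_gt(r1, r2)  # clearly bimodal data
})

test_that("midpoint recovery is unbiased and precise over replications", {
  est <- vapply(1:100, function(s) {
    sim <- gen_redox_titration(-118, seed = 1000 + s)
    fit_redox(sim$data)$midpoints
  }, numeric(1))
  expect_lt(abs(mean(est) + 118), 0.5)          # no material bias
  expect_gte(mean(abs(est + 118) <= 4), 0.9)    # tolerance met >= 90%
  expect_lt(sd(est), 2)
})

test_that("morrison_bound_fraction has the right limits", {
  expect_identical(morrison_bound_fraction(1000, 0, 4.2), 0)
  expect_equal(morrison_bound_fraction(1000, 1e9, 4.2), 1, tolerance = 1e-4)
  # weak-binding limit reduces to the hyperbola when depletion is negligible
  L <- c(10, 50, 200)
  expect_equal(morrison_bound_fraction(1e-6, L, 100), L / (L + 100),
               tolerance = 1e-4)
  # stoichiometric limit: Kd -> 0 gives min(L/P, 1)
  expect_equal(morrison_bound_fraction(1000, 400, 1e-9), 0.4,
               tolerance = 1e-6)
  expect_true(all(diff(morrison_bound_fraction(1000, 0:2000, 4.2)) >= 0))
  expect_error(morrison_bound_fraction(-1, 0, 4.2), "P > 0")
  expect_error(morrison_bound_fraction(1000, -5, 4.2), "L >= 0")
})

test_that("fit_kd recovers noiseless truth including the signal model", {
  L <- seq(0, 6000, length.out = 24)
  y <- 0.3 + 2 * morrison_bound_fraction(3000, L, 4.2)
  f <- fit_kd(data.frame(ligand = L, signal = y), site_conc = 3000)
  expect_equal(f$kd, 4.2, tolerance = 1e-3)
  expect_equal(f$scale, 2, tolerance = 1e-4)
  expect_equal(f$offset, 0.3, tolerance = 1e-4)
  expect_false(f$is_upper_limit)
})

test_that("fit_kd flags sub-resolution affinities as upper limits", {
  # truth 0.1 nM at 1.5 uM sites: far below what the isotherm can resolve
  sim <- gen_binding_isotherm(0.1, 1500, seed = 4)
  f <- fit_kd(sim$data, site_conc = 1500)
  expect_true(f$is_upper_limit)
  expect_true(is.finite(f$upper_limit))
  expect_lt(f$upper_limit, 1500)
  # a resolvable Kd at the same noise level is not flagged
  sim2 <- gen_binding_isotherm(25, 3000, seed = 4)
  f2 <- fit_kd(sim2$data, site_conc = 3000)
  expect_false(f2$is_upper_limit)
  expect_lt(abs(f2$kd - 25), 0.25 * 25)
})

test_that("fit_kd validates inputs and honours column aliases", {
  L <- seq(0, 6000, length.out = 24)
  y <- morrison_bound_fraction(3000, L, 25)
  expect_error(fit_kd(data.frame(ligand = L, signal = y), 3000, n_sites = 3),
               "n_sites")
  f <- fit_kd(data.frame(L = L, signal = y), 3000)
  expect_equal(f$kd, 25, tolerance = 1e-3)
  # two identical independent sites halve the apparent site concentration
  y2 <- morrison_bound_fraction(2 * 3000, L, 25)
  f2 <- fit_kd(data.frame(ligand = L, signal = y2), 3000, n_sites = 2)
  expect_equal(f2$kd, 25, tolerance = 1e-3)
})
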