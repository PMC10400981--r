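test_that("exact titration of one redox site is the closed-form Nernst curve", {
  sys <- make_single_heme_system(em = -118)
  tc <- exact_titrate(sys)
  nernst <- 1 / (1 + 10^((tc$grid - (-118)) / 59.16))
  expect_lt(max(abs(tc$occupancy[, 1] - nernst)), 1e-3)
  expect_true(all(tc$occupancy >= 0 & tc$occupancy <= 1))
  expect_true(all(diff(tc$occupancy[, 1]) <= 0))  # monotone in E
  expect_true(all(tc$se == 0))
  expect_lt(abs(extract_em(tc) - (-118)), 0.05)
})

test_that("two identical non-interacting sites titrate like one", {
  m <- interaction_model()
  one <- make_single_heme_system(em = -100)
  two <- site_system(list(
    titratable_site("heme1", "redox", -100, c(0, 0, 0)),
    titratable_site("heme2", "redox", -100, c(500, 0, 0))), m,
    W = matrix(0, 2, 2))  # strictly non-interacting
  a <- exact_titrate(one)
  b <- exact_titrate(two)
  expect_equal(b$occupancy[, 1], a$occupancy[, 1], tolerance = 1e-9)
  expect_equal(b$occupancy[, 2], a$occupancy[, 1], tolerance = 1e-9)
})

test_that("strong repulsion splits two identical sites into two waves", {
  m <- interaction_model()
  mk <- function(r) site_system(list(
    titratable_site("h1", "redox", -100, c(0, 0, 0)),
    titratable_site("h2", "redox", -100, c(r, 0, 0))), m)
  grid <- seq(-500, 200, by = 2)
  strong <- exact_titrate(mk(2.4), grid)   # W ~ 300 meV
  weak <- exact_titrate(mk(400), grid)     # W ~ 0
  sep <- function(tc) {
    mean_occ <- rowMeans(tc$occupancy)
    e75 <- approx(mean_occ, tc$grid, xout = 0.75)$y
    e25 <- approx(mean_occ, tc$grid, xout = 0.25)$y
    e25 - e75
  }
  expect_lt(sep(weak), 60)    # single-wave width ~ 56.5 mV
  expect_gt(sep(strong), 250) # two waves separated by ~ W
  # plateau at half reduction between the waves
  mid <- approx(grid, rowMeans(strong$occupancy),
                xout = -100 - 300 / 2)$y
  expect_equal(mid, 0.5, tolerance = 0.02)
})

test_that("exact enumeration refuses more than 20 sites", {
  m <- interaction_model()
  sites <- lapply(1:21, function(i)
    titratable_site(paste0("s", i), "acid", 5, c(10 * i, 0, 0)))
  sys <- site_system(sites, m)
  expect_error(exact_titrate(sys), "20 sites")
})

test_that("Monte-Carlo titration is seeded, deterministic and validated", {
  sys <- make_single_heme_system()
  expect_error(mc_titrate(sys), "seed")
  expect_error(mc_titrate(sys, seed = 1, n_steps = 500), "1000")
  t1 <- mc_titrate(sys, grid = seq(-200, -40, by = 20), seed = 11,
                   n_steps = 20000)
  t2 <- mc_titrate(sys, grid = seq(-200, -40, by = 20), seed = 11,
                   n_steps = 20000)
  expect_identical(t1$occupancy, t2$occupancy)  # bitwise
  expect_identical(t1$se, t2$se)
  t3 <- mc_titrate(sys, grid = seq(-200, -40, by = 20), seed = 12,
                   n_steps = 20000)
  expect_false(identical(t1$occupancy, t3$occupancy))
  expect_true(all(t1$occupancy >= 0 & t1$occupancy <= 1))
})

test_that("MC occupancy at E = E_m,int is one half within error", {
  sys <- make_single_heme_system(em = -118)
  tc <- mc_titrate(sys, grid = -118, seed = 3)
  expect_lt(abs(tc$occupancy[1, 1] - 0.5),
            3 * max(tc$se[1, 1], sqrt(0.25 / 8e4)))
})

test_that("MC agrees with exact enumeration on a coupled 3-site system", {
  sys <- make_three_site_system()
  ex <- exact_titrate(sys)
  mc <- mc_titrate(sys, seed = 101, n_batches = 25)
  s <- mc_exact_summary(mc, ex, n_kept = 8e4)
  expect_lte(s$frac_over_3, 0.05)
  expect_lt(s$max_ratio, 6)
  # midpoints from the two engines agree closely at 1e5 steps
  expect_lt(abs(extract_em(mc) - extract_em(ex)), 2)
})

test_that("extract_em is orientation invariant and bounded by the grid", {
  sys <- make_single_heme_system(em = -118)
  tc <- exact_titrate(sys)
  rev_tc <- tc
  rev_tc$grid <- rev(tc$grid)
  rev_tc$occupancy <- tc$occupancy[rev(seq_along(tc$grid)), , drop = FALSE]
  expect_equal(extract_em(rev_tc), extract_em(tc), tolerance = 1e-9)
  # site selection by label
  expect_equal(extract_em(tc, "heme1"), extract_em(tc, 1))
  expect_error(extract_em(tc, "nope"), "unknown site")
  # no crossing inside a too-narrow grid
  narrow <- exact_titrate(sys, grid = seq(100, 200, by = 10))
  expect_error(extract_em(narrow), "extend")
})

test_that("predict_shift obeys the closed-form fixed-charge algebra", {
  m <- interaction_model()
  base <- make_single_heme_system(em = -118)
  w8 <- 14399.645 / (20 * 8)
  plus1 <- site_system(base$sites, m,
                       fixed_charges = data.frame(x = 8, y = 0, z = 0, q = -1))
  # a single fixed -1 charge shifts E_m by exactly -W (interpolation error
  # only)
  expect_lt(abs(predict_shift(plus1, base, grid = seq(-450, 100, by = 5)) +
                  w8), 0.02)
  # identical systems: zero shift
  expect_equal(predict_shift(base, base), 0, tolerance = 1e-9)
  # additivity of non-titrating perturbations
  qa <- data.frame(x = 8, y = 0, z = 0, q = -1)
  qb <- data.frame(x = 0, y = -10, z = 0, q = -1)
  g <- seq(-500, 100, by = 5)
  sa <- predict_shift(site_system(base$sites, m, fixed_charges = qa), base, g)
  sb <- predict_shift(site_system(base$sites, m, fixed_charges = qb), base, g)
  sab <- predict_shift(site_system(base$sites, m,
                                   fixed_charges = rbind(qa, qb)), base, g)
  expect_lt(abs(sab - (sa + sb)), 0.05)
  # perturbation magnitude decreases with distance (1/r law through the
  # titration machinery)
  s10 <- predict_shift(site_system(base$sites, m,
                                   fixed_charges = data.frame(
                                     x = 10, y = 0, z = 0, q = -1)), base, g)
  expect_gt(abs(sa), abs(s10))
  expect_error(predict_shift(site_system(list(titratable_site(
    "x", "acid", 4, c(0, 0, 0))), m), base), "redox")
})

test_that("net-negative perturbations near the heme lower E_m", {
  base <- make_single_heme_system()
  g <- seq(-500, 100, by = 5)
  for (r in c(6, 9, 14)) {
    v <- site_system(base$sites, base$model,
                     fixed_charges = data.frame(x = r, y = 0, z = 0, q = -1))
    expect_lt(predict_shift(v, base, g), 0)
  }
})

test_that("an always-protonated acid contributes nothing to the shift", {
  m <- interaction_model()
  base <- make_single_heme_system()
  inert <- site_system(c(base$sites, list(
    titratable_site("d", "acid", 25, c(8, 0, 0)))), m)  # pKa >> pH
  active <- site_system(c(base$sites, list(
    titratable_site("d2", "acid", 4, c(8, 0, 0)))), m)  # fully deprotonated
  g <- seq(-500, 100, by = 5)
  expect_lt(abs(predict_shift(inert, base, g, site_id = "heme1")), 0.05)
  expect_lt(predict_shift(active, base, g, site_id = "heme1"), -80)
})
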