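test_that("expected_lad: closed form, limits and monotonicity", {
  # rho = 1 preserves coupling exactly
  expect_equal(expected_lad(c = 0.3, g = 7, rho = 1, m = 0), 1)
  # closed form at rho = 0, m = 0
  expect_equal(expected_lad(c = 0.1, g = 10, rho = 0, m = 0), 0.9^10,
               tolerance = 1e-14)
  expect_equal(round(expected_lad(0.1, 10, 0, 0), 5), 0.34868)

  # strictly decreasing in g and c, increasing in rho; always in (0, 1]
  cs <- c(0.05, 0.2, 0.4)
  for (m in c(0, 0.01, 0.1)) {
    for (rho in c(0, 0.3, 0.6)) {
      vals_g <- vapply(1:15, function(g) expected_lad(0.2, g, rho, m),
                       numeric(1))
      expect_true(all(diff(vals_g) < 0))
      vals_c <- expected_lad(cs, 8, rho, m)
      expect_true(all(diff(vals_c) < 0))
      expect_true(all(vals_g > 0 & vals_g <= 1))
    }
    vals_rho <- vapply(c(0, 0.25, 0.5, 0.75),
                       function(r) expected_lad(0.2, 8, r, m), numeric(1))
    expect_true(all(diff(vals_rho) > 0))
  }
  expect_error(expected_lad(0.6, 5, 0, 0), "c must")
  expect_error(expected_lad(0.1, 5, 0, 1), "m must")
})

test_that("noiseless LAD inverts to the generating g; assumed rho shifts it up", {
  dist_cm <- rep(10, 50)
  cfrac <- (1 - exp(-2 * dist_cm / 100)) / 2
  lad12 <- expected_lad(cfrac, g = 12, rho = 0, m = 0)
  fit <- fit_generations(lad12, rho = 0, m = 0, dist_cm = dist_cm)
  expect_equal(fit$best_g, 12)
  # fitting the same decay while (wrongly) assuming assortment needs more
  # generations to reach the observed decay
  fit_rho <- fit_generations(lad12, rho = 0.3, m = 0, dist_cm = dist_cm)
  expect_gt(fit_rho$best_g, 12)
  # boundary warning
  expect_warning(
    fit_generations(expected_lad(cfrac, 3, 0, 0), rho = 0, m = 0,
                    dist_cm = dist_cm), "boundary")
  expect_error(fit_generations(numeric(0), dist_cm = numeric(0)), "empty")
})

test_that("migration and assortment both retain LAD in paired simulations", {
  map <- small_map(3, mb = 40)
  base <- simulate_lad_reference(g = 6, rho = 0, m = 0, h0 = 0.65, map = map,
                                 N = 300, reps = 5, seed = 50)
  assort <- simulate_lad_reference(g = 6, rho = 0.6, m = 0, h0 = 0.65,
                                   map = map, N = 300, reps = 5, seed = 50)
  expect_gt(assort$mean_lad, base$mean_lad)
  migr <- simulate_lad_reference(g = 6, rho = 0, m = 0.2, h0 = 0.65,
                                 map = map, N = 300, reps = 5, seed = 50)
  expect_gt(migr$mean_lad, base$mean_lad)
  # g = 1: a single post-founding meiosis round leaves LAD near 1
  g1 <- simulate_lad_reference(g = 1, rho = 0, m = 0, h0 = 0.65, map = map,
                               N = 300, reps = 5, seed = 51)
  expect_gt(g1$mean_lad, 0.85)
})

test_that("expected_lad matches the simulator under random mating with migration", {
  map <- small_map(4, mb = 40)
  ref <- simulate_lad_reference(g = 10, rho = 0, m = 0.01, h0 = 0.65,
                                map = map, N = 1000, reps = 10, seed = 60)
  w <- ref$windows
  cfrac <- (1 - exp(-2 * w$dist_cm / 100)) / 2
  model <- expected_lad(cfrac, g = 10, rho = 0, m = 0.01, h0 = 0.65)
  z <- (ref$mean_lad - mean(model)) / max(ref$se_mean_lad, 1e-6)
  expect_lt(abs(z), 3)
})

test_that("under assortment the simulator sits between the rho = 0 and target-rho curves", {
  # The cross-homolog coupling rho * D_t is exact at rho = 0 and rho = 1 but
  # overstates LAD retention at intermediate rho (the true coupling scales
  # with the variance of genome-wide ancestry, which is far below D_t at
  # short range). The simulated decay must therefore exceed the
  # random-mating curve while staying below the rho-coupled curve.
  map <- small_map(4, mb = 40)
  ref <- simulate_lad_reference(g = 10, rho = 0.4, m = 0.01, h0 = 0.65,
                                map = map, N = 500, reps = 10, seed = 61)
  w <- ref$windows
  cfrac <- (1 - exp(-2 * w$dist_cm / 100)) / 2
  low <- mean(expected_lad(cfrac, 10, 0, 0.01, 0.65))
  high <- mean(expected_lad(cfrac, 10, 0.4, 0.01, 0.65))
  slack <- 3 * ref$se_mean_lad
  expect_gt(ref$mean_lad, low - slack)
  expect_lt(ref$mean_lad, high + slack)
})

test_that("generation-to-year conversion uses the 20-30 year range", {
  expect_equal(generations_to_years(0, 2010)$point, 2010)
  g10 <- generations_to_years(10, 2010)
  expect_equal(g10$point, 1760)
  expect_equal(g10$interval, c(1710, 1810))
  expect_equal(generations_to_years(20, 2010)$point, 1510)
})
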