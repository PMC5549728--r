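kbt_phys <- 0.0083144626 * 310

test_that("thermal-unit conversions reproduce the printed worked examples", {
  th <- thermo_params()  # arithmetic convention, 2.5 kJ/mol
  expect_equal(th$kbt, 2.5)
  expect_equal(as.numeric(to_kbt(-22, th)), -8.8)
  expect_equal(as.numeric(to_kbt(-33, th)), -13.2)
  expect_equal(as.numeric(to_kbt(-33, th)) - as.numeric(to_kbt(-22, th)), -4.4)
  expect_equal(as.numeric(to_kbt(0, th)), 0)
  # the physical convention differs and is recorded
  thp <- thermo_params(convention = "physical")
  expect_equal(thp$kbt, kbt_phys)
  expect_equal(attr(to_kbt(-22, thp), "kbt"), kbt_phys)
})

test_that("preference factors follow Boltzmann weighting with inverse symmetry", {
  th <- thermo_params()
  pf <- preference_factor(-33, -22, th)
  expect_equal(pf, exp(11 / 2.5))
  expect_equal(round(pf, 2), 81.45)
  expect_equal(round(pf / 10) * 10, 80)  # nearest ten
  expect_equal(preference_factor(-10, -10, th), 1)
  expect_equal(preference_factor(-33, -22, th) * preference_factor(-22, -33, th),
               1)
  expect_error(preference_factor(NA, -22, th), "finite")
})

test_that("umbrella window files round-trip", {
  w <- umbrella_window(1.5, 500, rnorm(100, 1.5, 0.07), temperature = 310)
  f <- tempfile()
  write_umbrella_window(w, f)
  w2 <- read_umbrella_window(f)
  expect_equal(w2$center, 1.5)
  expect_equal(w2$k, 500)
  expect_equal(w2$temperature, 310)
  expect_equal(w2$xi, w$xi, tolerance = 1e-12)
  expect_error(umbrella_window(1, 500, numeric(0)), "no samples")
  expect_error(umbrella_window(1, -1, 1), ">= 0")
})

test_that("WHAM on one unbiased window recovers -kT log p of a known density", {
  # bimodal mixture with known density
  set.seed(5)
  n <- 4e4
  comp <- runif(n) < 0.3
  x <- ifelse(comp, rnorm(n, 1.0, 0.12), rnorm(n, 2.0, 0.25))
  dens <- function(g) 0.3 * dnorm(g, 1.0, 0.12) + 0.7 * dnorm(g, 2.0, 0.25)
  win <- umbrella_window(0, 0, x, temperature = 310)
  pmf <- wham(list(win), bins = 60, n_boot = 0)
  keep <- is.finite(pmf$G) & dens(pmf$xi) > 0.15
  want <- -kbt_phys * log(dens(pmf$xi[keep]))
  got <- pmf$G[keep]
  # agreement up to an additive constant
  resid <- got - want
  expect_lt(sd(resid), 0.15)
})

test_that("WHAM cancels a harmonic bias exactly sampled from the biased density", {
  set.seed(6)
  k <- 400
  sigma <- sqrt(kbt_phys / k)
  win <- umbrella_window(1.5, k, rnorm(5e4, 1.5, sigma), temperature = 310)
  pmf <- wham(list(win), bins = 50, n_boot = 0)
  core <- abs(pmf$xi - 1.5) < 2 * sigma & is.finite(pmf$G)
  expect_lt(sd(pmf$G[core]), 0.2)
})

test_that("uniform unbiased samples give a flat profile", {
  set.seed(7)
  win <- umbrella_window(0, 0, runif(4e4, 1, 3), temperature = 310)
  pmf <- wham(list(win), bins = 40, n_boot = 0)
  expect_lt(sd(pmf$G[is.finite(pmf$G)]), 0.2)
})

test_that("WHAM rejects non-overlapping windows and reports non-convergence", {
  w1 <- umbrella_window(1, 500, rnorm(500, 1, 0.05), 310)
  w2 <- umbrella_window(3, 500, rnorm(500, 3, 0.05), 310)
  expect_error(wham(list(w1, w2)), "coverage gap")
  w3 <- umbrella_window(1.15, 500, rnorm(500, 1.15, 0.05), 310)
  expect_error(wham(list(w1, w3), max_iter = 2, tol = 1e-12),
               "did not converge")
})

test_that("WHAM is invariant to window order and covariant under translation", {
  set.seed(8)
  k <- 300; sd <- sqrt(kbt_phys / k)
  wins <- lapply(seq(1, 2, by = 0.1), function(c0)
    umbrella_window(c0, k, rnorm(3000, c0, sd), 310))
  g1 <- wham(wins, bins = 80, n_boot = 0)
  g2 <- wham(rev(wins), bins = 80, n_boot = 0)
  expect_equal(g1$G, g2$G, tolerance = 1e-8)
  # translate all samples and centres by a constant
  delta <- 0.73
  wins_t <- lapply(wins, function(w)
    umbrella_window(w$center + delta, w$k, w$xi + delta, 310))
  g3 <- wham(wins_t, bins = 80, n_boot = 0, grid = g1$xi + delta,
             bulk_region = attr(g1, "bulk_region") + delta)
  expect_equal(g3$G, g1$G, tolerance = 1e-8)
})

test_that("profile anchoring zeroes the bulk mean and dG_min measures well depth", {
  xi <- seq(0, 4, length.out = 200)
  G <- -10 * exp(-(xi - 1)^2 / (2 * 0.15^2))  # single -10 kJ/mol well
  pmf <- pmf_profile(xi, G + 3.7)             # arbitrary offset is removed
  expect_equal(mean(pmf$G[bulk_index(pmf)]), 0, tolerance = 1e-12)
  expect_equal(delta_g_min(pmf), -10, tolerance = 0.01)
  flat <- pmf_profile(xi, rep(2, 200))
  expect_equal(delta_g_min(flat), 0)
  expect_error(pmf_profile(xi, G, bulk_region = c(10, 12)), "outside the grid")
})

test_that("population free energy matches closed forms", {
  # flat profile with the partition at the midpoint: equal integrals
  xi <- seq(0, 2, length.out = 401)
  flat <- pmf_profile(xi, rep(0, 401), temperature = 310)
  expect_equal(delta_g_population(flat, xi_star = 1), 0, tolerance = 0.02)
  # square well depth G0 width w against bulk width W
  G0 <- 12; wwell <- 0.25
  G <- ifelse(xi < wwell, -G0, 0)
  sq <- pmf_profile(xi, G, temperature = 310, bulk_region = c(1, 2))
  got <- delta_g_population(sq, xi_star = wwell)
  W <- max(xi) - wwell
  want <- -kbt_phys * log(wwell * exp(G0 / kbt_phys) / W)
  # trapezoid at the discontinuity contributes one half-bin
  expect_equal(got, want, tolerance = 0.05)
  expect_error(delta_g_population(sq, xi_star = 5), "inside the grid")
})

test_that("population preference is compressed relative to point-minimum preference", {
  # deep narrow well vs shallow wide well: entropy favours the wide one
  xi <- seq(0, 3, length.out = 601)
  deep <- pmf_profile(xi, ifelse(xi < 0.1, -20, 0), temperature = 310,
                      bulk_region = c(2, 3))
  wide <- pmf_profile(xi, ifelse(xi < 1.0, -12, 0), temperature = 310,
                      bulk_region = c(2, 3))
  th <- thermo_params(convention = "physical")
  point_pref <- preference_factor(delta_g_min(deep), delta_g_min(wide), th)
  pop_pref <- preference_factor(delta_g_population(deep, 1.5),
                                delta_g_population(wide, 1.5), th)
  expect_gt(point_pref, pop_pref)
  expect_gt(pop_pref, 0)
})

test_that("population free energy approaches the point minimum for deep narrow wells", {
  xi <- seq(0, 3, length.out = 3001)
  wwell <- 0.02; G0 <- 35
  # analytic square-well population limit: -G0 - kT log(w/W) -> -G0 dominates
  G <- ifelse(xi < wwell, -G0, 0)
  pmf <- pmf_profile(xi, G, temperature = 310, bulk_region = c(2, 3))
  dpop <- delta_g_population(pmf, xi_star = 0.05)
  expect_equal(dpop, delta_g_min(pmf) - kbt_phys * log(wwell / (3 - 0.05)),
               tolerance = 0.2)
})

test_that("binned WHAM matches the independent binless estimator on a 5-window toy", {
  set.seed(9)
  k <- 500; sd <- sqrt(kbt_phys / k)
  centers <- seq(1, 1.8, by = 0.2)
  wins <- lapply(centers, function(c0)
    umbrella_window(c0, k, rnorm(4000, c0, sd), 310))
  pmf <- wham(wins, bins = 80, n_boot = 0)
  core <- pmf$xi >= min(centers) & pmf$xi <= max(centers)
  oracle <- oracle_wham(wins, pmf$xi, kbt_phys)
  resid <- (pmf$G - oracle)[core]
  resid <- resid - mean(resid, na.rm = TRUE)
  expect_lt(max(abs(resid), na.rm = TRUE), 0.1)
})
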