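test_that("noiseless enthalpy curves are recovered exactly", {
  cu <- generate_synthetic_itc(gamma = 3.2e-3, e_int = -300,
                               temperatures = c(278, 288, 298, 308, 318),
                               sigma = 0)
  fit <- fit_enthalpy_vs_temperature(cu)
  expect_equal(fit$gamma, 3.2e-3, tolerance = 1e-10)
  expect_equal(fit$e_int, -300, tolerance = 1e-8)
  # implied heat capacity at 310 K
  expect_equal(delta_cp(fit, 310), -1.984, tolerance = 1e-9)
  expect_lt(delta_cp(fit, 298), 0)
  expect_error(fit_enthalpy_vs_temperature(itc_curve(c(280, 290), c(1, 2))),
               "3 distinct")
})

test_that("noisy enthalpy fits recover the truth within two standard errors", {
  gammas <- numeric(200); ses <- numeric(200)
  for (r in 1:200) {
    cu <- generate_synthetic_itc(gamma = 3.2e-3, e_int = -300, sigma = 2,
                                 rng_seed = r)
    fit <- fit_enthalpy_vs_temperature(cu)
    gammas[r] <- fit$gamma; ses[r] <- fit$se_gamma
  }
  se_mean <- sd(gammas) / sqrt(length(gammas))
  expect_lt(abs(mean(gammas) - 3.2e-3), 2 * se_mean)
  # reported standard errors are consistent with the replicate spread
  expect_lt(abs(mean(ses) / sd(gammas) - 1), 0.3)
})

test_that("isodesmic fraction has the exact closed-form values and limits", {
  # x = K [M]_T = 1:  y = (3 - sqrt(5)) / 2
  rt <- GAS_CONSTANT_KJ * 298.15
  expect_equal(isodesmic_fraction(0, 0, 0, total_conc = 1,
                                  temperature = 298.15),
               (3 - sqrt(5)) / 2, tolerance = 1e-12)
  # x = 100 (dG0 chosen so K = 100 at [M]_T = 1)
  dg <- -rt * log(100)
  expect_equal(isodesmic_fraction(dg, 0, 0, 1, 298.15), 0.0090488,
               tolerance = 1e-5)
  # strongly unfavourable polymerisation: all monomer
  expect_equal(isodesmic_fraction(50, 0, 0, 1e-5, 298.15), 1)
  # y is non-decreasing in the denaturant concentration (m > 0)
  y <- isodesmic_fraction(-37.5, 1.5, seq(0, 8, 0.25), 10e-6, 298.15)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y > 0 & y <= 1))
})

test_that("noiseless depolymerisation curves are recovered exactly", {
  cu <- generate_synthetic_depoly(delta_g0 = -37.5, m_value = 1.5,
                                  total_conc = 10e-6, sigma = 0)
  fit <- fit_isodesmic(cu)
  expect_equal(fit$delta_g0, -37.5, tolerance = 1e-6)
  expect_equal(fit$m_value, 1.5, tolerance = 1e-6)
  # fitted curve is monotone in the denaturant
  expect_true(all(diff(fit$fitted[order(cu$denaturant)]) >= -1e-10))
  flat <- depoly_curve(seq(0, 8, length.out = 10), rep(0.99, 10), 1e-5)
  expect_error(fit_isodesmic(flat), "transition")
})

test_that("noisy depolymerisation fits have small parameter bias", {
  dgs <- numeric(200)
  for (r in 1:200) {
    cu <- generate_synthetic_depoly(delta_g0 = -37.5, m_value = 1.5,
                                    total_conc = 10e-6, sigma = 0.02,
                                    rng_seed = r)
    dgs[r] <- fit_isodesmic(cu)$delta_g0
  }
  expect_lt(abs(mean(dgs) - (-37.5)), 0.5)
})

test_that("hydrophobic areas sum the table over the hydrophobic set", {
  expect_equal(hydrophobic_area("TSTNQ"), 0)
  expect_equal(hydrophobic_area("FF", area_table = c(F = 210)), 420)
  # GNNQQNY: only the tyrosine is hydrophobic
  tab <- max_asa_table()
  expect_equal(hydrophobic_area("GNNQQNY"), unname(tab["Y"]))
  expect_error(hydrophobic_area("FBF", area_table = c(F = 1)), "position 2")
})

test_that("the gamma-area regression recovers through-origin slopes", {
  tab <- max_asa_table()
  a_h <- c(400, 900, 1500, 2300, 3100, 5000)
  rec <- data.frame(a_h = a_h, gamma = 1.42e-6 * a_h)
  fit <- fit_gamma_vs_area(rec)
  expect_equal(fit$slope, 1.42e-6, tolerance = 1e-12)
  # one-point through-origin fit
  one <- fit_gamma_vs_area(data.frame(a_h = 1000, gamma = 1.42e-3))
  expect_equal(one$slope, 1.42e-6, tolerance = 1e-12)
  expect_error(fit_gamma_vs_area(data.frame(a_h = 0, gamma = 1)), "zero")
  # 10% relative noise, 200 replicates: mean slope within 2 SE of the truth
  set.seed(9)
  slopes <- replicate(200, {
    noisy <- transform(rec, gamma = gamma * (1 + rnorm(6, 0, 0.1)))
    fit_gamma_vs_area(noisy)$slope
  })
  expect_lt(abs(mean(slopes) - 1.42e-6),
            2 * sd(slopes) / sqrt(length(slopes)))
})

test_that("synthetic generators are deterministic and exact at zero noise", {
  a <- generate_synthetic_itc(sigma = 1, rng_seed = 5)
  b <- generate_synthetic_itc(sigma = 1, rng_seed = 5)
  expect_identical(a, b)
  c2 <- generate_synthetic_itc(sigma = 1, rng_seed = 6)
  expect_false(identical(a$delta_h, c2$delta_h))
  exact <- generate_synthetic_itc(gamma = 2e-3, e_int = -100, sigma = 0)
  expect_equal(exact$delta_h,
               2e-3 * (343.15^2 - exact$temperature^2) - 100)
  d <- generate_synthetic_depoly(sigma = 0, rng_seed = 1)
  expect_equal(d$fraction_monomer,
               isodesmic_fraction(-37.5, 1.5, d$denaturant, 10e-6, 298.15))
})

test_that("crossover of a fitted enthalpy marks the endothermic regime", {
  cu <- generate_synthetic_itc(gamma = 3.2e-3, e_int = -300, sigma = 0)
  fit <- fit_enthalpy_vs_temperature(cu)
  tx <- crossover_temperature(elongation_params(fit$gamma, fit$e_int,
                                                fit$t0))
  # the fitted dH changes sign at tx: endothermic below, exothermic above
  dh <- function(T) fit$gamma * (fit$t0^2 - T^2) + fit$e_int
  expect_gt(dh(tx - 1), 0)
  expect_lt(dh(tx + 1), 0)
})
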