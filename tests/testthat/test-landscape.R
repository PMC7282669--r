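test_that("state classification follows the contact thresholds", {
  expect_equal(as.character(classify_state(0, 0)), "monomeric")
  expect_equal(as.character(classify_state(1, 0.2)), "monomeric")
  expect_equal(as.character(classify_state(21, 1)), "fully_aggregated")
  expect_equal(as.character(classify_state(20, 19 / 21)), "fibrillar")
  expect_equal(as.character(classify_state(10, 0.2)), "amorphous")
  # vectorised over sample frames, thresholds configurable
  df <- data.frame(c_ext = c(0, 21, 5), native_fraction = c(0, 1, 0.5))
  expect_equal(as.character(classify_state(df)),
               c("monomeric", "fully_aggregated", "amorphous"))
  th <- state_thresholds(mono_max_cext = 0, fib_native_fraction = 2 / 3,
                         full_cext = 3)
  expect_equal(as.character(classify_state(2, 2 / 3, th)), "fibrillar")
})

test_that("free-energy landscapes are -T log P shifted to zero", {
  # two-bin synthetic histogram: counts 900 / 100 at T = 0.3
  df <- data.frame(temperature = 0.3,
                   c_ext = rep(c(0, 10), c(900, 100)),
                   c_h_exposed = rep(c(6, 0), c(900, 100)))
  fl <- free_energy_landscape(df, t = 0.3)
  expect_equal(nrow(fl), 2L)
  expect_equal(min(fl$free_energy), 0)
  expect_equal(max(fl$free_energy), -0.3 * log(100 / 900),
               tolerance = 1e-12)
  # uniform visitation: flat landscape
  dfu <- data.frame(temperature = 0.2, c_ext = rep(1:4, each = 25),
                    c_h_exposed = 0)
  expect_true(all(free_energy_landscape(dfu, t = 0.2)$free_energy == 0))
  expect_error(free_energy_landscape(df, t = 0.9), "no samples")
})

test_that("elongation curves recover known weights from a synthetic stream", {
  set.seed(1)
  n <- 4000
  p_fib <- 0.8
  fib <- runif(n) < p_fib
  df <- data.frame(temperature = 0.3, sweep = seq_len(n),
                   c_ext = ifelse(fib, 21, 0),
                   native_fraction = ifelse(fib, 1, 0),
                   e_est = ifelse(fib, -30, -10))
  cu <- elongation_curves(df, min_visits = 50)
  expect_true(cu$sampled)
  expect_equal(cu$delta_g, -0.3 * log(sum(fib) / sum(!fib)),
               tolerance = 1e-12)
  expect_equal(cu$delta_e, -20)
  expect_equal(cu$delta_g, cu$delta_e + cu$minus_t_delta_s)
  # a temperature with a one-sided basin is flagged, not interpolated
  df2 <- df
  df2$c_ext <- 21; df2$native_fraction <- 1
  cu2 <- elongation_curves(rbind(df, transform(df2, temperature = 0.4)),
                           min_visits = 50)
  expect_false(cu2$sampled[cu2$temperature == 0.4])
  expect_true(is.na(cu2$delta_g[cu2$temperature == 0.4]))
})

test_that("visitation free energies match partition-function ratios on a toy", {
  sys <- toy_system()
  tb <- default_tables()
  hp <- hydrophobic_params(20)
  th <- state_thresholds(mono_max_cext = 0, fib_native_fraction = 2 / 3,
                         full_cext = 3)
  en <- enumerate_states(sys, tb, hp)
  asserted <- 0L
  for (tt in c(0.45, 0.5, 0.55)) {
    ep <- enum_probabilities(en, hp, tt)
    p_fib <- sum(ep$prob[ep$native_contacts >= 2])
    p_mono <- sum(ep$prob[ep$c_ext == 0])
    if (p_fib < 0.01 || p_mono < 0.01) next
    dg_exact <- -tt * log(p_fib / p_mono)
    run <- cached_run(sprintf("toy-dg-%g", tt), function()
      run_elongation(sys, tb, hp,
                     mc_config(temperatures = tt, sweeps = 150000,
                               equilibration_sweeps = 10000,
                               sample_interval = 4, rng_seed = 8,
                               replica_exchange = FALSE,
                               move_weights = no_seed_moves()),
                     init = "current"))
    cu <- elongation_curves(run, thresholds = th, min_visits = 20)
    if (!isTRUE(cu$sampled)) next
    # 3-sigma against the exact ratio, block errors from the stream
    expect_lt(abs(cu$delta_g - dg_exact), 3 * cu$se_delta_g + 0.02)
    asserted <- asserted + 1L
  }
  expect_gte(asserted, 1L)
})

test_that("heat capacity is the centred slope of the enthalpy curve", {
  gamma <- 240
  tt <- seq(0.2, 0.5, by = 0.025)
  cu <- data.frame(temperature = tt,
                   delta_e = gamma * (0.4^2 - tt^2) - 24,
                   se_delta_e = 0.1)
  hc <- heat_capacity(cu)
  # central differences are exact for a quadratic: slope -2 gamma T
  expect_equal(hc$delta_cp, -2 * gamma * hc$temperature, tolerance = 1e-9)
  expect_true(all(hc$delta_cp < 0))
  hc0 <- heat_capacity(data.frame(temperature = tt, delta_e = 5))
  expect_true(all(hc0$delta_cp == 0))
  expect_error(heat_capacity(data.frame(temperature = c(0.2, 0.3),
                                        delta_e = c(1, 2))), "3 sampled")
})

test_that("state diagrams record modal states and flag thin cells", {
  df <- data.frame(temperature = rep(c(0.2, 0.4), each = 30),
                   c_ext = rep(c(21, 0), each = 30),
                   native_fraction = rep(c(1, 0), each = 30),
                   e_est = 0)
  run <- structure(list(samples = df), class = "mc_samples")
  sw <- structure(list(run), param = "alpha", values = 60,
                  class = "mc_sweep")
  sd <- state_diagram(sw, min_samples = 10)
  expect_equal(nrow(sd), 2L)
  expect_equal(sd$state, c("fully_aggregated", "monomeric"))
  expect_true(all(sd$sampled))
  sd2 <- state_diagram(sw, min_samples = 100)
  expect_false(any(sd2$sampled))
})
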