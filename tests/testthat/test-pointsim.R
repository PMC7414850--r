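# Single-compartment dynamic model: event trains, gating, Euler stepping,
# chloride-load and activity scenarios.

test_that("poisson_train is reproducible, rate-faithful and validated", {
  expect_identical(poisson_train(0, 1000, 0.1, seed = 1),
                   rep(0L, 10000))
  a <- poisson_train(50, 1e5, 0.1, seed = 7)
  b <- poisson_train(50, 1e5, 0.1, seed = 7)
  expect_identical(a, b)
  # 50 Hz for 100 s: binomial mean 5000, SD ~ 70.7
  expect_lt(abs(sum(a) - 5000), 3 * sqrt(5000 * (1 - 0.005)))
  expect_error(poisson_train(50, 100, dt = 100), "too coarse")
})

test_that("synaptic_step follows the printed Euler decay exactly", {
  g <- 1
  for (k in 1:250) g <- synaptic_step(g, 25, 0.1, 1, 0)
  expect_equal(g, (1 - 0.1 / 25)^250)
  expect_equal(synaptic_step(0.3, 25, 0.1, 1, 1), 0.3 * (1 - 0.004) + 1)
  expect_equal(synaptic_step(0, 25, 0.1, 0.5, 0), 0)
})

test_that("Morris-Lecar gating hits its midpoints and saturates", {
  sp <- spiking_params()
  g <- ml_gating(-40, sp)
  expect_equal(g$m_inf, 0.5)
  g <- ml_gating(-30, sp)
  expect_equal(g$w_inf, 0.5)
  expect_equal(g$tau_w, sp$tau_w_scale)
  expect_equal(ml_gating(500, sp)$m_inf, 1, tolerance = 1e-9)
  expect_equal(ml_gating(500, sp)$w_inf, 1, tolerance = 1e-9)
  # monotone-increasing K+ activation under the default |V4| convention
  v <- seq(-80, 20, 1)
  expect_true(all(diff(ml_gating(v, sp)$w_inf) > 0))
  # the literal printed form reverses it
  expect_true(all(diff(ml_gating(v, spiking_params(as_printed = TRUE))$w_inf)
                  < 0))
})

test_that("step_state conserves state when all pathways are silent", {
  prm <- point_params(kcc2 = kcc2_params(0),
                      spiking = spiking_params(g_na = 0, g_k = 0),
                      leak = leak_pump_params(g_leak_total = 0,
                                              pump_factor = 0))
  st <- point_state(v_m = -55, w = 0.2, cl_in = 8, k_out = 3)
  s2 <- step_state(st, prm, dt = 0.1)
  expect_equal(s2$cl_in, 8)       # no Cl pathway at all
  expect_equal(s2$k_out, 3)
  expect_equal(s2$v_m, -55)       # no conductance: V frozen
})

test_that("with conductances present V relaxes to the leak potential", {
  prm <- point_params(kcc2 = kcc2_params(0),
                      spiking = spiking_params(g_na = 0, g_k = 0))
  st <- initial_state(prm)
  st$v_m <- -50
  for (i in 1:5000) st <- step_state(st, prm, 0.1)
  expect_equal(st$v_m, prm$leak$e_leak, tolerance = 0.05)
  expect_equal(st$cl_in, 5)       # no GABA permeability: Cl conserved
})

test_that("a single Euler step matches an independent hand evaluation", {
  prm <- point_params()
  pp <- prm$pp
  st <- point_state(v_m = -60, w = 0.15, cl_in = 6, k_out = 3.2,
                    g_inh = 0.8, g_exc = 0.4)
  out <- step_state(st, prm, dt = 0.1, events = c(inh = 1, exc = 0))
  # independent spreadsheet-style evaluation of every printed equation
  rtf <- 25.69259
  gi <- 0.8 * (1 - 0.1 / 25) + 1
  ge <- 0.4 * (1 - 0.1 / 15)
  ek <- rtf * log(3.2 / 120)
  u <- -60 / rtf
  pcl <- gi * pp$p_per_ns
  icl <- pcl * 96485.33212 * u * (6 - 120 * exp(u)) / (1 - exp(u)) * 1e12
  ihc <- 0.25 * pcl * 96485.33212 * u * (15 - 30 * exp(u)) / (1 - exp(u)) * 1e12
  m <- (1 + tanh((-60 + 40) / 18)) / 2
  ina <- 2 * m * (-60 - 60)
  ikv <- 8 * 0.15 * (-60 - ek)
  il <- 1.2 * (-60 + 65)
  iexc <- ge * (-60 - 0)
  vn <- -60 - 0.1 * (il + ina + ikv + iexc + icl + ihc) / pp$c_m
  winf <- (1 + tanh((-60 + 30) / 30)) / 2
  tw <- 25 / cosh((-60 + 30) / 60)
  wn <- 0.15 + 0.1 * (winf - 0.15) / tw
  j <- 10 * ((6 - 3.2) / 12) / (1 + (6 - 3.2) / 12)
  cln <- 6 + 0.1e-3 * (icl * 1e6 / (96485.33212 * pp$vol) - j * pp$surf / pp$vol)
  ilk <- 0.96 * (-60 - ek)
  ipump <- -1.5 * abs(0.96 * (-65 - rtf * log(3 / 120)))
  kon <- 3.2 + 0.1e-3 * ((ilk + ikv + ipump) * 1e6 /
                           (96485.33212 * pp$vol / 5) +
                           j * pp$surf / (pp$vol / 5)) +
    0.1 * (3 - 3.2) / 200
  expect_equal(out$v_m, vn, tolerance = 1e-6)
  expect_equal(out$w, wn, tolerance = 1e-8)
  expect_equal(out$cl_in, cln, tolerance = 1e-8)
  expect_equal(out$k_out, kon, tolerance = 1e-8)
  expect_equal(out$g_inh, gi)
  expect_equal(out$g_exc, ge)
})

test_that("simulation loop and step_state agree step for step", {
  prm <- point_params(synaptic = synaptic_params(20, 40))
  n <- 400
  set.seed(9)
  evi <- stats::runif(n) < 20 * 1e-4
  eve <- stats::runif(n) < 40 * 1e-4
  st <- initial_state(prm)
  for (k in seq_len(n))
    st <- step_state(st, prm, 0.1, c(inh = evi[k], exc = eve[k]))
  sim <- sdhcl:::.run_point(prm, n * 0.1 / 1000, 0.1, seed = 9,
                            p_i = 20 * 1e-4, p_e = 40 * 1e-4,
                            sample_ms = n * 0.1)
  last <- sim$series[nrow(sim$series), ]
  expect_identical(st$v_m, last$v_m)
  expect_identical(st$cl_in, last$cl_in)
  expect_identical(st$w, last$w)
  expect_identical(st$k_out, last$k_out)
})

test_that("[K+]_o relaxes to rest with tau_K = 200 ms when K currents are off", {
  prm <- point_params(spiking = spiking_params(g_k = 0),
                      leak = leak_pump_params(k_fraction = 0,
                                              pump_factor = 0),
                      kcc2 = kcc2_params(0))
  st <- point_state(v_m = -65, w = 0, cl_in = 5, k_out = 5)
  for (i in 1:1000) st <- step_state(st, prm, 0.1)  # 100 ms
  expect_equal(st$k_out, 3 + 2 * exp(-100 / 200), tolerance = 0.005)
})

test_that("chloride load under clamp reaches passive equilibrium without KCC2", {
  prm <- point_params(kcc2 = kcc2_params(0))
  res <- simulate_gaba_load(prm, hold_v = -70, duration_s = 90)
  expect_true(res$summary$converged)
  expect_equal(res$summary$e_cl, -70, tolerance = 0.1)
  expect_equal(res$summary$cl_in, 120 * exp(-70 / 25.693), tolerance = 0.05)
  # magnitude of the initial net current equals the calibration target
  expect_equal(abs(res$series$i_net[1]), 10, tolerance = 0.2)
  # the Cl component is much larger than the net current
  expect_gt(abs(res$series$i_cl[1]), 3 * abs(res$series$i_net[1]))
})

test_that("blocking extrusion depolarizes the steady chloride reversal", {
  ctr <- simulate_gaba_load(point_params(kcc2 = kcc2_params(10)),
                            duration_s = 90)
  blk <- simulate_gaba_load(point_params(kcc2 = kcc2_params(0)),
                            duration_s = 90)
  expect_gt(blk$summary$e_cl - ctr$summary$e_cl, 0)
})

test_that("halving dt changes the steady chloride by far less than 1%", {
  a <- simulate_gaba_load(point_params(kcc2 = kcc2_params(10)),
                          duration_s = 60, dt = 0.2)
  b <- simulate_gaba_load(point_params(kcc2 = kcc2_params(10)),
                          duration_s = 60, dt = 0.1)
  expect_lt(abs(a$summary$cl_in - b$summary$cl_in) / b$summary$cl_in, 0.01)
})

test_that("with zero drive chloride settles at the transporter null point", {
  prm <- point_params(synaptic = synaptic_params(0, 0),
                      kcc2 = kcc2_params(10))
  res <- simulate_activity(prm, duration_s = 20, seed = 3)
  expect_equal(res$summary$cl_in, res$summary$k_out, tolerance = 0.05)
})

test_that("steady chloride is non-decreasing in excitatory drive", {
  sc <- 0.002   # weak-extrusion regime where drive matters
  cl <- vapply(c(0, 10, 50), function(fe) {
    simulate_activity(point_params(synaptic = synaptic_params(2, fe),
                                   kcc2 = kcc2_params(10),
                                   extrusion_scale = sc),
                      duration_s = 30, seed = 11)$summary$cl_in
  }, numeric(1))
  expect_true(all(diff(cl) > 0))
})

test_that("spiking needs excitatory drive", {
  hi <- simulate_activity(point_params(synaptic = synaptic_params(5, 50)),
                          duration_s = 10, seed = 2)
  lo <- simulate_activity(point_params(synaptic = synaptic_params(5, 0)),
                          duration_s = 10, seed = 2)
  expect_gt(hi$summary$spike_rate, 0)
  expect_equal(lo$summary$spike_rate, 0)
})

test_that("identical seeds give bit-identical trajectories", {
  prm <- point_params(synaptic = synaptic_params(5, 20))
  a <- simulate_activity(prm, duration_s = 5, seed = 123)
  b <- simulate_activity(prm, duration_s = 5, seed = 123)
  expect_identical(a$series, b$series)
})

test_that("a zero-amplitude ramp reduces exactly to constant-rate activity", {
  prm <- point_params(synaptic = synaptic_params(1, 1))
  a <- simulate_capsaicin_ramp(prm, rest = c(1, 1), high = c(1, 1),
                               baseline_s = 2, ramp_s = 3, duration_s = 10,
                               seed = 5)
  b <- simulate_activity(prm, duration_s = 10, seed = 5)
  expect_identical(a$series$cl_in, b$series$cl_in)
  expect_identical(a$series$v_m, b$series$v_m)
})

test_that("the ramp plateau matches constant high-rate activity", {
  prm <- point_params(synaptic = synaptic_params(5, 50),
                      kcc2 = kcc2_params(10))
  for (seed in 1:3) {
    ramp <- simulate_capsaicin_ramp(prm, rest = c(1, 1), high = c(5, 50),
                                    baseline_s = 5, ramp_s = 10,
                                    duration_s = 45, seed = seed)
    const <- simulate_activity(prm, duration_s = 45, seed = seed + 100)
    expect_equal(ramp$summary$cl_in, const$summary$cl_in, tolerance = 0.15)
  }
})

test_that("chloride trends upward during a rising-drive ramp", {
  prm <- point_params(synaptic = synaptic_params(1, 1),
                      kcc2 = kcc2_params(10), extrusion_scale = 0.002)
  res <- simulate_capsaicin_ramp(prm, baseline_s = 5, ramp_s = 20,
                                 duration_s = 60, seed = 8,
                                 init = initial_state(prm, cl_in = 5.5))
  s <- res$series
  thirds <- cut(s$time_ms, 3, labels = FALSE)
  m <- tapply(s$cl_in, thirds, mean)
  expect_true(all(diff(m) > 0))
})

test_that("the extrusion-scale calibration balances influx at the target", {
  sc <- calibrate_extrusion_scale(point_params(), vmax_ref = 10,
                                  target_cl = 5.5, duration_s = 10, seed = 1)
  expect_gt(sc, 1e-4)
  expect_lt(sc, 0.1)
  # at the calibrated scale, resting chloride stays near the target
  prm <- point_params(kcc2 = kcc2_params(10), extrusion_scale = sc)
  res <- simulate_activity(prm, duration_s = 60, seed = 4,
                           init = initial_state(prm, cl_in = 5.5))
  expect_equal(res$summary$cl_in, 5.5, tolerance = 0.5)
})
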