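test_that("stimulus, noise and config constructors validate their fields", {
  s <- stimulus_spec(targets = c(1, 4), phases = c(0, 3 * pi))
  expect_equal(s$phases, c(0, pi))
  expect_equal(s$f_ext, 11)
  expect_equal(s$c_ext, 0.5)
  expect_error(stimulus_spec(targets = c(2, 2)), "duplicate")
  n <- noise_spec()
  expect_equal(c(n$low, n$high), c(120, 320))
  expect_error(noise_spec(300, 100))
  expect_error(sim_config(transient = 10, duration = 5))
})

test_that("driver_signal follows the stated sinusoid and shift identity", {
  s <- stimulus_spec(targets = c(3, 5), f_ext = 11, c_ext = 0.5,
                     phases = c(0, pi / 2))
  expect_equal(driver_signal(0, s, 3), 0)
  expect_equal(driver_signal(0, s, 5), 0.5)
  expect_equal(driver_signal(0.2, s, 7), 0)  # non-target
  # phase dphi equals a time shift of dphi / (2 pi f)
  tt <- seq(0, 1, by = 1e-3)
  expect_equal(driver_signal(tt, s, 5),
               driver_signal(tt + (pi / 2) / (2 * pi * 11), s, 3))
})

test_that("history_init sizes the buffer from the maximum delay", {
  con <- make_motif("bi_2node", 160)
  h <- history_init(con, global_coupling(v = 2.6), sim_config())
  expect_equal(dim(h), c(62, 2))
  expect_true(all(h == 0))
  empty <- connectome(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(nrow(history_init(empty)), 0)
})

test_that("simulation is bit-reproducible and matches the pure-R reference", {
  con <- make_motif("chain_3node", 120)
  cfg <- sim_config(duration = 2, transient = 0.5, seed = 99)
  stim <- stimulus_spec(targets = c(1, 3), phases = c(0, pi / 3))
  a <- simulate(con, global_coupling(), stim, noise_spec(), cfg)
  b <- simulate(con, global_coupling(), stim, noise_spec(), cfg)
  expect_identical(a$V, b$V)
  r <- simulate_reference(con, global_coupling(), stim, noise_spec(), cfg)
  expect_equal(a$V, r$V, tolerance = 1e-12)
})

test_that("uncoupled network equals independent single-node runs and permutes", {
  # deterministic setting (no noise) so RNG interleaving plays no role
  con2 <- connectome(matrix(0, 2, 2), matrix(c(0, 50, 50, 0), 2, 2))
  cfg <- sim_config(duration = 3, transient = 1)
  stim <- stimulus_spec(targets = c(1, 2), phases = c(0, pi / 2))
  both <- simulate(con2, global_coupling(), stim, noise = NULL, cfg = cfg)
  con1 <- connectome(matrix(0, 1, 1), matrix(0, 1, 1))
  one_a <- simulate(con1, stim = stimulus_spec(1, phases = 0), cfg = cfg)
  one_b <- simulate(con1, stim = stimulus_spec(1, phases = pi / 2), cfg = cfg)
  expect_equal(unname(both$V[, 1]), unname(one_a$V[, 1]))
  expect_equal(unname(both$V[, 2]), unname(one_b$V[, 1]))
  # permuting node order permutes outputs exactly
  swapped <- simulate(con2, global_coupling(),
                      stimulus_spec(targets = c(2, 1), phases = c(0, pi / 2)),
                      noise = NULL, cfg = cfg)
  expect_equal(unname(swapped$V[, 2:1]), unname(both$V))
})

test_that("with the rate transform zeroed, all states decay to rest", {
  con <- make_motif("bi_2node", 100)
  cfg <- sim_config(duration = 1, transient = 0)
  ts <- simulate_reference(con, global_coupling(), stim = NULL, noise = NULL,
                           cfg = cfg, rate_fun = function(V, p) 0 * V)
  expect_true(all(abs(ts$V) == 0))  # rest stays rest for the linear system
  # and from a perturbed start the linear synapses are stable: drive with a
  # brief driver, then check the tail decays
  stim <- stimulus_spec(targets = 1, c_ext = 1)
  ts2 <- simulate_reference(con, global_coupling(), stim, noise = NULL,
                            cfg = sim_config(duration = 1, transient = 0),
                            rate_fun = function(V, p) 0 * V)
  # without any rate input the only signal is the driver itself on node 1
  expect_lt(max(abs(ts2$V[, 2])), 1e-12)
})

test_that("divergence is reported with the offending step", {
  # bounded rates make genuine blow-up unreachable; a non-finite driver
  # exercises the guard
  con <- make_motif("bi_2node", 100)
  expect_error(
    simulate(con, global_coupling(), stimulus_spec(1, c_ext = Inf),
             noise = NULL, cfg = sim_config(duration = 1, transient = 0)),
    "diverged")
})

test_that("a noise-driven node stays in the stated input equilibrium band", {
  con1 <- connectome(matrix(0, 1, 1), matrix(0, 1, 1))
  ts <- simulate(con1, cfg = sim_config(duration = 20, transient = 5, seed = 2),
                 noise = noise_spec())
  # e2p equilibrium band for u in [120, 320] is H tau u in [3.9, 10.4] mV;
  # V_pyr = v_e2p - v_i2p fluctuates around it, mean well inside
  expect_gt(mean(ts$V[, 1]), 3.9)
  expect_lt(mean(ts$V[, 1]), 10.4)
})
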