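test_that("zero drive is a fixed point: no charging, no events", {
  run <- run_rset(homog_ensemble(4), input = 0,
                  sim_config(duration = 100, seed = 1, record_traces = TRUE))
  expect_equal(nrow(run$events), 0)
  expect_true(all(run$traces$V == 0))
  expect_equal(sum(lengths(run$spikes$times)), 0)
})

test_that("zero duration yields an empty spike train", {
  run <- run_rset(homog_ensemble(2), 120, sim_config(duration = 0, seed = 1))
  expect_equal(nrow(run$events), 0)
  expect_equal(run$spikes$duration, 0)
})

test_that("low-temperature inter-spike interval matches the closed-form period", {
  # oracle equivalence: stochastic engine vs deterministic_period at T -> 0
  dt <- 0.05
  ens <- homog_ensemble(1)
  run <- run_rset(ens, 120,
                  sim_config(duration = 800, dt = dt, temperature = 1e-3,
                             seed = 11))
  isi <- diff(run$spikes$times[[1]])
  expect_gt(length(isi), 30)
  oracle <- deterministic_period(120, rset_params())
  expect_lt(abs(mean(isi) - oracle), 2 * dt)
})

test_that("sub-threshold drive produces essentially no spikes", {
  run <- run_rset(homog_ensemble(64), 60, sim_config(duration = 600, seed = 3))
  expect_equal(nrow(run$events), 0)
})

test_that("runs are bit-reproducible under a fixed seed", {
  ens <- heterog_ensemble(16, seed = 2)
  cfg <- sim_config(duration = 200, seed = 99)
  a <- run_rset(ens, 120, cfg)
  b <- run_rset(ens, 120, cfg)
  expect_identical(a$events, b$events)
})

test_that("event log is well-formed", {
  ens <- heterog_ensemble(8, seed = 2)
  run <- run_rset(ens, 120, sim_config(duration = 400, seed = 5))
  expect_true(all(run$events$time > 0 & run$events$time <= 400))
  # per-member times strictly increasing
  expect_true(all(vapply(run$spikes$times,
                         function(x) !is.unsorted(x, strictly = TRUE),
                         logical(1))))
  # thermal smearing bound: events fire near or above threshold
  kTe <- thermal_energy(5) / E_CHARGE
  depth <- ens$V_th[run$events$member] - run$events$pre_potential
  expect_true(all(depth <= 10 * kTe))
  expect_gte(mean(depth <= 5 * kTe), 0.95)
})

test_that("node potential solves current conservation at the star point", {
  expect_equal(node_potential(100, c(0, 100), c(10, 10), 0), 100)
  expect_equal(node_potential(77, c(77, 77, 77), c(5, 10, 20), 3), 77)
  expect_equal(node_potential(100, c(0, 100), c(10, 10), 10), 200 / 3,
               tolerance = 1e-12)
  expect_error(node_potential(1, 0, 1, -1), "non-negative")
})

test_that("coupling strength is the dimensionless N r_c / mean(r)", {
  ens <- homog_ensemble(20)
  expect_equal(coupling_strength(0, ens), 0)
  expect_equal(coupling_strength(10, ens), 20)
  # linear in r_c, and coupling_resistance inverts it
  expect_equal(coupling_strength(4, ens), 2 * coupling_strength(2, ens))
  expect_equal(coupling_resistance(20, ens), 10)
  het <- heterog_ensemble(20, seed = 3)
  for (K in c(0, 1, 40)) {
    expect_equal(coupling_strength(coupling_resistance(K, het), het), K)
  }
})

test_that("r_c = 0 coupled run equals the uncoupled run bit-exactly", {
  ens <- heterog_ensemble(8, seed = 4)
  cfg <- sim_config(duration = 150, seed = 21)
  a <- run_rset(ens, 120, cfg, r_c = 0)
  b <- run_rset(ens, 120, cfg, r_c = function(t) rep(0, length(t)))
  expect_identical(a$events, b$events)
})

test_that("coupling slows the ensemble: node sags below the source", {
  ens <- homog_ensemble(8, seed = 1)
  cfg <- sim_config(duration = 150, seed = 33)
  free <- run_rset(ens, 120, cfg)
  coupled <- run_rset(ens, 120, cfg, r_c = 5)
  expect_lt(nrow(coupled$events), nrow(free$events))
})

test_that("ensemble spike rate is non-decreasing in the applied potential", {
  ens <- heterog_ensemble(16, seed = 6)
  volts <- c(60, 85, 110, 135, 160)
  means <- vapply(volts, function(V) {
    mean(vapply(1:20, function(r) {
      nrow(run_rset(ens, V, sim_config(duration = 30, seed = 100 * V + r))$events)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("binned spike counts use half-open bins and conserve totals", {
  empty <- make_train(list(numeric(0), numeric(0)), duration = 90)
  b0 <- bin_spike_counts(empty, 30)
  expect_equal(b0$counts, c(0, 0, 0))
  expect_false(b0$partial_last)

  # boundary spike at t = 30 falls in the second bin (half-open convention)
  tr <- make_train(list(c(30)), duration = 60)
  expect_equal(bin_spike_counts(tr, 30)$counts, c(0, 1))

  tr2 <- make_train(list(c(1, 29.9, 30, 45), c(10, 70)), duration = 70)
  b2 <- bin_spike_counts(tr2, 30)
  expect_equal(sum(b2$counts), 6)
  expect_equal(b2$counts, c(3, 2, 1))            # final partial bin retained
  expect_true(b2$partial_last)
  expect_equal(b2$centers, c(15, 45, 75))
  expect_error(bin_spike_counts(tr2, 0), "positive")
})

test_that("coarse steps and the kinetic-MC rule emit accuracy warnings", {
  ens <- homog_ensemble(2)
  expect_warning(
    run_rset(ens, 120, sim_config(duration = 10, dt = 1, seed = 1)),
    "coarser")
  # kinetic-MC decision rule reproduces oscillations too, with a firing lag
  run <- run_rset(ens, 120,
                  sim_config(duration = 300, temperature = 1e-3, seed = 2,
                             rule = "kmc"))
  isi <- unlist(lapply(run$spikes$times, diff))
  oracle <- deterministic_period(120, rset_params())
  expect_gt(mean(isi), oracle)          # finite tunnel resistance delays firing
  expect_lt(mean(isi), oracle + 1.5)    # but only by a sub-ns lag
})

test_that("traces are recorded on the requested stride", {
  run <- run_rset(homog_ensemble(3), 100,
                  sim_config(duration = 50, dt = 0.1, seed = 1,
                             record_traces = TRUE, trace_stride = 50))
  expect_equal(dim(run$traces$V), c(10, 3))
  expect_equal(run$traces$time, seq(5, 50, by = 5))
  # potentials stay below the drive and above the reset floor
  expect_true(all(run$traces$V < 100))
  expect_true(all(run$traces$V > -2 * DEFAULT_VTH))
})
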