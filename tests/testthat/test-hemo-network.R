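# Network data model and pulsatile solver

test_that("segment_resistance follows the Poiseuille closure", {
  blood <- blood_properties()
  # hand evaluation: 8*0.004*0.05 / (pi * (2e-3)^4)
  expect_equal(segment_resistance(0.05, 2e-3, blood), 3.183099e7,
               tolerance = 1e-6)
  # r^4 scaling
  r1 <- segment_resistance(0.1, 1e-3, blood)
  expect_equal(segment_resistance(0.1, 2e-3, blood), r1 / 16)
  expect_identical(segment_resistance(0, 2e-3, blood), 0)
  expect_error(segment_resistance(-0.1, 2e-3, blood),
               class = "cf_invalid_geometry")
  expect_error(segment_resistance(0.1, 0, blood),
               class = "cf_invalid_geometry")
})

test_that("stenosis_pressure_drop is odd with linear + turbulent terms", {
  el <- stenosis_element(1e8, 1e13, 1e-3, 5e-3)
  expect_identical(stenosis_pressure_drop(0, el), 0)
  # hand evaluation: 1e8*5e-6 + 1e13*(5e-6)^2 = 500 + 250
  expect_equal(stenosis_pressure_drop(5e-6, el), 750)
  expect_equal(stenosis_pressure_drop(-5e-6, el), -750)  # sign-preserving
  lin <- stenosis_element(1e8, 0, 1e-3, 5e-3)
  q <- c(1e-6, 2e-6, -3e-6)
  expect_equal(stenosis_pressure_drop(q, lin), 1e8 * q)
  expect_error(stenosis_element(1e8, 1e13, 5e-3, 5e-3),
               class = "cf_invalid_stenosis")
})

test_that("network validation rejects malformed graphs", {
  seg <- function(id, a, b) vessel_segment(id, a, b, 0.05, 0.002)
  expect_error(network_model(list(seg("a", "n1", "n2"), seg("a", "n2", "n3")),
                             "n1", c(O = "n3")),
               class = "cf_invalid_network")
  expect_error(network_model(list(seg("a", "n1", "n2")), "n1", c(O = "zz")),
               class = "cf_invalid_network")
  # disconnected component
  expect_error(network_model(list(seg("a", "n1", "n2"), seg("b", "x1", "x2")),
                             "n1", c(O = "n2", P = "x2")),
               class = "cf_invalid_network")
})

test_that("network JSON round-trips including stenosis blocks", {
  sten <- list(list(vessel = "RICA", min_frac = 0.3))
  net <- make_network("complete", seed = 3, stenoses = sten)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  net2 <- read_network_json(path)
  expect_equal(segment_table(net2), segment_table(net))
  expect_identical(net2$outlets, net$outlets)
  expect_identical(net2$neck_arteries, net$neck_arteries)
  expect_equal(net2$segments$RICA$stenosis$k_turb, net$segments$RICA$stenosis$k_turb)
})

test_that("steady inflow reproduces the closed-form series resistance", {
  net <- single_segment_net()
  wk <- windkessel_set(list(windkessel_bc("O", 1e7, 1e8, 1e-9)))
  q <- 5e-6
  res <- solve_transient(net, wk, steady_wave(q))
  r_seg <- net$segments$s$resistance
  expect_equal(mean(res$outlet_pressures), q * 1.1e8, tolerance = 1e-8)
  expect_equal(mean(res$node_pressures["in", ]), q * (r_seg + 1.1e8),
               tolerance = 1e-8)
  expect_equal(unname(outlet_mean_flows(res)), q, tolerance = 1e-8)
})

test_that("sinusoidal response matches the analytic Windkessel impedance", {
  net <- single_segment_net(resistance = 1)   # negligible upstream resistance
  rp <- 1e7; rd <- 1e8; cc <- 1e-9
  wk <- windkessel_set(list(windkessel_bc("O", rp, rd, cc)))
  w <- sine_wave(5e-6, 1e-6, n = 100)
  res <- solve_transient(net, wk, w,
                         solver_options(periodicity_tol = 1e-6, max_cycles = 60))
  om <- 2 * pi
  z <- rp + rd / (1 + 1i * om * rd * cc)
  p <- res$outlet_pressures[1, ]
  fit <- stats::lm(p ~ sin(om * res$times) + cos(om * res$times))
  amp <- sqrt(sum(stats::coef(fit)[2:3]^2))
  expect_equal(amp, 1e-6 * Mod(z), tolerance = 0.01)  # 1st-order time stepping
  expect_equal(mean(p), 5e-6 * (rp + rd), tolerance = 1e-4)
})

test_that("symmetric Y splits flow exactly in half at all times", {
  net <- y_network()
  res <- solve_transient(net, wk_pair(), sine_wave(5e-6, 2e-6))
  expect_lt(max(abs(res$seg_flows["a", ] - res$seg_flows["b", ])), 1e-18)
})

test_that("mass is conserved at every junction at every step", {
  net <- make_network("complete", seed = 1,
                      stenoses = list(list(vessel = "RICA", min_frac = 0.3)))
  inflow <- synthetic_aortic_inflow()
  res <- solve_transient(net, true_windkessel(inflow), inflow)
  # residual at each interior node: signed sum of segment flows
  nodes <- setdiff(net$nodes, c(net$inlet, unname(net$outlets)))
  q_in_scale <- max(abs(res$inflow))
  for (n in nodes) {
    resid <- 0
    for (s in net$segments) {
      if (s$from == n) resid <- resid - res$seg_flows[s$id, ]
      if (s$to == n) resid <- resid + res$seg_flows[s$id, ]
    }
    expect_lt(max(abs(resid)) / q_in_scale, 1e-10)
  }
  # Windkessel energy identity at periodicity: Pbar = Qbar * (Rp + Rd)
  qbar <- outlet_mean_flows(res)
  pbar <- outlet_mean_pressures(res)
  for (o in names(net$outlets)) {
    expect_equal(pbar[[o]], qbar[[o]] * wk_total(res$wk[[o]]), tolerance = 2e-3)
  }
})

test_that("constant inflow converges to the independent resistive solve", {
  net <- y_network(branch_r = c(0.002, 0.0015))
  wk <- wk_pair(rd = c(1e8, 1.6e8))
  q <- 6e-6
  res <- solve_transient(net, wk, steady_wave(q),
                         solver_options(periodicity_tol = 1e-6, max_cycles = 60))
  oracle <- steady_network_oracle(net, wk, q)
  expect_equal(outlet_mean_flows(res), oracle$outlet_flows, tolerance = 1e-6)
  for (n in c("in", "j")) {
    expect_equal(mean(res$node_pressures[n, ]), oracle$pressures[[n]],
                 tolerance = 1e-6)
  }
})

test_that("halving the time step changes outlet means by < 0.5%", {
  net <- y_network(branch_r = c(0.002, 0.0015))
  wk <- wk_pair()
  w <- sine_wave(5e-6, 3e-6)
  q1 <- outlet_mean_flows(solve_transient(net, wk, w, solver_options(dt = 1e-3)))
  q2 <- outlet_mean_flows(solve_transient(net, wk, w, solver_options(dt = 5e-4)))
  expect_lt(max(abs(q2 / q1 - 1)), 0.005)
})

test_that("check_periodicity reports the stored convergence state", {
  net <- single_segment_net()
  wk <- windkessel_set(list(windkessel_bc("O", 1e7, 1e8, 2e-9)))
  res <- solve_transient(net, wk, sine_wave(5e-6, 1e-6))
  expect_true(check_periodicity(res, tol = 1e-3))
  expect_false(check_periodicity(res, tol = 1e-12))
  one_cycle <- res
  one_cycle$cycles_run <- 1L
  one_cycle$periodicity_trace <- numeric(0)
  expect_error(check_periodicity(one_cycle), class = "cf_insufficient_data")
  # first passing cycle in the trace equals a brute-force scan
  trace <- res$periodicity_trace
  expect_identical(which(trace < 1e-3)[1], length(trace))
})

test_that("non-convergence raises a classed error with diagnostics", {
  net <- single_segment_net()
  wk <- windkessel_set(list(windkessel_bc("O", 1e7, 1e8, 5e-8)))  # RC >> period
  expect_error(
    solve_transient(net, wk, sine_wave(5e-6, 1e-6),
                    solver_options(periodicity_tol = 1e-9, max_cycles = 3)),
    class = "cf_convergence")
})
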