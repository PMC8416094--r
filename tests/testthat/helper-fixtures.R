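# Shared fixtures built in code. Networks are deliberately tiny so the
# solver-based tests stay fast; the full anatomy comes from make_network().

# one resistive segment feeding a single Windkessel outlet
single_segment_net <- function(resistance = NULL, inertance = 0) {
  seg <- vessel_segment("s", "in", "out", 0.1, 0.003,
                        resistance = resistance, inertance = inertance)
  network_model(list(seg), inlet = "in", outlets = c(O = "out"))
}

# symmetric (or not) Y bifurcation: trunk -> two branches
y_network <- function(branch_r = c(0.002, 0.002), inertance = NULL) {
  mk <- function(id, from, to, r) {
    vessel_segment(id, from, to, 0.05, r, inertance = inertance)
  }
  network_model(list(mk("trunk", "in", "j", 0.003),
                     mk("a", "j", "oa", branch_r[1]),
                     mk("b", "j", "ob", branch_r[2])),
                inlet = "in", outlets = c(A = "oa", B = "ob"))
}

wk_pair <- function(rp = 1e7, rd = 1e8, c = 1e-9, names = c("A", "B")) {
  rp <- rep_len(rp, length(names)); rd <- rep_len(rd, length(names))
  c <- rep_len(c, length(names))
  windkessel_set(lapply(seq_along(names), function(i) {
    windkessel_bc(names[i], rp[i], rd[i], c[i])
  }))
}

steady_wave <- function(q, period = 1, n = 100) {
  waveform(seq(0, period, length.out = n + 1)[1:n], rep(q, n), period = period)
}

sine_wave <- function(q0, amp, period = 1, n = 200) {
  t <- seq(0, period, length.out = n + 1)[1:n]
  waveform(t, q0 + amp * sin(2 * pi * t / period), period = period)
}

# hand-built steady "simulation" for supply-tracking oracles: constant flows
# satisfying junction mass balance, no solver involved
fake_sim_result <- function(net, seg_flows_steady, outlet_flows_steady,
                            n_steps = 10, period = 1) {
  ids <- names(net$segments)
  F <- matrix(rep(seg_flows_steady[ids], n_steps), nrow = length(ids),
              dimnames = list(ids, NULL))
  OQ <- matrix(rep(outlet_flows_steady[names(net$outlets)], n_steps),
               nrow = length(net$outlets),
               dimnames = list(names(net$outlets), NULL))
  structure(list(times = seq_len(n_steps) * period / n_steps,
                 dt = period / n_steps, period = period,
                 seg_flows = F, outlet_flows = OQ,
                 node_pressures = NULL, network = net,
                 cycles_run = 2L, periodicity_error = 0,
                 periodicity_trace = 0),
            class = "sim_result")
}

# diamond collateral fixture: two labeled inflows, a communicating segment,
# hand-solvable composition (RACA outlet: 2/3 RICA, 1/3 LICA)
diamond_fixture <- function() {
  mk <- function(id, from, to) vessel_segment(id, from, to, 0.02, 0.002,
                                              inertance = 0)
  net <- network_model(
    list(mk("Rtrunk", "in", "r0"), mk("Ltrunk", "in", "l0"),
         mk("RICA", "r0", "a"), mk("LICA", "l0", "b"),
         mk("AComA", "b", "a"),
         mk("RA2", "a", "oa"), mk("LA2", "b", "ob")),
    inlet = "in", outlets = c(RACA = "oa", LACA = "ob"),
    neck_arteries = c(RICA = "RICA", LICA = "LICA"))
  flows <- c(Rtrunk = 2e-6, Ltrunk = 4e-6, RICA = 2e-6, LICA = 4e-6,
             AComA = 1e-6, RA2 = 3e-6, LA2 = 3e-6)
  out <- c(RACA = 3e-6, LACA = 3e-6)
  list(net = net, sim = fake_sim_result(net, flows, out),
       truth_raca = c(RICA = 2 / 3, LICA = 1 / 3),
       truth_laca = c(RICA = 0, LICA = 1))
}

# independent steady resistive-network oracle: solve the nodal conductance
# system for constant inflow, Windkessel outlets collapsed to R_p + R_d
steady_network_oracle <- function(net, wk, q_in) {
  nodes <- net$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  A <- matrix(0, n, n)
  for (s in net$segments) {
    g <- 1 / (s$resistance + if (is.null(s$stenosis)) 0 else s$stenosis$k_linear)
    i <- idx[[s$from]]; j <- idx[[s$to]]
    A[i, i] <- A[i, i] + g; A[j, j] <- A[j, j] + g
    A[i, j] <- A[i, j] - g; A[j, i] <- A[j, i] - g
  }
  for (o in names(net$outlets)) {
    i <- idx[[net$outlets[[o]]]]
    A[i, i] <- A[i, i] + 1 / wk_total(wk[[o]])
  }
  b <- numeric(n)
  b[idx[[net$inlet]]] <- q_in
  p <- solve(A, b)
  names(p) <- nodes
  out_q <- vapply(names(net$outlets), function(o) {
    p[[net$outlets[[o]]]] / wk_total(wk[[o]])
  }, numeric(1))
  list(pressures = p, outlet_flows = out_q)
}

# rescale the Rp:Rd ratio of selected outlets, total held fixed (mirrors the
# stage-2 parameterization, written independently for oracle use)
apply_ratio_scale_for_test <- function(wk, s, outlets = c("RMCA", "LMCA")) {
  windkessel_set(lapply(names(wk), function(o) {
    bc <- wk[[o]]
    if (!o %in% outlets) return(bc)
    tot <- bc$r_prox + bc$r_dist
    rho <- (bc$r_prox / bc$r_dist) * s
    windkessel_bc(o, tot * rho / (1 + rho), tot / (1 + rho), bc$capacitance)
  }))
}

# small, fast solver options for tests
fast_opts <- function(...) solver_options(...)

# noise-free acquisition for construction-inverse tests
clean_spec <- function(seed = 1, grid = c(32, 32, 12)) {
  acquisition_spec(grid = grid, asl_noise_sd = 0, waveform_noise_sd = 0,
                   efficiencies = c(RICA = 1, LICA = 1, RVA = 1, LVA = 1),
                   seed = seed)
}
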