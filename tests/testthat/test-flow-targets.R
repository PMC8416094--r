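# Target mean flows and initial Windkessel distribution

test_that("summarize_inflow extracts mean, extrema and wrap-aware time lapse", {
  # Q(t) = 5 + sin(2 pi t / T) ml/s: mean 5, range 2, max->min lapse T/2
  w <- sine_wave(mls_to_m3s(5), mls_to_m3s(1), period = 0.8, n = 400)
  s <- summarize_inflow(w, mmHg_to_Pa(120), mmHg_to_Pa(80))
  expect_equal(s$q_mean, mls_to_m3s(5), tolerance = 1e-9)
  expect_equal(s$q_max - s$q_min, mls_to_m3s(2), tolerance = 1e-4)
  expect_equal(s$dt_max_to_min, 0.4, tolerance = 1e-2)
  expect_equal(s$p_mean, mmHg_to_Pa(120) / 3 + 2 * mmHg_to_Pa(80) / 3)
  # sampled waveform extrema equal a brute-force scan
  set.seed(21)
  t <- seq(0, 0.99, 0.01)
  v <- 5e-6 + cumsum(rnorm(100, 0, 1e-7))
  w2 <- waveform(t, v, period = 1)
  s2 <- summarize_inflow(w2, 16000, 10600)
  i_max <- which.max(v); i_min <- which.min(v)
  expect_identical(s2$q_max, v[i_max])
  expect_identical(s2$q_min, v[i_min])
  expect_equal(s2$dt_max_to_min, (t[i_min] - t[i_max]) %% 1)
  expect_error(summarize_inflow(steady_wave(5e-6), 16000, 10600),
               class = "cf_degenerate_waveform")
  expect_error(summarize_inflow(w, 10600, 16000), class = "cf_invalid_pressure")
})

test_that("total_resistance applies the cuff mean formula with SI units", {
  w <- sine_wave(mls_to_m3s(83.3), mls_to_m3s(10))
  s <- summarize_inflow(w, mmHg_to_Pa(120), mmHg_to_Pa(80))
  # hand: P_mean = 93.33 mmHg = 12443.4 Pa; / 83.3e-6
  expect_equal(total_resistance(s), 1.4937e8, tolerance = 1e-4)
  s2 <- s; s2$q_mean <- 2 * s$q_mean
  expect_equal(total_resistance(s2), total_resistance(s) / 2)
  s3 <- s; s3$p_mean <- mmHg_to_Pa(100)
  expect_equal(total_resistance(s3), mmHg_to_Pa(100) / s$q_mean)
  s4 <- s; s4$q_mean <- 0
  expect_error(total_resistance(s4), class = "cf_invalid_flow")
})

test_that("total_compliance applies the flow-pulse formula", {
  s <- structure(list(q_mean = 8e-5, q_max = mls_to_m3s(400), q_min = 0,
                      dt_max_to_min = 0.3,
                      p_systolic = mmHg_to_Pa(120), p_diastolic = mmHg_to_Pa(80),
                      p_mean = mmHg_to_Pa(93.33), period = 1),
                 class = "inflow_summary")
  # hand: 400e-6 / 5332.9 * 0.3
  expect_equal(total_compliance(s), 2.2502e-8, tolerance = 1e-4)
  s2 <- s; s2$dt_max_to_min <- 0
  expect_equal(total_compliance(s2), 0)
  s3 <- s; s3$p_systolic <- mmHg_to_Pa(160)
  expect_equal(total_compliance(s3), total_compliance(s) / 2)
  s4 <- s; s4$p_systolic <- s$p_diastolic
  expect_error(total_compliance(s4), class = "cf_invalid_pressure")
})

test_that("cow_inflow sums neck means and warns on hypoplasia", {
  mk <- function(q) steady_wave(mls_to_m3s(q))
  expect_equal(cow_inflow(mk(4), mk(5), mk(1.5), mk(1.5)), mls_to_m3s(12))
  expect_warning(q <- cow_inflow(mk(4), mk(5), NULL, mk(1.5)), "missing RVA")
  expect_equal(q, mls_to_m3s(10.5))
  # trapezoidal-mean oracle on a nonuniform pulsatile waveform
  set.seed(31)
  t <- sort(runif(60))
  t <- t[t < 0.98]
  v <- 3e-6 * (1 + 0.8 * sin(2 * pi * t))
  w <- waveform(t, v, period = 1)
  xs <- c(t, t[1] + 1); ys <- c(v, v[1])
  trap <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  expect_equal(cow_inflow(w, w, w, w), 4 * trap, tolerance = 1e-12)
})

test_that("intracranial_targets distributes the CoW inflow by territory", {
  ps <- stats::setNames(rep(1 / 7, 7), TERRITORY_NAMES)
  q <- intracranial_targets(ps, mls_to_m3s(14))
  expect_equal(unname(q[c("RMCA", "LACA")]), rep(mls_to_m3s(2), 2))
  expect_equal(unname(q[c("RSCA", "LSCA")]), rep(mls_to_m3s(1), 2))
  ps2 <- stats::setNames(c(0.3, rep(0.7 / 6, 6)),
                         c("RMCA", setdiff(TERRITORY_NAMES, "RMCA")))
  q2 <- intracranial_targets(ps2, mls_to_m3s(10))
  expect_equal(unname(q2["RMCA"]), mls_to_m3s(3))
  # conservation for arbitrary splits
  set.seed(41)
  for (i in 1:5) {
    p <- abs(rnorm(7)); p <- stats::setNames(p / sum(p), TERRITORY_NAMES)
    expect_equal(sum(intracranial_targets(p, 1.4e-5)), 1.4e-5)
  }
  # hypoplastic artery with positive share is reported, not dropped
  expect_error(intracranial_targets(ps, 1e-5,
                                    arteries = setdiff(INTRACRANIAL_ARTERIES, "RPCA")),
               class = "cf_missing_artery")
  expect_error(intracranial_targets(ps * 2, 1e-5), class = "cf_invalid_split")
})

test_that("extracranial_targets assigns subclavians and the remainder", {
  w <- sine_wave(mls_to_m3s(100), mls_to_m3s(10))
  s <- summarize_inflow(w, mmHg_to_Pa(120), mmHg_to_Pa(80))
  ex <- extracranial_targets(mls_to_m3s(2), mls_to_m3s(2), s, mls_to_m3s(12))
  expect_equal(unname(ex["RSubclavian"]), mls_to_m3s(5.6), tolerance = 1e-9)
  # hand arithmetic: 100 - 12 - 2 - 2 - 11.2
  expect_equal(unname(ex["DAo"]), mls_to_m3s(72.8), tolerance = 1e-9)
  expect_equal(sum(ex) + mls_to_m3s(12), s$q_mean)
  expect_error(extracranial_targets(mls_to_m3s(50), mls_to_m3s(50), s,
                                    mls_to_m3s(12)),
               class = "cf_inconsistent_measurements")
})

test_that("init_windkessel satisfies aggregate and per-outlet identities", {
  w <- synthetic_aortic_inflow()
  s <- summarize_inflow(w, mmHg_to_Pa(120), mmHg_to_Pa(80))
  # two equal outlets -> identical BCs with R_i = 2 R_T
  q2 <- stats::setNames(rep(s$q_mean / 2, 2), c("A", "B"))
  wk2 <- init_windkessel(q2, s)
  expect_equal(wk_total(wk2$A), 2 * total_resistance(s))
  expect_equal(wk2$A$capacitance, wk2$B$capacitance)
  expect_equal(wk2$A$r_prox / wk_total(wk2$A), 0.06)
  # 13-outlet distribution: parallel(R_i) = R_T, sum C_i = C_T, and each
  # outlet draws its target at mean pressure
  set.seed(51)
  q <- abs(rnorm(13, 5e-6, 2e-6)) + 1e-6
  q <- stats::setNames(q * s$q_mean / sum(q), OUTLET_NAMES)
  wk <- init_windkessel(q, s)
  tot <- wk_totals(wk)
  expect_equal(tot$r_total, total_resistance(s), tolerance = 1e-12)
  expect_equal(tot$c_total, total_compliance(s), tolerance = 1e-12)
  for (o in OUTLET_NAMES) {
    expect_equal(s$p_mean / wk_total(wk[[o]]), unname(q[o]), tolerance = 1e-12)
  }
  expect_error(init_windkessel(c(A = 0, B = 1e-5), s),
               class = "cf_invalid_targets")
})

test_that("waveform CSV I/O converts units and rejects bad files", {
  w <- sine_wave(5e-6, 2e-6, period = 0.9, n = 37)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, path, unit = "flow_mls")
  back <- read_waveform_csv(path)
  expect_equal(back$values, w$values, tolerance = 1e-12)
  expect_equal(back$period, w$period)
  # explicit m3/s column
  write_waveform_csv(w, path, unit = "flow_m3s")
  expect_equal(read_waveform_csv(path)$values, w$values, tolerance = 1e-12)
  # shuffled rows are rejected
  lines <- readLines(path)
  writeLines(c(lines[1:2], lines[5], lines[3:4], lines[6:length(lines)]), path)
  expect_error(read_waveform_csv(path), class = "cf_format")
})
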