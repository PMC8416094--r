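#' Calibration configuration
#'
#' Controller settings for the three-stage Windkessel calibration. Updates
#' are applied once per cardiac cycle using cycle-mean quantities.
#'
#' @param stage1_gain proportional gain on the distal-resistance update
#' @param stage1_tol relative mean-flow tolerance terminating stage 1
#'   (the clinical convergence criterion is 1%)
#' @param stage1_max_iter iteration cap for stage 1
#' @param stage2_pulsatility_tol tolerance on the mean absolute pulsatility
#'   index mismatch over the four neck arteries
#' @param stage2_max_iter bisection iteration cap for stage 2
#' @param stage3_pressure_tol pressure tolerance, mmHg, on systolic and
#'   diastolic brachial errors
#' @param stage3_max_iter iteration cap for stage 3
#' @param cycles_per_update cardiac cycles simulated between controller
#'   updates (cycle-mean control)
#' @return an object of class `calibration_config`
#' @export
calibration_config <- function(stage1_gain = 0.5, stage1_tol = 0.01,
                               stage1_max_iter = 60,
                               stage2_pulsatility_tol = 0.02,
                               stage2_max_iter = 25,
                               stage3_pressure_tol = 1,
                               stage3_max_iter = 30,
                               cycles_per_update = 1) {
  stopifnot(stage1_gain > 0, stage1_tol > 0, stage2_pulsatility_tol > 0,
            stage3_pressure_tol > 0, cycles_per_update >= 1)
  structure(list(stage1_gain = stage1_gain, stage1_tol = stage1_tol,
                 stage1_max_iter = stage1_max_iter,
                 stage2_pulsatility_tol = stage2_pulsatility_tol,
                 stage2_max_iter = stage2_max_iter,
                 stage3_pressure_tol = stage3_pressure_tol,
                 stage3_max_iter = stage3_max_iter,
                 cycles_per_update = cycles_per_update),
            class = "calibration_config")
}

# run a fixed number of cycles without requiring periodicity (controller mode)
run_cycles <- function(net, wk, inflow, opts, n_cycles, state = NULL) {
  o <- opts
  o$periodicity_tol <- Inf
  o$min_cycles <- n_cycles
  o$max_cycles <- n_cycles
  solve_transient(net, wk, inflow, o, state = state)
}

#' Stage 1: match target mean flows by adjusting distal resistances
#'
#' After every simulated cycle, each outlet's distal resistance is updated
#' proportionally to its relative mean-flow error,
#' R_d <- R_d * (1 + gain * (Qbar - Qtarget)/Qtarget), floored at a small
#' positive value, until the maximum per-outlet relative error measured on a
#' fully periodic solution is below `cfg$stage1_tol`. Proximal resistances
#' and capacitances are untouched.
#'
#' @param net a [network_model()]
#' @param wk a [windkessel_set()]
#' @param targets a [flow_targets()] (or named vector over the outlets)
#' @param inflow inlet [waveform()]
#' @param cfg a [calibration_config()]
#' @param opts a [solver_options()]
#' @return list: `wk` (updated set), `trace` (per-iteration max relative
#'   error), `converged`, `final` (periodic `sim_result` at the returned
#'   parameters), `max_error` (verified on the periodic solution)
#' @export
stage1_flow_match <- function(net, wk, targets, inflow,
                              cfg = calibration_config(),
                              opts = solver_options()) {
  q_t <- if (inherits(targets, "flow_targets")) targets$q else targets
  q_t <- q_t[names(net$outlets)]
  if (any(is.na(q_t)) || any(q_t <= 0)) {
    cf_stop("cf_invalid_targets", "positive targets required for every outlet")
  }
  state <- NULL
  trace <- numeric(0)
  final <- NULL
  converged <- FALSE
  for (iter in seq_len(cfg$stage1_max_iter)) {
    res <- run_cycles(net, wk, inflow, opts, cfg$cycles_per_update, state)
    state <- res$state
    qbar <- outlet_mean_flows(res)[names(q_t)]
    err <- (qbar - q_t) / q_t
    trace <- c(trace, max(abs(err)))
    if (max(abs(err)) < cfg$stage1_tol) {
      # verify on a fully periodic solution before declaring convergence
      final <- solve_transient(net, wk, inflow, opts, state = state)
      state <- final$state
      qbar <- outlet_mean_flows(final)[names(q_t)]
      err <- (qbar - q_t) / q_t
      if (max(abs(err)) < cfg$stage1_tol) {
        converged <- TRUE
        trace <- c(trace, max(abs(err)))
        break
      }
    }
    fac <- pmin(pmax(1 + cfg$stage1_gain * err, 0.2), 5)
    wk <- windkessel_set(lapply(names(wk), function(o) {
      bc <- wk[[o]]
      windkessel_bc(o, bc$r_prox, max(bc$r_dist * fac[[o]], 1e3), bc$capacitance)
    }))
  }
  if (!converged) {
    cf_stop("cf_convergence",
            "stage 1 did not converge in %d iterations (last max error %.3g)",
            cfg$stage1_max_iter, trace[length(trace)])
  }
  list(wk = wk, trace = trace, converged = converged, final = final,
       max_error = trace[length(trace)])
}

#' Pulsatility index of a waveform
#'
#' PI = (Q_max - Q_min) / Q_mean, the standard clinical pulsatility measure.
#'
#' @param w a [waveform()]
#' @return dimensionless PI
#' @export
pulsatility_index <- function(w) {
  m <- waveform_mean(w)
  if (abs(m) < .Machine$double.eps) {
    cf_stop("cf_degenerate_waveform", "zero-mean waveform has no pulsatility index")
  }
  (max(w$values) - min(w$values)) / m
}

# set the Rp:Rd ratio of intracranial outlets to base_ratio * s, preserving
# each outlet's total resistance exactly
apply_ratio_scale <- function(wk, base_ratio, s, outlets) {
  windkessel_set(lapply(names(wk), function(o) {
    bc <- wk[[o]]
    if (!o %in% outlets) return(bc)
    total <- bc$r_prox + bc$r_dist
    rho <- base_ratio[[o]] * s
    windkessel_bc(o, r_prox = total * rho / (1 + rho),
                  r_dist = total / (1 + rho),
                  capacitance = bc$capacitance)
  }))
}

#' Stage 2: match neck-artery pulsatility by tuning the Rp/Rd ratio
#'
#' A single scalar factor multiplying the proximal-to-distal resistance
#' ratio of every cerebral and cerebellar outlet is adjusted by bisection
#' until the mean pulsatility-index mismatch between simulated and measured
#' flow waveforms in the four neck arteries (ICAs and VAs) is below
#' tolerance, or the bracket is exhausted (best factor returned, flagged).
#' Every candidate preserves each outlet's total resistance R_p + R_d
#' exactly, so stage-1 mean flows are untouched.
#'
#' @param net a [network_model()] with the four neck arteries labeled
#' @param wk a [windkessel_set()] (stage-1 output)
#' @param measured_neck named list of measured [waveform()]s keyed
#'   RICA, LICA, RVA, LVA (absent vessels may be omitted)
#' @param inflow inlet [waveform()]
#' @param cfg a [calibration_config()]
#' @param opts a [solver_options()]
#' @param bracket log-spaced search interval for the ratio factor
#' @return list: `wk`, `factor`, `pi_error` (mean absolute PI mismatch),
#'   `converged`, `trace` (factor, error per evaluation)
#' @export
stage2_pulsatility <- function(net, wk, measured_neck, inflow,
                               cfg = calibration_config(),
                               opts = solver_options(),
                               bracket = c(0.05, 20)) {
  neck <- intersect(names(measured_neck), names(net$neck_arteries))
  if (!length(neck)) cf_stop("cf_invalid_study", "no measured neck waveforms")
  cerebral <- intersect(names(wk), INTRACRANIAL_ARTERIES)
  base_ratio <- vapply(cerebral, function(o) wk[[o]]$r_prox / wk[[o]]$r_dist,
                       numeric(1))
  pi_meas <- vapply(measured_neck[neck], pulsatility_index, numeric(1))
  state <- NULL
  trace <- data.frame(factor = numeric(0), error = numeric(0))
  eval_pi <- function(s) {
    wks <- apply_ratio_scale(wk, base_ratio, s, cerebral)
    res <- solve_transient(net, wks, inflow, opts, state = state)
    state <<- res$state
    pi_sim <- vapply(neck, function(k) {
      pulsatility_index(segment_waveform(res, net$neck_arteries[[k]]))
    }, numeric(1))
    err <- mean(pi_sim - pi_meas)      # signed, for bisection
    aerr <- mean(abs(pi_sim - pi_meas))
    trace <<- rbind(trace, data.frame(factor = s, error = aerr))
    list(signed = err, abs = aerr, wk = wks)
  }
  lo <- log(bracket[1]); hi <- log(bracket[2])
  e1 <- eval_pi(1)
  if (e1$abs < cfg$stage2_pulsatility_tol) {
    return(list(wk = e1$wk, factor = 1, pi_error = e1$abs, converged = TRUE,
                trace = trace))
  }
  elo <- eval_pi(exp(lo)); ehi <- eval_pi(exp(hi))
  best <- list(s = 1, abs = e1$abs, wk = e1$wk)
  upd_best <- function(s, e) {
    if (e$abs < best$abs) best <<- list(s = s, abs = e$abs, wk = e$wk)
  }
  upd_best(exp(lo), elo); upd_best(exp(hi), ehi)
  converged <- FALSE
  if (sign(elo$signed) != sign(ehi$signed)) {
    for (i in seq_len(cfg$stage2_max_iter)) {
      mid <- (lo + hi) / 2
      em <- eval_pi(exp(mid))
      upd_best(exp(mid), em)
      if (em$abs < cfg$stage2_pulsatility_tol) { converged <- TRUE; break }
      if (sign(em$signed) == sign(elo$signed)) { lo <- mid; elo <- em }
      else { hi <- mid; ehi <- em }
    }
  }
  if (!converged) {
    warning(sprintf(
      "stage 2: pulsatility tolerance %.3g not reached; best mean |dPI| = %.3g at factor %.3g",
      cfg$stage2_pulsatility_tol, best$abs, best$s))
  }
  list(wk = best$wk, factor = best$s, pi_error = best$abs,
       converged = converged, trace = trace)
}

#' Stage 3: match brachial pressures by scaling total resistance and compliance
#'
#' Iterates R_T <- R_T * (Pbar_meas / Pbar_sim) and
#' C_T <- C_T * (pulse_sim / pulse_meas); each relative change is applied
#' multiplicatively to every outlet's R_i (preserving the R_p:R_d split) and
#' C_i. Pressures are evaluated at the subclavian outlet node (the brachial
#' surrogate). Terminates when both the systolic and diastolic errors are
#' below `cfg$stage3_pressure_tol` mmHg; three consecutive error increases
#' trigger a damped retry before failure.
#'
#' @param net a [network_model()]
#' @param wk a [windkessel_set()] (stage-2 output)
#' @param p_sys_meas,p_dia_meas measured brachial pressures, Pa
#' @param inflow inlet [waveform()]
#' @param cfg a [calibration_config()]
#' @param opts a [solver_options()]
#' @param brachial_outlet outlet name used as the brachial surrogate
#' @return list: `wk`, `trace` (per-iteration pressures and factors),
#'   `converged`, `final` (periodic `sim_result`)
#' @export
stage3_pressure_match <- function(net, wk, p_sys_meas, p_dia_meas, inflow,
                                  cfg = calibration_config(),
                                  opts = solver_options(),
                                  brachial_outlet = "RSubclavian") {
  if (!brachial_outlet %in% names(net$outlets)) {
    cf_stop("cf_invalid_network", "no outlet '%s' for brachial pressure",
            brachial_outlet)
  }
  p_mean_meas <- p_sys_meas / 3 + 2 * p_dia_meas / 3
  pulse_meas <- p_sys_meas - p_dia_meas
  tol_pa <- mmHg_to_Pa(cfg$stage3_pressure_tol)
  state <- NULL
  trace <- data.frame()
  err_hist <- numeric(0)
  damp <- 1
  converged <- FALSE
  final <- NULL
  for (iter in seq_len(cfg$stage3_max_iter)) {
    res <- solve_transient(net, wk, inflow, opts, state = state)
    state <- res$state
    pb <- res$outlet_pressures[brachial_outlet, ]
    p_sys_sim <- max(pb); p_dia_sim <- min(pb)
    # cuff-formula mean on both sides so that (mean, pulse) fixed point
    # pins systolic and diastolic individually
    p_mean_sim <- p_sys_sim / 3 + 2 * p_dia_sim / 3
    e_sys <- p_sys_sim - p_sys_meas
    e_dia <- p_dia_sim - p_dia_meas
    err <- max(abs(e_sys), abs(e_dia))
    trace <- rbind(trace, data.frame(
      iter = iter, p_sys_mmHg = Pa_to_mmHg(p_sys_sim),
      p_dia_mmHg = Pa_to_mmHg(p_dia_sim), err_mmHg = Pa_to_mmHg(err)))
    if (err < tol_pa) { converged <- TRUE; final <- res; break }
    err_hist <- c(err_hist, err)
    n <- length(err_hist)
    if (n >= 4 && all(diff(err_hist[(n - 3):n]) > 0)) {
      if (damp > 0.2) {
        damp <- damp / 2          # damped retry
        err_hist <- numeric(0)
      } else {
        cf_stop("cf_convergence",
                "stage 3 oscillating: pressure error increasing (%.3g mmHg)",
                Pa_to_mmHg(err))
      }
    }
    f_r <- (p_mean_meas / p_mean_sim)^damp
    f_c <- (((p_sys_sim - p_dia_sim)) / pulse_meas)^damp
    wk <- windkessel_set(lapply(names(wk), function(o) {
      bc <- wk[[o]]
      windkessel_bc(o, bc$r_prox * f_r, bc$r_dist * f_r, bc$capacitance * f_c)
    }))
  }
  if (!converged) {
    cf_stop("cf_convergence",
            "stage 3 did not converge in %d iterations (error %.3g mmHg)",
            cfg$stage3_max_iter, trace$err_mmHg[nrow(trace)])
  }
  list(wk = wk, trace = trace, converged = converged, final = final)
}

#' In-memory study inputs
#'
#' The complete measurement set for one subject: the vascular network, the
#' atlas, non-selective ASL (label/control pairs or a precomputed perfusion
#' volume), a vessel-selective ASL study, the waveform set (aorta, RICA,
#' LICA, RVA, LVA, RECA, LECA) and the brachial pressure pair.
#'
#' @param network a [network_model()]
#' @param atlas a [territory_atlas()]
#' @param waveforms named list of [waveform()]s: aorta, RICA, LICA, RVA,
#'   LVA, RECA, LECA (hypoplastic vessels may be NULL)
#' @param p_sys,p_dia brachial pressures, Pa
#' @param ns_pairs optional list(labels=, controls=) of 3D arrays
#' @param ns_perf optional precomputed [perfusion_volume()]
#' @param vsasl optional [vsasl_study()]
#' @return an object of class `study_data`
#' @export
study_data <- function(network, atlas, waveforms, p_sys, p_dia,
                       ns_pairs = NULL, ns_perf = NULL, vsasl = NULL) {
  if (is.null(ns_pairs) && is.null(ns_perf)) {
    cf_stop("cf_invalid_study", "need ns_pairs or ns_perf")
  }
  need <- c("aorta", "RECA", "LECA")
  if (!all(need %in% names(waveforms))) {
    cf_stop("cf_invalid_study", "waveforms must include %s",
            paste(need, collapse = ", "))
  }
  structure(list(network = network, atlas = atlas, waveforms = waveforms,
                 p_sys = p_sys, p_dia = p_dia, ns_pairs = ns_pairs,
                 ns_perf = ns_perf, vsasl = vsasl),
            class = "study_data")
}

#' Full three-stage patient-specific calibration
#'
#' Derives perfusion splits from the non-selective ASL data, target flows
#' from the splits and PC-MRI waveforms, initial Windkessel parameters from
#' the brachial pressures and aortic inflow, then runs calibration stages
#' 1 (mean flows), 2 (neck pulsatility) and 3 (brachial pressures). Because
#' stage 3 rescales total resistance, stage-1 flow errors are re-checked
#' afterwards and stage 1 is repeated once if any outlet drifted beyond
#' tolerance.
#'
#' @param study a [study_data()]
#' @param cfg a [calibration_config()]
#' @param opts a [solver_options()]
#' @param stages integer vector of stages to run (default 1:3)
#' @return list of class `calibrated_model`: `network`, `wk`, `targets`,
#'   `summary`, `splits`, `result` (final periodic `sim_result`) and
#'   `report` (per-stage traces and convergence flags)
#' @export
calibrate <- function(study, cfg = calibration_config(),
                      opts = solver_options(), stages = 1:3) {
  stopifnot(inherits(study, "study_data"))
  net <- study$network
  perf <- if (!is.null(study$ns_perf)) study$ns_perf else
    subtract_and_average(study$ns_pairs$labels, study$ns_pairs$controls,
                         voxel_dim = study$atlas$voxel_dim)
  splits <- perfusion_splits(perf, study$atlas)
  wfs <- study$waveforms
  q_cow <- cow_inflow(wfs$RICA, wfs$LICA, wfs$RVA, wfs$LVA)
  summ <- summarize_inflow(wfs$aorta, study$p_sys, study$p_dia)
  intr <- intracranial_targets(splits, q_cow,
                               arteries = intersect(names(net$outlets),
                                                    INTRACRANIAL_ARTERIES))
  extr <- extracranial_targets(wfs$RECA, wfs$LECA, summ, sum(intr))
  targets <- flow_targets(intr, extr)
  wk <- init_windkessel(targets, summ)
  report <- list()
  result <- NULL
  if (1 %in% stages) {
    s1 <- stage1_flow_match(net, wk, targets, wfs$aorta, cfg, opts)
    wk <- s1$wk; result <- s1$final
    report$stage1 <- list(trace = s1$trace, converged = s1$converged,
                          max_error = s1$max_error)
  }
  if (2 %in% stages) {
    neck_meas <- wfs[intersect(c("RICA", "LICA", "RVA", "LVA"), names(wfs))]
    neck_meas <- Filter(Negate(is.null), neck_meas)
    s2 <- stage2_pulsatility(net, wk, neck_meas, wfs$aorta, cfg, opts)
    wk <- s2$wk
    report$stage2 <- list(factor = s2$factor, pi_error = s2$pi_error,
                          converged = s2$converged, trace = s2$trace)
  }
  if (3 %in% stages) {
    s3 <- stage3_pressure_match(net, wk, study$p_sys, study$p_dia, wfs$aorta,
                                cfg, opts)
    wk <- s3$wk; result <- s3$final
    report$stage3 <- list(trace = s3$trace, converged = s3$converged)
    # stage 3 rescales R_T; re-check stage-1 flows once
    qbar <- outlet_mean_flows(s3$final)[names(targets$q)]
    drift <- max(abs((qbar - targets$q) / targets$q))
    report$stage1_recheck <- list(drift = drift, repeated = FALSE)
    if (drift > cfg$stage1_tol && 1 %in% stages) {
      s1b <- stage1_flow_match(net, wk, targets, wfs$aorta, cfg, opts)
      wk <- s1b$wk; result <- s1b$final
      report$stage1_recheck <- list(drift = drift, repeated = TRUE,
                                    max_error = s1b$max_error)
    }
  }
  if (is.null(result)) result <- solve_transient(net, wk, wfs$aorta, opts)
  structure(list(network = net, wk = wk, targets = targets, summary = summ,
                 splits = splits, result = result, report = report),
            class = "calibrated_model")
}
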