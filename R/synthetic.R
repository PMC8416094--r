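#' Synthetic aortic inflow waveform
#'
#' A smooth two-harmonic pulse with exact mean `q_mean`, a single systolic
#' peak and a single diastolic minimum, emulating an ascending-aorta PC-MRI
#' waveform (brief retrograde flow near valve closure is possible and
#' physiologic).
#'
#' @param q_mean cardiac output, m^3/s
#' @param period cardiac period, s
#' @param n samples per period
#' @return a [waveform()]
#' @export
synthetic_aortic_inflow <- function(q_mean = mls_to_m3s(83), period = 1,
                                    n = 100) {
  t <- seq(0, period, length.out = n + 1)[1:n]
  shape <- 1 + 1.3 * cos(2 * pi * t / period - 1.1) +
    0.5 * cos(4 * pi * t / period - 2.4)
  waveform(t, q_mean * shape, period = period)
}

#' Acquisition specification for the synthetic generator
#'
#' The stated acquisition world: image grid and voxel size, additive ASL
#' voxel noise as a fraction of the mean territory signal, the number of
#' label/control pairs (8, the consensus NS-ASL protocol), per-artery
#' labeling efficiencies (< 1, as measured for vessel-selective labeling),
#' waveform measurement noise, and one master seed.
#'
#' @param grid image grid shape, default 64 x 64 x 24
#' @param voxel_dim voxel size mm, default 3 x 3 x 3
#' @param asl_noise_sd additive voxel noise sd as a fraction of the mean
#'   within-brain signal (0 = noise-free)
#' @param n_pairs label/control pairs for NS-ASL (default 8)
#' @param efficiencies named labeling efficiencies in (0, 1]
#' @param waveform_noise_sd additive waveform noise sd as a fraction of each
#'   vessel's mean flow
#' @param seed master RNG seed
#' @return an object of class `acquisition_spec`
#' @export
acquisition_spec <- function(grid = c(64, 64, 24), voxel_dim = c(3, 3, 3),
                             asl_noise_sd = 0.05, n_pairs = 8,
                             efficiencies = c(RICA = 0.85, LICA = 0.85,
                                              RVA = 0.80, LVA = 0.80),
                             waveform_noise_sd = 0.02, seed = 1) {
  stopifnot(asl_noise_sd >= 0, waveform_noise_sd >= 0, n_pairs >= 1,
            all(efficiencies > 0), all(efficiencies <= 1))
  structure(list(grid = grid, voxel_dim = voxel_dim,
                 asl_noise_sd = asl_noise_sd, n_pairs = n_pairs,
                 efficiencies = efficiencies,
                 waveform_noise_sd = waveform_noise_sd, seed = seed),
            class = "acquisition_spec")
}

#' Synthetic block-partition territory atlas
#'
#' A labeled block partition of the grid (not brain-shaped): a background
#' margin, a lower cerebellar slab, and an upper cerebral block split
#' left/right and into anterior/middle/posterior thirds.
#'
#' @param grid grid shape
#' @param voxel_dim voxel size mm
#' @return a [territory_atlas()]
#' @export
make_atlas <- function(grid = c(64, 64, 24), voxel_dim = c(3, 3, 3)) {
  lab <- array(0L, dim = grid)
  mx <- max(2L, round(grid[1] * 0.08)); my <- max(2L, round(grid[2] * 0.08))
  mz <- max(1L, round(grid[3] * 0.10))
  xs <- (mx + 1L):(grid[1] - mx)
  ys <- (my + 1L):(grid[2] - my)
  zs <- (mz + 1L):(grid[3] - mz)
  z_cereb <- zs[zs <= mz + ceiling(length(zs) * 0.25)]
  z_cer <- setdiff(zs, z_cereb)
  lab[xs, ys, z_cereb] <- 7L
  x_r <- xs[xs <= grid[1] / 2]; x_l <- setdiff(xs, x_r)
  third <- ceiling(length(ys) / 3)
  y_ant <- ys[seq_len(third)]
  y_mid <- ys[(third + 1):(2 * third)]
  y_pos <- setdiff(ys, c(y_ant, y_mid))
  lab[x_r, y_ant, z_cer] <- 1L  # RACA
  lab[x_l, y_ant, z_cer] <- 2L  # LACA
  lab[x_r, y_mid, z_cer] <- 3L  # RMCA
  lab[x_l, y_mid, z_cer] <- 4L  # LMCA
  lab[x_r, y_pos, z_cer] <- 5L  # RPCA
  lab[x_l, y_pos, z_cer] <- 6L  # LPCA
  territory_atlas(lab, voxel_dim)
}

# segment spec rows for the full anatomy; radii/lengths are
# literature-plausible adult values (m)
cow_segment_specs <- function() {
  s <- function(id, from, to, L, r) list(id = id, from = from, to = to, L = L, r = r)
  list(
    s("AAo", "inlet", "arch1", 0.040, 0.0145),
    s("BCT", "arch1", "bct", 0.035, 0.0062),
    s("RSubA", "bct", "rsub1", 0.020, 0.0042),
    s("RSub_out", "rsub1", "rsub_end", 0.030, 0.0040),
    s("RCCA", "bct", "rcca1", 0.100, 0.0035),
    s("RICA", "rcca1", "rica1", 0.120, 0.0025),
    s("RECA_seg", "rcca1", "reca_end", 0.050, 0.0020),
    s("Arch2", "arch1", "arch2", 0.010, 0.0130),
    s("LCCA", "arch2", "lcca1", 0.120, 0.0035),
    s("LICA", "lcca1", "lica1", 0.120, 0.0025),
    s("LECA_seg", "lcca1", "leca_end", 0.050, 0.0020),
    s("Arch3", "arch2", "arch3", 0.010, 0.0120),
    s("LSubA", "arch3", "lsub1", 0.020, 0.0042),
    s("LSub_out", "lsub1", "lsub_end", 0.030, 0.0040),
    s("DAo_seg", "arch3", "dao_end", 0.050, 0.0110),
    s("RVA", "rsub1", "rva1", 0.100, 0.0019),
    s("RVA_dist", "rva1", "bas0", 0.050, 0.0017),
    s("LVA", "lsub1", "lva1", 0.100, 0.0019),
    s("LVA_dist", "lva1", "bas0", 0.050, 0.0017),
    s("Basilar", "bas0", "bas1", 0.025, 0.0016),
    s("RSCA_seg", "bas1", "rsca_end", 0.015, 0.0008),
    s("LSCA_seg", "bas1", "lsca_end", 0.015, 0.0008),
    s("RP1", "bas1", "rpca1", 0.008, 0.0011),
    s("LP1", "bas1", "lpca1", 0.008, 0.0011),
    s("RP2", "rpca1", "rpca_end", 0.030, 0.0011),
    s("LP2", "lpca1", "lpca_end", 0.030, 0.0011),
    s("RPCom", "rica1", "rpca1", 0.015, 0.0008),
    s("LPCom", "lica1", "lpca1", 0.015, 0.0008),
    s("RM1", "rica1", "rmca_end", 0.030, 0.0014),
    s("LM1", "lica1", "lmca_end", 0.030, 0.0014),
    s("RA1", "rica1", "raca1", 0.013, 0.0012),
    s("LA1", "lica1", "laca1", 0.013, 0.0012),
    s("AComA", "raca1", "laca1", 0.003, 0.0008),
    s("RA2", "raca1", "raca_end", 0.030, 0.0012),
    s("LA2", "laca1", "laca_end", 0.030, 0.0012)
  )
}

#' Build a synthetic Circle-of-Willis network
#'
#' Deterministic for a given (variant, seed): the seed applies a small
#' (+/- 3%) anatomical jitter to segment lengths and radii. Hypoplastic
#' variants are encoded by segment removal, never by zero radius:
#' `pcom_hypoplasia_bilateral` removes both posterior communicating
#' arteries; `p1_and_va_hypoplasia` removes the right P1 segment and the
#' distal right vertebral artery (the communicating pathways then supply the
#' right posterior circulation from the carotid side).
#'
#' @param variant one of "complete", "pcom_hypoplasia_bilateral",
#'   "p1_and_va_hypoplasia"
#' @param seed anatomical jitter seed
#' @param stenoses optional list of `list(vessel=, min_frac=, length=)`
#'   entries; `min_frac` is the minimal lumen diameter as a fraction of the
#'   vessel's reference diameter
#' @param blood a [blood_properties()]
#' @return a [network_model()] with 13 outlets and 4 labeled neck arteries
#' @export
make_network <- function(variant = c("complete", "pcom_hypoplasia_bilateral",
                                     "p1_and_va_hypoplasia"),
                         seed = 1, stenoses = NULL,
                         blood = blood_properties()) {
  variant <- match.arg(variant)
  specs <- cow_segment_specs()
  drop <- switch(variant,
                 complete = character(0),
                 pcom_hypoplasia_bilateral = c("RPCom", "LPCom"),
                 p1_and_va_hypoplasia = c("RP1", "RVA_dist"))
  specs <- Filter(function(s) !s$id %in% drop, specs)
  set.seed(seed)
  jit <- function() 1 + stats::runif(1, -0.03, 0.03)
  sten_by_vessel <- list()
  for (st in stenoses) {
    if (!st$vessel %in% vapply(specs, `[[`, character(1), "id")) {
      cf_stop("cf_config", "stenosis on absent segment '%s'", st$vessel)
    }
    sten_by_vessel[[st$vessel]] <- st
  }
  segs <- lapply(specs, function(sp) {
    sten <- NULL
    st <- sten_by_vessel[[sp$id]]
    if (!is.null(st)) {
      len <- if (is.null(st$length)) 0.01 else st$length
      sten <- stenosis_from_geometry(len, st$min_frac * 2 * sp$r, 2 * sp$r,
                                     blood = blood)
    }
    vessel_segment(sp$id, sp$from, sp$to, sp$L * jit(), sp$r * jit(),
                   blood = blood, stenosis = sten)
  })
  outlets <- c(DAo = "dao_end", RSubclavian = "rsub_end",
               LSubclavian = "lsub_end", RECA = "reca_end", LECA = "leca_end",
               RACA = "raca_end", LACA = "laca_end", RMCA = "rmca_end",
               LMCA = "lmca_end", RPCA = "rpca_end", LPCA = "lpca_end",
               RSCA = "rsca_end", LSCA = "lsca_end")
  network_model(segs, inlet = "inlet", outlets = outlets,
                neck_arteries = c(RICA = "RICA", LICA = "LICA",
                                  RVA = "RVA", LVA = "LVA"))
}

#' Ground-truth Windkessel set for the synthetic cohort
#'
#' Plausible resting mean flows (cardiac output 83 ml/s, CoW inflow about
#' 14 ml/s, 5.6% of cardiac output per subclavian) distributed with
#' [init_windkessel()] under a 120/80 mmHg brachial pair, against the given
#' inflow waveform.
#'
#' @param inflow aortic inflow [waveform()]
#' @param flows_mls optional named per-outlet mean flows, ml/s
#' @param p_sys,p_dia brachial pressures, mmHg
#' @return a [windkessel_set()]
#' @export
true_windkessel <- function(inflow = synthetic_aortic_inflow(),
                            flows_mls = NULL, p_sys = 120, p_dia = 80) {
  if (is.null(flows_mls)) {
    q_t <- m3s_to_mls(waveform_mean(inflow))
    intr <- c(RACA = 1.6, LACA = 1.7, RMCA = 3.2, LMCA = 3.4,
              RPCA = 1.2, LPCA = 1.3, RSCA = 0.8, LSCA = 0.8)
    sub <- 0.056 * q_t
    flows_mls <- c(DAo = q_t - sum(intr) - 2 * 2.0 - 2 * sub,
                   RSubclavian = sub, LSubclavian = sub,
                   RECA = 2.0, LECA = 2.0, intr)
  }
  summ <- summarize_inflow(inflow, mmHg_to_Pa(p_sys), mmHg_to_Pa(p_dia))
  init_windkessel(mls_to_m3s(flows_mls[OUTLET_NAMES]), summ)
}

#' Generate a complete synthetic study from a known truth
#'
#' Simulates the true model on the network and inverts the measurement
#' pipeline: NS-ASL label/control pairs whose territory-wise mean signal
#' difference is proportional to each territory's true blood flow (additive
#' Gaussian voxel noise); per-artery VS-ASL volumes equal to the NS signal
#' times the territory's true fractional supply from that artery times the
#' labeling efficiency, plus noise; neck/ECA/aortic waveforms exported from
#' the simulation with additive measurement noise (downsampled to PC-MRI-like
#' frame counts); brachial pressures read at the subclavian outlet and
#' rounded to 1 mmHg (cuff resolution).
#'
#' @param network a [network_model()] from [make_network()]
#' @param true_wk a [windkessel_set()] (the ground truth)
#' @param spec an [acquisition_spec()]
#' @param inflow aortic inflow [waveform()]
#' @param opts a [solver_options()]
#' @return list: `study` (a [study_data()]), `truth` (true Windkessel set,
#'   outlet flows, perfusion splits, transport FBS table, pressures),
#'   `sim` (the ground-truth `sim_result`), `atlas`
#' @export
forward_study <- function(network, true_wk = true_windkessel(inflow),
                          spec = acquisition_spec(),
                          inflow = synthetic_aortic_inflow(),
                          opts = solver_options()) {
  set.seed(spec$seed)
  sim <- solve_transient(network, true_wk, inflow, opts)
  q_out <- outlet_mean_flows(sim)
  map <- territory_artery_map()
  terr_flow <- vapply(names(map), function(terr) {
    sum(q_out[intersect(names(map[[terr]]), names(q_out))])
  }, numeric(1))
  splits_true <- terr_flow / sum(terr_flow)
  fbs_true <- transport_fractions(sim, network)
  atlas <- make_atlas(spec$grid, spec$voxel_dim)
  lab <- atlas$labels
  n_terr <- length(TERRITORY_NAMES)
  n_vox <- vapply(seq_len(n_terr), function(j) sum(lab == j), numeric(1))
  # per-voxel signal so each territory integrates to its split
  s_vox <- splits_true / n_vox * 1e4
  signal <- array(0, dim = spec$grid)
  for (j in seq_len(n_terr)) signal[lab == j] <- s_vox[j]
  sd_abs <- spec$asl_noise_sd * mean(signal[lab > 0])
  base <- 10 * max(signal)
  mk_noise <- function() {
    if (sd_abs <= 0) array(0, dim = spec$grid) else
      array(stats::rnorm(prod(spec$grid), 0, sd_abs), dim = spec$grid)
  }
  labels <- controls <- vector("list", spec$n_pairs)
  for (i in seq_len(spec$n_pairs)) {
    controls[[i]] <- base + signal / 2 + mk_noise()
    labels[[i]] <- base - signal / 2 + mk_noise()
  }
  # VS-ASL: territory-constant FBS map times NS signal times efficiency
  vs_vols <- lapply(NECK_ARTERIES, function(k) {
    v <- array(0, dim = spec$grid)
    for (j in seq_len(n_terr)) {
      v[lab == j] <- s_vox[j] * fbs_true$m[TERRITORY_NAMES[j], k]
    }
    perfusion_volume(v * spec$efficiencies[[k]] + mk_noise(), spec$voxel_dim)
  })
  names(vs_vols) <- NECK_ARTERIES
  vsasl <- vsasl_study(vs_vols, spec$efficiencies)
  # waveforms: downsample simulated series and add measurement noise
  n_frames <- 40
  mk_wave <- function(series) {
    idx <- round(seq(1, length(series), length.out = n_frames + 1))[1:n_frames]
    tt <- (idx - 1) * sim$dt
    v <- series[idx]
    if (spec$waveform_noise_sd > 0) {
      v <- v + stats::rnorm(n_frames, 0, spec$waveform_noise_sd * abs(mean(series)))
    }
    waveform(tt, v, period = sim$period)
  }
  wfs <- list(aorta = mk_wave(sim$inflow),
              RICA = mk_wave(sim$seg_flows["RICA", ]),
              LICA = mk_wave(sim$seg_flows["LICA", ]),
              RVA = mk_wave(sim$seg_flows["RVA", ]),
              LVA = mk_wave(sim$seg_flows["LVA", ]),
              RECA = mk_wave(sim$seg_flows["RECA_seg", ]),
              LECA = mk_wave(sim$seg_flows["LECA_seg", ]))
  pb <- sim$outlet_pressures["RSubclavian", ]
  p_sys <- mmHg_to_Pa(round(Pa_to_mmHg(max(pb))))
  p_dia <- mmHg_to_Pa(round(Pa_to_mmHg(min(pb))))
  study <- study_data(network, atlas, wfs, p_sys, p_dia,
                      ns_pairs = list(labels = labels, controls = controls),
                      vsasl = vsasl)
  truth <- list(wk = true_wk, flows = q_out, splits = splits_true,
                fbs = fbs_true, p_sys = max(pb), p_dia = min(pb),
                terr_flow = terr_flow, seed = spec$seed)
  list(study = study, truth = truth, sim = sim, atlas = atlas)
}

#' End-to-end recovery harness
#'
#' Generates a synthetic study, runs the full calibration and supply
#' tracking, and compares recovered quantities against the generator truth.
#'
#' @param variant anatomy variant passed to [make_network()]
#' @param spec an [acquisition_spec()]
#' @param stenoses optional stenosis list for [make_network()]
#' @param cfg a [calibration_config()]
#' @param opts a [solver_options()]
#' @param stages calibration stages to run
#' @return list: `model` (calibrated), `truth`, `errors` (per-outlet flow
#'   and total-resistance relative errors, neck-flow errors vs the synthetic
#'   PC-MRI means), `fbs` (recovered transport FBS), `fbs_compare` (vs truth)
#' @export
end_to_end_recovery <- function(variant = "complete",
                                spec = acquisition_spec(),
                                stenoses = NULL,
                                cfg = calibration_config(),
                                opts = solver_options(),
                                stages = 1:3) {
  net <- make_network(variant, seed = spec$seed, stenoses = stenoses)
  inflow <- synthetic_aortic_inflow()
  fs <- forward_study(net, true_windkessel(inflow), spec, inflow, opts)
  model <- calibrate(fs$study, cfg, opts, stages = stages)
  q_rec <- outlet_mean_flows(model$result)
  q_true <- fs$truth$flows[names(q_rec)]
  flow_err <- (q_rec - q_true) / q_true
  r_rec <- vapply(model$wk, wk_total, numeric(1))[names(q_rec)]
  r_true <- vapply(fs$truth$wk, wk_total, numeric(1))[names(q_rec)]
  r_err <- (r_rec - r_true) / r_true
  neck_meas <- vapply(c("RICA", "LICA", "RVA", "LVA"), function(k) {
    waveform_mean(fs$study$waveforms[[k]])
  }, numeric(1))
  neck_sim <- vapply(c("RICA", "LICA", "RVA", "LVA"), function(k) {
    mean(model$result$seg_flows[net$neck_arteries[[k]], ])
  }, numeric(1))
  neck_err <- (neck_sim - neck_meas) / neck_meas
  fbs_rec <- transport_fractions(model$result, net)
  cmp <- fbs_compare(fbs_rec, fs$truth$fbs)
  list(model = model, truth = fs$truth, study = fs$study,
       errors = list(flow = flow_err, resistance = r_err, neck = neck_err),
       fbs = fbs_rec, fbs_compare = cmp)
}
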