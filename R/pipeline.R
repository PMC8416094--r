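#' Write a synthetic study to a directory
#'
#' Emits the on-disk study layout consumed by [read_study()]: NS-ASL
#' label/control pairs and VS-ASL volumes as NIfTI, the atlas (with JSON
#' label sidecar), waveform CSVs, the network JSON, and a study manifest
#' (brachial pressures, labeling efficiencies, generator seed).
#'
#' @param fs a [forward_study()] result
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_study <- function(fs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- fs$study
  vd <- st$atlas$voxel_dim
  for (i in seq_along(st$ns_pairs$labels)) {
    write_nifti(st$ns_pairs$labels[[i]],
                file.path(dir, sprintf("ns_label_%02d.nii", i)), vd, "float64")
    write_nifti(st$ns_pairs$controls[[i]],
                file.path(dir, sprintf("ns_control_%02d.nii", i)), vd, "float64")
  }
  for (k in NECK_ARTERIES) {
    write_nifti_volume(st$vsasl$volumes[[k]],
                       file.path(dir, sprintf("vs_%s.nii", k)))
  }
  write_nifti_atlas(st$atlas, file.path(dir, "atlas.nii"))
  for (nm in names(st$waveforms)) {
    if (!is.null(st$waveforms[[nm]])) {
      write_waveform_csv(st$waveforms[[nm]],
                         file.path(dir, sprintf("flow_%s.csv", nm)), "flow_mls")
    }
  }
  write_network_json(st$network, file.path(dir, "network.json"))
  manifest <- list(
    n_pairs = length(st$ns_pairs$labels),
    p_systolic_mmHg = Pa_to_mmHg(st$p_sys),
    p_diastolic_mmHg = Pa_to_mmHg(st$p_dia),
    efficiencies = as.list(st$vsasl$efficiencies),
    seed = fs$truth$seed,
    generator = paste0("cowflow ", as.character(utils::packageVersion("cowflow")))
  )
  jsonlite::write_json(manifest, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  truth <- list(
    flows_m3s = as.list(fs$truth$flows),
    splits = as.list(fs$truth$splits),
    fbs = as.data.frame(fs$truth$fbs$m),
    windkessel = lapply(fs$truth$wk, unclass)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study directory
#'
#' @param dir directory written by [write_study()] (or hand-assembled to the
#'   same layout)
#' @return a [study_data()]
#' @export
read_study <- function(dir) {
  manifest_path <- file.path(dir, "study.json")
  if (!file.exists(manifest_path)) {
    cf_stop("cf_missing_file", "no study manifest at %s", manifest_path)
  }
  man <- jsonlite::read_json(manifest_path)
  need <- function(p) {
    if (!file.exists(p)) cf_stop("cf_missing_file", "missing study file: %s", p)
    p
  }
  atlas <- read_nifti_atlas(need(file.path(dir, "atlas.nii")))
  n_pairs <- man$n_pairs
  labels <- controls <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    labels[[i]] <- read_nifti(need(file.path(dir, sprintf("ns_label_%02d.nii", i))))$data
    controls[[i]] <- read_nifti(need(file.path(dir, sprintf("ns_control_%02d.nii", i))))$data
  }
  effs <- unlist(man$efficiencies)
  vols <- lapply(NECK_ARTERIES, function(k) {
    read_nifti_volume(need(file.path(dir, sprintf("vs_%s.nii", k))))
  })
  names(vols) <- NECK_ARTERIES
  wf_names <- c("aorta", "RICA", "LICA", "RVA", "LVA", "RECA", "LECA")
  wfs <- lapply(wf_names, function(nm) {
    p <- file.path(dir, sprintf("flow_%s.csv", nm))
    if (file.exists(p)) read_waveform_csv(p) else NULL
  })
  names(wfs) <- wf_names
  net <- read_network_json(need(file.path(dir, "network.json")))
  study_data(net, atlas, wfs,
             p_sys = mmHg_to_Pa(man$p_systolic_mmHg),
             p_dia = mmHg_to_Pa(man$p_diastolic_mmHg),
             ns_pairs = list(labels = labels, controls = controls),
             vsasl = vsasl_study(vols, effs))
}

#' Run the full pipeline on a study directory
#'
#' calibrate -> solve -> track -> report; writes the calibrated Windkessel
#' set, FBS tables (ASL, transport, particles), the hemodynamic report, and
#' a run manifest with per-stage timings into `out_dir`. On a stage failure
#' the partial artifacts are retained and the manifest records the error.
#'
#' @param study_dir input study directory (layout of [write_study()])
#' @param out_dir output directory
#' @param cfg a [calibration_config()]
#' @param opts a [solver_options()]
#' @param n_particles particle budget for [particle_fbs()]
#' @param seed RNG seed for particle routing
#' @return list: `model`, `report`, `fbs` (named list of tables), `manifest`
#' @export
run_pipeline <- function(study_dir, out_dir, cfg = calibration_config(),
                         opts = solver_options(), n_particles = 1e4,
                         seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(study_dir = study_dir, seed = seed, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(e)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }
  study <- t_stage("read", read_study(study_dir))
  model <- t_stage("calibrate", calibrate(study, cfg, opts))
  wk_out <- lapply(model$wk, unclass)
  jsonlite::write_json(wk_out, file.path(out_dir, "windkessel.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fbs_tr <- t_stage("track_transport",
                    transport_fractions(model$result, study$network))
  pf <- t_stage("track_particles",
                particle_fbs(model$result, study$network,
                             n_total = n_particles, seed = seed))
  fbs_asl <- t_stage("asl_fbs", {
    scaled <- scale_by_efficiency(study$vsasl)
    territory_fbs_stats(fbs_maps(scaled), study$atlas)
  })
  write_fbs_csv(fbs_tr, file.path(out_dir, "fbs_transport.csv"))
  write_fbs_csv(pf$fbs, file.path(out_dir, "fbs_particles.csv"))
  write_fbs_csv(fbs_asl, file.path(out_dir, "fbs_asl.csv"))
  jsonlite::write_json(pf$ledger[c("counts", "retired", "per_cycle_arrivals",
                                   "periodic", "seed", "n_total")],
                       file.path(out_dir, "particle_ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  rep <- t_stage("report", hemodynamic_report(model, fbs_model = fbs_tr,
                                              fbs_asl = fbs_asl))
  write_report_json(rep, file.path(out_dir, "report.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(model = model, report = rep,
       fbs = list(transport = fbs_tr, particles = pf$fbs, asl = fbs_asl),
       manifest = manifest)
}
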