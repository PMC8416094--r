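#' Trans-stenotic pressure drop and fractional flow
#'
#' Cycle-mean pressures at the nodes bounding a vessel (in reduced order, the
#' nodes bracketing the stenosis element), the mean pressure drop
#' dP = Pbar_prox - Pbar_dist, and the fractional flow index
#' FF = Pbar_dist / Pbar_prox. FF is reported against the conventional 0.8
#' hemodynamic-significance threshold as an annotation, never as a hard
#' classification.
#'
#' @param result a periodic `sim_result`
#' @param vessel segment id of the (stenosed) vessel
#' @param prox_node,dist_node node names bracketing the vessel; default to
#'   the segment's `from`/`to` nodes
#' @return an object of class `stenosis_assessment` with mmHg/ml-per-s fields
#' @export
pressure_drop <- function(result, vessel, prox_node = NULL, dist_node = NULL) {
  net <- result$network
  if (!vessel %in% names(net$segments)) {
    cf_stop("cf_unknown_segment", "no segment '%s'", vessel)
  }
  seg <- net$segments[[vessel]]
  if (is.null(prox_node)) prox_node <- seg$from
  if (is.null(dist_node)) dist_node <- seg$to
  P <- result$node_pressures
  if (!all(c(prox_node, dist_node) %in% rownames(P))) {
    cf_stop("cf_unknown_segment", "nodes must exist in the result")
  }
  p_prox <- mean(P[prox_node, ])
  p_dist <- mean(P[dist_node, ])
  if (p_prox <= 0) cf_stop("cf_undefined_ff", "nonpositive proximal mean pressure")
  q_mean <- mean(result$seg_flows[vessel, ])
  structure(list(vessel = vessel,
                 p_prox_mean = Pa_to_mmHg(p_prox),
                 p_dist_mean = Pa_to_mmHg(p_dist),
                 dp_mean = Pa_to_mmHg(p_prox - p_dist),
                 ff = p_dist / p_prox,
                 q_mean = m3s_to_mls(q_mean),
                 ff_threshold = 0.8,
                 hemodynamically_significant_annotation =
                   (p_dist / p_prox) < 0.8),
            class = "stenosis_assessment")
}

#' @export
print.stenosis_assessment <- function(x, ...) {
  cat(sprintf("%s: dP = %.2f mmHg, FF = %.2f (threshold 0.8), Q = %.2f ml/s\n",
              x$vessel, x$dp_mean, x$ff, x$q_mean))
  invisible(x)
}

#' Distal outlet resistance from mean pressure and flow
#'
#' R = Pbar / Qbar with the distal (venous) reference pressure at 0; inputs
#' in clinical units, output in SI.
#'
#' @param p_mean mean outlet pressure, mmHg
#' @param q_mean mean outlet flow, ml/s (> 0)
#' @return resistance, Pa s m^-3
#' @export
outlet_resistance <- function(p_mean, q_mean) {
  if (!is.finite(q_mean) || q_mean <= 0) {
    cf_stop("cf_invalid_flow", "q_mean must be positive")
  }
  mmHg_to_Pa(p_mean) / mls_to_m3s(q_mean)
}

#' Per-outlet hemodynamic summaries
#'
#' @param result a periodic `sim_result`
#' @return data.frame: outlet, mean pressure (mmHg), mean flow (ml/s), and
#'   total distal resistance Pbar/Qbar (Pa s m^-3)
#' @export
outlet_summaries <- function(result) {
  p <- Pa_to_mmHg(outlet_mean_pressures(result))
  q <- m3s_to_mls(outlet_mean_flows(result))
  data.frame(outlet = names(p), p_mean_mmHg = unname(p), q_mean_mls = unname(q),
             r_total = vapply(seq_along(p),
                              function(i) outlet_resistance(p[i], q[i]),
                              numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Structured hemodynamic report
#'
#' Aggregates, for a calibrated model: one stenosis assessment per stenosed
#' segment, one outlet summary per outlet, neck-artery mean flows and
#' pulsatility indices, and (optionally) FBS tables with their comparison.
#'
#' @param model a `calibrated_model` (from [calibrate()]) or a list with
#'   `network` and `result`
#' @param fbs_model optional model-side [fbs_table()]
#' @param fbs_asl optional ASL-side [fbs_table()]
#' @return list of class `hemodynamic_report`
#' @export
hemodynamic_report <- function(model, fbs_model = NULL, fbs_asl = NULL) {
  result <- model$result
  net <- model$network
  sten <- Filter(function(s) !is.null(s$stenosis), net$segments)
  assessments <- lapply(names(sten), function(id) pressure_drop(result, id))
  names(assessments) <- names(sten)
  neck <- lapply(names(net$neck_arteries), function(k) {
    w <- segment_waveform(result, net$neck_arteries[[k]])
    list(artery = k, q_mean_mls = m3s_to_mls(waveform_mean(w)),
         pulsatility_index = pulsatility_index(w))
  })
  names(neck) <- names(net$neck_arteries)
  rep <- list(stenoses = assessments, outlets = outlet_summaries(result),
              neck_arteries = neck,
              cycles_run = result$cycles_run,
              periodicity_error = result$periodicity_error)
  if (!is.null(fbs_model)) rep$fbs_model <- fbs_model$m
  if (!is.null(fbs_asl)) rep$fbs_asl <- fbs_asl$m
  if (!is.null(fbs_model) && !is.null(fbs_asl)) {
    cmp <- fbs_compare(fbs_model, fbs_asl)
    rep$fbs_comparison <- list(r = cmp$r, mean_abs_diff = cmp$mean_abs_diff,
                               dominant_agreement = cmp$dominant_agreement)
  }
  structure(rep, class = "hemodynamic_report")
}

#' Write a hemodynamic report as JSON
#'
#' @param report a [hemodynamic_report()]
#' @param path output path
#' @export
write_report_json <- function(report, path) {
  ser <- list(
    stenoses = lapply(report$stenoses, function(a) unclass(a)),
    outlets = report$outlets,
    neck_arteries = report$neck_arteries,
    cycles_run = report$cycles_run,
    periodicity_error = report$periodicity_error
  )
  if (!is.null(report$fbs_model)) ser$fbs_model <- as.data.frame(report$fbs_model)
  if (!is.null(report$fbs_asl)) ser$fbs_asl <- as.data.frame(report$fbs_asl)
  if (!is.null(report$fbs_comparison)) ser$fbs_comparison <- report$fbs_comparison
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
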