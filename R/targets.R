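#' Canonical outlet and artery names
#'
#' The full anatomy has 13 outlets: descending aorta, the two subclavian
#' arteries, the two external carotids, and 8 intracranial arteries
#' (anterior/middle/posterior cerebral and superior cerebellar, left and
#' right). The 4 labeled neck arteries feed the Circle of Willis.
#'
#' @name anatomy_names
NULL

#' @rdname anatomy_names
#' @export
INTRACRANIAL_ARTERIES <- c("RACA", "LACA", "RMCA", "LMCA",
                           "RPCA", "LPCA", "RSCA", "LSCA")

#' @rdname anatomy_names
#' @export
OUTLET_NAMES <- c("DAo", "RSubclavian", "LSubclavian", "RECA", "LECA",
                  INTRACRANIAL_ARTERIES)

#' @rdname anatomy_names
#' @export
NECK_ARTERIES <- c("RICA", "LICA", "RVA", "LVA")

#' @rdname anatomy_names
#' @export
TERRITORY_NAMES <- c("RACA", "LACA", "RMCA", "LMCA", "RPCA", "LPCA",
                     "Cerebellum")

#' Default territory-to-artery map
#'
#' Each cerebral territory is perfused by the artery of the same name with
#' share 1; the cerebellum territory is perfused evenly by the right and left
#' superior cerebellar arteries (share 0.5 each).
#'
#' @return named list: territory -> named numeric vector of artery shares
#'   (shares per territory sum to 1)
#' @export
territory_artery_map <- function() {
  m <- list(
    RACA = c(RACA = 1), LACA = c(LACA = 1),
    RMCA = c(RMCA = 1), LMCA = c(LMCA = 1),
    RPCA = c(RPCA = 1), LPCA = c(LPCA = 1),
    Cerebellum = c(RSCA = 0.5, LSCA = 0.5)
  )
  structure(m, class = "territory_artery_map")
}

#' Summarize the aortic inflow waveform and brachial pressures
#'
#' Extracts cardiac output (mean aortic flow), flow extrema, and the signed
#' time lapse from the flow maximum to the following minimum (wrapping across
#' the period end), together with the brachial pressure pair. The derived
#' mean pressure uses the standard cuff estimate
#' P_mean = 1/3 P_systolic + 2/3 P_diastolic.
#'
#' @param aortic aortic inflow [waveform()], m^3/s
#' @param p_sys,p_dia brachial systolic and diastolic pressures, Pa
#' @return an object of class `inflow_summary`
#' @export
summarize_inflow <- function(aortic, p_sys, p_dia) {
  stopifnot(inherits(aortic, "waveform"))
  if (!is.finite(p_sys) || !is.finite(p_dia) || p_sys <= p_dia) {
    cf_stop("cf_invalid_pressure", "need p_sys > p_dia")
  }
  v <- aortic$values
  if (max(v) - min(v) <= 0) {
    cf_stop("cf_degenerate_waveform", "flat inflow waveform: no extrema")
  }
  i_max <- which.max(v)
  i_min <- which.min(v)
  dt <- (aortic$times[i_min] - aortic$times[i_max]) %% aortic$period
  structure(list(q_mean = waveform_mean(aortic),
                 q_max = v[i_max], q_min = v[i_min],
                 dt_max_to_min = dt,
                 p_systolic = p_sys, p_diastolic = p_dia,
                 p_mean = p_sys / 3 + 2 * p_dia / 3,
                 period = aortic$period),
            class = "inflow_summary")
}

#' Total arterial resistance
#'
#' R_T = P_mean / Q_T with P_mean = 1/3 P_systolic + 2/3 P_diastolic.
#'
#' @param summary an [summarize_inflow()] result
#' @return Pa s m^-3
#' @export
total_resistance <- function(summary) {
  if (summary$q_mean <= 0) {
    cf_stop("cf_invalid_flow", "cardiac output must be positive")
  }
  summary$p_mean / summary$q_mean
}

#' Total arterial compliance
#'
#' C_T = (Q_T,max - Q_T,min) / (P_systolic - P_diastolic) * dt, where dt is
#' the time lapse between the aortic flow maximum and minimum.
#'
#' @param summary an [summarize_inflow()] result
#' @return m^3 Pa^-1
#' @export
total_compliance <- function(summary) {
  pulse <- summary$p_systolic - summary$p_diastolic
  if (pulse <= 0) cf_stop("cf_invalid_pressure", "zero pulse pressure")
  (summary$q_max - summary$q_min) / pulse * summary$dt_max_to_min
}

#' Total mean inflow to the Circle of Willis
#'
#' Sum of the mean flows of the four neck-artery waveforms. A missing vessel
#' (hypoplasia) is treated as zero flow with a warning.
#'
#' @param ica_r,ica_l,va_r,va_l neck-artery [waveform()]s or NULL if absent
#' @return mean CoW inflow, m^3/s
#' @export
cow_inflow <- function(ica_r, ica_l, va_r, va_l) {
  ws <- list(RICA = ica_r, LICA = ica_l, RVA = va_r, LVA = va_l)
  total <- 0
  for (nm in names(ws)) {
    if (is.null(ws[[nm]])) {
      warning(sprintf("missing %s waveform: treated as zero flow (hypoplasia?)", nm))
    } else {
      total <- total + waveform_mean(ws[[nm]])
    }
  }
  if (total <= 0) warning("total CoW inflow is not positive")
  total
}

#' Intracranial target mean flows from a perfusion split
#'
#' Q_target,i = Q_CoW * ps_j * share(i in territory j): each cerebral
#' territory maps its whole split to its artery; the cerebellum split is
#' divided between the two superior cerebellar arteries.
#'
#' @param ps perfusion split: named numeric over the 7 territories summing
#'   to 1 (or a `perfusion_split` object)
#' @param q_cow mean CoW inflow, m^3/s (> 0)
#' @param map a [territory_artery_map()]
#' @param arteries character vector of arteries present in the network;
#'   NULL (default) means all 8. A missing artery whose territory share is
#'   positive raises a classed error for explicit re-mapping.
#' @return named numeric over the 8 intracranial arteries, m^3/s
#' @export
intracranial_targets <- function(ps, q_cow, map = territory_artery_map(),
                                 arteries = NULL) {
  if (inherits(ps, "perfusion_split")) ps <- ps$ps
  stopifnot(is.numeric(ps), !is.null(names(ps)))
  if (abs(sum(ps) - 1) > 1e-8) {
    cf_stop("cf_invalid_split", "perfusion split must sum to 1 (got %g)", sum(ps))
  }
  if (q_cow <= 0) cf_stop("cf_invalid_flow", "q_cow must be positive")
  targets <- stats::setNames(numeric(length(INTRACRANIAL_ARTERIES)),
                             INTRACRANIAL_ARTERIES)
  for (terr in names(map)) {
    shares <- map[[terr]]
    for (art in names(shares)) {
      targets[art] <- targets[art] + q_cow * ps[[terr]] * shares[[art]]
    }
  }
  if (!is.null(arteries)) {
    missing <- setdiff(names(targets)[targets > 0], arteries)
    if (length(missing)) {
      cf_stop("cf_missing_artery",
              "territory map assigns flow to absent arteries: %s",
              paste(missing, collapse = ", "))
    }
  }
  targets
}

#' Extracranial target mean flows
#'
#' External carotid targets are the PC-MRI means; each subclavian artery is
#' assigned a fixed fraction of cardiac output (default 5.6%); the descending
#' thoracic aorta receives the remainder of the inflow.
#'
#' @param eca_r,eca_l external-carotid [waveform()]s (or numeric mean flows)
#' @param summary an [summarize_inflow()] result
#' @param intracranial_total sum of the intracranial targets, m^3/s
#' @param subclavian_fraction per-subclavian fraction of cardiac output
#' @return named numeric: RECA, LECA, RSubclavian, LSubclavian, DAo (m^3/s)
#' @export
extracranial_targets <- function(eca_r, eca_l, summary, intracranial_total,
                                 subclavian_fraction = 0.056) {
  q_eca_r <- if (inherits(eca_r, "waveform")) waveform_mean(eca_r) else eca_r
  q_eca_l <- if (inherits(eca_l, "waveform")) waveform_mean(eca_l) else eca_l
  q_sub <- subclavian_fraction * summary$q_mean
  q_dao <- summary$q_mean - intracranial_total - q_eca_r - q_eca_l - 2 * q_sub
  if (q_dao <= 0) {
    cf_stop("cf_inconsistent_measurements",
            "assigned branch flows exceed cardiac output (remainder %g m^3/s)", q_dao)
  }
  c(RECA = q_eca_r, LECA = q_eca_l,
    RSubclavian = q_sub, LSubclavian = q_sub, DAo = q_dao)
}

#' Per-outlet target mean flows
#'
#' @param intracranial named numeric over the 8 intracranial arteries, m^3/s
#' @param extracranial named numeric from [extracranial_targets()]
#' @return an object of class `flow_targets`: `q` (named vector over the 13
#'   outlets), `q_cow`, `q_total`
#' @export
flow_targets <- function(intracranial, extracranial) {
  q <- c(extracranial[c("DAo", "RSubclavian", "LSubclavian", "RECA", "LECA")],
         intracranial[INTRACRANIAL_ARTERIES])
  if (any(is.na(q))) cf_stop("cf_invalid_targets", "incomplete target set")
  structure(list(q = q, q_cow = sum(intracranial), q_total = sum(q)),
            class = "flow_targets")
}

#' Initial Windkessel distribution
#'
#' Distributes the total arterial resistance and compliance among the
#' outlets: R_i = P_mean / Q_target,i (so the parallel combination equals
#' R_T and each outlet carries its target flow at mean pressure) and
#' C_i = C_T * R_T / R_i (compliance proportional to flow share). Each R_i
#' is split into a small proximal fraction (default 6%, re-tuned in
#' calibration stage 2) and the distal remainder.
#'
#' @param targets a [flow_targets()] (or named positive vector of mean flows)
#' @param summary an [summarize_inflow()] result
#' @param prox_fraction proximal share of each outlet's total resistance
#' @return a [windkessel_set()]
#' @export
init_windkessel <- function(targets, summary, prox_fraction = 0.06) {
  q <- if (inherits(targets, "flow_targets")) targets$q else targets
  if (any(q <= 0)) cf_stop("cf_invalid_targets", "all target flows must be > 0")
  r_t <- total_resistance(summary)
  c_t <- total_compliance(summary)
  r_i <- summary$p_mean / q
  c_i <- c_t * r_t / r_i
  windkessel_set(lapply(names(q), function(o) {
    windkessel_bc(o, r_prox = prox_fraction * r_i[[o]],
                  r_dist = (1 - prox_fraction) * r_i[[o]],
                  capacitance = c_i[[o]])
  }))
}
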