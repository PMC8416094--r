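#' Three-element Windkessel boundary condition
#'
#' Proximal resistance, distal resistance and capacitance representing the
#' vascular bed distal to one outlet. The distal (venous) reference pressure
#' is fixed at 0.
#'
#' @param outlet_id outlet name this boundary condition attaches to
#' @param r_prox proximal resistance, Pa s m^-3 (> 0)
#' @param r_dist distal resistance, Pa s m^-3 (> 0)
#' @param capacitance compliance, m^3 Pa^-1 (>= 0)
#' @return an object of class `windkessel_bc`
#' @export
windkessel_bc <- function(outlet_id, r_prox, r_dist, capacitance) {
  if (!is.finite(r_prox) || r_prox <= 0 || !is.finite(r_dist) || r_dist <= 0 ||
      !is.finite(capacitance) || capacitance < 0) {
    cf_stop("cf_invalid_windkessel",
            "outlet '%s': resistances must be > 0 and capacitance >= 0", outlet_id)
  }
  structure(list(outlet_id = as.character(outlet_id), r_prox = r_prox,
                 r_dist = r_dist, capacitance = capacitance),
            class = "windkessel_bc")
}

#' Total resistance of a Windkessel boundary condition
#' @param bc a [windkessel_bc()]
#' @return r_prox + r_dist, Pa s m^-3
#' @export
wk_total <- function(bc) bc$r_prox + bc$r_dist

#' Set of Windkessel boundary conditions for all outlets
#'
#' @param bcs list of [windkessel_bc()], one per outlet
#' @return an object of class `windkessel_set`, keyed by outlet name
#' @export
windkessel_set <- function(bcs) {
  ids <- vapply(bcs, `[[`, character(1), "outlet_id")
  if (anyDuplicated(ids)) cf_stop("cf_invalid_windkessel", "duplicate outlet ids")
  names(bcs) <- ids
  structure(bcs, class = "windkessel_set")
}

#' Aggregate totals of a Windkessel set
#'
#' @param wk a [windkessel_set()]
#' @return list with `r_total` (parallel combination of the per-outlet total
#'   resistances, Pa s m^-3) and `c_total` (sum of capacitances, m^3 Pa^-1)
#' @export
wk_totals <- function(wk) {
  r <- vapply(wk, wk_total, numeric(1))
  list(r_total = 1 / sum(1 / r),
       c_total = sum(vapply(wk, `[[`, numeric(1), "capacitance")))
}

#' Solver options for the pulsatile network solver
#'
#' @param dt time step, s (default 1 ms; the lumped system is not stiff at
#'   this resolution and outlet means change < 0.5% on halving)
#' @param periodicity_tol relative L2 cycle-to-cycle tolerance (default 1e-3)
#' @param max_cycles maximum cardiac cycles before a convergence error
#' @param min_cycles minimum cycles to run (periodicity needs >= 2)
#' @param picard_iter fixed-point iterations per step for the nonlinear
#'   stenosis elements (ignored for linear networks)
#' @return an object of class `solver_options`
#' @export
solver_options <- function(dt = 1e-3, periodicity_tol = 1e-3, max_cycles = 20,
                           min_cycles = 2, picard_iter = 3) {
  stopifnot(dt > 0, periodicity_tol > 0, max_cycles >= min_cycles, min_cycles >= 1)
  structure(list(dt = dt, periodicity_tol = periodicity_tol,
                 max_cycles = max_cycles, min_cycles = min_cycles,
                 picard_iter = picard_iter),
            class = "solver_options")
}

# Build the constant data needed to assemble the time-stepping system.
# Unknowns: [network node pressures, capacitor pressures (one per outlet)].
build_solver_layout <- function(net, wk, dt) {
  nodes <- net$nodes
  n_node <- length(nodes)
  out_names <- names(net$outlets)
  if (!all(out_names %in% names(wk))) {
    cf_stop("cf_invalid_windkessel", "Windkessel set does not cover all outlets")
  }
  n_out <- length(out_names)
  node_idx <- stats::setNames(seq_len(n_node), nodes)
  cap_idx <- stats::setNames(n_node + seq_len(n_out), out_names)
  segs <- net$segments
  sfrom <- vapply(segs, function(s) node_idx[[s$from]], integer(1))
  sto <- vapply(segs, function(s) node_idx[[s$to]], integer(1))
  res <- vapply(segs, `[[`, numeric(1), "resistance")
  ine <- vapply(segs, `[[`, numeric(1), "inertance")
  kv <- vapply(segs, function(s) if (is.null(s$stenosis)) 0 else s$stenosis$k_linear,
               numeric(1))
  kt <- vapply(segs, function(s) if (is.null(s$stenosis)) 0 else s$stenosis$k_turb,
               numeric(1))
  n_all <- n_node + n_out
  # static matrix: linear segments + Windkessel rows
  A0 <- matrix(0, n_all, n_all)
  g_lin <- 1 / (res + ine / dt + kv)  # conductance excluding the |q| term
  if (any(!is.finite(g_lin))) {
    cf_stop("cf_invalid_network",
            "segment(s) with zero impedance (resistance, inertance and k_linear all 0)")
  }
  nonlin <- which(kt > 0)
  for (k in seq_along(segs)) {
    if (k %in% nonlin) next
    f <- sfrom[k]; t <- sto[k]; g <- g_lin[k]
    A0[f, f] <- A0[f, f] + g; A0[f, t] <- A0[f, t] - g
    A0[t, t] <- A0[t, t] + g; A0[t, f] <- A0[t, f] - g
  }
  rp <- vapply(out_names, function(o) wk[[o]]$r_prox, numeric(1))
  rd <- vapply(out_names, function(o) wk[[o]]$r_dist, numeric(1))
  cc <- vapply(out_names, function(o) wk[[o]]$capacitance, numeric(1))
  onode <- vapply(out_names, function(o) node_idx[[net$outlets[[o]]]], integer(1))
  for (j in seq_len(n_out)) {
    n <- onode[j]; c <- cap_idx[j]
    A0[n, n] <- A0[n, n] + 1 / rp[j]; A0[n, c] <- A0[n, c] - 1 / rp[j]
    A0[c, c] <- cc[j] / dt + 1 / rd[j] + 1 / rp[j]
    A0[c, n] <- -1 / rp[j]
  }
  list(nodes = nodes, node_idx = node_idx, cap_idx = cap_idx,
       n_node = n_node, n_out = n_out, n_all = n_all,
       sfrom = sfrom, sto = sto, res = res, ine = ine, kv = kv, kt = kt,
       nonlin = nonlin, g_lin = g_lin, A0 = A0,
       rp = rp, rd = rd, cc = cc, onode = onode, out_names = out_names,
       inlet_idx = node_idx[[net$inlet]], dt = dt)
}

#' Solve pulsatile flow and pressure on a lumped network
#'
#' Implicit (backward-Euler) time stepping of the resistive-inertial network
#' with nonlinear stenosis elements (Picard-linearized) and three-element
#' Windkessel outflow boundary conditions. Whole cardiac cycles are iterated
#' until the relative L2 cycle-to-cycle change of every monitored signal
#' (all segment flows and outlet pressures) drops below
#' `opts$periodicity_tol`.
#'
#' @param net a [network_model()]
#' @param wk a [windkessel_set()] covering all outlets
#' @param inflow inflow [waveform()] at the inlet node, m^3/s
#' @param opts a [solver_options()]
#' @param state optional warm-start state from a previous `sim_result`
#'   (its `state` element); reuses final pressures and flows
#' @return an object of class `sim_result`: final-cycle time series
#'   (`times`, `seg_flows` segments x steps, `node_pressures` nodes x steps,
#'   `outlet_flows`, `outlet_pressures`, `cap_pressures`), `cycles_run`,
#'   `periodicity_error`, per-cycle `periodicity_trace`, and `state` for
#'   warm restarts
#' @export
solve_transient <- function(net, wk, inflow, opts = solver_options(),
                            state = NULL) {
  stopifnot(inherits(net, "network_model"), inherits(wk, "windkessel_set"),
            inherits(inflow, "waveform"))
  dt <- opts$dt
  lay <- build_solver_layout(net, wk, dt)
  n_steps <- max(2L, as.integer(round(inflow$period / dt)))
  dt <- inflow$period / n_steps  # snap dt so cycles tile the period exactly
  if (abs(dt - opts$dt) > 0.5 * opts$dt) {
    cf_stop("cf_solver", "period %g s is too short for dt %g", inflow$period, opts$dt)
  }
  lay <- build_solver_layout(net, wk, dt)
  tgrid <- seq_len(n_steps) * dt
  qin <- wave_at(inflow, tgrid)

  n_seg <- length(lay$sfrom)
  if (is.null(state)) {
    # initialize at the steady mean-flow operating point to shorten transients
    p0 <- rep(waveform_mean(inflow) * wk_totals(wk)$r_total, lay$n_all)
    q0 <- rep(0, n_seg)
  } else {
    p0 <- state$p; q0 <- state$q
  }

  prev_F <- NULL; prev_P <- NULL
  per_err <- Inf
  trace <- numeric(0)
  cycles <- 0L
  F <- matrix(0, n_seg, n_steps)
  P <- matrix(0, lay$n_all, n_steps)

  while (cycles < opts$max_cycles) {
    cycles <- cycles + 1L
    for (k in seq_len(n_steps)) {
      A <- lay$A0
      b <- numeric(lay$n_all)
      # inertial history terms
      cseg <- lay$g_lin * (lay$ine / dt) * q0
      # nonlinear stenosis segments: Picard on |q|
      q_star <- q0[lay$nonlin]
      n_pic <- if (length(lay$nonlin)) opts$picard_iter else 1L
      for (pic in seq_len(n_pic)) {
        if (length(lay$nonlin)) {
          g_nl <- 1 / (lay$res[lay$nonlin] + lay$ine[lay$nonlin] / dt +
                       lay$kv[lay$nonlin] + lay$kt[lay$nonlin] * abs(q_star))
          c_nl <- g_nl * (lay$ine[lay$nonlin] / dt) * q0[lay$nonlin]
          A <- lay$A0
          for (m in seq_along(lay$nonlin)) {
            s <- lay$nonlin[m]; f <- lay$sfrom[s]; t <- lay$sto[s]; g <- g_nl[m]
            A[f, f] <- A[f, f] + g; A[f, t] <- A[f, t] - g
            A[t, t] <- A[t, t] + g; A[t, f] <- A[t, f] - g
          }
          cseg[lay$nonlin] <- c_nl
        }
        b <- numeric(lay$n_all)
        # segment constant parts: outflow at 'from', inflow at 'to'
        for (s in seq_len(n_seg)) {
          b[lay$sfrom[s]] <- b[lay$sfrom[s]] - cseg[s]
          b[lay$sto[s]] <- b[lay$sto[s]] + cseg[s]
        }
        b[lay$inlet_idx] <- b[lay$inlet_idx] + qin[k]
        b[lay$cap_idx] <- b[lay$cap_idx] + (lay$cc / dt) * p0[lay$cap_idx]
        p <- solve(A, b)
        # flows at this iterate
        gall <- lay$g_lin
        if (length(lay$nonlin)) gall[lay$nonlin] <- g_nl
        q <- gall * (p[lay$sfrom] - p[lay$sto]) + cseg
        if (length(lay$nonlin)) {
          conv <- max(abs(q[lay$nonlin] - q_star) /
                        (abs(q_star) + 1e-12))
          q_star <- q[lay$nonlin]
          if (conv < 1e-8) break
        }
      }
      F[, k] <- q
      P[, k] <- p
      p0 <- p
      q0 <- q
    }
    # periodicity over all segment flows and all pressures
    if (!is.null(prev_F)) {
      sc <- max(abs(prev_F), 1e-12)
      errF <- sqrt(rowSums((F - prev_F)^2)) / pmax(sqrt(rowSums(prev_F^2)), sc * 1e-3)
      scp <- max(abs(prev_P), 1e-9)
      errP <- sqrt(rowSums((P - prev_P)^2)) / pmax(sqrt(rowSums(prev_P^2)), scp * 1e-3)
      per_err <- max(errF, errP)
      trace <- c(trace, per_err)
      if (cycles >= opts$min_cycles && per_err < opts$periodicity_tol) break
    }
    # non-finite tolerance = run exactly min_cycles cycles (controller mode)
    if (!is.finite(opts$periodicity_tol) && cycles >= opts$min_cycles) break
    prev_F <- F; prev_P <- P
    F <- matrix(0, n_seg, n_steps)
    P <- matrix(0, lay$n_all, n_steps)
  }
  if (is.finite(opts$periodicity_tol) &&
      !(per_err < opts$periodicity_tol) && cycles >= opts$max_cycles) {
    cf_stop("cf_convergence",
            "no cycle-to-cycle periodicity after %d cycles (error %.3g, tol %.3g)",
            cycles, per_err, opts$periodicity_tol)
  }
  if (identical(dim(F), dim(prev_F)) && all(F == 0) && !is.null(prev_F)) {
    # loop broke right after reset (cannot happen: break occurs before reset)
    F <- prev_F; P <- prev_P
  }
  out_p <- P[lay$onode, , drop = FALSE]
  cap_p <- P[lay$cap_idx, , drop = FALSE]
  out_q <- (out_p - cap_p) / lay$rp
  rownames(F) <- names(net$segments)
  rownames(P) <- c(lay$nodes, paste0("cap_", lay$out_names))
  rownames(out_q) <- lay$out_names
  rownames(out_p) <- lay$out_names
  structure(list(times = tgrid, dt = dt, period = inflow$period,
                 seg_flows = F,
                 node_pressures = P[seq_len(lay$n_node), , drop = FALSE],
                 cap_pressures = cap_p,
                 outlet_flows = out_q, outlet_pressures = out_p,
                 cycles_run = cycles, periodicity_error = per_err,
                 periodicity_trace = trace,
                 inflow = qin,
                 network = net, wk = wk,
                 state = list(p = p0, q = q0)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d cycles, periodicity error %.3g, %d steps/cycle\n",
              x$cycles_run, x$periodicity_error, length(x$times)))
  invisible(x)
}

#' Cycle-mean outlet flows of a simulation
#' @param result a `sim_result`
#' @return named vector of mean outlet flows, m^3/s
#' @export
outlet_mean_flows <- function(result) rowMeans(result$outlet_flows)

#' Cycle-mean outlet pressures of a simulation
#' @param result a `sim_result`
#' @return named vector of mean outlet pressures, Pa
#' @export
outlet_mean_pressures <- function(result) rowMeans(result$outlet_pressures)

#' Cycle-mean segment flows of a simulation
#' @param result a `sim_result`
#' @return named vector of mean segment flows, m^3/s
#' @export
segment_mean_flows <- function(result) rowMeans(result$seg_flows)

#' Check cycle-to-cycle periodicity of a simulation
#'
#' @param result a `sim_result`
#' @param tol relative L2 tolerance
#' @return TRUE iff the final cycle-to-cycle change of every monitored signal
#'   is below `tol`
#' @export
check_periodicity <- function(result, tol = 1e-3) {
  if (result$cycles_run < 2L || !length(result$periodicity_trace)) {
    cf_stop("cf_insufficient_data", "need at least 2 simulated cycles")
  }
  result$periodicity_error < tol
}

#' Simulated flow waveform of a named segment
#' @param result a `sim_result`
#' @param segment segment id
#' @return a [waveform()] of the final-cycle flow
#' @export
segment_waveform <- function(result, segment) {
  if (!segment %in% rownames(result$seg_flows)) {
    cf_stop("cf_unknown_segment", "no segment '%s' in result", segment)
  }
  waveform(result$times - result$dt, result$seg_flows[segment, ],
           period = result$period)
}
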