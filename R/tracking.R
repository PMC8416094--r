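#' Fractional blood supply by deterministic junction mixing
#'
#' Solves the steady composition-transport system on the cycle-mean flows:
#' each labeled neck-artery segment carries a pure source composition, and at
#' every junction the outflow composition is the flow-weighted mixture of the
#' inflow compositions (complete mixing — a 0D network carries no secondary
#' flow structure). Outlet compositions give the fraction of each outlet's
#' flow originating at each neck artery; intracranial outlets are mapped to
#' territory FBS (cerebellum = flow-weighted mix of the two superior
#' cerebellar outlets).
#'
#' @param result a periodic `sim_result`
#' @param net the [network_model()] (defaults to the one in `result`)
#' @param sources named character vector artery -> source segment id
#'   (defaults to the network's neck arteries)
#' @param map a [territory_artery_map()]
#' @return an [fbs_table()] with source "transport"; attribute
#'   `outlet_fbs` holds the raw outlet x source matrix and attribute
#'   `reversing_segments` any segments whose flow changes sign over the cycle
#' @export
transport_fractions <- function(result, net = result$network,
                                sources = net$neck_arteries,
                                map = territory_artery_map()) {
  qbar <- segment_mean_flows(result)
  # flag segments whose instantaneous flow changes sign over the cycle
  sgn <- apply(result$seg_flows, 1, function(v) {
    any(v > 1e-15) && any(v < -1e-15)
  })
  reversing <- names(which(sgn))
  # orient every segment along its mean flow
  segs <- net$segments
  up <- vapply(segs, `[[`, character(1), "from")
  dn <- vapply(segs, `[[`, character(1), "to")
  flip <- qbar[names(segs)] < 0
  tmp <- up[flip]; up[flip] <- dn[flip]; dn[flip] <- tmp
  qabs <- abs(qbar[names(segs)])
  nodes <- net$nodes
  n_node <- length(nodes)
  node_idx <- stats::setNames(seq_len(n_node), nodes)
  n_src <- length(sources)
  A <- matrix(0, n_node, n_node)
  B <- matrix(0, n_node, n_src, dimnames = list(nodes, names(sources)))
  inflow_tot <- stats::setNames(numeric(n_node), nodes)
  for (s in names(segs)) {
    inflow_tot[dn[s]] <- inflow_tot[dn[s]] + qabs[s]
  }
  scale <- max(qabs, 1e-12)
  for (n in nodes) {
    i <- node_idx[[n]]
    if (inflow_tot[n] <= 1e-12 * scale) {
      A[i, i] <- 1                      # unlabeled head node (aortic inlet)
      next
    }
    A[i, i] <- inflow_tot[n]
    for (s in names(segs)) {
      if (dn[s] != n) next
      src_k <- names(sources)[match(s, sources)]
      if (!is.na(src_k)) {
        B[i, src_k] <- B[i, src_k] + qabs[s]   # labeled source segment
      } else {
        A[i, node_idx[[up[s]]]] <- A[i, node_idx[[up[s]]]] - qabs[s]
      }
    }
  }
  comp <- tryCatch(solve(A, B), error = function(e) {
    cf_stop("cf_structural", "singular junction-mixing system: %s",
            conditionMessage(e))
  })
  rownames(comp) <- nodes
  out_nodes <- net$outlets
  out_fbs <- comp[out_nodes, , drop = FALSE]
  rownames(out_fbs) <- names(out_nodes)
  q_out <- outlet_mean_flows(result)
  # map intracranial outlets to territories
  M <- matrix(0, length(map), n_src,
              dimnames = list(names(map), names(sources)))
  for (terr in names(map)) {
    arts <- names(map[[terr]])
    arts <- intersect(arts, rownames(out_fbs))
    if (!length(arts)) {
      M[terr, ] <- NA_real_
      next
    }
    w <- q_out[arts]
    if (sum(w) <= 0) w <- rep(1, length(arts))
    M[terr, ] <- colSums(out_fbs[arts, , drop = FALSE] * (w / sum(w)))
  }
  tab <- fbs_table(M, source = "transport")
  attr(tab, "outlet_fbs") <- out_fbs
  attr(tab, "reversing_segments") <- reversing
  tab
}

#' Fractional blood supply by stochastic particle routing
#'
#' The reduced-order analog of Lagrangian particle tracking: particles are
#' seeded at the labeled neck-artery segments at a rate proportional to each
#' artery's instantaneous flow, re-injected over `inject_cycles` cardiac
#' cycles, advected segment-by-segment with transit time given by segment
#' volume over the time-resolved flow, and routed at junctions with
#' probabilities proportional to the instantaneous outflows. Arrivals are
#' counted at the intracranial outlets; per-cycle arrival counts are checked
#' for periodicity (relative change of the last two populated cycles < 5%).
#'
#' @param result a periodic `sim_result`
#' @param net the [network_model()]
#' @param n_total total particle budget across the four sources (>= 1000)
#' @param seed RNG seed for reproducible routing
#' @param sources named artery -> source segment map
#' @param map a [territory_artery_map()]
#' @param inject_cycles cycles over which particles are re-injected
#' @param n_bins phase bins for the arrival histograms
#' @return list: `fbs` (an [fbs_table()], source "particles"), `ledger`
#'   (counts per outlet x source, arrival phase histograms, retired count,
#'   per-cycle arrival totals, periodic flag)
#' @export
particle_fbs <- function(result, net = result$network, n_total = 1e4,
                         seed = 1, sources = net$neck_arteries,
                         map = territory_artery_map(),
                         inject_cycles = 4, n_bins = 20) {
  if (n_total < 1e3) cf_stop("cf_invalid_budget", "n_total must be >= 1000")
  set.seed(seed)
  segs <- net$segments
  seg_ids <- names(segs)
  Tp <- result$period
  dt <- result$dt
  F <- result$seg_flows
  n_steps <- ncol(F)
  tg <- c(0, result$times)              # n_steps + 1 grid points
  # per-segment cumulative volume over one cycle and geometry
  vol <- vapply(segs, function(s) pi * s$radius^2 * s$length, numeric(1))
  vol[vol <= 0] <- 1e-9                 # zero-length connectors: tiny volume
  cum <- lapply(seg_ids, function(s) c(0, cumsum(F[s, ] * dt)))
  names(cum) <- seg_ids
  cum_rev <- lapply(seg_ids, function(s) c(0, cumsum(-F[s, ] * dt)))
  names(cum_rev) <- seg_ids
  vcyc <- vapply(cum, function(x) x[length(x)], numeric(1))
  qmean <- segment_mean_flows(result)
  # adjacency: segments touching each node
  seg_from <- vapply(segs, `[[`, character(1), "from")
  seg_to <- vapply(segs, `[[`, character(1), "to")
  by_node <- split(rep(seg_ids, 2), c(seg_from, seg_to))
  out_node_of <- stats::setNames(names(net$outlets), net$outlets)
  wk_q <- result$outlet_flows           # outlet WK flows, n_out x n_steps
  step_at <- function(t) {
    k <- as.integer(floor((t %% Tp) / dt)) + 1L
    if (k > n_steps) k <- n_steps
    k
  }
  # transit along segment s in direction dir (+1 = from->to, -1 = to->from):
  # advance the direction-signed cumulated volume by the segment volume
  transit_exit_time <- function(s, t0, dir) {
    cc <- if (dir > 0) cum[[s]] else cum_rev[[s]]
    vc <- cc[length(cc)]
    if (vc <= 0) return(NA_real_)       # stagnant or net-retrograde traversal
    phi0 <- t0 %% Tp
    v0 <- stats::approx(tg, cc, xout = phi0, rule = 2, ties = "ordered")$y
    v <- v0 + vol[s]
    nfull <- floor(v / vc)
    rem <- v - nfull * vc
    phi1 <- stats::approx(cc, tg, xout = rem, rule = 2, ties = "ordered")$y
    (t0 - phi0) + nfull * Tp + phi1
  }
  # injection times per source: inverse-CDF of the cumulative source flow,
  # replicated over inject_cycles cycles
  q_src <- pmax(qmean[sources], 0)
  if (sum(q_src) <= 0) cf_stop("cf_structural", "no positive source flow")
  n_k <- round(n_total * q_src / sum(q_src))
  n_k[n_k < 1] <- 1
  counts <- matrix(0L, length(net$outlets), length(sources),
                   dimnames = list(names(net$outlets), names(sources)))
  hist_arr <- array(0L, dim = c(length(net$outlets), length(sources), n_bins),
                    dimnames = list(names(net$outlets), names(sources), NULL))
  retired <- 0L
  arrival_cycle <- integer(0)
  for (k in seq_along(sources)) {
    src_seg <- sources[[k]]
    n_p <- n_k[k]
    cs <- cum[[src_seg]]
    if (vcyc[src_seg] <= 0) next
    u <- (seq_len(n_p) - 0.5) / n_p     # stratified over cumulative flow
    per_cycle <- ceiling(n_p / inject_cycles)
    t_inj <- numeric(0)
    for (cyc in seq_len(inject_cycles)) {
      idx <- ((cyc - 1) * per_cycle + 1):min(cyc * per_cycle, n_p)
      if (!length(idx) || idx[1] > n_p) break
      uu <- (seq_along(idx) - stats::runif(length(idx))) / length(idx)
      phi <- stats::approx(cs / vcyc[src_seg], tg, xout = uu, rule = 2,
                           ties = "ordered")$y
      t_inj <- c(t_inj, (cyc - 1) * Tp + phi)
    }
    for (t0 in t_inj) {
      s <- src_seg
      dir <- 1L
      t <- t0
      arrived <- FALSE
      for (hop in seq_len(200L)) {
        t_exit <- transit_exit_time(s, t, dir)
        if (!is.finite(t_exit)) { retired <- retired + 1L; break }
        t <- t_exit
        node <- if (dir > 0) seg_to[s] else seg_from[s]
        kk <- step_at(t)
        # candidate outflows at the arrival instant (segment, direction, weight)
        cand <- character(0); cdir <- integer(0); w <- numeric(0)
        add_cands <- function(flow_of) {
          for (s2 in by_node[[node]]) {
            if (s2 == s) next
            q2 <- flow_of(s2)
            if (seg_from[s2] == node && q2 > 0) {
              cand <<- c(cand, s2); cdir <<- c(cdir, 1L); w <<- c(w, q2)
            }
            if (seg_to[s2] == node && q2 < 0) {
              cand <<- c(cand, s2); cdir <<- c(cdir, -1L); w <<- c(w, -q2)
            }
          }
        }
        add_cands(function(s2) F[s2, kk])
        onm <- out_node_of[node]
        if (!is.na(onm)) {
          qo <- wk_q[onm, kk]
          if (qo > 0) { cand <- c(cand, paste0("@", onm)); cdir <- c(cdir, 1L); w <- c(w, qo) }
        }
        if (!length(cand)) {            # momentary stagnation: use mean flows
          add_cands(function(s2) qmean[s2])
          if (!is.na(onm)) {
            qo <- mean(wk_q[onm, ])
            if (qo > 0) { cand <- c(cand, paste0("@", onm)); cdir <- c(cdir, 1L); w <- c(w, qo) }
          }
        }
        if (!length(cand)) { retired <- retired + 1L; break }
        j <- sample.int(length(cand), 1L, prob = w)
        pick <- cand[j]
        if (startsWith(pick, "@")) {
          onm <- substring(pick, 2)
          counts[onm, k] <- counts[onm, k] + 1L
          bin <- min(n_bins, 1L + as.integer(floor((t %% Tp) / Tp * n_bins)))
          hist_arr[onm, k, bin] <- hist_arr[onm, k, bin] + 1L
          arrival_cycle <- c(arrival_cycle, as.integer(floor(t / Tp)))
          arrived <- TRUE
          break
        }
        s <- pick
        dir <- cdir[j]
      }
      if (!arrived && hop >= 200L) retired <- retired + 1L
    }
  }
  # per-cycle arrival periodicity (interior injection cycles only)
  cyc_tot <- table(factor(arrival_cycle, levels = 0:max(arrival_cycle, 1)))
  interior <- as.integer(cyc_tot)[2:max(2, inject_cycles)]
  periodic <- length(interior) < 2 ||
    abs(diff(range(interior))) / max(mean(interior), 1) < 0.05
  # FBS over intracranial outlets only
  intr <- intersect(rownames(counts), INTRACRANIAL_ARTERIES)
  cc <- counts[intr, , drop = FALSE]
  M <- matrix(NA_real_, length(map), length(sources),
              dimnames = list(names(map), names(sources)))
  for (terr in names(map)) {
    arts <- intersect(names(map[[terr]]), intr)
    if (!length(arts)) next
    tot <- colSums(cc[arts, , drop = FALSE])
    if (sum(tot) > 0) M[terr, ] <- tot / sum(tot)
  }
  tab <- fbs_table(M, source = "particles")
  list(fbs = tab,
       ledger = list(counts = counts, histograms = hist_arr,
                     retired = retired, per_cycle_arrivals = as.integer(cyc_tot),
                     periodic = periodic, seed = seed, n_total = n_total))
}

#' Compare two fractional-blood-supply tables
#'
#' Pearson correlation over all territory x artery cells (pairwise complete),
#' the per-cell difference matrix, and per-territory dominant-source
#' agreement (does each table name the same largest-share artery).
#'
#' @param model an [fbs_table()] (model side)
#' @param asl an [fbs_table()] (measurement side), same labels
#' @return list: `r` (Pearson), `diff` (model - asl), `mean_abs_diff`,
#'   `dominant_agreement` (fraction of territories agreeing), `n_missing`
#' @export
fbs_compare <- function(model, asl) {
  stopifnot(inherits(model, "fbs_table"), inherits(asl, "fbs_table"))
  if (!identical(dimnames(model$m), dimnames(asl$m))) {
    cf_stop("cf_invalid_fbs", "FBS tables must share territory/artery labels")
  }
  a <- as.vector(model$m); b <- as.vector(asl$m)
  ok <- is.finite(a) & is.finite(b)
  n_missing <- sum(!ok)
  if (sum(ok) < 3) cf_stop("cf_invalid_fbs", "too few complete cells to compare")
  r <- stats::cor(a[ok], b[ok], method = "pearson")
  d <- model$m - asl$m
  dom <- vapply(rownames(model$m), function(terr) {
    ma <- model$m[terr, ]; aa <- asl$m[terr, ]
    if (any(!is.finite(ma)) || any(!is.finite(aa))) return(NA)
    names(which.max(ma)) == names(which.max(aa))
  }, logical(1))
  list(r = r, diff = d, mean_abs_diff = mean(abs(d[is.finite(d)])),
       dominant_agreement = mean(dom, na.rm = TRUE),
       dominant_by_territory = dom, n_missing = n_missing)
}
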