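#' Vessel segment
#'
#' A lumped vessel segment joining two named nodes. Resistance and inertance
#' default to the Poiseuille / plug-flow closures for the given geometry and
#' blood; either can be overridden (e.g. zero-resistance connectors in test
#' fixtures).
#'
#' @param id unique segment identifier
#' @param from,to node names (flow is positive from `from` to `to`)
#' @param length segment length, m
#' @param radius lumen radius, m
#' @param name anatomical label (defaults to `id`)
#' @param blood a [blood_properties()] object used to derive coefficients
#' @param resistance override Poiseuille resistance, Pa s m^-3
#' @param inertance override inertance, Pa s^2 m^-3 (set 0 for purely resistive)
#' @param stenosis optional [stenosis_element()]
#' @return an object of class `vessel_segment`
#' @export
vessel_segment <- function(id, from, to, length, radius, name = id,
                           blood = blood_properties(),
                           resistance = NULL, inertance = NULL,
                           stenosis = NULL) {
  if (!is.finite(length) || length < 0 || !is.finite(radius) || radius <= 0) {
    cf_stop("cf_invalid_geometry",
            "segment '%s': length must be >= 0 and radius > 0", id)
  }
  if (is.null(resistance)) resistance <- segment_resistance(length, radius, blood)
  if (is.null(inertance)) inertance <- segment_inertance(length, radius, blood)
  if (!is.null(stenosis)) stopifnot(inherits(stenosis, "stenosis_element"))
  structure(list(id = as.character(id), name = as.character(name),
                 from = as.character(from), to = as.character(to),
                 length = length, radius = radius,
                 resistance = resistance, inertance = inertance,
                 stenosis = stenosis),
            class = "vessel_segment")
}

#' Vascular network model
#'
#' A directed graph of [vessel_segment()]s from a single inflow node to a set
#' of named outlet nodes. Junctions enforce pressure continuity and mass
#' conservation (no junction losses). Outlet nodes are where three-element
#' Windkessel boundary conditions attach; `neck_arteries` names the labeled
#' source segments used for supply tracking (RICA, LICA, RVA, LVA in the full
#' anatomy).
#'
#' @param segments list of [vessel_segment()]
#' @param inlet inlet node name (ascending aorta in the full anatomy)
#' @param outlets named character vector mapping outlet name -> node name
#' @param neck_arteries named character vector mapping artery name -> segment id
#' @return an object of class `network_model`
#' @export
network_model <- function(segments, inlet, outlets, neck_arteries = character()) {
  ids <- vapply(segments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) cf_stop("cf_invalid_network", "duplicate segment ids")
  names(segments) <- ids
  nodes <- unique(c(vapply(segments, `[[`, character(1), "from"),
                    vapply(segments, `[[`, character(1), "to")))
  if (!inlet %in% nodes) cf_stop("cf_invalid_network", "inlet node not in graph")
  if (is.null(names(outlets)) || any(names(outlets) == "")) {
    cf_stop("cf_invalid_network", "outlets must be a named character vector")
  }
  if (!all(outlets %in% nodes)) {
    cf_stop("cf_invalid_network", "outlet node(s) not in graph: %s",
            paste(setdiff(outlets, nodes), collapse = ", "))
  }
  if (length(neck_arteries) && !all(neck_arteries %in% ids)) {
    cf_stop("cf_invalid_network", "neck artery segment(s) not in graph")
  }
  net <- structure(list(segments = segments, inlet = inlet, outlets = outlets,
                        neck_arteries = neck_arteries, nodes = nodes),
                   class = "network_model")
  # every outlet must be reachable from the inlet (undirected connectivity
  # is not enough: segments are directed only by sign convention, so we
  # check connectivity on the undirected graph)
  reach <- reachable_nodes(net, inlet)
  if (!all(nodes %in% reach)) {
    cf_stop("cf_invalid_network", "graph is not connected: unreachable node(s) %s",
            paste(setdiff(nodes, reach), collapse = ", "))
  }
  net
}

# undirected reachability from a node
reachable_nodes <- function(net, start) {
  adj <- list()
  for (s in net$segments) {
    adj[[s$from]] <- c(adj[[s$from]], s$to)
    adj[[s$to]] <- c(adj[[s$to]], s$from)
  }
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d segments, %d nodes, %d outlets, %d neck arteries\n",
              length(x$segments), length(x$nodes), length(x$outlets),
              length(x$neck_arteries)))
  cat("  inlet:", x$inlet, "\n")
  cat("  outlets:", paste(names(x$outlets), collapse = " "), "\n")
  invisible(x)
}

#' Segment summary table
#'
#' @param net a [network_model()]
#' @return data.frame with one row per segment
#' @export
segment_table <- function(net) {
  data.frame(
    id = vapply(net$segments, `[[`, character(1), "id"),
    name = vapply(net$segments, `[[`, character(1), "name"),
    from = vapply(net$segments, `[[`, character(1), "from"),
    to = vapply(net$segments, `[[`, character(1), "to"),
    length = vapply(net$segments, `[[`, numeric(1), "length"),
    radius = vapply(net$segments, `[[`, numeric(1), "radius"),
    resistance = vapply(net$segments, `[[`, numeric(1), "resistance"),
    inertance = vapply(net$segments, `[[`, numeric(1), "inertance"),
    stenosed = vapply(net$segments, function(s) !is.null(s$stenosis), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a network model to JSON
#'
#' @param net a [network_model()]
#' @param path output path
#' @export
write_network_json <- function(net, path) {
  segs <- lapply(net$segments, function(s) {
    out <- list(id = s$id, name = s$name, from = s$from, to = s$to,
                length_m = s$length, radius_m = s$radius,
                resistance = s$resistance, inertance = s$inertance)
    if (!is.null(s$stenosis)) {
      out$stenosis <- list(k_linear = s$stenosis$k_linear,
                           k_turb = s$stenosis$k_turb,
                           min_diameter = s$stenosis$min_diameter,
                           reference_diameter = s$stenosis$reference_diameter)
    }
    out
  })
  obj <- list(segments = unname(segs), inlet = net$inlet,
              outlets = as.list(net$outlets),
              neck_arteries = as.list(net$neck_arteries))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a network model from JSON
#'
#' @param path path to a JSON file written by [write_network_json()]
#' @return a [network_model()]
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path)
  segs <- lapply(obj$segments, function(s) {
    sten <- NULL
    if (!is.null(s$stenosis)) {
      sten <- stenosis_element(s$stenosis$k_linear, s$stenosis$k_turb,
                               s$stenosis$min_diameter,
                               s$stenosis$reference_diameter)
    }
    vessel_segment(s$id, s$from, s$to, s$length_m, s$radius_m, name = s$name,
                   resistance = s$resistance, inertance = s$inertance,
                   stenosis = sten)
  })
  network_model(segs, inlet = obj$inlet,
                outlets = unlist(obj$outlets),
                neck_arteries = unlist(obj$neck_arteries))
}
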