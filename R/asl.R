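#' Perfusion volume
#'
#' A 3D scalar perfusion-signal image (arbitrary units; negative voxels are
#' legitimate ASL noise) on the same grid as the territory atlas.
#'
#' @param data 3D numeric array
#' @param voxel_dim voxel size in mm, length 3
#' @return an object of class `perfusion_volume`
#' @export
perfusion_volume <- function(data, voxel_dim = c(3, 3, 3)) {
  if (length(dim(data)) != 3L) cf_stop("cf_shape", "perfusion volume must be 3D")
  if (any(!is.finite(data))) cf_stop("cf_shape", "perfusion volume must be finite")
  structure(list(data = data, voxel_dim = voxel_dim,
                 voxel_volume = prod(voxel_dim)),
            class = "perfusion_volume")
}

#' Vascular territory atlas
#'
#' Integer label image: 0 = background, 1..7 = vascular territories
#' (1 RACA, 2 LACA, 3 RMCA, 4 LMCA, 5 RPCA, 6 LPCA, 7 Cerebellum).
#'
#' @param labels 3D integer array with values in 0..7
#' @param voxel_dim voxel size in mm, length 3
#' @param territory_names label -> name map (default the canonical 7)
#' @return an object of class `territory_atlas`
#' @export
territory_atlas <- function(labels, voxel_dim = c(3, 3, 3),
                            territory_names = TERRITORY_NAMES) {
  if (length(dim(labels)) != 3L) cf_stop("cf_shape", "atlas must be 3D")
  u <- sort(unique(as.vector(labels)))
  if (any(u != round(u)) || any(u < 0) || any(u > length(territory_names))) {
    cf_stop("cf_atlas_labels", "atlas labels must be integers in 0..%d",
            length(territory_names))
  }
  missing <- setdiff(seq_along(territory_names), u)
  if (length(missing)) {
    cf_stop("cf_atlas_labels", "empty territory label(s): %s",
            paste(territory_names[missing], collapse = ", "))
  }
  structure(list(labels = array(as.integer(labels), dim = dim(labels)),
                 voxel_dim = voxel_dim,
                 territory_names = territory_names),
            class = "territory_atlas")
}

check_same_grid <- function(a, b) {
  da <- dim(if (!is.null(a$data)) a$data else a$labels)
  db <- dim(if (!is.null(b$data)) b$data else b$labels)
  if (!identical(da, db)) {
    cf_stop("cf_shape", "grid mismatch: %s vs %s",
            paste(da, collapse = "x"), paste(db, collapse = "x"))
  }
  invisible(TRUE)
}

#' Average label/control difference images
#'
#' The ASL perfusion signal is the voxelwise mean over acquired pairs of
#' (control - label).
#'
#' @param labels list of 3D arrays (label images)
#' @param controls list of 3D arrays (control images), same length and grid
#' @param voxel_dim voxel size in mm
#' @return a [perfusion_volume()]
#' @export
subtract_and_average <- function(labels, controls, voxel_dim = c(3, 3, 3)) {
  if (length(labels) != length(controls) || !length(labels)) {
    cf_stop("cf_shape", "need equal, nonzero counts of label and control images")
  }
  d <- dim(labels[[1]])
  acc <- array(0, dim = d)
  for (i in seq_along(labels)) {
    if (!identical(dim(labels[[i]]), d) || !identical(dim(controls[[i]]), d)) {
      cf_stop("cf_shape", "label/control pair %d is not on the common grid", i)
    }
    acc <- acc + (controls[[i]] - labels[[i]])
  }
  perfusion_volume(acc / length(labels), voxel_dim)
}

#' Perfusion splits over the vascular territories
#'
#' ps_j = (integral of perfusion signal over territory j) /
#' (integral over the union of all territories). Background voxels are
#' excluded from the whole-brain integral.
#'
#' @param perf a [perfusion_volume()]
#' @param atlas a [territory_atlas()] on the same grid
#' @return an object of class `perfusion_split` with `ps` (named fractions
#'   summing to 1) and `territory_signal` (raw integrals)
#' @export
perfusion_splits <- function(perf, atlas) {
  check_same_grid(perf, atlas)
  lab <- as.vector(atlas$labels)
  sig <- as.vector(perf$data)
  n_terr <- length(atlas$territory_names)
  sums <- vapply(seq_len(n_terr), function(j) sum(sig[lab == j]), numeric(1))
  names(sums) <- atlas$territory_names
  total <- sum(sums)
  if (abs(total) < .Machine$double.eps * length(sig)) {
    cf_stop("cf_degenerate_signal", "whole-brain perfusion integral is zero")
  }
  structure(list(ps = sums / total,
                 territory_signal = sums * perf$voxel_volume),
            class = "perfusion_split")
}

#' Vessel-selective ASL study
#'
#' One perfusion volume per neck artery plus the measured labeling
#' efficiency for each (fraction of ideal inversion, in (0, 1]).
#'
#' @param volumes named list of [perfusion_volume()] keyed RICA, LICA, RVA, LVA
#' @param efficiencies named numeric in (0, 1], same keys
#' @return an object of class `vsasl_study`
#' @export
vsasl_study <- function(volumes, efficiencies) {
  if (!setequal(names(volumes), NECK_ARTERIES) ||
      !setequal(names(efficiencies), NECK_ARTERIES)) {
    cf_stop("cf_invalid_study", "need all four neck arteries: %s",
            paste(NECK_ARTERIES, collapse = ", "))
  }
  if (any(efficiencies <= 0) || any(efficiencies > 1)) {
    cf_stop("cf_invalid_efficiency", "labeling efficiencies must be in (0, 1]")
  }
  structure(list(volumes = volumes[NECK_ARTERIES],
                 efficiencies = efficiencies[NECK_ARTERIES]),
            class = "vsasl_study")
}

#' Scale vessel-selective volumes by labeling efficiency
#'
#' Each artery's perfusion volume is divided by its labeling efficiency so
#' signals are comparable across arteries.
#'
#' @param study a [vsasl_study()]
#' @return named list of scaled [perfusion_volume()]s
#' @export
scale_by_efficiency <- function(study) {
  stopifnot(inherits(study, "vsasl_study"))
  out <- lapply(NECK_ARTERIES, function(k) {
    v <- study$volumes[[k]]
    perfusion_volume(v$data / study$efficiencies[[k]], v$voxel_dim)
  })
  stats::setNames(out, NECK_ARTERIES)
}

#' Voxelwise fractional-blood-supply maps
#'
#' map_k = scaled_k / sum_k scaled_k per voxel. Voxels whose total perfusion
#' magnitude is below `floor_frac` times the maximum total are masked invalid
#' (NA) rather than divided.
#'
#' @param scaled named list of 4 scaled [perfusion_volume()]s (one grid)
#' @param floor_frac relative floor on |total| below which a voxel is masked
#' @return list with `maps` (named list of 3D arrays with NA at invalid
#'   voxels) and `valid` (logical 3D array)
#' @export
fbs_maps <- function(scaled, floor_frac = 1e-9) {
  stopifnot(setequal(names(scaled), NECK_ARTERIES))
  for (k in NECK_ARTERIES[-1]) check_same_grid(scaled[[1]], scaled[[k]])
  total <- Reduce(`+`, lapply(scaled[NECK_ARTERIES], function(v) v$data))
  valid <- abs(total) > floor_frac * max(abs(total))
  maps <- lapply(NECK_ARTERIES, function(k) {
    m <- scaled[[k]]$data / total
    m[!valid] <- NA_real_
    m
  })
  list(maps = stats::setNames(maps, NECK_ARTERIES), valid = valid)
}

#' Median and median absolute deviation
#'
#' The raw (unscaled) MAD: median of absolute deviations from the median.
#'
#' @param x numeric vector (NAs removed)
#' @return list with `m` and `mad`
#' @export
median_mad <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(list(m = NA_real_, mad = NA_real_))
  m <- stats::median(x)
  list(m = m, mad = stats::median(abs(x - m)))
}

#' Fractional-blood-supply table
#'
#' Territories (rows) by neck arteries (columns) matrix of fractional blood
#' supply, with an optional dispersion matrix (ASL source only) and a source
#' tag. For conservative sources (`transport`, `particles`) rows sum to 1 and
#' entries lie in [0, 1]; ASL entries may be negative or exceed 1 (noise).
#'
#' @param m 7 x 4 numeric matrix (territories x arteries)
#' @param mad optional matching dispersion matrix
#' @param source one of "asl", "transport", "particles"
#' @return an object of class `fbs_table`
#' @export
fbs_table <- function(m, mad = NULL, source = c("asl", "transport", "particles")) {
  source <- match.arg(source)
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- TERRITORY_NAMES
  if (is.null(colnames(m))) colnames(m) <- NECK_ARTERIES
  if (source != "asl") {
    ok <- is.finite(m)
    if (any(m[ok] < -1e-9 | m[ok] > 1 + 1e-9)) {
      cf_stop("cf_invalid_fbs", "%s FBS entries must lie in [0, 1]", source)
    }
    rs <- rowSums(m)
    if (any(abs(rs[is.finite(rs)] - 1) > 1e-6)) {
      cf_stop("cf_invalid_fbs", "%s FBS rows must sum to 1", source)
    }
  }
  structure(list(m = m, mad = mad, source = source), class = "fbs_table")
}

#' @export
print.fbs_table <- function(x, ...) {
  cat(sprintf("fbs_table (source=%s):\n", x$source))
  print(round(x$m, 3))
  invisible(x)
}

#' Territory-wise FBS statistics from voxelwise maps
#'
#' For each (territory, artery) cell: median and raw median absolute
#' deviation of the valid voxel values. Negative voxel values are retained
#' (ASL noise can produce them). A territory with no valid voxels yields an
#' NA cell and a warning.
#'
#' @param maps result of [fbs_maps()]
#' @param atlas a [territory_atlas()] on the same grid
#' @return an [fbs_table()] with source "asl" and a matching `mad` matrix
#' @export
territory_fbs_stats <- function(maps, atlas) {
  lab <- as.vector(atlas$labels)
  n_terr <- length(atlas$territory_names)
  M <- matrix(NA_real_, n_terr, 4,
              dimnames = list(atlas$territory_names, NECK_ARTERIES))
  D <- M
  for (j in seq_len(n_terr)) {
    sel <- lab == j
    for (k in NECK_ARTERIES) {
      vals <- as.vector(maps$maps[[k]])[sel]
      st <- median_mad(vals)
      M[j, k] <- st$m
      D[j, k] <- st$mad
    }
  }
  if (any(is.na(M))) warning("territory with zero valid voxels: NA cells flagged")
  fbs_table(M, mad = D, source = "asl")
}

#' Write an FBS table as long-format CSV
#'
#' Columns: territory, artery, value, mad (NA unless ASL), source.
#'
#' @param tab an [fbs_table()]
#' @param path output path
#' @export
write_fbs_csv <- function(tab, path) {
  df <- expand.grid(territory = rownames(tab$m), artery = colnames(tab$m),
                    stringsAsFactors = FALSE)
  df$value <- tab$m[cbind(df$territory, df$artery)]
  df$mad <- if (is.null(tab$mad)) NA_real_ else tab$mad[cbind(df$territory, df$artery)]
  df$source <- tab$source
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an FBS table from long-format CSV
#'
#' @param path path written by [write_fbs_csv()]
#' @return an [fbs_table()]
#' @export
read_fbs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  terrs <- unique(df$territory)
  arts <- unique(df$artery)
  m <- matrix(NA_real_, length(terrs), length(arts), dimnames = list(terrs, arts))
  m[cbind(df$territory, df$artery)] <- df$value
  mad <- NULL
  if (any(!is.na(df$mad))) {
    mad <- m
    mad[cbind(df$territory, df$artery)] <- df$mad
  }
  fbs_table(m, mad = mad, source = df$source[1])
}

#' Read a NIfTI file as a perfusion volume
#'
#' @param path .nii path
#' @return a [perfusion_volume()]
#' @export
read_nifti_volume <- function(path) {
  nii <- read_nifti(path)
  perfusion_volume(nii$data, voxel_dim = nii$voxel_dim)
}

#' Read a NIfTI file as a territory atlas
#'
#' The volume must be integer-typed (or integer-valued) with at most 8
#' distinct labels in 0..7.
#'
#' @param path .nii path
#' @return a [territory_atlas()]
#' @export
read_nifti_atlas <- function(path) {
  nii <- read_nifti(path)
  v <- as.vector(nii$data)
  if (any(v != round(v))) {
    cf_stop("cf_atlas_labels", "atlas volume is not integer-valued: %s", path)
  }
  if (length(unique(v)) > 8L) {
    cf_stop("cf_atlas_labels", "atlas has more than 8 distinct labels: %s", path)
  }
  territory_atlas(array(as.integer(nii$data), dim = dim(nii$data)),
                  voxel_dim = nii$voxel_dim)
}

#' Write a perfusion volume to NIfTI
#' @param vol a [perfusion_volume()]
#' @param path output .nii path
#' @export
write_nifti_volume <- function(vol, path) {
  write_nifti(vol$data, path, voxel_dim = vol$voxel_dim, datatype = "float64")
}

#' Write a territory atlas to NIfTI (int16) with a JSON label sidecar
#' @param atlas a [territory_atlas()]
#' @param path output .nii path (sidecar written as `<path>.json`)
#' @export
write_nifti_atlas <- function(atlas, path) {
  write_nifti(atlas$labels, path, voxel_dim = atlas$voxel_dim, datatype = "int16")
  side <- stats::setNames(as.list(atlas$territory_names),
                          as.character(seq_along(atlas$territory_names)))
  jsonlite::write_json(c(list(`0` = "background"), side),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
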