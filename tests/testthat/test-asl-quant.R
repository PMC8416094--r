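# ASL perfusion quantification against the territory atlas

# tiny atlas with known voxel counts per territory
tiny_atlas <- function(equal = FALSE) {
  lab <- array(0L, dim = c(7, 4, 3))
  if (equal) {
    # 7 territories x 12 voxels each: territory j = slab x == j
    for (j in 1:7) lab[j, , ] <- j
  } else {
    for (j in 1:7) lab[j, seq_len(min(j, 4)), 1] <- j
  }
  territory_atlas(lab, voxel_dim = c(2, 2, 2))
}

test_that("subtract_and_average matches a per-voxel loop oracle", {
  d <- c(4, 3, 2)
  img <- function(x) array(x, dim = d)
  # control = label -> zero
  z <- subtract_and_average(list(img(5)), list(img(5)))
  expect_true(all(z$data == 0))
  # pair diffs {2, 4} -> 3
  m <- subtract_and_average(list(img(0), img(0)), list(img(2), img(4)))
  expect_true(all(m$data == 3))
  # 8 noisy pairs vs naive loop
  set.seed(11)
  labs <- replicate(8, array(rnorm(prod(d)), dim = d), simplify = FALSE)
  ctls <- replicate(8, array(rnorm(prod(d)), dim = d), simplify = FALSE)
  got <- subtract_and_average(labs, ctls)$data
  want <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (p in 1:8) acc <- acc + (ctls[[p]][i, j, k] - labs[[p]][i, j, k])
    want[i, j, k] <- acc / 8
  }
  expect_equal(got, want)
  expect_error(subtract_and_average(labs[1:2], ctls[1:3]), class = "cf_shape")
  bad <- labs
  bad[[1]] <- array(0, dim = c(2, 2, 2))
  expect_error(subtract_and_average(bad, ctls), class = "cf_shape")
})

test_that("perfusion_splits: uniform signal over equal territories gives 1/7", {
  atlas <- tiny_atlas(equal = TRUE)
  vol <- perfusion_volume(array(2.5, dim = dim(atlas$labels)),
                          voxel_dim = atlas$voxel_dim)
  ps <- perfusion_splits(vol, atlas)
  expect_equal(unname(ps$ps), rep(1 / 7, 7), tolerance = 1e-14)
})

test_that("perfusion_splits localizes signal and matches a loop oracle", {
  atlas <- tiny_atlas()
  d <- dim(atlas$labels)
  sig <- array(0, dim = d)
  sig[atlas$labels == 3] <- 7    # all signal in RMCA territory
  ps <- perfusion_splits(perfusion_volume(sig, atlas$voxel_dim), atlas)
  expect_equal(unname(ps$ps["RMCA"]), 1)
  expect_equal(sum(ps$ps), 1)
  # arbitrary (including negative) voxel values vs naive summation
  set.seed(7)
  sig <- array(rnorm(prod(d), mean = 1), dim = d)
  ps <- perfusion_splits(perfusion_volume(sig, atlas$voxel_dim), atlas)
  want <- numeric(7)
  tot <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    l <- atlas$labels[i, j, k]
    if (l > 0) {
      want[l] <- want[l] + sig[i, j, k]
      tot <- tot + sig[i, j, k]
    }
  }
  expect_equal(unname(ps$ps), want / tot)
  expect_equal(sum(ps$ps), 1, tolerance = 1e-12)
  # degenerate zero total
  expect_error(perfusion_splits(perfusion_volume(array(0, dim = d),
                                                 atlas$voxel_dim), atlas),
               class = "cf_degenerate_signal")
})

test_that("scale_by_efficiency divides each artery by its efficiency", {
  d <- c(3, 3, 2)
  effs <- c(RICA = 0.8, LICA = 0.9, RVA = 0.85, LVA = 0.95)
  set.seed(3)
  vols <- lapply(NECK_ARTERIES, function(k) {
    perfusion_volume(array(rnorm(prod(d), 5), dim = d), c(2, 2, 2))
  })
  names(vols) <- NECK_ARTERIES
  sc <- scale_by_efficiency(vsasl_study(vols, effs))
  for (k in NECK_ARTERIES) {
    expect_equal(sc[[k]]$data, vols[[k]]$data / effs[[k]])
  }
  unit <- scale_by_efficiency(vsasl_study(vols, c(RICA = 1, LICA = 1,
                                                  RVA = 1, LVA = 1)))
  expect_equal(unit$RICA$data, vols$RICA$data)
  expect_error(vsasl_study(vols, c(RICA = 0, LICA = 1, RVA = 1, LVA = 1)),
               class = "cf_invalid_efficiency")
})

test_that("fbs_maps normalizes per voxel and masks near-zero totals", {
  d <- c(2, 2, 1)
  mk <- function(x) perfusion_volume(array(x, dim = d), c(1, 1, 1))
  vols <- list(RICA = mk(2), LICA = mk(1), RVA = mk(1), LVA = mk(0))
  fm <- fbs_maps(vols)
  expect_equal(unique(as.vector(fm$maps$RICA)), 0.5)
  expect_equal(unique(as.vector(fm$maps$LICA)), 0.25)
  expect_equal(unique(as.vector(fm$maps$LVA)), 0)
  # noisy volumes with negatives still sum to 1 at valid voxels
  set.seed(5)
  vols <- lapply(vols, function(v) mk(array(rnorm(prod(d)), dim = d)))
  fm <- fbs_maps(vols)
  tot <- Reduce(`+`, fm$maps)
  expect_equal(as.vector(tot)[as.vector(fm$valid)],
               rep(1, sum(fm$valid)), tolerance = 1e-12)
  # exact-zero total is masked, not divided
  vols <- list(RICA = mk(c(1, 0, 0, 0)), LICA = mk(c(-1, 0, 0, 0)),
               RVA = mk(c(0, 1, 1, 1)), LVA = mk(0))
  fm <- fbs_maps(vols)
  expect_false(fm$valid[1, 1, 1])
  expect_true(is.na(fm$maps$RICA[1, 1, 1]))
})

test_that("median_mad matches a sort-based brute force", {
  expect_equal(median_mad(c(0.1, 0.4, 0.7)), list(m = 0.4, mad = 0.3))
  expect_equal(median_mad(c(-0.1, -0.05, 0.02))$m, -0.05)  # negatives retained
  brute <- function(x) {
    s <- sort(x); n <- length(s)
    med <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    dev <- sort(abs(x - med))
    md <- if (n %% 2) dev[(n + 1) / 2] else (dev[n / 2] + dev[n / 2 + 1]) / 2
    list(m = med, mad = md)
  }
  set.seed(9)
  for (n in c(1, 2, 17, 1000)) {
    x <- rnorm(n)
    expect_equal(median_mad(x), brute(x))
  }
})

test_that("territory_fbs_stats yields per-cell median/MAD", {
  atlas <- tiny_atlas(equal = TRUE)
  d <- dim(atlas$labels)
  const <- lapply(c(RICA = 0.6, LICA = 0.4, RVA = 0, LVA = 0), function(x) {
    array(x, dim = d)
  })
  maps <- list(maps = const, valid = array(TRUE, dim = d))
  tab <- territory_fbs_stats(maps, atlas)
  expect_s3_class(tab, "fbs_table")
  expect_equal(unname(tab$m[, "RICA"]), rep(0.6, 7))
  expect_true(all(tab$mad == 0))
})

test_that("NIfTI volumes round-trip through the minimal reader/writer", {
  d <- c(6, 5, 4)
  set.seed(2)
  vol <- perfusion_volume(array(rnorm(prod(d)), dim = d), c(3, 3, 3.5))
  path <- withr::local_tempfile(fileext = ".nii")
  write_nifti_volume(vol, path)
  back <- read_nifti_volume(path)
  expect_equal(back$data, vol$data)          # float64 storage: exact
  expect_equal(back$voxel_dim, vol$voxel_dim, tolerance = 1e-6)
  # atlas round trip is bit-stable (int16)
  atlas <- tiny_atlas()
  apath <- withr::local_tempfile(fileext = ".nii")
  write_nifti_atlas(atlas, apath)
  back <- read_nifti_atlas(apath)
  expect_identical(back$labels, atlas$labels)
  expect_true(file.exists(paste0(apath, ".json")))
  # a float volume is rejected as an atlas; out-of-range labels rejected
  fpath <- withr::local_tempfile(fileext = ".nii")
  write_nifti(array(1.5, dim = c(2, 2, 2)), fpath, datatype = "float32")
  expect_error(read_nifti_atlas(fpath), class = "cf_atlas_labels")
  expect_error(territory_atlas(array(9L, dim = c(2, 2, 2))),
               class = "cf_atlas_labels")
})

test_that("FBS tables round-trip through long-format CSV", {
  set.seed(4)
  m <- matrix(runif(28), 7, 4, dimnames = list(TERRITORY_NAMES, NECK_ARTERIES))
  mad <- matrix(runif(28, 0, 0.1), 7, 4,
                dimnames = dimnames(m))
  tab <- fbs_table(m, mad = mad, source = "asl")
  path <- withr::local_tempfile(fileext = ".csv")
  write_fbs_csv(tab, path)
  back <- read_fbs_csv(path)
  expect_equal(back$m, tab$m)
  expect_equal(back$mad, tab$mad)
  expect_identical(back$source, "asl")
  # conservative sources are validated
  expect_error(fbs_table(m, source = "transport"), class = "cf_invalid_fbs")
})
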