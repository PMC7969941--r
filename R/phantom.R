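#' Synthetic CT phantom specification
#'
#' Defines a scaled-down abdominal scene with the challenges the segmentation
#' pipeline targets: a large lobed "liver" (union of overlapping ellipsoids,
#' singly connected in 3D but splitting into multiple regions on some
#' slices), smooth intensity inhomogeneity, Gaussian noise, and an adjacent
#' organ of overlapping intensity attached through a thin neck (to exercise
#' bottleneck removal). Geometry and noise use separate sub-seeds derived
#' from `rng_seed`, so the ground truth never depends on the noise draw.
#'
#' @param shape grid `(nz, ny, nx)`, at least `(8, 32, 32)`.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param liver_mean_hu,organ_mean_hu,background_hu class mean intensities.
#'   The defaults (110, 100, -20 HU) sit inside the W150/L80 liver display
#'   window with a 10 HU liver-organ gap, mimicking the fuzzy separation of
#'   liver and heart tissue.
#' @param liver_sd_hu,organ_sd_hu per-class texture standard deviations
#'   (default 0; global noise is usually sufficient).
#' @param bias_amplitude amplitude (HU) of the smooth sinusoidal
#'   inhomogeneity field.
#' @param neck_width_px width in pixels of the bridge joining liver and
#'   adjacent organ (0 = organ detached).
#' @param noise_sd_hu global additive Gaussian noise standard deviation.
#' @param rng_seed integer seed; runs are bit-reproducible for a fixed spec.
#' @param with_organ include the adjacent organ (and neck) at all.
#' @param vessel_radius_px radius of an optional bright tube along z inside
#'   the liver (0 = none), for exercising the vessel-extraction mode.
#' @param vessel_mean_hu intensity of the tube.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48, 320, 320), spacing = c(0.7, 0.7, 2.0),
                         liver_mean_hu = 110, liver_sd_hu = 0,
                         organ_mean_hu = 100, organ_sd_hu = 0,
                         background_hu = -20, bias_amplitude = 10,
                         neck_width_px = 3, noise_sd_hu = 12,
                         rng_seed = 42L, with_organ = TRUE,
                         vessel_radius_px = 0, vessel_mean_hu = 170) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(8L, 32L, 32L)))
    stop("shape must be (nz, ny, nx) with nz >= 8 and ny, nx >= 32")
  if (any(c(liver_sd_hu, organ_sd_hu, noise_sd_hu) < 0))
    stop("standard deviations must be >= 0")
  structure(list(
    shape = shape, spacing = as.numeric(spacing),
    liver_mean_hu = liver_mean_hu, liver_sd_hu = liver_sd_hu,
    organ_mean_hu = organ_mean_hu, organ_sd_hu = organ_sd_hu,
    background_hu = background_hu, bias_amplitude = bias_amplitude,
    neck_width_px = neck_width_px, noise_sd_hu = noise_sd_hu,
    rng_seed = as.integer(rng_seed), with_organ = isTRUE(with_organ),
    vessel_radius_px = vessel_radius_px, vessel_mean_hu = vessel_mean_hu
  ), class = "phantom_spec")
}

# logical ellipsoid mask on the (z, y, x) grid; centre/semi in voxel units
ellipsoid_mask <- function(shape, centre, semi) {
  z <- slice.index(array(0, shape), 1)
  y <- slice.index(array(0, shape), 2)
  x <- slice.index(array(0, shape), 3)
  ((z - centre[1]) / semi[1])^2 + ((y - centre[2]) / semi[2])^2 +
    ((x - centre[3]) / semi[3])^2 <= 1
}

#' Generate a synthetic CT phantom
#'
#' Builds the scene described by a [phantom_spec()]: liver truth mask,
#' adjacent organ (with its connecting neck recorded in the organ mask), CT
#' volume with class means, inhomogeneity bias, and noise, plus a suggested
#' seed at the liver centroid. The geometry scales with the grid so the liver
#' occupies a clinically proportionate share of the field of view.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_result`: list with `volume` ([ct_volume]), `truth`
#'   ([binary_mask]), `organ_mask` ([binary_mask]), `vessel_mask` (or `NULL`),
#'   `suggested_seed` ([seed_point]), and the `spec`.
#' @export
generate_phantom <- function(spec) {
  d <- spec$shape
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  sy <- ny / 200; sx <- nx / 200; sz <- nz / 24  # reference geometry scale
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$rng_seed)               # geometry stream
  jit <- stats::runif(6, -2, 2) * c(sy, sx, sy, sx, sy, sx)
  liver <- ellipsoid_mask(d, c(12 * sz, 106 * sy + jit[1], 87 * sx + jit[2]),
                          c(9 * sz, 65 * sy, 77 * sx)) |
    ellipsoid_mask(d, c(10 * sz, 69 * sy + jit[3], 125 * sx + jit[4]),
                   c(7 * sz, 44 * sy, 47 * sx)) |
    ellipsoid_mask(d, c(20 * sz, 137 * sy + jit[5], 150 * sx + jit[6]),
                   c(5.5 * sz, 27 * sy, 30 * sx))
  organ <- array(FALSE, d)
  if (spec$with_organ) {
    oc <- c(12 * sz, 20 * sy, 56 * sx)
    os <- c(6 * sz, 14 * sy, 16 * sx)
    if (oc[2] - os[2] < 1 || oc[3] - os[3] < 1 || oc[3] + os[3] > nx)
      stop("impossible geometry: adjacent organ falls outside the grid")
    organ <- ellipsoid_mask(d, oc, os)
    if (spec$neck_width_px > 0) {
      # bridge from the organ into the liver along the organ's whole z-extent,
      # so the organ abuts the liver on every slice where it exists
      xw <- max(1L, round(spec$neck_width_px))
      xs <- round(56 * sx - (xw - 1) / 2); xs <- max(1L, xs)
      xe <- min(nx, xs + xw - 1L)
      ys <- round(20 * sy); ye <- round(50 * sy)
      zs <- max(1L, round((12 - 5) * sz)); ze <- min(nz, round((12 + 5) * sz))
      organ[zs:ze, ys:ye, xs:xe] <- TRUE
    }
    organ <- organ & !liver
  }
  vessel <- NULL
  if (spec$vessel_radius_px > 0) {
    y <- slice.index(array(0, d), 2); x <- slice.index(array(0, d), 3)
    z <- slice.index(array(0, d), 1)
    tube <- (y - 106 * sy)^2 + (x - 87 * sx)^2 <= spec$vessel_radius_px^2
    # confined to the central liver so every tube slice is a full disk
    tube <- tube & (abs(z - 12 * sz) <= 0.72 * 9 * sz)
    vessel <- tube & liver
  }

  # intensities: class means + smooth sinusoidal bias + noise
  vol <- array(spec$background_hu, d)
  vol[liver] <- spec$liver_mean_hu
  vol[organ] <- spec$organ_mean_hu
  if (!is.null(vessel)) vol[vessel] <- spec$vessel_mean_hu
  if (spec$liver_sd_hu > 0)
    vol[liver] <- vol[liver] + stats::rnorm(sum(liver), 0, spec$liver_sd_hu)
  if (spec$organ_sd_hu > 0 && any(organ))
    vol[organ] <- vol[organ] + stats::rnorm(sum(organ), 0, spec$organ_sd_hu)
  if (spec$bias_amplitude != 0) {
    y <- slice.index(array(0, d), 2); x <- slice.index(array(0, d), 3)
    vol <- vol + spec$bias_amplitude *
      sin(2 * pi * x / nx + 0.7) * sin(2 * pi * y / ny + 1.3)
  }
  set.seed(spec$rng_seed + 1L)          # independent noise stream
  if (spec$noise_sd_hu > 0)
    vol <- vol + array(stats::rnorm(prod(d), 0, spec$noise_sd_hu), d)

  # seed at the liver centroid (snapped into the mask if the centroid falls
  # outside, e.g. for crescent geometries)
  idx <- which(liver, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  if (!liver[ctr[1], ctr[2], ctr[3]]) {
    dd <- rowSums(sweep(idx, 2, ctr)^2)
    ctr <- idx[which.min(dd), ]
  }
  seed <- seed_point(x = ctr[3] - 1L, y = ctr[2] - 1L, z = ctr[1] - 1L)

  structure(list(
    volume = ct_volume(vol, spec$spacing),
    truth = binary_mask(liver + 0L, spec$spacing),
    organ_mask = binary_mask(organ + 0L, spec$spacing),
    vessel_mask = if (!is.null(vessel)) binary_mask(vessel + 0L, spec$spacing),
    suggested_seed = seed, spec = spec
  ), class = "phantom_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# polynomial rolling digest of a spec's canonical JSON, for the manifest
spec_hash <- function(spec) {
  s <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write the canonical phantom fixture suite
#'
#' Generates and writes three cases -- `clean` (no noise, no bias, no
#' adjacent organ), `necked` (the default spec: organ of near-liver intensity
#' attached by a thin neck), and `noisy` (elevated noise) -- as MetaImage
#' volumes with their truth and organ masks, plus a JSON manifest recording
#' each case's seed, spec and spec digest.
#'
#' @param out_dir writable output directory (created if missing).
#' @param rng_seed base seed for the suite.
#' @param shape grid passed to every case's [phantom_spec()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
make_fixture_suite <- function(out_dir, rng_seed = 42L, shape = c(48, 320, 320)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    clean = phantom_spec(shape = shape, noise_sd_hu = 0, bias_amplitude = 0,
                         with_organ = FALSE, rng_seed = rng_seed),
    necked = phantom_spec(shape = shape, rng_seed = rng_seed + 1L),
    noisy = phantom_spec(shape = shape, noise_sd_hu = 20,
                         rng_seed = rng_seed + 2L)
  )
  manifest <- list()
  for (nm in names(specs)) {
    ph <- generate_phantom(specs[[nm]])
    vol_path <- file.path(out_dir, paste0(nm, ".mhd"))
    write_volume(ph$volume, vol_path)
    write_mask(ph$truth, file.path(out_dir, paste0(nm, "_truth.mhd")))
    if (any(ph$organ_mask$voxels > 0))
      write_mask(ph$organ_mask, file.path(out_dir, paste0(nm, "_organ.mhd")))
    manifest[[nm]] <- list(
      volume = basename(vol_path),
      truth = paste0(nm, "_truth.mhd"),
      rng_seed = specs[[nm]]$rng_seed,
      spec_digest = spec_hash(specs[[nm]]),
      suggested_seed = unclass(ph$suggested_seed),
      liver_voxels = sum(ph$truth$voxels),
      organ_voxels = sum(ph$organ_mask$voxels),
      organ_liver_hu_gap = abs(specs[[nm]]$organ_mean_hu -
                                 specs[[nm]]$liver_mean_hu)
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
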