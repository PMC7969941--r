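# Shared fixtures. The heavy full-scale pipeline runs are computed once per
# test session and reused across test files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

clean_phantom <- function() cached("clean_ph", generate_phantom(
  phantom_spec(noise_sd_hu = 0, bias_amplitude = 0, with_organ = FALSE)))

clean_run <- function() cached("clean_run", suppressWarnings(
  segment_liver(clean_phantom()$volume, clean_phantom()$suggested_seed)))

necked_phantom <- function() cached("necked_ph", generate_phantom(phantom_spec()))

necked_run <- function() cached("necked_run", suppressWarnings(
  segment_liver(necked_phantom()$volume, necked_phantom()$suggested_seed)))

# adjacent organ of liver-identical intensity joined by a wide neck: the
# configuration where the over-segment genuinely leaks into the initial
# segmentation and must be cut away by bottleneck detection + the
# adjacent-contour constraint
fuzzy_phantom <- function() cached("fuzzy_ph", generate_phantom(
  phantom_spec(organ_mean_hu = 110, neck_width_px = 15,
               noise_sd_hu = 0, bias_amplitude = 0)))

fuzzy_run <- function() cached("fuzzy_run", suppressWarnings(
  segment_liver(fuzzy_phantom()$volume, fuzzy_phantom()$suggested_seed)))

# small phantom for fast property / determinism checks (liver too small for
# high-fidelity recovery, which these tests do not assert)
small_phantom <- function(...) generate_phantom(
  phantom_spec(shape = c(12, 96, 96), noise_sd_hu = 0, bias_amplitude = 0,
               with_organ = FALSE, ...))

# dumbbell mask: two 10x10 squares joined by a 2-wide, 6-long corridor
dumbbell_mask <- function() {
  d <- matrix(0L, 30, 40)
  d[10:19, 5:14] <- 1L
  d[10:19, 21:30] <- 1L
  d[14:15, 15:20] <- 1L
  d
}

# a slice_contour stub carrying only the fields contour_constraint reads
fake_contour <- function(pixels, dim = c(300, 300)) {
  structure(list(vertices = matrix(0, 3, 2), slice_index = 0L,
                 area = length(pixels), pixels = sort(pixels), dim = dim,
                 keypoints = NULL),
            class = "slice_contour")
}

# elongated wavy blob: two convex bulge apexes facing each other across the
# short axis, with long boundary arcs between them (low bottleneck cost but
# convex exterior angles)
lens_polygon <- function() {
  t <- seq(0, 2 * pi, length.out = 241)[-241]
  x <- 50 * cos(t); y <- 10 * sin(t)
  keep <- !(abs(x) < 10 & abs(y) > 5)   # excise around both short-axis apexes
  v <- cbind(x, y)[keep, ]
  top <- which(v[, 2] > 5 & v[, 1] <= 10)  # insertion point after x = +10, top
  # counter-clockwise ellipse runs right -> top -> left; insert bump apexes
  i_top <- max(which(v[, 1] >= 10 & v[, 2] > 0))
  i_bot <- max(which(v[, 1] <= -10 & v[, 2] < 0))
  ytop <- 10 * sqrt(1 - (10 / 50)^2)
  apex_top <- c(0, ytop + 10 * tan(15 * pi / 180))       # side slopes 15 deg
  apex_bot <- c(0, -ytop - 10 * tan(32.5 * pi / 180))    # side slopes 32.5 deg
  rbind(v[seq_len(i_top), ], apex_top,
        v[(i_top + 1):i_bot, ], apex_bot,
        v[(i_bot + 1):nrow(v), , drop = FALSE])
}

# Chebyshev (square structuring element) erosion / dilation of a 0/1 matrix
erode_mask <- function(m, r) {
  out <- m
  for (dy in -r:r) for (dx in -r:r) {
    sh <- matrix(0L, nrow(m), ncol(m))
    ys <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
    xs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
    sh[ys - dy, xs - dx] <- m[ys, xs]
    out <- out * sh
  }
  out
}
dilate_mask <- function(m, r) {
  out <- m
  for (dy in -r:r) for (dx in -r:r) {
    sh <- matrix(0L, nrow(m), ncol(m))
    ys <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
    xs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
    sh[ys - dy, xs - dx] <- m[ys, xs]
    out <- pmax(out, sh)
  }
  out
}

# random blobby 3D mask: union of a few random balls (never empty)
random_mask3 <- function(d, seed, nballs = 3) {
  set.seed(seed)
  v <- array(FALSE, d)
  z <- slice.index(v, 1); y <- slice.index(v, 2); x <- slice.index(v, 3)
  for (b in seq_len(nballs)) {
    c0 <- c(runif(1, 2, d[1] - 1), runif(1, 2, d[2] - 1), runif(1, 2, d[3] - 1))
    r <- runif(1, 2, max(3, min(d) / 2))
    v <- v | ((z - c0[1])^2 + (y - c0[2])^2 + (x - c0[3])^2 <= r^2)
  }
  v + 0L
}
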