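#' Per-pixel local intensity statistics
#'
#' For every pixel of a windowed slice, the mean and standard deviation of the
#' intensities in its `window x window` neighbourhood. These two numbers are
#' the classification feature of the tissue model: using local statistics
#' rather than raw intensities makes the model robust to imaging noise, so no
#' denoising pre-processing is needed. Borders are handled by mirror
#' (symmetric, edge-repeating) padding to avoid artificial gradients at slice
#' edges. The standard deviation is the population form (divisor = number of
#' window pixels).
#'
#' @param slice 2D matrix of windowed intensities (rows y, cols x).
#' @param window odd neighbourhood side length in pixels, >= 3 (default 11,
#'   about 2.75-4.00 mm either side of a pixel at clinical CT resolutions).
#' @return A `feature_field`: list with matrices `mu` and `sigma` (same shape
#'   as `slice`) and the `window` used.
#' @export
local_stats <- function(slice, window = 11L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  slice <- as.matrix(slice)
  r <- (window - 1L) %/% 2L
  p <- pad_mirror(slice, r)
  n <- window * window
  s1 <- box_sum(p, window)
  s2 <- box_sum(p * p, window)
  mu <- s1 / n
  var <- pmax(s2 / n - mu * mu, 0)
  structure(list(mu = mu, sigma = sqrt(var), window = window),
            class = "feature_field")
}

# symmetric (edge-repeating) mirror padding by r pixels on each side
pad_mirror <- function(m, r) {
  if (r == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (r > nr || r > nc) stop("mirror padding wider than the slice")
  ri <- c(r:1, 1:nr, nr:(nr - r + 1L))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1L))
  m[ri, ci, drop = FALSE]
}

# sliding window x window sums of a padded matrix via an integral image;
# returns a matrix sized (nrow - window + 1) x (ncol - window + 1)
box_sum <- function(p, window) {
  ii <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  w <- window
  nr <- nrow(p) - w + 1L
  nc <- ncol(p) - w + 1L
  ii[(w + 1L):(nr + w), (w + 1L):(nc + w)] -
    ii[(w + 1L):(nr + w), 1:nc] -
    ii[1:nr, (w + 1L):(nc + w)] +
    ii[1:nr, 1:nc]
}

#' Fit the seed-patch bivariate normal tissue model
#'
#' Collects the per-pixel `(mu, sigma)` features over a `patch x patch` region
#' centred on the seed and takes their sample mean and sample covariance as
#' the subject-specific liver model. A small ridge is added to the covariance
#' so that a perfectly homogeneous patch still yields an invertible model.
#'
#' @param features a `feature_field` from [local_stats()] for the seed slice.
#' @param seed a [seed_point]; its `x`, `y` locate the patch centre.
#' @param patch odd patch side length (default 11 px).
#' @param ridge regulariser added to the covariance diagonal (default 1e-6).
#' @return An `mnd_model`: list with `mean` (length 2), `cov` (2 x 2, ridge
#'   included), and `ridge`.
#' @export
fit_mnd <- function(features, seed, patch = 11L, ridge = 1e-6) {
  patch <- as.integer(patch)
  if (patch < 3L || patch %% 2L == 0L) stop("patch must be an odd integer >= 3")
  r <- (patch - 1L) %/% 2L
  cy <- seed$y + 1L; cx <- seed$x + 1L  # to 1-based
  nr <- nrow(features$mu); nc <- ncol(features$mu)
  if (cy - r < 1L || cy + r > nr || cx - r < 1L || cx + r > nc)
    stop("seed patch does not fit inside the slice")
  rows <- (cy - r):(cy + r); cols <- (cx - r):(cx + r)
  f <- cbind(as.vector(features$mu[rows, cols]),
             as.vector(features$sigma[rows, cols]))
  m <- colMeans(f)
  cv <- stats::cov(f)
  if (!all(is.finite(cv)) || all(abs(cv) < .Machine$double.eps)) {
    warning("degenerate seed patch (all features identical); covariance is pure ridge")
    cv <- matrix(0, 2, 2)
  }
  structure(list(mean = m, cov = cv + diag(ridge, 2), ridge = ridge),
            class = "mnd_model")
}

#' Bivariate normal density of a feature vector
#'
#' Evaluates the exact 2D normal density of `f` under a fitted model.
#'
#' @param f numeric length-2 feature vector `(local mean, local sd)`, or an
#'   `n x 2` matrix of such vectors.
#' @param model an `mnd_model` from [fit_mnd()].
#' @return Density value(s), non-negative.
#' @export
mnd_density <- function(f, model) {
  k <- 2
  si <- solve(model$cov)
  det_s <- det(model$cov)
  norm_c <- 1 / ((2 * pi)^(k / 2) * sqrt(det_s))
  if (is.matrix(f)) {
    d <- sweep(f, 2, model$mean)
    q <- rowSums((d %*% si) * d)
  } else {
    d <- f - model$mean
    q <- sum(d * (si %*% d))
  }
  norm_c * exp(-q / 2)
}

# squared Mahalanobis distance of stacked (mu, sigma) features to the model
mnd_mahalanobis2 <- function(mu, sigma, model) {
  si <- solve(model$cov)
  d1 <- mu - model$mean[1]
  d2 <- sigma - model$mean[2]
  si[1, 1] * d1 * d1 + 2 * si[1, 2] * d1 * d2 + si[2, 2] * d2 * d2
}

#' Liver probability map of a windowed volume
#'
#' For every pixel of every slice, the model density of its local-statistics
#' feature, normalised by the density at the model mean so the map lies in
#' `[0, 1]` (value 1 is attained exactly where the feature equals the model
#' mean). The background probability used downstream is `1 - P(liver)`.
#'
#' @param wvol a `windowed_volume` from [apply_window()].
#' @param model an `mnd_model` from [fit_mnd()].
#' @param window feature neighbourhood size passed to [local_stats()]
#'   (default 11; use the size the model was built with).
#' @return A `probability_map`: list with `values` (3D array in `[0, 1]`,
#'   `(z, y, x)` order) and `spacing`.
#' @export
probability_map <- function(wvol, model, window = 11L) {
  d <- dim(wvol$intensities)
  vals <- array(0, dim = d)
  for (z in seq_len(d[1])) {
    ff <- local_stats(wvol$intensities[z, , ], window = window)
    vals[z, , ] <- exp(-0.5 * mnd_mahalanobis2(ff$mu, ff$sigma, model))
  }
  structure(list(values = vals, spacing = wvol$spacing),
            class = "probability_map")
}

#' Export a probability map as a volume file
#'
#' Writes the map as a float volume, or scaled by 255 to 8-bit for
#' visual inspection.
#'
#' @param pm a `probability_map`.
#' @param path output path (`.mhd` or `.nii`/`.nii.gz`).
#' @param scale8 if `TRUE`, write `round(255 * P)` as unsigned 8-bit.
#' @return `path`, invisibly.
#' @export
export_probability_map <- function(pm, path, scale8 = FALSE) {
  if (scale8) {
    vol <- ct_volume(round(pm$values * 255), spacing = pm$spacing)
    write_volume(vol, path, element_type = "MET_UCHAR")
  } else {
    vol <- ct_volume(pm$values, spacing = pm$spacing)
    write_volume(vol, path, element_type = "MET_FLOAT")
  }
  invisible(path)
}
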