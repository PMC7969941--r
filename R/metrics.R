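#' Volumetric overlap error (percent)
#'
#' `VOE = 100 (1 - |A  B| / |A  B|)`: 0 for identical masks, 100 for
#' disjoint non-empty masks. Two empty masks return 0 by convention (with a
#' warning).
#'
#' @param A,B [binary_mask] objects on the same grid (A = segmented,
#'   B = reference).
#' @return Percentage in `[0, 100]`.
#' @export
voe <- function(A, B) {
  check_same_grid(A, B)
  a <- A$voxels != 0; b <- B$voxels != 0
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both masks empty: VOE set to 0 by convention")
    return(0)
  }
  100 * (1 - sum(a & b) / uni)
}

#' Relative volume difference (percent, signed)
#'
#' `RVD = 100 (|A| - |B|) / |B|`: positive for over-segmentation, negative
#' for under-segmentation. The scoring uses its absolute value.
#'
#' @inheritParams voe
#' @return Signed percentage.
#' @export
rvd <- function(A, B) {
  check_same_grid(A, B)
  nb <- sum(B$voxels != 0)
  if (nb == 0) stop("reference mask is empty: RVD undefined")
  100 * (sum(A$voxels != 0) - nb) / nb
}

check_same_grid <- function(A, B) {
  if (!all(dim(A$voxels) == dim(B$voxels)))
    stop("masks are on different grids: ",
         paste(dim(A$voxels), collapse = "x"), " vs ",
         paste(dim(B$voxels), collapse = "x"))
  # float32 containers (NIfTI pixdim) round 0.7 to ~0.69999999; compare loosely
  if (!isTRUE(all.equal(A$spacing, B$spacing, tolerance = 1e-5)))
    stop("masks have different voxel spacing")
  invisible(TRUE)
}

#' Surface voxels of a mask
#'
#' Foreground voxels with at least one of their six face-neighbours in the
#' background (volume borders count as background).
#'
#' @param mask a [binary_mask] (or a 3D 0/1 array).
#' @return Integer matrix with one row per surface voxel, columns `z`, `y`,
#'   `x` (1-based array indices).
#' @export
surface_voxels <- function(mask) {
  surf <- which(surface_mask(mask), arr.ind = TRUE)
  colnames(surf) <- c("z", "y", "x")
  surf
}

# logical array marking 6-neighbour-exposed foreground voxels
surface_mask <- function(mask) {
  v <- if (inherits(mask, "binary_mask")) mask$voxels else mask
  d <- dim(v)
  fg <- v != 0
  # pad with background so borders count as exposed
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  core <- p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- p[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        p[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        p[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        p[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        p[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        p[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !nb
}

#' Symmetric surface distances (mm)
#'
#' Distances between the two masks' surface voxel centres in physical mm:
#' the average (ASD), root-mean-square (RMSD) and maximum (MSD) over the
#' symmetric pooled set of nearest-surface distances. Computed with an exact
#' separable Euclidean distance transform under the anisotropic spacing, so
#' whole-volume surfaces are handled in linear time.
#'
#' @inheritParams voe
#' @return Named numeric vector `c(asd, rmsd, msd)` in mm.
#' @export
surface_distances <- function(A, B) {
  check_same_grid(A, B)
  sa <- surface_mask(A); sb <- surface_mask(B)
  if (!any(sa) || !any(sb))
    stop("surface distances undefined: ",
         if (!any(sa)) "segmented" else "reference", " mask is empty")
  d <- dim(A$voxels)
  sp <- c(A$spacing[3], A$spacing[2], A$spacing[1])  # (dz, dy, dx) per axis
  dt_b <- .edt3d(as.vector(sb), d, sp)
  dt_a <- .edt3d(as.vector(sa), d, sp)
  dab <- sqrt(dt_b[which(as.vector(sa))])
  dba <- sqrt(dt_a[which(as.vector(sb))])
  all_d <- c(dab, dba)
  c(asd = mean(all_d),
    rmsd = sqrt(mean(all_d^2)),
    msd = max(all_d))
}

#' Metric-to-score transform
#'
#' `score = max(100 - 25 e / ebar, 0)`: 100 for a perfect result, 75 at the
#' reference (average human) error, 0 at four times the reference error and
#' beyond. Signed errors (RVD) are scored on their magnitude.
#'
#' @param e error value (its absolute value is used).
#' @param ebar reference error for the metric (> 0).
#' @return Score in `[0, 100]` (vectorised).
#' @export
score <- function(e, ebar) {
  if (any(ebar <= 0)) stop("ebar must be > 0")
  pmax(100 - 25 * abs(e) / ebar, 0)
}

#' Reference errors for scoring
#'
#' The five per-metric reference errors (`ebar`) that anchor the score
#' transform. No defaults are shipped: they are an external calibration
#' (average human rater errors on the evaluation dataset) and must be
#' supplied explicitly.
#'
#' @param voe,rvd percentages (> 0).
#' @param asd,rmsd,msd millimetres (> 0).
#' @return A named numeric vector of class `reference_errors`.
#' @export
reference_errors <- function(voe, rvd, asd, rmsd, msd) {
  e <- c(voe = voe, rvd = rvd, asd = asd, rmsd = rmsd, msd = msd)
  if (any(!is.finite(e)) || any(e <= 0))
    stop("all reference errors must be positive")
  structure(e, class = "reference_errors")
}

#' Evaluate a segmentation against a reference
#'
#' Computes all five metrics (VOE, RVD, ASD, RMSD, MSD) and, when reference
#' errors are given, the per-metric scores and their mean (the overall score).
#'
#' @param A segmented [binary_mask].
#' @param B reference [binary_mask] (same grid).
#' @param refs optional [reference_errors()] for scoring.
#' @return A `metric_report`: list with `voe_pct`, `rvd_pct`, `asd_mm`,
#'   `rmsd_mm`, `msd_mm` and, if `refs` given, `scores` (length 5) and
#'   `overall`.
#' @export
evaluate_masks <- function(A, B, refs = NULL) {
  sd3 <- surface_distances(A, B)
  rep <- list(voe_pct = voe(A, B), rvd_pct = rvd(A, B),
              asd_mm = unname(sd3["asd"]), rmsd_mm = unname(sd3["rmsd"]),
              msd_mm = unname(sd3["msd"]))
  if (!is.null(refs)) {
    e <- c(rep$voe_pct, rep$rvd_pct, rep$asd_mm, rep$rmsd_mm, rep$msd_mm)
    sc <- score(e, unclass(refs))
    names(sc) <- names(refs)
    rep$scores <- sc
    rep$overall <- mean(sc)
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("VOE %.2f%%  RVD %+.2f%%  ASD %.3f mm  RMSD %.3f mm  MSD %.3f mm\n",
              x$voe_pct, x$rvd_pct, x$asd_mm, x$rmsd_mm, x$msd_mm))
  if (!is.null(x$scores))
    cat(sprintf("scores: %s  overall %.1f\n",
                paste(sprintf("%s=%.1f", names(x$scores), x$scores),
                      collapse = " "), x$overall))
  invisible(x)
}

#' Dice coefficient of two masks
#'
#' `2 |A  B| / (|A| + |B|)`; handy for phantom validation.
#'
#' @inheritParams voe
#' @return Value in `[0, 1]` (1 when both masks are empty).
#' @export
dice <- function(A, B) {
  a <- (if (inherits(A, "binary_mask")) A$voxels else A) != 0
  b <- (if (inherits(B, "binary_mask")) B$voxels else B) != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
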