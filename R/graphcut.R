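#' Robust noise-scale estimate of a slice
#'
#' `1.4826 x median(|horizontal and vertical neighbour differences|)`, the
#' median-absolute-deviation estimate of the noise scale from pairwise
#' intensity differences, floored at 1 so that the boundary cost never divides
#' by a vanishing scale.
#'
#' @param slice 2D matrix of windowed intensities.
#' @return Positive scalar sigma in windowed-intensity units.
#' @export
estimate_sigma <- function(slice) {
  slice <- as.matrix(slice)
  dh <- abs(slice[, -1, drop = FALSE] - slice[, -ncol(slice), drop = FALSE])
  dv <- abs(slice[-1, , drop = FALSE] - slice[-nrow(slice), , drop = FALSE])
  max(1.4826 * stats::median(c(dh, dv)), 1)
}

#' Region (data) costs from a liver probability
#'
#' Negative log-probabilities `R(c) = -ln P(p | c)` with
#' `P(p | liver) = P` and `P(p | background) = 1 - P`, clamped at `eps`
#' so that probabilities of exactly 0 or 1 stay finite.
#'
#' @param p_liver liver probability (scalar, vector or matrix) in `[0, 1]`.
#' @param eps clamp inside the logarithm (default 1e-10).
#' @return List with `bg` (= R(background)) and `liver` (= R(liver)), same
#'   shape as the input.
#' @export
region_cost <- function(p_liver, eps = 1e-10) {
  list(bg = -log(pmax(1 - p_liver, eps)),
       liver = -log(pmax(p_liver, eps)))
}

#' Boundary (smoothness) cost between two pixels
#'
#' `exp(-(I_p - I_q)^2 / (2 sigma^2)) / dist(p, q)`: high for similar
#' neighbouring intensities (discouraging a cut there), decaying with the
#' intensity contrast and with the pixel distance.
#'
#' @param i_p,i_q intensities of the two pixels.
#' @param dist Euclidean distance between them, in pixels (1 for axial,
#'   sqrt(2) for diagonal neighbours).
#' @param sigma noise scale, e.g. from [estimate_sigma()].
#' @return Non-negative cost (vectorised).
#' @export
boundary_cost <- function(i_p, i_q, dist, sigma) {
  if (any(dist <= 0)) stop("dist must be > 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  exp(-((i_p - i_q)^2) / (2 * sigma^2)) / dist
}

# 8-connected in-slice neighbour pairs (each unordered pair once):
# offsets E, S, SE, SW relative to pixel (row-major (y, x) grid)
gc_pairs <- function(nr, nc) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  pair_block <- function(dy, dx) {
    rs <- seq_len(nr - abs(dy)); cs <- seq_len(nc - abs(dx))
    r0 <- if (dy >= 0) rs else rs + abs(dy)
    c0 <- if (dx >= 0) cs else cs + abs(dx)
    cbind(p = as.vector(idx[r0, c0]),
          q = as.vector(idx[r0 + dy, c0 + dx]),
          dist = sqrt(dy^2 + dx^2))
  }
  rbind(pair_block(0, 1), pair_block(1, 0), pair_block(1, 1), pair_block(1, -1))
}

#' Per-slice binary energy
#'
#' Builds the full energy specification for one slice:
#' `E(L) = alpha * sum_p R(C_p) + (1 - alpha) * sum_{p~q, C_p != C_q} B(p, q)`
#' with 8-connected neighbour pairs, region costs from the probability map and
#' boundary costs from the windowed intensities. The boundary term is charged
#' only across label disagreements (Potts convention), making it submodular
#' (all `B >= 0`) and hence exactly minimised by an s-t min-cut.
#'
#' @param slice 2D windowed intensity matrix.
#' @param prob_slice 2D liver probability matrix, same shape.
#' @param alpha balance weight in `[0, 1]` between the region and boundary
#'   terms (default 0.5).
#' @param sigma noise scale; estimated from `slice` when `NULL`.
#' @return A `gc_energy`: list with `alpha`, `sigma`, `region` (list `bg`,
#'   `liver`), `pairs` (matrix with columns p, q, dist, b), `dim`.
#' @export
gc_energy <- function(slice, prob_slice, alpha = 0.5, sigma = NULL) {
  slice <- as.matrix(slice); prob_slice <- as.matrix(prob_slice)
  if (!all(dim(slice) == dim(prob_slice)))
    stop("slice and probability slice shapes differ")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.null(sigma)) sigma <- estimate_sigma(slice)
  pr <- gc_pairs(nrow(slice), ncol(slice))
  b <- boundary_cost(slice[pr[, "p"]], slice[pr[, "q"]], pr[, "dist"], sigma)
  structure(
    list(alpha = alpha, sigma = sigma,
         region = region_cost(prob_slice),
         pairs = cbind(pr, b = b), dim = dim(slice)),
    class = "gc_energy"
  )
}

#' Evaluate the energy of a labeling
#'
#' @param energy a `gc_energy`.
#' @param labels 0/1 matrix (1 = liver) of the energy's slice shape.
#' @return Scalar energy value.
#' @export
gc_energy_value <- function(energy, labels) {
  lab <- as.vector(labels)
  reg <- sum(ifelse(lab == 1, energy$region$liver, energy$region$bg))
  cut <- lab[energy$pairs[, "p"]] != lab[energy$pairs[, "q"]]
  energy$alpha * reg + (1 - energy$alpha) * sum(energy$pairs[cut, "b"])
}

#' Exact minimiser of a slice energy via s-t min-cut
#'
#' Translates the energy into the standard two-terminal graph (terminal links
#' carry the weighted region costs, neighbour links the weighted boundary
#' costs) and solves it with a max-flow/min-cut algorithm. Pixels on the
#' source side of the minimum cut are labelled liver. The construction is
#' exact: the cut value equals the energy up to a constant, so the returned
#' labeling attains the global minimum.
#'
#' @param energy a `gc_energy` from [gc_energy()].
#' @return 0/1 label matrix (1 = liver) of the slice shape.
#' @export
solve_min_cut <- function(energy) {
  n <- prod(energy$dim)
  a <- energy$alpha
  rb <- as.vector(energy$region$bg); rl <- as.vector(energy$region$liver)
  pr <- energy$pairs
  lab <- .dinic_min_cut(n, a * rb, a * rl,
                        as.integer(pr[, "p"]), as.integer(pr[, "q"]),
                        (1 - a) * pr[, "b"])
  matrix(lab, energy$dim[1], energy$dim[2])
}

#' Segment one slice by graph cut
#'
#' Convenience wrapper: build the energy with [gc_energy()] and minimise it
#' with [solve_min_cut()].
#'
#' @inheritParams gc_energy
#' @return 0/1 label matrix (1 = liver).
#' @export
min_cut_segment <- function(slice, prob_slice, alpha = 0.5, sigma = NULL) {
  solve_min_cut(gc_energy(slice, prob_slice, alpha = alpha, sigma = sigma))
}
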