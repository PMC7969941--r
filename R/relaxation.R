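#' 8-neighbourhood specification for relaxation labeling
#'
#' The eight surrounding pixel displacements with inverse-Euclidean-distance
#' weights, normalised to sum to one (axial : diagonal weight ratio is
#' sqrt(2) : 1 before normalisation).
#'
#' @return List with `offsets` (8 x 2 matrix of (dy, dx)) and `weights`
#'   (length 8, summing to 1).
#' @export
neighbourhood_spec <- function() {
  off <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  w <- 1 / sqrt(off[, 1]^2 + off[, 2]^2)
  list(offsets = unname(off), weights = unname(w / sum(w)))
}

# shift a matrix by (dy, dx) with mirror handling of out-of-slice neighbours:
# result[i, j] = m[i + dy, j + dx], reflected at the borders
shift_mirror <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr) + dy
  ci <- seq_len(nc) + dx
  ri[ri < 1L] <- 2L - ri[ri < 1L]
  ri[ri > nr] <- 2L * nr - ri[ri > nr]
  ci[ci < 1L] <- 2L - ci[ci < 1L]
  ci[ci > nc] <- 2L * nc - ci[ci > nc]
  m[ri, ci, drop = FALSE]
}

#' Contextual support for the liver class
#'
#' The support a pixel receives for a class is the weighted sum of its eight
#' neighbours' probabilities of the same class (the compatibility is the
#' identity: 1 for same class, 0 otherwise), with weights from
#' [neighbourhood_spec()]. Computed for the whole slice at once.
#'
#' @param p_liver 2D matrix of liver probabilities.
#' @return Matrix of the same shape: per-pixel support for the liver class.
#'   The background support is obtained by passing `1 - p_liver`.
#' @export
rl_support <- function(p_liver) {
  spec <- neighbourhood_spec()
  s <- matrix(0, nrow(p_liver), ncol(p_liver))
  for (i in seq_len(nrow(spec$offsets))) {
    s <- s + spec$weights[i] *
      shift_mirror(p_liver, spec$offsets[i, 1], spec$offsets[i, 2])
  }
  s
}

#' One synchronous relaxation-labeling step
#'
#' Updates every pixel of a two-class (liver / background) probability slice
#' from the previous state:
#' `P'(lambda) = P(lambda) (1 + S(lambda)) / sum_mu P(mu) (1 + S(mu))`.
#' All pixels are updated from the same previous state, so pixel visit order
#' is immaterial.
#'
#' @param p_liver 2D matrix of liver probabilities in `[0, 1]`; the background
#'   plane is `1 - p_liver`.
#' @return Updated liver probability matrix.
#' @export
rl_step <- function(p_liver) {
  p_bg <- 1 - p_liver
  num_l <- p_liver * (1 + rl_support(p_liver))
  num_b <- p_bg * (1 + rl_support(p_bg))
  num_l / (num_l + num_b)
}

#' Relaxation-labeling refinement of a probability map
#'
#' Applies [rl_step()] slice by slice (the neighbourhood is strictly 2D) for a
#' small fixed number of iterations. The update is run for a few iterations
#' only, not to convergence: enough to suppress isolated misclassified pixels
#' and consolidate dispersed regions without over-smoothing genuine boundaries.
#'
#' @param pm a `probability_map` (or a bare 2D matrix, refined in place).
#' @param iterations number of update steps (default 5; 0 returns the input
#'   unchanged).
#' @return Object of the same kind as the input, refined.
#' @export
rl_refine <- function(pm, iterations = 5L) {
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0")
  if (is.matrix(pm)) {
    for (t in seq_len(iterations)) pm <- rl_step(pm)
    return(pm)
  }
  vals <- pm$values
  for (z in seq_len(dim(vals)[1])) {
    s <- vals[z, , ]
    for (t in seq_len(iterations)) s <- rl_step(s)
    vals[z, , ] <- s
  }
  pm$values <- vals
  pm
}
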