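# Independent oracles: deliberately plain-loop implementations kept separate
# from the package's vectorised/compiled code paths.

# per-pixel local mean/sd by explicit neighbourhood loops with symmetric
# (edge-repeating) mirror padding
oracle_local_stats <- function(slice, window) {
  r <- (window - 1) %/% 2
  nr <- nrow(slice); nc <- ncol(slice)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  mu <- sig <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, slice[reflect(i + di, nr), reflect(j + dj, nc)])
    mu[i, j] <- mean(vals)
    sig[i, j] <- sqrt(mean((vals - mean(vals))^2))
  }
  list(mu = mu, sigma = sig)
}

# generic quadratic-form bivariate normal density
oracle_mvn_density <- function(f, m, S) {
  d <- f - m
  solve_d <- solve(S, d)
  (1 / (2 * pi * sqrt(det(S)))) * exp(-0.5 * sum(d * solve_d))
}

# weighted same-class neighbour support at one interior pixel, by direct loop
oracle_support <- function(p_liver, i, j) {
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                c(1, -1), c(1, 0), c(1, 1))
  w <- 1 / sqrt(rowSums(offs^2))
  w <- w / sum(w)
  s <- 0
  for (k in 1:8) s <- s + w[k] * p_liver[i + offs[k, 1], j + offs[k, 2]]
  s
}

# exhaustive minimiser of a slice energy over all 2^n labelings
oracle_min_energy <- function(energy) {
  n <- prod(energy$dim)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- matrix(as.integer(intToBits(code))[seq_len(n)],
                  energy$dim[1], energy$dim[2])
    e <- gc_energy_value(energy, lab)
    if (e < best) best <- e
  }
  best
}

# 8-connected component pixel count by stack-based flood fill
oracle_flood_count <- function(mask, start) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  stack <- list(start)
  count <- 0
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (seen[p[1], p[2]]) next
    seen[p[1], p[2]] <- TRUE
    count <- count + 1
    for (di in -1:1) for (dj in -1:1) {
      i <- p[1] + di; j <- p[2] + dj
      if ((di | dj) && i >= 1 && i <= nr && j >= 1 && j <= nc &&
          mask[i, j] != 0 && !seen[i, j])
        stack[[length(stack) + 1]] <- c(i, j)
    }
  }
  count
}

# O(n^2) symmetric surface distances from first principles
oracle_surface_metrics <- function(A, B) {
  surf <- function(m) {
    v <- m$voxels
    d <- dim(v)
    out <- NULL
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      if (v[z, y, x] == 0) next
      nb6 <- c(
        if (z > 1) v[z - 1, y, x] else 0, if (z < d[1]) v[z + 1, y, x] else 0,
        if (y > 1) v[z, y - 1, x] else 0, if (y < d[2]) v[z, y + 1, x] else 0,
        if (x > 1) v[z, y, x - 1] else 0, if (x < d[3]) v[z, y, x + 1] else 0)
      if (any(nb6 == 0) || z == 1 || z == d[1] || y == 1 || y == d[2] ||
          x == 1 || x == d[3])
        out <- rbind(out, c(z, y, x))
    }
    out
  }
  mm <- function(idx, sp) cbind(idx[, 3] * sp[1], idx[, 2] * sp[2], idx[, 1] * sp[3])
  sa <- mm(surf(A), A$spacing); sb <- mm(surf(B), B$spacing)
  d_ab <- vapply(seq_len(nrow(sa)), function(i)
    min(sqrt(colSums((t(sb) - sa[i, ])^2))), 0)
  d_ba <- vapply(seq_len(nrow(sb)), function(i)
    min(sqrt(colSums((t(sa) - sb[i, ])^2))), 0)
  pooled <- c(d_ab, d_ba)
  list(asd = mean(pooled), rmsd = sqrt(mean(pooled^2)), msd = max(pooled))
}

# 26-connected 3D component count by frontier flood fill
oracle_components_3d <- function(vox) {
  d <- dim(vox)
  lab <- array(0L, d)
  ncomp <- 0L
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  todo <- which(vox != 0 & lab == 0L)
  while (length(todo)) {
    ncomp <- ncomp + 1L
    frontier <- todo[1]
    lab[frontier] <- ncomp
    while (length(frontier)) {
      iz <- ((frontier - 1L) %% d[1]) + 1L
      rest <- (frontier - 1L) %/% d[1]
      iy <- (rest %% d[2]) + 1L
      ix <- (rest %/% d[2]) + 1L
      nxt <- c()
      for (k in seq_len(nrow(offs))) {
        z <- iz + offs[k, 1]; y <- iy + offs[k, 2]; x <- ix + offs[k, 3]
        ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
        lin <- (x[ok] - 1L) * d[1] * d[2] + (y[ok] - 1L) * d[1] + z[ok]
        nxt <- c(nxt, lin[vox[lin] != 0 & lab[lin] == 0L])
      }
      nxt <- unique(nxt)
      lab[nxt] <- ncomp
      frontier <- nxt
    }
    todo <- which(vox != 0 & lab == 0L)
  }
  ncomp
}
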