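#' Post-processing configuration
#'
#' Parameters of the anatomical cleanup stage.
#'
#' @param tb bottleneck cost threshold (default 0.60): a keypoint pair is a
#'   bottleneck only if its Euclidean gap over the shorter arc-length is below
#'   `tb`.
#' @param angle_max exterior-angle gate in degrees (default 150): only
#'   keypoints whose exterior angle is below this are bottleneck candidates,
#'   which protects salient convex features (e.g. the tip of the left lobe)
#'   from being cut off.
#' @param tc_base,tc_slope intercept and per-mm slope of the adjacent-contour
#'   similarity threshold `tc = tc_base - tc_slope * (dz - 1)`.
#' @param approx_tol polygonal-approximation tolerance in pixels (default 2).
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(tb = 0.60, angle_max = 150, tc_base = 0.8,
                               tc_slope = 0.05, approx_tol = 2.0) {
  if (tb <= 0 || tb >= 1) stop("tb must be in (0, 1)")
  if (angle_max <= 0 || angle_max >= 360) stop("angle_max must be in (0, 360)")
  if (approx_tol < 0) stop("approx_tol must be >= 0")
  structure(list(tb = tb, angle_max = angle_max, tc_base = tc_base,
                 tc_slope = tc_slope, approx_tol = approx_tol),
            class = "postprocess_config")
}

#' Otsu binarization of a probability slice
#'
#' Threshold chosen over a 256-bin histogram of the map by maximising the
#' between-class variance; pixels strictly above the threshold form the
#' foreground. A constant slice yields an empty mask with a warning.
#'
#' @param prob_slice 2D matrix of probabilities in `[0, 1]`.
#' @return 0/1 matrix of the slice shape, with the chosen threshold attached
#'   as attribute `"threshold"`.
#' @export
binarize_otsu <- function(prob_slice) {
  prob_slice <- as.matrix(prob_slice)
  if (diff(range(prob_slice)) == 0) {
    warning("constant slice: Otsu threshold undefined, returning empty mask")
    out <- matrix(0L, nrow(prob_slice), ncol(prob_slice))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  bins <- 256L
  idx <- pmin(pmax(floor(prob_slice * bins) + 1, 1), bins)
  h <- tabulate(idx, nbins = bins)
  n <- sum(h)
  levels <- (seq_len(bins) - 0.5) / bins   # bin centres
  w0 <- cumsum(h) / n
  m0 <- cumsum(h * levels) / n
  mt <- m0[bins]
  # between-class variance for threshold after bin k (k = 1..bins-1)
  w <- w0[-bins]; mu <- m0[-bins]
  bcv <- ifelse(w > 0 & w < 1, (mt * w - mu)^2 / (w * (1 - w)), 0)
  k <- which.max(bcv)
  thr <- k / bins   # upper edge of bin k
  out <- (prob_slice > thr) + 0L
  attr(out, "threshold") <- thr
  out
}

# ---- connected components & boundary tracing --------------------------------

# 8-connected labeling of a 0/1 matrix by vectorised frontier expansion
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- mask != 0
  next_lab <- 0L
  todo <- which(fg & lab == 0L)
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  while (length(todo)) {
    next_lab <- next_lab + 1L
    frontier <- todo[1]
    lab[frontier] <- next_lab
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      cands <- rep(frontier, each = 8L) + rep(off, length(frontier))
      rr <- rep(r, each = 8L) + rep(c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L),
                                    length(frontier))
      ok <- cands >= 1L & cands <= nr * nc & rr >= 1L & rr <= nr
      cands <- unique(cands[ok])
      cands <- cands[fg[cands] & lab[cands] == 0L]
      lab[cands] <- next_lab
      frontier <- cands
    }
    todo <- which(fg & lab == 0L)
  }
  lab
}

# Moore-neighbour boundary trace of the component containing `start`
# (linear index). Returns the boundary pixel walk as linear indices.
.moore_nbr <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                       0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                     ncol = 2, byrow = TRUE)  # W NW N NE E SE S SW

trace_boundary <- function(fg, start) {
  nr <- nrow(fg); nc <- ncol(fg)
  at <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && fg[r, c]
  r0 <- ((start - 1L) %% nr) + 1L
  c0 <- ((start - 1L) %/% nr) + 1L
  walk_r <- r0; walk_c <- c0
  # backtrack starts at the (background) pixel left of the raster-scan start
  br <- r0; bc <- c0 - 1L
  cr <- r0; cc <- c0
  first_move <- NULL
  max_steps <- 8L * (sum(fg) + 2L)
  for (step in seq_len(max_steps)) {
    d <- c(br - cr, bc - cc)
    i0 <- which(.moore_nbr[, 1] == d[1] & .moore_nbr[, 2] == d[2])
    found <- FALSE
    for (j in 1:8) {
      k <- ((i0 - 1L + j) %% 8L) + 1L
      nr_ <- cr + .moore_nbr[k, 1]; nc_ <- cc + .moore_nbr[k, 2]
      if (at(nr_, nc_)) {
        kp <- ((i0 - 1L + j - 1L) %% 8L) + 1L
        br <- cr + .moore_nbr[kp, 1]; bc <- cc + .moore_nbr[kp, 2]
        cr <- nr_; cc <- nc_
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    move <- c(cr, cc, br, bc)
    if (is.null(first_move)) {
      first_move <- move
    } else if (all(move == first_move)) {
      break  # same position entered from the same direction: walk is closed
    }
    walk_r <- c(walk_r, cr); walk_c <- c(walk_c, cc)
  }
  # drop a duplicated closing vertex
  n <- length(walk_r)
  if (n > 1L && walk_r[n] == walk_r[1] && walk_c[n] == walk_c[1]) {
    walk_r <- walk_r[-n]; walk_c <- walk_c[-n]
  }
  cbind(r = walk_r, c = walk_c)
}

polygon_signed_area <- function(v) {
  # shoelace on (x, y) columns; positive = counter-clockwise
  x <- v[, 1]; y <- v[, 2]
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

new_slice_contour <- function(vertices, slice_index, pixels, dim) {
  area <- length(pixels)
  if (nrow(vertices) >= 3) {
    sa <- polygon_signed_area(vertices)
    if (sa < 0) vertices <- vertices[nrow(vertices):1, , drop = FALSE]
  }
  structure(list(vertices = vertices, slice_index = slice_index,
                 area = area, pixels = sort(pixels), dim = dim,
                 keypoints = NULL),
            class = "slice_contour")
}

#' Extract outer contours of a binary slice
#'
#' Labels the 8-connected foreground components and traces the outer boundary
#' of each with Moore-neighbour tracing. Contours are returned
#' counter-clockwise (normalised by signed area) with 0-based pixel
#' coordinates; each carries the filled component's pixel indices, whose count
#' is the contour area `|c|`.
#'
#' @param mask 0/1 matrix.
#' @param slice_index z index to record on the contours (0-based).
#' @return List of `slice_contour` objects (empty list for an empty mask).
#' @export
extract_contours <- function(mask, slice_index = 0L) {
  mask <- as.matrix(mask)
  lab <- label_components(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  out <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    pix <- which(lab == l)
    comp <- lab == l
    # raster-scan start: first pixel in column-major order has its W neighbour
    # outside the component only if we scan rows first; use min row within
    # min column of each row instead: first by row, then by column
    rs <- ((pix - 1L) %% nrow(mask)) + 1L
    cs <- ((pix - 1L) %/% nrow(mask)) + 1L
    o <- order(rs, cs)
    start <- pix[o[1]]
    walk <- trace_boundary(comp, start)
    verts <- cbind(x = walk[, "c"] - 1, y = walk[, "r"] - 1)
    out[[l]] <- new_slice_contour(verts, slice_index, pix, dim(mask))
  }
  out
}

# ---- polygonal approximation ------------------------------------------------

# perpendicular distance of points to the segment (a, b)
point_segment_dist <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  l2 <- vx * vx + vy * vy
  if (l2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(pmax(((px - a[1]) * vx + (py - a[2]) * vy) / l2, 0), 1)
  sqrt((px - a[1] - t * vx)^2 + (py - a[2] - t * vy)^2)
}

dp_chain <- function(v, i, j, tol, keep) {
  # open chain v[i..j]; marks interior points to keep
  if (j - i < 2L) return(keep)
  ids <- (i + 1L):(j - 1L)
  d <- point_segment_dist(v[ids, 1], v[ids, 2], v[i, ], v[j, ])
  m <- which.max(d)
  if (d[m] > tol) {
    k <- ids[m]
    keep[k] <- TRUE
    keep <- dp_chain(v, i, k, tol, keep)
    keep <- dp_chain(v, k, j, tol, keep)
  }
  keep
}

#' Polygonal approximation key points
#'
#' Douglas-Peucker simplification of a closed contour. The two anchors are
#' the farthest-apart vertex pair (taken on the convex hull), so dominant
#' shape corners survive any starting-vertex choice; every dropped vertex is
#' within `tol` of the approximating polygon. `tol = 0` keeps all vertices.
#'
#' @param contour a `slice_contour`.
#' @param tol tolerance in pixels (>= 0).
#' @return The contour with `$keypoints` set to the (increasing) indices of
#'   the retained vertices.
#' @export
approx_keypoints <- function(contour, tol = 2.0) {
  if (tol < 0) stop("tol must be >= 0")
  v <- contour$vertices
  n <- nrow(v)
  if (tol == 0 || n <= 3) {
    contour$keypoints <- seq_len(n)
    return(contour)
  }
  h <- grDevices::chull(v[, 1], v[, 2])
  hv <- v[h, , drop = FALSE]
  dm <- as.matrix(stats::dist(hv))
  far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  a1 <- h[far[1]]; a2 <- h[far[2]]
  if (a1 == a2) { contour$keypoints <- seq_len(n); return(contour) }
  lo <- min(a1, a2); hi <- max(a1, a2)
  keep <- rep(FALSE, n)
  keep[c(lo, hi)] <- TRUE
  keep <- dp_chain(v, lo, hi, tol, keep)
  # wrap-around chain hi .. n, 1 .. lo as a re-indexed open chain
  wrap_ids <- c(hi:n, seq_len(lo))
  vw <- v[wrap_ids, , drop = FALSE]
  kw <- rep(FALSE, length(wrap_ids))
  kw[c(1L, length(wrap_ids))] <- TRUE
  kw <- dp_chain(vw, 1L, length(wrap_ids), tol, kw)
  keep[wrap_ids[kw]] <- TRUE
  contour$keypoints <- which(keep)
  contour
}

#' Exterior angle at a polygon vertex
#'
#' For a counter-clockwise polygon, the exterior angle is 360 degrees minus
#' the interior angle: collinear vertices measure 180, convex corners above
#' 180, concave notches below 180. Concave notches are where spurious attached
#' lobes join the liver outline, which is why the bottleneck gate keeps only
#' vertices with exterior angle below the threshold.
#'
#' @param poly `n x 2` matrix of polygon vertices (counter-clockwise), or a
#'   `slice_contour` (its keypoint polygon is used if keypoints are set).
#' @param i vertex index into `poly` (or into the keypoint polygon).
#' @return Angle in degrees, in `(0, 360)`.
#' @export
exterior_angle <- function(poly, i) {
  v <- polygon_of(poly)
  n <- nrow(v)
  if (n < 3) stop("polygon needs at least 3 vertices")
  ip <- ((i - 2L) %% n) + 1L
  nx <- (i %% n) + 1L
  a <- v[ip, ]; b <- v[i, ]; cc <- v[nx, ]
  v1 <- b - a; v2 <- cc - b
  if (all(v1 == 0) || all(v2 == 0)) stop("duplicate adjacent vertices")
  turn <- atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2)) * 180 / pi
  ang <- 180 + turn
  if (ang <= 0) ang <- ang + 360
  if (ang >= 360) ang <- ang - 360
  unname(ang)
}

polygon_of <- function(poly) {
  if (inherits(poly, "slice_contour")) {
    if (!is.null(poly$keypoints))
      return(poly$vertices[poly$keypoints, , drop = FALSE])
    return(poly$vertices)
  }
  as.matrix(poly)
}

#' Bottleneck cost of a vertex pair
#'
#' The Euclidean distance between two contour points divided by the shorter
#' of the two arc-lengths connecting them along the contour. Small values
#' flag a narrow neck relative to the material on both sides.
#'
#' @param contour a `slice_contour`.
#' @param p,q indices into `contour$vertices` (distinct).
#' @return Non-negative cost.
#' @export
bottleneck_cost <- function(contour, p, q) {
  if (p == q) stop("p and q must differ")
  v <- contour$vertices
  n <- nrow(v)
  seg <- sqrt(rowSums((v[c(2:n, 1), , drop = FALSE] - v)^2))
  cum <- c(0, cumsum(seg))  # cum[i] = arc-length from vertex 1 to vertex i
  i <- min(p, q); j <- max(p, q)
  arc1 <- cum[j] - cum[i]
  arc2 <- cum[n + 1] - arc1
  d <- sqrt(sum((v[p, ] - v[q, ])^2))
  d / min(arc1, arc2)
}

#' Detect bottleneck pairs on a contour
#'
#' Candidate vertices are the polygon-approximation keypoints whose exterior
#' angle is below `cfg$angle_max`; among candidate pairs (non-adjacent on the
#' keypoint polygon), those with bottleneck cost below `cfg$tb` are returned,
#' sorted by increasing cost. Vertices failing the angle gate never appear,
#' whatever their cost.
#'
#' @param contour a `slice_contour` (keypoints are computed with
#'   `cfg$approx_tol` if absent).
#' @param cfg a [postprocess_config()].
#' @return List of pairs, each a list with `p`, `q` (vertex indices into
#'   `contour$vertices`), `cost`, `exterior_angles`.
#' @export
detect_bottlenecks <- function(contour, cfg = postprocess_config()) {
  if (is.null(contour$keypoints))
    contour <- approx_keypoints(contour, cfg$approx_tol)
  kp <- contour$keypoints
  m <- length(kp)
  if (m < 4) return(list())
  kpoly <- contour$vertices[kp, , drop = FALSE]
  ang <- vapply(seq_len(m), function(i) exterior_angle(kpoly, i), 0)
  cand <- which(ang < cfg$angle_max)
  if (length(cand) < 2) return(list())
  out <- list()
  for (ii in seq_along(cand)) for (jj in seq_along(cand)) {
    if (jj <= ii) next
    a <- cand[ii]; b <- cand[jj]
    # skip keypoints adjacent on the keypoint polygon: no lobe between them
    if (abs(a - b) == 1 || abs(a - b) == m - 1) next
    cost <- bottleneck_cost(contour, kp[a], kp[b])
    if (cost < cfg$tb)
      out[[length(out) + 1L]] <- list(p = kp[a], q = kp[b], cost = cost,
                                      exterior_angles = c(ang[a], ang[b]))
  }
  out[order(vapply(out, function(x) x$cost, 0))]
}

# even-odd ray-casting point-in-polygon, vectorised over points
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# cut a contour along a bottleneck chord into the retained piece and the
# detached lobe(s); returns list(kept = slice_contour or NULL, lobes = list)
cut_bottleneck <- function(contour, pair) {
  v <- contour$vertices
  n <- nrow(v)
  i <- min(pair$p, pair$q); j <- max(pair$p, pair$q)
  chain_a <- i:j
  chain_b <- c(j:n, 1:i)
  if (length(chain_a) < 3 || length(chain_b) < 3) {
    warning("bottleneck cut would leave a degenerate polygon; skipped")
    return(list(kept = contour, lobes = list()))
  }
  nr <- contour$dim[1]
  pix <- contour$pixels
  py <- ((pix - 1L) %% nr)            # 0-based y (row)
  px <- ((pix - 1L) %/% nr)           # 0-based x (col)
  in_a <- points_in_polygon(px, py, v[chain_a, , drop = FALSE])
  # pixels on the lobe's own boundary belong to it regardless of ray casting
  key_a <- pix %in% vert_pixels(v[chain_a, , drop = FALSE], nr)
  key_b <- pix %in% vert_pixels(v[chain_b, , drop = FALSE], nr)
  set_a <- (in_a | key_a) & !(!in_a & key_b & !key_a)
  n_a <- sum(set_a); n_b <- contour$area - n_a
  keep_a <- if (n_a != n_b) n_a > n_b else {
    ca <- c(mean(px[set_a]), mean(py[set_a]))
    cb <- c(mean(px[!set_a]), mean(py[!set_a]))
    # discard the lobe with smaller centroid x (then y)
    if (ca[1] != cb[1]) ca[1] > cb[1] else ca[2] > cb[2]
  }
  keep <- if (keep_a) set_a else !set_a
  if (sum(keep) < 1 || sum(!keep) < 1) {
    warning("bottleneck cut would discard the whole contour; skipped")
    return(list(kept = contour, lobes = list()))
  }
  retrace <- function(sel) {
    sub <- matrix(FALSE, contour$dim[1], contour$dim[2])
    sub[pix[sel]] <- TRUE
    extract_contours(sub + 0L, contour$slice_index)
  }
  kept_cc <- retrace(keep)
  if (!length(kept_cc)) {
    warning("bottleneck cut left no traceable region; skipped")
    return(list(kept = contour, lobes = list()))
  }
  ka <- vapply(kept_cc, function(x) x$area, 0)
  list(kept = kept_cc[[which.max(ka)]],
       lobes = c(kept_cc[-which.max(ka)], retrace(!keep)))
}

#' Remove one bottleneck lobe from a contour
#'
#' Cuts the contour along the chord `(p, q)`, splitting it into two lobes;
#' the lobe enclosing fewer of the contour's filled pixels is discarded and
#' the remaining region is re-traced into a fresh closed counter-clockwise
#' contour. Equal lobes are broken deterministically: the lobe whose pixel
#' centroid has smaller x (then smaller y) is discarded. If the cut would
#' leave a degenerate polygon, the contour is returned unchanged with a
#' warning.
#'
#' @param contour a `slice_contour`.
#' @param pair a bottleneck pair from [detect_bottlenecks()].
#' @return A `slice_contour` for the retained lobe.
#' @export
remove_bottleneck <- function(contour, pair) {
  cut_bottleneck(contour, pair)$kept
}

vert_pixels <- function(v, nr) {
  round(v[, 1]) * nr + round(v[, 2]) + 1L
}

#' Adjacent-contour similarity threshold
#'
#' Linear in the inter-slice distance: `tc = 0.8 - 0.05 (dz - 1)`. Thicker
#' slices allow more shape change between neighbours, so the required overlap
#' fraction is relaxed by 0.05 per mm beyond 1 mm.
#'
#' @param dz inter-slice distance in mm (> 0).
#' @param base,slope intercept (at 1 mm) and per-mm slope.
#' @return The similarity threshold.
#' @export
tc_threshold <- function(dz, base = 0.8, slope = 0.05) {
  if (any(dz <= 0)) stop("dz must be > 0")
  base - slope * (dz - 1)
}

#' Adjacent-slice contour constraint
#'
#' For each contour of the current slice, the similarity to a reference
#' contour is the overlap of their filled regions over the smaller area:
#' `S = |c  r| / min(|c|, |r|)`. A current contour is removed when its best
#' similarity over all reference contours falls below `tc` *and* it is the
#' smaller member of that best-matching pair; otherwise it is retained.
#'
#' @param current list of `slice_contour` for the slice being processed.
#' @param reference list of `slice_contour` of the neighbouring processed
#'   slice (same grid).
#' @param tc similarity threshold, e.g. [tc_threshold()].
#' @return The retained subset of `current`.
#' @export
contour_constraint <- function(current, reference, tc) {
  if (!length(reference)) {
    warning("empty reference slice: contour constraint skipped")
    return(current)
  }
  keep <- vapply(current, function(cc) {
    s_best <- -1; r_best <- NULL
    for (rr in reference) {
      ov <- length(intersect(cc$pixels, rr$pixels))
      s <- ov / min(cc$area, rr$area)
      if (s > s_best) { s_best <- s; r_best <- rr }
    }
    !(s_best < tc && cc$area < r_best$area)
  }, TRUE)
  current[keep]
}

# cut bottlenecks repeatedly (lowest cost first) until no pair qualifies;
# returns list(main = slice_contour, lobes = list of detached slice_contours)
split_all_bottlenecks <- function(contour, cfg) {
  lobes <- list()
  repeat {
    if (nrow(contour$vertices) < 4) break
    contour$keypoints <- NULL
    pairs <- detect_bottlenecks(contour, cfg)
    if (!length(pairs)) break
    cut <- cut_bottleneck(contour, pairs[[1]])
    if (cut$kept$area >= contour$area) break  # no progress; stop
    lobes <- c(lobes, cut$lobes)
    contour <- cut$kept
  }
  list(main = contour, lobes = lobes)
}

# apply bottleneck removal repeatedly until no pair qualifies
remove_all_bottlenecks <- function(contour, cfg) {
  split_all_bottlenecks(contour, cfg)$main
}

#' Anatomical polish of a segmented volume
#'
#' The full post-processing pass. Per slice, the contours of the two parallel
#' segmentation routes -- the graph-cut labels and the Otsu-binarized
#' probability map -- are each cut at every detected bottleneck, which turns
#' a spurious attached region into a separate candidate lobe. The bottleneck
#' only *proposes* a removal: the adjacent-contour constraint decides. On the
#' anchor slice (largest single contour; ties toward lower z) no neighbour
#' evidence exists, so detached lobes are dropped outright. Stepping outward
#' one slice at a time in both directions, every candidate piece (retained
#' bodies and detached lobes alike) is kept or removed by
#' [contour_constraint()] against the previously accepted slice (the last
#' non-empty one if a slice loses everything): a lobe well supported by the
#' neighbouring anatomy is re-attached, an unsupported one disappears. The
#' final mask is the union of all retained filled contours, so polish never
#' adds foreground beyond the two routes' union.
#'
#' @param prob a `probability_map` (relaxation-refined).
#' @param labels 3D 0/1 array of per-slice graph-cut labels, `(z, y, x)`.
#' @param vol the source [ct_volume] (supplies `dz` for [tc_threshold()]).
#' @param cfg a [postprocess_config()].
#' @return A [binary_mask].
#' @export
polish_volume <- function(prob, labels, vol, cfg = postprocess_config()) {
  d <- dim(labels)
  nz <- d[1]
  tc <- tc_threshold(vol$spacing[3], cfg$tc_base, cfg$tc_slope)
  mains <- vector("list", nz)
  lobes <- vector("list", nz)
  largest <- numeric(nz)
  for (z in seq_len(nz)) {
    cont <- c(extract_contours(labels[z, , ], z - 1L),
              extract_contours(binarize_otsu_quiet(prob$values[z, , ]), z - 1L))
    sp <- lapply(cont, split_all_bottlenecks, cfg = cfg)
    mains[[z]] <- lapply(sp, function(x) x$main)
    lobes[[z]] <- do.call(c, c(list(list()), lapply(sp, function(x) x$lobes)))
    largest[z] <- if (length(mains[[z]]))
      max(vapply(mains[[z]], function(x) x$area, 0)) else 0
  }
  if (all(largest == 0)) {
    warning("no foreground anywhere: empty mask")
    return(binary_mask(array(0L, d), vol$spacing))
  }
  anchor <- which.max(largest)  # ties -> lower z
  accepted <- vector("list", nz)
  accepted[[anchor]] <- mains[[anchor]]  # lobes lack neighbour support here
  for (dir in c(1L, -1L)) {
    ref <- accepted[[anchor]]
    z <- anchor + dir
    while (z >= 1L && z <= nz) {
      cand <- c(mains[[z]], lobes[[z]])
      kept <- if (length(cand)) contour_constraint(cand, ref, tc) else list()
      accepted[[z]] <- kept
      if (length(kept)) ref <- kept  # else keep last non-empty reference
      z <- z + dir
    }
  }
  out <- array(0L, d)
  for (z in seq_len(nz)) {
    if (!length(accepted[[z]])) next
    sl <- matrix(0L, d[2], d[3])
    for (cc in accepted[[z]]) sl[cc$pixels] <- 1L
    out[z, , ] <- sl
  }
  binary_mask(out, vol$spacing)
}

binarize_otsu_quiet <- function(prob_slice) {
  suppressWarnings(binarize_otsu(prob_slice))
}
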