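test_that("Otsu binarization maximises between-class variance over 256 bins", {
  bi <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  m <- binarize_otsu(bi)
  thr <- attr(m, "threshold")
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)
  expect_equal(sum(m), 50)
  expect_true(all(m[bi > 0.5] == 1))

  # random bimodal map: mask equals the exhaustive threshold-sweep optimum
  set.seed(51)
  v <- matrix(c(rnorm(150, 0.25, 0.05), rnorm(106, 0.75, 0.05)), 16, 16)
  v <- pmin(pmax(v, 0), 1)
  m2 <- binarize_otsu(v)
  bins <- 256
  idx <- pmin(pmax(floor(v * bins) + 1, 1), bins)
  best <- -1; best_k <- 1
  for (k in 1:(bins - 1)) {
    lo <- v[idx <= k]; hi <- v[idx > k]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  expect_equal(attr(m2, "threshold"), best_k / bins)
  expect_equal(unclass(m2), (v > best_k / bins) + 0L, ignore_attr = TRUE)

  expect_warning(m0 <- binarize_otsu(matrix(0.4, 5, 5)), "constant")
  expect_equal(sum(m0), 0)
})

test_that("contour extraction reports filled areas matching flood fill", {
  m <- matrix(0L, 20, 20); m[5:14, 6:15] <- 1L
  cc <- extract_contours(m)
  expect_length(cc, 1)
  expect_equal(cc[[1]]$area, 100)
  expect_gte(nrow(cc[[1]]$vertices), 3)

  two <- matrix(0L, 20, 30)
  two[3:6, 3:6] <- 1L; two[10:17, 12:21] <- 1L
  cc2 <- extract_contours(two)
  expect_length(cc2, 2)
  expect_setequal(vapply(cc2, function(x) x$area, 0), c(16, 80))

  set.seed(52)
  blob <- dilate_mask(matrix(rbinom(900, 1, 0.02), 30, 30), 2)
  ccb <- extract_contours(blob)
  for (co in ccb) {
    start_lin <- co$pixels[1]
    start <- c(((start_lin - 1) %% 30) + 1, ((start_lin - 1) %/% 30) + 1)
    expect_equal(co$area, oracle_flood_count(blob, start))
  }
  # orientation is normalised counter-clockwise
  expect_gt(liverseg:::polygon_signed_area(cc[[1]]$vertices), 0)
})

test_that("polygonal approximation keeps corners and honours the tolerance", {
  m <- matrix(0L, 30, 40); m[8:23, 5:34] <- 1L  # 16 x 30 rectangle
  cc <- extract_contours(m)[[1]]
  k <- approx_keypoints(cc, tol = 2)
  expect_length(k$keypoints, 4)
  corners <- k$vertices[k$keypoints, ]
  expect_setequal(corners[, 1], c(4, 33))
  expect_setequal(corners[, 2], c(7, 22))

  k0 <- approx_keypoints(cc, tol = 0)
  expect_length(k0$keypoints, nrow(cc$vertices))

  # noisy circle: every dropped vertex lies within tol of the kept polygon
  set.seed(53)
  t <- seq(0, 2 * pi, length.out = 121)[-121]
  circ <- cbind(20 + (10 + runif(120, -0.8, 0.8)) * cos(t),
                20 + (10 + runif(120, -0.8, 0.8)) * sin(t))
  con <- structure(list(vertices = circ, slice_index = 0L, area = 300,
                        pixels = 1:300, dim = c(40, 40), keypoints = NULL),
                   class = "slice_contour")
  tol <- 1.5
  ka <- approx_keypoints(con, tol)
  kp <- ka$vertices[ka$keypoints, ]
  dropped <- setdiff(seq_len(120), ka$keypoints)
  for (i in dropped) {
    dmin <- min(vapply(seq_len(nrow(kp)), function(j) {
      a <- kp[j, ]; b <- kp[(j %% nrow(kp)) + 1, ]
      liverseg:::point_segment_dist(circ[i, 1], circ[i, 2], a, b)
    }, 0))
    expect_lte(dmin, tol + 1e-9)
  }
})

test_that("exterior angles follow the 360-minus-interior convention", {
  collinear <- rbind(c(0, 0), c(5, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(exterior_angle(collinear, 2), 180)
  square <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  expect_equal(exterior_angle(square, 2), 270)  # convex corner, interior 90
  # notch vertex with interior 270 (concave): exterior 90
  lshape <- rbind(c(0, 0), c(4, 0), c(4, 2), c(2, 2), c(2, 4), c(0, 4))
  expect_equal(exterior_angle(lshape, 4), 90)
  # prescribed oblique interior angles at the tip of a CCW isoceles triangle
  mk_tri <- function(interior) {
    h <- 5 / tan(interior / 2 * pi / 180)
    rbind(c(-5, h), c(0, 0), c(5, h))
  }
  expect_equal(exterior_angle(mk_tri(150), 2), 210, tolerance = 1e-8)
  expect_equal(exterior_angle(mk_tri(115), 2), 245, tolerance = 1e-8)

  dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 2))
  expect_error(exterior_angle(dup, 2), "duplicate")
})

test_that("bottleneck cost is the gap over the shorter arc", {
  sq <- structure(list(vertices = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                       slice_index = 0L, area = 4, pixels = 1:4,
                       dim = c(2, 2), keypoints = 1:4),
                  class = "slice_contour")
  expect_equal(bottleneck_cost(sq, 1, 3), sqrt(2) / 2)  # not a neck at 0.6
  expect_equal(bottleneck_cost(sq, 1, 2), 1)
  expect_error(bottleneck_cost(sq, 2, 2), "differ")

  # dumbbell: the neck pair is the all-pairs minimum and well under 0.6
  cc <- extract_contours(dumbbell_mask())[[1]]
  cc <- approx_keypoints(cc, 2)
  kp <- cc$keypoints
  costs <- outer(seq_along(kp), seq_along(kp), Vectorize(function(i, j)
    if (i < j) bottleneck_cost(cc, kp[i], kp[j]) else Inf))
  pairs <- detect_bottlenecks(cc, postprocess_config())
  expect_gt(length(pairs), 0)
  expect_equal(pairs[[1]]$cost, min(costs), tolerance = 1e-9)
  expect_lt(pairs[[1]]$cost, 0.6)
})

test_that("the exterior-angle gate admits notches and protects convex vertices", {
  cfg <- postprocess_config()
  # dumbbell neck: both angles concave (< 150), detected
  cc <- approx_keypoints(extract_contours(dumbbell_mask())[[1]], 2)
  pairs <- detect_bottlenecks(cc, cfg)
  expect_gt(length(pairs), 0)
  expect_true(all(pairs[[1]]$exterior_angles < 150))

  # convex polygon: no candidate whatever the cost
  t <- seq(0, 2 * pi, length.out = 9)[-9]
  oct <- structure(list(vertices = cbind(10 * cos(t), 4 * sin(t)),
                        slice_index = 0L, area = 100, pixels = 1:100,
                        dim = c(30, 30), keypoints = 1:8),
                   class = "slice_contour")
  expect_length(detect_bottlenecks(oct, cfg), 0)

  # elongated wavy blob: facing bulge apexes have low cost but convex
  # exterior angles, so the gate excludes them
  v <- lens_polygon()
  lens <- structure(list(vertices = v, slice_index = 0L, area = 1000,
                         pixels = 1:1000, dim = c(200, 200), keypoints = NULL),
                    class = "slice_contour")
  lens <- approx_keypoints(lens, 1.0)
  kp <- lens$keypoints
  kpoly <- lens$vertices[kp, ]
  i_top <- kp[which.max(kpoly[, 2])]
  i_bot <- kp[which.min(kpoly[, 2])]
  ang_top <- exterior_angle(kpoly, which.max(kpoly[, 2]))
  ang_bot <- exterior_angle(kpoly, which.min(kpoly[, 2]))
  expect_equal(ang_top, 210, tolerance = 3)
  expect_equal(ang_bot, 245, tolerance = 3)
  cost <- bottleneck_cost(lens, i_top, i_bot)
  expect_lt(cost, 0.35)   # would be flagged by the cost test alone
  pairs <- detect_bottlenecks(lens, cfg)
  flagged <- vapply(pairs, function(p) all(sort(c(p$p, p$q)) ==
                                             sort(c(i_top, i_bot))), TRUE)
  expect_false(any(flagged))
})

test_that("bottleneck removal discards the smaller lobe with deterministic ties", {
  cfg <- postprocess_config()
  cc <- approx_keypoints(extract_contours(dumbbell_mask())[[1]], 2)
  pairs <- detect_bottlenecks(cc, cfg)
  r <- remove_bottleneck(cc, pairs[[1]])
  expect_lt(r$area, cc$area)
  # area loss is about one square lobe (100 px), the corridor stub may remain
  expect_gte(r$area, 100)
  expect_lte(cc$area - r$area, 112)

  # symmetric dumbbell: the lobe with smaller centroid x is discarded
  kept_cx <- mean(((r$pixels - 1) %/% 30))
  expect_gt(kept_cx, 20)  # right-hand square retained

  # contour with no detected pair is untouched
  sq <- matrix(0L, 12, 12); sq[3:10, 3:10] <- 1L
  sc <- approx_keypoints(extract_contours(sq)[[1]], 2)
  expect_length(detect_bottlenecks(sc, cfg), 0)
})

test_that("detection is invariant to starting vertex and orientation", {
  cfg <- postprocess_config()
  cc <- approx_keypoints(extract_contours(dumbbell_mask())[[1]], 2)
  p0 <- detect_bottlenecks(cc, cfg)
  coords0 <- lapply(p0, function(p) {
    m <- rbind(cc$vertices[p$p, ], cc$vertices[p$q, ])
    m[order(m[, 1], m[, 2]), ]
  })
  v <- cc$vertices
  n <- nrow(v)
  for (variant in list(v[c(15:n, 1:14), ], v[n:1, ])) {
    cc2 <- cc
    cc2$vertices <- variant
    if (liverseg:::polygon_signed_area(variant) < 0)
      cc2$vertices <- variant[n:1, ]
    cc2$keypoints <- NULL
    cc2 <- approx_keypoints(cc2, 2)
    p2 <- detect_bottlenecks(cc2, cfg)
    coords2 <- lapply(p2, function(p) {
      m <- rbind(cc2$vertices[p$p, ], cc2$vertices[p$q, ])
      m[order(m[, 1], m[, 2]), ]
    })
    # same set of detected pairs (cost ties may reorder within the list)
    canon <- function(l) sort(vapply(l, function(m) paste(m, collapse = ","), ""))
    expect_equal(canon(coords2), canon(coords0))
  }
})

test_that("the slice-distance threshold follows the linear formula", {
  expect_identical(tc_threshold(1), 0.8)
  expect_equal(tc_threshold(3), 0.7)
  expect_equal(tc_threshold(5), 0.6)
  dz <- sort(runif(20, 0.5, 6))
  expect_true(all(diff(tc_threshold(dz)) <= 0))
  expect_error(tc_threshold(0), "dz")
})

test_that("the contour constraint removes poorly-supported smaller contours", {
  ref_big <- fake_contour(1:42670)
  keep_same <- contour_constraint(list(ref_big), list(ref_big), 0.8)
  expect_length(keep_same, 1)

  # disjoint and smaller: removed
  lonely <- fake_contour(80000 + 1:100)
  expect_length(contour_constraint(list(lonely), list(ref_big), 0.8), 0)

  # the printed-area configuration: overlaps 42/242 and 51/52 at tc = 0.8
  c1 <- fake_contour(c(1:42, 50000 + 1:200))        # area 242, overlap 42
  c2 <- fake_contour(c(101:151, 60000 + 1))         # area 52, overlap 51
  kept <- contour_constraint(list(c1, c2), list(ref_big), 0.8)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$area, 52)

  expect_warning(
    out <- contour_constraint(list(c1), list(), 0.8), "empty reference")
  expect_length(out, 1)
})

test_that("single-slice volumes get bottleneck cleanup only", {
  d <- dumbbell_mask()
  vol <- ct_volume(array(d * 100, c(1, nrow(d), ncol(d))), c(1, 1, 1))
  prob <- structure(list(values = array(d * 0.98, c(1, nrow(d), ncol(d))),
                         spacing = c(1, 1, 1)), class = "probability_map")
  labels <- array(d, c(1, nrow(d), ncol(d)))
  out <- polish_volume(prob, labels, vol)
  expect_lt(sum(out$voxels), sum(d))       # anchor slice: lobe dropped
  expect_gte(sum(out$voxels), 100)
  # polish never adds foreground
  expect_true(all(out$voxels[1, , ] <= d))
})
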