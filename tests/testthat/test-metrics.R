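mask_of <- function(v, spacing = c(1, 1, 1)) binary_mask(v, spacing)

test_that("overlap metrics match their closed forms", {
  a <- array(0L, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- 1L
  A <- mask_of(a)
  expect_equal(voe(A, A), 0)
  b <- array(0L, c(4, 4, 4)); b[1, 1, 1] <- 1L
  expect_equal(voe(A, mask_of(b)), 100)
  # |intersection| 50, |union| 100
  x <- array(0L, c(5, 5, 5)); x[seq_len(75)] <- 1L
  y <- array(0L, c(5, 5, 5)); y[26:100] <- 1L
  expect_equal(voe(mask_of(x), mask_of(y)), 50)
  expect_equal(voe(mask_of(x), mask_of(y)), voe(mask_of(y), mask_of(x)))
  expect_warning(
    expect_equal(voe(mask_of(array(0L, c(2, 2, 2))),
                     mask_of(array(0L, c(2, 2, 2)))), 0), "empty")

  expect_equal(rvd(A, A), 0)
  big <- array(0L, c(5, 5, 5)); big[seq_len(110)] <- 1L
  ref <- array(0L, c(5, 5, 5)); ref[seq_len(100)] <- 1L
  expect_equal(rvd(mask_of(big), mask_of(ref)), 10)
  small <- array(0L, c(5, 5, 5)); small[seq_len(90)] <- 1L
  expect_equal(rvd(mask_of(small), mask_of(ref)), -10)
  expect_error(rvd(A, mask_of(array(0L, c(4, 4, 4)))), "empty")
  expect_error(voe(A, mask_of(array(0L, c(5, 5, 5)))), "grids")
})

test_that("surface voxels are the 6-neighbour-exposed foreground", {
  cube <- array(1L, c(3, 3, 3))
  expect_equal(nrow(surface_voxels(cube)), 26)
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  sv <- surface_voxels(one)
  expect_equal(nrow(sv), 1)
  expect_equal(unname(sv[1, ]), c(2, 2, 2))
  solid5 <- array(1L, c(5, 5, 5))
  expect_equal(nrow(surface_voxels(solid5)), 125 - 27)
})

test_that("surface distances are exact on two-point and identical masks", {
  a <- array(0L, c(3, 3, 3)); a[2, 2, 2] <- 1L
  b <- array(0L, c(3, 3, 3)); b[2, 2, 1] <- 1L
  A <- mask_of(a, c(3, 1, 1)); B <- mask_of(b, c(3, 1, 1))
  expect_equal(unname(surface_distances(A, B)), c(3, 3, 3))
  expect_equal(unname(surface_distances(A, A)), c(0, 0, 0))
  expect_error(surface_distances(A, mask_of(array(0L, c(3, 3, 3)), c(3, 1, 1))),
               "empty")
})

test_that("all five metrics agree with O(n^2) brute-force oracles", {
  spacing <- c(0.8, 1.1, 2.3)
  for (seed in c(61, 62, 63)) {
    A <- mask_of(random_mask3(c(12, 14, 13), seed), spacing)
    B <- mask_of(random_mask3(c(12, 14, 13), seed + 100), spacing)
    o <- oracle_surface_metrics(A, B)
    sd3 <- surface_distances(A, B)
    expect_equal(unname(sd3["asd"]), o$asd, tolerance = 1e-9)
    expect_equal(unname(sd3["rmsd"]), o$rmsd, tolerance = 1e-9)
    expect_equal(unname(sd3["msd"]), o$msd, tolerance = 1e-9)
    av <- A$voxels != 0; bv <- B$voxels != 0
    expect_equal(voe(A, B), 100 * (1 - sum(av & bv) / sum(av | bv)),
                 tolerance = 1e-12)
    expect_equal(rvd(A, B), 100 * (sum(av) - sum(bv)) / sum(bv),
                 tolerance = 1e-12)
  }
})

test_that("ordering asd <= rmsd <= msd holds on random mask pairs", {
  for (seed in 71:75) {
    A <- mask_of(random_mask3(c(10, 12, 12), seed))
    B <- mask_of(random_mask3(c(10, 12, 12), seed + 50))
    sd3 <- surface_distances(A, B)
    expect_lte(sd3["asd"], sd3["rmsd"] + 1e-12)
    expect_lte(sd3["rmsd"], sd3["msd"] + 1e-12)
  }
})

test_that("the score transform anchors at 100, 75 and clamps at zero", {
  expect_equal(score(0, 2), 100)
  expect_equal(score(2, 2), 75)
  expect_equal(score(8, 2), 0)
  expect_equal(score(10, 2), 0)
  expect_equal(score(-3, 3), 75)  # signed errors scored on magnitude
  expect_error(score(1, 0), "ebar")
  expect_error(reference_errors(1, 1, 1, 0, 1), "positive")
})

test_that("evaluation of identical masks is perfect across the board", {
  A <- mask_of(random_mask3(c(8, 10, 10), 81), c(0.7, 0.7, 2))
  refs <- reference_errors(5, 5, 1, 2, 20)
  rep <- evaluate_masks(A, A, refs)
  expect_equal(rep$voe_pct, 0)
  expect_equal(rep$rvd_pct, 0)
  expect_equal(rep$asd_mm, 0)
  expect_equal(unname(rep$scores), rep(100, 5))
  expect_equal(rep$overall, 100)

  B <- mask_of(random_mask3(c(8, 10, 10), 82), c(0.7, 0.7, 2))
  rep2 <- evaluate_masks(A, B, refs)
  expect_equal(rep2$overall, mean(rep2$scores))  # overall is the plain mean
  expect_true(all(rep2$scores >= 0 & rep2$scores <= 100))
})

test_that("growing A strictly away from B never improves voe or msd", {
  A <- array(0L, c(6, 8, 8)); A[3:4, 3:4, 3:4] <- 1L
  B <- array(0L, c(6, 8, 8)); B[3:4, 3:4, 3:4] <- 1L
  base_voe <- voe(mask_of(A), mask_of(B))
  base_msd <- surface_distances(mask_of(A), mask_of(B))["msd"]
  A2 <- A; A2[1, 7:8, 7:8] <- 1L  # far-away blob added to A
  expect_gte(voe(mask_of(A2), mask_of(B)), base_voe)
  expect_gte(surface_distances(mask_of(A2), mask_of(B))["msd"], base_msd)
})
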