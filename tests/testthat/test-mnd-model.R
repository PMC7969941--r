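test_that("local statistics reproduce closed-form and brute-force values", {
  f <- local_stats(matrix(7, 10, 10), 5)
  expect_true(all(f$mu == 7))
  expect_true(all(f$sigma == 0))

  imp <- matrix(0, 9, 9); imp[5, 5] <- 18
  f3 <- local_stats(imp, 3)
  expect_equal(f3$mu[5, 5], 2)  # 18 / 9

  set.seed(21)
  sl <- matrix(runif(400, 0, 255), 20, 20)
  f5 <- local_stats(sl, 5)
  o <- oracle_local_stats(sl, 5)
  expect_equal(f5$mu, o$mu, tolerance = 1e-10)
  expect_equal(f5$sigma, o$sigma, tolerance = 1e-8)

  expect_error(local_stats(sl, 4), "odd")
})

test_that("seed-patch model moments match a direct moment computation", {
  # constant region: mean (c, 0) and pure-ridge covariance, with a warning
  fconst <- local_stats(matrix(42, 30, 30), 11)
  expect_warning(m <- fit_mnd(fconst, seed_point(15, 15, 0)), "degenerate")
  expect_equal(m$mean, c(42, 0))
  expect_equal(m$cov, diag(1e-6, 2))

  set.seed(22)
  sl <- matrix(runif(900, 0, 255), 30, 30)
  ff <- local_stats(sl, 5)
  seed <- seed_point(14, 16, 0)
  m <- fit_mnd(ff, seed, patch = 7, ridge = 1e-6)
  rows <- (16 + 1 - 3):(16 + 1 + 3); cols <- (14 + 1 - 3):(14 + 1 + 3)
  fs <- cbind(as.vector(ff$mu[rows, cols]), as.vector(ff$sigma[rows, cols]))
  expect_equal(m$mean, colMeans(fs))
  expect_equal(m$cov, cov(fs) + diag(1e-6, 2), tolerance = 1e-12)

  # patch holding two feature values in equal proportion (plus one midpoint
  # row): the model mean lands exactly on their midpoint
  ffh <- structure(list(mu = rbind(matrix(10, 5, 11), 20, matrix(30, 5, 11)),
                        sigma = matrix(0, 11, 11), window = 11L),
                   class = "feature_field")
  mh <- fit_mnd(ffh, seed_point(5, 5, 0), patch = 11)
  expect_equal(mh$mean[1], 20)

  expect_error(fit_mnd(ff, seed_point(1, 1, 0), patch = 7), "patch")
})

test_that("bivariate normal density matches closed forms and a generic oracle", {
  m <- structure(list(mean = c(0, 0), cov = diag(2), ridge = 0),
                 class = "mnd_model")
  expect_equal(mnd_density(c(0, 0), m), 1 / (2 * pi))
  expect_equal(mnd_density(c(1, 1), m), exp(-1) / (2 * pi))

  set.seed(23)
  for (k in 1:10) {
    a <- matrix(rnorm(4), 2)
    S <- crossprod(a) + diag(0.1, 2)
    mu <- rnorm(2)
    mod <- structure(list(mean = mu, cov = S, ridge = 0), class = "mnd_model")
    f <- rnorm(2, sd = 3)
    expect_equal(mnd_density(f, mod), oracle_mvn_density(f, mu, S),
                 tolerance = 1e-12)
  }

  # density integrates to ~1 over a fine grid (identity covariance)
  g <- seq(-6, 6, by = 0.05)
  gr <- as.matrix(expand.grid(g, g))
  expect_equal(sum(mnd_density(gr, m)) * 0.05^2, 1, tolerance = 1e-3)
})

test_that("probability map is 1 at the model mean and separates blob from background", {
  ph <- small_phantom()
  wv <- apply_window(ph$volume)
  seed <- ph$suggested_seed
  ff <- local_stats(wv$intensities[seed$z + 1, , ], 11)
  model <- suppressWarnings(fit_mnd(ff, seed))
  pm <- probability_map(wv, model)
  expect_true(all(pm$values >= 0 & pm$values <= 1))
  # noise-free uniform blob: interior (eroded by the feature window) is
  # exactly at the model mean; background features sit far away
  interior <- ph$truth$voxels
  for (z in seq_len(dim(interior)[1]))
    interior[z, , ] <- erode_mask(interior[z, , ], 6)
  expect_true(all(pm$values[interior == 1] > 0.999))
  bg <- ph$truth$voxels == 0
  # trim a margin around the liver where windows straddle the boundary
  near <- ph$truth$voxels
  for (z in seq_len(dim(near)[1])) near[z, , ] <- dilate_mask(near[z, , ], 6)
  expect_lt(mean(pm$values[near == 0]), 0.05)
})

test_that("probability map is invariant to HU shifts within the window's linear range", {
  ph <- small_phantom(liver_mean_hu = 100, background_hu = 40)
  run_map <- function(vol) {
    wv <- apply_window(vol)
    seed <- ph$suggested_seed
    ff <- local_stats(wv$intensities[seed$z + 1, , ], 11)
    model <- suppressWarnings(fit_mnd(ff, seed))
    probability_map(wv, model)$values
  }
  base <- run_map(ph$volume)
  shifted <- run_map(ct_volume(ph$volume$voxels + 10, ph$volume$spacing))
  expect_equal(shifted, base, tolerance = 1e-6)
})
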