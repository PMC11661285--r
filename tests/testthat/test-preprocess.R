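# Preprocessing chain: smoothing, leakage-safe fitting, round trips, exact
# weight back-projection.

toy_gmv <- function(n = 30, grid = c(6, 6, 6), seed = 1) {
  set.seed(seed)
  gmv_matrix(matrix(rnorm(n * prod(grid), 10), n), grid)
}

test_that("smoothing is identity at fwhm 0 and preserves constant images", {
  g <- toy_gmv()
  expect_identical(smooth_gmv(g, 0), g)
  const <- gmv_matrix(matrix(3, 4, 6^3), c(6, 6, 6))
  sm <- smooth_gmv(const, 2)
  expect_equal(max(abs(sm$data - 3)), 0, tolerance = 1e-12)
})

test_that("a unit impulse smooths to the normalized kernel peak", {
  grid <- c(9, 9, 9)
  x <- matrix(0, 1, prod(grid))
  center <- 5 + 9 * 4 + 81 * 4  # voxel (5,5,5), first axis fastest
  x[1, center] <- 1
  sm <- smooth_gmv(gmv_matrix(x, grid), 2)
  k <- braingap:::gaussian_kernel_1d(2)
  peak <- max(k)^3  # separable kernel, interior voxel: mass already 1
  expect_equal(unname(sm$data[1, center]), peak, tolerance = 1e-12)
})

test_that("age residualization uses training statistics and kills training age correlation", {
  set.seed(2)
  n <- 60; p <- 40
  age <- runif(n, 20, 70)
  x <- matrix(rnorm(n * p), n, p) + outer(age, runif(p, -0.05, 0.05))
  ch <- fit_chain(x, age = age,
                  config = preproc_config(fwhm = 0, site_correct = FALSE,
                                          pca = FALSE, scale01 = FALSE))
  f <- ch$train_features
  expect_lt(max(abs(cor(f, age))), 1e-10)
  # null ages: fitted slopes indistinguishable from zero
  x0 <- matrix(rnorm(n * p), n, p)
  ch0 <- fit_chain(x0, age = age,
                   config = preproc_config(fwhm = 0, site_correct = FALSE,
                                           pca = FALSE, scale01 = FALSE))
  se <- apply(x0, 2, sd) / (sd(age) * sqrt(n - 1))
  expect_true(all(abs(ch0$age_slopes) < 4 * se))
})

test_that("site offsets are zero for a single site and centre the global mean per site", {
  set.seed(3)
  x <- matrix(rnorm(40 * 20, 5), 40, 20)
  ch1 <- fit_chain(x, site = rep("a", 40),
                   config = preproc_config(fwhm = 0, age_residualize = FALSE,
                                           pca = FALSE, scale01 = FALSE))
  expect_equal(unname(ch1$site_offsets), 0, tolerance = 1e-12)
  site <- rep(c("a", "b"), each = 20)
  x2 <- x + ifelse(site == "b", 0.7, 0)
  ch2 <- fit_chain(x2, site = site,
                   config = preproc_config(fwhm = 0, age_residualize = FALSE,
                                           pca = FALSE, scale01 = FALSE))
  g <- tapply(rowMeans(ch2$train_features), site, mean)
  expect_equal(unname(g["a"]), unname(g["b"]), tolerance = 1e-10)
})

test_that("PCA at full retained variance round-trips to machine precision", {
  set.seed(4)
  x <- matrix(rnorm(50 * 20), 50, 20)
  cfg <- preproc_config(fwhm = 0, age_residualize = FALSE, site_correct = FALSE,
                        retained_variance = 1, scale01 = FALSE)
  ch <- fit_chain(x, config = cfg)
  back <- ch$train_features %*% t(ch$rotation)
  back <- sweep(back, 2, ch$pca_center, "+")
  expect_lt(max(abs(back - x)), 1e-10)
})

test_that("apply_chain replays frozen parameters: train reproduction, row equivariance, clipping", {
  set.seed(5)
  g <- toy_gmv(40)
  age <- runif(40, 20, 70)
  site <- rep(c("a", "b"), 20)
  ch <- fit_chain(g, age = age, site = site, config = preproc_config())
  f <- apply_chain(ch, g, age = age, site = site)
  expect_equal(f, ch$train_features, tolerance = 1e-12)
  perm <- sample(40)
  fp <- apply_chain(ch, gmv_matrix(g$data[perm, ], g$grid), age = age[perm],
                    site = site[perm])
  expect_equal(unname(fp), unname(f[perm, ]), tolerance = 1e-12)
  # extreme new subject: clipped into [0, 1], no error
  xnew <- g$data[1:2, , drop = FALSE] * 50
  fn <- apply_chain(ch, xnew, age = age[1:2], site = site[1:2])
  expect_true(all(fn >= 0 & fn <= 1))
  expect_error(apply_chain(ch, g$data[, 1:10]), "features")
})

test_that("fitting never touches held-out rows (leakage sentinel)", {
  set.seed(6)
  x <- matrix(rnorm(50 * 30), 50, 30)
  age <- runif(50, 20, 70)
  train <- 1:40
  ch1 <- fit_chain(x[train, ], age = age[train],
                   config = preproc_config(fwhm = 0, site_correct = FALSE))
  x2 <- x
  x2[41:50, ] <- x2[41:50, ] + 100  # corrupt the held-out rows
  ch2 <- fit_chain(x2[train, ], age = age[train],
                   config = preproc_config(fwhm = 0, site_correct = FALSE))
  expect_identical(ch1$age_slopes, ch2$age_slopes)
  expect_identical(ch1$rotation, ch2$rotation)
  expect_identical(ch1$scale_min, ch2$scale_min)
})

test_that("back-projected weights reproduce linear decision values exactly", {
  set.seed(7)
  g <- toy_gmv(45)
  age <- runif(45, 20, 70)
  site <- rep(c("a", "b", "c"), 15)
  ch <- fit_chain(g, age = age, site = site, config = preproc_config(fwhm = 0))
  k <- ncol(ch$train_features)
  w <- rnorm(k); b <- 0.3
  bp <- backproject_weights(ch, w, b)
  # the pullback applies to the post-age/site, pre-PCA matrix
  xm <- g$data - outer(age - ch$age_mean, ch$age_slopes)
  gmean <- rowMeans(xm)
  xm <- xm - as.vector(c(tapply(gmean, site, mean))[site] - ch$grand_mean)
  f_direct <- drop(xm %*% bp$w_voxel) + bp$intercept
  f_model <- drop(ch$train_features %*% w) + b
  expect_lt(max(abs(f_direct - f_model)), 1e-8)
})

test_that("trivial chains back-project to the identity", {
  cfg <- preproc_config(fwhm = 0, age_residualize = FALSE, site_correct = FALSE,
                        pca = FALSE, scale01 = FALSE)
  x <- matrix(rnorm(20 * 5), 20, 5)
  ch <- fit_chain(x, config = cfg)
  bp <- backproject_weights(ch, 1:5, 2)
  expect_equal(bp$w_voxel, 1:5)
  expect_equal(bp$intercept, 2)
})
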