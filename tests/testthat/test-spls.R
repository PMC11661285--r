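# Sparse PLS: penalized rank-1 fits, SVD oracle equivalence, deflation,
# permutation gating, sparsity selection, bootstrap stability.

std_blocks <- function(n, p, q, seed, f = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  Y <- matrix(rnorm(n * q), n)
  if (!is.null(f)) { X <- X + f$X; Y <- Y + f$Y }
  spls_input(X, Y)
}

test_that("single-column blocks give unit weights and d = (n-1) * cor", {
  set.seed(1)
  x <- rnorm(30); y <- 0.7 * x + rnorm(30)
  inp <- spls_input(cbind(x), cbind(y))
  f <- fit_rank1(inp$X, inp$Y)
  expect_equal(unname(f$u), 1)
  expect_equal(unname(f$v), 1)
  expect_equal(unname(f$d), (30 - 1) * cor(x, y), tolerance = 1e-10)
  expect_equal(f$rho, cor(x, y), tolerance = 1e-10)
})

test_that("without sparsity the fit equals the leading singular pair of X'Y", {
  for (s in 1:30) {
    inp <- std_blocks(40, 6, 50, s)
    f <- fit_rank1(inp$X, inp$Y)
    sv <- svd(crossprod(inp$X, inp$Y), nu = 1, nv = 1)
    expect_gt(abs(sum(f$u * sv$u)), 0.999)
    expect_gt(abs(sum(f$v * sv$v)), 0.999)
    expect_equal(f$d, sv$d[1], tolerance = 1e-6)
  }
})

test_that("the L1 constraint binds and the sign convention holds", {
  inp <- std_blocks(50, 6, 20, 3)
  f <- fit_rank1(inp$X, inp$Y, c_u = 1.3, c_v = 2.5)
  expect_lte(sum(abs(f$u)), 1.3 + 1e-6)
  expect_lte(sum(abs(f$v)), 2.5 + 1e-6)
  expect_equal(sqrt(sum(f$u^2)), 1, tolerance = 1e-8)
  expect_gt(f$u[which.max(abs(f$u))], 0)
  expect_gte(f$d, 0)
  expect_error(fit_rank1(inp$X, inp$Y, c_u = 0.5), "c_u")
})

test_that("independent blocks give a small d and a non-significant LV", {
  inp <- std_blocks(500, 6, 20, 4)
  f <- fit_rank1(inp$X, inp$Y)
  pt <- permutation_test_lv(inp$X, inp$Y, f, sqrt(6), sqrt(20),
                            n_perm = 99, seed = 5)
  expect_gt(pt$p, 0.05)
  expect_gte(pt$p, 1 / 100)
})

test_that("projection deflation removes the fitted rank and orthogonalizes scores", {
  set.seed(6)
  n <- 120
  L <- rnorm(n)
  f1 <- list(X = outer(L, c(3, 2, rep(0, 4))), Y = outer(L, rep(c(1, 0), c(8, 12))))
  inp <- std_blocks(n, 6, 20, 7, f1)
  f <- fit_rank1(inp$X, inp$Y)
  dd <- deflate(inp$X, inp$Y, f)
  expect_lt(max(abs(crossprod(f$xi, dd$X))), 1e-8)
  expect_lt(max(abs(crossprod(f$omega, dd$Y))), 1e-8)
  f2 <- fit_rank1(dd$X, dd$Y)
  expect_lt(f2$d / f$d, 0.25)  # the coupled rank is gone
})

test_that("a two-factor coupling yields two LVs matched to the true factors", {
  set.seed(8)
  n <- 200
  L1 <- rnorm(n); L2 <- rnorm(n)
  # unequal strengths keep the two singular directions well separated
  fx <- cbind(5 * L1, 4 * L1, 3.5 * L2, 3 * L2, 0, 0)
  fy <- outer(L1, rep(c(1.8, 0), c(10, 20))) + outer(L2, rep(c(0, 1.2), c(20, 10)))
  inp <- std_blocks(n, 6, 30, 9, list(X = fx, Y = fy))
  m <- fit_spls(inp$X, inp$Y, n_perm = 99, max_lv = 3, seed = 10)
  expect_gte(m$n_lv, 2)
  match1 <- max(abs(cor(m$lvs[[1]]$xi, L1)), abs(cor(m$lvs[[1]]$xi, L2)))
  match2 <- max(abs(cor(m$lvs[[2]]$xi, L1)), abs(cor(m$lvs[[2]]$xi, L2)))
  expect_gt(match1, 0.8)
  expect_gt(match2, 0.8)
  # each LV picks a different factor
  which1 <- which.max(c(abs(cor(m$lvs[[1]]$xi, L1)), abs(cor(m$lvs[[1]]$xi, L2))))
  which2 <- which.max(c(abs(cor(m$lvs[[2]]$xi, L1)), abs(cor(m$lvs[[2]]$xi, L2))))
  expect_false(which1 == which2)
  # singular values non-increasing across recorded LVs
  expect_true(all(diff(vapply(m$lvs, `[[`, numeric(1), "d")) <= 1e-8))
})

test_that("the LV loop records one LV for one factor, none for null data, none at max_lv 0", {
  set.seed(11)
  n <- 150
  L <- rnorm(n)
  fx <- cbind(2.5 * L, 2 * L, 0, 0, 0, 0)
  fy <- outer(L, rep(c(0.9, 0), c(10, 20)))
  inp <- std_blocks(n, 6, 30, 12, list(X = fx, Y = fy))
  m1 <- fit_spls(inp$X, inp$Y, n_perm = 99, max_lv = 4, seed = 13)
  expect_equal(m1$n_lv, 1)
  null_in <- std_blocks(150, 6, 30, 14)
  m0 <- fit_spls(null_in$X, null_in$Y, n_perm = 99, max_lv = 4, seed = 15)
  expect_equal(m0$n_lv, 0)
  me <- fit_spls(inp$X, inp$Y, n_perm = 99, max_lv = 0, seed = 16)
  expect_equal(me$n_lv, 0)
})

test_that("sparsity selection prefers sparse settings for sparse truths", {
  grid <- expand.grid(c_u = c(1, 1.4, 1.8, 2.2, sqrt(6)), c_v = c(3, sqrt(30)))
  single <- select_sparsity(NULL, NULL, grid[3, , drop = FALSE])
  expect_equal(single$c_u, grid$c_u[3])
  set.seed(17)
  n <- 150
  L <- rnorm(n)
  fx <- cbind(3 * L, 2.5 * L, 0, 0, 0, 0)     # 2 of 6 features load
  fy <- outer(L, rep(c(1, 0), c(10, 20)))
  inp <- std_blocks(n, 6, 30, 18, list(X = fx, Y = fy))
  sel <- select_sparsity(inp$X, inp$Y, grid, seed = 19)
  expect_lte(sel$c_u, 1.8)  # lower half of the c_u grid
})

test_that("bootstrap stability separates coupled from noise features", {
  set.seed(20)
  n <- 150
  L <- rnorm(n)
  fx <- cbind(3 * L, 0, 0, 0, 0, 0)
  fy <- outer(L, rep(c(1, 0), c(10, 20)))
  inp <- std_blocks(n, 6, 30, 21, list(X = fx, Y = fy))
  bs <- bootstrap_weights(inp$X, inp$Y, c_u = 1.5, c_v = 3,
                          n_boot = 120, seed = 22)
  expect_gt(bs$u_ci[1, 1], 0)          # coupled feature: CI excludes 0
  expect_gt(bs$u_freq[1], 0.9)
  expect_lte(bs$u_ci[1, 4], 0)         # noise feature: CI covers 0
  expect_gte(bs$u_ci[2, 4], 0)
  bs2 <- bootstrap_weights(inp$X, inp$Y, c_u = 1.5, c_v = 3,
                           n_boot = 240, seed = 22)
  expect_lt(max(abs(bs$u_freq - bs2$u_freq)), 0.1)
})
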