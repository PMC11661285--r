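# Nested cross-validation engine: fold construction, evaluation metrics,
# signal and null behaviour, leakage, permutation significance.

test_that("cv assignments have the promised geometry and determinism", {
  cv <- make_cv(10, 5, 1, seed = 1)
  expect_equal(as.integer(table(cv$folds[, 1])), rep(2L, 5))
  cv2 <- make_cv(10, 5, 1, seed = 1)
  expect_identical(cv$folds, cv2$folds)
  cv3 <- make_cv(37, 5, 5, seed = 2)
  expect_equal(ncol(cv3$folds), 5)          # 5 x 5 = 25 training partitions
  expect_true(all(apply(cv3$folds, 2, function(f) diff(range(table(f)))) <= 1))
  # stratification balances classes per fold
  y <- rep(c(0, 1), c(30, 10))
  cvs <- make_cv(40, 5, 2, seed = 3, stratify = y)
  per_fold <- tapply(y, cvs$folds[, 1], sum)
  expect_true(all(per_fold == 2))
  expect_warning(make_cv(10, 5, 1, seed = 1, stratify = rep(c(0, 1), c(8, 2))),
                 "stratum")
})

test_that("regression metrics match hand-computed values", {
  pt <- data.frame(truth = c(20, 25, 30), ensemble = c(22, 25, 28))
  m <- evaluate_regression(pt)
  expect_equal(m$MAE, 4 / 3)
  expect_equal(m$R2, 1 - 8 / 50)
  expect_equal(m$r, 1)
  expect_equal(evaluate_regression(
    data.frame(truth = c(1, 2, 3), ensemble = c(2, 2, 2)))$R2, 0)
  expect_error(evaluate_regression(data.frame(truth = c(2, 2), ensemble = c(1, 2))),
               "variance")
})

test_that("balanced accuracy combines sensitivity and specificity", {
  expect_equal(evaluate_classification(sensitivity = 72.2, specificity = 72.6)$BAC,
               72.4)
  expect_equal(evaluate_classification(sensitivity = 64.9, specificity = 53.5)$BAC,
               59.2)
  pt <- data.frame(truth = c(1, 1, 0, 0), decision_score = c(1, 1, 1, 1))
  m <- evaluate_classification(pt)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 0)
  expect_equal(m$BAC, 50)
  expect_error(evaluate_classification(
    data.frame(truth = c(1, 1), decision_score = c(1, -1))), "both classes")
})

test_that("the BMI model learns the seeded signature and fails on shuffled labels", {
  pr <- phantom_run()
  m <- evaluate_regression(pr$fit_svr$predictions)
  expect_gt(m$R2, 0)
  expect_lt(m$MAE, sd(pr$subjects$bmi[pr$hc]))
  # back-projected weights recover the seeded sign structure
  mw <- colMeans(pr$w_bmi)
  expect_lt(mean(mw[pr$atlas$bmi_signature < 0]), 0)
  expect_gt(mean(mw[pr$atlas$bmi_signature > 0]), 0)
  # shuffled labels: no out-of-fold skill
  set.seed(11)
  hc <- pr$hc[1:150]
  ysh <- sample(pr$subjects$bmi[hc])
  cv <- make_cv(length(hc), 5, 1, seed = 12)
  fit <- train_nested(pr$gmv_of(hc), ysh,
                      covariates = pr$subjects[hc, c("age", "site")],
                      cv = cv, task = "svr",
                      grid = data.frame(cost = 0.5, epsilon = 0.1),
                      preproc = preproc_config(), seed = 13)
  expect_lte(evaluate_regression(fit$predictions)$R2, 0.05)
})

test_that("a separable disease effect at vanishing noise is classified perfectly", {
  at <- make_phantom_atlas(c(8, 8, 8), 8, c(30, 30), 0.5, seed = 2)
  cfg <- cohort_config(groups = c(HC = 40L, SCZ = 40L), noise_sd = 1e-6,
                       beta_dis = 0.5, beta_bmi = 0, lambda_clin = 0,
                       propensity_sd = 1e-9, site_sd = 0,
                       age_slope_mean = 0, age_slope_sd = 0, sex_effect_sd = 0)
  sim <- simulate_cohort(at, cfg, seed = 3)
  y <- as.integer(sim$subjects$group == "SCZ")
  cv <- make_cv(80, 5, 1, seed = 4, stratify = y)
  fit <- train_nested(sim$gmv, y, covariates = sim$subjects[, c("age", "site")],
                      cv = cv, task = "svc",
                      grid = data.frame(cost = 1, epsilon = NA),
                      preproc = preproc_config(fwhm = 0), seed = 5)
  expect_equal(evaluate_classification(fit$predictions)$BAC, 100)
})

test_that("outer-test perturbations change no fitted member parameters", {
  set.seed(21)
  n <- 60; grid <- c(6, 6, 6)
  x <- matrix(rnorm(n * prod(grid), 5), n)
  y <- rnorm(n, 25, 3)
  covs <- data.frame(age = runif(n, 20, 60), site = rep(c("a", "b"), n / 2))
  cv <- make_cv(n, 5, 1, seed = 22)
  args <- list(labels = y, covariates = covs, cv = cv, task = "svr",
               grid = data.frame(cost = c(0.5, 2), epsilon = 0.2),
               preproc = preproc_config(fwhm = 2), inner_k = 5, inner_r = 1,
               seed = 23)
  f1 <- do.call(train_nested, c(list(gmv_matrix(x, grid)), args))
  victim <- 7L
  x2 <- x
  x2[victim, ] <- x2[victim, ] + rnorm(prod(grid), 0, 10)
  f2 <- do.call(train_nested, c(list(gmv_matrix(x2, grid)), args))
  vf <- cv$folds[victim, 1]
  m1 <- f1$ensemble$members[[vf]]
  m2 <- f2$ensemble$members[[vf]]
  expect_equal(m1$w, m2$w, tolerance = 1e-12)
  expect_equal(m1$b, m2$b, tolerance = 1e-12)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$chain$rotation, m2$chain$rotation, tolerance = 1e-12)
  # ... while the victim's own prediction does change
  expect_false(isTRUE(all.equal(f1$predictions$ensemble[victim],
                                f2$predictions$ensemble[victim])))
})

test_that("every member's voxel weights reproduce its decision values", {
  pr <- phantom_run()
  hc <- pr$hc
  xm <- pr$gmv_of(hc)$data %*%
    braingap:::smoothing_operator(c(12, 12, 12), 2)
  xm <- as.matrix(xm)
  folds <- pr$fit_svr$ensemble$cv$folds
  for (m in pr$fit_svr$ensemble$members[c(1, 13, 25)]) {
    # restrict to the member's training rows: inside the fitted scaling
    # bounds, so the clip in apply_chain is inactive and the map is linear
    tr <- which(folds[, m$rep] != m$fold)
    age <- pr$subjects$age[hc][tr]; site <- pr$subjects$site[hc][tr]
    ch <- m$chain
    z <- xm[tr, ] - outer(age - ch$age_mean, ch$age_slopes)
    z <- z - as.vector(c(ch$site_offsets)[site] - 0)
    f_feat <- apply_chain(ch, xm[tr, ], age = age, site = site)
    expect_lt(max(abs((z %*% m$w_voxel + m$intercept_voxel) -
                        (f_feat %*% m$w + m$b))), 1e-8)
  }
})

test_that("applying an ensemble is pure and averages over members", {
  pr <- phantom_run()
  idx <- pr$pat[1:10]
  g <- pr$gmv_of(c(idx, idx[1]))  # duplicate first subject
  pt <- apply_ensemble(pr$fit_svr$ensemble, g,
                       covariates = pr$subjects[c(idx, idx[1]), c("age", "site")])
  expect_equal(pt$ensemble[1], pt$ensemble[11])
  expect_true(all(is.finite(pt$ensemble)))
  expect_error(apply_ensemble(pr$fit_svr$ensemble, matrix(0, 2, 10)), "voxels")
})

test_that("permutation p-values respect the add-one bound and detect strong signal", {
  set.seed(31)
  n <- 50
  x <- matrix(rnorm(n * 10), n)
  y <- drop(x %*% c(3, -3, rep(0, 8))) + rnorm(n, 0, 0.3)
  cv <- make_cv(n, 5, 1, seed = 32)
  pp <- preproc_config(fwhm = 0, age_residualize = FALSE, site_correct = FALSE,
                       pca = FALSE, scale01 = FALSE, standardize = TRUE)
  res <- permutation_significance(x, y, cv = cv, task = "svr",
                                  grid = data.frame(cost = 1, epsilon = 0.1),
                                  preproc = pp, n_perm = 19, seed = 33)
  expect_equal(res$p, 1 / 20)  # the smallest attainable value
  expect_gte(res$p, 1 / (19 + 1))
})

test_that("null permutation p-values are uniform across seeds", {
  pv <- null_pvals_nestedcv()
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("degenerate training partitions abort the run when too frequent", {
  x <- matrix(rnorm(20 * 5), 20)
  cv <- make_cv(20, 5, 1, seed = 41)
  expect_error(
    train_nested(x, rep(25, 20), cv = cv, task = "svr",
                 grid = data.frame(cost = 1, epsilon = 0.1),
                 preproc = preproc_config(fwhm = 0, age_residualize = FALSE,
                                          site_correct = FALSE, pca = FALSE,
                                          scale01 = FALSE, standardize = TRUE),
                 seed = 42),
    "degenerate")
})
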