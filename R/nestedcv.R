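# Repeated nested cross-validation for linear epsilon-SVR (phenotype
# regression) and linear C-SVC (diagnosis classification): hyperparameter
# selection in inner folds strictly inside each outer training partition,
# out-of-fold prediction aggregation across repetitions, external application
# of the trained ensemble, and permutation-based model significance.

#' Build a repeated cross-validation assignment
#'
#' @param n number of subjects.
#' @param k folds per repetition (default 5).
#' @param r repetitions (default 5).
#' @param seed integer seed; the assignment is deterministic given all
#'   arguments.
#' @param stratify optional label vector; folds are then balanced per
#'   stratum (strata smaller than `k` are spread round-robin with a warning).
#' @return Object of class `cv_assignment` with an `n x r` fold-id matrix.
#' @export
make_cv <- function(n, k = 5L, r = 5L, seed = 1L, stratify = NULL) {
  if (n < k) stop("need n >= k")
  folds <- matrix(NA_integer_, n, r)
  small <- FALSE
  for (rep in seq_len(r)) {
    with_seed(derive_seed(seed, rep), {
      if (is.null(stratify)) {
        ord <- sample.int(n)
        folds[ord, rep] <- rep_len(seq_len(k), n)
      } else {
        for (s in unique(stratify)) {
          idx <- which(stratify == s)
          if (length(idx) < k) small <- TRUE
          ord <- idx[sample.int(length(idx))]
          folds[ord, rep] <- rep_len(seq_len(k), length(idx))
        }
      }
    })
  }
  if (small) warning("a stratum is smaller than k; distributed round-robin")
  structure(list(n = n, k = as.integer(k), r = as.integer(r),
                 folds = folds, seed = seed),
            class = "cv_assignment")
}

#' Default hyperparameter grid
#'
#' Geometric cost grid `2^(-6..4)`; for regression, epsilon at
#' `{0.05, 0.1, 0.2}` times the label SD.
#'
#' @param task `"svr"` or `"svc"`.
#' @param labels training labels (used to scale epsilon for `"svr"`).
#' @return data.frame with columns `cost` and `epsilon` (`NA` for `"svc"`).
#' @export
default_grid <- function(task = c("svr", "svc"), labels = NULL) {
  task <- match.arg(task)
  cost <- 2^seq(-6, 4)
  if (task == "svr") {
    s <- if (is.null(labels)) 1 else stats::sd(labels)
    expand.grid(cost = cost, epsilon = c(0.05, 0.1, 0.2) * s)
  } else {
    data.frame(cost = cost, epsilon = NA_real_)
  }
}

# Fit a linear SVM and extract primal weights; decision sign oriented so that
# larger values mean larger y (svr trivially) / the positive class (svc).
fit_linear_svm <- function(features, y, task, cost, epsilon = 0.1) {
  if (task == "svr") {
    m <- e1071::svm(x = features, y = y, type = "eps-regression",
                    kernel = "linear", cost = cost, epsilon = epsilon,
                    scale = FALSE)
    list(w = drop(crossprod(m$coefs, m$SV)), b = -m$rho)
  } else {
    yf <- factor(y, levels = c(0, 1))
    tab <- table(yf)
    cw <- sum(tab) / (2 * tab)  # inverse-frequency class weighting
    m <- e1071::svm(x = features, y = yf, type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = cw)
    w <- drop(crossprod(m$coefs, m$SV))
    b <- -m$rho
    f <- drop(features %*% w) + b
    if (mean(f[y == 1]) < mean(f[y == 0])) {
      w <- -w; b <- -b
    }
    list(w = w, b = b)
  }
}

predict_linear <- function(features, model) drop(features %*% model$w) + model$b

grid_stat <- function(pred, truth, task) {
  ok <- !is.na(pred)
  if (task == "svr") {
    mean(abs(pred[ok] - truth[ok]))
  } else {
    yhat <- as.integer(pred[ok] > 0)
    y <- truth[ok]
    if (!any(y == 1) || !any(y == 0)) return(NA_real_)
    (mean(yhat[y == 1] == 1) + mean(yhat[y == 0] == 0)) / 2
  }
}

pick_grid_row <- function(stats_vec, grid, task) {
  if (all(is.na(stats_vec))) return(1L)
  if (task == "svr") {
    best <- min(stats_vec, na.rm = TRUE)
    cand <- which(!is.na(stats_vec) & stats_vec <= best + 1e-12)
  } else {
    best <- max(stats_vec, na.rm = TRUE)
    cand <- which(!is.na(stats_vec) & stats_vec >= best - 1e-12)
  }
  # ties broken toward the smaller regularization constant, then epsilon
  cand[order(grid$cost[cand], grid$epsilon[cand])][1]
}

#' Train a model under repeated nested cross-validation
#'
#' For every (repetition, outer fold) the preprocessing chain and the linear
#' SVM are fitted on the outer-training partition only; when the grid has
#' more than one row, inner repeated CV (within the outer-training partition)
#' selects the hyperparameters minimizing inner out-of-fold MAE (regression)
#' or maximizing balanced accuracy (classification), refitting the winner on
#' the full outer-training partition.  Gaussian smoothing, a strictly
#' per-subject operation with no fitted parameters, is applied once up front;
#' the ensemble records the kernel so [apply_ensemble()] smooths new data
#' identically.
#'
#' @param x [gmv_matrix()] or numeric matrix (subjects x features).
#' @param labels numeric phenotype (`task = "svr"`) or 0/1 class labels
#'   (`task = "svc"`).
#' @param covariates optional data.frame with `age` and/or `site` columns, as
#'   required by the preprocessing config.
#' @param cv a [make_cv()] assignment for `nrow(x)` subjects.
#' @param task `"svr"` or `"svc"`.
#' @param grid hyperparameter data.frame (`cost`, `epsilon`); defaults to
#'   [default_grid()].
#' @param preproc a [preproc_config()].
#' @param inner_k,inner_r inner CV folds and repetitions (default 5 x 5).
#' @param seed integer seed for the inner fold assignments.
#' @param max_degenerate_frac abort when more than this fraction of members
#'   is degenerate (single-class or constant-label training partition).
#' @return List with `ensemble` (class `trained_ensemble`) and `predictions`
#'   (the out-of-fold prediction table: per-repetition predictions, their
#'   ensemble mean, and for classifiers the decision score).
#' @export
train_nested <- function(x, labels, covariates = NULL, cv,
                         task = c("svr", "svc"), grid = NULL,
                         preproc = preproc_config(), inner_k = 5L, inner_r = 5L,
                         seed = 1L, max_degenerate_frac = 0.2) {
  task <- match.arg(task)
  stopifnot(inherits(cv, "cv_assignment"))
  if (is.null(grid)) grid <- default_grid(task, labels)
  grid_shape <- if (inherits(x, "gmv_matrix")) x$grid else NULL
  mask <- if (inherits(x, "gmv_matrix")) x$mask else NULL
  ids <- if (inherits(x, "gmv_matrix")) x$ids else rownames(x) %||%
    sprintf("S%04d", seq_len(nrow(as_feature_matrix(x))))
  xm <- as_feature_matrix(x)
  n <- nrow(xm)
  if (cv$n != n) stop("cv assignment size does not match data")
  if (length(labels) != n) stop("labels length does not match data")
  if (task == "svc") labels <- as.integer(as.character(labels))

  fwhm <- preproc$fwhm
  if (fwhm > 0) {
    if (is.null(grid_shape)) stop("grid shape required for smoothing")
    xm <- as.matrix(xm %*% smoothing_operator(grid_shape, fwhm, mask))
  }
  member_cfg <- preproc
  member_cfg$fwhm <- 0

  age <- covariates$age
  site <- covariates$site
  members <- vector("list", cv$k * cv$r)
  preds <- matrix(NA_real_, n, cv$r)
  mi <- 0L
  for (rep in seq_len(cv$r)) {
    for (fold in seq_len(cv$k)) {
      mi <- mi + 1L
      test <- which(cv$folds[, rep] == fold)
      train <- setdiff(seq_len(n), test)
      y_tr <- labels[train]
      degenerate <- (task == "svc" && length(unique(y_tr)) < 2) ||
        (task == "svr" && stats::var(y_tr) == 0)
      if (degenerate) {
        members[[mi]] <- list(rep = rep, fold = fold, degenerate = TRUE)
        next
      }
      if (nrow(grid) > 1L) {
        icv <- make_cv(length(train), inner_k, inner_r,
                       seed = derive_seed(seed, rep * 53L + fold),
                       stratify = if (task == "svc") y_tr else NULL)
        gstats <- matrix(NA_real_, nrow(grid), inner_r)
        for (irep in seq_len(inner_r)) {
          ipred <- matrix(NA_real_, length(train), nrow(grid))
          for (ifold in seq_len(inner_k)) {
            iva <- which(icv$folds[, irep] == ifold)
            itr <- setdiff(seq_along(train), iva)
            if (task == "svc" && length(unique(y_tr[itr])) < 2) next
            chain_i <- fit_chain(xm[train[itr], , drop = FALSE],
                                 age = age[train[itr]], site = site[train[itr]],
                                 config = member_cfg)
            f_tr <- chain_i$train_features
            f_va <- apply_chain(chain_i, xm[train[iva], , drop = FALSE],
                                age = age[train[iva]], site = site[train[iva]])
            for (g in seq_len(nrow(grid))) {
              mdl <- fit_linear_svm(f_tr, y_tr[itr], task,
                                    cost = grid$cost[g], epsilon = grid$epsilon[g])
              ipred[iva, g] <- predict_linear(f_va, mdl)
            }
          }
          gstats[, irep] <- vapply(seq_len(nrow(grid)), function(g)
            grid_stat(ipred[, g], y_tr, task), numeric(1))
        }
        sel <- pick_grid_row(rowMeans(gstats, na.rm = TRUE), grid, task)
      } else sel <- 1L
      chain <- fit_chain(xm[train, , drop = FALSE],
                         age = age[train], site = site[train],
                         config = member_cfg)
      mdl <- fit_linear_svm(chain$train_features, y_tr, task,
                            cost = grid$cost[sel], epsilon = grid$epsilon[sel])
      f_te <- apply_chain(chain, xm[test, , drop = FALSE],
                          age = age[test], site = site[test])
      preds[test, rep] <- predict_linear(f_te, mdl)
      bp <- backproject_weights(chain, mdl$w, mdl$b)
      members[[mi]] <- list(rep = rep, fold = fold, chain = chain,
                            params = list(cost = grid$cost[sel],
                                          epsilon = grid$epsilon[sel]),
                            w = mdl$w, b = mdl$b,
                            w_voxel = bp$w_voxel,
                            intercept_voxel = bp$intercept,
                            degenerate = FALSE)
    }
  }
  n_deg <- sum(vapply(members, `[[`, logical(1), "degenerate"))
  if (n_deg / length(members) > max_degenerate_frac) {
    stop(sprintf("%d of %d ensemble members degenerate", n_deg, length(members)))
  }
  ensemble <- structure(list(members = members, task = task,
                             k = cv$k, r = cv$r, fwhm = fwhm,
                             grid_shape = grid_shape, mask = mask,
                             cv = cv, grid = grid, preproc = member_cfg,
                             seed = seed, n_features = ncol(xm)),
                        class = "trained_ensemble")
  pt <- prediction_table(ids, labels, preds, task)
  list(ensemble = ensemble, predictions = pt)
}

prediction_table <- function(ids, truth, preds, task) {
  colnames(preds) <- sprintf("rep_%d", seq_len(ncol(preds)))
  out <- data.frame(id = ids, truth = truth, preds,
                    ensemble = rowMeans(preds, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  if (task == "svc") out$decision_score <- out$ensemble
  attr(out, "task") <- task
  out
}

#' @export
print.trained_ensemble <- function(x, ...) {
  deg <- sum(vapply(x$members, `[[`, logical(1), "degenerate"))
  cat(sprintf("<trained_ensemble> %s, %d x %d members (%d degenerate), %d features\n",
              x$task, x$k, x$r, deg, x$n_features))
  invisible(x)
}

#' Per-member back-projected voxel weight matrix
#'
#' @param ensemble a `trained_ensemble`.
#' @return Numeric matrix, non-degenerate members x voxels.
#' @export
ensemble_voxel_weights <- function(ensemble) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  ok <- !vapply(ensemble$members, `[[`, logical(1), "degenerate")
  do.call(rbind, lapply(ensemble$members[ok], `[[`, "w_voxel"))
}

#' Regression performance of out-of-fold predictions
#'
#' @param pred a prediction table from [train_nested()] (ensemble-mean
#'   predictions are evaluated).
#' @return List with `MAE`, `R2` (1 - SS_res/SS_tot) and Pearson `r`.
#' @export
evaluate_regression <- function(pred) {
  y <- pred$truth; yhat <- pred$ensemble
  if (length(y) < 2) stop("need at least 2 subjects")
  if (stats::var(y) == 0) stop("zero label variance: R^2 undefined")
  list(MAE = mean(abs(yhat - y)),
       R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       r = if (stats::sd(yhat) > 0) stats::cor(yhat, y) else NA_real_)
}

#' Classification performance (balanced accuracy)
#'
#' Either evaluates a prediction table (ensemble decision scores thresholded
#' at 0) or combines already-known sensitivity/specificity percentages.
#'
#' @param pred prediction table with 0/1 `truth` and `decision_score`.
#' @param sensitivity,specificity alternatively, rates in percent.
#' @return List with `BAC`, `sensitivity`, `specificity`, all in percent.
#' @export
evaluate_classification <- function(pred = NULL, sensitivity = NULL,
                                    specificity = NULL) {
  if (is.null(pred)) {
    if (is.null(sensitivity) || is.null(specificity)) {
      stop("provide either `pred` or both `sensitivity` and `specificity`")
    }
    return(list(BAC = (sensitivity + specificity) / 2,
                sensitivity = sensitivity, specificity = specificity))
  }
  y <- pred$truth
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  yhat <- as.integer(pred$decision_score > 0)
  sens <- 100 * mean(yhat[y == 1] == 1)
  spec <- 100 * mean(yhat[y == 0] == 0)
  list(BAC = (sens + spec) / 2, sensitivity = sens, specificity = spec)
}

#' Permutation significance of a nested-CV model
#'
#' Labels are permuted across subjects (fold assignment fixed) and the full
#' nested pipeline is re-run per permutation; the p-value is
#' `(1 + #\{permuted statistic at least as good as observed\}) / (1 + n_perm)`
#' with "as good" meaning lower MAE (regression) or higher BAC
#' (classification).
#'
#' @inheritParams train_nested
#' @param n_perm number of label permutations (>= 19).
#' @return List with `p`, `observed` statistic, and the permutation
#'   distribution `perm`.
#' @export
permutation_significance <- function(x, labels, covariates = NULL, cv,
                                     task = c("svr", "svc"), grid = NULL,
                                     preproc = preproc_config(),
                                     inner_k = 5L, inner_r = 5L,
                                     n_perm = 1000L, seed = 1L) {
  task <- match.arg(task)
  if (n_perm < 19) stop("need n_perm >= 19")
  stat_of <- function(lab) {
    fit <- train_nested(x, lab, covariates, cv, task, grid, preproc,
                        inner_k, inner_r, seed = seed)
    if (task == "svr") evaluate_regression(fit$predictions)$MAE
    else evaluate_classification(fit$predictions)$BAC
  }
  observed <- stat_of(labels)
  perm <- vapply(seq_len(n_perm), function(i) {
    lab_p <- with_seed(derive_seed(seed, 5000L + i), sample(labels))
    stat_of(lab_p)
  }, numeric(1))
  as_good <- if (task == "svr") perm <= observed else perm >= observed
  list(p = (1 + sum(as_good)) / (1 + n_perm), observed = observed, perm = perm)
}

#' Apply a trained ensemble to new subjects
#'
#' Every non-degenerate member predicts every new subject (after the
#' ensemble's smoothing kernel is applied); per-repetition predictions are
#' the mean over that repetition's members and the ensemble prediction is
#' the mean over repetitions.
#'
#' @param ensemble a `trained_ensemble`.
#' @param x new data in the ensemble's voxel space.
#' @param covariates data.frame with `age`/`site` for the new subjects
#'   (unseen sites get offsets estimated from their own application-sample
#'   mean).
#' @param truth optional true labels to carry into the table.
#' @return A prediction table (see [train_nested()]).
#' @export
apply_ensemble <- function(ensemble, x, covariates = NULL, truth = NULL) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  ids <- if (inherits(x, "gmv_matrix")) x$ids else rownames(x) %||%
    sprintf("N%04d", seq_len(nrow(as_feature_matrix(x))))
  xm <- as_feature_matrix(x)
  if (ncol(xm) != ensemble$n_features) {
    stop(sprintf("ensemble expects %d voxels, data has %d",
                 ensemble$n_features, ncol(xm)))
  }
  if (ensemble$fwhm > 0) {
    xm <- as.matrix(xm %*% smoothing_operator(ensemble$grid_shape,
                                              ensemble$fwhm, ensemble$mask))
  }
  n <- nrow(xm)
  acc <- matrix(0, n, ensemble$r)
  cnt <- integer(ensemble$r)
  for (m in ensemble$members) {
    if (m$degenerate) next
    f <- apply_chain(m$chain, xm, age = covariates$age, site = covariates$site)
    acc[, m$rep] <- acc[, m$rep] + drop(f %*% m$w) + m$b
    cnt[m$rep] <- cnt[m$rep] + 1L
  }
  preds <- sweep(acc, 2, pmax(cnt, 1L), "/")
  preds[, cnt == 0] <- NA_real_
  prediction_table(ids, truth %||% rep(NA_real_, n), preds, ensemble$task)
}
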