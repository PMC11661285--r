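# Sparse partial least squares between a clinical feature matrix and an
# overlap-region voxel matrix: penalized rank-1 cross-covariance
# decompositions (soft-thresholded power iterations with an L1 constraint
# enforced by bisection), projection deflation, permutation-tested latent
# variables, sparsity selection by cross-validated latent correlation, and
# bootstrap weight stability.

#' Standardize and validate the two SPLS data blocks
#'
#' @param X subjects x clinical-features matrix.
#' @param Y subjects x voxels matrix.
#' @return List with column-standardized `X` and `Y` (mean 0, SD 1).
#' @export
spls_input <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (any(apply(X, 2, stats::sd) == 0) || any(apply(Y, 2, stats::sd) == 0)) {
    stop("zero-variance column; drop constant features before SPLS")
  }
  list(X = scale(X)[, , drop = FALSE], Y = scale(Y)[, , drop = FALSE])
}

# Unit-L2 vector proportional to soft-thresholded `a`, with the smallest
# threshold delta >= 0 such that the L1 norm is <= c (bisection; the L1
# constraint binds whenever delta > 0).
soft_l1_unit <- function(a, c) {
  if (all(a == 0)) return(a)
  u <- a / sqrt(sum(a^2))
  if (sum(abs(u)) <= c) return(u)
  lo <- 0; hi <- max(abs(a))
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    s <- sign(a) * pmax(abs(a) - mid, 0)
    ns <- sqrt(sum(s^2))
    l1 <- if (ns > 0) sum(abs(s)) / ns else 0
    if (ns > 0 && l1 > c) lo <- mid else hi <- mid
  }
  s <- sign(a) * pmax(abs(a) - hi, 0)
  ns <- sqrt(sum(s^2))
  if (ns == 0) {
    # keep the single largest entry when the constraint forces maximal sparsity
    s <- numeric(length(a))
    j <- which.max(abs(a))
    s[j] <- sign(a[j])
    return(s)
  }
  s / ns
}

#' Penalized rank-1 cross-covariance decomposition
#'
#' Alternating updates `u <- S(M v)`, `v <- S(M'u)` on `M = X'Y`, where `S`
#' soft-thresholds and renormalizes so that `||.||_2 = 1` and `||.||_1 <= c`.
#' With the constraints released (`c_u = sqrt(p)`, `c_v = sqrt(q)`) the fixed
#' point is the leading singular-vector pair of `M`.  The sign convention
#' makes the largest-magnitude clinical weight positive.
#'
#' @param X,Y standardized data blocks (see [spls_input()]).
#' @param c_u,c_v L1 bounds on the clinical and voxel weight vectors, in
#'   `[1, sqrt(ncol)]`; default: unconstrained.
#' @param tol convergence tolerance on successive weight changes.
#' @param max_iter iteration cap (warning + best iterate on hitting it).
#' @return List of class `spls_lv`: `u`, `v`, `d` (= `u'Mv`), latent scores
#'   `xi = Xu`, `omega = Yv`, latent correlation `rho`, `iters`,
#'   `converged`, `degenerate`.
#' @export
fit_rank1 <- function(X, Y, c_u = sqrt(ncol(X)), c_v = sqrt(ncol(Y)),
                      tol = 1e-7, max_iter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X); q <- ncol(Y)
  if (c_u < 1 || c_u > sqrt(p) + 1e-9) stop("c_u must be in [1, sqrt(p)]")
  if (c_v < 1 || c_v > sqrt(q) + 1e-9) stop("c_v must be in [1, sqrt(q)]")
  M <- crossprod(X, Y)
  if (all(M == 0)) {
    return(structure(list(u = numeric(p), v = numeric(q), d = 0,
                          xi = numeric(nrow(X)), omega = numeric(nrow(X)),
                          rho = NA_real_, iters = 0L, converged = TRUE,
                          degenerate = TRUE), class = "spls_lv"))
  }
  sv <- svd(M, nu = 1, nv = 1)
  u <- drop(sv$u); v <- drop(sv$v)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    u_new <- soft_l1_unit(drop(M %*% v), c_u)
    v_new <- soft_l1_unit(drop(crossprod(M, u_new)), c_v)
    if (max(abs(u_new - u)) < tol && max(abs(v_new - v)) < tol) {
      u <- u_new; v <- v_new
      converged <- TRUE
      break
    }
    u <- u_new; v <- v_new
  }
  if (!converged) warning("fit_rank1 hit max_iter; returning best iterate")
  j <- which.max(abs(u))
  if (u[j] < 0) { u <- -u; v <- -v }
  xi <- drop(X %*% u); omega <- drop(Y %*% v)
  rho <- if (stats::sd(xi) > 0 && stats::sd(omega) > 0) stats::cor(xi, omega) else NA_real_
  structure(list(u = u, v = v, d = drop(crossprod(u, M %*% v)),
                 xi = xi, omega = omega, rho = rho, iters = iters,
                 converged = converged, degenerate = FALSE),
            class = "spls_lv")
}

#' Permutation test of a fitted latent variable
#'
#' Rows of `X` are permuted (breaking the X-Y coupling), the rank-1 fit is
#' re-run at the same sparsity, and the latent correlation is compared with
#' the observed one: `p = (1 + #\{rho_perm >= rho_obs\}) / (1 + n_perm)`.
#'
#' @param X,Y the data blocks the LV was fitted on.
#' @param lv a fitted `spls_lv`.
#' @param c_u,c_v the sparsity the LV was fitted at.
#' @param n_perm number of permutations (>= 19).
#' @param seed integer seed.
#' @return List with `p` and the permutation distribution `rho_perm`.
#' @export
permutation_test_lv <- function(X, Y, lv, c_u, c_v, n_perm = 200L, seed = 1L) {
  if (n_perm < 19) stop("need n_perm >= 19")
  n <- nrow(X)
  rho_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- with_seed(derive_seed(seed, 900L + i), sample.int(n))
    fit <- fit_rank1(X[idx, , drop = FALSE], Y, c_u, c_v)
    if (is.na(fit$rho)) -Inf else fit$rho
  }, numeric(1))
  list(p = (1 + sum(rho_perm >= lv$rho)) / (1 + n_perm), rho_perm = rho_perm)
}

#' Projection deflation of both blocks
#'
#' Removes the fitted latent scores from their own blocks:
#' `X' = X - xi (xi'xi)^{-1} xi' X` and likewise for `Y`, leaving the
#' deflated columns orthogonal to the scores.
#'
#' @param X,Y current data blocks.
#' @param lv the fitted `spls_lv` to remove.
#' @return List with deflated `X`, `Y` and a `skipped` flag per side (a
#'   zero-norm score leaves its block untouched).
#' @export
deflate <- function(X, Y, lv) {
  skipped <- c(x = FALSE, y = FALSE)
  xi <- lv$xi; omega <- lv$omega
  if (sum(xi^2) > 0) {
    X <- X - xi %*% (crossprod(xi, X) / sum(xi^2))
  } else skipped["x"] <- TRUE
  if (sum(omega^2) > 0) {
    Y <- Y - omega %*% (crossprod(omega, Y) / sum(omega^2))
  } else skipped["y"] <- TRUE
  list(X = X, Y = Y, skipped = skipped)
}

#' Select sparsity by cross-validated latent correlation
#'
#' Each grid point is scored by the mean out-of-fold correlation between the
#' held-out latent scores; ties go to the sparser setting (smaller
#' `c_u + c_v`).
#'
#' @param X,Y standardized data blocks.
#' @param grid data.frame with columns `c_u`, `c_v`.
#' @param k_folds CV folds.
#' @param seed integer seed for the fold assignment.
#' @return The selected grid row as a list `(c_u, c_v)`.
#' @export
select_sparsity <- function(X, Y, grid, k_folds = 5L, seed = 1L) {
  if (!nrow(grid)) stop("empty sparsity grid")
  if (nrow(grid) == 1L) return(list(c_u = grid$c_u[1], c_v = grid$c_v[1]))
  n <- nrow(X)
  cv <- make_cv(n, k_folds, 1L, seed = seed)
  score <- vapply(seq_len(nrow(grid)), function(g) {
    rhos <- vapply(seq_len(k_folds), function(f) {
      te <- which(cv$folds[, 1] == f)
      tr <- setdiff(seq_len(n), te)
      fit <- fit_rank1(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                       grid$c_u[g], grid$c_v[g])
      xi <- drop(X[te, , drop = FALSE] %*% fit$u)
      om <- drop(Y[te, , drop = FALSE] %*% fit$v)
      if (stats::sd(xi) > 0 && stats::sd(om) > 0) stats::cor(xi, om) else NA_real_
    }, numeric(1))
    mean(rhos, na.rm = TRUE)
  }, numeric(1))
  best <- max(score, na.rm = TRUE)
  cand <- which(!is.na(score) & score >= best - 1e-12)
  sel <- cand[order(grid$c_u[cand] + grid$c_v[cand])][1]
  list(c_u = grid$c_u[sel], c_v = grid$c_v[sel])
}

#' Fit a full SPLS model with permutation-gated latent variables
#'
#' Iterates: (optionally) select sparsity, fit a penalized rank-1 LV, test
#' it by permutation; significant LVs are recorded and both blocks deflated;
#' the loop stops at the first non-significant LV or at `max_lv`.
#'
#' @param X,Y raw data blocks; standardized internally via [spls_input()]
#'   (descriptive analysis: the analysis sample's own mean/SD).
#' @param c_u,c_v fixed sparsity (used when `sparsity_grid` is `NULL`;
#'   default: unconstrained).
#' @param sparsity_grid optional data.frame (`c_u`, `c_v`) re-selected per LV.
#' @param n_perm permutations per LV.
#' @param alpha significance level for recording an LV.
#' @param max_lv maximum number of LVs (`0` gives an empty model).
#' @param k_folds folds for sparsity selection.
#' @param seed integer seed.
#' @return Object of class `spls_model`: list of recorded LVs (each with
#'   weights, `d`, `rho`, `p`, sparsity used) plus the settings.
#' @export
fit_spls <- function(X, Y, c_u = NULL, c_v = NULL, sparsity_grid = NULL,
                     n_perm = 200L, alpha = 0.05, max_lv = 5L,
                     k_folds = 5L, seed = 1L) {
  inp <- spls_input(X, Y)
  Xd <- inp$X; Yd <- inp$Y
  if (is.null(c_u)) c_u <- sqrt(ncol(Xd))
  if (is.null(c_v)) c_v <- sqrt(ncol(Yd))
  lvs <- list()
  if (max_lv >= 1L) {
    for (l in seq_len(max_lv)) {
      if (!is.null(sparsity_grid)) {
        sel <- select_sparsity(Xd, Yd, sparsity_grid, k_folds,
                               seed = derive_seed(seed, 70L + l))
        c_u_l <- sel$c_u; c_v_l <- sel$c_v
      } else {
        c_u_l <- c_u; c_v_l <- c_v
      }
      lv <- fit_rank1(Xd, Yd, c_u_l, c_v_l)
      if (lv$degenerate || is.na(lv$rho)) break
      pt <- permutation_test_lv(Xd, Yd, lv, c_u_l, c_v_l, n_perm,
                                seed = derive_seed(seed, 300L + l))
      if (pt$p >= alpha) break
      lv$p <- pt$p
      lv$c_u <- c_u_l; lv$c_v <- c_v_l
      lv$index <- length(lvs) + 1L
      lvs[[length(lvs) + 1L]] <- lv
      defl <- deflate(Xd, Yd, lv)
      Xd <- defl$X; Yd <- defl$Y
    }
  }
  structure(list(lvs = lvs, n_lv = length(lvs), alpha = alpha,
                 n_perm = n_perm, seed = seed),
            class = "spls_model")
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf("<spls_model> %d significant latent variable(s) at alpha = %g\n",
              x$n_lv, x$alpha))
  for (lv in x$lvs) {
    cat(sprintf("  LV%d: d = %.3f, rho = %.3f, p = %.4g, |u|_0 = %d, |v|_0 = %d\n",
                lv$index, lv$d, lv$rho, lv$p, sum(lv$u != 0), sum(lv$v != 0)))
  }
  invisible(x)
}

#' Bootstrap stability of SPLS weights
#'
#' Case-resampling bootstrap at fixed sparsity; each resample's weights are
#' sign-aligned to the original fit before aggregation.  Resamples producing
#' a constant column are skipped and counted.
#'
#' @param X,Y standardized data blocks.
#' @param c_u,c_v sparsity of the fit being assessed.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @return List with per-weight 95% percentile CIs (`u_ci`, `v_ci`, 2 x p
#'   matrices), nonzero-selection frequencies (`u_freq`, `v_freq`), the
#'   reference fit, and `n_used` / `n_skipped`.
#' @export
bootstrap_weights <- function(X, Y, c_u = sqrt(ncol(X)), c_v = sqrt(ncol(Y)),
                              n_boot = 200L, seed = 1L) {
  if (n_boot < 100) stop("need n_boot >= 100")
  ref <- fit_rank1(X, Y, c_u, c_v)
  n <- nrow(X)
  us <- matrix(NA_real_, n_boot, ncol(X))
  vs <- matrix(NA_real_, n_boot, ncol(Y))
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, 400L + b), sample.int(n, replace = TRUE))
    Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
    if (any(apply(Xb, 2, stats::sd) == 0) || any(apply(Yb, 2, stats::sd) == 0)) {
      skipped <- skipped + 1L
      next
    }
    fit <- fit_rank1(Xb, Yb, c_u, c_v)
    s <- sum(fit$u * ref$u)
    if (s == 0) s <- sum(fit$v * ref$v)
    s <- if (s < 0) -1 else 1
    us[b, ] <- s * fit$u
    vs[b, ] <- s * fit$v
  }
  used <- !is.na(us[, 1])
  ci <- function(m) apply(m[used, , drop = FALSE], 2, stats::quantile,
                          probs = c(0.025, 0.975))
  list(u_ci = ci(us), v_ci = ci(vs),
       u_freq = colMeans(us[used, , drop = FALSE] != 0),
       v_freq = colMeans(vs[used, , drop = FALSE] != 0),
       ref = ref, n_used = sum(used), n_skipped = skipped)
}
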