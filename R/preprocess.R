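# In-fold preprocessing chain.  Every parameter is fitted on training data
# only and applied frozen to held-out data; model weights in component space
# can be pulled back exactly to voxel space.

# --- Gaussian smoothing -----------------------------------------------------

gaussian_kernel_1d <- function(fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), 0, sigma)
  k / sum(k)
}

# Unnormalized 1-D convolution band matrix (rows may sum < 1 at edges).
band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  i <- rep(seq_len(n), each = length(kernel))
  j <- i + rep(seq(-r, r), times = n)
  v <- rep(kernel, times = n)
  ok <- j >= 1L & j <= n
  Matrix::sparseMatrix(i = i[ok], j = j[ok], x = v[ok], dims = c(n, n))
}

.smooth_cache <- new.env(parent = emptyenv())

# Right-multiplication smoothing operator: smoothed = X %*% op.
# Kernel mass is restricted to the mask and renormalized per output voxel.
smoothing_operator <- function(grid, fwhm, mask = NULL) {
  if (fwhm <= 0) stop("fwhm must be > 0 for an explicit operator")
  p <- prod(grid)
  if (is.null(mask)) mask <- rep(TRUE, p)
  key <- paste(paste(grid, collapse = "x"), fwhm, hash_obj(mask), sep = "|")
  if (!is.null(.smooth_cache[[key]])) return(.smooth_cache[[key]])
  k <- gaussian_kernel_1d(fwhm)
  # voxel order: first axis fastest => flattened operator K3 (x) K2 (x) K1
  s <- Matrix::kronecker(band_matrix(grid[3], k),
                         Matrix::kronecker(band_matrix(grid[2], k),
                                           band_matrix(grid[1], k)))
  if (!all(mask)) s[, !mask] <- 0
  rs <- Matrix::rowSums(s)
  rs[rs == 0] <- 1
  s <- Matrix::Diagonal(x = 1 / rs) %*% s
  op <- Matrix::t(s)
  .smooth_cache[[key]] <- op
  op
}

#' Gaussian-smooth a GMV matrix
#'
#' Per-subject separable 3-D Gaussian convolution with edge renormalization:
#' kernel mass falling outside the grid or the voxel mask is renormalized
#' away, so constant images stay constant.  `fwhm = 0` is the identity.
#'
#' @param gmv a [gmv_matrix()] (or plain matrix with known `grid`).
#' @param fwhm kernel full width at half maximum, in voxel units.
#' @param grid grid dimensions (taken from `gmv` when it is a `gmv_matrix`).
#' @return The smoothed object, same class as the input.
#' @export
smooth_gmv <- function(gmv, fwhm, grid = NULL) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (inherits(gmv, "gmv_matrix")) {
    if (fwhm == 0) return(gmv)
    op <- smoothing_operator(gmv$grid, fwhm, gmv$mask)
    gmv$data <- as.matrix(gmv$data %*% op)
    rownames(gmv$data) <- gmv$ids
    return(gmv)
  }
  if (fwhm == 0) return(gmv)
  if (is.null(grid)) stop("grid shape required to smooth a plain matrix")
  as.matrix(gmv %*% smoothing_operator(grid, fwhm))
}

# --- chain configuration ----------------------------------------------------

#' Preprocessing chain settings
#'
#' Steps run in the order smoothing, per-voxel age residualization, scalar
#' per-site global-mean offset correction, PCA, per-component min-max scaling
#' to `[0, 1]`.  `standardize = TRUE` replaces the PCA/scaling tail with
#' per-feature z-scoring (used for low-dimensional tabular models) and
#' `impute = TRUE` median-imputes missing feature values with training
#' medians.
#'
#' @param fwhm smoothing kernel FWHM in voxel units (default 2, i.e. 6 mm at
#'   3 mm voxels); 0 disables.
#' @param age_residualize remove per-voxel linear age effects (training fit).
#' @param site_correct subtract per-site scalar global-mean offsets.
#' @param pca run PCA and retain components up to `retained_variance`.
#' @param retained_variance cumulative variance fraction retained (default
#'   0.8; 1 keeps every non-null component).
#' @param scale01 min-max scale retained components to `[0, 1]` (training
#'   bounds, clipped on application).
#' @param standardize z-score features instead of PCA + scaling.
#' @param impute median-impute missing values (training medians).
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(fwhm = 2, age_residualize = TRUE, site_correct = TRUE,
                           pca = TRUE, retained_variance = 0.8, scale01 = TRUE,
                           standardize = FALSE, impute = FALSE) {
  if (retained_variance <= 0 || retained_variance > 1) {
    stop("`retained_variance` must be in (0, 1]")
  }
  structure(as.list(environment()), class = "preproc_config")
}

as_feature_matrix <- function(x) {
  if (inherits(x, "gmv_matrix")) x$data else as.matrix(x)
}

# --- fit --------------------------------------------------------------------

#' Fit the preprocessing chain on training data
#'
#' All statistics (age slopes, site offsets, PCA basis, scaling bounds) come
#' from the training data alone; [apply_chain()] replays them frozen.
#'
#' @param x training data: a [gmv_matrix()] or numeric matrix
#'   (subjects x features).
#' @param age training ages (required when `config$age_residualize`).
#' @param site training site labels (required when `config$site_correct`).
#' @param config a [preproc_config()].
#' @return An object of class `preproc_chain`.
#' @export
fit_chain <- function(x, age = NULL, site = NULL, config = preproc_config()) {
  grid <- if (inherits(x, "gmv_matrix")) x$grid else NULL
  mask <- if (inherits(x, "gmv_matrix")) x$mask else NULL
  xm <- as_feature_matrix(x)
  n <- nrow(xm); p <- ncol(xm)
  ch <- list(config = config, grid = grid, mask = mask, p = p, flags = character(0))

  if (config$impute) {
    med <- apply(xm, 2, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0
    ch$impute_median <- med
    nai <- which(is.na(xm))
    if (length(nai)) xm[nai] <- med[((nai - 1L) %/% n) + 1L]
  }
  if (config$fwhm > 0) {
    if (is.null(grid)) stop("grid shape required for smoothing")
    xm <- as.matrix(xm %*% smoothing_operator(grid, config$fwhm, mask))
    ch$fwhm <- config$fwhm
  } else ch$fwhm <- 0

  if (config$age_residualize) {
    if (is.null(age)) stop("`age` required for age residualization")
    age_c <- age - mean(age)
    ss <- sum(age_c^2)
    slopes <- if (ss > 0) drop(crossprod(age_c, xm)) / ss else rep(0, p)
    slopes[!is.finite(slopes)] <- 0
    ch$age_mean <- mean(age)
    ch$age_slopes <- slopes
    # residual re-centred on the training voxel mean: subtract slope*(age-mean)
    xm <- xm - outer(age_c, slopes)
  }

  if (config$site_correct) {
    if (is.null(site)) stop("`site` required for site correction")
    site <- as.character(site)
    g <- rowMeans(xm)
    grand <- mean(g)
    off <- c(tapply(g, site, mean)) - grand  # named vector, dims dropped
    singles <- names(which(table(site) == 1L))
    if (length(singles)) {
      ch$flags <- c(ch$flags, sprintf("site '%s' has a single training subject", singles))
    }
    ch$site_offsets <- off
    ch$grand_mean <- grand
    xm <- xm - off[site]
  }

  if (config$standardize) {
    mu <- colMeans(xm)
    sdv <- apply(xm, 2, stats::sd)
    degen <- !is.finite(sdv) | sdv == 0
    if (any(degen)) ch$flags <- c(ch$flags, sprintf("%d zero-variance feature(s)", sum(degen)))
    sdv[degen] <- 1
    ch$std_mean <- mu
    ch$std_sd <- sdv
    ch$train_features <- sweep(sweep(xm, 2, mu), 2, sdv, "/")
    class(ch) <- "preproc_chain"
    return(ch)
  }

  if (config$pca) {
    ctr <- colMeans(xm)
    xc <- sweep(xm, 2, ctr)
    sv <- svd(xc, nu = 0)
    tol <- max(dim(xc)) * max(sv$d) * .Machine$double.eps
    pos <- sv$d > tol
    varfrac <- cumsum(sv$d[pos]^2) / sum(sv$d[pos]^2)
    k <- which(varfrac >= config$retained_variance)[1]
    ch$pca_center <- ctr
    ch$rotation <- sv$v[, seq_len(k), drop = FALSE]
    ch$retained_variance <- varfrac[k]
    xm <- xc %*% ch$rotation
  }

  if (config$scale01) {
    mn <- apply(xm, 2, min)
    mx <- apply(xm, 2, max)
    degen <- (mx - mn) == 0
    if (any(degen)) ch$flags <- c(ch$flags, sprintf("%d degenerate scaling range(s)", sum(degen)))
    ch$scale_min <- mn
    ch$scale_max <- mx
    rng <- mx - mn
    rng[degen] <- 1
    xm <- sweep(sweep(xm, 2, mn), 2, rng, "/")
    xm[, degen] <- 0
  }
  ch$train_features <- xm
  class(ch) <- "preproc_chain"
  ch
}

# --- apply ------------------------------------------------------------------

#' Apply a fitted preprocessing chain to data
#'
#' Replays the frozen training parameters.  Scaled values falling outside
#' `[0, 1]` are clipped.  Sites unseen during training get their offset
#' estimated from the application sample's own global mean (flagged), so the
#' chain can be transferred to new cohorts.
#'
#' @param chain a fitted `preproc_chain`.
#' @param x data to transform (same feature space as training).
#' @param age,site covariates for the new subjects (as required by the
#'   fitted steps).
#' @return Numeric feature matrix.
#' @export
apply_chain <- function(chain, x, age = NULL, site = NULL) {
  stopifnot(inherits(chain, "preproc_chain"))
  xm <- as_feature_matrix(x)
  if (ncol(xm) != chain$p) {
    stop(sprintf("chain was fitted on %d features, data has %d", chain$p, ncol(xm)))
  }
  cfg <- chain$config
  n <- nrow(xm)
  if (cfg$impute) {
    nai <- which(is.na(xm))
    if (length(nai)) xm[nai] <- chain$impute_median[((nai - 1L) %/% n) + 1L]
  }
  if (chain$fwhm > 0) {
    xm <- as.matrix(xm %*% smoothing_operator(chain$grid, chain$fwhm, chain$mask))
  }
  if (cfg$age_residualize) {
    if (is.null(age)) stop("`age` required by this chain")
    xm <- xm - outer(age - chain$age_mean, chain$age_slopes)
  }
  if (cfg$site_correct) {
    if (is.null(site)) stop("`site` required by this chain")
    site <- as.character(site)
    g <- rowMeans(xm)
    off <- chain$site_offsets[site]
    unseen <- is.na(off)
    if (any(unseen)) {
      for (s in unique(site[unseen])) {
        off[site == s] <- mean(g[site == s]) - chain$grand_mean
      }
    }
    xm <- xm - as.vector(off)
  }
  if (cfg$standardize) {
    return(sweep(sweep(xm, 2, chain$std_mean), 2, chain$std_sd, "/"))
  }
  if (cfg$pca) {
    xm <- sweep(xm, 2, chain$pca_center) %*% chain$rotation
  }
  if (cfg$scale01) {
    rng <- chain$scale_max - chain$scale_min
    degen <- rng == 0
    rng[degen] <- 1
    xm <- sweep(sweep(xm, 2, chain$scale_min), 2, rng, "/")
    xm[xm < 0] <- 0
    xm[xm > 1] <- 1
    xm[, degen] <- 0
  }
  xm
}

# --- weight back-projection -------------------------------------------------

#' Pull component-space model weights back to voxel space
#'
#' For a linear model `f(z) = z w + b` on the chain's output features, the
#' exact pullback through min-max scaling and PCA is
#' `w_voxel = P (w / (max - min))`; smoothing, age residualization and site
#' correction mix no voxels into the weights (they contribute only to the
#' additive constant / covariate terms).  Components with a degenerate
#' (zero-width) scaling range contribute nothing and are flagged.
#'
#' @param chain a fitted `preproc_chain`.
#' @param weights component-space weight vector (length = number of chain
#'   output features).
#' @param intercept model intercept `b` (default 0).
#' @return List with `w_voxel` (per-voxel weights) and `intercept` such that
#'   `f(x) = x_pre %*% w_voxel + intercept` for any input `x_pre` in the
#'   chain's post-smoothing/age/site, pre-PCA space.
#' @export
backproject_weights <- function(chain, weights, intercept = 0) {
  stopifnot(inherits(chain, "preproc_chain"))
  cfg <- chain$config
  if (cfg$standardize) {
    w <- weights / chain$std_sd
    return(list(w_voxel = w,
                intercept = intercept - sum(chain$std_mean * w)))
  }
  w <- weights
  if (cfg$scale01) {
    rng <- chain$scale_max - chain$scale_min
    degen <- rng == 0
    rng[degen] <- 1
    w <- weights / rng
    w[degen] <- 0
    intercept <- intercept - sum(chain$scale_min * w)
  }
  if (cfg$pca) {
    wv <- drop(chain$rotation %*% w)
    intercept <- intercept - sum(chain$pca_center * wv)
  } else {
    wv <- w
  }
  list(w_voxel = wv, intercept = intercept)
}
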