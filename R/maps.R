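# Voxel-level model interpretation: cross-validation-ratio maps, sign-based
# consistency with exact binomial testing and Benjamini-Hochberg control,
# binarization, and overlap of binarized maps.

CVR_CAP <- 1e6

#' Cross-validation-ratio map
#'
#' Per voxel, the mean back-projected weight across ensemble members divided
#' by the standard error of that mean.  Voxels with zero SE get a signed
#' capped CVR (+-1e6) and are flagged.
#'
#' @param weights members x voxels matrix (e.g. [ensemble_voxel_weights()]).
#' @param grid optional grid dimensions carried along for export.
#' @return data.frame of class `voxel_stat_map` with columns `voxel`,
#'   `mean_w`, `se`, `cvr`, `cvr_capped`.
#' @export
cvr_map <- function(weights, grid = NULL) {
  if (nrow(weights) < 2) stop("need at least 2 ensemble members")
  m <- nrow(weights)
  mw <- colMeans(weights)
  se <- apply(weights, 2, stats::sd) / sqrt(m)
  capped <- se == 0
  cvr <- ifelse(capped, sign(mw) * CVR_CAP, mw / se)
  out <- data.frame(voxel = seq_along(mw), mean_w = mw, se = se,
                    cvr = cvr, cvr_capped = capped)
  attr(out, "grid") <- grid
  class(out) <- c("voxel_stat_map", class(out))
  out
}

# Exact two-sided binomial p against 0.5 (symmetric case).
binom_p_half <- function(k, n) {
  ifelse(n == 0, NA_real_,
         pmin(1, 2 * stats::pbinom(pmin(k, n - k), n, 0.5)))
}

#' Sign-based consistency map
#'
#' Per voxel: the fraction of ensemble members agreeing on the weight sign
#' (majority convention, exact zeros excluded from the count), an exact
#' two-sided binomial test of that split against chance, and
#' Benjamini-Hochberg q-values across tested voxels.  Voxels with all-zero
#' weights are excluded (`NA` statistics).
#'
#' @inheritParams cvr_map
#' @return data.frame of class `voxel_stat_map` with columns `voxel`,
#'   `mean_w`, `n_nonzero`, `consistency`, `p`, `q`.
#' @export
sign_consistency_map <- function(weights, grid = NULL) {
  if (nrow(weights) < 8) stop("need at least 8 members for a meaningful binomial test")
  n_pos <- colSums(weights > 0)
  n_neg <- colSums(weights < 0)
  m <- n_pos + n_neg
  consistency <- ifelse(m > 0, pmax(n_pos, n_neg) / m, NA_real_)
  p <- binom_p_half(pmax(n_pos, n_neg), m)
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(voxel = seq_along(p), mean_w = colMeans(weights),
                    n_nonzero = m, consistency = consistency, p = p, q = q)
  attr(out, "grid") <- grid
  class(out) <- c("voxel_stat_map", class(out))
  out
}

#' Binarize a consistency map at an FDR threshold
#'
#' @param map a [sign_consistency_map()] result (q-values present).
#' @param q_threshold FDR threshold (default 0.05).
#' @return Logical voxel mask (`TRUE` where `q <= q_threshold`).
#' @export
binarize_map <- function(map, q_threshold = 0.05) {
  stop_if_not_cols(map, "q", "voxel stat map")
  !is.na(map$q) & map$q <= q_threshold
}

#' Overlap of two binarized voxel masks
#'
#' Logical AND of the masks, with per-voxel sign concordance read from the
#' parents' mean weights.  Overlap is sign-agnostic: a voxel may predict the
#' two phenotypes in opposite directions and still overlap; concordance is
#' reported.
#'
#' @param mask_a,mask_b logical masks on the same grid.
#' @param map_a,map_b optional parent maps supplying mean-weight signs.
#' @return List of class `overlap_mask` with `mask`, `n_overlap`,
#'   `concordant` (logical per overlapping voxel, `NA` without parent maps)
#'   and `provenance`.
#' @export
overlap_masks <- function(mask_a, mask_b, map_a = NULL, map_b = NULL) {
  if (length(mask_a) != length(mask_b)) stop("masks are on different grids")
  ov <- mask_a & mask_b
  idx <- which(ov)
  conc <- if (!is.null(map_a) && !is.null(map_b)) {
    sign(map_a$mean_w[idx]) == sign(map_b$mean_w[idx])
  } else rep(NA, length(idx))
  structure(list(mask = ov, n_overlap = sum(ov), voxels = idx,
                 concordant = conc,
                 provenance = list(n_a = sum(mask_a), n_b = sum(mask_b))),
            class = "overlap_mask")
}
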