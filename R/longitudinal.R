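# BMI-gap and future weight change: weight-change tables, threshold and
# age-window correlation scans, weight-gain classification with and without
# the gap feature, and a paired sign-flip model comparison.

#' Compute weight changes and percentage changes at the follow-up horizons
#'
#' `dW1 = weight_t1 - weight_t0`, `dW2 = weight_t2 - weight_t0`, and the
#' corresponding percentage changes relative to baseline.  Missing follow-up
#' weights give `NA` changes (subject retained); rows with non-positive
#' baseline weight are invalidated and logged in attribute `"invalid"`.
#'
#' @param table subject table with `weight_t0` and optional `weight_t1`,
#'   `weight_t2` columns (all kg).
#' @return The table with `dw1`, `dw2`, `pct1`, `pct2` columns added.
#' @export
compute_weight_change <- function(table) {
  stop_if_not_cols(table, c("id", "weight_t0"), "weight table")
  w0 <- table$weight_t0
  bad <- !is.na(w0) & w0 <= 0
  w0[bad | is.na(w0)] <- NA_real_
  w1 <- if ("weight_t1" %in% names(table)) table$weight_t1 else NA_real_
  w2 <- if ("weight_t2" %in% names(table)) table$weight_t2 else NA_real_
  table$dw1 <- w1 - w0
  table$dw2 <- w2 - w0
  table$pct1 <- 100 * table$dw1 / w0
  table$pct2 <- 100 * table$dw2 / w0
  attr(table, "invalid") <- table$id[bad]
  table
}

#' Correlation scan between corrected gap and weight change over subgroups
#'
#' For each combination of horizon, minimum percentage weight-gain threshold,
#' age window, sex and group, reports the Pearson correlation between the
#' corrected gap and the weight change at that horizon.  Cells with fewer
#' than `min_n` subjects are reported with a missing correlation.
#'
#' @param gap a [gap_table()] (corrected gaps are used).
#' @param wc a [compute_weight_change()] table carrying `age`, `sex`,
#'   `group`.
#' @param horizons follow-up horizons to scan (`"T1"`, `"T2"`).
#' @param thresholds minimum percent weight gain for subgroup membership;
#'   `NA` means all subjects with an observed change.
#' @param age_windows list of `c(lo, hi)` windows (`NULL` = all ages).
#' @param sexes,groups filter levels; `NA` means all.
#' @param min_n minimum cell size for a reported correlation.
#' @return data.frame of class `scan_result`: one row per cell with `n`,
#'   `r`, `p`.
#' @export
subgroup_correlation_scan <- function(gap, wc,
                                      horizons = c("T1", "T2"),
                                      thresholds = c(NA, 3, 5, 7),
                                      age_windows = list(NULL, c(15, Inf), c(20, Inf),
                                                         c(25, Inf), c(30, Inf), c(35, Inf),
                                                         c(15, 20), c(20, 25), c(25, 30),
                                                         c(30, 35), c(35, 40)),
                                      sexes = c(NA, "F", "M"),
                                      groups = NA,
                                      min_n = 5L) {
  stop_if_not_cols(gap, c("id", "gap_corrected"), "gap table")
  stop_if_not_cols(wc, c("id", "age", "sex", "group"), "weight-change table")
  df <- merge(wc, gap[, c("id", "gap_corrected")], by = "id")
  rows <- list()
  for (h in horizons) {
    dw <- if (h == "T1") df$dw1 else df$dw2
    pct <- if (h == "T1") df$pct1 else df$pct2
    for (th in thresholds) for (wi in seq_along(age_windows)) {
      win <- age_windows[[wi]]
      for (sx in sexes) for (gr in groups) {
        keep <- !is.na(dw)
        if (!is.na(th)) keep <- keep & !is.na(pct) & pct >= th
        if (!is.null(win)) keep <- keep & df$age >= win[1] & df$age < win[2]
        if (!is.na(sx)) keep <- keep & df$sex == sx
        if (!is.na(gr)) keep <- keep & df$group == gr
        n <- sum(keep)
        if (n >= min_n && stats::sd(df$gap_corrected[keep]) > 0 &&
            stats::sd(dw[keep]) > 0) {
          ct <- stats::cor.test(df$gap_corrected[keep], dw[keep])
          r <- unname(ct$estimate); pval <- ct$p.value
        } else {
          r <- NA_real_; pval <- NA_real_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          horizon = h, threshold = th,
          age_lo = if (is.null(win)) NA_real_ else win[1],
          age_hi = if (is.null(win)) NA_real_ else win[2],
          sex = sx, group = gr, n = n, r = r, p = pval,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", class(out))
  out
}

#' Binary weight-gain labels at a percentage threshold
#'
#' @param wc a [compute_weight_change()] table.
#' @param threshold_pct minimum percent gain counted as weight gain
#'   (inclusive).
#' @param horizon `"T1"` or `"T2"`.
#' @return Named integer vector (1 = gained at least `threshold_pct`%);
#'   subjects with missing follow-up are excluded.
#' @export
weight_gain_labels <- function(wc, threshold_pct, horizon = c("T2", "T1")) {
  horizon <- match.arg(horizon)
  pct <- if (horizon == "T1") wc$pct1 else wc$pct2
  ok <- !is.na(pct)
  stats::setNames(as.integer(pct[ok] >= threshold_pct), wc$id[ok])
}

#' Assemble the tabular weight-gain feature matrix
#'
#' Features: corrected gap, age, sex (female = 1), clinical-group dummies,
#' exercise, history of somatic comorbidities, and optionally tobacco use.
#'
#' @param subjects subject table.
#' @param gap a [gap_table()] (matched by `id`).
#' @param include_gap include the corrected gap column (set `FALSE` for the
#'   ablated model).
#' @param include_tobacco include the tobacco-use flag.
#' @return Numeric matrix with subject ids as rownames.
#' @export
weight_gain_features <- function(subjects, gap, include_gap = TRUE,
                                 include_tobacco = TRUE) {
  df <- merge(subjects, gap[, c("id", "gap_corrected")], by = "id", sort = FALSE)
  out <- data.frame(row.names = df$id)
  if (include_gap) out$bmigap <- df$gap_corrected
  out$age <- df$age
  out$sex_female <- as.numeric(df$sex == "F")
  lev <- sort(unique(df$group))
  for (g in lev[-1]) {  # first level is the reference
    out[[paste0("group_", g)]] <- as.numeric(df$group == g)
  }
  out$exercise <- df$exercise
  out$somatic_history <- df$somatic_history
  if (include_tobacco) out$tobacco <- df$tobacco
  as.matrix(out)
}

#' Predict future weight gain from tabular features
#'
#' Linear SVC under the nested-CV engine; preprocessing is in-fold median
#' imputation plus standardization only (no smoothing/site/PCA steps for a
#' handful of tabular features).  Per-feature contributions are the mean
#' back-projected weights across ensemble members.
#'
#' @param features numeric matrix (subjects x features, ids as rownames).
#' @param labels named 0/1 labels (a subset of the feature rows is allowed).
#' @param cv optional [make_cv()] assignment (shared across ablation arms).
#' @param k,r,inner_k,inner_r CV geometry.
#' @param grid hyperparameter grid (cost only).
#' @param n_perm if positive, a label-permutation p-value for the BAC.
#' @param seed integer seed.
#' @return List of class `classifier_report`: `predictions`, `metrics`
#'   (BAC/sensitivity/specificity, percent), `feature_weights`, `perm_p`,
#'   `cv`, `ensemble`.
#' @export
predict_weight_gain <- function(features, labels, cv = NULL, k = 5L, r = 5L,
                                inner_k = 5L, inner_r = 1L, grid = NULL,
                                n_perm = 0L, seed = 1L) {
  ids <- intersect(rownames(features), names(labels))
  if (length(unique(labels[ids])) < 2) stop("labels must contain both classes")
  x <- features[ids, , drop = FALSE]
  y <- unname(labels[ids])
  if (is.null(cv)) cv <- make_cv(length(ids), k, r, seed = seed, stratify = y)
  pp <- preproc_config(fwhm = 0, age_residualize = FALSE, site_correct = FALSE,
                       pca = FALSE, scale01 = FALSE, standardize = TRUE,
                       impute = TRUE)
  if (is.null(grid)) grid <- data.frame(cost = 2^seq(-6, 2, 2), epsilon = NA_real_)
  fit <- train_nested(x, y, covariates = NULL, cv = cv, task = "svc",
                      grid = grid, preproc = pp, inner_k = inner_k,
                      inner_r = inner_r, seed = seed)
  w <- ensemble_voxel_weights(fit$ensemble)
  fw <- data.frame(feature = colnames(x), mean_weight = colMeans(w),
                   stringsAsFactors = FALSE)
  perm_p <- NA_real_
  if (n_perm > 0) {
    perm_p <- permutation_significance(x, y, covariates = NULL, cv = cv,
                                       task = "svc", grid = grid, preproc = pp,
                                       inner_k = inner_k, inner_r = inner_r,
                                       n_perm = n_perm, seed = seed)$p
  }
  structure(list(predictions = fit$predictions,
                 metrics = evaluate_classification(fit$predictions),
                 feature_weights = fw, perm_p = perm_p,
                 cv = cv, ensemble = fit$ensemble),
            class = "classifier_report")
}

#' Paired sign-flip comparison of two classifiers
#'
#' Both models must have been evaluated on identical subjects under the same
#' CV assignment.  The per-subject out-of-fold correctness difference is
#' sign-flip permuted; the p-value is two-sided on the absolute mean
#' difference.
#'
#' @param report_with,report_without two [predict_weight_gain()] reports
#'   sharing subjects and CV assignment.
#' @param n_perm number of sign-flip permutations.
#' @param seed integer seed.
#' @return List with `p`, `delta_bac` (BAC_with - BAC_without, percentage
#'   points) and `mean_diff` (mean per-subject correctness difference).
#' @export
ablation_compare <- function(report_with, report_without, n_perm = 2000L,
                             seed = 1L) {
  a <- report_with$predictions; b <- report_without$predictions
  if (!identical(a$id, b$id)) stop("reports cover different subjects")
  if (!identical(report_with$cv$folds, report_without$cv$folds)) {
    stop("CV assignments differ between the two reports")
  }
  ca <- as.integer((a$decision_score > 0) == (a$truth == 1))
  cb <- as.integer((b$decision_score > 0) == (b$truth == 1))
  d <- ca - cb
  obs <- mean(d)
  perm <- vapply(seq_len(n_perm), function(i) {
    s <- with_seed(derive_seed(seed, 600L + i),
                   sample(c(-1, 1), length(d), replace = TRUE))
    mean(s * d)
  }, numeric(1))
  list(p = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm),
       delta_bac = report_with$metrics$BAC - report_without$metrics$BAC,
       mean_diff = obs)
}
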