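# Config-driven end-to-end orchestration over the phantom pipeline:
# simulate -> cohort -> train -> gap -> maps -> spls -> longitudinal.
# Every stage writes its artifacts plus a manifest (inputs, config hash,
# seed, version); a single master seed is expanded into per-stage substreams
# so stages are independently reproducible.

#' Build a validated pipeline run configuration
#'
#' Unknown keys are rejected with a schema error listing them.
#'
#' @param out_dir run directory (created if missing).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param atlas list of [make_phantom_atlas()] arguments.
#' @param cohort a [cohort_config()].
#' @param longitudinal a [longitudinal_config()].
#' @param binning list: `lo`, `hi`, `width` for [bin_spec()].
#' @param discovery_n discovery sample size (default: half the healthy
#'   controls).
#' @param cv list: outer `k`, `r`; `inner_k`, `inner_r`.
#' @param grid hyperparameter data.frame for [train_nested()] (default: a
#'   reduced cost grid).
#' @param preproc a [preproc_config()].
#' @param q_threshold FDR threshold for map binarization.
#' @param spls list: `n_perm`, `alpha`, `max_lv`.
#' @param weightgain list: `threshold`, `horizon`, `n_perm` (ablation).
#' @param ... rejected; triggers the schema error.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       atlas = list(), cohort = cohort_config(),
                       longitudinal = longitudinal_config(),
                       binning = list(lo = 18.5, hi = 35, width = 0.5),
                       discovery_n = NULL,
                       cv = list(k = 5L, r = 2L, inner_k = 5L, inner_r = 1L),
                       grid = data.frame(cost = 2^c(-4, -1, 2), epsilon = 0.1),
                       preproc = preproc_config(),
                       q_threshold = 0.05,
                       spls = list(n_perm = 99L, alpha = 0.05, max_lv = 5L),
                       weightgain = list(threshold = 7, horizon = "T2",
                                         n_perm = 1000L),
                       ...) {
  extra <- list(...)
  if (length(extra)) {
    stop(sprintf("unknown config key(s): %s",
                 paste(names(extra), collapse = ", ")))
  }
  structure(as.list(environment())[setdiff(names(formals()), "...")],
            class = "run_config")
}

stage_manifest <- function(out_dir, stage, config, seed, files) {
  man <- list(stage = stage, seed = seed,
              config_hash = hash_obj(config),
              package_version = as.character(utils::packageVersion("braingap")),
              files = as.list(stats::setNames(
                vapply(files, function(f) unname(tools::md5sum(f)), character(1)),
                basename(files))),
              created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(man, file.path(out_dir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE)
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s'; run stage '%s' first",
                 basename(path), produced_by), call. = FALSE)
  }
  path
}

#' Run the phantom analysis pipeline
#'
#' Stages execute in dependency order; later stages read the artifacts of
#' earlier ones from the run directory, so subsets can be re-run.  A rerun
#' with the same configuration produces byte-identical artifacts.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("simulate", "cohort", "train", "gap", "maps", "spls", "longitudinal")`.
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "cohort", "train", "gap",
                                    "maps", "spls", "longitudinal")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "cohort", "train", "gap", "maps", "spls",
                  "longitudinal")
  stages <- all_stages[all_stages %in% match.arg(stages, all_stages,
                                                 several.ok = TRUE)]
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  path <- function(...) file.path(out, ...)

  if ("simulate" %in% stages) {
    atlas <- do.call(make_phantom_atlas,
                     c(config$atlas, list(seed = derive_seed(seed, 11L))))
    sim <- simulate_cohort(atlas, config$cohort, seed = derive_seed(seed, 12L))
    subjects <- simulate_longitudinal(sim$subjects, sim$truth,
                                      config$longitudinal,
                                      seed = derive_seed(seed, 13L))
    write_subject_table(subjects, path("subjects.csv"))
    write_gmv(sim$gmv, path("gmv"))
    jsonlite::write_json(list(grid_shape = atlas$grid_shape,
                              region_labels = atlas$region_labels,
                              bmi_signature = atlas$bmi_signature,
                              disease_signature = atlas$disease_signature,
                              overlap_voxels = atlas$overlap_voxels),
                         path("atlas.json"), auto_unbox = FALSE, digits = NA)
    jsonlite::write_json(list(propensity = sim$truth$propensity,
                              clin_latent = sim$truth$clin_latent,
                              site_offsets = sim$truth$site_offsets,
                              seed = sim$truth$seed),
                         path("truth.json"), auto_unbox = FALSE, digits = NA)
    stage_manifest(out, "simulate", config, seed,
                   path(c("subjects.csv", "gmv.tsv", "gmv.json",
                          "atlas.json", "truth.json")))
  }

  if (any(c("cohort", "train", "gap", "maps", "spls", "longitudinal") %in% stages)) {
    subjects <- read_subject_table(need_artifact(path("subjects.csv"), "simulate"))
  }

  if ("cohort" %in% stages) {
    hc <- apply_inclusion(subjects[subjects$group == "HC", ])
    spec <- bin_spec(config$binning$lo, config$binning$hi, config$binning$width)
    n_disc <- config$discovery_n %||% (nrow(hc) %/% 2L)
    split <- sample_uniform_with_matching(hc, spec, n_disc,
                                          seed = derive_seed(seed, 21L))
    data.table::fwrite(as.data.frame(split), path("split.csv"), na = "NA")
    stage_manifest(out, "cohort", config, seed, path("split.csv"))
  }

  if (any(c("train", "gap", "maps", "spls", "longitudinal") %in% stages)) {
    gmv <- read_gmv(sub("\\.tsv$", "", need_artifact(path("gmv.tsv"), "simulate")))
    split <- as.data.frame(data.table::fread(
      need_artifact(path("split.csv"), "cohort"), na.strings = "NA"))
    disc_ids <- split$id[split$partition == "discovery"]
    disc <- match(disc_ids, subjects$id)
  }

  if ("train" %in% stages) {
    cvA <- make_cv(length(disc), config$cv$k, config$cv$r,
                   seed = derive_seed(seed, 31L))
    fit <- train_nested(
      gmv_matrix(gmv$data[disc, , drop = FALSE], gmv$grid, gmv$mask,
                 ids = subjects$id[disc]),
      subjects$bmi[disc],
      covariates = subjects[disc, c("age", "site")],
      cv = cvA, task = "svr", grid = config$grid, preproc = config$preproc,
      inner_k = config$cv$inner_k, inner_r = config$cv$inner_r,
      seed = derive_seed(seed, 32L))
    others <- setdiff(seq_len(nrow(subjects)), disc)
    pred_ext <- apply_ensemble(
      fit$ensemble,
      gmv_matrix(gmv$data[others, , drop = FALSE], gmv$grid, gmv$mask,
                 ids = subjects$id[others]),
      covariates = subjects[others, c("age", "site")],
      truth = subjects$bmi[others])
    data.table::fwrite(fit$predictions, path("predictions_discovery.csv"), na = "NA")
    data.table::fwrite(pred_ext, path("predictions_external.csv"), na = "NA")
    saveRDS(fit$ensemble, path("ensemble_bmi.rds"))
    jsonlite::write_json(list(task = "svr", members = config$cv$k * config$cv$r,
                              file = "ensemble_bmi.rds"),
                         path("ensemble_bmi_manifest.json"), auto_unbox = TRUE)
    stage_manifest(out, "train", config, seed,
                   path(c("predictions_discovery.csv", "predictions_external.csv")))
  }

  if (any(c("gap", "maps", "spls", "longitudinal") %in% stages)) {
    pred_disc <- as.data.frame(data.table::fread(
      need_artifact(path("predictions_discovery.csv"), "train"), na.strings = "NA"))
    pred_ext <- as.data.frame(data.table::fread(
      need_artifact(path("predictions_external.csv"), "train"), na.strings = "NA"))
  }

  if ("gap" %in% stages) {
    corr <- fit_gap_correction(compute_gap(pred_disc$ensemble, pred_disc$truth),
                               pred_disc$truth, cohort_id = "HC_discovery")
    all_pred <- rbind(pred_disc[, c("id", "truth", "ensemble")],
                      pred_ext[, c("id", "truth", "ensemble")])
    grp <- subjects$group[match(all_pred$id, subjects$id)]
    grp[all_pred$id %in% disc_ids] <- "HC_discovery"
    grp[grp == "HC"] <- "HC_validation"
    gt <- gap_table(all_pred$id, grp, all_pred$truth, all_pred$ensemble, corr)
    data.table::fwrite(gt, path("gap.csv"), na = "NA")
    jsonlite::write_json(unclass(corr), path("gap_correction.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_manifest(out, "gap", config, seed,
                   path(c("gap.csv", "gap_correction.json")))
  }

  if (any(c("maps", "spls") %in% stages)) {
    ens_bmi <- readRDS(need_artifact(path("ensemble_bmi.rds"), "train"))
  }

  if ("maps" %in% stages) {
    # disease classifier: SCZ vs the discovery controls, same settings
    scz <- which(subjects$group == "SCZ")
    idx <- c(disc, scz)
    y <- as.integer(subjects$group[idx] == "SCZ")
    cvB <- make_cv(length(idx), config$cv$k, config$cv$r,
                   seed = derive_seed(seed, 41L), stratify = y)
    grid_c <- data.frame(cost = unique(config$grid$cost), epsilon = NA_real_)
    fit_scz <- train_nested(
      gmv_matrix(gmv$data[idx, , drop = FALSE], gmv$grid, gmv$mask,
                 ids = subjects$id[idx]),
      y, covariates = subjects[idx, c("age", "site")],
      cv = cvB, task = "svc", grid = grid_c, preproc = config$preproc,
      inner_k = config$cv$inner_k, inner_r = config$cv$inner_r,
      seed = derive_seed(seed, 42L))
    saveRDS(fit_scz$ensemble, path("ensemble_scz.rds"))
    data.table::fwrite(fit_scz$predictions, path("predictions_scz.csv"), na = "NA")
    w_bmi <- ensemble_voxel_weights(ens_bmi)
    w_scz <- ensemble_voxel_weights(fit_scz$ensemble)
    map_bmi <- sign_consistency_map(w_bmi, grid = gmv$grid)
    map_scz <- sign_consistency_map(w_scz, grid = gmv$grid)
    ov <- overlap_masks(binarize_map(map_bmi, config$q_threshold),
                        binarize_map(map_scz, config$q_threshold),
                        map_bmi, map_scz)
    write_voxel_map(cbind(map_bmi, cvr = cvr_map(w_bmi)$cvr), path("map_bmi.csv"))
    write_voxel_map(cbind(map_scz, cvr = cvr_map(w_scz)$cvr), path("map_scz.csv"))
    jsonlite::write_json(list(overlap_voxels = ov$voxels,
                              n_overlap = ov$n_overlap,
                              n_bmi = ov$provenance$n_a,
                              n_scz = ov$provenance$n_b),
                         path("overlap.json"), auto_unbox = TRUE)
    stage_manifest(out, "maps", config, seed,
                   path(c("map_bmi.csv", "map_scz.csv", "overlap.json")))
  }

  if ("spls" %in% stages) {
    gt <- as.data.frame(data.table::fread(need_artifact(path("gap.csv"), "gap"),
                                          na.strings = "NA"))
    ovj <- jsonlite::read_json(need_artifact(path("overlap.json"), "maps"),
                               simplifyVector = TRUE)
    pred_scz <- as.data.frame(data.table::fread(
      need_artifact(path("predictions_scz.csv"), "maps"), na.strings = "NA"))
    scz_ids <- subjects$id[subjects$group == "SCZ"]
    xdf <- data.frame(
      bmigap = gt$gap_corrected[match(scz_ids, gt$id)],
      scz_expression = pred_scz$decision_score[match(scz_ids, pred_scz$id)],
      panss_total = subjects$panss_total[match(scz_ids, subjects$id)],
      age_of_onset = subjects$age_of_onset[match(scz_ids, subjects$id)],
      illness_duration = subjects$illness_duration[match(scz_ids, subjects$id)],
      hospitalizations = subjects$hospitalizations[match(scz_ids, subjects$id)])
    ok <- stats::complete.cases(xdf)
    yv <- gmv$data[match(scz_ids, subjects$id)[ok], ovj$overlap_voxels, drop = FALSE]
    model <- fit_spls(as.matrix(xdf[ok, ]), yv,
                      n_perm = config$spls$n_perm, alpha = config$spls$alpha,
                      max_lv = config$spls$max_lv,
                      seed = derive_seed(seed, 51L))
    jsonlite::write_json(
      lapply(model$lvs, function(lv) list(index = lv$index, d = lv$d,
                                          rho = lv$rho, p = lv$p,
                                          u = lv$u, v = lv$v)),
      path("spls.json"), auto_unbox = TRUE, digits = NA)
    stage_manifest(out, "spls", config, seed, path("spls.json"))
  }

  if ("longitudinal" %in% stages) {
    gt <- as.data.frame(data.table::fread(need_artifact(path("gap.csv"), "gap"),
                                          na.strings = "NA"))
    wc <- compute_weight_change(subjects)
    pats <- wc[wc$group %in% c("CHR", "ROD"), ]
    scan <- subgroup_correlation_scan(gt, pats,
                                      groups = c(NA, unique(pats$group)))
    data.table::fwrite(scan, path("scan.csv"), na = "NA")
    labs <- weight_gain_labels(pats, config$weightgain$threshold,
                               config$weightgain$horizon)
    feats <- weight_gain_features(pats, gt)
    ids <- intersect(rownames(feats), names(labs))
    cvW <- make_cv(length(ids), config$cv$k, config$cv$r,
                   seed = derive_seed(seed, 61L), stratify = unname(labs[ids]))
    rep_with <- predict_weight_gain(feats, labs, cv = cvW,
                                    seed = derive_seed(seed, 62L))
    rep_without <- predict_weight_gain(
      weight_gain_features(pats, gt, include_gap = FALSE), labs, cv = cvW,
      seed = derive_seed(seed, 62L))
    cmp <- ablation_compare(rep_with, rep_without,
                            n_perm = config$weightgain$n_perm,
                            seed = derive_seed(seed, 63L))
    jsonlite::write_json(
      list(threshold = config$weightgain$threshold,
           horizon = config$weightgain$horizon,
           with_gap = rep_with$metrics, without_gap = rep_without$metrics,
           feature_weights = rep_with$feature_weights,
           ablation = cmp),
      path("weightgain.json"), auto_unbox = TRUE, digits = NA)
    stage_manifest(out, "longitudinal", config, seed,
                   path(c("scan.csv", "weightgain.json")))
  }

  invisible(out)
}
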