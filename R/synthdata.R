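# Phantom cohorts with known ground truth.
#
# The generator emulates the structure of a multi-site voxel-based-morphometry
# study: a 3-D voxel grid carved into regions, a sparse spatially contiguous
# (and predominantly negative) BMI voxel signature, a partially overlapping
# disease signature, multi-site offsets, age/sex confounds, a latent clinical
# severity factor expressed in the overlap region, and a per-subject latent
# "gap propensity" that shifts the brain pattern without shifting measured BMI.

#' Construct a grey-matter-volume matrix container
#'
#' Bundles a subjects-by-voxels value matrix with its 3-D grid geometry and an
#' in-analysis voxel mask.  Voxels are stored flattened with the first grid
#' axis fastest (the natural `as.vector()` order of an R array of dimension
#' `grid`).
#'
#' @param data numeric matrix, subjects in rows, voxels in columns.
#' @param grid integer vector of length 3, the voxel grid dimensions.
#' @param mask logical vector of length `prod(grid)`; `TRUE` voxels are in the
#'   analysis.  Defaults to all voxels.
#' @param ids subject identifiers (defaults to rownames of `data`).
#' @return An object of class `gmv_matrix`.
#' @export
gmv_matrix <- function(data, grid, mask = NULL, ids = rownames(data)) {
  data <- as.matrix(data)
  grid <- as.integer(grid)
  if (length(grid) != 3L) stop("`grid` must have length 3")
  if (ncol(data) != prod(grid)) {
    stop(sprintf("matrix has %d voxel columns but grid %s implies %d",
                 ncol(data), paste(grid, collapse = "x"), prod(grid)))
  }
  if (is.null(mask)) mask <- rep(TRUE, prod(grid))
  if (length(mask) != prod(grid)) stop("mask length does not match grid")
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(data)))
  rownames(data) <- ids
  structure(list(data = data, grid = grid, mask = as.logical(mask), ids = ids),
            class = "gmv_matrix")
}

#' @export
print.gmv_matrix <- function(x, ...) {
  cat(sprintf("<gmv_matrix> %d subjects x %d voxels (grid %s, %d in mask)\n",
              nrow(x$data), ncol(x$data), paste(x$grid, collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

# Signed clinical-latent pattern on the overlap voxels: the BMI-signature
# sign with every second voxel flipped, so the pattern is (near-)orthogonal
# to the BMI-predictive direction and cannot masquerade as a BMI shift.
clin_overlap_pattern <- function(atlas) {
  pat <- numeric(prod(atlas$grid_shape))
  ovv <- atlas$overlap_voxels
  if (length(ovv)) {
    pat[ovv] <- atlas$bmi_signature[ovv] *
      rep_len(c(1, -1), length(ovv))
  }
  pat
}

# Flattened-index 6-neighbourhood on a 3-D grid (first axis fastest).
voxel_neighbors <- function(idx, grid) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  i0 <- idx - 1L
  x <- i0 %% nx
  y <- (i0 %/% nx) %% ny
  z <- i0 %/% (nx * ny)
  out <- integer(0)
  if (x > 0L)      out <- c(out, idx - 1L)
  if (x < nx - 1L) out <- c(out, idx + 1L)
  if (y > 0L)      out <- c(out, idx - nx)
  if (y < ny - 1L) out <- c(out, idx + nx)
  if (z > 0L)      out <- c(out, idx - nx * ny)
  if (z < nz - 1L) out <- c(out, idx + nx * ny)
  out
}

# Grow a spatially contiguous blob of `size` voxels by seeded random
# accretion, restricted to `allowed` (logical over the grid).  Returns voxel
# indices in growth order.
grow_blob <- function(start, size, allowed, grid) {
  if (!allowed[start]) stop("blob start voxel not in allowed set")
  in_blob <- logical(length(allowed))
  in_blob[start] <- TRUE
  blob <- start
  frontier <- setdiff(voxel_neighbors(start, grid)[allowed[voxel_neighbors(start, grid)]],
                      start)
  while (length(blob) < size) {
    frontier <- frontier[!in_blob[frontier]]
    if (!length(frontier)) {
      stop(sprintf("signature size %d exceeds contiguous capacity (%d grown)",
                   size, length(blob)))
    }
    nxt <- frontier[sample.int(length(frontier), 1L)]
    in_blob[nxt] <- TRUE
    blob <- c(blob, nxt)
    nb <- voxel_neighbors(nxt, grid)
    frontier <- unique(c(frontier, nb[allowed[nb] & !in_blob[nb]]))
  }
  blob
}

#' Build a phantom brain atlas with seeded BMI and disease voxel signatures
#'
#' Carves the grid into `n_regions` contiguous regions (Voronoi cells of
#' seeded centres) and grows two spatially contiguous signature blobs: a BMI
#' signature (predominantly negative weights, reflecting that lower grey
#' matter volume tends to predict higher BMI) and a disease signature sharing
#' a configurable fraction of its voxels with the BMI signature.
#'
#' @param grid_shape integer length-3 grid dimensions (each `>= 4`).
#' @param n_regions number of atlas regions.
#' @param signature_sizes integer length-2: voxel counts of the BMI and the
#'   disease signature.
#' @param overlap_fraction fraction of disease-signature voxels shared with
#'   the BMI signature, in `[0, 1]`.
#' @param neg_fraction fraction of negative-sign voxels in each signature
#'   (length 1 or 2; default 0.8).
#' @param seed integer RNG seed; the atlas is deterministic given all
#'   arguments.
#' @return An object of class `phantom_atlas` with fields `grid_shape`,
#'   `region_labels`, `bmi_signature`, `disease_signature`,
#'   `overlap_fraction`, and `overlap_voxels`.
#' @export
make_phantom_atlas <- function(grid_shape = c(12L, 12L, 12L), n_regions = 8L,
                               signature_sizes = c(60L, 60L),
                               overlap_fraction = 0.5,
                               neg_fraction = 0.8, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    stop("`grid_shape` must be 3 dimensions, each >= 4")
  }
  p <- prod(grid_shape)
  signature_sizes <- as.integer(signature_sizes)
  if (length(signature_sizes) != 2L || any(signature_sizes < 1L)) {
    stop("`signature_sizes` must be two positive voxel counts")
  }
  if (any(signature_sizes > p)) stop("signature size exceeds voxel count")
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("`overlap_fraction` must be in [0, 1]")
  }
  neg_fraction <- rep_len(neg_fraction, 2L)

  with_seed(seed, {
    # Voronoi regions of seeded centres (ties to the lowest centre id).
    centers <- sample.int(p, n_regions)
    coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                    y = seq_len(grid_shape[2]),
                                    z = seq_len(grid_shape[3])))
    d2 <- vapply(centers, function(cc) {
      rowSums(sweep(coords, 2L, coords[cc, ], "-")^2)
    }, numeric(p))
    region_labels <- max.col(-d2, ties.method = "first")

    s_bmi <- signature_sizes[1]; s_dis <- signature_sizes[2]
    cap <- tabulate(region_labels, n_regions)
    if (s_bmi > max(cap)) {
      stop(sprintf("BMI signature size %d exceeds largest region capacity %d",
                   s_bmi, max(cap)))
    }
    bmi_region <- which.max(cap)
    allowed_bmi <- region_labels == bmi_region
    start_bmi <- which(allowed_bmi)[sample.int(sum(allowed_bmi), 1L)]
    bmi_vox <- grow_blob(start_bmi, s_bmi, allowed_bmi, grid_shape)

    n_ov <- as.integer(round(overlap_fraction * s_dis))
    in_bmi <- logical(p); in_bmi[bmi_vox] <- TRUE
    if (n_ov > 0L) {
      if (n_ov > s_bmi) stop("requested overlap exceeds BMI signature size")
      start_ov <- bmi_vox[sample.int(length(bmi_vox), 1L)]
      ov_vox <- grow_blob(start_ov, n_ov, in_bmi, grid_shape)
      rest <- s_dis - n_ov
      if (rest > 0L) {
        allowed_out <- !in_bmi
        seeds <- unique(unlist(lapply(ov_vox, voxel_neighbors, grid = grid_shape)))
        seeds <- seeds[allowed_out[seeds]]
        if (!length(seeds)) stop("overlap blob has no exterior neighbours to extend into")
        start_out <- seeds[sample.int(length(seeds), 1L)]
        out_vox <- grow_blob(start_out, rest, allowed_out, grid_shape)
      } else out_vox <- integer(0)
      dis_vox <- c(ov_vox, out_vox)
    } else {
      other <- which(cap >= s_dis & seq_len(n_regions) != bmi_region)
      allowed_dis <- if (length(other)) region_labels == other[1] else !in_bmi
      allowed_dis <- allowed_dis & !in_bmi
      if (!any(allowed_dis)) stop("no capacity for a disjoint disease signature")
      start_dis <- which(allowed_dis)[sample.int(sum(allowed_dis), 1L)]
      dis_vox <- grow_blob(start_dis, s_dis, allowed_dis, grid_shape)
    }

    signed <- function(vox, frac_neg) {
      w <- numeric(p)
      n_neg <- round(frac_neg * length(vox))
      # growth order keeps same-sign voxels spatially contiguous
      w[vox[seq_len(n_neg)]] <- -1
      if (n_neg < length(vox)) w[vox[(n_neg + 1L):length(vox)]] <- 1
      w
    }
    structure(list(grid_shape = grid_shape,
                   region_labels = region_labels,
                   bmi_signature = signed(bmi_vox, neg_fraction[1]),
                   disease_signature = signed(dis_vox, neg_fraction[2]),
                   overlap_fraction = overlap_fraction,
                   overlap_voxels = intersect(bmi_vox, dis_vox),
                   seed = seed),
              class = "phantom_atlas")
  })
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat(sprintf(paste0("<phantom_atlas> grid %s, %d regions, BMI signature %d",
                     " voxels, disease signature %d voxels, overlap %d voxels\n"),
              paste(x$grid_shape, collapse = "x"),
              max(x$region_labels), sum(x$bmi_signature != 0),
              sum(x$disease_signature != 0), length(x$overlap_voxels)))
  invisible(x)
}

#' Cohort simulation settings
#'
#' Defaults define the phantom study conditions: four clinical groups across
#' four sites, ages 15-75, BMI truncated-normal on 18.5-35 kg/m^2 with a mild
#' age correlation, and effect sizes chosen so that seeded signatures are
#' recoverable by the downstream pipeline at a few hundred subjects.
#'
#' @param groups named integer vector of per-group subject counts; names from
#'   `HC`, `SCZ`, `CHR`, `ROD`.
#' @param n_sites number of acquisition sites.
#' @param baseline grand-mean voxel value (arbitrary GMV units).
#' @param beta_bmi voxel change per kg/m^2 of (BMI - centre + propensity)
#'   along the BMI signature.
#' @param beta_dis voxel change along the disease signature per unit of the
#'   group's disease loading.
#' @param disease_load named per-group loading on the disease signature.
#' @param lambda_clin voxel change along the signed overlap pattern per unit
#'   of the clinical latent factor (patients only); the pattern is
#'   sign-balanced against the BMI signature.
#' @param noise_sd iid Gaussian voxel noise SD.
#' @param site_sd SD of the per-site scalar offsets.
#' @param age_range,bmi_mean,bmi_sd,bmi_range,age_bmi_cor demographic model.
#' @param age_slope_mean,age_slope_sd per-voxel age slope distribution
#'   (GMV units per year).
#' @param sex_effect_sd SD of the per-voxel additive female-sex effect.
#' @param propensity_sd SD of the latent gap propensity (kg/m^2), drawn
#'   independently of measured BMI.
#' @param group_gap_shift named per-group mean shift of the gap propensity
#'   (kg/m^2).
#' @param clin_loadings,clin_means,clin_noise_sd loadings, means and residual
#'   SDs of the four clinical variables on the shared latent factor.
#' @param smooth_fwhm optional Gaussian smoothing (voxel-units FWHM) applied
#'   to the generated volumes; 0 disables.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(groups = c(HC = 300L, SCZ = 100L, CHR = 100L, ROD = 100L),
                          n_sites = 4L,
                          baseline = 0.5,
                          beta_bmi = 0.02,
                          beta_dis = 0.05,
                          disease_load = c(HC = 0, SCZ = 1, CHR = 0.5, ROD = 0.3),
                          lambda_clin = 0.05,
                          noise_sd = 0.15,
                          site_sd = 0.05,
                          age_range = c(15, 75),
                          bmi_mean = 24.5, bmi_sd = 3.5,
                          bmi_range = c(18.5, 35),
                          age_bmi_cor = 0.25,
                          age_slope_mean = -0.002, age_slope_sd = 0.001,
                          sex_effect_sd = 0.01,
                          propensity_sd = 1.5,
                          group_gap_shift = c(HC = 0, SCZ = 1.0, CHR = 0.5, ROD = -0.8),
                          clin_loadings = c(panss = 12, onset = 3, duration = 2, hosp = 1.2),
                          clin_means = c(panss = 50, onset = 25, duration = 4, hosp = 1.5),
                          clin_noise_sd = c(panss = 8, onset = 2, duration = 1, hosp = 0.8),
                          smooth_fwhm = 0) {
  groups <- groups[groups > 0]
  if (!length(groups) || is.null(names(groups)) ||
      !all(names(groups) %in% c("HC", "SCZ", "CHR", "ROD"))) {
    stop("`groups` must be a named vector over HC/SCZ/CHR/ROD with positive counts")
  }
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (!all(is.finite(c(beta_bmi, beta_dis, lambda_clin)))) {
    stop("effect sizes must be finite")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a phantom cohort
#'
#' Generates a subject table, a voxel-wise GMV matrix and a ground-truth
#' record from a phantom atlas.  Each voxel value is
#' `baseline + age_slope*(age - age_centre) + sex_effect + site_offset
#'  + beta_bmi*(BMI - bmi_centre + propensity)*bmi_signature
#'  + beta_dis*disease_load[group]*disease_signature
#'  + lambda_clin*latent*overlap_pattern + noise`,
#' where the overlap pattern is a signed (+-1) template on the overlap voxels
#' constructed to be orthogonal to the BMI signature (so clinical severity
#' cannot masquerade as a BMI shift),
#' optionally Gaussian-smoothed.  The latent gap propensity is drawn
#' independently of measured BMI (plus a per-group mean shift), so its
#' population correlation with BMI is zero by construction.
#'
#' @param atlas a `phantom_atlas`.
#' @param config a [cohort_config()].
#' @param seed integer RNG seed.
#' @return A list with elements `subjects` (data.frame), `gmv`
#'   ([gmv_matrix()]) and `truth` (class `truth_record`; coefficients
#'   sufficient to rebuild every systematic component, see
#'   [reconstruct_systematic()]).
#' @export
simulate_cohort <- function(atlas, config = cohort_config(), seed = 1L) {
  stopifnot(inherits(atlas, "phantom_atlas"), inherits(config, "cohort_config"))
  cfg <- config
  groups <- cfg$groups
  n <- sum(groups)
  p <- prod(atlas$grid_shape)
  group <- rep(names(groups), groups)
  age_center <- mean(cfg$age_range)
  bmi_center <- cfg$bmi_mean

  with_seed(seed, {
    site <- sample.int(cfg$n_sites, n, replace = TRUE)
    sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    z_age <- as.numeric(scale(age))
    rho <- cfg$age_bmi_cor
    z <- rho * z_age + sqrt(1 - rho^2) * stats::rnorm(n)
    bmi <- cfg$bmi_mean + cfg$bmi_sd * z
    for (it in 1:200) {
      bad <- which(bmi < cfg$bmi_range[1] | bmi > cfg$bmi_range[2])
      if (!length(bad)) break
      zb <- rho * z_age[bad] + sqrt(1 - rho^2) * stats::rnorm(length(bad))
      bmi[bad] <- cfg$bmi_mean + cfg$bmi_sd * zb
    }
    bmi <- pmin(pmax(bmi, cfg$bmi_range[1]), cfg$bmi_range[2])
    height <- ifelse(sex == "M", stats::rnorm(n, 178, 7), stats::rnorm(n, 165, 6.5))
    weight_t0 <- bmi * (height / 100)^2

    shift <- cfg$group_gap_shift[group]
    shift[is.na(shift)] <- 0
    propensity <- stats::rnorm(n, 0, cfg$propensity_sd) + unname(shift)

    patient <- group != "HC"
    latent <- ifelse(patient, stats::rnorm(n), 0)
    cl <- cfg$clin_loadings; cm <- cfg$clin_means; cs <- cfg$clin_noise_sd
    panss <- ifelse(patient, cm["panss"] + cl["panss"] * latent +
                      stats::rnorm(n, 0, cs["panss"]), NA_real_)
    onset <- ifelse(patient, cm["onset"] + cl["onset"] * latent +
                      stats::rnorm(n, 0, cs["onset"]), NA_real_)
    duration <- ifelse(patient, pmax(0.1, cm["duration"] + cl["duration"] * latent +
                                       stats::rnorm(n, 0, cs["duration"])), NA_real_)
    hosp <- ifelse(patient, pmax(0, round(cm["hosp"] + cl["hosp"] * latent +
                                            stats::rnorm(n, 0, cs["hosp"]))), NA_real_)
    exercise <- stats::rbinom(n, 1, 0.5)
    somatic <- stats::rbinom(n, 1, 0.3)
    tobacco <- stats::rbinom(n, 1, 0.4)

    age_slopes <- stats::rnorm(p, cfg$age_slope_mean, cfg$age_slope_sd)
    sex_effects <- stats::rnorm(p, 0, cfg$sex_effect_sd)
    site_offsets <- stats::rnorm(cfg$n_sites, 0, cfg$site_sd)
    noise <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)

    subjects <- data.frame(
      id = sprintf("S%04d", seq_len(n)),
      group = group,
      site = sprintf("site%02d", site),
      sex = sex, age = age, bmi = bmi,
      height = height, weight_t0 = weight_t0,
      panss_total = panss, age_of_onset = onset,
      illness_duration = duration, hospitalizations = hosp,
      exercise = exercise, somatic_history = somatic, tobacco = tobacco,
      stringsAsFactors = FALSE
    )
    truth <- structure(list(
      propensity = propensity, clin_latent = latent,
      site_offsets = site_offsets, age_slopes = age_slopes,
      sex_effects = sex_effects, age_center = age_center,
      bmi_center = bmi_center, config = cfg, seed = seed,
      gamma = NULL
    ), class = "truth_record")

    x <- reconstruct_systematic(truth, subjects, atlas) + noise
    if (cfg$smooth_fwhm > 0) {
      x <- as.matrix(x %*% smoothing_operator(atlas$grid_shape, cfg$smooth_fwhm))
    }
    gmv <- gmv_matrix(x, atlas$grid_shape, ids = subjects$id)
    list(subjects = subjects, gmv = gmv, truth = truth)
  })
}

#' Rebuild the systematic (noise-free) part of a simulated GMV matrix
#'
#' Uses only the truth record, the subject table and the atlas; with the
#' generator's noise SD taken to zero (same seed) the simulated matrix equals
#' this reconstruction exactly (before optional smoothing).
#'
#' @param truth a `truth_record` from [simulate_cohort()].
#' @param subjects the matching subject table.
#' @param atlas the `phantom_atlas` used for simulation.
#' @return numeric matrix, subjects x voxels.
#' @export
reconstruct_systematic <- function(truth, subjects, atlas) {
  cfg <- truth$config
  n <- nrow(subjects)
  site_idx <- as.integer(sub("site", "", subjects$site))
  dl <- cfg$disease_load[subjects$group]
  dl[is.na(dl)] <- 0
  overlap_pat <- clin_overlap_pattern(atlas)
  x <- matrix(cfg$baseline, n, prod(atlas$grid_shape))
  x <- x + outer(subjects$age - truth$age_center, truth$age_slopes)
  x <- x + outer(as.numeric(subjects$sex == "F"), truth$sex_effects)
  x <- x + truth$site_offsets[site_idx]
  x <- x + outer(cfg$beta_bmi * (subjects$bmi - truth$bmi_center + truth$propensity),
                 atlas$bmi_signature)
  x <- x + outer(cfg$beta_dis * unname(dl), atlas$disease_signature)
  x <- x + outer(cfg$lambda_clin * truth$clin_latent, overlap_pat)
  x
}

#' Longitudinal weight-change simulation settings
#'
#' Weight change at each follow-up is
#' `drift + gamma * propensity + age_modifier*(age-30) + group_modifier + noise`;
#' the 2-year coupling `gamma2` is at least the 1-year coupling `gamma1` by
#' default, matching the stronger long-horizon coupling the pipeline is built
#' to detect.  Modifiers default to zero so the latent gap propensity is the
#' only systematic driver of weight change.
#'
#' @param gamma1,gamma2 propensity-to-weight-change couplings (kg per kg/m^2).
#' @param drift length-2 mean weight change (kg) at the two horizons.
#' @param noise_sd residual SD of weight change (kg).
#' @param missing length-2 missing-at-random follow-up dropout rates.
#' @param age_modifier kg per year of (age - 30).
#' @param group_modifier optional named per-group additive shift (kg).
#' @return A list of class `longitudinal_config`.
#' @export
longitudinal_config <- function(gamma1 = 0.8, gamma2 = 1.5,
                                drift = c(1.0, 2.0), noise_sd = 3,
                                missing = c(0.2, 0.35),
                                age_modifier = 0, group_modifier = NULL) {
  if (any(missing < 0 | missing > 1)) stop("`missing` rates must be in [0, 1]")
  if (abs(gamma2) < abs(gamma1)) {
    warning("|gamma2| < |gamma1|: 2-year coupling weaker than 1-year")
  }
  structure(as.list(environment()), class = "longitudinal_config")
}

#' Simulate follow-up weights coupled to the latent gap propensity
#'
#' @param subjects subject table with `weight_t0`, `age`, `group`.
#' @param truth matching `truth_record` (supplies the gap propensity).
#' @param config a [longitudinal_config()].
#' @param seed integer RNG seed.
#' @return The subject table with `weight_t1` and `weight_t2` columns added
#'   (`NA` for simulated dropouts); the coupling settings are attached as
#'   attribute `"coupling"`.
#' @export
simulate_longitudinal <- function(subjects, truth, config = longitudinal_config(),
                                  seed = 1L) {
  stop_if_not_cols(subjects, c("weight_t0", "age", "group"), "subjects")
  if (anyNA(subjects$weight_t0)) stop("weight_t0 must be present for all subjects")
  cfg <- config
  n <- nrow(subjects)
  gm <- function() {
    if (is.null(cfg$group_modifier)) return(0)
    v <- cfg$group_modifier[subjects$group]; v[is.na(v)] <- 0; unname(v)
  }
  with_seed(seed, {
    dw1 <- cfg$drift[1] + cfg$gamma1 * truth$propensity +
      cfg$age_modifier * (subjects$age - 30) + gm() + stats::rnorm(n, 0, cfg$noise_sd)
    dw2 <- cfg$drift[2] + cfg$gamma2 * truth$propensity +
      cfg$age_modifier * (subjects$age - 30) + gm() + stats::rnorm(n, 0, cfg$noise_sd)
    w1 <- subjects$weight_t0 + dw1
    w2 <- subjects$weight_t0 + dw2
    w1[stats::runif(n) < cfg$missing[1]] <- NA_real_
    w2[stats::runif(n) < cfg$missing[2]] <- NA_real_
    subjects$weight_t1 <- w1
    subjects$weight_t2 <- w2
    attr(subjects, "coupling") <- cfg
    subjects
  })
}
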