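# Cohort construction: inclusion filtering, uniform BMI-bin sampling with
# within-bin age matching, discovery/validation split.

#' Apply age and BMI inclusion criteria
#'
#' Rows outside the closed age or BMI ranges are removed; rows with missing
#' age or BMI are removed with reason `"missing"`.  Exclusions are attached
#' as attribute `"exclusions"` (a data.frame with `id` and `reason`).
#'
#' @param table subject table with `age` and `bmi` columns.
#' @param age_range,bmi_range closed inclusion intervals.
#' @return The filtered table.
#' @export
apply_inclusion <- function(table, age_range = c(15, 75), bmi_range = c(18.5, 35)) {
  stop_if_not_cols(table, c("id", "age", "bmi"), "subject table")
  if (!nrow(table)) {
    attr(table, "exclusions") <- data.frame(id = character(0), reason = character(0))
    return(table)
  }
  reason <- rep(NA_character_, nrow(table))
  miss <- is.na(table$age) | is.na(table$bmi)
  reason[miss] <- "missing"
  out_age <- !miss & (table$age < age_range[1] | table$age > age_range[2])
  reason[out_age] <- "age"
  out_bmi <- !miss & !out_age & (table$bmi < bmi_range[1] | table$bmi > bmi_range[2])
  reason[out_bmi] <- "bmi"
  keep <- is.na(reason)
  res <- table[keep, , drop = FALSE]
  attr(res, "exclusions") <- data.frame(id = table$id[!keep],
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
  res
}

#' BMI bin specification
#'
#' Half-open bins `[lo + k*width, lo + (k+1)*width)`, with the final bin
#' closed at `hi`.  The default (18.5-35 kg/m^2 at 0.5 kg/m^2) yields 33 bins.
#'
#' @param lo,hi BMI range (kg/m^2).
#' @param width bin width (kg/m^2).
#' @return A list of class `bin_spec` with `lo`, `hi`, `width`, `n_bins`.
#' @export
bin_spec <- function(lo = 18.5, hi = 35, width = 0.5) {
  if (hi <= lo || width <= 0) stop("need hi > lo and width > 0")
  n_bins <- as.integer(round((hi - lo) / width))
  structure(list(lo = lo, hi = hi, width = width, n_bins = n_bins),
            class = "bin_spec")
}

#' Assign BMI values to bins
#'
#' @param bmi numeric BMI values, all within `[spec$lo, spec$hi]` (apply
#'   inclusion filtering first).
#' @param spec a [bin_spec()].
#' @return Integer bin indices in `0 .. n_bins - 1` (the spec's half-open
#'   convention; the final bin is closed at `hi`).
#' @export
bin_bmi <- function(bmi, spec) {
  stopifnot(inherits(spec, "bin_spec"))
  if (any(is.na(bmi)) || any(bmi < spec$lo | bmi > spec$hi)) {
    stop("BMI value outside binning range; run apply_inclusion() first")
  }
  idx <- as.integer(floor((bmi - spec$lo) / spec$width))
  pmin(idx, spec$n_bins - 1L)
}

#' Sample a discovery cohort with an approximately uniform BMI distribution
#'
#' Subjects are allocated to BMI bins; per-bin quotas (as equal as the supply
#' allows, shortfalls redistributed to neighbouring bins) are then filled by
#' greedy quantile matching of the matching covariate (age by default)
#' against its pooled distribution, which flattens the BMI histogram while
#' keeping the per-bin age distributions close to the overall one.  Remaining
#' subjects form the validation split.
#'
#' @param table included subject table (`id`, `bmi`, and the matching
#'   covariate).
#' @param spec a [bin_spec()].
#' @param total_n discovery sample size (`<= nrow(table)`).
#' @param match_on name of the covariate matched within bins (default
#'   `"age"`).
#' @param seed integer seed controlling deterministic tie-breaking.
#' @return A data.frame of class `split_assignment` with columns `id`,
#'   `partition` (`"discovery"`/`"validation"`) and `bin`; per-bin diagnostics
#'   (count, covariate mean/SD, redistribution log) are in attribute
#'   `"diagnostics"`.
#' @export
sample_uniform_with_matching <- function(table, spec, total_n,
                                         match_on = "age", seed = 1L) {
  stop_if_not_cols(table, c("id", "bmi", match_on), "subject table")
  n <- nrow(table)
  if (total_n > n) stop("`total_n` exceeds table size")
  bins <- bin_bmi(table$bmi, spec)
  nb <- spec$n_bins
  avail <- tabulate(bins + 1L, nb)

  # Per-bin targets: ceil(total_n/n_bins), trimmed greedily to hit total_n
  # (extra units go to the best-supplied bins first), then capped at supply
  # with shortfalls redistributed to the nearest bins that still have room.
  base <- total_n %/% nb
  extra <- total_n %% nb
  target <- rep(base, nb)
  if (extra > 0) {
    ord <- order(-avail, seq_len(nb))
    target[ord[seq_len(extra)]] <- base + 1L
  }
  quota <- pmin(target, avail)
  log_lines <- character(0)
  shortfall <- sum(target) - sum(quota)
  while (shortfall > 0) {
    short_bins <- which(target > avail)
    room <- which(quota < avail)
    if (!length(room)) break
    # nearest bin with room to the first shortfall bin
    ref <- if (length(short_bins)) short_bins[1] else which.max(avail - quota)
    pick <- room[which.min(abs(room - ref))]
    quota[pick] <- quota[pick] + 1L
    target[ref] <- quota[ref]  # mark satisfied as we go
    log_lines <- c(log_lines,
                   sprintf("bin %d short; 1 slot moved to bin %d", ref - 1L, pick - 1L))
    shortfall <- shortfall - 1L
  }
  if (sum(quota) < total_n) {
    warning("insufficient supply to reach total_n; discovery sample is smaller")
  }

  cov_all <- table[[match_on]]
  selected <- logical(n)
  with_seed(seed, {
    shuffle <- sample.int(n)  # deterministic tie-breaking order
    for (b in seq_len(nb)) {
      q <- quota[b]
      if (q == 0L) next
      cand <- which(bins == b - 1L)
      cand <- cand[order(match(cand, shuffle))]
      probs <- (seq_len(q) - 0.5) / q
      targets <- stats::quantile(cov_all, probs, names = FALSE, type = 7)
      taken <- logical(length(cand))
      for (tg in targets) {
        open <- which(!taken)
        j <- open[which.min(abs(cov_all[cand[open]] - tg))]
        taken[j] <- TRUE
      }
      selected[cand[taken]] <- TRUE
    }
  })

  out <- data.frame(id = table$id,
                    partition = ifelse(selected, "discovery", "validation"),
                    bin = bins, stringsAsFactors = FALSE)
  per_bin <- data.frame(
    bin = seq_len(nb) - 1L, available = avail, selected = quota,
    cov_mean = vapply(seq_len(nb), function(b) {
      v <- cov_all[selected & bins == b - 1L]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    cov_sd = vapply(seq_len(nb), function(b) {
      v <- cov_all[selected & bins == b - 1L]
      if (length(v) > 1) stats::sd(v) else NA_real_
    }, numeric(1))
  )
  attr(out, "diagnostics") <- list(per_bin = per_bin, match_on = match_on,
                                   redistribution = log_lines)
  class(out) <- c("split_assignment", class(out))
  out
}
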