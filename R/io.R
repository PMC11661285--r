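# Standard-format I/O: subject tables as CSV, GMV matrices as a dense TSV
# plus a JSON sidecar (grid shape, mask, voxel order), optional per-subject
# NIfTI volumes.  CSV dialect is fixed (comma, UTF-8, '.' decimal, NA) to
# avoid locale drift.

#' Write / read a subject table as CSV
#'
#' @param table subject data.frame.
#' @param path file path.
#' @return `read_subject_table` returns the data.frame.
#' @export
write_subject_table <- function(table, path) {
  data.table::fwrite(table, path, na = "NA", quote = TRUE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  as.data.frame(data.table::fread(path, na.strings = "NA"))
}

#' Write a GMV matrix as a dense TSV with a JSON sidecar
#'
#' The sidecar (`<prefix>.json`) records the grid shape, the voxel mask, the
#' subject ids and the flattening convention (first grid axis fastest), so
#' the matrix file round-trips exactly.
#'
#' @param gmv a [gmv_matrix()].
#' @param prefix path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `read_gmv` returns the [gmv_matrix()].
#' @export
write_gmv <- function(gmv, prefix) {
  stopifnot(inherits(gmv, "gmv_matrix"))
  data.table::fwrite(data.table::as.data.table(gmv$data),
                     paste0(prefix, ".tsv"), sep = "\t", col.names = FALSE)
  jsonlite::write_json(
    list(grid = gmv$grid, mask = as.integer(gmv$mask), ids = gmv$ids,
         n_subjects = nrow(gmv$data), voxel_order = "first-axis-fastest"),
    paste0(prefix, ".json"), auto_unbox = FALSE)
  invisible(prefix)
}

#' @rdname write_gmv
#' @export
read_gmv <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- as.matrix(data.table::fread(paste0(prefix, ".tsv"), header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != side$n_subjects || ncol(m) != prod(side$grid)) {
    stop("GMV matrix does not match its sidecar (grid/subject mismatch)")
  }
  gmv_matrix(m, side$grid, mask = as.logical(side$mask), ids = side$ids)
}

#' Write / read per-subject NIfTI volumes
#'
#' One volume per subject plus a `manifest.json` (ids, grid, mask).  Volumes
#' are unflattened with the first grid axis fastest; reading applies the
#' manifest mask.  Requires the RNifti package.
#'
#' @param gmv a [gmv_matrix()].
#' @param dir output directory (created if missing).
#' @return `read_gmv_nifti` returns the [gmv_matrix()].
#' @export
write_gmv_nifti <- function(gmv, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI export")
  }
  stopifnot(inherits(gmv, "gmv_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(gmv$ids)) {
    vol <- array(gmv$data[i, ], dim = gmv$grid)
    RNifti::writeNifti(RNifti::asNifti(vol),
                       file.path(dir, paste0(gmv$ids[i], ".nii.gz")))
  }
  jsonlite::write_json(list(ids = gmv$ids, grid = gmv$grid,
                            mask = as.integer(gmv$mask)),
                       file.path(dir, "manifest.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' @rdname write_gmv_nifti
#' @export
read_gmv_nifti <- function(dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI import")
  }
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  p <- prod(man$grid)
  rows <- lapply(man$ids, function(id) {
    vol <- RNifti::readNifti(file.path(dir, paste0(id, ".nii.gz")))
    v <- as.vector(vol)
    if (length(v) != p) {
      stop(sprintf("volume '%s' has %d voxels, manifest grid implies %d",
                   id, length(v), p))
    }
    v
  })
  m <- do.call(rbind, rows)
  m[, !as.logical(man$mask)] <- 0
  gmv_matrix(m, man$grid, mask = as.logical(man$mask), ids = man$ids)
}

#' Export a voxel statistic map or mask as CSV
#'
#' @param map a `voxel_stat_map` data.frame (or any per-voxel data.frame).
#' @param path file path.
#' @export
write_voxel_map <- function(map, path) {
  data.table::fwrite(as.data.frame(map), path, na = "NA")
  invisible(path)
}
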