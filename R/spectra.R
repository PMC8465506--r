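#' Assemble a spectra collection
#'
#' Couples an absorbance matrix (rows = egg samples, columns = spectral
#' variables) to its wavelength grid and per-sample metadata. The storage
#' design of the emulated study stores eggs for 1, 3, 5, 7, 9, 11 and 13
#' days at one of two temperatures (25 C room storage, 4 C refrigerated),
#' but any positive integer storage days are accepted.
#'
#' @param absorbance numeric matrix `[n_samples x n_variables]`, no missing
#'   values.
#' @param grid a [make_grid()] object whose length equals `ncol(absorbance)`.
#' @param sample_ids unique character vector, one per row.
#' @param metadata data.frame with columns `storage_day` (positive integer),
#'   `temp_group` (`"25C"` or `"4C"`) and `replicate` (integer), one row per
#'   sample.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(absorbance, grid, sample_ids, metadata) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  validate_grid(grid)
  if (ncol(absorbance) != length(grid$values))
    stop("absorbance has ", ncol(absorbance), " columns but grid has ",
         length(grid$values), " points")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("absorbance contains missing or non-finite values")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance))
    stop("sample_ids length does not match row count")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample_id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  metadata <- as.data.frame(metadata)
  req <- c("storage_day", "temp_group", "replicate")
  if (!all(req %in% names(metadata)))
    stop("metadata must have columns ", paste(req, collapse = ", "))
  if (nrow(metadata) != nrow(absorbance))
    stop("metadata row count does not match spectra row count")
  if (any(metadata$storage_day <= 0 | metadata$storage_day %% 1 != 0))
    stop("storage_day must be a positive integer")
  if (!all(metadata$temp_group %in% c("25C", "4C")))
    stop("temp_group must be '25C' or '4C'")
  rownames(absorbance) <- sample_ids
  structure(
    list(absorbance = absorbance, grid = grid, sample_ids = sample_ids,
         metadata = metadata[, req, drop = FALSE]),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d variables, %.4g-%.4g %s\n",
              nrow(x$absorbance), ncol(x$absorbance),
              min(x$grid$values), max(x$grid$values), x$grid$unit))
  cat("  storage days:",
      paste(sort(unique(x$metadata$storage_day)), collapse = ", "),
      "| groups:", paste(unique(x$metadata$temp_group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra collection by sample
#' @param x a `spectra_set`.
#' @param i row (sample) index vector.
#' @param ... unused.
#' @return A `spectra_set` containing the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$absorbance[i, , drop = FALSE], x$grid,
              x$sample_ids[i], x$metadata[i, , drop = FALSE])
}

#' Read a spectra collection from CSV files
#'
#' The spectra file is wide CSV: first column `sample_id`, remaining column
#' headers the numeric wavelengths. The metadata file is keyed by
#' `sample_id` with columns `storage_day`, `temp_group`, `replicate`.
#' Samples are returned in metadata-file order. An optional JSON sidecar
#' written by [write_spectra()] (`<spectra_path>.grid.json`) restores the
#' grid's unit and endpoint dialect; without it the unit defaults to nm.
#'
#' @param spectra_path,metadata_path CSV file paths.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(spectra_path, metadata_path) {
  sp <- read.csv(spectra_path, check.names = FALSE)
  md <- read.csv(metadata_path, check.names = FALSE)
  if (names(sp)[1] != "sample_id" || !"sample_id" %in% names(md))
    stop("both files must carry a sample_id column (first in the spectra file)")
  wl <- suppressWarnings(as.numeric(names(sp)[-1]))
  if (anyNA(wl)) stop("non-numeric wavelength column headers")
  if (any(diff(wl) <= 0)) stop("wavelength columns must be strictly increasing")
  ids_sp <- as.character(sp$sample_id)
  ids_md <- as.character(md$sample_id)
  only_sp <- setdiff(ids_sp, ids_md)
  only_md <- setdiff(ids_md, ids_sp)
  if (length(only_sp) || length(only_md))
    stop("sample_id mismatch between files: ",
         paste(c(only_sp, only_md), collapse = ", "))
  side <- paste0(spectra_path, ".grid.json")
  grid <- if (file.exists(side)) {
    g <- jsonlite::read_json(side, simplifyVector = TRUE)
    make_grid(g$start, g$stop, g$step, unit = g$unit, dialect = g$dialect)
  } else grid_from_values(wl)
  if (length(grid$values) != length(wl) ||
      max(abs(grid$values - wl)) > 1e-6)
    grid <- grid_from_values(wl, unit = grid$unit)
  X <- as.matrix(sp[match(ids_md, ids_sp), -1, drop = FALSE])
  spectra_set(X, grid, ids_md, md[setdiff(names(md), "sample_id")])
}

#' Write a spectra collection to CSV files
#'
#' Inverse of [read_spectra()]; numeric values are written with 17
#' significant digits so a write/read round trip is bit-identical. A JSON
#' sidecar `<spectra_path>.grid.json` records the grid unit and dialect.
#'
#' @param s a [spectra_set()].
#' @param spectra_path,metadata_path output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_spectra <- function(s, spectra_path, metadata_path) {
  stopifnot(inherits(s, "spectra_set"))
  header <- paste(c("sample_id", format_full(s$grid$values)), collapse = ",")
  rows <- if (nrow(s$absorbance) == 0) character(0) else
    paste(s$sample_ids,
          apply(s$absorbance, 1, function(r) paste(format_full(r), collapse = ",")),
          sep = ",")
  writeLines(c(header, rows), spectra_path)
  md <- cbind(sample_id = s$sample_ids, s$metadata)
  write.csv(md, metadata_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    s$grid[c("unit", "start", "stop", "step", "dialect")],
    paste0(spectra_path, ".grid.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(spectra_path, metadata_path))
}

format_full <- function(x) formatC(x, digits = 17, format = "g")

#' Split samples into calibration and prediction sets
#'
#' Applies the every-third-sample rule: after a stable sort by
#' `(storage_day, replicate)`, every third sample (positions 3, 6, 9, ...)
#' is assigned to the prediction set and the rest to calibration. With the
#' emulated design of 15 eggs per day over 7 storage days (105 samples)
#' this yields 70 calibration and 35 prediction samples, 10/5 within each
#' day subgroup.
#'
#' @param s a [spectra_set()] with at least 3 samples.
#' @return An object of class `split_plan`: list with integer vectors
#'   `calibration` and `prediction` (row indices into `s`), disjoint and
#'   jointly covering all samples.
#' @export
make_split <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  n <- nrow(s$absorbance)
  if (n < 3) stop("need at least 3 samples to split")
  ord <- order(s$metadata$storage_day, s$metadata$replicate)
  pos <- seq_len(n)
  pred <- ord[pos %% 3 == 0]
  cal <- ord[pos %% 3 != 0]
  structure(list(calibration = sort(cal), prediction = sort(pred)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d calibration / %d prediction\n",
              length(x$calibration), length(x$prediction)))
  invisible(x)
}
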