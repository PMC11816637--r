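#' Manual seed annotations for one image
#'
#' Seeds follow the package's coordinate convention: 0-based `(row, col)`
#' pixel coordinates, row-major, and axis-aligned rectangles given as
#' `(row0, col0, row1, col1)` half-open on the right (`row0 <= r < row1`).
#'
#' @param cell_seeds Data frame with columns `cell_id` (unique integers
#'   >= 1), `row`, `col` (0-based) marking one interior point per cell.
#' @param outside_seed Length-2 integer vector, a point in extracellular
#'   space.
#' @param background_roi Length-4 integer vector `(row0, col0, row1, col1)`,
#'   a cell-free rectangle used for background estimation.
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(cell_seeds, outside_seed, background_roi) {
  cell_seeds <- as.data.frame(cell_seeds)
  stopifnot(all(c("cell_id", "row", "col") %in% names(cell_seeds)))
  cell_seeds$cell_id <- as.integer(cell_seeds$cell_id)
  cell_seeds$row <- as.integer(cell_seeds$row)
  cell_seeds$col <- as.integer(cell_seeds$col)
  x <- structure(list(cell_seeds = cell_seeds,
                      outside_seed = as.integer(outside_seed),
                      background_roi = as.integer(background_roi)),
                 class = "seed_set")
  validate_seed_set(x)
  x
}

#' Validate a seed set
#'
#' Checks unique positive cell ids, a well-formed non-empty background
#' rectangle, and that the rectangle contains no cell seed. Bounds against
#' a concrete image are checked at use time (see [segment_cells()]).
#'
#' @param x A [seed_set()].
#' @param dim Optional image dimensions `c(nrow, ncol)` to bound-check
#'   against.
#' @return `x`, invisibly.
#' @export
validate_seed_set <- function(x, dim = NULL) {
  stopifnot(inherits(x, "seed_set"))
  cs <- x$cell_seeds
  if (nrow(cs) < 1) stop("seed set must contain at least one cell seed", call. = FALSE)
  if (anyDuplicated(cs$cell_id)) stop("cell_ids must be unique", call. = FALSE)
  if (any(cs$cell_id < 1)) stop("cell_ids must be >= 1", call. = FALSE)
  if (anyDuplicated(cs[, c("row", "col")]))
    stop("two cell seeds occupy the same pixel", call. = FALSE)
  if (length(x$outside_seed) != 2)
    stop("outside_seed must be a (row, col) pair", call. = FALSE)
  roi <- x$background_roi
  if (length(roi) != 4)
    stop("background_roi must be (row0, col0, row1, col1)", call. = FALSE)
  if (roi[3] <= roi[1] || roi[4] <= roi[2])
    stop("background_roi is empty (half-open rectangle has no pixels)", call. = FALSE)
  in_roi <- cs$row >= roi[1] & cs$row < roi[3] & cs$col >= roi[2] & cs$col < roi[4]
  if (any(in_roi))
    stop("background_roi overlaps cell seed(s): ",
         paste(cs$cell_id[in_roi], collapse = ", "), call. = FALSE)
  if (!is.null(dim)) {
    pts <- rbind(as.matrix(cs[, c("row", "col")]), x$outside_seed)
    if (any(pts[, 1] < 0 | pts[, 1] >= dim[1] | pts[, 2] < 0 | pts[, 2] >= dim[2]))
      stop("seed outside image bounds", call. = FALSE)
    if (roi[1] < 0 || roi[2] < 0 || roi[3] > dim[1] || roi[4] > dim[2])
      stop("background_roi outside image bounds", call. = FALSE)
  }
  invisible(x)
}

#' Read / write seed annotations (JSON)
#'
#' The JSON schema is
#' \preformatted{
#' {"cells": [{"cell_id": 1, "seed": [row, col]}, ...],
#'  "outside_seed": [row, col],
#'  "background_roi": [row0, col0, row1, col1]}
#' }
#' with 0-based coordinates and a half-open rectangle, so that annotation
#' files are diff-able text.
#'
#' @param path JSON file path.
#' @return A [seed_set()].
#' @export
read_seed_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$cells) || is.null(j$outside_seed) || is.null(j$background_roi))
    stop("seed file must contain 'cells', 'outside_seed' and 'background_roi'",
         call. = FALSE)
  cells <- j$cells
  seeds <- if (is.data.frame(cells)) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
      data.frame(cell_id = cells$cell_id[i],
                 row = cells$seed[[i]][1], col = cells$seed[[i]][2])))
  } else {
    do.call(rbind, lapply(cells, function(cl)
      data.frame(cell_id = cl$cell_id, row = cl$seed[[1]], col = cl$seed[[2]])))
  }
  seed_set(seeds, unlist(j$outside_seed), unlist(j$background_roi))
}

#' @rdname read_seed_set
#' @param x A [seed_set()] to write.
#' @export
write_seed_set <- function(x, path) {
  validate_seed_set(x)
  cells <- lapply(seq_len(nrow(x$cell_seeds)), function(i)
    list(cell_id = x$cell_seeds$cell_id[i],
         seed = c(x$cell_seeds$row[i], x$cell_seeds$col[i])))
  jsonlite::write_json(list(cells = cells,
                            outside_seed = x$outside_seed,
                            background_roi = x$background_roi),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Analysis run configuration
#'
#' Collects the tunable parameters of the pipeline with their defaults.
#'
#' @param f66_threshold_multiplier Intracellular-membrane threshold as a
#'   multiple of the mean background F66 intensity (default 4).
#' @param pm_line_dilation_px Dilation radius (px) applied to the watershed
#'   line to form the plasma-membrane mask (default 1).
#' @param histogram_bins Bins of the marker histogram for maximum-entropy
#'   thresholding (default 256).
#' @param ratio_denominator_epsilon Minimum background-subtracted N* count
#'   for a pixel ratio to be valid (default 1 count).
#' @param organelle_label One of `"lysosome"`, `"golgi"`, `"er"`,
#'   `"mitochondria"`, or `NULL` when no marker channel is analyzed.
#' @param random_seed Optional integer recorded in reports.
#' @param marker_threshold_override Optional scalar replacing the automatic
#'   maximum-entropy marker threshold (mirrors thresholds "confirmed by
#'   visual inspection" on real data).
#' @param min_pixels Minimum valid pixels for a per-cell compartment median
#'   (default 10); smaller compartments are dropped with a warning.
#' @param relief_channel Relief for the watershed: `"sum"` (N*+T*, default),
#'   `"n"` or `"t"`.
#' @param include_border_cells Keep cells whose basin touches the image
#'   border (default FALSE: they are measured but flagged, and excluded
#'   from group statistics).
#' @param intersect_f66 Also require organelle pixels to pass the F66
#'   intracellular-membrane threshold (default FALSE: the organelle mask is
#'   defined by the marker alone).
#' @return An object of class `run_config`.
#' @export
run_config <- function(f66_threshold_multiplier = 4,
                       pm_line_dilation_px = 1L,
                       histogram_bins = 256L,
                       ratio_denominator_epsilon = 1,
                       organelle_label = NULL,
                       random_seed = NULL,
                       marker_threshold_override = NULL,
                       min_pixels = 10L,
                       relief_channel = c("sum", "n", "t"),
                       include_border_cells = FALSE,
                       intersect_f66 = FALSE) {
  relief_channel <- match.arg(relief_channel)
  if (f66_threshold_multiplier <= 0) stop("f66_threshold_multiplier must be > 0", call. = FALSE)
  if (histogram_bins < 2) stop("histogram_bins must be >= 2", call. = FALSE)
  if (ratio_denominator_epsilon <= 0) stop("ratio_denominator_epsilon must be > 0", call. = FALSE)
  if (pm_line_dilation_px < 0) stop("pm_line_dilation_px must be >= 0", call. = FALSE)
  if (!is.null(organelle_label))
    organelle_label <- match.arg(organelle_label, c("lysosome", "golgi", "er", "mitochondria"))
  structure(list(f66_threshold_multiplier = f66_threshold_multiplier,
                 pm_line_dilation_px = as.integer(pm_line_dilation_px),
                 histogram_bins = as.integer(histogram_bins),
                 ratio_denominator_epsilon = ratio_denominator_epsilon,
                 organelle_label = organelle_label,
                 random_seed = random_seed,
                 marker_threshold_override = marker_threshold_override,
                 min_pixels = as.integer(min_pixels),
                 relief_channel = relief_channel,
                 include_border_cells = include_border_cells,
                 intersect_f66 = intersect_f66),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file with a subset of the configuration fields.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(j), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, j)
}

measurement_columns <- c("cell_id", "compartment", "median_ratio", "q1", "q3",
                         "n_pixels", "normalized_ratio", "border_flag")

#' Write / read per-cell measurement tables (CSV)
#'
#' One row per (cell, compartment) with the fields of a cell measurement:
#' `cell_id`, `compartment`, `median_ratio`, `q1`, `q3`, `n_pixels`,
#' `normalized_ratio`, `border_flag` (plus any extra columns such as an
#' image index). Ratios are written at full precision (17 significant
#' digits) so the table round-trips to the last bit.
#'
#' @param records Data frame of measurements (see [measure_cells()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("no measurement records to write", call. = FALSE)
  missing <- setdiff(measurement_columns, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  out <- records
  for (cl in names(out))
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$border_flag <- as.logical(d$border_flag)
  d
}
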