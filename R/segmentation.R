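#' Seeded watershed by priority flooding
#'
#' Floods an intensity relief from labeled seed pixels: pixels are claimed
#' in non-descending order of relief value (4-connected growth), so basins
#' grow from low-intensity seed regions and meet on bright ridges. A pixel
#' whose already-labeled 4-neighbours carry two or more distinct labels
#' becomes a watershed-line pixel (thickness 1) and does not propagate.
#' Ties between equal relief values are broken by queue insertion order,
#' with pixels queued in lexicographic (row, col) order, so the result is
#' fully deterministic, including on plateaus.
#'
#' @param relief Numeric matrix of finite values (the flooding surface).
#' @param seeds Integer matrix of the same size: 0 everywhere except seed
#'   pixels, which carry their (positive) basin label.
#' @return A list with `labels` (integer matrix; 0 on watershed-line
#'   pixels) and `line` (logical matrix marking line pixels).
#' @export
seeded_watershed <- function(relief, seeds) {
  if (!is.matrix(relief) || !all(is.finite(relief)))
    stop("relief must be a finite numeric matrix", call. = FALSE)
  if (!identical(dim(relief), dim(seeds)))
    stop("relief and seeds must have identical dimensions", call. = FALSE)
  storage.mode(relief) <- "double"
  storage.mode(seeds) <- "integer"
  if (any(seeds < 0)) stop("seed labels must be >= 0", call. = FALSE)
  if (!any(seeds > 0)) stop("no seeds given", call. = FALSE)
  .ws_flood(relief, seeds)
}

#' Binary dilation / erosion by shifting
#'
#' Small helpers used for plasma-membrane mask construction and synthetic
#' geometry. `connectivity = 4` uses a diamond structuring element,
#' `8` a 3x3 square; radius `r` applies the element `r` times. Erosion
#' treats pixels beyond the border as background.
#'
#' @param mask Logical matrix.
#' @param r Radius (iterations), >= 0.
#' @param connectivity 4 or 8.
#' @return Logical matrix.
#' @export
binary_dilate <- function(mask, r = 1L, connectivity = 8L) {
  stopifnot(is.matrix(mask), r >= 0)
  m <- mask
  for (i in seq_len(r)) m <- dilate1(m, connectivity)
  m
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, r = 1L, connectivity = 4L) {
  !binary_dilate(!mask, r, connectivity)
}

dilate1 <- function(m, connectivity) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  if (connectivity == 8) {
    out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
    out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
    out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
  }
  out
}

#' Estimate per-channel background from a cell-free rectangle
#'
#' Arithmetic mean and SD of each channel over the background ROI. The N*
#' mean (plus the T* mean, for the summed relief) anchors the
#' intracellular-membrane threshold; the per-channel means are subtracted
#' pixel-by-pixel before ratio formation.
#'
#' @param stack A [channel_stack()].
#' @param background_roi `(row0, col0, row1, col1)`, 0-based half-open.
#' @return An object of class `background_estimate`: per channel `mean` and
#'   `sd`, plus `n_pixels`.
#' @export
estimate_background <- function(stack, background_roi) {
  validate_channel_stack(stack)
  roi <- as.integer(background_roi)
  d <- dim(stack$n)
  if (length(roi) != 4 || roi[3] <= roi[1] || roi[4] <= roi[2])
    stop("background_roi is empty", call. = FALSE)
  if (roi[1] < 0 || roi[2] < 0 || roi[3] > d[1] || roi[4] > d[2])
    stop("background_roi outside image bounds", call. = FALSE)
  rows <- (roi[1] + 1):roi[3]
  cols <- (roi[2] + 1):roi[4]
  one <- function(img) {
    if (is.null(img)) return(NULL)
    v <- img[rows, cols]
    list(mean = mean(v), sd = stats::sd(as.numeric(v)))
  }
  structure(list(n = one(stack$n), t = one(stack$t), marker = one(stack$marker),
                 n_pixels = length(rows) * length(cols)),
            class = "background_estimate")
}

relief_image <- function(stack, relief_channel = "sum") {
  switch(relief_channel,
         sum = stack$n + stack$t,
         n = stack$n,
         t = stack$t)
}

relief_background_mean <- function(background, relief_channel = "sum") {
  switch(relief_channel,
         sum = background$n$mean + background$t$mean,
         n = background$n$mean,
         t = background$t$mean)
}

#' Segment individual cells from the F66 relief
#'
#' Runs the seeded watershed on the F66 intensity relief (by default the
#' sum of the N* and T* images, where the plasma membrane is the brightest
#' ridge) with one seed per cell interior plus the outside seed. Per cell,
#' the interior mask is that cell's basin; the plasma-membrane mask is the
#' set of watershed-line pixels adjacent to the basin, dilated by
#' `pm_line_dilation_px` (3x3 element) and restricted to pixels not inside
#' any cell basin. Line pixels adjacent to several cells are assigned to
#' the lowest cell id so that per-cell masks stay pairwise disjoint.
#' Interiors, plasma-membrane masks and the outside mask partition the
#' image. Cells whose basin touches the image border are flagged.
#'
#' @param stack A [channel_stack()].
#' @param seeds A [seed_set()].
#' @param config A [run_config()].
#' @return An object of class `cell_segmentation`: `interior` and `pm`
#'   (integer label matrices, 0 = none), `outside` (logical), `line`
#'   (logical, raw watershed line), `cell_ids`, `border_flag` (named
#'   logical), and the outside label used internally.
#' @export
segment_cells <- function(stack, seeds, config = run_config()) {
  validate_channel_stack(stack)
  d <- dim(stack$n)
  validate_seed_set(seeds, dim = d)
  cs <- seeds$cell_seeds
  roi <- seeds$background_roi
  # a cell seed inside the background rectangle contradicts "cell-free"
  # (also enforced by the seed-set validator; kept here for label images)
  in_roi <- cs$row >= roi[1] & cs$row < roi[3] & cs$col >= roi[2] & cs$col < roi[4]
  if (any(in_roi)) stop("cell seed lies inside background_roi", call. = FALSE)

  relief <- relief_image(stack, config$relief_channel)
  lab0 <- matrix(0L, d[1], d[2])
  for (i in seq_len(nrow(cs)))
    lab0[cs$row[i] + 1L, cs$col[i] + 1L] <- cs$cell_id[i]
  outside_label <- max(cs$cell_id) + 1L
  if (lab0[seeds$outside_seed[1] + 1L, seeds$outside_seed[2] + 1L] != 0L)
    stop("outside seed coincides with a cell seed", call. = FALSE)
  lab0[seeds$outside_seed[1] + 1L, seeds$outside_seed[2] + 1L] <- outside_label

  ws <- seeded_watershed(relief, lab0)
  labels <- ws$labels
  line <- ws$line

  interior <- labels
  interior[interior == outside_label] <- 0L
  any_basin <- labels > 0L

  pm <- matrix(0L, d[1], d[2])
  ids <- sort(cs$cell_id)
  for (id in ids) {
    basin <- labels == id
    adj <- line & binary_dilate(basin, 1L, connectivity = 4L)
    pm_id <- if (config$pm_line_dilation_px > 0)
      binary_dilate(adj, config$pm_line_dilation_px, connectivity = 8L)
    else adj
    pm_id <- pm_id & !any_basin & pm == 0L # never eat basins or earlier cells' pm
    pm[pm_id] <- id
  }

  outside <- interior == 0L & pm == 0L
  border <- vapply(ids, function(id) {
    basin <- labels == id
    any(basin[1, ]) || any(basin[d[1], ]) || any(basin[, 1]) || any(basin[, d[2]])
  }, logical(1))
  names(border) <- ids

  structure(list(interior = interior, pm = pm, outside = outside, line = line,
                 cell_ids = ids, border_flag = border,
                 outside_label = outside_label),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("cell_segmentation: %d cell(s) [%s], %d border-flagged\n",
              length(x$cell_ids), paste(x$cell_ids, collapse = ", "),
              sum(x$border_flag)))
  invisible(x)
}
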