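#' Background-subtracted pixelwise T*/N* ratio map
#'
#' Per pixel, `(T - bg_T) / (N - bg_N)` using the per-channel background
#' means of the same image. A pixel is valid when its denominator exceeds
#' `epsilon` (default 1 count): below that, the ratio is dominated by shot
#' noise. Negative numerators are allowed (only the denominator gates
#' validity, which keeps the estimator unbiased near zero); invalid pixels
#' carry `NA` and are excluded from every downstream statistic.
#'
#' @param stack A [channel_stack()].
#' @param background A [estimate_background()] result.
#' @param epsilon Positive scalar, minimum valid denominator.
#' @return An object of class `ratio_map`: `value` (numeric matrix, `NA`
#'   where invalid) and `valid` (logical matrix).
#' @export
ratio_map <- function(stack, background, epsilon = 1) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  den <- stack$n - background$n$mean
  num <- stack$t - background$t$mean
  valid <- den > epsilon
  value <- matrix(NA_real_, nrow(den), ncol(den))
  value[valid] <- num[valid] / den[valid]
  structure(list(value = value, valid = valid, epsilon = epsilon),
            class = "ratio_map")
}

#' Median and quartiles of a ratio map over a region
#'
#' Statistics are taken over the valid masked pixels only. The quantile
#' convention (used identically for group summaries) is type-7:
#' the even-count median is the mean of the two central order statistics.
#'
#' @param rmap A [ratio_map()].
#' @param mask Logical matrix selecting the region.
#' @param min_pixels Minimum number of valid pixels (default 1; the
#'   pipeline applies its own `min_pixels` from the configuration).
#' @return List `(median, q1, q3, n_pixels)`, or `NULL` (with a warning)
#'   when fewer than `min_pixels` valid pixels remain.
#' @export
region_stats <- function(rmap, mask, min_pixels = 1L) {
  v <- rmap$value[mask & rmap$valid]
  if (length(v) < min_pixels) {
    warning(sprintf("region has %d valid pixel(s), fewer than min_pixels = %d: dropped",
                    length(v), min_pixels), call. = FALSE)
    return(NULL)
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3], n_pixels = length(v))
}

#' Normalize an organelle median to the plasma membrane of the same cell
#'
#' The quotient organelle median / plasma-membrane median removes
#' cell-to-cell staining and detection variability, so relative
#' dipole-potential differences between compartments can be compared
#' across cells and cell lines.
#'
#' @param organelle_median Per-cell organelle median T*/N* ratio.
#' @param pm_median Plasma-membrane median of the same cell; must be > 0.
#' @return The normalized ratio.
#' @export
normalize_to_pm <- function(organelle_median, pm_median) {
  if (any(pm_median <= 0)) stop("pm_median must be > 0", call. = FALSE)
  organelle_median / pm_median
}

#' Per-cell, per-compartment ratio measurements
#'
#' For every cell, computes median/quartile T*/N* ratios in the plasma
#' membrane, the configured organelle (when present), and the whole
#' intracellular-membrane mask, plus the PM-normalized ratio (1 for the
#' plasma membrane by definition). Compartments with fewer than
#' `config$min_pixels` valid pixels are dropped with a warning; a cell
#' whose plasma membrane cannot be measured yields no records.
#'
#' @param stack A [channel_stack()].
#' @param segmentation A [segment_cells()] result.
#' @param masks A [build_compartment_masks()] result.
#' @param background A [estimate_background()] result.
#' @param config A [run_config()].
#' @return Data frame with columns `cell_id`, `compartment` (`"PM"`, the
#'   organelle label, or `"intracellular_all"`), `median_ratio`, `q1`,
#'   `q3`, `n_pixels`, `normalized_ratio`, `border_flag`.
#' @export
measure_cells <- function(stack, segmentation, masks, background,
                          config = run_config()) {
  rmap <- ratio_map(stack, background, config$ratio_denominator_epsilon)
  rows <- list()
  for (id in segmentation$cell_ids) {
    flag <- unname(segmentation$border_flag[as.character(id)])
    pm_stats <- region_stats(rmap, segmentation$pm == id, config$min_pixels)
    if (is.null(pm_stats)) {
      warning(sprintf("cell %d: plasma membrane unmeasurable, cell skipped", id),
              call. = FALSE)
      next
    }
    add <- function(compartment, st) {
      if (is.null(st)) return()
      rows[[length(rows) + 1]] <<- data.frame(
        cell_id = id, compartment = compartment,
        median_ratio = st$median, q1 = st$q1, q3 = st$q3,
        n_pixels = st$n_pixels,
        normalized_ratio = normalize_to_pm(st$median, pm_stats$median),
        border_flag = flag)
    }
    add("PM", pm_stats)
    if (!is.null(masks$organelle)) {
      org_stats <- region_stats(rmap, masks$organelle == id, config$min_pixels)
      if (is.null(org_stats))
        warning(sprintf("cell %d: organelle compartment dropped", id), call. = FALSE)
      add(config$organelle_label, org_stats)
    }
    add("intracellular_all",
        region_stats(rmap, masks$intracellular == id, config$min_pixels))
  }
  if (!length(rows))
    return(data.frame(cell_id = integer(), compartment = character(),
                      median_ratio = double(), q1 = double(), q3 = double(),
                      n_pixels = integer(), normalized_ratio = double(),
                      border_flag = logical()))
  do.call(rbind, rows)
}
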