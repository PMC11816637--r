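#' Intracellular-membrane intensity threshold
#'
#' The threshold for calling an intracellular pixel a membrane pixel is a
#' fixed multiple (default 4) of the mean F66 intensity of the cell-free
#' background area, taken on the same relief channel that drives the
#' watershed (N*+T* by default, so the background mean is the sum of the
#' two channel means over the ROI).
#'
#' @param background A [estimate_background()] result.
#' @param multiplier Positive scalar, default 4.
#' @param relief_channel `"sum"`, `"n"` or `"t"`.
#' @return Scalar threshold.
#' @export
f66_membrane_threshold <- function(background, multiplier = 4,
                                   relief_channel = "sum") {
  if (multiplier <= 0) stop("multiplier must be > 0", call. = FALSE)
  multiplier * relief_background_mean(background, relief_channel)
}

#' Maximum-entropy (Kapur) histogram threshold
#'
#' Selects the split of a histogram into a below class (bins `1..t-1`) and
#' an above class (bins `t..K`) that maximizes the sum of the Shannon
#' entropies of the two within-class renormalized bin distributions.
#' Zero-probability bins contribute nothing; splits leaving either class
#' empty are not candidates; ties are broken toward the lower bin.
#'
#' @param counts Non-negative numeric vector of bin counts (>= 2 bins).
#' @return List with `bin` (1-based index of the first above-class bin),
#'   and `criterion` (the entropy sum at every split; `NA` where a class
#'   is empty).
#' @export
maxentropy_threshold <- function(counts) {
  if (length(counts) < 2) stop("histogram needs >= 2 bins", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("bin counts must be finite and non-negative", call. = FALSE)
  if (sum(counts > 0) < 2)
    stop("all histogram mass in one bin: no threshold definable", call. = FALSE)
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)       # P[k]  = mass of bins 1..k
  S <- -cumsum(plogp)  # S[k]  = -sum p log p over bins 1..k
  K <- length(p)
  t_cand <- 2:K        # below class = bins 1..t-1
  P0 <- P[t_cand - 1]
  crit <- rep(NA_real_, K)
  valid <- P0 > 0 & P0 < 1
  H_below <- S[t_cand - 1] / P0 + log(P0)
  H_above <- (S[K] - S[t_cand - 1]) / (1 - P0) + log(1 - P0)
  crit[t_cand] <- ifelse(valid, H_below + H_above, NA_real_)
  # ties (exact or within floating-point noise of the maximum) resolve to
  # the lowest bin
  top <- max(crit, na.rm = TRUE)
  best <- which(!is.na(crit) & crit >= top - 1e-12)[1]
  list(bin = best, criterion = crit)
}

marker_histogram <- function(values, bins) {
  top <- max(values)
  if (top <= 0) stop("all histogram mass in one bin: no threshold definable",
                     call. = FALSE)
  edges <- seq(0, top, length.out = bins + 1)
  h <- graphics::hist(values, breaks = edges, right = TRUE,
                      include.lowest = TRUE, plot = FALSE)
  list(counts = h$counts, edges = edges)
}

#' Build per-cell compartment masks
#'
#' Two masks per cell, both subsets of the cell's interior: the
#' intracellular-membrane mask (relief intensity above the
#' background-derived F66 threshold) and, when an organelle is configured,
#' the organelle mask (marker intensity above the maximum-entropy
#' threshold). The marker histogram spans `[0, max]` of the marker within
#' the union of all cell interiors of the image (one threshold per field,
#' as organelle markers are thresholded globally per image), using
#' `config$histogram_bins` equal-width bins; `marker_threshold_override`
#' replaces the automatic value and is flagged as provenance "override".
#'
#' @param stack A [channel_stack()].
#' @param segmentation A [segment_cells()] result.
#' @param background A [estimate_background()] result.
#' @param config A [run_config()].
#' @return An object of class `compartment_masks`: `intracellular` and
#'   `organelle` label matrices (0 = none; `organelle` is `NULL` when no
#'   organelle is configured), `f66_threshold`, `marker_threshold`,
#'   `marker_threshold_provenance` ("auto"/"override").
#' @export
build_compartment_masks <- function(stack, segmentation, background,
                                    config = run_config()) {
  relief <- relief_image(stack, config$relief_channel)
  thr <- f66_membrane_threshold(background, config$f66_threshold_multiplier,
                                config$relief_channel)
  interior_any <- segmentation$interior > 0L
  intracellular <- segmentation$interior
  intracellular[!(interior_any & relief > thr)] <- 0L

  organelle <- NULL
  marker_thr <- NA_real_
  provenance <- NA_character_
  if (!is.null(config$organelle_label)) {
    if (is.null(stack$marker))
      stop("organelle '", config$organelle_label,
           "' requested but the stack has no marker channel", call. = FALSE)
    if (!is.null(config$marker_threshold_override)) {
      marker_thr <- config$marker_threshold_override
      provenance <- "override"
    } else {
      hh <- marker_histogram(stack$marker[interior_any], config$histogram_bins)
      me <- maxentropy_threshold(hh$counts)
      marker_thr <- hh$edges[me$bin]
      provenance <- "auto"
    }
    organelle <- segmentation$interior
    keep <- interior_any & stack$marker > marker_thr
    if (config$intersect_f66) keep <- keep & relief > thr
    organelle[!keep] <- 0L
  }
  structure(list(intracellular = intracellular, organelle = organelle,
                 f66_threshold = thr, marker_threshold = marker_thr,
                 marker_threshold_provenance = provenance),
            class = "compartment_masks")
}
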