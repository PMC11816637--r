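#' Packaged per-cell-line ratio parameter sets
#'
#' Per cell line and organelle, the mean and SD of the per-cell median
#' T*/N* emission ratio in the organelle membrane and in the plasma
#' membrane, the number of measured cells, and the mean/SD of the
#' PM-normalized organelle ratio. These are the printed population values
#' the synthetic generator reproduces; per-cell true ratios are drawn from
#' normal distributions with these moments.
#'
#' @param cell_line `"skbr3"`, `"hela"` or `"shsy5y"`.
#' @param organelle `"lysosome"`, `"golgi"`, `"er"` or `"mitochondria"`.
#' @return List with `organelle_mean`, `organelle_sd`, `pm_mean`, `pm_sd`,
#'   `n_cells`, `norm_mean`, `norm_sd`, `n_norm`.
#' @export
f66_parameter_set <- function(cell_line = c("skbr3", "hela", "shsy5y"),
                              organelle = c("lysosome", "golgi", "er",
                                            "mitochondria")) {
  cell_line <- match.arg(cell_line)
  organelle <- match.arg(organelle)
  .f66_param_table[[cell_line]][[organelle]]
}

.f66_param_table <- list(
  skbr3 = list(
    lysosome     = list(organelle_mean = 2.488, organelle_sd = 0.424, pm_mean = 3.441, pm_sd = 0.263, n_cells = 107, norm_mean = 0.722, norm_sd = 0.101, n_norm = 107),
    golgi        = list(organelle_mean = 2.178, organelle_sd = 0.226, pm_mean = 3.460, pm_sd = 0.321, n_cells = 137, norm_mean = 0.633, norm_sd = 0.070, n_norm = 137),
    er           = list(organelle_mean = 2.047, organelle_sd = 0.310, pm_mean = 3.414, pm_sd = 0.240, n_cells = 152, norm_mean = 0.600, norm_sd = 0.084, n_norm = 152),
    mitochondria = list(organelle_mean = 2.421, organelle_sd = 0.342, pm_mean = 3.438, pm_sd = 0.236, n_cells = 110, norm_mean = 0.698, norm_sd = 0.100, n_norm = 110)),
  hela = list(
    lysosome     = list(organelle_mean = 2.518, organelle_sd = 0.351, pm_mean = 3.947, pm_sd = 0.333, n_cells = 115, norm_mean = 0.640, norm_sd = 0.086, n_norm = 115),
    golgi        = list(organelle_mean = 2.193, organelle_sd = 0.182, pm_mean = 3.952, pm_sd = 0.272, n_cells = 133, norm_mean = 0.558, norm_sd = 0.061, n_norm = 133),
    er           = list(organelle_mean = 2.143, organelle_sd = 0.213, pm_mean = 3.946, pm_sd = 0.265, n_cells = 114, norm_mean = 0.545, norm_sd = 0.058, n_norm = 114),
    mitochondria = list(organelle_mean = 2.588, organelle_sd = 0.282, pm_mean = 3.975, pm_sd = 0.309, n_cells = 108, norm_mean = 0.655, norm_sd = 0.091, n_norm = 108)),
  shsy5y = list(
    lysosome     = list(organelle_mean = 2.759, organelle_sd = 0.391, pm_mean = 4.224, pm_sd = 0.330, n_cells = 154, norm_mean = 0.655, norm_sd = 0.093, n_norm = 154),
    golgi        = list(organelle_mean = 2.468, organelle_sd = 0.359, pm_mean = 4.170, pm_sd = 0.282, n_cells = 138, norm_mean = 0.594, norm_sd = 0.089, n_norm = 138),
    er           = list(organelle_mean = 2.246, organelle_sd = 0.321, pm_mean = 4.207, pm_sd = 0.270, n_cells = 139, norm_mean = 0.536, norm_sd = 0.084, n_norm = 128),
    mitochondria = list(organelle_mean = 2.938, organelle_sd = 0.405, pm_mean = 4.206, pm_sd = 0.290, n_cells = 135, norm_mean = 0.699, norm_sd = 0.093, n_norm = 135))
)

#' Synthetic-image generator parameters
#'
#' Geometry and intensity model of the generator. Each cell is an
#' elliptical ring (the surface-stained plasma membrane: a 1-px crest at
#' `amp_pm` flanked by one pixel at `flank_frac * amp_pm` on either side)
#' around an interior containing organelle structures (discs for
#' lysosomes, a curved ribbon for the Golgi, a reticular web for the ER,
#' elongated filaments for mitochondria), a generic endomembrane web, and
#' flat background. Expected N* intensity is `background + amplitude` on
#' each structure; expected T* is `background + ratio * amplitude`, so the
#' background-subtracted pixel ratio equals the structure's true ratio
#' exactly when noise is off. The marker channel is bright only on the
#' organelle structures. Noise, when on, is Poisson on the expected counts
#' plus Gaussian read noise.
#'
#' @param image_size Image edge length in pixels (default 256).
#' @param cells_per_image Cells laid out side by side per image (default 1).
#' @param axis_range Semi-axis range as a fraction of `image_size/2`
#'   (divided by `cells_per_image`).
#' @param amp_pm N* amplitude of the membrane crest above background.
#' @param flank_frac Flank amplitude relative to the crest.
#' @param amp_organelle,amp_endomembrane N* amplitudes of organelle and
#'   generic endomembrane structures.
#' @param background Named per-channel background levels (`n`, `t`,
#'   `marker`).
#' @param marker_amp Marker amplitude above background on the organelle.
#' @param read_noise_sd Gaussian read-noise SD (counts).
#' @param noise Apply the noise model (FALSE gives exact expectations).
#' @param endomembrane_ratio Mean/SD of the generic endomembrane true
#'   ratio.
#' @param ratio_truncation Lower truncation of drawn true ratios.
#' @param lysosome_n,lysosome_r Number of discs and radius range (px).
#' @param golgi_width Ribbon half-width (px).
#' @param er_coverage Fraction of the eligible interior covered by the ER
#'   web.
#' @param mito_n,mito_len Number of filaments and length range (px).
#' @param pixel_size_nm Recorded pixel size.
#' @return List of class `synthetic_params`.
#' @export
synthetic_params <- function(image_size = 256L, cells_per_image = 1L,
                             axis_range = c(0.30, 0.40),
                             amp_pm = 150, flank_frac = 0.8,
                             amp_organelle = 100, amp_endomembrane = 80,
                             background = c(n = 20, t = 20, marker = 10),
                             marker_amp = 120,
                             read_noise_sd = 2, noise = TRUE,
                             endomembrane_ratio = c(mean = 2.4, sd = 0.3),
                             ratio_truncation = 0.1,
                             lysosome_n = 8L, lysosome_r = c(2, 5),
                             golgi_width = 2L,
                             er_coverage = 0.28,
                             mito_n = 6L, mito_len = c(12, 24),
                             pixel_size_nm = 52) {
  stopifnot(image_size >= 48, cells_per_image >= 1,
            amp_pm > 0, amp_organelle > 0, amp_endomembrane > 0,
            all(background >= 0), marker_amp > 0)
  structure(as.list(environment()), class = "synthetic_params")
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# jointly truncated draws of (pm, organelle, endomembrane) true ratios with
# optional within-cell pm-organelle correlation
draw_truth_ratios <- function(n, ps, endo, correlation, lower) {
  draw <- function(k) {
    z1 <- stats::rnorm(k); z2 <- stats::rnorm(k); z3 <- stats::rnorm(k)
    cbind(pm = ps$pm_mean + ps$pm_sd * z1,
          org = ps$organelle_mean + ps$organelle_sd *
            (correlation * z1 + sqrt(1 - correlation^2) * z2),
          endo = endo[["mean"]] + endo[["sd"]] * z3)
  }
  x <- draw(n)
  while (any(bad <- apply(x < lower, 1, any))) x[bad, ] <- draw(sum(bad))
  x
}

# geometry of one cell placed at `center` (1-based rows/cols), returns masks
cell_geometry <- function(params, center, axes_px, angle, organelle) {
  s <- params$image_size
  rows <- matrix(seq_len(s), s, s)
  cols <- matrix(seq_len(s), s, s, byrow = TRUE)
  dy <- rows - center[1]
  dx <- cols - center[2]
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  q <- (u / axes_px[2])^2 + (v / axes_px[1])^2
  G <- q <= 1
  e1 <- binary_erode(G, 1L, 4L)
  e2 <- binary_erode(e1, 1L, 4L)
  outer_flank <- G & !e1
  crest <- e1 & !e2
  inner_flank <- e2 & !binary_erode(e2, 1L, 4L)
  interior <- e2                      # = the watershed basin on a clean image
  allowed <- q <= 0.6 & binary_erode(e2, 2L, 4L) # organelle placement zone

  pick_px <- function(n) {
    idx <- which(allowed)
    idx[ceiling(stats::runif(n) * length(idx))]
  }
  org <- matrix(FALSE, s, s)
  if (organelle == "lysosome") {
    ctr <- arrayInd(pick_px(params$lysosome_n), c(s, s))
    rr <- stats::runif(params$lysosome_n, params$lysosome_r[1], params$lysosome_r[2])
    for (i in seq_len(params$lysosome_n)) {
      d2 <- (rows - ctr[i, 1])^2 + (cols - ctr[i, 2])^2
      org <- org | d2 <= rr[i]^2
    }
  } else if (organelle == "golgi") {
    phi0 <- stats::runif(1, 0, 2 * pi)
    tt <- seq(phi0, phi0 + 0.7 * pi, length.out = 200)
    pr <- round(center[1] + 0.45 * axes_px[1] * sin(tt) * cos(angle) +
                  0.45 * axes_px[2] * cos(tt) * sin(angle))
    pc <- round(center[2] + 0.45 * axes_px[2] * cos(tt) * cos(angle) -
                  0.45 * axes_px[1] * sin(tt) * sin(angle))
    keep <- pr >= 1 & pr <= s & pc >= 1 & pc <= s
    org[cbind(pr[keep], pc[keep])] <- TRUE
    org <- binary_dilate(org, params$golgi_width, 8L)
  } else if (organelle == "er") {
    field <- matrix(stats::runif(s * s), s, s)
    sm <- box_blur(box_blur(field, 5L), 5L)
    cutoff <- stats::quantile(sm[allowed], 1 - params$er_coverage, names = FALSE)
    org <- sm > cutoff
  } else if (organelle == "mitochondria") {
    ctr <- arrayInd(pick_px(params$mito_n), c(s, s))
    for (i in seq_len(params$mito_n)) {
      len <- stats::runif(1, params$mito_len[1], params$mito_len[2])
      th <- stats::runif(1, 0, pi)
      st <- seq(-len / 2, len / 2, by = 0.5)
      pr <- round(ctr[i, 1] + st * sin(th))
      pc <- round(ctr[i, 2] + st * cos(th))
      keep <- pr >= 1 & pr <= s & pc >= 1 & pc <= s
      seg <- matrix(FALSE, s, s)
      seg[cbind(pr[keep], pc[keep])] <- TRUE
      org <- org | binary_dilate(seg, 1L, 8L)
    }
  }
  org <- org & allowed

  # generic endomembrane web, never overlapping the marker-positive organelle
  field <- matrix(stats::runif(s * s), s, s)
  sm <- box_blur(box_blur(field, 5L), 5L)
  cutoff <- stats::quantile(sm[allowed], 0.85, names = FALSE)
  endo <- sm > cutoff & allowed & !org

  list(ring = outer_flank | crest, crest = crest, outer_flank = outer_flank,
       inner_flank = inner_flank, interior = interior, organelle = org,
       endomembrane = endo, filled = G)
}

box_blur <- function(m, k) {
  # separable box filter with edge clamping
  half <- (k - 1L) %/% 2L
  pad_filter <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- apply(m, 2, pad_filter)
  t(apply(t(m), 2, pad_filter))
}

#' Generate one synthetic multi-channel image with ground truth
#'
#' Renders `cells_per_image` cells with the supplied per-cell true ratios
#' and returns the channel stack, the ground-truth masks and ratios, and
#' an auto-derived seed set (cell centroid seeds, a corner outside seed,
#' and a top-left cell-free background rectangle).
#'
#' Randomness is consumed from the current RNG state in two phases so that
#' callers can separate the streams: geometry first, then (only when
#' `params$noise` is on) noise. [generate_experiment()] seeds the truth,
#' geometry and noise streams independently.
#'
#' @param params A [synthetic_params()].
#' @param truth_ratios Data frame with one row per cell: `cell_id`,
#'   `pm_ratio`, `organelle_ratio`, `endo_ratio`.
#' @param organelle Organelle class to render for the marker.
#' @param noise_seed Optional integer; when given, the noise phase runs
#'   under this seed so identical truths can carry different noise.
#' @return List with `stack` ([channel_stack()]), `truth` (masks, true
#'   ratios, `background_roi`), and `seeds` ([seed_set()]).
#' @export
generate_cell_image <- function(params, truth_ratios, organelle,
                                noise_seed = NULL) {
  s <- params$image_size
  m <- params$cells_per_image
  stopifnot(nrow(truth_ratios) == m)
  bg <- params$background
  Nimg <- matrix(bg[["n"]], s, s)
  Timg <- matrix(bg[["t"]], s, s)
  Mimg <- matrix(bg[["marker"]], s, s)

  geoms <- vector("list", m)
  centers <- matrix(0, m, 2)
  for (j in seq_len(m)) {
    ctr_col <- s * (2 * j - 1) / (2 * m) + stats::runif(1, -0.02, 0.02) * s
    ctr_row <- s / 2 + stats::runif(1, -0.02, 0.02) * s
    ax <- stats::runif(2, params$axis_range[1], params$axis_range[2]) *
      (s / 2) / m
    ang <- stats::runif(1, 0, pi)
    centers[j, ] <- round(c(ctr_row, ctr_col))
    geoms[[j]] <- cell_geometry(params, centers[j, ], ax, ang, organelle)
  }
  overlap <- Reduce(`+`, lapply(geoms, function(g) g$filled))
  if (any(overlap > 1)) stop("generated cells overlap; reduce axis_range or cells_per_image",
                             call. = FALSE)

  for (j in seq_len(m)) {
    g <- geoms[[j]]
    tr <- truth_ratios[j, ]
    ringN <- params$amp_pm * (g$crest + params$flank_frac * (g$outer_flank | g$inner_flank))
    structN <- params$amp_organelle * g$organelle + params$amp_endomembrane * g$endomembrane
    Nimg <- Nimg + ringN + structN
    Timg <- Timg + tr$pm_ratio * ringN +
      tr$organelle_ratio * params$amp_organelle * g$organelle +
      tr$endo_ratio * params$amp_endomembrane * g$endomembrane
    Mimg <- Mimg + params$marker_amp * g$organelle
  }

  if (params$noise) {
    if (!is.null(noise_seed)) set.seed(noise_seed)
    shot <- function(img) {
      noisy <- stats::rpois(length(img), lambda = img) +
        stats::rnorm(length(img), 0, params$read_noise_sd)
      matrix(pmax(noisy, 0), nrow(img), ncol(img))
    }
    Nimg <- shot(Nimg); Timg <- shot(Timg); Mimg <- shot(Mimg)
  }

  roi <- c(2L, 2L, 26L, 26L)
  seeds <- seed_set(
    data.frame(cell_id = truth_ratios$cell_id,
               row = centers[, 1] - 1L, col = centers[, 2] - 1L),
    outside_seed = c(s - 3L, s - 3L),
    background_roi = roi)

  lbl <- function(field) {
    lab <- matrix(0L, s, s)
    for (j in seq_len(m)) lab[geoms[[j]][[field]]] <- truth_ratios$cell_id[j]
    lab
  }
  truth <- list(
    cell_id = truth_ratios$cell_id,
    pm_ratio = truth_ratios$pm_ratio,
    organelle_ratio = truth_ratios$organelle_ratio,
    endo_ratio = truth_ratios$endo_ratio,
    organelle = organelle,
    pm_mask = lbl("ring"), crest_mask = lbl("crest"),
    interior_mask = lbl("interior"), organelle_mask = lbl("organelle"),
    endomembrane_mask = lbl("endomembrane"),
    background_roi = roi)

  list(stack = channel_stack(Nimg, Timg, Mimg,
                             pixel_size_nm = params$pixel_size_nm),
       truth = truth, seeds = seeds)
}

#' Generate a full synthetic experiment for a packaged parameter set
#'
#' Draws per-cell true plasma-membrane and organelle ratios independently
#' from the packaged normal distributions (truncated at
#' `params$ratio_truncation`), then renders one single-cell image per cell.
#' Three separate RNG streams are derived from `seed` (truth = `seed`,
#' geometry = `seed + 1e6 + i`, noise = `seed + 2e6 + i` for image `i`), so
#' the same truths can be re-rendered with or without noise and noise can
#' be varied independently of the truth draws.
#'
#' @param cell_line `"skbr3"`, `"hela"` or `"shsy5y"`.
#' @param organelle `"lysosome"`, `"golgi"`, `"er"` or `"mitochondria"`.
#' @param n_cells Number of cells (= images); 0 gives an empty dataset.
#' @param seed Integer seed (must stay below 2^31 - 2e6 - n_cells).
#' @param params A [synthetic_params()]; defaults target the packaged
#'   acquisition conditions.
#' @param noise Override `params$noise`.
#' @param ratio_correlation Within-cell correlation between the true
#'   plasma-membrane and organelle ratios (default 0: independent draws;
#'   the dispersion of normalized ratios shrinks as it approaches 1).
#' @return An object of class `f66_dataset`: list of per-image entries
#'   (`stack`, `truth`, `seeds`) plus `cell_line`, `organelle`, `params`,
#'   `truth_table` (the drawn per-cell true ratios).
#' @export
generate_experiment <- function(cell_line, organelle, n_cells, seed,
                                params = synthetic_params(),
                                noise = NULL, ratio_correlation = 0) {
  ps <- f66_parameter_set(cell_line, organelle) # errors on unknown names
  if (!is.null(noise)) params$noise <- noise
  stopifnot(ratio_correlation >= -1, ratio_correlation <= 1)
  seed <- as.integer(seed)
  if (seed + 2e6 + n_cells >= 2^31) stop("seed too large", call. = FALSE)
  if (params$cells_per_image != 1L)
    stop("generate_experiment renders one cell per image", call. = FALSE)

  set.seed(seed) # truth stream
  draws <- draw_truth_ratios(n_cells, ps, params$endomembrane_ratio,
                             ratio_correlation, params$ratio_truncation)
  truths <- data.frame(
    cell_id = seq_len(n_cells),
    pm_ratio = draws[, "pm"],
    organelle_ratio = draws[, "org"],
    endo_ratio = draws[, "endo"])
  images <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(seed + 1e6 + i) # geometry stream
    images[[i]] <- generate_cell_image(params, truths[i, , drop = FALSE],
                                       organelle,
                                       noise_seed = seed + 2e6 + i)
  }
  structure(list(images = images, cell_line = cell_line,
                 organelle = organelle, params = params,
                 truth_table = truths, seed = seed),
            class = "f66_dataset")
}

#' @export
print.f66_dataset <- function(x, ...) {
  cat(sprintf("f66_dataset: %s / %s, %d image(s) of %d px, noise %s\n",
              x$cell_line, x$organelle, length(x$images),
              x$params$image_size, if (x$params$noise) "on" else "off"))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' One multi-page TIFF (N*, T*, marker), one seeds JSON and one truth JSON
#' per image, ready for [analyze()] or the command-line interface.
#'
#' @param dataset An [generate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$images)) {
    entry <- dataset$images[[i]]
    base <- file.path(dir, sprintf("image_%03d", i))
    stack <- entry$stack
    # noisy counts are continuous; store rounded 16-bit counts
    stack$n <- round(stack$n); stack$t <- round(stack$t)
    stack$marker <- round(stack$marker)
    write_channel_stack(stack, paste0(base, ".tif"))
    write_seed_set(entry$seeds, paste0(base, ".seeds.json"))
    jsonlite::write_json(entry$truth[c("cell_id", "pm_ratio",
                                       "organelle_ratio", "endo_ratio",
                                       "organelle")],
                         paste0(base, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
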