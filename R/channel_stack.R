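#' Aligned multi-channel intensity maps
#'
#' A `channel_stack` holds the two F66 emission-band images and an optional
#' organelle-marker image of one confocal field, all as numeric matrices of
#' identical size, together with pixel metadata. The N* band (463--527 nm)
#' and the T* band (543--589 nm) correspond to the normal and tautomer
#' excited states of the dye; their background-subtracted per-pixel ratio
#' is the dipole-potential readout.
#'
#' @param n_image Numeric matrix, N*-band intensities (detector counts).
#' @param t_image Numeric matrix, T*-band intensities.
#' @param marker_image Optional numeric matrix, organelle-marker intensities.
#' @param pixel_size_nm Physical pixel edge length in nanometres (default 52,
#'   the acquisition setting the package assumes when none is recorded).
#' @param channel_names Character labels for the channels.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(n_image, t_image, marker_image = NULL,
                          pixel_size_nm = 52,
                          channel_names = c(n = "N* 463-527nm",
                                            t = "T* 543-589nm",
                                            marker = "marker")) {
  n_image <- as_intensity_matrix(n_image, "n_image")
  t_image <- as_intensity_matrix(t_image, "t_image")
  if (!is.null(marker_image))
    marker_image <- as_intensity_matrix(marker_image, "marker_image")
  x <- structure(list(n = n_image, t = t_image, marker = marker_image,
                      pixel_size_nm = pixel_size_nm,
                      channel_names = channel_names),
                 class = "channel_stack")
  validate_channel_stack(x)
  x
}

as_intensity_matrix <- function(m, what) {
  if (!is.matrix(m)) stop(sprintf("%s must be a matrix", what), call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("channel_stack: %d x %d px (%g nm/px), marker %s\n",
              nrow(x$n), ncol(x$n), x$pixel_size_nm,
              if (is.null(x$marker)) "absent" else "present"))
  invisible(x)
}

#' Validate a channel stack
#'
#' Checks the type invariants: all present images share one height/width,
#' all intensities are finite and non-negative, and the pixel size is
#' positive.
#'
#' @param x A [channel_stack()].
#' @return `x`, invisibly; stops on violation.
#' @export
validate_channel_stack <- function(x) {
  stopifnot(inherits(x, "channel_stack"))
  dims <- dim(x$n)
  for (ch in c("t", "marker")) {
    img <- x[[ch]]
    if (is.null(img)) next
    if (!identical(dim(img), dims))
      stop(sprintf("channel '%s' is %dx%d but N* is %dx%d: all channels must share dimensions",
                   ch, nrow(img), ncol(img), dims[1], dims[2]), call. = FALSE)
  }
  for (ch in c("n", "t", "marker")) {
    img <- x[[ch]]
    if (is.null(img)) next
    if (!all(is.finite(img)))
      stop(sprintf("channel '%s' contains non-finite intensities", ch), call. = FALSE)
    if (any(img < 0))
      stop(sprintf("channel '%s' contains negative intensities", ch), call. = FALSE)
  }
  if (!is.numeric(x$pixel_size_nm) || length(x$pixel_size_nm) != 1 ||
      !is.finite(x$pixel_size_nm) || x$pixel_size_nm <= 0)
    stop("pixel_size_nm must be a single positive number", call. = FALSE)
  invisible(x)
}

read_tiff_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) # collapse trivial colour axis if present
      pg <- pg[, , 1]
    fmt <- attr(pg, "sample.format")
    bits <- attr(pg, "bits.per.sample")
    if (is.null(fmt) || identical(fmt, "uint")) {
      # undo the 0..1 normalisation so integer counts survive losslessly
      if (is.null(bits)) bits <- 16L
      pg <- round(pg * (2^bits - 1))
    }
    m <- matrix(as.numeric(pg), nrow = nrow(pg), ncol = ncol(pg))
    m
  })
}

#' Read a channel stack from TIFF files or a multi-page TIFF
#'
#' Page/file order is never guessed from metadata: `channel_map` states
#' explicitly which page (1-based) of which file carries which channel.
#' Unsigned 8/16-bit pages are returned as integer counts without loss;
#' 32-bit float pages are returned as stored.
#'
#' @param paths Character vector of TIFF paths. A single path may contain
#'   multiple pages.
#' @param channel_map Named list/vector with entries `n`, `t` and optionally
#'   `marker`. When `paths` has one element, values are page numbers; when
#'   it has several, values index into `paths` (each file single-page).
#' @param pixel_size_nm Pixel edge length in nm recorded on the stack.
#' @return A [channel_stack()].
#' @export
read_channel_stack <- function(paths, channel_map, pixel_size_nm = 52) {
  channel_map <- as.list(channel_map)
  if (is.null(channel_map$n) || is.null(channel_map$t))
    stop("channel_map must assign both the 'n' and 't' channels", call. = FALSE)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("file not found: ", paste(paths[missing], collapse = ", "), call. = FALSE)
  if (length(paths) == 1) {
    pages <- read_tiff_pages(paths)
    pick <- function(i) {
      if (i > length(pages))
        stop(sprintf("channel_map asks for page %d but file has %d page(s)",
                     i, length(pages)), call. = FALSE)
      pages[[i]]
    }
  } else {
    pick <- function(i) read_tiff_pages(paths[i])[[1]]
  }
  channel_stack(
    n_image = pick(channel_map$n),
    t_image = pick(channel_map$t),
    marker_image = if (!is.null(channel_map$marker)) pick(channel_map$marker),
    pixel_size_nm = pixel_size_nm
  )
}

#' Write a channel stack as a multi-page unsigned-integer TIFF
#'
#' Pages are written in the order N*, T*, marker (when present). Intensities
#' must be non-negative integers representable at the requested bit depth;
#' they round-trip bit-identically through [read_channel_stack()].
#'
#' @param stack A [channel_stack()].
#' @param path Output path.
#' @param bits 8 or 16 bits per sample.
#' @return The channel map describing the written page order, invisibly.
#' @export
write_channel_stack <- function(stack, path, bits = 16L) {
  validate_channel_stack(stack)
  stopifnot(bits %in% c(8L, 16L))
  imgs <- list(stack$n, stack$t)
  map <- list(n = 1L, t = 2L)
  if (!is.null(stack$marker)) {
    imgs <- c(imgs, list(stack$marker))
    map$marker <- 3L
  }
  top <- 2^bits - 1
  imgs <- lapply(imgs, function(m) {
    if (any(m != round(m)) || any(m > top))
      stop(sprintf("intensities must be integers in [0, %d] for %d-bit TIFF output",
                   top, bits), call. = FALSE)
    m / top
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = bits, compression = "none")
  invisible(map)
}

#' Write a ratio map as a 32-bit float TIFF for visual inspection
#'
#' Values are divided by `scale` to fit the float TIFF's unit range
#' (ratios above `scale` are clipped by the writer); invalid pixels are
#' written as NaN. This export is for inspection in image viewers, not a
#' lossless store.
#'
#' @param rmap A ratio map from [ratio_map()].
#' @param path Output path.
#' @param scale Divisor applied before writing (default 10).
#' @export
write_ratio_tiff <- function(rmap, path, scale = 10) {
  v <- rmap$value / scale
  v[!rmap$valid] <- NaN
  suppressWarnings(tiff::writeTIFF(v, path, bits.per.sample = 32L,
                                   compression = "none"))
  invisible(path)
}

#' Export segmentation masks as an 8-bit label TIFF
#'
#' Encoding: 0 = outside, k = interior of cell k, 255 = plasma-membrane
#' pixels (any cell).
#'
#' @param seg A segmentation from [segment_cells()].
#' @param path Output path.
#' @export
write_label_tiff <- function(seg, path) {
  lab <- seg$interior
  lab[seg$pm > 0] <- 255L
  tiff::writeTIFF(lab / 255, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}
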