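#' A named multi-channel fluorescence image
#'
#' @param channels Named list of equal-shape 2-D numeric matrices with
#'   finite, non-negative values (e.g. `nuclear_stain`, `reporter`,
#'   `soma_marker` -- any subset).
#' @param pixel_size Pixel edge length in arbitrary units (default 1).
#' @return An object of class `multi_channel_image`.
#' @export
multi_channel_image <- function(channels, pixel_size = 1) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stopf("`channels` must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stopf("all channels must be 2-D matrices")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stopf("all channels must share one shape")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (any(!is.finite(ch)) || any(ch < 0))
      stopf("channel '%s' has non-finite or negative values", nm)
  }
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "multi_channel_image")
}

# triangle threshold on a 256-bin histogram: the gray level maximizing the
# distance between the histogram and the chord from its peak to its far end
triangle_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(255L, floor((x - rng[1]) / diff(rng) * 256L)) + 1L, 256L)
  peak <- which.max(h)
  # a sensor-clipping spike in a boundary bin is not the background mode;
  # locate the peak among interior bins in that case
  if (peak == 1L && h[1] > 2L * h[2]) peak <- 1L + which.max(h[-1])
  if (peak == 256L && h[256] > 2L * h[255]) peak <- which.max(h[-256])
  tail_idx <- if (sum(h[peak:256]) - h[peak] >= sum(h[1:peak]) - h[peak])
    256L else 1L
  span <- seq(peak, tail_idx)
  dx <- tail_idx - peak
  dy <- h[tail_idx] - h[peak]
  nrm <- sqrt(dx^2 + dy^2)
  d <- abs(dy * (span - peak) - dx * (h[span] - h[peak])) / nrm
  level <- span[which.max(d)]
  rng[1] + (level - 0.5) / 256 * diff(rng)
}

#' Subtract image background
#'
#' Default (`"median"`) builds a coarse foreground mask with a triangle
#' threshold, subtracts the median of the remaining background pixels and
#' clips at zero -- idempotent up to noise on already-corrected images. If
#' everything is classified foreground, the global minimum is subtracted
#' with a warning. The method and its parameters are recorded as
#' attributes.
#'
#' @param channel 2-D numeric matrix.
#' @param method `"median"` (default), `"constant"` or `"none"`.
#' @param offset Background level for `method = "constant"`.
#' @return Corrected matrix with attributes `bg_method` and `bg_level`.
#' @export
remove_background <- function(channel, method = c("median", "constant",
                                                  "none"), offset = 0) {
  method <- match.arg(method)
  bg <- switch(method,
    none = 0,
    constant = offset,
    median = {
      thr <- triangle_threshold(channel)
      bg_px <- channel[channel <= thr]
      if (!length(bg_px)) {
        warnf("no background pixels below triangle threshold; subtracting minimum")
        min(channel)
      } else median(bg_px)
    })
  out <- pmax(channel - bg, 0)
  attr(out, "bg_method") <- method
  attr(out, "bg_level") <- bg
  out
}

# largest connected component of a logical mask (EBImage 8-connectivity)
.largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(lab[lab > 0])
  out <- matrix(as.vector(lab) == which.max(tab), nrow = nrow(mask))
  out
}

.get_channel <- function(image, source) {
  stopifnot(inherits(image, "multi_channel_image"))
  if (!source %in% names(image$channels))
    stopf("channel '%s' not present (have: %s)", source,
          paste(names(image$channels), collapse = ", "))
  image$channels[[source]]
}

.otsu_mask <- function(corrected, scale_threshold = 1, close_radius = 2L) {
  mx <- max(corrected)
  if (mx == 0) return(matrix(FALSE, nrow(corrected), ncol(corrected)))
  thr <- EBImage::otsu(EBImage::Image(corrected / mx), range = c(0, 1)) * mx
  mask <- corrected > thr * scale_threshold
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2L * close_radius + 1L, shape = "disc")
    mask <- EBImage::closing(EBImage::Image(mask * 1), brush) > 0.5
  }
  matrix(as.vector(mask), nrow = nrow(corrected))
}

#' Segment the nucleus
#'
#' Otsu's global threshold on the background-removed source channel (a
#' nuclear stain, or the reporter itself when it is predominantly nuclear),
#' followed by binary closing and retention of the largest connected
#' component. An empty result is returned as a flagged no-cell mask, never
#' an error.
#'
#' @param image A [multi_channel_image()].
#' @param source Channel to threshold (`"nuclear_stain"` or `"reporter"`).
#' @param background `"median"`, `"constant"` or `"none"`, passed to
#'   [remove_background()].
#' @param close_radius Closing brush radius in px (default 2).
#' @return Logical matrix with attribute `found` (`FALSE` when no cell).
#' @export
segment_nucleus <- function(image, source = "nuclear_stain",
                            background = "median", close_radius = 2L) {
  ch <- remove_background(.get_channel(image, source), method = background)
  mask <- .largest_component(.otsu_mask(ch, close_radius = close_radius))
  attr(mask, "found") <- any(mask)
  mask
}

#' Segment the soma
#'
#' Like [segment_nucleus()] but thresholding at a fraction of the Otsu
#' level (default 0.5) so dim cytoplasm is captured, with hole filling;
#' the nucleus mask, when given, is united in so `nucleus` is always a
#' subset of `soma`.
#'
#' @inheritParams segment_nucleus
#' @param source Channel defining the cell boundary (e.g. a soma marker or
#'   the reporter).
#' @param nucleus Optional nucleus mask to enforce containment.
#' @param threshold_fraction Fraction of the Otsu threshold used as cutoff.
#' @return Logical matrix with attribute `found`.
#' @export
segment_soma <- function(image, source = "soma_marker", nucleus = NULL,
                         background = "median", threshold_fraction = 0.5,
                         close_radius = 2L) {
  ch <- remove_background(.get_channel(image, source), method = background)
  mask <- .otsu_mask(ch, scale_threshold = threshold_fraction,
                     close_radius = close_radius)
  if (any(mask)) {
    mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
    mask <- .largest_component(matrix(as.vector(mask), nrow = nrow(ch)))
  }
  if (!is.null(nucleus)) mask <- mask | nucleus
  attr(mask, "found") <- any(mask)
  mask
}

#' Combine nucleus and soma masks into compartments
#'
#' The cytoplasm is the area inside the soma and outside the nucleus; the
#' partition identity `soma = nucleus + cytoplasm` (disjoint union) holds
#' bit-exactly. A nucleus escaping the soma is united in first.
#'
#' @param nucleus,soma Logical matrices of equal shape.
#' @return A `segmentation_masks` list with `nucleus`, `soma`, `cytoplasm`
#'   and `found`.
#' @export
segmentation_masks <- function(nucleus, soma) {
  stopifnot(is.logical(nucleus) || all(nucleus %in% c(0, 1)),
            identical(dim(nucleus), dim(soma)))
  nucleus <- nucleus == TRUE
  soma <- (soma == TRUE) | nucleus
  structure(list(nucleus = nucleus, soma = soma,
                 cytoplasm = soma & !nucleus,
                 found = any(soma)),
            class = "segmentation_masks")
}

#' Mean intensity per unit area per compartment
#'
#' Mean of the background-removed channel over each compartment mask
#' (total intensity divided by area), with areas in pixels. Empty
#' compartments yield `NA` means, flagged, never zero.
#'
#' @param image A [multi_channel_image()].
#' @param masks A [segmentation_masks()].
#' @param channel Channel name to measure.
#' @param background Background-removal method (see [remove_background()]).
#' @return Data frame `channel, compartment, mean_intensity, area_px`.
#' @export
measure_compartments <- function(image, masks, channel,
                                 background = "median") {
  stopifnot(inherits(masks, "segmentation_masks"))
  ch <- remove_background(.get_channel(image, channel), method = background)
  if (!identical(dim(ch), dim(masks$soma)))
    stopf("mask and image shapes differ")
  one <- function(compartment) {
    m <- masks[[compartment]]
    area <- sum(m)
    data.frame(channel = channel, compartment = compartment,
               mean_intensity = if (area) mean(ch[m]) else NA_real_,
               area_px = area)
  }
  do.call(rbind, lapply(c("soma", "nucleus", "cytoplasm"), one))
}

#' Per-cell compartment quantification pipeline
#'
#' Segment (nucleus from `nucleus_source`, soma from `soma_source`),
#' combine into compartments and measure every requested channel. Returns
#' zero rows with `found = FALSE` for a background-only image.
#'
#' @param image A [multi_channel_image()].
#' @param nucleus_source,soma_source Channels driving segmentation.
#' @param measure_channels Channels to quantify (default: all).
#' @param background Background-removal method used throughout.
#' @return List with `masks` and `intensities` (data frame with a
#'   `cell_found` column).
#' @export
quantify_cell <- function(image, nucleus_source = "nuclear_stain",
                          soma_source = "soma_marker",
                          measure_channels = names(image$channels),
                          background = "median") {
  nuc <- segment_nucleus(image, nucleus_source, background = background)
  if (!attr(nuc, "found")) {
    masks <- segmentation_masks(nuc, nuc)
    return(list(masks = masks,
                intensities = data.frame(channel = character(),
                                         compartment = character(),
                                         mean_intensity = numeric(),
                                         area_px = integer(),
                                         cell_found = logical())))
  }
  soma <- segment_soma(image, soma_source, nucleus = nuc,
                       background = background)
  masks <- segmentation_masks(nuc, soma)
  out <- do.call(rbind, lapply(measure_channels, function(chn)
    measure_compartments(image, masks, chn, background = background)))
  out$cell_found <- TRUE
  list(masks = masks, intensities = out)
}

#' Write a multi-channel image as a multi-page TIFF
#'
#' Channels are stored one per page as 16-bit grayscale, scaled by
#' `max_value`; [read_image_tiff()] restores the original scale. The
#' channel order is the channel-name order, which the caller must supply
#' again on reading (TIFF has no channel-name field).
#'
#' @param image A [multi_channel_image()].
#' @param path Output TIFF path.
#' @param max_value Full-scale intensity mapped to the 16-bit maximum.
#' @return Invisibly, `path`.
#' @export
write_image_tiff <- function(image, path, max_value = 65535) {
  stopifnot(inherits(image, "multi_channel_image"))
  arr <- simplify2array(image$channels)
  if (max(arr) > max_value)
    stopf("intensities exceed max_value = %s", format(max_value))
  EBImage::writeImage(EBImage::Image(arr / max_value), path,
                      type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a multi-channel image
#'
#' @param path TIFF path (one channel per page).
#' @param channel_names Names for the pages, in page order.
#' @param max_value Scale factor matching [write_image_tiff()].
#' @return A [multi_channel_image()] of real-valued grids.
#' @export
read_image_tiff <- function(path, channel_names, max_value = 65535) {
  img <- EBImage::readImage(path)
  arr <- EBImage::imageData(img) * max_value
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (dim(arr)[3] != length(channel_names))
    stopf("TIFF has %d pages but %d channel names given",
          dim(arr)[3], length(channel_names))
  multi_channel_image(setNames(
    lapply(seq_len(dim(arr)[3]), function(i) arr[, , i]), channel_names))
}
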