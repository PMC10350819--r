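#' Simulation parameters for a single-cell fluorescence image
#'
#' Geometry is a nucleus disk strictly inside a soma disk; each channel has
#' configured mean intensities above background for the nucleus and the
#' cytoplasm, over a background level with an optional linear gradient and
#' Gaussian noise.
#'
#' @param shape Image shape in pixels, `c(rows, cols)`.
#' @param soma_center,soma_radius Soma disk (px).
#' @param nucleus_center,nucleus_radius Nucleus disk (px); must lie
#'   strictly inside the soma disk.
#' @param channel_means Named list; each element a numeric vector with
#'   entries `nucleus` and `cytoplasm` (mean intensities above background).
#' @param background Scalar background level.
#' @param gradient Left-to-right linear background drift across the image
#'   (total rise, same units).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return An object of class `cell_image_sim_params`.
#' @export
cell_image_sim_params <- function(shape = c(128L, 128L),
                                  soma_center = c(64, 64), soma_radius = 40,
                                  nucleus_center = c(64, 64),
                                  nucleus_radius = 18,
                                  channel_means = list(
                                    nuclear_stain = c(nucleus = 200, cytoplasm = 0),
                                    reporter = c(nucleus = 200, cytoplasm = 100),
                                    soma_marker = c(nucleus = 150, cytoplasm = 150)),
                                  background = 10, gradient = 0,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 8))
  d <- sqrt(sum((soma_center - nucleus_center)^2))
  if (d + nucleus_radius >= soma_radius)
    stopf("nucleus disk must lie strictly inside the soma disk")
  for (nm in names(channel_means)) {
    v <- channel_means[[nm]]
    if (!all(c("nucleus", "cytoplasm") %in% names(v)) || any(v < 0))
      stopf("channel_means[['%s']] needs non-negative 'nucleus' and 'cytoplasm'",
            nm)
  }
  assert_scalar_number(background, "background", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(list(shape = as.integer(shape), soma_center = soma_center,
                 soma_radius = soma_radius,
                 nucleus_center = nucleus_center,
                 nucleus_radius = nucleus_radius,
                 channel_means = channel_means, background = background,
                 gradient = gradient, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cell_image_sim_params")
}

.disk_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius^2
}

#' Render a synthetic single-cell image with ground-truth masks
#'
#' Channels are rendered as nucleus/cytoplasm disks over a (possibly
#' tilted) background plane plus Gaussian noise, truncated at zero. An
#' empty image (all `channel_means` zero) exercises the no-cell path of
#' the segmentation.
#'
#' @param params A [cell_image_sim_params()].
#' @return List with `image` (a [multi_channel_image()]), `masks` (the
#'   ground-truth [segmentation_masks()]) and `params`.
#' @export
sim_cell_image <- function(params) {
  stopifnot(inherits(params, "cell_image_sim_params"))
  soma <- .disk_mask(params$shape, params$soma_center, params$soma_radius)
  nuc <- .disk_mask(params$shape, params$nucleus_center,
                    params$nucleus_radius)
  truth <- segmentation_masks(nuc, soma)
  grad <- matrix(seq(0, params$gradient, length.out = params$shape[2]),
                 params$shape[1], params$shape[2], byrow = TRUE)
  channels <- with_seed(params$seed, {
    lapply(params$channel_means, function(v) {
      img <- matrix(params$background, params$shape[1], params$shape[2]) +
        grad
      img[truth$cytoplasm] <- img[truth$cytoplasm] + v[["cytoplasm"]]
      img[truth$nucleus] <- img[truth$nucleus] + v[["nucleus"]]
      if (params$noise_sd > 0)
        img <- img + rnorm(length(img), 0, params$noise_sd)
      pmax(img, 0)
    })
  })
  list(image = multi_channel_image(channels), masks = truth,
       params = params)
}
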