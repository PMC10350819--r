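test_that("remove_background zeroes a flat image and recovers a disk", {
  flat <- matrix(7, 32, 32)
  out <- remove_background(flat)
  expect_true(all(out == 0))

  sim <- sim_cell_image(cell_image_sim_params(
    shape = c(64, 64), soma_center = c(32, 32), soma_radius = 20,
    nucleus_center = c(32, 32), nucleus_radius = 8,
    channel_means = list(reporter = c(nucleus = 100, cytoplasm = 100)),
    background = 10, noise_sd = 0))
  corr <- remove_background(sim$image$channels$reporter)
  expect_equal(max(abs(corr[!sim$masks$soma])), 0)
  expect_equal(unique(corr[sim$masks$soma]), 100)

  # idempotence on an already-corrected image
  again <- remove_background(corr)
  expect_equal(as.numeric(again), as.numeric(corr), tolerance = 1e-8)
})

test_that("segmentation recovers synthetic geometry with high overlap", {
  sim <- sim_cell_image(cell_image_sim_params(noise_sd = 0))
  nuc <- segment_nucleus(sim$image, "nuclear_stain")
  soma <- segment_soma(sim$image, "soma_marker", nucleus = nuc)
  jaccard <- function(a, b) sum(a & b) / sum(a | b)
  expect_gte(jaccard(nuc, sim$masks$nucleus), 0.9)
  expect_gte(jaccard(soma, sim$masks$soma), 0.9)
  expect_true(all(soma[nuc]))      # nucleus contained in soma
})

test_that("background-only images raise the no-cell flag", {
  empty <- multi_channel_image(list(
    nuclear_stain = matrix(5, 48, 48), soma_marker = matrix(5, 48, 48)))
  nuc <- segment_nucleus(empty, "nuclear_stain")
  expect_false(attr(nuc, "found"))
  q <- quantify_cell(empty)
  expect_equal(nrow(q$intensities), 0L)
  expect_false(q$masks$found)
})

test_that("largest connected component wins with two nuclei", {
  ch <- matrix(0, 64, 64)
  ch[10:20, 10:20] <- 200    # 11x11
  ch[40:44, 40:44] <- 200    # 5x5
  img <- multi_channel_image(list(nuclear_stain = ch))
  nuc <- segment_nucleus(img, "nuclear_stain", background = "none",
                         close_radius = 0L)
  expect_true(all(nuc[10:20, 10:20]))
  expect_false(any(nuc[40:44, 40:44]))
})

test_that("mask partition identity holds bit-exactly", {
  set.seed(5)
  for (i in 1:20) {
    sim <- sim_cell_image(cell_image_sim_params(
      soma_radius = 30 + i, nucleus_radius = 10 + (i %% 8),
      noise_sd = 5, seed = i))
    nuc <- segment_nucleus(sim$image, "nuclear_stain")
    soma <- segment_soma(sim$image, "soma_marker", nucleus = nuc)
    m <- segmentation_masks(nuc, soma)
    expect_identical(m$soma, m$nucleus | m$cytoplasm)
    expect_false(any(m$nucleus & m$cytoplasm))
  }
})

test_that("measure_compartments reports per-unit-area means", {
  sim <- sim_cell_image(cell_image_sim_params(noise_sd = 0))
  m <- sim$masks
  # uniform channel -> all three means equal
  uni <- multi_channel_image(list(x = matrix(42, 128, 128)))
  res <- measure_compartments(uni, m, "x", background = "none")
  expect_true(all(res$mean_intensity == 42))

  # nucleus 200 / cytoplasm 100 -> ratio 2 after background subtraction
  res2 <- measure_compartments(sim$image, m, "reporter")
  nuc_mean <- res2$mean_intensity[res2$compartment == "nucleus"]
  cyt_mean <- res2$mean_intensity[res2$compartment == "cytoplasm"]
  expect_equal(nuc_mean / cyt_mean, 2, tolerance = 0.02)

  # soma mean is the exact area-weighted mean of nucleus and cytoplasm
  soma_mean <- res2$mean_intensity[res2$compartment == "soma"]
  areas <- res2$area_px
  names(areas) <- res2$compartment
  expect_equal(soma_mean,
               (areas[["nucleus"]] * nuc_mean +
                  areas[["cytoplasm"]] * cyt_mean) /
                 (areas[["nucleus"]] + areas[["cytoplasm"]]))

  # empty compartment flagged absent, not zero
  empty_masks <- segmentation_masks(m$nucleus, m$nucleus)
  res3 <- measure_compartments(sim$image, empty_masks, "reporter")
  expect_true(is.na(res3$mean_intensity[res3$compartment == "cytoplasm"]))
})

test_that("intensities are background-invariant and gain-equivariant", {
  base <- cell_image_sim_params(noise_sd = 0, background = 10)
  sim_lo <- sim_cell_image(base)
  hi <- base; hi$background <- 60
  sim_hi <- sim_cell_image(hi)
  q_lo <- quantify_cell(sim_lo$image)$intensities
  q_hi <- quantify_cell(sim_hi$image)$intensities
  expect_equal(q_hi$mean_intensity, q_lo$mean_intensity, tolerance = 1e-6)

  gained <- multi_channel_image(lapply(sim_lo$image$channels, `*`, 3))
  q_g <- quantify_cell(gained)$intensities
  expect_equal(q_g$mean_intensity, 3 * q_lo$mean_intensity,
               tolerance = 1e-6)
})

test_that("TIFF round trip preserves channels and scale", {
  sim <- sim_cell_image(cell_image_sim_params(shape = c(48L, 48L),
                                              soma_radius = 16,
                                              nucleus_radius = 6,
                                              noise_sd = 2, seed = 9))
  path <- tempfile(fileext = ".tiff")
  write_image_tiff(sim$image, path)
  back <- read_image_tiff(path, names(sim$image$channels))
  for (nm in names(sim$image$channels))
    expect_equal(back$channels[[nm]], sim$image$channels[[nm]],
                 tolerance = 1)   # 16-bit quantization
})

test_that("simulator rejects a nucleus escaping the soma", {
  expect_error(cell_image_sim_params(soma_radius = 20,
                                     nucleus_center = c(80, 80),
                                     nucleus_radius = 10),
               "strictly inside")
})
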