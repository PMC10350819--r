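#' Build a gel lane from band measurements
#'
#' A lane holds the bands of one RT-PCR reaction separated on an agarose
#' gel: exactly one PE-skipped band and zero or more PE-included bands, each
#' with a background-subtracted intensity (arbitrary units, as measured in
#' e.g. FIJI) and a fragment length in bp.
#'
#' @param lane_id Lane identifier.
#' @param intensity Numeric vector of band intensities (\eqn{\ge 0}).
#' @param length_bp Numeric vector of fragment lengths (> 0).
#' @param isoform_label Character vector over `{"inclusion", "skip"}`.
#' @param isoform_name Optional free-text names (e.g. `"PE-included 3a-L"`).
#' @return A `gel_lane` object (data frame of bands plus lane id).
#' @export
gel_lane <- function(lane_id, intensity, length_bp, isoform_label,
                     isoform_name = NULL) {
  n <- length(intensity)
  if (length(length_bp) != n || length(isoform_label) != n)
    stopf("intensity, length_bp and isoform_label must have equal length")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stopf("band intensities must be finite and >= 0")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stopf("band lengths must be finite and > 0")
  if (!all(isoform_label %in% c("inclusion", "skip")))
    stopf("isoform_label entries must be 'inclusion' or 'skip'")
  if (sum(isoform_label == "skip") > 1L)
    stopf("lane '%s' must contain at most one skip band (found %d)",
          lane_id, sum(isoform_label == "skip"))
  bands <- data.frame(
    lane_id = as.character(lane_id),
    isoform_label = isoform_label,
    isoform_name = isoform_name %||% isoform_label,
    intensity = as.numeric(intensity),
    length_bp = as.numeric(length_bp))
  structure(list(lane_id = as.character(lane_id), bands = bands),
            class = "gel_lane")
}

#' Length-normalized gel PSI
#'
#' Intercalating dyes stain double-stranded DNA in proportion to its mass,
#' so band intensity is proportional to (molar amount x fragment length).
#' Dividing each intensity by its fragment length recovers molar
#' proportions, giving
#' \deqn{\Psi = \frac{\sum_i I_{inc,i}/L_{inc,i}}
#'   {\sum_i I_{inc,i}/L_{inc,i} + I_{skip}/L_{skip}}}
#' which reduces to the familiar one- and two-inclusion-band forms. The
#' result is invariant to rescaling all intensities by any positive gain.
#'
#' @param lane A [gel_lane()].
#' @return A [psi_value()] with `method = "gel"`; undefined (flagged) when
#'   every band has zero intensity.
#' @export
gel_psi <- function(lane) {
  stopifnot(inherits(lane, "gel_lane"))
  b <- lane$bands
  if (!any(b$isoform_label == "skip"))
    stopf("lane '%s' has no skip band; PSI requires one", lane$lane_id)
  if (all(b$intensity == 0))
    return(psi_value(NA_real_, "gel", components = list(bands = b)))
  molar <- b$intensity / b$length_bp
  inc <- sum(molar[b$isoform_label == "inclusion"])
  skp <- molar[b$isoform_label == "skip"]
  psi_value(inc / (inc + skp), "gel", components = list(bands = b))
}

#' Read a band-intensity table and compute per-lane gel PSI
#'
#' Expects CSV columns `lane_id, isoform_label, isoform_name, intensity,
#' length_bp`.
#'
#' @param path CSV file path.
#' @return A data frame with one row per lane: `lane_id`, `psi`,
#'   `undefined`.
#' @export
gel_psi_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lane_id", "isoform_label", "intensity", "length_bp")
  if (!all(need %in% names(tab)))
    stopf("band table must have columns: %s", paste(need, collapse = ", "))
  res <- lapply(split(tab, tab$lane_id), function(d) {
    p <- gel_psi(gel_lane(d$lane_id[1], d$intensity, d$length_bp,
                          d$isoform_label,
                          d$isoform_name %||% NULL))
    data.frame(lane_id = d$lane_id[1], psi = p$psi, undefined = p$undefined)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate a gel lane under the mass-proportional staining model
#'
#' Band intensity is `molar_amount * length_bp * gain` plus Gaussian noise,
#' truncated at zero. With zero noise, [gel_psi()] on the result recovers
#' the molar inclusion fraction exactly.
#'
#' @param molar_amounts Positive molar amounts per isoform (zero amounts
#'   produce no band, mirroring an absent isoform).
#' @param lengths_bp Fragment lengths in bp.
#' @param isoform_label Labels over `{"inclusion", "skip"}` parallel to
#'   `molar_amounts`.
#' @param gain Detector gain (arbitrary units per mass unit).
#' @param noise_sd Gaussian noise standard deviation on intensities.
#' @param lane_id Lane identifier.
#' @param seed Integer seed.
#' @return A [gel_lane()] with a `truth` attribute holding the molar
#'   inclusion fraction.
#' @export
sim_gel <- function(molar_amounts, lengths_bp, isoform_label,
                    gain = 1, noise_sd = 0, lane_id = "sim", seed = 1L) {
  if (any(molar_amounts < 0) || any(lengths_bp <= 0))
    stopf("molar amounts must be >= 0 and lengths > 0")
  stopifnot(length(molar_amounts) == length(lengths_bp),
            length(molar_amounts) == length(isoform_label))
  assert_scalar_number(gain, "gain", lower = 1e-12)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  keep <- molar_amounts > 0
  intensity <- molar_amounts[keep] * lengths_bp[keep] * gain
  intensity <- with_seed(seed,
    pmax(intensity + rnorm(length(intensity), 0, noise_sd), 0))
  lane <- gel_lane(lane_id, intensity, lengths_bp[keep],
                   isoform_label[keep])
  inc <- sum(molar_amounts[isoform_label == "inclusion"])
  attr(lane, "truth") <- list(
    molar_inclusion = inc / sum(molar_amounts))
  lane
}
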