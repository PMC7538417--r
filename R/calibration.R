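#' Calibration settings for a run
#'
#' Bundles the camera dark-noise image, the per-channel flat-field image,
#' per-channel axial chromatic shifts, and the axial distance correction
#' factor. The axial factor rescales the nominal section spacing
#' (`corrected spacing = nominal_z_spacing * axial_factor`) to undo the
#' apparent stretching of round objects along the optical axis seen on
#' widefield systems; it is the only Z spacing used downstream by extrusion
#' and volume computation. This module applies given calibration values;
#' estimating them (e.g. from bead images) is up to the user.
#'
#' @param dark_noise_image 2D matrix of camera counts, or NULL for 0.
#' @param flatfield_image 2D matrix (same XY shape as the data), or NULL to
#'   skip flat-field correction.
#' @param z_shift integer axial chromatic shift in optical sections
#'   (applied per channel via [shift_channel_z()]).
#' @param axial_factor dimensionless axial distance correction (> 0).
#' @param nominal_z_spacing nominal section spacing in micrometres (> 0).
#' @return a `calibration_config` object.
#' @export
calibration_config <- function(dark_noise_image = NULL,
                               flatfield_image = NULL,
                               z_shift = 0L,
                               axial_factor = 1,
                               nominal_z_spacing = 0.1) {
  if (!is.numeric(axial_factor) || axial_factor <= 0) {
    stop("axial_factor must be > 0")
  }
  if (!is.numeric(nominal_z_spacing) || nominal_z_spacing <= 0) {
    stop("nominal_z_spacing must be > 0")
  }
  structure(
    list(
      dark_noise_image = dark_noise_image,
      flatfield_image = flatfield_image,
      z_shift = as.integer(z_shift),
      axial_factor = axial_factor,
      nominal_z_spacing = nominal_z_spacing
    ),
    class = "calibration_config"
  )
}

#' Corrected axial section spacing
#'
#' @param config a `calibration_config`.
#' @return `nominal_z_spacing * axial_factor`, in micrometres.
#' @export
corrected_z_spacing <- function(config) {
  config$nominal_z_spacing * config$axial_factor
}

#' Dark-noise subtraction and flat-field correction
#'
#' Subtracts the dark-noise image from every section, then divides by the
#' normalized flat-field image `norm_flat = (flat - dark) / mean(flat - dark)`
#' (which has mean exactly 1). Negative values after dark subtraction are
#' clamped to 0 because camera counts are non-negative. When the config has
#' no flat-field image, only dark subtraction (if any) is applied.
#'
#' @param raw an `image_stack` of raw counts.
#' @param config a `calibration_config`.
#' @return corrected `image_stack`.
#' @export
correct_flatfield <- function(raw, config) {
  d <- dim(raw$data)
  dark <- config$dark_noise_image
  flat <- config$flatfield_image
  if (is.null(dark)) dark <- matrix(0, d[1L], d[2L])
  if (!all(dim(dark) == d[1:2])) {
    stop("dark-noise image does not match stack XY dimensions")
  }
  out <- raw$data - as.vector(dark)  # recycles dark over sections (col-major)
  out[out < 0] <- 0
  if (!is.null(flat)) {
    if (!all(dim(flat) == d[1:2])) {
      stop("flat-field image does not match stack XY dimensions")
    }
    fd <- flat - dark
    m <- mean(fd)
    if (m <= 0) stop("degenerate calibration: flat minus dark has no signal")
    norm_flat <- fd / m
    if (any(norm_flat <= 0)) {
      stop("degenerate calibration: non-positive normalized flat-field pixels")
    }
    out <- out / as.vector(norm_flat)
  }
  image_stack(out, raw$pixel_size, raw$z_spacing, raw$sections)
}

#' Axial chromatic shift of a channel
#'
#' Shifts the stack by an integer number of optical sections: section `i`
#' of the output is section `i + n_sections_shift` of the input (a positive
#' shift moves content towards lower section indices). Planes
#' shifted out of range are dropped and the output's `sections` field keeps
#' the original acquisition indices of the surviving planes, so all
#' channels can later be cropped to their common Z overlap.
#'
#' @param stack an `image_stack`.
#' @param n_sections_shift integer shift (sign = direction along Z).
#' @return shifted (possibly shallower) `image_stack`.
#' @export
shift_channel_z <- function(stack, n_sections_shift) {
  n <- n_sections(stack)
  s <- as.integer(n_sections_shift)
  if (abs(s) >= n) stop("empty overlap: |shift| >= stack depth")
  if (s == 0L) return(stack)
  idx <- seq_len(n) + s
  keep <- idx >= 1L & idx <= n
  image_stack(stack$data[, , idx[keep], drop = FALSE],
              stack$pixel_size, stack$z_spacing,
              sections = stack$sections[seq_len(n)][keep])
}

#' Crop stacks to their common Z overlap
#'
#' After per-channel axial shifts, channels cover different original
#' section ranges; this keeps only sections present in every stack.
#'
#' @param stacks list of `image_stack`.
#' @return list of cropped `image_stack` with identical `sections`.
#' @export
crop_common_z <- function(stacks) {
  common <- Reduce(intersect, lapply(stacks, function(s) s$sections))
  if (length(common) == 0L) stop("empty overlap: channels share no sections")
  lapply(stacks, function(s) {
    keep <- s$sections %in% common
    image_stack(s$data[, , keep, drop = FALSE], s$pixel_size, s$z_spacing,
                sections = s$sections[keep])
  })
}
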