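#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults. Where a
#' parameter has an established value from practice on fission yeast
#' widefield stacks, that value is the default: nuclear linking distance
#' 2.0 um, centroid drift limit 3.0 um, minimum 5 sections per nucleus,
#' circularity cutoff 0.6, nuclear dilation 0.1 um, aspect-ratio window
#' [0.8, 1.2], watershed separator 20 px on the external-import path.
#'
#' @param ... named overrides of any default.
#' @return a `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    pixel_size_um = 0.1071,
    nominal_z_spacing_um = 0.1,
    axial_factor = 0.65,
    z_shift_nuclear = 0L,        # axial chromatic shift, sections
    # nuclear 2D segmentation
    nuc_blur_sigma = 1,
    nuc_unsharp_radius = 2,
    nuc_unsharp_weight = 0.6,
    nuc_smooth_sigma = 1,
    min_circularity = 0.6,
    nuc_min_area_um2 = 0.2,
    dilation_um = 0.1,
    fit_ellipses = TRUE,
    # nuclear 3D grouping
    link_dist_um = 2.0,
    drift_max_um = 3.0,
    min_sections = 5L,
    max_gap = 2L,
    # whole-cell 2D segmentation
    cell_blur_sigma = 2,
    cell_unsharp_radius = 4,
    cell_unsharp_weight = 0.6,
    above_focus = FALSE,
    separator_size = -1L,        # native path: watershed off by default
    separator_size_import = 20L, # external-import path
    gap_threshold_px2 = 9L,
    periphery_margin_px = 10L,
    min_solidity = NULL,         # optional solidity filter, NULL = off
    cell_min_area_px = 200L,
    # reconstruction & filters
    spur_prune = TRUE,
    reassign_midplanes = TRUE,
    aspect_bounds = c(0.8, 1.2),
    exclude_region_ids = integer()
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path file path.
#' @return for `read_config`, a `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals[!vapply(vals, is.null, logical(1))])
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full reconstruction pipeline
#'
#' End-to-end driver: axial correction of the Z spacing, nuclear 2D
#' segmentation and 3D grouping, whole-cell 2D segmentation (native
#' brightfield chain, or imported external midplane labels), optional
#' re-assignment of each cell's extrusion midplane to its nucleus's
#' midplane, spherical extrusion of every cell, nucleus-cell pairing and
#' the full morphometry table.
#'
#' @param brightfield brightfield `image_stack`, or NULL when
#'   `external_labels` is given.
#' @param nuclear nuclear-marker `image_stack`.
#' @param config a `run_config`.
#' @param external_labels optional integer label matrix of externally
#'   produced midplane segmentations (switches the import path).
#' @param external_midplane_index section index of the external midplanes
#'   (defaults to the nuclear stack's middle section).
#' @param channels named list of fluorescence `image_stack`s for intensity
#'   extraction.
#' @return a `sphex_run` list: regions, nuclei, cell_stacks, records
#'   (all pairs), filtered (quality-filtered records), log.
#' @export
run_pipeline <- function(brightfield = NULL, nuclear, config = default_config(),
                         external_labels = NULL,
                         external_midplane_index = NULL, channels = list()) {
  if (is.null(brightfield) && is.null(external_labels)) {
    stop("either a brightfield stack or external midplane labels are required")
  }
  if (!is.null(brightfield) && !is.null(external_labels)) {
    stop("brightfield stack and external labels are mutually exclusive")
  }
  z_corr <- config$nominal_z_spacing_um * config$axial_factor
  log <- list()

  if (config$z_shift_nuclear != 0L) {
    nuclear <- shift_channel_z(nuclear, config$z_shift_nuclear)
  }
  nuclear$z_spacing <- z_corr

  regs_2d <- segment_nuclei_2d(
    nuclear,
    blur_sigma = config$nuc_blur_sigma,
    unsharp_radius = config$nuc_unsharp_radius,
    unsharp_weight = config$nuc_unsharp_weight,
    smooth_sigma = config$nuc_smooth_sigma,
    min_circularity = config$min_circularity,
    min_area_um2 = config$nuc_min_area_um2,
    dilation_um = config$dilation_um,
    fit_ellipses = config$fit_ellipses
  )
  grouping <- group_nuclei(
    regs_2d,
    link_dist = config$link_dist_um, drift_max = config$drift_max_um,
    min_sections = config$min_sections, pixel_size = nuclear$pixel_size,
    z_spacing = z_corr, max_gap = config$max_gap
  )
  nuclei <- grouping$nuclei
  log$n_nuclei <- length(nuclei)
  log$nuclei_excluded <- grouping$exclusions

  if (is.null(external_labels)) {
    brightfield$z_spacing <- z_corr
    seg <- segment_cells(
      brightfield,
      blur_sigma = config$cell_blur_sigma,
      unsharp_radius = config$cell_unsharp_radius,
      unsharp_weight = config$cell_unsharp_weight,
      above_focus = config$above_focus,
      separator_size = config$separator_size,
      gap_threshold = config$gap_threshold_px2,
      margin = config$periphery_margin_px,
      min_solidity = config$min_solidity,
      min_area_px = config$cell_min_area_px
    )
    regions <- seg$regions
    midplane_default <- seg$focus_index
    log$focus_index <- seg$focus_index
    log$band_halfwidth <- seg$band_halfwidth
    n_total <- n_sections(brightfield)
  } else {
    regions <- import_external_midplanes(external_labels)
    n_total <- n_sections(nuclear)
    midplane_default <- external_midplane_index %||% round(n_total / 2)
    if (config$separator_size_import >= 0 && length(regions) > 0L) {
      shape <- dim(external_labels)
      mask <- matrix(FALSE, shape[1L], shape[2L])
      for (r in regions) mask[r$pixels] <- TRUE
      mask <- split_touching(mask, config$separator_size_import)
      regions <- label_regions(mask, midplane_default)
    }
    regions <- lapply(regions, smooth_fill,
                      gap_threshold = config$gap_threshold_px2)
    regions <- exclude_periphery(regions, config$periphery_margin_px,
                                 dim(external_labels))
  }
  if (length(config$exclude_region_ids) > 0) {
    regions <- regions[setdiff(seq_along(regions), config$exclude_region_ids)]
  }
  log$n_cell_regions <- length(regions)

  # optional per-cell midplane re-assignment from the paired nucleus
  midplanes <- rep(as.integer(midplane_default), length(regions))
  if (config$reassign_midplanes && length(nuclei) > 0L) {
    for (i in seq_along(regions)) {
      mid <- regions[[i]]
      hits <- which(vapply(nuclei, function(nm) {
        p <- c(round(nm$mean_centroid[2L]), round(nm$mean_centroid[1L]))
        any(mid$pixels[, 1L] == p[1L] & mid$pixels[, 2L] == p[2L])
      }, logical(1)))
      if (length(hits) == 1L) {
        midplanes[i] <- reassign_midplane(
          mid, nuclei[[hits]]$midplane_index, n_total
        )$midplane_index
      }
    }
  }

  ex <- extrude_all(regions, midplanes, n_total,
                    pixel_size = nuclear$pixel_size, z_spacing = z_corr,
                    prune = config$spur_prune)
  cell_stacks <- ex$stacks
  log$extrusion_failures <- ex$failures
  log$n_cells <- length(cell_stacks)

  pairing <- pair_nuclei_cells(cell_stacks, nuclei)
  # map pairing's positional cell ids back to region indices
  if (nrow(pairing$pairs) > 0) {
    pairing$pairs$cell_region <- as.integer(names(cell_stacks))[pairing$pairs$cell]
  }
  records <- cell_records(cell_stacks, nuclei, pairing, channels,
                          aspect_bounds = config$aspect_bounds)
  log$pairing_exclusions <- pairing$exclusions
  log$n_records <- nrow(records)
  filtered <- filter_records(records)
  log$n_filtered <- nrow(filtered)

  structure(
    list(regions = regions, midplanes = midplanes, nuclei = nuclei,
         cell_stacks = cell_stacks, records = records, filtered = filtered,
         config = config, log = log),
    class = "sphex_run"
  )
}

#' @export
print.sphex_run <- function(x, ...) {
  cat(sprintf(
    "<sphex_run> %d cell regions, %d nuclei, %d reconstructions, %d paired records (%d after filters)\n",
    length(x$regions), length(x$nuclei), length(x$cell_stacks),
    nrow(x$records), nrow(x$filtered)))
  invisible(x)
}
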