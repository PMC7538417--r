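#' Read a TIFF Z-stack
#'
#' Reads a multi-page TIFF into one or more `image_stack`s. Multi-channel
#' stacks are assumed channel-interleaved per section (c1 z1, c2 z1, c1
#' z2, ...), the convention used by [write_stack()].
#'
#' @param path TIFF file path.
#' @param pixel_size,z_spacing voxel geometry, micrometres.
#' @param n_channels number of interleaved channels (default 1).
#' @return an `image_stack`, or a list of them when `n_channels > 1`.
#' @export
read_stack <- function(path, pixel_size, z_spacing, n_channels = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop extra colour planes
    p
  })
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    stop("inconsistent page dimensions in ", path, ": ",
         paste(unique(shapes), collapse = " vs "))
  }
  if (length(pages) %% n_channels != 0L) {
    stop("page count ", length(pages), " is not a multiple of n_channels = ",
         n_channels)
  }
  if (n_channels == 1L) {
    return(image_stack(pages, pixel_size, z_spacing))
  }
  lapply(seq_len(n_channels), function(ch) {
    image_stack(pages[seq(ch, length(pages), by = n_channels)],
                pixel_size, z_spacing)
  })
}

#' Write an `image_stack` (or several channels) as a multi-page TIFF
#'
#' Intensities are scaled to the stack maximum and written as 16-bit
#' pages; multiple channels are interleaved per section.
#'
#' @param stacks an `image_stack` or list of them (equal depth).
#' @param path output path.
#' @param scale common intensity scale (default: max over stacks).
#' @return the path, invisibly.
#' @export
write_stack <- function(stacks, path, scale = NULL) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  if (is.null(scale)) scale <- max(vapply(stacks, function(s) max(s$data),
                                          numeric(1)))
  if (scale <= 0) scale <- 1
  ns <- n_sections(stacks[[1L]])
  pages <- list()
  for (k in seq_len(ns)) {
    for (s in stacks) {
      pages[[length(pages) + 1L]] <- pmin(pmax(s$data[, , k] / scale, 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a 3D label image of reconstructions as a 16-bit TIFF stack
#'
#' One label per `region_stack` (its position in the list); later stacks
#' overwrite earlier ones where reconstructions overlap.
#'
#' @param stacks list of `region_stack`.
#' @param shape integer c(rows, cols).
#' @param n_total total number of sections.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_label_stack <- function(stacks, shape, n_total, path) {
  pages <- lapply(seq_len(n_total), function(k) {
    matrix(0, shape[1L], shape[2L])
  })
  for (i in seq_along(stacks)) {
    for (r in stacks[[i]]$regions) {
      pages[[r$section]][r$pixels] <- i
    }
  }
  pages <- lapply(pages, function(p) p / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 2D label mask (16-bit TIFF or PNG-like) written by this package
#' @param path file path.
#' @return integer matrix of labels.
#' @export
read_label_mask <- function(path) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  round(p * 65535)
}

#' Write all outputs of a pipeline run
#'
#' Writes the midplane label mask, the 3D cell and nucleus label stacks,
#' the nuclei / records / filtered CSV tables and a YAML run log (config
#' echo plus per-stage counts and exclusion reasons).
#'
#' @param run a `sphex_run` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @param shape integer c(rows, cols) of the field.
#' @param n_total total number of sections.
#' @return out_dir, invisibly.
#' @export
write_outputs <- function(run, out_dir, shape, n_total) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  # midplane 2D label mask
  mid <- matrix(0, shape[1L], shape[2L])
  for (i in seq_along(run$regions)) mid[run$regions[[i]]$pixels] <- i
  tiff::writeTIFF(mid / 65535, file.path(out_dir, "midplane_labels.tif"),
                  bits.per.sample = 16L)
  write_label_stack(run$cell_stacks, shape, n_total,
                    file.path(out_dir, "cells_3d.tif"))
  write_label_stack(lapply(run$nuclei, function(n) n$stack), shape, n_total,
                    file.path(out_dir, "nuclei_3d.tif"))
  nuclei_df <- if (length(run$nuclei)) {
    do.call(rbind, lapply(seq_along(run$nuclei), function(i) {
      nm <- run$nuclei[[i]]
      data.frame(
        id = i, midplane_index = nm$midplane_index,
        centroid_x_px = nm$mean_centroid[1L],
        centroid_y_px = nm$mean_centroid[2L],
        n_sections = nm$n_regions,
        volume_um3 = stack_volume(nm$stack),
        surface_um2 = stack_surface(nm$stack)
      )
    }))
  } else {
    data.frame(id = integer(), midplane_index = integer(),
               centroid_x_px = numeric(), centroid_y_px = numeric(),
               n_sections = integer(), volume_um3 = numeric(),
               surface_um2 = numeric())
  }
  utils::write.csv(nuclei_df, file.path(out_dir, "nuclei.csv"),
                   row.names = FALSE)
  utils::write.csv(run$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(run$filtered, file.path(out_dir, "records_filtered.csv"),
                   row.names = FALSE)
  log <- run$log
  log$config <- unclass(run$config)
  log$nuclei_excluded <- if (nrow(log$nuclei_excluded)) {
    as.list(table(log$nuclei_excluded$reason))
  } else NULL
  log$pairing_exclusions <- if (nrow(log$pairing_exclusions)) {
    as.list(table(log$pairing_exclusions$reason))
  } else NULL
  log$extrusion_failures <- nrow(log$extrusion_failures)
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(out_dir)
}
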