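#' Most in-focus optical section of a brightfield stack
#'
#' The in-focus section of a brightfield image of a flat cell layer is the
#' one whose pixel-intensity standard deviation is minimal: away from focus
#' the dark boundary bands around cells grow and inflate the contrast.
#' Ties break to the lower index.
#'
#' @param stack brightfield `image_stack`.
#' @return integer section index.
#' @export
find_focus <- function(stack) {
  n <- n_sections(stack)
  if (n < 2L) {
    warning("single-section stack: focus set to 1")
    return(1L)
  }
  sds <- vapply(seq_len(n), function(k) stats::sd(stack$data[, , k]),
                numeric(1))
  which.min(sds)
}

#' Boundary-band map from the defocused sections
#'
#' For every section on one side of the focus (below it by default), the
#' section is enhanced (Gaussian blur + unsharp mask) and Otsu-binarized;
#' the mean of these binaries is a grayscale map in which cell boundary
#' bands - dark in every defocused section - appear as valleys, while
#' cytoplasm and background stay bright.
#'
#' @param stack brightfield `image_stack`.
#' @param focus focus section index from [find_focus()].
#' @param blur_sigma,unsharp_radius,unsharp_weight enhancement parameters.
#' @param above_focus use the sections above the focus instead (stacks
#'   acquired in the opposite direction).
#' @return a `boundary_map` object: list(grid, focus_index, band_halfwidth).
#' @export
boundary_map <- function(stack, focus, blur_sigma = 2, unsharp_radius = 4,
                         unsharp_weight = 0.6, above_focus = FALSE) {
  n <- n_sections(stack)
  idx <- if (above_focus) seq_len(n)[seq_len(n) > focus]
         else seq_len(n)[seq_len(n) < focus]
  if (length(idx) == 0L) {
    stop(paste0(
      "no sections ", if (above_focus) "above" else "below", " the focus; ",
      "check the stack orientation (see `above_focus`)"
    ))
  }
  acc <- matrix(0, dim(stack$data)[1L], dim(stack$data)[2L])
  for (k in idx) {
    enh <- unsharp_mask(gaussian_blur(stack$data[, , k], blur_sigma),
                        unsharp_radius, unsharp_weight)
    acc <- acc + binarize_otsu(enh)
  }
  structure(
    list(grid = acc / length(idx), focus_index = focus,
         band_halfwidth = NA_real_),
    class = "boundary_map"
  )
}

#' Initial whole-cell regions from a boundary map
#'
#' Otsu-binarizes the boundary map; the dark boundary bands become
#' background, and connected bright components fully enclosed by bands
#' (i.e. not touching the image border, which the sea of background
#' always does) are candidate cell interiors. The bands straddle the true
#' cell outlines symmetrically, so the outline runs along the band ridge
#' (the local maxima of the band's distance transform): the enlargement
#' half-width is measured directly as the median distance from the ridge
#' to the nearest candidate region (median: robust to debris), and every
#' candidate is grown by that amount with a real-valued distance-transform
#' dilation, placing its boundary on the ridge.
#'
#' @param bmap a `boundary_map`.
#' @param min_area_px minimum candidate area before enlargement, pixels.
#' @return list(regions = list of `planar_region`, band_halfwidth = pixels).
#' @export
initial_regions <- function(bmap, min_area_px = 50L) {
  grid <- bmap$grid
  if (diff(range(grid)) == 0) {
    return(list(regions = list(), band_halfwidth = 0))
  }
  bright <- binarize_otsu(grid)
  band <- !bright
  if (!any(band) || !any(bright)) {
    return(list(regions = list(), band_halfwidth = 0))
  }
  lab <- label8(bright)
  border_labels <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                            lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  keep <- setdiff(seq_len(max(lab)), border_labels)
  kept_mask <- matrix(FALSE, nrow(grid), ncol(grid))
  px <- which(bright, arr.ind = TRUE)
  ids <- lab[px]
  kept_px <- list()
  for (l in keep) {
    pix <- px[ids == l, , drop = FALSE]
    if (nrow(pix) < min_area_px) next
    kept_px[[length(kept_px) + 1L]] <- pix
    kept_mask[pix] <- TRUE
  }
  if (length(kept_px) == 0L) {
    return(list(regions = list(), band_halfwidth = 0))
  }
  # band ridge = local maxima of the band distance transform
  dband <- distance_map(band)
  dil <- matrix(EBImage::imageData(EBImage::dilate(EBImage::Image(dband),
                                                   EBImage::makeBrush(3L, "box"))),
                nrow(dband))
  ridge <- band & dband >= dil - 1e-9 & dband > 0
  # half-width: ridge-to-region distance (to the region edge, hence -0.5)
  dreg <- distance_map(!kept_mask)
  vals <- dreg[ridge] - 0.5
  vals <- vals[vals > 0]
  halfwidth <- if (length(vals)) stats::median(vals) else 0
  regions <- lapply(kept_px, function(pix) {
    reg <- planar_region(pix, bmap$focus_index, dim(grid))
    grow_region(reg, halfwidth)
  })
  list(regions = regions, band_halfwidth = halfwidth)
}

# real-valued dilation: include pixels whose centre lies within `radius`
# of the region edge (distance transform of the complement, edge offset)
grow_region <- function(region, radius) {
  if (radius <= 0) return(region)
  pad <- ceiling(radius) + 2L
  bb <- region_bbox_mask(region, pad = pad)
  dout <- distance_map(!bb$mask)
  region_from_bbox(dout - 0.5 <= radius, bb$row0, bb$col0,
                   region$section, region$shape)
}

#' Split touching cells by a distance-transform watershed
#'
#' Watersheds the Euclidean distance transform of the mask and removes the
#' one-pixel separator lines between adjacent catchment basins - but only
#' where the contact line is short (at most `separator_size` pixels):
#' longer contacts indicate a genuinely continuous region that must not be
#' cut. A negative `separator_size` disables splitting.
#'
#' @param mask logical matrix.
#' @param separator_size maximum separator length in pixels (default 20).
#' @param tolerance watershed merging tolerance (object depth), pixels.
#' @return logical matrix with separators removed.
#' @export
split_touching <- function(mask, separator_size = 20L, tolerance = 1) {
  if (separator_size < 0 || !any(mask)) return(mask)
  d <- EBImage::distmap(EBImage::Image(mask))
  lab <- matrix(EBImage::imageData(EBImage::watershed(d, tolerance = tolerance)),
                nrow(mask))
  if (max(lab) < 2L) return(mask)
  # separator: for each touching basin pair, the higher-label pixels that
  # are 8-adjacent to the lower label (removing them separates the basins
  # under 8-connectivity)
  cuts <- list()
  nr <- nrow(lab)
  nc <- ncol(lab)
  for (shift in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    s1 <- shift[1L]; s2 <- shift[2L]
    rowsA <- (1L + max(-s1, 0L)):(nr - max(s1, 0L))
    colsA <- (1L + max(-s2, 0L)):(nc - max(s2, 0L))
    a <- lab[rowsA, colsA]
    b <- lab[rowsA + s1, colsA + s2]
    touch <- which(a > 0 & b > 0 & a != b, arr.ind = TRUE)
    if (nrow(touch) == 0L) next
    for (r in seq_len(nrow(touch))) {
      la <- a[touch[r, 1L], touch[r, 2L]]
      lb <- b[touch[r, 1L], touch[r, 2L]]
      key <- paste(min(la, lb), max(la, lb))
      # remove on the higher-label side
      if (la > lb) {
        pxr <- rowsA[touch[r, 1L]]
        pxc <- colsA[touch[r, 2L]]
      } else {
        pxr <- rowsA[touch[r, 1L]] + s1
        pxc <- colsA[touch[r, 2L]] + s2
      }
      cuts[[key]] <- rbind(cuts[[key]], c(pxr, pxc))
    }
  }
  out <- mask
  for (key in names(cuts)) {
    sep <- unique(cuts[[key]])
    if (nrow(sep) <= separator_size) out[sep] <- FALSE
  }
  out
}

#' Close small gaps and notches in a region
#'
#' Fills interior holes smaller than `gap_threshold` pixels and closes
#' boundary notches (morphological closing) whose added area stays below
#' the same threshold; larger gaps are genuine features (e.g. a forming
#' septum between separated cells) and are left untouched. A threshold of
#' 0 is the identity.
#'
#' @param region a `planar_region`.
#' @param gap_threshold maximum gap area to close, square pixels.
#' @return smoothed `planar_region`.
#' @export
smooth_fill <- function(region, gap_threshold) {
  if (gap_threshold < 0) stop("gap_threshold must be >= 0")
  if (gap_threshold == 0) return(region)
  r_close <- max(1L, ceiling(sqrt(gap_threshold)))
  bb <- region_bbox_mask(region, pad = r_close + 1L)
  m <- bb$mask
  # interior holes below threshold
  filled <- matrix(EBImage::imageData(EBImage::fillHull(EBImage::Image(m))) > 0,
                   nrow(m))
  holes <- filled & !m
  if (any(holes)) {
    hlab <- matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(holes))),
                   nrow(holes))
    for (l in seq_len(max(hlab))) {
      hp <- hlab == l
      if (sum(hp) < gap_threshold) m[hp] <- TRUE
    }
  }
  # boundary notches: candidate closing, keep added components below threshold
  brush <- EBImage::makeBrush(2L * r_close + 1L, shape = "disc")
  closed <- matrix(EBImage::imageData(EBImage::closing(EBImage::Image(m), brush)) > 0,
                   nrow(m))
  added <- closed & !m
  if (any(added)) {
    alab <- matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(added))),
                   nrow(added))
    for (l in seq_len(max(alab))) {
      ap <- alab == l
      if (sum(ap) < gap_threshold) m[ap] <- TRUE
    }
  }
  region_from_bbox(m, bb$row0, bb$col0, region$section, region$shape)
}

#' Exclude regions near the image periphery
#'
#' Cells cut by the field of view cannot be reconstructed; any region with
#' a pixel within `margin` pixels of the image edge is removed.
#'
#' @param regions list of `planar_region`.
#' @param margin margin width in pixels (>= 0).
#' @param shape integer c(rows, cols) of the image.
#' @return filtered list.
#' @export
exclude_periphery <- function(regions, margin, shape) {
  if (margin < 0) stop("margin must be >= 0")
  if (margin == 0 || length(regions) == 0L) return(regions)
  keep <- vapply(regions, function(r) {
    all(r$pixels[, 1L] > margin) && all(r$pixels[, 2L] > margin) &&
      all(r$pixels[, 1L] <= shape[1L] - margin) &&
      all(r$pixels[, 2L] <= shape[2L] - margin)
  }, logical(1))
  regions[keep]
}

#' Import externally produced midplane segmentations
#'
#' Converts a 2D label mask (0 = background, positive integer = one cell),
#' e.g. the output of a CNN segmenter, into planar regions that then run
#' through the same optional split / smooth / filter chain as the native
#' segmentation.
#'
#' @param label_image integer matrix of labels.
#' @param section section index to stamp on the regions.
#' @return list of `planar_region`, ordered by label.
#' @export
import_external_midplanes <- function(label_image, section = 1L) {
  if (any(label_image < 0) || any(label_image != round(label_image))) {
    stop("label image must contain non-negative integers")
  }
  labs <- sort(unique(label_image[label_image > 0]))
  lapply(labs, function(l) {
    planar_region(which(label_image == l, arr.ind = TRUE), section,
                  dim(label_image))
  })
}

#' Re-assign the extrusion midplane of a cell
#'
#' The native midplane is the image-wide focus section, which need not be
#' the section where the cell's nucleus is widest; when nuclear data are
#' available the whole-cell extrusion can be re-centred on the nuclear
#' midplane to remove the vertical misalignment.
#'
#' @param region the cell's midplane `planar_region`.
#' @param nucleus_mid_z nuclear midplane section index.
#' @param n_sections total number of optical sections.
#' @return list(region, midplane_index).
#' @export
reassign_midplane <- function(region, nucleus_mid_z, n_sections) {
  if (nucleus_mid_z < 1L || nucleus_mid_z > n_sections) {
    stop("nucleus midplane outside the stack Z range")
  }
  list(region = region, midplane_index = as.integer(nucleus_mid_z))
}

#' Whole-cell 2D segmentation of a brightfield stack
#'
#' The full native chain: focus detection, boundary-band map from the
#' defocused sections, Otsu thresholding with band-half-width enlargement,
#' optional watershed splitting of touching cells, gap smoothing, optional
#' solidity filtering, and periphery exclusion.
#'
#' @param stack brightfield `image_stack`.
#' @param blur_sigma,unsharp_radius,unsharp_weight enhancement parameters.
#' @param above_focus direction of the defocused sections.
#' @param separator_size watershed separator limit, px (negative = off).
#' @param gap_threshold smoothing gap threshold, square px.
#' @param margin periphery margin, px.
#' @param min_solidity optional solidity cutoff (NULL = filter off).
#' @param min_area_px minimum region area in pixels.
#' @return list(regions, focus_index, band_halfwidth).
#' @export
segment_cells <- function(stack, blur_sigma = 2, unsharp_radius = 4,
                          unsharp_weight = 0.6, above_focus = FALSE,
                          separator_size = -1L, gap_threshold = 9L,
                          margin = 10L, min_solidity = NULL,
                          min_area_px = 50L) {
  focus <- find_focus(stack)
  bmap <- boundary_map(stack, focus, blur_sigma, unsharp_radius,
                       unsharp_weight, above_focus)
  init <- initial_regions(bmap, min_area_px)
  regions <- init$regions
  if (separator_size >= 0 && length(regions) > 0L) {
    shape <- dim(bmap$grid)
    mask <- matrix(FALSE, shape[1L], shape[2L])
    for (r in regions) mask[r$pixels] <- TRUE
    mask <- split_touching(mask, separator_size)
    regions <- label_regions(mask, focus)
    regions <- regions[vapply(regions, region_area, integer(1)) >= min_area_px]
  }
  regions <- lapply(regions, smooth_fill, gap_threshold = gap_threshold)
  if (!is.null(min_solidity)) {
    keep <- vapply(regions, function(r) {
      region_solidity(r) >= min_solidity
    }, logical(1))
    regions <- regions[keep]
  }
  regions <- exclude_periphery(regions, margin, dim(bmap$grid))
  list(regions = regions, focus_index = focus,
       band_halfwidth = init$band_halfwidth)
}
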