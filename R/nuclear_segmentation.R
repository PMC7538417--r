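#' Enhance a fluorescence stack for nuclear segmentation
#'
#' Per-section Gaussian blur (noise suppression) followed by unsharp
#' masking (edge contrast), the standard preparation before thresholding
#' nuclear marker images.
#'
#' @param stack an `image_stack`.
#' @param blur_sigma Gaussian sigma of the denoising blur, pixels.
#' @param unsharp_radius sigma of the unsharp mask, pixels.
#' @param unsharp_weight unsharp weight in (0, 1).
#' @return enhanced `image_stack`.
#' @export
enhance_sections <- function(stack, blur_sigma = 1, unsharp_radius = 2,
                             unsharp_weight = 0.6) {
  if (blur_sigma <= 0 || unsharp_radius <= 0) {
    stop("blur_sigma and unsharp_radius must be > 0")
  }
  out <- stack$data
  for (k in seq_len(n_sections(stack))) {
    out[, , k] <- unsharp_mask(
      gaussian_blur(stack$data[, , k], blur_sigma),
      unsharp_radius, unsharp_weight
    )
  }
  image_stack(out, stack$pixel_size, stack$z_spacing, stack$sections)
}

#' Otsu threshold binarization of one section
#'
#' Threshold maximizing the between-class variance of the 256-bin
#' histogram; pixels strictly above the threshold are foreground. A
#' constant section yields an all-background mask.
#'
#' @param section numeric matrix.
#' @param levels number of histogram bins (default 256).
#' @param floor_threshold optional lower bound on the threshold (e.g. the
#'   stack-global Otsu threshold): per-section Otsu assumes a bimodal
#'   histogram and splits pure background noise in half on sections that
#'   contain no object, so Z-stack segmentation floors each section's
#'   threshold at the global one.
#' @return logical matrix.
#' @export
binarize_otsu <- function(section, levels = 256L, floor_threshold = NULL) {
  rng <- range(section)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(section), ncol(section)))
  thr <- EBImage::otsu(EBImage::Image(section), range = rng, levels = levels)
  if (!is.null(floor_threshold)) thr <- max(thr, floor_threshold)
  section > thr
}

#' Otsu threshold of an entire stack
#'
#' The between-class-variance-maximizing threshold of the pooled stack
#' histogram, used as the per-section floor in [segment_nuclei_2d()]. The
#' histogram is built from a deterministic subsample when the stack is
#' large.
#'
#' @param stack an `image_stack` (or numeric array).
#' @param levels number of histogram bins.
#' @param max_values subsample cap.
#' @return numeric threshold.
#' @export
stack_otsu <- function(stack, levels = 256L, max_values = 4e6) {
  vals <- if (inherits(stack, "image_stack")) stack$data else stack
  n <- length(vals)
  if (n > max_values) {
    vals <- vals[seq(1L, n, by = ceiling(n / max_values))]
  }
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1L])
  m <- matrix(vals, ncol = 1L)
  EBImage::otsu(EBImage::Image(m), range = rng, levels = levels)
}

#' Smooth a binary mask by blur and remasking
#'
#' Gaussian-blurs the 0/1 mask and re-thresholds at `level`; removes
#' speckle smaller than the blur scale and rounds jagged boundaries.
#'
#' @param mask logical matrix.
#' @param sigma blur sigma in pixels (> 0).
#' @param level remasking level in (0, 1), default 0.5.
#' @return logical matrix.
#' @export
smooth_binary <- function(mask, sigma = 1, level = 0.5) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (!any(mask)) return(mask)
  gaussian_blur(mask * 1, sigma) > level
}

#' Regions from a binary mask with circularity and size filtering
#'
#' Labels 8-connected components and drops those whose circularity
#' `4*pi*A/P^2` falls below `min_circularity` (low-circularity nuclear
#' sections are typically crescents left where the dim nucleolar region
#' escaped the threshold) or whose pixel area is below `min_area`.
#'
#' @param mask logical matrix.
#' @param min_circularity circularity cutoff in `[0, 1]` (default 0.6).
#' @param min_area minimum component area in pixels (default 5).
#' @param section section index stamped on the regions.
#' @return list of `planar_region`.
#' @export
regions_from_mask <- function(mask, min_circularity = 0.6, min_area = 5L,
                              section = 1L) {
  stopifnot(min_circularity >= 0, min_circularity <= 1)
  regs <- label_regions(mask, section)
  keep <- vapply(regs, function(r) {
    region_area(r) >= min_area && region_circularity(r) >= min_circularity
  }, logical(1))
  regs[keep]
}

#' Segment nuclei in every optical section
#'
#' The per-section 2D chain: enhance (blur + unsharp), Otsu threshold,
#' binary smoothing, component extraction with circularity and size
#' filters, optional dilation (to capture fluorophores at the nuclear
#' periphery), and elliptical regularization. Sections that fail the
#' ellipse fit (too small or degenerate) keep their original region.
#'
#' @param stack nuclear-marker `image_stack`.
#' @param blur_sigma,unsharp_radius,unsharp_weight see [enhance_sections()].
#' @param smooth_sigma sigma of the binary smoothing blur, pixels.
#' @param min_circularity circularity cutoff (default 0.6).
#' @param min_area_um2 minimum region area, square micrometres.
#' @param dilation_um dilation margin in micrometres (0 disables).
#' @param fit_ellipses regularize each region to its fitted ellipse.
#' @return list (one element per section) of lists of `planar_region`.
#' @export
segment_nuclei_2d <- function(stack, blur_sigma = 1, unsharp_radius = 2,
                              unsharp_weight = 0.6, smooth_sigma = 1,
                              min_circularity = 0.6, min_area_um2 = 0.2,
                              dilation_um = 0.1, fit_ellipses = TRUE) {
  enhanced <- enhance_sections(stack, blur_sigma, unsharp_radius,
                               unsharp_weight)
  thr_floor <- stack_otsu(enhanced)
  min_area <- max(5L, round(min_area_um2 / stack$pixel_size^2))
  out <- vector("list", n_sections(stack))
  for (k in seq_len(n_sections(stack))) {
    mask <- smooth_binary(
      binarize_otsu(enhanced$data[, , k], floor_threshold = thr_floor),
      smooth_sigma
    )
    regs <- regions_from_mask(mask, min_circularity, min_area, section = k)
    if (dilation_um > 0) {
      regs <- lapply(regs, dilate_region, margin = dilation_um,
                     pixel_size = stack$pixel_size)
    }
    if (fit_ellipses) {
      regs <- lapply(regs, function(r) {
        tryCatch(fit_ellipse(r), error = function(e) r)
      })
    }
    out[[k]] <- regs
  }
  out
}

#' Grouped 3D nucleus
#'
#' A contiguous run of per-section nuclear regions with its midplane
#' (largest-area section), mean centroid, and stacked-ROI volume/surface.
#'
#' @param stack a `region_stack` of the nuclear sections.
#' @return a `nucleus_model` object.
#' @export
nucleus_model <- function(stack) {
  ctrs <- t(vapply(stack$regions, region_centroid, numeric(2)))
  structure(
    list(
      stack = stack,
      mean_centroid = colMeans(ctrs),
      midplane_index = stack$midplane_index,
      n_regions = length(stack$regions)
    ),
    class = "nucleus_model"
  )
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat(sprintf(
    "<nucleus_model> %d sections, midplane %d, centroid (%.1f, %.1f)\n",
    x$n_regions, x$midplane_index, x$mean_centroid[1], x$mean_centroid[2]))
  invisible(x)
}

#' Group per-section nuclear regions into 3D nuclei
#'
#' Greedy Z-linking of regions in adjacent sections whose centroid XY
#' distance does not exceed `link_dist` (nearest pair first; ties go to
#' the larger candidate area). Chains may bridge up to `max_gap` missing
#' sections; afterwards only the largest contiguous run of each chain is
#' kept. Chains are then discarded when (in this order, each recorded):
#' any centroid lies more than `drift_max` from the chain's mean centroid
#' (nucleus moved during acquisition), fewer than `min_sections` sections
#' remain, or the largest-area (midplane) section sits at the top or
#' bottom of the run (truncated nucleus).
#'
#' @param regions_by_section list of per-section region lists, as produced
#'   by [segment_nuclei_2d()].
#' @param link_dist maximum adjacent-section centroid distance, um.
#' @param drift_max maximum centroid distance from the mean centroid, um.
#' @param min_sections minimum number of sections per nucleus.
#' @param pixel_size lateral pixel size, um.
#' @param z_spacing corrected section spacing, um.
#' @param max_gap maximum number of bridged empty sections (default 2).
#' @return list with `nuclei` (list of `nucleus_model`) and `exclusions`
#'   (data.frame chain id + reason).
#' @export
group_nuclei <- function(regions_by_section, link_dist = 2.0, drift_max = 3.0,
                         min_sections = 5L, pixel_size, z_spacing,
                         max_gap = 2L) {
  chains <- list()  # each: list(regions = list, sections = int vector)
  open_idx <- integer()
  for (s in seq_along(regions_by_section)) {
    regs <- regions_by_section[[s]]
    # close chains that fell too far behind
    if (length(open_idx)) {
      last <- vapply(open_idx, function(i) max(chains[[i]]$sections),
                     integer(1))
      open_idx <- open_idx[s - last <= max_gap + 1L]
    }
    if (length(regs) == 0L) next
    ctrs <- t(vapply(regs, region_centroid, numeric(2)))
    assigned <- rep(FALSE, length(regs))
    if (length(open_idx)) {
      last_ctr <- t(vapply(open_idx, function(i) {
        region_centroid(chains[[i]]$regions[[length(chains[[i]]$regions)]])
      }, numeric(2)))
      # candidate links within link_dist, nearest first, larger area on ties
      cand <- expand.grid(chain = seq_along(open_idx), reg = seq_along(regs))
      cand$dist <- sqrt(
        (last_ctr[cand$chain, 1L] - ctrs[cand$reg, 1L])^2 +
          (last_ctr[cand$chain, 2L] - ctrs[cand$reg, 2L])^2
      ) * pixel_size
      cand <- cand[cand$dist <= link_dist, , drop = FALSE]
      areas <- vapply(regs, region_area, integer(1))
      cand <- cand[order(cand$dist, -areas[cand$reg]), , drop = FALSE]
      used_chain <- rep(FALSE, length(open_idx))
      for (r in seq_len(nrow(cand))) {
        ci <- cand$chain[r]
        ri <- cand$reg[r]
        if (used_chain[ci] || assigned[ri]) next
        gi <- open_idx[ci]
        chains[[gi]]$regions <- c(chains[[gi]]$regions, list(regs[[ri]]))
        chains[[gi]]$sections <- c(chains[[gi]]$sections, s)
        used_chain[ci] <- TRUE
        assigned[ri] <- TRUE
      }
    }
    for (ri in which(!assigned)) {
      chains[[length(chains) + 1L]] <- list(regions = list(regs[[ri]]),
                                            sections = s)
      open_idx <- c(open_idx, length(chains))
    }
  }

  nuclei <- list()
  excl_id <- integer()
  excl_reason <- character()
  n_stack <- length(regions_by_section)
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    run <- largest_contiguous_run(ch$sections)
    regs <- ch$regions[run]
    secs <- ch$sections[run]
    ctrs <- t(vapply(regs, region_centroid, numeric(2)))
    drift <- sqrt((ctrs[, 1L] - mean(ctrs[, 1L]))^2 +
                    (ctrs[, 2L] - mean(ctrs[, 2L]))^2) * pixel_size
    if (any(drift > drift_max)) {
      excl_id <- c(excl_id, i)
      excl_reason <- c(excl_reason, "centroid_drift")
      next
    }
    if (length(regs) < min_sections) {
      excl_id <- c(excl_id, i)
      excl_reason <- c(excl_reason, "too_few_sections")
      next
    }
    areas <- vapply(regs, region_area, integer(1))
    mid_pos <- which.max(areas)
    if (mid_pos == 1L || mid_pos == length(regs) ||
        secs[mid_pos] == 1L || secs[mid_pos] == n_stack) {
      excl_id <- c(excl_id, i)
      excl_reason <- c(excl_reason, "midplane_at_stack_edge")
      next
    }
    st <- region_stack(regs, secs[mid_pos], pixel_size, z_spacing)
    nuclei[[length(nuclei) + 1L]] <- nucleus_model(st)
  }
  list(nuclei = nuclei,
       exclusions = data.frame(chain = excl_id, reason = excl_reason))
}

# indices of the longest run of consecutive values in a sorted-by-order
# integer vector (first run wins ties)
largest_contiguous_run <- function(sections) {
  breaks <- c(0L, which(diff(sections) != 1L), length(sections))
  lens <- diff(breaks)
  k <- which.max(lens)
  (breaks[k] + 1L):breaks[k + 1L]
}
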