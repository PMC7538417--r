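#' Volume of a 3D region stack
#'
#' Sum over sections of (pixel area x pixel_size^2 x z_spacing), with the
#' axially corrected section spacing.
#'
#' @param stack a `region_stack`.
#' @return volume in cubic micrometres.
#' @export
stack_volume <- function(stack) {
  areas <- vapply(stack$regions, region_area, integer(1))
  sum(areas) * stack$pixel_size^2 * stack$z_spacing
}

#' Voxel count of a 3D region stack
#' @param stack a `region_stack`.
#' @return integer voxel count.
#' @export
stack_voxels <- function(stack) {
  sum(vapply(stack$regions, region_area, integer(1)))
}

#' Surface area of a 3D region stack (staircase formula)
#'
#' `S = (sum_i P_i * Z) + 2 * A`: the per-section perimeters times the
#' section spacing account for all faces orthogonal to the XY plane, and
#' twice the midplane area for the faces parallel to it.
#'
#' @param stack a `region_stack`.
#' @return surface in square micrometres.
#' @export
stack_surface <- function(stack) {
  perims <- vapply(stack$regions, region_perimeter, numeric(1))
  mid <- stack$regions[[as.character(stack$midplane_index)]]
  if (is.null(mid)) {
    # midplane may be absent for degenerate stacks; use the largest section
    areas <- vapply(stack$regions, region_area, integer(1))
    mid <- stack$regions[[which.max(areas)]]
  }
  sum(perims) * stack$pixel_size * stack$z_spacing +
    2 * region_area(mid) * stack$pixel_size^2
}

#' Idealized rod volume (cylinder with hemispherical caps)
#'
#' `V = h * pi * r^2 + (4/3) * pi * r^3` with `r = W/2`, `h = L - W`.
#'
#' @param L cell length (micrometres).
#' @param W cell width (micrometres); requires `L >= W`.
#' @return volume in cubic micrometres. Vectorized.
#' @export
rod_volume <- function(L, W) {
  if (any(W < 0) || any(L < W)) stop("rod dimensions require L >= W >= 0")
  r <- W / 2
  h <- L - W
  h * pi * r^2 + (4 / 3) * pi * r^3
}

#' Idealized rod surface
#'
#' `S = 2 * h * pi * r + 4 * pi * r^2` (lateral cylinder face plus the two
#' hemispherical caps).
#'
#' @inheritParams rod_volume
#' @return surface in square micrometres. Vectorized.
#' @export
rod_surface <- function(L, W) {
  if (any(W < 0) || any(L < W)) stop("rod dimensions require L >= W >= 0")
  r <- W / 2
  h <- L - W
  2 * h * pi * r + 4 * pi * r^2
}

#' Idealized (prolate) ellipsoid volume
#'
#' `V = (4/3) * pi * a * b^2` with semi-axes `a = L/2`, `b = W/2`.
#'
#' @param L long diameter (micrometres).
#' @param W short diameter (micrometres); requires `L >= W`.
#' @return volume in cubic micrometres. Vectorized.
#' @export
ellipsoid_volume <- function(L, W) {
  if (any(W < 0) || any(L < W)) stop("ellipsoid dimensions require L >= W >= 0")
  (4 / 3) * pi * (L / 2) * (W / 2)^2
}

#' Approximate prolate ellipsoid surface
#'
#' The Knud Thomsen approximation with exponent `P = 1.6075` for a prolate
#' spheroid with semi-axes (a, b, b), `a = L/2`, `b = W/2`:
#' `S ~ 4 * pi * ((2 * a^P * b^P + b^(2P)) / 3)^(1/P)`.
#' It reduces exactly to `4 * pi * a^2` at `a = b` and stays within about
#' 1.2% of the closed-form prolate surface over biological axis ratios.
#'
#' @inheritParams ellipsoid_volume
#' @param P approximation exponent (default 1.6075).
#' @return surface in square micrometres. Vectorized.
#' @export
ellipsoid_surface <- function(L, W, P = 1.6075) {
  if (any(W <= 0) || any(L < W)) stop("ellipsoid dimensions require L >= W > 0")
  a <- L / 2
  b <- W / 2
  4 * pi * ((2 * a^P * b^P + b^(2 * P)) / 3)^(1 / P)
}

#' Aspect ratio of a 3D region stack
#'
#' Z extension divided by the XY reference extent: for cells the reference
#' is the minimum Feret diameter of the midplane (cell width - the Z
#' extent of a radially symmetric rod tracks its width, not its length);
#' for nuclei it is the maximum Feret diameter (largest XY diameter).
#' Truncated reconstructions fall below ~0.8, over-grouped ones exceed
#' ~1.2.
#'
#' @param stack a `region_stack`.
#' @param kind "cell" or "nucleus".
#' @return dimensionless aspect ratio.
#' @export
aspect_ratio <- function(stack, kind = c("cell", "nucleus")) {
  kind <- match.arg(kind)
  mid <- stack$regions[[as.character(stack$midplane_index)]]
  if (is.null(mid)) {
    areas <- vapply(stack$regions, region_area, integer(1))
    mid <- stack$regions[[which.max(areas)]]
  }
  fd <- feret_dims(mid)
  ref <- if (kind == "cell") fd["W"] else fd["L"]
  z_extent <- length(stack$regions) * stack$z_spacing
  unname(z_extent / (ref * stack$pixel_size))
}

#' Is a nucleus fully contained in its cell's 3D ROI?
#'
#' TRUE iff every nuclear voxel belongs to the cell reconstruction
#' (shared boundary voxels count as inside).
#'
#' @param cell_stack a `region_stack` (cell).
#' @param nucleus_stack a `region_stack` (nucleus).
#' @return logical.
#' @export
nucleus_within_cell <- function(cell_stack, nucleus_stack) {
  for (r in nucleus_stack$regions) {
    cr <- cell_stack$regions[[as.character(r$section)]]
    if (is.null(cr)) return(FALSE)
    cm <- region_mask(cr)
    if (!all(cm[r$pixels])) return(FALSE)
  }
  TRUE
}

#' Fluorescence intensity of a 3D ROI
#'
#' Integrated density is the sum of pixel intensities over every
#' cross-sectional region (area times mean, summed over sections); the
#' volumetric mean divides it by the 3D ROI volume in cubic micrometres.
#' The voxel count is returned as well so a per-voxel mean can be formed.
#'
#' @param stack a `region_stack`.
#' @param channel an `image_stack` of the (corrected) fluorescence channel.
#' @return list(integrated_density, mean_intensity, n_voxels).
#' @export
stack_intensity <- function(stack, channel) {
  total <- 0
  nvox <- 0L
  for (r in stack$regions) {
    plane <- match(r$section, channel$sections)
    if (is.na(plane)) next
    sec <- channel$data[, , plane]
    total <- total + sum(sec[r$pixels])
    nvox <- nvox + region_area(r)
  }
  list(integrated_density = total,
       mean_intensity = total / stack_volume(stack),
       n_voxels = nvox)
}

#' Pair nuclei with whole-cell reconstructions
#'
#' A nucleus belongs to the cell whose midplane region contains the
#' nucleus's mean XY centroid. Only one-to-one pairs are kept: cells
#' containing two or more nuclear centroids (septating cells or poor
#' segmentation) are excluded as multinucleate, cells without a nucleus
#' and nuclei outside every cell are excluded as unpaired.
#'
#' @param cells list of cell `region_stack`.
#' @param nuclei list of `nucleus_model`.
#' @return list(pairs = data.frame(cell, nucleus), exclusions =
#'   data.frame(kind, index, reason)).
#' @export
pair_nuclei_cells <- function(cells, nuclei) {
  n_cells <- length(cells)
  n_nuc <- length(nuclei)
  owner <- rep(NA_integer_, n_nuc)
  for (j in seq_len(n_nuc)) {
    ctr <- nuclei[[j]]$mean_centroid  # (x, y)
    px <- c(round(ctr[2L]), round(ctr[1L]))  # (row, col)
    for (i in seq_len(n_cells)) {
      mid <- cells[[i]]$regions[[as.character(cells[[i]]$midplane_index)]]
      if (is.null(mid)) next
      if (any(mid$pixels[, 1L] == px[1L] & mid$pixels[, 2L] == px[2L])) {
        owner[j] <- i
        break
      }
    }
  }
  excl_kind <- character()
  excl_idx <- integer()
  excl_reason <- character()
  for (j in which(is.na(owner))) {
    excl_kind <- c(excl_kind, "nucleus")
    excl_idx <- c(excl_idx, j)
    excl_reason <- c(excl_reason, "no_enclosing_cell")
  }
  counts <- tabulate(owner, nbins = n_cells)
  pairs_cell <- integer()
  pairs_nuc <- integer()
  for (i in seq_len(n_cells)) {
    if (counts[i] == 0L) {
      excl_kind <- c(excl_kind, "cell")
      excl_idx <- c(excl_idx, i)
      excl_reason <- c(excl_reason, "no_nucleus")
    } else if (counts[i] > 1L) {
      excl_kind <- c(excl_kind, "cell")
      excl_idx <- c(excl_idx, i)
      excl_reason <- c(excl_reason, "multinucleate")
      for (j in which(!is.na(owner) & owner == i)) {
        excl_kind <- c(excl_kind, "nucleus")
        excl_idx <- c(excl_idx, j)
        excl_reason <- c(excl_reason, "multinucleate_cell")
      }
    } else {
      pairs_cell <- c(pairs_cell, i)
      pairs_nuc <- c(pairs_nuc, which(!is.na(owner) & owner == i))
    }
  }
  list(
    pairs = data.frame(cell = pairs_cell, nucleus = pairs_nuc),
    exclusions = data.frame(kind = excl_kind, index = excl_idx,
                            reason = excl_reason)
  )
}

#' Full morphometry table for paired cells and nuclei
#'
#' One row per one-to-one cell/nucleus pair with all measurements:
#' voxelized volume and surface for cell and nucleus, Feret- and
#' ellipse-based length/width with the corresponding idealized rod
#' (cell) and ellipsoid (nucleus) volumes and surfaces, midplane solidity,
#' aspect ratios, the nuclear-to-cell volume ratio, per-channel
#' fluorescence intensities, and the quality-filter flags
#' (`aspect_ok`: both aspect ratios within `aspect_bounds`;
#' `nucleus_inside`: nuclear ROI fully inside the cell ROI).
#'
#' @param cells list of cell `region_stack`.
#' @param nuclei list of `nucleus_model`.
#' @param pairing result of [pair_nuclei_cells()] (computed when NULL).
#' @param channels named list of `image_stack` fluorescence channels for
#'   intensity extraction (may be empty).
#' @param aspect_bounds numeric c(lo, hi) for the aspect-ratio flag.
#' @return data.frame, one row per pair.
#' @export
cell_records <- function(cells, nuclei, pairing = NULL, channels = list(),
                         aspect_bounds = c(0.8, 1.2)) {
  if (is.null(pairing)) pairing <- pair_nuclei_cells(cells, nuclei)
  pairs <- pairing$pairs
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    cs <- cells[[pairs$cell[k]]]
    nm <- nuclei[[pairs$nucleus[k]]]
    ns <- nm$stack
    px <- cs$pixel_size
    mid <- cs$regions[[as.character(cs$midplane_index)]]
    if (is.null(mid)) {
      areas <- vapply(cs$regions, region_area, integer(1))
      mid <- cs$regions[[which.max(areas)]]
    }
    nmid <- ns$regions[[as.character(ns$midplane_index)]]
    fd <- feret_dims(mid) * px
    ed <- ellipse_dims(mid) * px
    nfd <- feret_dims(nmid) * ns$pixel_size
    ar_cell <- aspect_ratio(cs, "cell")
    ar_nuc <- aspect_ratio(ns, "nucleus")
    vol_cell <- stack_volume(cs)
    vol_nuc <- stack_volume(ns)
    row <- data.frame(
      cell_id = pairs$cell[k],
      nucleus_id = pairs$nucleus[k],
      cell_volume_um3 = vol_cell,
      cell_surface_um2 = stack_surface(cs),
      cell_voxels = stack_voxels(cs),
      nuc_volume_um3 = vol_nuc,
      nuc_surface_um2 = stack_surface(ns),
      nuc_voxels = stack_voxels(ns),
      length_feret_um = unname(fd["L"]),
      width_feret_um = unname(fd["W"]),
      length_ellipse_um = unname(ed["L"]),
      width_ellipse_um = unname(ed["W"]),
      rod_volume_feret_um3 = rod_volume(max(fd), min(fd)),
      rod_surface_feret_um2 = rod_surface(max(fd), min(fd)),
      rod_volume_ellipse_um3 = rod_volume(max(ed), min(ed)),
      rod_surface_ellipse_um2 = rod_surface(max(ed), min(ed)),
      nuc_length_um = unname(nfd["L"]),
      nuc_width_um = unname(nfd["W"]),
      ellipsoid_volume_um3 = ellipsoid_volume(max(nfd), min(nfd)),
      ellipsoid_surface_um2 = ellipsoid_surface(max(nfd), min(nfd)),
      solidity = region_solidity(mid),
      aspect_ratio_cell = ar_cell,
      aspect_ratio_nucleus = ar_nuc,
      nc_ratio = vol_nuc / vol_cell,
      aspect_ok = ar_cell >= aspect_bounds[1L] & ar_cell <= aspect_bounds[2L] &
        ar_nuc >= aspect_bounds[1L] & ar_nuc <= aspect_bounds[2L],
      nucleus_inside = nucleus_within_cell(cs, ns)
    )
    for (ch in names(channels)) {
      ic <- stack_intensity(cs, channels[[ch]])
      inn <- stack_intensity(ns, channels[[ch]])
      row[[paste0("cell_intden_", ch)]] <- ic$integrated_density
      row[[paste0("cell_mean_", ch)]] <- ic$mean_intensity
      row[[paste0("nuc_intden_", ch)]] <- inn$integrated_density
      row[[paste0("nuc_mean_", ch)]] <- inn$mean_intensity
    }
    rows[[k]] <- row
  }
  if (length(rows) == 0L) return(empty_records())
  do.call(rbind, rows)
}

empty_records <- function() {
  data.frame(
    cell_id = integer(), nucleus_id = integer(),
    cell_volume_um3 = numeric(), cell_surface_um2 = numeric(),
    cell_voxels = integer(), nuc_volume_um3 = numeric(),
    nuc_surface_um2 = numeric(), nuc_voxels = integer(),
    length_feret_um = numeric(), width_feret_um = numeric(),
    length_ellipse_um = numeric(), width_ellipse_um = numeric(),
    rod_volume_feret_um3 = numeric(), rod_surface_feret_um2 = numeric(),
    rod_volume_ellipse_um3 = numeric(), rod_surface_ellipse_um2 = numeric(),
    nuc_length_um = numeric(), nuc_width_um = numeric(),
    ellipsoid_volume_um3 = numeric(), ellipsoid_surface_um2 = numeric(),
    solidity = numeric(), aspect_ratio_cell = numeric(),
    aspect_ratio_nucleus = numeric(), nc_ratio = numeric(),
    aspect_ok = logical(), nucleus_inside = logical()
  )
}

#' Apply the optional quality filters to a record table
#'
#' Keeps rows whose aspect ratios both lie within the bounds (when
#' `aspect = TRUE`) and whose nucleus is fully contained in the cell ROI
#' (when `containment = TRUE`). The flags were computed by
#' [cell_records()]; this merely subsets on them.
#'
#' @param records data.frame from [cell_records()].
#' @param aspect apply the aspect-ratio filter.
#' @param containment apply the nucleus-inside-cell filter.
#' @return filtered data.frame.
#' @export
filter_records <- function(records, aspect = TRUE, containment = TRUE) {
  keep <- rep(TRUE, nrow(records))
  if (aspect) keep <- keep & records$aspect_ok
  if (containment) keep <- keep & records$nucleus_inside
  records[keep, , drop = FALSE]
}
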