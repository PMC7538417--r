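#' Euclidean distance map of a binary mask
#'
#' For every foreground pixel, the Euclidean distance (in pixels) to the
#' nearest background pixel; background is 0. Interior maxima equal the
#' radius of the largest inscribed disk, which is what makes the map usable
#' as a radius source for spherical extrusion.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return numeric matrix of distances.
#' @export
distance_map <- function(mask) {
  if (!any(mask)) stop("distance_map: empty mask")
  d <- EBImage::distmap(EBImage::Image(mask), metric = "euclidean")
  matrix(EBImage::imageData(d), nrow(mask))
}

# one pass of Zhang-Suen thinning over a padded logical matrix; returns the
# thinned matrix (same padding)
zhang_suen <- function(mask) {
  nr <- nrow(mask) + 2L
  nc <- ncol(mask) + 2L
  m <- matrix(FALSE, nr, nc)
  m[2:(nr - 1L), 2:(nc - 1L)] <- mask
  ci <- 2:(nr - 1L)
  cj <- 2:(nc - 1L)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p1 <- m[ci, cj]
      p2 <- m[ci - 1L, cj]
      p3 <- m[ci - 1L, cj + 1L]
      p4 <- m[ci, cj + 1L]
      p5 <- m[ci + 1L, cj + 1L]
      p6 <- m[ci + 1L, cj]
      p7 <- m[ci + 1L, cj - 1L]
      p8 <- m[ci, cj - 1L]
      p9 <- m[ci - 1L, cj - 1L]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      del <- if (sub == 1L) {
        p1 & b >= 2 & b <= 6 & a == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        p1 & b >= 2 & b <= 6 & a == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(del)) {
        # parallel deletion can erase a final 2x2 core completely; keep one
        # pixel so every component leaves at least a point skeleton
        if (sum(del) == sum(p1)) del[which(del)[1L]] <- FALSE
        p1[del] <- FALSE
        m[ci, cj] <- p1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  minimal_skeleton(m[ci, cj])
}

# sequential cleanup of Zhang-Suen staircase corners: repeatedly delete
# non-endpoint pixels whose 8-neighbourhood foreground forms a single
# 8-connected component (deletion cannot disconnect the skeleton there);
# interior pixels of clean lines have two separate neighbour groups and
# are never touched, so the pass terminates with a minimal 8-connected
# skeleton
minimal_skeleton <- function(skel) {
  offs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  n_nbhd_components <- function(p) {
    pts <- NULL
    for (k in seq_len(8L)) {
      q <- p + offs[k, ]
      if (q[1L] >= 1L && q[2L] >= 1L && q[1L] <= nrow(skel) &&
          q[2L] <= ncol(skel) && skel[q[1L], q[2L]]) {
        pts <- rbind(pts, q)
      }
    }
    if (is.null(pts)) return(0L)
    n <- nrow(pts)
    comp <- seq_len(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j && max(abs(pts[i, ] - pts[j, ])) <= 1L) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
    length(unique(comp))
  }
  repeat {
    px <- which(skel, arr.ind = TRUE)
    deleted <- FALSE
    for (i in seq_len(nrow(px))) {
      p <- px[i, ]
      nb <- 0L
      for (k in seq_len(8L)) {
        q <- p + offs[k, ]
        if (q[1L] >= 1L && q[2L] >= 1L && q[1L] <= nrow(skel) &&
            q[2L] <= ncol(skel) && skel[q[1L], q[2L]]) nb <- nb + 1L
      }
      if (nb >= 2L && n_nbhd_components(p) == 1L) {
        skel[p[1L], p[2L]] <- FALSE
        deleted <- TRUE
      }
    }
    if (!deleted) return(skel)
  }
}

# 8-neighbour count for every pixel of a logical matrix
neighbour_count <- function(m) {
  nr <- nrow(m) + 2L
  nc <- ncol(m) + 2L
  p <- matrix(0L, nr, nc)
  p[2:(nr - 1L), 2:(nc - 1L)] <- m
  ci <- 2:(nr - 1L)
  cj <- 2:(nc - 1L)
  p[ci - 1L, cj] + p[ci - 1L, cj + 1L] + p[ci, cj + 1L] +
    p[ci + 1L, cj + 1L] + p[ci + 1L, cj] + p[ci + 1L, cj - 1L] +
    p[ci, cj - 1L] + p[ci - 1L, cj - 1L]
}

# remove terminal branches of a skeleton that are shorter than the local
# distance-map value at their junction (spur suppression); iterates until
# stable. A skeleton that is a single simple path (two endpoints, no
# junction) is left alone.
prune_spurs <- function(skel, dmap) {
  repeat {
    nb <- neighbour_count(skel)
    junctions <- skel & nb >= 3L
    if (!any(junctions)) return(skel)
    ends <- which(skel & nb == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) return(skel)
    removed <- FALSE
    for (k in seq_len(nrow(ends))) {
      path <- walk_branch(skel, nb, ends[k, ])
      if (is.null(path)) next
      jct <- path$junction
      if (nrow(path$pixels) < dmap[jct[1L], jct[2L]]) {
        skel[path$pixels] <- FALSE
        removed <- TRUE
        break  # neighbour counts are stale; recompute
      }
    }
    if (!removed) return(skel)
  }
}

# follow a skeleton branch from an endpoint until a junction (8-neighbour
# count >= 3); returns list(pixels = branch pixels excl. junction,
# junction = c(row, col)), or NULL if no junction is reached
walk_branch <- function(skel, nb, start) {
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  path <- matrix(start, ncol = 2L)
  cur <- start
  prev <- c(NA_integer_, NA_integer_)
  repeat {
    nxt <- NULL
    for (k in seq_len(8L)) {
      p <- cur + offs[k, ]
      if (p[1L] < 1L || p[2L] < 1L || p[1L] > nrow(skel) || p[2L] > ncol(skel))
        next
      if (!skel[p[1L], p[2L]]) next
      if (!is.na(prev[1L]) && p[1L] == prev[1L] && p[2L] == prev[2L]) next
      if (any(path[, 1L] == p[1L] & path[, 2L] == p[2L])) next
      nxt <- p
      break
    }
    if (is.null(nxt)) return(NULL)
    if (nb[nxt[1L], nxt[2L]] >= 3L) {
      return(list(pixels = path, junction = nxt))
    }
    prev <- cur
    cur <- nxt
    path <- rbind(path, cur)
    if (nrow(path) > sum(skel)) return(NULL)
  }
}

#' Topological skeleton of a binary mask
#'
#' Zhang-Suen thinning to a one-pixel-wide, 8-connected curve that is
#' approximately equidistant from the region boundaries. With `prune = TRUE`
#' (default), terminal side-branches shorter than the local distance-map
#' value are removed, leaving a single well-defined path for typical
#' rod-shaped regions; boundary rasterization noise otherwise seeds short
#' spurs. With `extend_tips = TRUE` (default) each skeleton endpoint is
#' continued along the distance-map ridge towards the region tip: thinning
#' stops roughly one local radius short of the medial-axis endpoints, and
#' without the continuation the extruded reconstruction would truncate the
#' hemispherical end caps. Extension points carry decreasing radii, so they
#' only add spheres already contained in the union of maximal disks.
#'
#' @param mask logical matrix, one connected foreground component.
#' @param prune suppress short terminal spurs (default TRUE).
#' @param extend_tips continue endpoints along the ridge (default TRUE).
#' @return logical matrix of the skeleton.
#' @export
skeletonize <- function(mask, prune = TRUE, extend_tips = TRUE) {
  if (!any(mask)) stop("skeletonize: empty mask")
  skel <- zhang_suen(mask)
  dmap <- distance_map(mask)
  if (prune) skel <- prune_spurs(skel, dmap)
  if (sum(skel) <= 2L) {
    # round blob with no elongation: thinning leaves an arbitrary interior
    # pixel; anchor the skeleton on the central distance plateau instead
    skel <- dmap >= max(dmap) - 0.5
  }
  if (extend_tips) skel <- extend_skeleton_tips(skel, dmap)
  skel
}

# continue each skeleton endpoint along the distance-map ridge: step into
# the forward cone (last direction +/- 45 degrees), choosing the neighbour
# with the largest non-increasing distance value, until the tip is reached
extend_skeleton_tips <- function(skel, dmap) {
  nb <- neighbour_count(skel)
  ends <- which(skel & nb == 1L, arr.ind = TRUE)
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (k in seq_len(nrow(ends))) {
    cur <- ends[k, ]
    # direction away from the endpoint's unique neighbour
    prev <- NULL
    for (o in seq_len(8L)) {
      p <- cur + offs[o, ]
      if (p[1L] >= 1L && p[2L] >= 1L && p[1L] <= nrow(skel) &&
          p[2L] <= ncol(skel) && skel[p[1L], p[2L]]) {
        prev <- p
        break
      }
    }
    if (is.null(prev)) next
    dir <- sign(cur - prev)
    steps <- 0L
    # the region tip is at most one local radius away from the endpoint
    max_steps <- ceiling(dmap[cur[1L], cur[2L]]) + 2L
    while (steps < max_steps) {
      best <- NULL
      best_d <- 0
      for (o in seq_len(8L)) {
        if (sum(offs[o, ] * dir) <= 0L) next  # forward cone only
        p <- cur + offs[o, ]
        if (p[1L] < 1L || p[2L] < 1L || p[1L] > nrow(skel) ||
            p[2L] > ncol(skel)) next
        if (skel[p[1L], p[2L]]) next
        d <- dmap[p[1L], p[2L]]
        if (d >= 1.5 && d <= dmap[cur[1L], cur[2L]] + 1e-9 && d > best_d) {
          best <- p
          best_d <- d
        }
      }
      if (is.null(best)) break
      skel[best[1L], best[2L]] <- TRUE
      dir <- sign(best - cur)
      cur <- best
      steps <- steps + 1L
    }
  }
  skel
}

#' Radius profile: skeleton annotated with local radii
#'
#' The union of the topological skeleton and the Euclidean distance map:
#' one profile point per skeleton pixel, whose radius R is the local
#' distance to the region edge. The distance map stores the distance to the
#' nearest background pixel centre, which overshoots the distance to the
#' region boundary (the crack between foreground and background) by half a
#' pixel; `edge_offset` (default 0.5) removes that bias so that extruded
#' widths match the segmented region instead of exceeding it by one pixel.
#'
#' With `refine = TRUE` (default) each profile point is additionally moved
#' onto the sub-pixel distance ridge: the distance function falls off with
#' unit slope on both sides of the medial axis, so sampling it one pixel
#' to either side along the local skeleton normal gives a tent profile
#' whose apex offset is `(d+ - d-) / 2`; the point moves there and its
#' radius grows by the distance moved. Skeleton pixels on thin or tilted
#' rods sit up to ~0.7 px off the true axis with correspondingly smaller
#' distance values, and without the refinement the reconstructed rod is
#' systematically thin. Points whose local tangent is undefined (isolated
#' clusters, e.g. the collapsed skeleton of a round blob) fall back to the
#' centroid of the local distance plateau.
#'
#' @param skeleton logical matrix (subset of the mask the distance map was
#'   computed from).
#' @param dmap numeric distance-map matrix (same shape).
#' @param edge_offset half-pixel correction subtracted from the distance
#'   value (default 0.5; 0 reproduces the raw background-pixel convention).
#' @param refine sub-pixel plateau refinement of centres (default TRUE).
#' @return data.frame with columns x, y (pixel units, possibly sub-pixel)
#'   and R (pixels).
#' @export
radius_profile <- function(skeleton, dmap, edge_offset = 0.5, refine = TRUE) {
  stopifnot(all(dim(skeleton) == dim(dmap)))
  px <- which(skeleton, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("radius_profile: empty skeleton")
  d0 <- dmap[px]
  if (any(d0 <= 0)) {
    stop("internal inconsistency: skeleton pixel with zero distance")
  }
  xs <- as.numeric(px[, 2L])
  ys <- as.numeric(px[, 1L])
  rr <- pmax(d0 - edge_offset, 0.5)
  if (refine) {
    nr <- nrow(dmap)
    nc <- ncol(dmap)
    interp <- function(y, x) {
      # bilinear interpolation of dmap at (row y, col x), clamped
      y <- min(max(y, 1), nr)
      x <- min(max(x, 1), nc)
      y0 <- floor(y); x0 <- floor(x)
      y1 <- min(y0 + 1L, nr); x1 <- min(x0 + 1L, nc)
      fy <- y - y0; fx <- x - x0
      dmap[y0, x0] * (1 - fy) * (1 - fx) + dmap[y1, x0] * fy * (1 - fx) +
        dmap[y0, x1] * (1 - fy) * fx + dmap[y1, x1] * fy * fx
    }
    for (i in seq_len(nrow(px))) {
      r0 <- px[i, 1L]
      c0 <- px[i, 2L]
      # local tangent from skeleton pixels within a 5x5 window
      near <- px[abs(px[, 1L] - r0) <= 2L & abs(px[, 2L] - c0) <= 2L, ,
                 drop = FALSE]
      tangent <- NULL
      if (nrow(near) >= 3L) {
        cc <- sweep(near, 2L, colMeans(near))
        sv <- svd(cc, nu = 0L, nv = 2L)
        if (sv$d[1L] > 2 * sv$d[2L]) tangent <- sv$v[, 1L]
      }
      if (!is.null(tangent)) {
        nrm <- c(-tangent[2L], tangent[1L])  # (row, col) normal
        dp <- interp(r0 + nrm[1L], c0 + nrm[2L])
        dm <- interp(r0 - nrm[1L], c0 - nrm[2L])
        tstar <- max(min((dp - dm) / 2, 0.71), -0.71)
        ys[i] <- r0 + tstar * nrm[1L]
        xs[i] <- c0 + tstar * nrm[2L]
        rr[i] <- pmax(d0[i] + abs(tstar) - 0.5, 0.5)
      } else {
        # round-cluster fallback: centroid of the local distance plateau
        rows <- max(1L, r0 - 1L):min(nr, r0 + 1L)
        cols <- max(1L, c0 - 1L):min(nc, c0 + 1L)
        patch <- dmap[rows, cols, drop = FALSE]
        plateau <- patch >= d0[i] - 0.5
        w <- sum(plateau)
        if (w > 1L) {
          cy <- sum(row(patch)[plateau] + rows[1L] - 1L) / w
          cx <- sum(col(patch)[plateau] + cols[1L] - 1L) / w
          shift <- sqrt((cy - r0)^2 + (cx - c0)^2)
          ys[i] <- cy
          xs[i] <- cx
          rr[i] <- pmax(d0[i] - 0.5 + shift, 0.5)
        }
      }
    }
  }
  data.frame(x = xs, y = ys, R = rr)
}

#' Cross-section radius of a sphere at an axial offset
#'
#' `r = sqrt(R^2 - dz^2)` for `dz < R`; `NA` (no cross-section) beyond the
#' sphere's pole. Both arguments must be in the same length unit (section
#' offsets are converted to pixel units with `z_spacing / pixel_size`
#' before calling).
#'
#' @param R parent-sphere radius (> 0).
#' @param dz axial distance from the sphere centre (>= 0).
#' @return cross-section radius, or NA where `dz >= R`. Vectorized.
#' @export
cross_section_radius <- function(R, dz) {
  if (any(R <= 0) || any(dz < 0)) stop("R must be > 0 and dz >= 0")
  r2 <- R^2 - dz^2
  ifelse(r2 > 0, sqrt(r2), NA_real_)
}

#' 3D region stack
#'
#' An ordered set of planar regions across optical sections forming one 3D
#' ROI (a reconstructed cell or a grouped nucleus), with a designated
#' midplane and the physical voxel geometry.
#'
#' @param regions list of `planar_region`, named by section index.
#' @param midplane_index section index of the midplane.
#' @param pixel_size lateral pixel size, micrometres.
#' @param z_spacing axial spacing (corrected), micrometres.
#' @return a `region_stack` object.
#' @export
region_stack <- function(regions, midplane_index, pixel_size, z_spacing) {
  stopifnot(length(regions) > 0L, pixel_size > 0, z_spacing > 0)
  secs <- vapply(regions, function(r) r$section, integer(1))
  regions <- regions[order(secs)]
  names(regions) <- sort(secs)
  structure(
    list(regions = regions, midplane_index = as.integer(midplane_index),
         pixel_size = pixel_size, z_spacing = z_spacing),
    class = "region_stack"
  )
}

#' @export
print.region_stack <- function(x, ...) {
  cat(sprintf("<region_stack> %d sections (%s..%s), midplane %d\n",
              length(x$regions), names(x$regions)[1],
              names(x$regions)[length(x$regions)], x$midplane_index))
  invisible(x)
}

#' Section indices covered by a region stack
#' @param stack a `region_stack`.
#' @return integer vector of section indices.
#' @export
stack_sections <- function(stack) as.integer(names(stack$regions))

#' Extrude a radius profile into a 3D region stack
#'
#' The reconstruction core: spheres are placed at every profile point with
#' the profile radius; at each optical section k the sphere of radius R
#' contributes a disk of radius `sqrt(R^2 - dz^2)` where
#' `dz = |k - midplane| * z_spacing / pixel_size`, and the section's region
#' is the union of all coplanar disks. A pixel belongs to a disk when its
#' centre lies inside the radius (inclusive boundary), which approximates
#' the majority-volume voxel rule to within half a voxel while keeping the
#' operation separable per section. By default disk centres keep their
#' sub-pixel profile coordinates; `round_centres = TRUE` snaps them to the
#' nearest pixel first (the convention of ROI systems that cannot represent
#' sub-pixel circles, at the cost of quantizing even-width rods to odd
#' pixel widths). Sections receiving no disk are absent from the output.
#'
#' @param profile data.frame from [radius_profile()].
#' @param midplane_index section index at which the profile was measured.
#' @param n_sections total number of optical sections available.
#' @param shape integer c(rows, cols) of the image.
#' @param pixel_size lateral pixel size, micrometres.
#' @param z_spacing axial section spacing (corrected), micrometres.
#' @param round_centres snap sphere centres to integer pixels (default
#'   FALSE).
#' @return a `region_stack`.
#' @export
extrude <- function(profile, midplane_index, n_sections, shape,
                    pixel_size, z_spacing, round_centres = FALSE) {
  if (nrow(profile) == 0L) stop("extrude: empty profile")
  if (z_spacing <= 0) stop("extrude: z_spacing must be > 0")
  if (midplane_index < 1L || midplane_index > n_sections) {
    stop("extrude: midplane_index out of range")
  }
  xs <- if (round_centres) round(profile$x) else profile$x
  ys <- if (round_centres) round(profile$y) else profile$y
  R2 <- profile$R^2
  step <- z_spacing / pixel_size
  regions <- list()
  for (k in seq_len(n_sections)) {
    dz2 <- (abs(k - midplane_index) * step)^2
    r2 <- R2 - dz2
    keep <- which(r2 > 0)
    if (length(keep) == 0L) next
    mask <- rasterize_disks(xs[keep], ys[keep], r2[keep], shape)
    if (!any(mask)) next
    regions[[as.character(k)]] <- planar_region(
      which(mask, arr.ind = TRUE), section = k, shape = shape
    )
  }
  region_stack(regions, midplane_index, pixel_size, z_spacing)
}

# union of disks: pixel centres within sqrt(r2) of any (x, y), inclusive
rasterize_disks <- function(xs, ys, r2, shape) {
  mask <- matrix(FALSE, shape[1L], shape[2L])
  for (i in seq_along(xs)) {
    rad <- sqrt(r2[i])
    rr <- max(1L, ceiling(ys[i] - rad)):min(shape[1L], floor(ys[i] + rad))
    cc <- max(1L, ceiling(xs[i] - rad)):min(shape[2L], floor(xs[i] + rad))
    if (length(rr) == 0L || length(cc) == 0L) next
    disk <- outer((rr - ys[i])^2, (cc - xs[i])^2, `+`) <= r2[i]
    mask[rr, cc] <- mask[rr, cc] | disk
  }
  mask
}

#' Calibrate a radius profile against its midplane region
#'
#' The reconstruction contract is that the union of the coplanar midplane
#' cross-sections reproduces the 2D midplane ROI. Distance-map radii carry
#' a small sub-pixel bias (the nearest background pixel centre overshoots
#' the region edge by an alignment-dependent fraction of a pixel), so a
#' common additive offset is fitted to all radii such that the rasterized
#' midplane union matches the ROI's pixel area; the bisection stops at the
#' offset whose area mismatch is smallest.
#'
#' @param profile data.frame from [radius_profile()].
#' @param target_area pixel area of the midplane region.
#' @param shape integer c(rows, cols) of the image.
#' @param limits numeric c(lo, hi) search window for the offset, pixels.
#' @return the profile with calibrated radii.
#' @export
calibrate_profile <- function(profile, target_area, shape,
                              limits = c(-1, 1.5)) {
  area_at <- function(delta) {
    r <- pmax(profile$R + delta, 0.25)
    sum(rasterize_disks(profile$x, profile$y, r^2, shape))
  }
  lo <- limits[1L]
  hi <- limits[2L]
  best_delta <- 0
  best_miss <- abs(area_at(0) - target_area)
  for (iter in seq_len(12L)) {
    mid <- (lo + hi) / 2
    a <- area_at(mid)
    miss <- abs(a - target_area)
    if (miss < best_miss) {
      best_miss <- miss
      best_delta <- mid
    }
    if (a == target_area) break
    if (a < target_area) lo <- mid else hi <- mid
  }
  profile$R <- pmax(profile$R + best_delta, 0.25)
  profile
}

#' Extrude a midplane region (skeleton + distance map + spheres)
#'
#' Convenience driver running [skeletonize()], [distance_map()],
#' [radius_profile()] and [extrude()] on a single midplane region.
#'
#' @param region a `planar_region` (the cell midplane ROI).
#' @param midplane_index section index to centre the extrusion on.
#' @param n_sections total number of optical sections.
#' @param pixel_size,z_spacing voxel geometry, micrometres.
#' @param prune passed to [skeletonize()].
#' @param calibrate fit the common radius offset that makes the midplane
#'   union reproduce the ROI area (see [calibrate_profile()]; default TRUE).
#' @return a `region_stack`.
#' @export
extrude_region <- function(region, midplane_index, n_sections,
                           pixel_size, z_spacing, prune = TRUE,
                           calibrate = TRUE) {
  mask <- region_mask(region)
  dmap <- distance_map(mask)
  skel <- skeletonize(mask, prune = prune)
  prof <- radius_profile(skel, dmap)
  if (calibrate) {
    prof <- calibrate_profile(prof, region_area(region), dim(mask))
  }
  extrude(prof, midplane_index, n_sections, dim(mask), pixel_size, z_spacing)
}

#' Batch extrusion over many midplane regions
#'
#' Applies [extrude_region()] per region; per-cell failures become failure
#' records instead of aborting the batch. Reconstructions of neighbouring
#' cells are independent, so their 3D ROIs may overlap; overlapping voxel
#' counts are reported with a warning.
#'
#' @param regions list of `planar_region` midplane ROIs.
#' @param midplane_indices integer vector (recycled) of per-cell midplane
#'   section indices.
#' @param n_sections total number of optical sections.
#' @param pixel_size,z_spacing voxel geometry, micrometres.
#' @param prune passed to [skeletonize()].
#' @return list with elements `stacks` (list of `region_stack`, named by
#'   region index) and `failures` (data.frame of region index + message).
#' @export
extrude_all <- function(regions, midplane_indices, n_sections,
                        pixel_size, z_spacing, prune = TRUE) {
  if (length(regions) == 0L) {
    return(list(stacks = list(),
                failures = data.frame(region = integer(), error = character())))
  }
  midplane_indices <- rep_len(as.integer(midplane_indices), length(regions))
  stacks <- list()
  fail_idx <- integer()
  fail_msg <- character()
  for (i in seq_along(regions)) {
    res <- tryCatch(
      extrude_region(regions[[i]], midplane_indices[i], n_sections,
                     pixel_size, z_spacing, prune = prune),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fail_idx <- c(fail_idx, i)
      fail_msg <- c(fail_msg, conditionMessage(res))
    } else {
      stacks[[as.character(i)]] <- res
    }
  }
  ov <- stack_overlap_voxels(stacks)
  if (ov > 0) {
    warning(sprintf("reconstructions of neighbouring cells overlap in %d voxels", ov))
  }
  list(stacks = stacks,
       failures = data.frame(region = fail_idx, error = fail_msg))
}

# total number of voxels claimed by more than one stack
stack_overlap_voxels <- function(stacks) {
  if (length(stacks) < 2L) return(0L)
  idx <- lapply(stacks, function(s) {
    shape <- s$regions[[1L]]$shape
    unlist(lapply(s$regions, function(r) {
      (r$section - 1) * prod(shape) + (r$pixels[, 2L] - 1) * shape[1L] +
        r$pixels[, 1L]
    }), use.names = FALSE)
  })
  all_idx <- unlist(idx, use.names = FALSE)
  sum(duplicated(all_idx))
}
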