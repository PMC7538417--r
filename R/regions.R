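#' Planar region (2D ROI) in one optical section
#'
#' A connected set of pixels in a single optical section, stored as an
#' `n x 2` integer matrix of (row, col) coordinates together with the image
#' shape it came from. All shape descriptors (area, perimeter, centroid,
#' circularity, solidity, Feret and ellipse dimensions) are computed from
#' the pixel set on demand.
#'
#' Coordinate convention: pixel (row r, col c) has its centre at x = c,
#' y = r, in pixel units.
#'
#' @param pixels integer matrix with columns (row, col), one row per pixel.
#' @param section 1-based optical-section index the region lives in.
#' @param shape integer c(rows, cols) of the source image.
#' @return a `planar_region` object.
#' @export
planar_region <- function(pixels, section, shape) {
  pixels <- matrix(as.integer(pixels), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(pixels) == 0L) stop("planar_region must contain at least 1 pixel")
  if (any(pixels[, 1L] < 1L) || any(pixels[, 2L] < 1L) ||
      any(pixels[, 1L] > shape[1L]) || any(pixels[, 2L] > shape[2L])) {
    stop("region pixels outside image shape")
  }
  structure(
    list(pixels = pixels, section = as.integer(section),
         shape = as.integer(shape)),
    class = "planar_region"
  )
}

#' @export
print.planar_region <- function(x, ...) {
  ctr <- region_centroid(x)
  cat(sprintf("<planar_region> section %d, %d px, centroid (%.1f, %.1f)\n",
              x$section, nrow(x$pixels), ctr[1], ctr[2]))
  invisible(x)
}

#' Binary mask of a region
#' @param region a `planar_region`.
#' @return logical matrix of the region's source image shape.
#' @export
region_mask <- function(region) {
  m <- matrix(FALSE, region$shape[1L], region$shape[2L])
  m[region$pixels] <- TRUE
  m
}

# bounding-box crop of the region mask with `pad` background pixels around it;
# returns list(mask, row0, col0) where (row0, col0) is the offset such that
# bbox row i corresponds to full-image row i + row0
region_bbox_mask <- function(region, pad = 1L) {
  rr <- range(region$pixels[, 1L])
  cc <- range(region$pixels[, 2L])
  nr <- rr[2L] - rr[1L] + 1L + 2L * pad
  nc <- cc[2L] - cc[1L] + 1L + 2L * pad
  m <- matrix(FALSE, nr, nc)
  m[cbind(region$pixels[, 1L] - rr[1L] + 1L + pad,
          region$pixels[, 2L] - cc[1L] + 1L + pad)] <- TRUE
  list(mask = m, row0 = rr[1L] - 1L - pad, col0 = cc[1L] - 1L - pad)
}

# rebuild a region from a bbox mask produced by region_bbox_mask()
region_from_bbox <- function(bbox_mask, row0, col0, section, shape) {
  px <- which(bbox_mask, arr.ind = TRUE)
  px[, 1L] <- px[, 1L] + row0
  px[, 2L] <- px[, 2L] + col0
  keep <- px[, 1L] >= 1L & px[, 2L] >= 1L &
    px[, 1L] <= shape[1L] & px[, 2L] <= shape[2L]
  planar_region(px[keep, , drop = FALSE], section, shape)
}

#' Region area in pixels
#' @param region a `planar_region`.
#' @return pixel count.
#' @export
region_area <- function(region) nrow(region$pixels)

#' Region centroid
#' @param region a `planar_region`.
#' @return numeric c(x, y) in pixel units.
#' @export
region_centroid <- function(region) {
  c(x = mean(region$pixels[, 2L]), y = mean(region$pixels[, 1L]))
}

# Moore boundary tracing of the single foreground object in `mask`
# (8-connected), with Jacob's stopping criterion (terminate on re-entering
# the start pixel from the same backtrack direction). Returns an m x 2
# matrix of (row, col) boundary pixel coordinates in order; the contour is
# closed (last connects to first).
trace_contour <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 1L) return(px)
  # ring of neighbour offsets in a fixed rotational order starting West;
  # the start pixel (topmost of the leftmost) has background to its west
  ring <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  fg <- function(p) {
    p[1L] >= 1L && p[2L] >= 1L && p[1L] <= nrow(mask) && p[2L] <= ncol(mask) &&
      mask[p[1L], p[2L]]
  }
  start <- px[order(px[, 2L], px[, 1L])[1L], ]
  contour <- matrix(0L, nrow = 4L * nrow(px) + 8L, ncol = 2L)
  contour[1L, ] <- start
  n <- 1L
  cur <- start
  back_dir <- 1L  # ring index pointing from cur to its backtrack pixel
  start_back <- back_dir
  repeat {
    found <- FALSE
    for (k in seq_len(8L)) {
      dir <- ((back_dir - 1L + k) %% 8L) + 1L
      cand <- cur + ring[dir, ]
      if (fg(cand)) {
        # backtrack of the next pixel: the background cell checked just
        # before the hit, expressed relative to the new position
        prev_dir <- ((dir - 2L) %% 8L) + 1L
        bg_cell <- cur + ring[prev_dir, ]
        d <- bg_cell - cand
        back_dir <- which(ring[, 1L] == d[1L] & ring[, 2L] == d[2L])
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (cur[1L] == start[1L] && cur[2L] == start[2L] &&
        back_dir == start_back) break
    n <- n + 1L
    contour[n, ] <- cur
    if (n >= nrow(contour)) break  # safety bound
  }
  contour[seq_len(n), , drop = FALSE]
}

# chain-code length of a closed contour (straight step 1, diagonal sqrt(2))
chain_length <- function(contour) {
  if (nrow(contour) < 2L) return(0)
  closed <- rbind(contour, contour[1L, , drop = FALSE])
  d <- diff(closed)
  sum(sqrt(rowSums(d^2)))
}

#' Region perimeter in pixels
#'
#' Chain-code length of the 8-connected Moore-traced boundary through
#' boundary pixel centres (straight steps count 1, diagonal steps
#' `sqrt(2)`), plus the boundary of any interior holes. Degenerate regions
#' (single pixels, dominoes) get the unit-square floor of 4 so circularity
#' stays defined.
#'
#' @param region a `planar_region`.
#' @return perimeter in pixel units.
#' @export
region_perimeter <- function(region) {
  bb <- region_bbox_mask(region)
  p <- chain_length(trace_contour(bb$mask))
  filled <- matrix(EBImage::imageData(EBImage::fillHull(EBImage::Image(bb$mask))) > 0,
                   nrow(bb$mask))
  holes <- filled & !bb$mask
  if (any(holes)) {
    lab <- matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(holes))),
                  nrow(holes))
    for (l in seq_len(max(lab))) {
      p <- p + chain_length(trace_contour(lab == l))
    }
  }
  max(p, 4)
}

#' Circularity of a region
#'
#' `C = 4 * pi * A / P^2`, clipped to `[0, 1]` to absorb rasterization
#' overshoot; 1 for an ideal circle.
#'
#' @param area region area (any consistent unit).
#' @param perimeter region perimeter (same length unit).
#' @return circularity in `[0, 1]`.
#' @export
circularity <- function(area, perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be > 0")
  pmin(1, pmax(0, 4 * pi * area / perimeter^2))
}

#' @describeIn circularity circularity of a `planar_region` using the
#'   chain-code perimeter.
#' @param region a `planar_region`.
#' @export
region_circularity <- function(region) {
  circularity(region_area(region), region_perimeter(region))
}

# area of the convex hull of a point set (shoelace over grDevices::chull)
hull_area <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) return(0)
  x <- hp[, 1L]; y <- hp[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Solidity of a region
#'
#' Area divided by convex-hull area (hull taken through pixel centres),
#' clipped at 1. A convex region has solidity 1; bent or concave regions
#' fall below 1, which makes solidity a practical curvature proxy.
#'
#' @param region a `planar_region`.
#' @return solidity in (0, 1].
#' @export
region_solidity <- function(region) {
  if (region_area(region) < 3L) stop("region too small for solidity")
  ha <- hull_area(region$pixels)
  if (ha <= 0) stop("degenerate (collinear) region")
  min(1, region_area(region) / ha)
}

#' Feret (caliper) diameters of a region
#'
#' Maximum and minimum caliper width over all rotations of the convex hull
#' (rotating calipers on pixel centres): the maximum Feret diameter is the
#' largest pairwise distance between hull vertices, the minimum is the
#' smallest band enclosing the hull between two parallel tangent lines.
#'
#' @param region a `planar_region`.
#' @return numeric c(L, W) in pixel units, L >= W.
#' @export
feret_dims <- function(region) {
  if (region_area(region) < 3L) stop("region too small for Feret diameters")
  pts <- unique(region$pixels)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) < 2L) stop("degenerate region")
  d2 <- as.matrix(stats::dist(hp))
  L <- max(d2)
  n <- nrow(hp)
  if (n == 2L) {
    W <- 0
  } else {
    W <- Inf
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      e <- hp[j, ] - hp[i, ]
      len <- sqrt(sum(e^2))
      if (len == 0) next
      # distance of every hull point from the line through edge i-j
      v <- sweep(hp, 2L, hp[i, ])
      W <- min(W, max(abs(v[, 1L] * e[2L] - v[, 2L] * e[1L]) / len))
    }
  }
  c(L = L, W = W)
}

# area-preserving second-moment ellipse parameters of a pixel set:
# list(cx, cy, theta, a, b) with semi-axes a >= b (pixel units) scaled so
# that pi*a*b equals the pixel count, orientation theta in radians
# (x towards +col, y towards +row).
moment_ellipse <- function(pixels) {
  n <- nrow(pixels)
  y <- pixels[, 1L]; x <- pixels[, 2L]
  cx <- mean(x); cy <- mean(y)
  # second central moments with the unit-pixel term (each pixel is a unit
  # square, variance 1/12) so single-row/column regions stay non-degenerate
  mxx <- mean((x - cx)^2) + 1 / 12
  myy <- mean((y - cy)^2) + 1 / 12
  mxy <- mean((x - cx) * (y - cy))
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (mxx + myy + common) / 2
  l2 <- (mxx + myy - common) / 2
  if (l2 <= 0) stop("degenerate (collinear) region")
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  ratio <- sqrt(l1 / l2)
  a <- sqrt(n * ratio / pi)
  b <- sqrt(n / (pi * ratio))
  list(cx = cx, cy = cy, theta = theta, a = a, b = b)
}

#' Major and minor axes of the area-preserving fitted ellipse
#'
#' Axes of the second-moment ellipse scaled so the ellipse area equals the
#' region's pixel area (the same fit used by [fit_ellipse()]).
#'
#' @param region a `planar_region`.
#' @return numeric c(L, W): major and minor axis lengths in pixel units.
#' @export
ellipse_dims <- function(region) {
  if (region_area(region) < 5L) stop("region too small for ellipse fit")
  e <- moment_ellipse(region$pixels)
  c(L = 2 * e$a, W = 2 * e$b)
}

#' Replace a region by its fitted ellipse
#'
#' Rasterizes the area-preserving second-moment ellipse of the region:
#' centroid and orientation are those of the input and the axes are scaled
#' so the rasterized area matches the input area as closely as the pixel
#' grid allows. Used to regularize nuclear sections whose nucleolar side
#' was under-segmented.
#'
#' @param region a `planar_region`.
#' @return a `planar_region` of the rasterized ellipse.
#' @export
fit_ellipse <- function(region) {
  if (region_area(region) < 5L) stop("region too small for ellipse fit")
  e <- moment_ellipse(region$pixels)
  target <- region_area(region)
  raster <- function(scale) {
    a <- e$a * scale; b <- e$b * scale
    rr <- max(1L, floor(e$cy - a)):min(region$shape[1L], ceiling(e$cy + a))
    cc <- max(1L, floor(e$cx - a)):min(region$shape[2L], ceiling(e$cx + a))
    dx <- outer(rep(1, length(rr)), cc - e$cx)
    dy <- outer(rr - e$cy, rep(1, length(cc)))
    u <- cos(e$theta) * dx + sin(e$theta) * dy
    v <- -sin(e$theta) * dx + cos(e$theta) * dy
    inside <- (u / a)^2 + (v / b)^2 <= 1
    px <- which(inside, arr.ind = TRUE)
    cbind(rr[px[, 1L]], cc[px[, 2L]])
  }
  # the moment scaling is already area-true in the continuum; nudge the
  # scale so the discrete pixel count matches the target area
  best <- raster(1)
  if (nrow(best) != target) {
    for (s in seq(0.9, 1.1, by = 0.005)) {
      cand <- raster(s)
      if (abs(nrow(cand) - target) < abs(nrow(best) - target)) best <- cand
      if (nrow(best) == target) break
    }
  }
  planar_region(best, region$section, region$shape)
}

#' Dilate a region by a physical margin
#'
#' Morphological dilation with a disc structuring element of radius
#' `round(margin / pixel_size)` pixels; a margin of 0 (or one that rounds
#' to 0 pixels) returns the region unchanged.
#'
#' @param region a `planar_region`.
#' @param margin dilation margin in micrometres (>= 0).
#' @param pixel_size pixel size in micrometres.
#' @return the dilated `planar_region` (clipped at image bounds).
#' @export
dilate_region <- function(region, margin, pixel_size) {
  if (margin < 0) stop("margin must be >= 0")
  r <- round(margin / pixel_size)
  if (r < 1) return(region)
  bb <- region_bbox_mask(region, pad = r + 1L)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  dil <- matrix(EBImage::dilate(EBImage::Image(bb$mask), brush) > 0,
                nrow(bb$mask))
  region_from_bbox(dil, bb$row0, bb$col0, region$section, region$shape)
}

#' Connected components of a binary mask as regions
#'
#' 8-connected labelling; one `planar_region` per component.
#'
#' @param mask logical matrix.
#' @param section optical-section index to stamp on the regions.
#' @return list of `planar_region` (possibly empty).
#' @export
label_regions <- function(mask, section = 1L) {
  if (!any(mask)) return(list())
  lab <- label8(mask)
  px <- which(mask, arr.ind = TRUE)
  ids <- lab[px]
  lapply(split(seq_len(nrow(px)), ids), function(i) {
    planar_region(px[i, , drop = FALSE], section, dim(mask))
  })
}

# 8-connected component labelling: 4-connected base labelling, then
# union-find merging of labels that touch diagonally
label8 <- function(mask) {
  lab <- matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask))),
                nrow(mask))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  merge_pairs <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    if (!any(sel)) return(invisible())
    pairs <- unique(cbind(a[sel], b[sel]))
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L])
      rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  nr <- nrow(lab)
  nc <- ncol(lab)
  merge_pairs(lab[-nr, -nc], lab[-1L, -1L])  # down-right diagonal
  merge_pairs(lab[-nr, -1L], lab[-1L, -nc])  # down-left diagonal
  roots <- vapply(seq_len(nlab), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- compact[lab[lab > 0]]
  out
}
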