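#' Scene geometry for synthetic phantoms
#'
#' Field size, stack depth and the true (physical) voxel geometry used to
#' render phantoms. The defaults mirror a typical widefield acquisition of
#' a fission yeast monolayer: 0.1071 um lateral pixels and 72 optical
#' sections whose nominal 0.1 um spacing shrinks to 0.065 um after axial
#' distance correction; phantoms are rendered directly at the corrected
#' spacing. The focus plane sits mid-stack where the cell layer lies.
#'
#' @param field_px integer c(rows, cols) of the field.
#' @param n_sections number of optical sections.
#' @param pixel_size lateral pixel size, micrometres.
#' @param z_spacing true (corrected) section spacing, micrometres.
#' @param focus_index most in-focus section.
#' @return a `scene_geometry` object.
#' @export
scene_geometry <- function(field_px = c(768L, 768L), n_sections = 72L,
                           pixel_size = 0.1071, z_spacing = 0.065,
                           focus_index = NULL) {
  if (is.null(focus_index)) focus_index <- round(n_sections / 2)
  structure(
    list(field_px = as.integer(field_px), n_sections = as.integer(n_sections),
         pixel_size = pixel_size, z_spacing = z_spacing,
         focus_index = as.integer(focus_index)),
    class = "scene_geometry"
  )
}

#' Phantom specification
#'
#' One synthetic cell: a straight, bent or tapered capsule (or a sphere)
#' with a prolate ellipsoidal nucleus inside. All dimensions are
#' micrometres; `length_um` is tip-to-tip (axis length `length - width`
#' plus the two hemispherical caps), `bend_angle` is the total turning
#' angle of the arc-shaped axis, and the nucleus is centred on the axis at
#' `nucleus_offset_um` from the cell centre.
#'
#' @param shape "straight", "bent", "tapered" or "sphere".
#' @param length_um tip-to-tip length.
#' @param width_um cell width (= 2 x radius); for spheres equal to length.
#' @param centre_um numeric c(x, y, z) centre in micrometres.
#' @param orientation_deg axis orientation in the XY plane.
#' @param bend_angle_deg total arc angle (bent shape only).
#' @param taper_ratio tip-to-base radius ratio (tapered shape only).
#' @param nucleus_axes_um c(a, b): prolate semi-axes of the nucleus.
#' @param nucleus_offset_um signed axial offset of the nucleus centre.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c("straight", "bent", "tapered", "sphere"),
                         length_um, width_um, centre_um,
                         orientation_deg = 0, bend_angle_deg = 0,
                         taper_ratio = 0.7,
                         nucleus_axes_um = NULL, nucleus_offset_um = 0) {
  shape <- match.arg(shape)
  if (shape == "sphere") width_um <- length_um
  if (width_um > length_um) stop("width must not exceed length")
  if (!is.null(nucleus_axes_um)) {
    if (2 * nucleus_axes_um[2L] >= width_um) {
      stop("nucleus does not fit inside the cell width")
    }
  }
  structure(
    list(shape = shape, length_um = length_um, width_um = width_um,
         centre_um = centre_um, orientation_deg = orientation_deg,
         bend_angle_deg = bend_angle_deg, taper_ratio = taper_ratio,
         nucleus_axes_um = nucleus_axes_um,
         nucleus_offset_um = nucleus_offset_um),
    class = "phantom_spec"
  )
}

#' Analytic volume of a phantom
#'
#' Straight and bent capsules: `V = h*pi*r^2 + (4/3)*pi*r^3` (for the bent
#' axis by Pappus' theorem, since the disk centroid travels the arc
#' length). Sphere: `(4/3)*pi*r^3`. Tapered capsule: conical frustum plus
#' two hemispherical caps of the end radii.
#'
#' @param spec a `phantom_spec`.
#' @return volume in cubic micrometres.
#' @export
phantom_volume <- function(spec) {
  r <- spec$width_um / 2
  h <- spec$length_um - spec$width_um
  switch(spec$shape,
    sphere = (4 / 3) * pi * r^3,
    straight = ,
    bent = h * pi * r^2 + (4 / 3) * pi * r^3,
    tapered = {
      r2 <- r * spec$taper_ratio
      # axis length so that tip-to-tip = length: h + r + r2
      ha <- spec$length_um - r - r2
      pi * ha * (r^2 + r * r2 + r2^2) / 3 +
        (2 / 3) * pi * r^3 + (2 / 3) * pi * r2^3
    }
  )
}

# XY distance from points (x, y) to the phantom axis, plus local radius;
# returns list(dist, radius). Axis lies in the z = centre z plane.
axis_distance_xy <- function(spec, x, y) {
  th <- spec$orientation_deg * pi / 180
  u <- c(cos(th), sin(th))
  ctr <- spec$centre_um[1:2]
  r <- spec$width_um / 2
  if (spec$shape == "sphere") {
    return(list(dist = sqrt((x - ctr[1L])^2 + (y - ctr[2L])^2),
                radius = rep(r, length(x))))
  }
  if (spec$shape == "tapered") {
    r2 <- r * spec$taper_ratio
    ha <- spec$length_um - r - r2
    p1 <- ctr - ha / 2 * u
    dx <- x - p1[1L]
    dy <- y - p1[2L]
    t <- pmin(pmax((dx * u[1L] + dy * u[2L]) / ha, 0), 1)
    ax <- p1[1L] + t * ha * u[1L]
    ay <- p1[2L] + t * ha * u[2L]
    return(list(dist = sqrt((x - ax)^2 + (y - ay)^2),
                radius = r + (r2 - r) * t))
  }
  h <- spec$length_um - spec$width_um
  if (spec$shape == "straight" || spec$bend_angle_deg == 0) {
    p1 <- ctr - h / 2 * u
    dx <- x - p1[1L]
    dy <- y - p1[2L]
    t <- pmin(pmax((dx * u[1L] + dy * u[2L]) / h, 0), 1)
    ax <- p1[1L] + t * h * u[1L]
    ay <- p1[2L] + t * h * u[2L]
    return(list(dist = sqrt((x - ax)^2 + (y - ay)^2),
                radius = rep(r, length(x))))
  }
  # bent: circular arc of length h, total angle theta, midpoint at centre;
  # arc centre perpendicular to the orientation direction
  theta <- spec$bend_angle_deg * pi / 180
  rho <- h / theta
  n <- c(-u[2L], u[1L])
  cc <- ctr + rho * n
  qx <- x - cc[1L]
  qy <- y - cc[2L]
  # signed angle of (qx, qy) measured from the direction (centre - cc)
  base <- -n
  phi <- atan2(base[1L] * qy - base[2L] * qx, base[1L] * qx + base[2L] * qy)
  phic <- pmin(pmax(phi, -theta / 2), theta / 2)
  ax <- cc[1L] + rho * (base[1L] * cos(phic) - base[2L] * sin(phic))
  ay <- cc[2L] + rho * (base[1L] * sin(phic) + base[2L] * cos(phic))
  list(dist = sqrt((x - ax)^2 + (y - ay)^2), radius = rep(r, length(x)))
}

# sampled points along the phantom axis (for overlap tests), micrometres
axis_points <- function(spec, step = 0.5) {
  th <- spec$orientation_deg * pi / 180
  u <- c(cos(th), sin(th))
  ctr <- spec$centre_um[1:2]
  if (spec$shape == "sphere") return(matrix(ctr, ncol = 2L))
  h <- max(spec$length_um - spec$width_um, 1e-6)
  t <- seq(-h / 2, h / 2, by = step)
  if (!h / 2 %in% t) t <- c(t, h / 2)
  if (spec$shape == "bent" && spec$bend_angle_deg > 0) {
    theta <- spec$bend_angle_deg * pi / 180
    rho <- h / theta
    n <- c(-u[2L], u[1L])
    cc <- ctr + rho * n
    base <- -n
    phi <- t / rho
    cbind(cc[1L] + rho * (base[1L] * cos(phi) - base[2L] * sin(phi)),
          cc[2L] + rho * (base[1L] * sin(phi) + base[2L] * cos(phi)))
  } else {
    cbind(ctr[1L] + t * u[1L], ctr[2L] + t * u[2L])
  }
}

#' Ground-truth voxel mask of a phantom
#'
#' Voxelizes the analytic solid over its bounding box: a voxel belongs to
#' the phantom when its centre lies within the local radius of the axis.
#' Pixel (r, c) of section k has its centre at x = c * pixel_size,
#' y = r * pixel_size, z = k * z_spacing.
#'
#' @param spec a `phantom_spec`.
#' @param geometry a `scene_geometry`.
#' @return list(mask = logical array, row0/col0/sec0 = offsets such that
#'   mask index (i, j, k) is field voxel (i + row0, j + col0, k + sec0),
#'   volume_um3 = analytic volume).
#' @export
truth_voxels <- function(spec, geometry) {
  px <- geometry$pixel_size
  zs <- geometry$z_spacing
  r <- spec$width_um / 2
  half <- spec$length_um / 2 + 2 * px
  ctr <- spec$centre_um
  rows <- max(1L, floor((ctr[2L] - half) / px)):
    min(geometry$field_px[1L], ceiling((ctr[2L] + half) / px))
  cols <- max(1L, floor((ctr[1L] - half) / px)):
    min(geometry$field_px[2L], ceiling((ctr[1L] + half) / px))
  secs <- max(1L, floor((ctr[3L] - r - zs) / zs)):
    min(geometry$n_sections, ceiling((ctr[3L] + r + zs) / zs))
  if (ctr[1L] - half < 0 || ctr[2L] - half < 0 ||
      ctr[1L] + half > geometry$field_px[2L] * px ||
      ctr[2L] + half > geometry$field_px[1L] * px ||
      ctr[3L] - r < 0 || ctr[3L] + r > geometry$n_sections * zs) {
    stop("phantom does not fit inside the stack")
  }
  xg <- rep(cols * px, each = length(rows))
  yg <- rep(rows * px, times = length(cols))
  ad <- axis_distance_xy(spec, xg, yg)
  mask <- array(FALSE, c(length(rows), length(cols), length(secs)))
  for (k in seq_along(secs)) {
    dz <- secs[k] * zs - ctr[3L]
    inside <- ad$dist^2 + dz^2 <= ad$radius^2
    mask[, , k] <- inside
  }
  list(mask = mask, row0 = rows[1L] - 1L, col0 = cols[1L] - 1L,
       sec0 = secs[1L] - 1L, volume_um3 = phantom_volume(spec))
}

#' Ground-truth midplane label mask of a scene
#'
#' 2D label image of the analytic midplane cross-sections (one label per
#' phantom, in list order), used to match segmented regions to the truth.
#'
#' @param specs list of `phantom_spec`.
#' @param geometry a `scene_geometry`.
#' @return integer matrix of labels.
#' @export
truth_midplane_labels <- function(specs, geometry) {
  px <- geometry$pixel_size
  lab <- matrix(0L, geometry$field_px[1L], geometry$field_px[2L])
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    half <- spec$length_um / 2 + 2 * px
    ctr <- spec$centre_um
    rows <- max(1L, floor((ctr[2L] - half) / px)):
      min(geometry$field_px[1L], ceiling((ctr[2L] + half) / px))
    cols <- max(1L, floor((ctr[1L] - half) / px)):
      min(geometry$field_px[2L], ceiling((ctr[1L] + half) / px))
    xg <- rep(cols * px, each = length(rows))
    yg <- rep(rows * px, times = length(cols))
    ad <- axis_distance_xy(spec, xg, yg)
    inside <- matrix(ad$dist <= ad$radius, length(rows))
    sub <- lab[rows, cols]
    sub[inside] <- i
    lab[rows, cols] <- sub
  }
  lab
}

#' Render the brightfield channel of a scene
#'
#' A geometric model of the defocus boundary band: at section k each cell
#' contributes a dark band of width `band_slope * |k - focus|` pixels
#' centred on its analytic midplane outline, over a bright background; at
#' the focus the band width is zero and the section is featureless, so
#' the focus is recoverable as the minimum-standard-deviation section.
#' Gaussian noise is added with the given seed. This is a band model, not
#' an optics simulation: it reproduces the features the segmentation
#' relies on (band growth with defocus, uniform focus section) and nothing
#' else.
#'
#' @param specs list of `phantom_spec`.
#' @param geometry a `scene_geometry`.
#' @param band_slope band width growth, pixels per section.
#' @param contrast band darkening fraction in (0, 1].
#' @param background background intensity.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed for the noise.
#' @return an `image_stack` (z_spacing = the true corrected spacing).
#' @export
render_brightfield <- function(specs, geometry, band_slope = 0.35,
                               contrast = 0.5, background = 0.8,
                               noise_sd = 0.02, seed = 1L) {
  px <- geometry$pixel_size
  nr <- geometry$field_px[1L]
  nc <- geometry$field_px[2L]
  ns <- geometry$n_sections
  dark <- background * (1 - contrast)
  # per-cell distance-to-outline field over a padded bounding box
  fields <- lapply(specs, function(spec) {
    pad_um <- band_slope * max(geometry$focus_index,
                               ns - geometry$focus_index) * px / 2 + 2 * px
    half <- spec$length_um / 2 + pad_um
    ctr <- spec$centre_um
    rows <- max(1L, floor((ctr[2L] - half) / px)):
      min(nr, ceiling((ctr[2L] + half) / px))
    cols <- max(1L, floor((ctr[1L] - half) / px)):
      min(nc, ceiling((ctr[1L] + half) / px))
    xg <- rep(cols * px, each = length(rows))
    yg <- rep(rows * px, times = length(cols))
    ad <- axis_distance_xy(spec, xg, yg)
    list(rows = rows, cols = cols,
         dist = matrix(abs(ad$dist - ad$radius) / px, length(rows)))
  })
  data <- array(background, c(nr, nc, ns))
  for (k in seq_len(ns)) {
    w <- band_slope * abs(k - geometry$focus_index)
    if (w <= 0) next
    plane <- data[, , k]
    for (f in fields) {
      sub <- plane[f$rows, f$cols]
      sub[f$dist <= w / 2] <- dark
      plane[f$rows, f$cols] <- sub
    }
    data[, , k] <- plane
  }
  if (noise_sd > 0) {
    set.seed(seed)
    data <- data + stats::rnorm(length(data), sd = noise_sd)
  }
  image_stack(data, px, geometry$z_spacing)
}

#' Render the nuclear marker channel of a scene
#'
#' Each nucleus is a bright prolate ellipsoid (long axis along the cell
#' axis) with a slightly dimmer central nucleolar sphere - dim enough to
#' be visible, bright enough that a background/foreground threshold keeps
#' it inside the nucleus, as in real nuclear-marker images - over a dark
#' background; Gaussian noise is seeded. Intensities are arbitrary
#' camera-count-like units.
#'
#' @param specs list of `phantom_spec` (those without a nucleus are
#'   skipped).
#' @param geometry a `scene_geometry`.
#' @param intensity nuclear signal level.
#' @param background background level.
#' @param nucleolus_dim nucleolar dimming factor in (0, 1]; 1 renders a
#'   uniform ellipsoid.
#' @param nucleolus_frac nucleolar radius as a fraction of the short
#'   nuclear semi-axis.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed for the noise.
#' @return an `image_stack`.
#' @export
render_nucleus_channel <- function(specs, geometry, intensity = 1000,
                                   background = 100, nucleolus_dim = 0.75,
                                   nucleolus_frac = 0.5, noise_sd = 20,
                                   seed = 1L) {
  px <- geometry$pixel_size
  zs <- geometry$z_spacing
  nr <- geometry$field_px[1L]
  nc <- geometry$field_px[2L]
  ns <- geometry$n_sections
  data <- array(background, c(nr, nc, ns))
  for (spec in specs) {
    if (is.null(spec$nucleus_axes_um)) next
    a <- spec$nucleus_axes_um[1L]
    b <- spec$nucleus_axes_um[2L]
    th <- spec$orientation_deg * pi / 180
    u <- c(cos(th), sin(th))
    nctr <- nucleus_centre(spec)
    rn <- nucleolus_frac * b
    rows <- max(1L, floor((nctr[2L] - a) / px)):
      min(nr, ceiling((nctr[2L] + a) / px))
    cols <- max(1L, floor((nctr[1L] - a) / px)):
      min(nc, ceiling((nctr[1L] + a) / px))
    xg <- rep(cols * px, each = length(rows)) - nctr[1L]
    yg <- rep(rows * px, times = length(cols)) - nctr[2L]
    lon <- xg * u[1L] + yg * u[2L]        # along the long axis
    lat <- -xg * u[2L] + yg * u[1L]       # across
    for (k in seq_len(ns)) {
      dz <- k * zs - nctr[3L]
      if (abs(dz) >= b) next
      inside <- (lon / a)^2 + (lat / b)^2 + (dz / b)^2 <= 1
      if (!any(inside)) next
      sub <- data[rows, cols, k]
      sub[inside] <- intensity
      if (nucleolus_dim < 1 && rn > 0) {
        nucleolus <- xg^2 + yg^2 + dz^2 <= rn^2
        sub[nucleolus] <- intensity * nucleolus_dim
      }
      data[rows, cols, k] <- sub
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    data <- data + stats::rnorm(length(data), sd = noise_sd)
  }
  image_stack(data, px, zs)
}

# 3D centre of a phantom's nucleus (offset along the axis), micrometres
nucleus_centre <- function(spec) {
  th <- spec$orientation_deg * pi / 180
  u <- c(cos(th), sin(th))
  off <- spec$nucleus_offset_um
  if (spec$shape == "bent" && spec$bend_angle_deg > 0) {
    h <- spec$length_um - spec$width_um
    theta <- spec$bend_angle_deg * pi / 180
    rho <- h / theta
    n <- c(-u[2L], u[1L])
    cc <- spec$centre_um[1:2] + rho * n
    base <- -n
    phi <- off / rho
    xy <- c(cc[1L] + rho * (base[1L] * cos(phi) - base[2L] * sin(phi)),
            cc[2L] + rho * (base[1L] * sin(phi) + base[2L] * cos(phi)))
    c(xy, spec$centre_um[3L])
  } else {
    c(spec$centre_um[1:2] + off * u, spec$centre_um[3L])
  }
}

#' Generate a random multi-cell scene with ground truth
#'
#' Draws `n_cells` non-overlapping phantoms (rejection sampling on the
#' axis-to-axis clearance) in a flat layer at the focus plane, renders the
#' brightfield and nuclear channels, and returns the analytic truth table.
#' Presets emulate typical fission yeast populations: `wt` straight rods
#' (8-13 um), `short` (5-7 um) and `long` (16-22 um) size mutants, and
#' `bent` curved rods (40-80 degree arcs). Widths are 3.6-4.2 um; each
#' nucleus is sized so its analytic volume is `nc_ratio` of the cell's,
#' with prolate axis ratio 1.1. All randomness flows from `seed`.
#'
#' @param n_cells number of phantoms.
#' @param preset "wt", "short", "long" or "bent".
#' @param geometry a `scene_geometry`.
#' @param seed integer seed.
#' @param nc_ratio generated nuclear-to-cell volume ratio.
#' @param clearance_um minimum surface-to-surface clearance between cells.
#' @param margin_um minimum distance of any cell tip from the field edge.
#' @param render render the image channels (FALSE returns specs and truth
#'   only).
#' @param noise_sd_bf,noise_sd_nuc channel noise levels.
#' @return list(specs, truth, geometry, brightfield, nuclear); `truth` is
#'   a data.frame with the per-cell analytic measurements.
#' @export
make_scene <- function(n_cells = 20L, preset = c("wt", "short", "long", "bent"),
                       geometry = scene_geometry(), seed = 1L,
                       nc_ratio = 0.125, clearance_um = 1.5, margin_um = 5,
                       render = TRUE, noise_sd_bf = 0.02, noise_sd_nuc = 20) {
  preset <- match.arg(preset)
  set.seed(seed)
  px <- geometry$pixel_size
  field_um <- rev(geometry$field_px) * px  # (x extent, y extent)
  z0 <- geometry$focus_index * geometry$z_spacing
  specs <- list()
  axes <- list()
  tries <- 0L
  while (length(specs) < n_cells) {
    tries <- tries + 1L
    if (tries > 400L * n_cells) {
      stop("could not place phantoms: field too dense for the preset")
    }
    len <- switch(preset,
      wt = stats::runif(1, 8, 13),
      short = stats::runif(1, 5, 7),
      long = stats::runif(1, 16, 22),
      bent = stats::runif(1, 8, 13)
    )
    wid <- stats::runif(1, 3.6, 4.2)
    bend <- if (preset == "bent") stats::runif(1, 40, 80) else 0
    orient <- stats::runif(1, 0, 180)
    lo <- margin_um + len / 2
    ctr <- c(stats::runif(1, lo, field_um[1L] - lo),
             stats::runif(1, lo, field_um[2L] - lo), z0)
    cand <- phantom_spec(
      shape = if (preset == "bent") "bent" else "straight",
      length_um = len, width_um = wid, centre_um = ctr,
      orientation_deg = orient, bend_angle_deg = bend
    )
    pts <- axis_points(cand)
    ok <- TRUE
    for (i in seq_along(specs)) {
      d2 <- outer(pts[, 1L], axes[[i]][, 1L], `-`)^2 +
        outer(pts[, 2L], axes[[i]][, 2L], `-`)^2
      lim <- (wid + specs[[i]]$width_um) / 2 + clearance_um
      if (min(d2) < lim^2) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    # nucleus sized to the target N/C ratio, prolate a/b = 1.1
    vn <- nc_ratio * phantom_volume(cand)
    b <- (3 * vn / (4 * pi * 1.1))^(1 / 3)
    a <- 1.1 * b
    h <- len - wid
    max_off <- max(0, h / 2 - a - 0.3)
    off <- stats::runif(1, -max_off, max_off)
    cand$nucleus_axes_um <- c(a, b)
    cand$nucleus_offset_um <- off
    specs[[length(specs) + 1L]] <- cand
    axes[[length(axes) + 1L]] <- pts
  }
  truth <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    nc <- nucleus_centre(s)
    data.frame(
      id = i, shape = s$shape, length_um = s$length_um,
      width_um = s$width_um, bend_deg = s$bend_angle_deg,
      orientation_deg = s$orientation_deg,
      centre_x_um = s$centre_um[1L], centre_y_um = s$centre_um[2L],
      volume_um3 = phantom_volume(s),
      rod_volume_um3 = rod_volume(s$length_um, s$width_um),
      nuc_a_um = s$nucleus_axes_um[1L], nuc_b_um = s$nucleus_axes_um[2L],
      nuc_volume_um3 = (4 / 3) * pi * s$nucleus_axes_um[1L] *
        s$nucleus_axes_um[2L]^2,
      nuc_centre_x_um = nc[1L], nuc_centre_y_um = nc[2L],
      nc_ratio = nc_ratio
    )
  }))
  out <- list(specs = specs, truth = truth, geometry = geometry)
  if (render) {
    out$brightfield <- render_brightfield(specs, geometry,
                                          noise_sd = noise_sd_bf,
                                          seed = seed + 1L)
    out$nuclear <- render_nucleus_channel(specs, geometry,
                                          noise_sd = noise_sd_nuc,
                                          seed = seed + 2L)
  }
  out
}
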