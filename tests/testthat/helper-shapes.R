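# analytic fixture rasterizers, independent of the package's own phantom code

# capsule: all pixel centres within r of the segment p1-p2 (x = col, y = row)
raster_capsule <- function(nr, nc, p1, p2, r) {
  jj <- matrix(rep(seq_len(nc), each = nr), nr)
  ii <- matrix(rep(seq_len(nr), nc), nr)
  vx <- p2[1] - p1[1]
  vy <- p2[2] - p1[2]
  l2 <- max(vx^2 + vy^2, 1e-12)
  t <- pmin(pmax(((jj - p1[1]) * vx + (ii - p1[2]) * vy) / l2, 0), 1)
  (jj - (p1[1] + t * vx))^2 + (ii - (p1[2] + t * vy))^2 <= r^2
}

# bent capsule: axis is a circular arc of length h and total angle ang_deg,
# arc midpoint at ctr = c(x, y), bending "upwards" in row direction
raster_bent_capsule <- function(nr, nc, ctr, ang_deg, h, r) {
  th <- ang_deg * pi / 180
  rho <- h / th
  jj <- matrix(rep(seq_len(nc), each = nr), nr)
  ii <- matrix(rep(seq_len(nr), nc), nr)
  cx <- ctr[1]
  cy <- ctr[2] + rho
  qx <- jj - cx
  qy <- ii - cy
  phi <- atan2(qx, -qy)
  phic <- pmin(pmax(phi, -th / 2), th / 2)
  ax <- cx + rho * sin(phic)
  ay <- cy - rho * cos(phic)
  (jj - ax)^2 + (ii - ay)^2 <= r^2
}

raster_disk <- function(n, cx, cy, r) {
  raster_capsule(n, n, c(cx, cy), c(cx, cy), r)
}

mask_region <- function(mask, section = 1L) {
  planar_region(which(mask, arr.ind = TRUE), section, dim(mask))
}

# standard test capsule: L = 120, W = 40 px at a generic tilt and sub-pixel
# centre (axis-aligned integer placement is a degenerate grid alignment)
test_capsule <- function(angle_deg = 20) {
  th <- angle_deg * pi / 180
  h <- 80
  ctr <- c(80.3, 80.7)
  p1 <- ctr - h / 2 * c(cos(th), sin(th))
  p2 <- ctr + h / 2 * c(cos(th), sin(th))
  raster_capsule(160, 160, p1, p2, 20)
}

capsule_volume_true <- function(h, r) h * pi * r^2 + (4 / 3) * pi * r^3
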