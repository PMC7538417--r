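# brute-force / closed-form oracles, written independently of the code
# paths they check

# direct 2D convolution with replicate padding (small images only)
brute_convolve <- function(img, kernel) {
  kr <- (nrow(kernel) - 1) / 2
  kc <- (ncol(kernel) - 1) / 2
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      acc <- 0
      for (a in -kr:kr) {
        for (b in -kc:kc) {
          ii <- min(max(i + a, 1), nrow(img))
          jj <- min(max(j + b, 1), ncol(img))
          acc <- acc + img[ii, jj] * kernel[a + kr + 1, b + kc + 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# all-pairs Euclidean distance transform (foreground to nearest background)
brute_distance_map <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2
    out[fg[k, 1], fg[k, 2]] <- sqrt(min(d2))
  }
  out
}

# exhaustive Otsu: maximize between-class variance over all bin thresholds
# of a 256-level histogram spanning the data range; returns the foreground
# mask (strictly above the best threshold)
brute_otsu_mask <- function(section, levels = 256L) {
  rng <- range(section)
  cand <- seq(rng[1], rng[2], length.out = levels + 1L)[2:levels]
  best_t <- NA
  best_v <- -1
  n <- length(section)
  for (t in cand) {
    w1 <- sum(section > t) / n
    w0 <- 1 - w1
    if (w0 == 0 || w1 == 0) next
    v <- w0 * w1 * (mean(section[section > t]) - mean(section[section <= t]))^2
    if (v > best_v) {
      best_v <- v
      best_t <- t
    }
  }
  section > best_t
}

# brute-force union-of-spheres voxelizer: voxel (i, j, k) belongs to the
# reconstruction iff its centre lies inside any sphere of the profile;
# identical centre and inclusive-boundary conventions as extrude()
brute_voxelize_spheres <- function(profile, midplane, n_sections, shape,
                                   step = 1) {
  arr <- array(FALSE, c(shape, n_sections))
  for (k in seq_len(n_sections)) {
    dz <- abs(k - midplane) * step
    for (p in seq_len(nrow(profile))) {
      r2 <- profile$R[p]^2 - dz^2
      if (r2 <= 0) next
      for (i in seq_len(shape[1])) {
        di2 <- (i - profile$y[p])^2
        if (di2 > r2) next
        for (j in seq_len(shape[2])) {
          if (di2 + (j - profile$x[p])^2 <= r2) arr[i, j, k] <- TRUE
        }
      }
    }
  }
  arr
}

# region_stack -> voxel array (for comparison with the brute voxelizer)
stack_to_array <- function(stack, shape, n_sections) {
  arr <- array(FALSE, c(shape, n_sections))
  for (r in stack$regions) {
    m <- matrix(FALSE, shape[1], shape[2])
    m[r$pixels] <- TRUE
    arr[, , r$section] <- m
  }
  arr
}

# independent chain-code perimeter via EBImage's own contour tracer
ocontour_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask))
  total <- 0
  for (ct in oc) {
    closed <- rbind(ct, ct[1, , drop = FALSE])
    d <- diff(closed)
    total <- total + sum(sqrt(rowSums(d^2)))
  }
  max(total, 4)
}

# closed-form prolate spheroid surface, semi-axes a > b
prolate_surface_exact <- function(a, b) {
  if (a == b) return(4 * pi * a^2)
  e <- sqrt(1 - b^2 / a^2)
  2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
}

# max/min caliper width by brute force over projection angles (361 angles
# over [0, pi] include the axis-aligned directions exactly)
brute_feret <- function(pixels, n_angles = 361L) {
  L <- 0
  W <- Inf
  for (th in seq(0, pi, length.out = n_angles)) {
    proj <- pixels[, 2] * cos(th) + pixels[, 1] * sin(th)
    ext <- max(proj) - min(proj)
    L <- max(L, ext)
    W <- min(W, ext)
  }
  c(L = L, W = W)
}
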