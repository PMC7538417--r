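test_that("section enhancement: constants, limit case, acutance gain", {
  const <- image_stack(matrix(5, 20, 20), 0.1, 0.1)
  out <- enhance_sections(const, 1, 2, 0.6)
  expect_equal(out$data, const$data, tolerance = 1e-8)
  # weight -> 0: unsharp is the identity, so output equals the blurred input
  img <- matrix(0, 21, 21)
  img[11, 11] <- 1
  st <- image_stack(img, 0.1, 0.1)
  w0 <- enhance_sections(st, 1, 2, 1e-9)
  expect_equal(w0$data[, , 1], gaussian_blur(img, 1), tolerance = 1e-6)
  # single bright pixel: unsharp at weight 0.6 raises the centre above the
  # plain blur (checked against a direct convolution oracle)
  enh <- enhance_sections(st, 1, 2, 0.6)
  size <- 2 * ceiling(3 * 1) + 1
  kern <- EBImage::makeBrush(size, "Gaussian", sigma = 1)
  blur_oracle <- brute_convolve(img, kern)
  expect_equal(gaussian_blur(img, 1), blur_oracle, tolerance = 1e-6)
  expect_gt(enh$data[11, 11, 1], blur_oracle[11, 11])
  expect_error(enhance_sections(st, -1, 2, 0.5), "blur_sigma")
})

test_that("Otsu binarization separates modes and matches brute force", {
  sep <- matrix(c(rep(10, 90), rep(200, 10)), 10, 10)
  expect_equal(binarize_otsu(sep), sep == 200)
  expect_false(any(binarize_otsu(matrix(3, 8, 8))))
  # tri-modal 2:1:1 toy: classification equals the exhaustive
  # between-class-variance maximizer
  tri <- matrix(c(rep(10, 32), rep(100, 16), rep(200, 16)), 8, 8)
  expect_equal(binarize_otsu(tri), brute_otsu_mask(tri))
  # threshold floor suppresses foreground on low-contrast sections
  noise <- matrix(sin(seq_len(64)), 8, 8) * 0.1 + 5
  expect_false(any(binarize_otsu(noise, floor_threshold = 10)))
})

test_that("binary smoothing removes speckle but keeps solid shapes", {
  disk <- raster_disk(50, 25.3, 25.4, 20)
  sm <- smooth_binary(disk, 1)
  expect_gt(sum(sm & disk) / sum(sm | disk), 0.98)
  speck <- matrix(FALSE, 20, 20)
  speck[10, 10] <- TRUE
  expect_false(any(smooth_binary(speck, 2)))
  empty <- matrix(FALSE, 10, 10)
  expect_equal(smooth_binary(empty, 1), empty)
})

test_that("region extraction drops crescents below the circularity cutoff", {
  disk <- raster_disk(100, 30.3, 30.4, 12)
  crescent <- raster_bent_capsule(100, 100, c(70.3, 60.7), 150, 50, 2.5)
  m <- disk | crescent
  regs <- regions_from_mask(m, min_circularity = 0.6)
  expect_length(regs, 1L)
  expect_equal(region_area(regs[[1]]), sum(disk))
  # monotone: lowering the cutoff never removes a kept region
  regs_low <- regions_from_mask(m, min_circularity = 0.2)
  expect_gte(length(regs_low), length(regs))
  expect_length(regions_from_mask(matrix(FALSE, 5, 5)), 0L)
  two <- raster_disk(80, 20.3, 20.4, 9) | raster_disk(80, 60.3, 60.4, 9)
  expect_length(regions_from_mask(two, 0.6), 2L)
})

make_section_regions <- function(centres_px, areas_r = 8, shape = c(120, 120)) {
  # helper: build per-section region lists from a list of per-section
  # centroid matrices (NULL = empty section)
  lapply(seq_along(centres_px), function(s) {
    ctrs <- centres_px[[s]]
    if (is.null(ctrs)) return(list())
    rr <- if (length(areas_r) > 1) areas_r[[s]] else rep(areas_r, nrow(ctrs))
    lapply(seq_len(nrow(ctrs)), function(i) {
      mask_region(raster_disk(shape[1], ctrs[i, 1], ctrs[i, 2], rr[i]), s)
    })
  })
}

test_that("nuclear grouping links jittered chains into one nucleus", {
  # 11 sections, centroid jitter 0.5 um/section at 0.1 um/px = 5 px
  set.seed(1)
  ctrs <- lapply(1:11, function(s) {
    cbind(60 + runif(1, -5, 5), 60 + runif(1, -5, 5))
  })
  radii <- lapply(1:11, function(s) 6 + min(s - 1, 11 - s))
  regs <- make_section_regions(ctrs, radii)
  out <- group_nuclei(regs, pixel_size = 0.1, z_spacing = 0.065)
  expect_length(out$nuclei, 1L)
  expect_equal(out$nuclei[[1]]$n_regions, 11L)
  # the midplane is the largest-area section
  areas <- vapply(out$nuclei[[1]]$stack$regions, region_area, integer(1))
  expect_equal(out$nuclei[[1]]$midplane_index,
               as.integer(names(which.max(areas))))
})

test_that("linking threshold splits chains and short chains are removed", {
  # centroid jump of 2.5 um (25 px) between sections 5 and 6:
  # two chains of 5 and 6 sections; at min_sections = 5 both survive,
  # at min_sections = 6 the short one is removed
  ctrs <- lapply(1:11, function(s) {
    if (s <= 5) cbind(40, 40) else cbind(40, 65)
  })
  radii <- lapply(1:11, function(s) if (s %in% c(3, 8)) 9 else 7)
  regs <- make_section_regions(ctrs, radii)
  out <- group_nuclei(regs, pixel_size = 0.1, z_spacing = 0.065)
  expect_length(out$nuclei, 2L)
  out6 <- group_nuclei(regs, min_sections = 6L, pixel_size = 0.1,
                       z_spacing = 0.065)
  expect_length(out6$nuclei, 1L)
  expect_true("too_few_sections" %in% out6$exclusions$reason)
  # a 4-section chain alone is below the default minimum of 5
  short <- make_section_regions(lapply(1:6, function(s) {
    if (s >= 2 && s <= 5) cbind(40, 40) else NULL
  }), lapply(1:6, function(s) if (s == 3) 9 else 7))
  expect_length(group_nuclei(short, pixel_size = 0.1,
                             z_spacing = 0.065)$nuclei, 0L)
})

test_that("drift exclusion removes nuclei that moved during acquisition", {
  # one centroid 3.5 um from the mean violates the 3.0 um drift limit
  ctrs <- lapply(1:7, function(s) {
    if (s == 4) cbind(60, 60 + 39) else cbind(60, 60)
  })
  radii <- lapply(1:7, function(s) if (s == 4) 9 else 7)
  regs <- make_section_regions(ctrs, radii)
  # linking distance must first admit the jump, so raise link_dist
  out <- group_nuclei(regs, link_dist = 6, pixel_size = 0.1,
                      z_spacing = 0.065)
  expect_length(out$nuclei, 0L)
  expect_true("centroid_drift" %in% out$exclusions$reason)
  # the same chain without the excursion is kept
  ok <- make_section_regions(lapply(1:7, function(s) cbind(60, 60)),
                             lapply(1:7, function(s) if (s == 4) 9 else 7))
  expect_length(group_nuclei(ok, link_dist = 6, pixel_size = 0.1,
                             z_spacing = 0.065)$nuclei, 1L)
})

test_that("intermittent sections: the largest contiguous run is isolated", {
  # sections 1..8 + gap + 10..12 -> bridged into one chain, then reduced
  # to the 8-section contiguous run; midplane inside that run
  ctrs <- lapply(1:12, function(s) if (s == 9) NULL else cbind(50, 50))
  radii <- lapply(1:12, function(s) {
    if (is.null(ctrs[[s]])) integer() else if (s == 4) 9L else 7L
  })
  regs <- make_section_regions(ctrs, radii)
  out <- group_nuclei(regs, pixel_size = 0.1, z_spacing = 0.065)
  expect_length(out$nuclei, 1L)
  expect_equal(out$nuclei[[1]]$n_regions, 8L)
  expect_equal(as.integer(names(out$nuclei[[1]]$stack$regions)), 1:8)
})

test_that("nuclei whose midplane sits at the stack edge are excluded", {
  # areas increase to the last section: truncated nucleus
  trunc <- make_section_regions(lapply(1:6, function(s) cbind(40, 40)),
                                lapply(1:6, function(s) 4L + s))
  out <- group_nuclei(trunc, pixel_size = 0.1, z_spacing = 0.065)
  expect_length(out$nuclei, 0L)
  expect_true("midplane_at_stack_edge" %in% out$exclusions$reason)
  # peak in the middle is fine
  mid <- make_section_regions(lapply(1:6, function(s) cbind(40, 40)),
                              lapply(1:6, function(s) 8L - abs(s - 3L)))
  expect_length(group_nuclei(mid, pixel_size = 0.1,
                             z_spacing = 0.065)$nuclei, 1L)
})

test_that("grouping is a partition: no 2D region is claimed twice", {
  set.seed(7)
  ctrs <- lapply(1:9, function(s) rbind(c(35, 35), c(85, 85)))
  radii <- lapply(1:9, function(s) rep(6 + min(s - 1, 9 - s), 2))
  regs <- make_section_regions(ctrs, radii)
  out <- group_nuclei(regs, pixel_size = 0.1, z_spacing = 0.065)
  expect_length(out$nuclei, 2L)
  keys <- unlist(lapply(out$nuclei, function(n) {
    vapply(n$stack$regions, function(r) {
      paste(r$section, r$pixels[1, 1], r$pixels[1, 2])
    }, character(1))
  }))
  expect_false(any(duplicated(keys)))
  # every emitted nucleus satisfies the model invariants
  for (n in out$nuclei) {
    expect_gte(n$n_regions, 5L)
    secs <- as.integer(names(n$stack$regions))
    expect_equal(secs, seq(min(secs), max(secs)))
    ctr <- t(vapply(n$stack$regions, region_centroid, numeric(2)))
    drift <- sqrt(rowSums(sweep(ctr, 2, n$mean_centroid)^2)) * 0.1
    expect_true(all(drift <= 3))
  }
})

test_that("a rendered ellipsoid nucleus is recovered within 5% volume", {
  # ellipsoid with diameters 2a = 3.0 um, 2b = 2.4 um, noise-free
  geom <- scene_geometry(field_px = c(96L, 96L), n_sections = 48L,
                         pixel_size = 0.1, z_spacing = 0.065,
                         focus_index = 24L)
  spec <- phantom_spec("straight", length_um = 8, width_um = 4,
                       centre_um = c(4.8, 4.8, 24 * 0.065),
                       orientation_deg = 30,
                       nucleus_axes_um = c(1.5, 1.2))
  ch <- render_nucleus_channel(list(spec), geom, noise_sd = 0)
  regs <- segment_nuclei_2d(ch, dilation_um = 0)
  out <- group_nuclei(regs, pixel_size = 0.1, z_spacing = 0.065)
  expect_length(out$nuclei, 1L)
  vol <- stack_volume(out$nuclei[[1]]$stack)
  expect_equal(vol, (4 / 3) * pi * 1.5 * 1.2^2, tolerance = 0.05)
})
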