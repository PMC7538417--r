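test_that("distance map matches the all-pairs brute-force oracle", {
  blob <- raster_disk(30, 15.3, 14.7, 9) | raster_capsule(30, 30, c(5, 20), c(22, 24), 3)
  expect_equal(distance_map(blob), brute_distance_map(blob), tolerance = 1e-9)
  one <- matrix(FALSE, 7, 7)
  one[4, 4] <- TRUE
  expect_equal(distance_map(one)[4, 4], 1)
  disk <- raster_disk(31, 15.6, 15.4, 10)
  expect_lt(abs(max(distance_map(disk)) - 10), 0.6)
  expect_error(distance_map(matrix(FALSE, 4, 4)), "empty")
})

test_that("skeleton of a straight capsule is a clean line along the axis", {
  m <- raster_capsule(62, 142, c(31.5, 31.5), c(111.5, 31.5), 20)
  sk <- skeletonize(m)
  expect_true(all(m[sk]))          # skeleton inside the mask
  px <- which(sk, arr.ind = TRUE)
  core <- px[px[, 2] > 40 & px[, 2] < 103, , drop = FALSE]
  expect_true(all(abs(core[, 1] - 31.5) <= 1))  # on the axis
  # degree census: no branches (max 2 neighbours) on the central part
  nb <- sphex:::neighbour_count(sk)
  expect_lte(max(nb[sk]), 2L)
})

test_that("skeleton of a disk collapses and 1-px masks are their own skeleton", {
  disk <- raster_disk(40, 20.3, 20.6, 12)
  sk <- skeletonize(disk, extend_tips = FALSE)
  expect_lte(sum(sk), 8L)
  line <- matrix(FALSE, 10, 10)
  line[5, 2:8] <- TRUE
  expect_equal(sum(skeletonize(line) & line), sum(skeletonize(line)))
})

test_that("bent capsule skeleton is connected and branch-free after pruning", {
  m <- raster_bent_capsule(200, 200, c(100.3, 80.7), 90, 80, 20)
  sk <- skeletonize(m)
  expect_equal(max(sphex:::label8(sk)), 1)  # one connected curve
  nb <- sphex:::neighbour_count(sk)
  expect_lte(max(nb[sk]), 2L)                 # no junctions
})

test_that("radius profile carries local half-widths along the skeleton", {
  m <- raster_capsule(50, 120, c(20.3, 25.6), c(100.3, 25.6), 15)  # W = 30
  dm <- distance_map(m)
  sk <- skeletonize(m)
  pr <- radius_profile(sk, dm)
  core <- pr$x > 30 & pr$x < 90
  expect_true(all(abs(pr$R[core] - 15) <= 0.5))
  # single-point profile on a disk
  disk <- raster_disk(31, 15.6, 15.4, 10)
  prd <- radius_profile(skeletonize(disk, extend_tips = FALSE),
                        distance_map(disk))
  expect_lt(abs(max(prd$R) - 10), 0.7)
  # skeleton outside the mask's support is inconsistent
  bad <- matrix(FALSE, 10, 10)
  bad[2, 2] <- TRUE
  expect_error(radius_profile(bad, matrix(0, 10, 10)), "zero distance")
})

test_that("radius decreases monotonically along a tapered phantom", {
  # width tapers 30 -> 20 px over the length, rounded end caps so the
  # medial axis is a single line
  nr <- 60; nc <- 140
  jj <- matrix(rep(1:nc, each = nr), nr)
  ii <- matrix(rep(1:nr, nc), nr)
  t <- pmin(pmax((jj - 20.5) / 100, 0), 1)
  m <- (abs(ii - 30.5) <= (15 - 5 * t) & jj >= 20.5 & jj <= 120.5) |
    raster_capsule(nr, nc, c(20.5, 30.5), c(20.5, 30.5), 15) |
    raster_capsule(nr, nc, c(120.5, 30.5), c(120.5, 30.5), 10)
  pr <- radius_profile(skeletonize(m), distance_map(m))
  core <- pr[pr$x > 30 & pr$x < 110, ]
  fit <- stats::lm(R ~ x, data = core)
  expect_lt(coef(fit)[2], -0.03)  # clear negative trend ~ -0.05 px/px
  expect_gt(stats::cor(core$x, core$R)^2, 0.9)
})

test_that("cross-section radii follow r = sqrt(R^2 - dz^2)", {
  expect_equal(cross_section_radius(5, 0), 5)
  expect_equal(cross_section_radius(5, 3), 4)
  expect_true(is.na(cross_section_radius(5, 6)))
  expect_true(is.na(cross_section_radius(5, 5)))  # pole: no cross-section
  expect_error(cross_section_radius(-1, 0), "R must")
  expect_error(cross_section_radius(5, -1), "dz")
})

test_that("extrude equals the brute-force union-of-spheres voxelizer", {
  profile <- data.frame(x = c(20.3, 26.7, 33.1), y = c(30.2, 30.9, 31.6),
                        R = c(9.4, 11.2, 8.8))
  st <- extrude(profile, midplane_index = 16L, n_sections = 31L,
                shape = c(60L, 60L), pixel_size = 1, z_spacing = 1)
  got <- stack_to_array(st, c(60L, 60L), 31L)
  want <- brute_voxelize_spheres(profile, 16L, 31L, c(60L, 60L))
  expect_identical(got, want)  # exact voxel-set equality
})

test_that("extruding a disk yields a sphere within 2% of (4/3) pi R^3", {
  n <- 64
  disk <- raster_disk(n, n / 2 + 0.31, n / 2 + 0.48, 20)
  st <- extrude_region(mask_region(disk, 32L), 32L, 63L, 1, 1)
  vol <- stack_voxels(st)
  expect_equal(vol, (4 / 3) * pi * 20^3, tolerance = 0.02)
  # per-section area is non-increasing away from the midplane
  areas <- vapply(st$regions, region_area, integer(1))
  secs <- as.integer(names(st$regions))
  up <- areas[secs >= 32]
  expect_true(all(diff(up) <= 0))
  down <- areas[secs <= 32]
  expect_true(all(diff(down) >= 0))
})

test_that("sphere volume error shrinks as the radius grows", {
  errs <- vapply(c(8, 16, 32), function(R0) {
    n <- 2 * ceiling(R0) + 24
    disk <- raster_disk(n, n / 2 + 0.31, n / 2 + 0.48, R0)
    st <- extrude_region(mask_region(disk), round(n / 2), n, 1, 1)
    abs(stack_voxels(st) - (4 / 3) * pi * R0^3) / ((4 / 3) * pi * R0^3)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("a straight capsule extrudes to the analytic capsule volume", {
  m <- test_capsule()
  reg <- mask_region(m, 41L)
  st <- extrude_region(reg, 41L, 81L, 1, 1)
  true_vol <- capsule_volume_true(80, 20)
  expect_equal(stack_voxels(st), true_vol, tolerance = 0.02)
  # midplane reproduces the input region
  mid <- region_mask(st$regions[["41"]])
  expect_gt(sum(mid & m) / sum(mid | m), 0.97)
  # far sections are absent (dz beyond every R)
  expect_false("81" %in% names(st$regions))
})

test_that("bent and straight capsules of equal arc length agree in volume", {
  straight <- extrude_region(mask_region(test_capsule()), 41L, 81L, 1, 1)
  vols <- vapply(c(60, 120), function(ang) {
    m <- raster_bent_capsule(200, 200, c(100.3, 80.7), ang, 80, 20)
    stack_voxels(extrude_region(mask_region(m), 41L, 81L, 1, 1))
  }, numeric(1))
  v0 <- stack_voxels(straight)
  expect_lt(abs(vols[1] - v0) / v0, 0.03)
  expect_lt(abs(vols[2] - v0) / v0, 0.03)
})

test_that("anisotropic voxels: dz converts through z_spacing / pixel_size", {
  profile <- data.frame(x = 20, y = 20, R = 10)
  st <- extrude(profile, 11L, 21L, c(40L, 40L), pixel_size = 0.1,
                z_spacing = 0.05)
  # half-resolution z: sphere spans ~2R * px / zs = 40 sections, clipped at 21
  expect_equal(length(st$regions), 21L)
  r5 <- sqrt(10^2 - (5 * 0.05 / 0.1)^2)
  got <- region_area(st$regions[["16"]])
  expect_equal(got, pi * r5^2, tolerance = 0.05)
})

test_that("batch extrusion isolates per-cell failures", {
  out <- extrude_all(list(), integer(), 10L, 1, 1)
  expect_length(out$stacks, 0L)
  expect_equal(nrow(out$failures), 0L)
  r1 <- mask_region(raster_disk(64, 16.3, 16.5, 8))
  r2 <- mask_region(raster_disk(64, 48.3, 48.5, 8))
  two <- extrude_all(list(r1, r2), c(10L, 10L), 20L, 1, 1)
  expect_length(two$stacks, 2L)
  # an out-of-range midplane fails that cell only
  mixed <- extrude_all(list(r1, r2), c(10L, 99L), 20L, 1, 1)
  expect_length(mixed$stacks, 1L)
  expect_equal(mixed$failures$region, 2L)
})
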