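test_that("stack volume is the sum of section volumes", {
  disk <- raster_disk(30, 15.3, 15.4, 8)
  reg <- mask_region(disk)
  one <- region_stack(list(reg), 1L, pixel_size = 0.1, z_spacing = 0.065)
  expect_equal(stack_volume(one), sum(disk) * 0.01 * 0.065)
  # 100-px section at 0.1 um pixels and 0.065 um spacing -> 0.065 um^3
  sq <- matrix(FALSE, 20, 20)
  sq[6:15, 6:15] <- TRUE
  s100 <- region_stack(list(mask_region(sq)), 1L, 0.1, 0.065)
  expect_equal(stack_volume(s100), 0.065)
  # doubling the z spacing doubles the volume
  two <- region_stack(list(reg), 1L, 0.1, 0.13)
  expect_equal(stack_volume(two), 2 * stack_volume(one))
})

test_that("voxelized sphere volume approaches the closed form", {
  n <- 64
  disk <- raster_disk(n, n / 2 + 0.31, n / 2 + 0.48, 20)
  st <- extrude_region(mask_region(disk), 32L, 63L, 0.1, 0.1)
  expect_equal(stack_volume(st), (4 / 3) * pi * 2^3, tolerance = 0.02)
})

test_that("staircase surface equals the per-section oracle exactly", {
  # S = sum(P_i * Z) + 2 * A_mid, recomputed with an independent tracer
  n <- 64
  disk <- raster_disk(n, n / 2 + 0.31, n / 2 + 0.48, 18)
  st <- extrude_region(mask_region(disk), 32L, 63L, 0.1, 0.065)
  oracle <- sum(vapply(st$regions, function(r) {
    ocontour_perimeter(region_mask(r))
  }, numeric(1))) * 0.1 * 0.065 +
    2 * region_area(st$regions[["32"]]) * 0.01
  expect_equal(stack_surface(st), oracle)
  # single-section stack: P * Z + 2 A exactly
  reg <- mask_region(raster_disk(30, 15.3, 15.4, 8))
  s1 <- region_stack(list(reg), 1L, 0.1, 0.065)
  expect_equal(stack_surface(s1),
               region_perimeter(reg) * 0.1 * 0.065 +
                 2 * region_area(reg) * 0.01)
  # uniform cylinder of n identical disks: n * P * Z + 2 A
  regs <- lapply(1:7, function(k) mask_region(raster_disk(30, 15.3, 15.4, 8), k))
  cyl <- region_stack(regs, 4L, 0.1, 0.065)
  expect_equal(stack_surface(cyl),
               7 * region_perimeter(reg) * 0.1 * 0.065 +
                 2 * region_area(reg) * 0.01)
})

test_that("idealized rod formulas and their sphere limits", {
  expect_equal(rod_volume(2, 2), (4 / 3) * pi)           # L = W: sphere
  expect_equal(rod_volume(4, 2), 10 * pi / 3)
  expect_equal(rod_volume(10, 0), 0)
  expect_equal(rod_surface(2, 2), 4 * pi)
  expect_equal(rod_surface(4, 2), 8 * pi)
  expect_equal(rod_surface(8, 4), 4 * rod_surface(4, 2)) # scales as c^2
  expect_error(rod_volume(2, 3), "L >= W")
  expect_error(rod_surface(2, 3), "L >= W")
})

test_that("ellipsoid volume and Thomsen surface approximation", {
  expect_equal(ellipsoid_volume(2, 2), (4 / 3) * pi)
  expect_equal(ellipsoid_volume(4, 2), (8 / 3) * pi)
  expect_equal(ellipsoid_volume(4, 0), 0)
  expect_error(ellipsoid_volume(2, 3), "L >= W")
  # a = b reduces exactly to the sphere surface
  expect_equal(ellipsoid_surface(3, 3), 4 * pi * 1.5^2)
  # a/b = 2: within 1.2% of the closed-form prolate surface
  approx <- ellipsoid_surface(4, 2)
  exact <- prolate_surface_exact(2, 1)
  expect_lt(abs(approx - exact) / exact, 0.012)
  # monotone in the long axis
  expect_gt(ellipsoid_surface(5, 2), ellipsoid_surface(4, 2))
  expect_error(ellipsoid_surface(2, 0), "L >= W > 0")
})

test_that("ellipse fit overestimates capsule length relative to Feret", {
  mid <- mask_region(test_capsule())
  expect_gte(ellipse_dims(mid)["L"], feret_dims(mid)["L"])
})

test_that("rod-from-Feret volume brackets the extruded volume", {
  # constant width: the two estimates agree within 2%
  st <- extrude_region(mask_region(test_capsule(), 41L), 41L, 81L, 1, 1)
  fd <- feret_dims(st$regions[["41"]])
  expect_equal(rod_volume(fd["L"], fd["W"]), stack_voxels(st),
               tolerance = 0.02, ignore_attr = TRUE)
  # waisted phantom (width varies along the length): rod overestimates
  nr <- 60; nc <- 140
  jj <- matrix(rep(1:nc, each = nr), nr)
  ii <- matrix(rep(1:nr, nc), nr)
  waist <- 15 - 4 * exp(-((jj - 70.3) / 15)^2)
  m <- abs(ii - 30.5) <= waist & jj >= 20.5 & jj <= 120.5
  # round the tube ends
  m <- m | raster_capsule(nr, nc, c(20.5, 30.5), c(20.5, 30.5), 15) |
    raster_capsule(nr, nc, c(120.5, 30.5), c(120.5, 30.5), 15)
  stw <- extrude_region(mask_region(m, 41L), 41L, 81L, 1, 1)
  fdw <- feret_dims(stw$regions[["41"]])
  expect_gt(rod_volume(fdw["L"], fdw["W"]), stack_voxels(stw))
})

test_that("measurements are invariant under translation and 90-degree rotation", {
  m <- test_capsule()
  mt <- matrix(FALSE, 170, 170)
  mt[7 + seq_len(160), 3 + seq_len(160)] <- m       # translation
  mr <- t(m)[rev(seq_len(ncol(m))), ]               # 90-degree rotation
  a0 <- region_area(mask_region(m))
  expect_equal(region_area(mask_region(mt)), a0)
  expect_equal(region_area(mask_region(mr)), a0)
  expect_equal(region_perimeter(mask_region(mt)), region_perimeter(mask_region(m)))
  expect_equal(feret_dims(mask_region(mr)), feret_dims(mask_region(m)),
               tolerance = 1e-9)
  v0 <- stack_voxels(extrude_region(mask_region(m, 41L), 41L, 81L, 1, 1))
  vr <- stack_voxels(extrude_region(mask_region(mr, 41L), 41L, 81L, 1, 1))
  expect_equal(vr, v0, tolerance = 0.01)
})

make_cell_stack <- function(cx, cy, r = 14, mid = 8L, n = 15L, shape = 80L) {
  regs <- lapply(seq_len(n), function(k) {
    rk <- sqrt(max(r^2 - (k - mid)^2 * (r / ((n - 1) / 2))^2 * 0.8, 4))
    mask_region(raster_disk(shape, cx, cy, rk), k)
  })
  region_stack(regs, mid, pixel_size = 0.1, z_spacing = 0.1)
}

make_nucleus <- function(cx, cy, r = 6, mid = 8L, sections = 5:11) {
  regs <- lapply(sections, function(k) {
    rk <- sqrt(max(r^2 - (k - mid)^2 * 2.5, 2))
    mask_region(raster_disk(80, cx, cy, rk), k)
  })
  nucleus_model(region_stack(regs, mid, pixel_size = 0.1, z_spacing = 0.1))
}

test_that("pairing keeps only one-to-one nucleus/cell matches", {
  cells <- list(make_cell_stack(25.3, 25.4), make_cell_stack(58.3, 58.4))
  nuc_in <- make_nucleus(25.1, 25.2)
  out <- pair_nuclei_cells(cells, list(nuc_in))
  expect_equal(nrow(out$pairs), 1L)
  expect_equal(out$pairs$cell, 1L)
  expect_true(any(out$exclusions$reason == "no_nucleus"))  # the second cell
  # two nuclei in one cell: multinucleate, no record
  two_in <- list(make_nucleus(22.1, 25.2), make_nucleus(29.1, 25.6))
  multi <- pair_nuclei_cells(cells[1], two_in)
  expect_equal(nrow(multi$pairs), 0L)
  expect_true("multinucleate" %in% multi$exclusions$reason)
  # a nucleus outside every cell is dropped with a reason
  stray <- pair_nuclei_cells(cells[1], list(make_nucleus(70.2, 10.4)))
  expect_equal(nrow(stray$pairs), 0L)
  expect_true("no_enclosing_cell" %in% stray$exclusions$reason)
})

test_that("aspect ratio flags truncated and over-grouped reconstructions", {
  n <- 48
  disk <- raster_disk(n, n / 2 + 0.31, n / 2 + 0.48, 12)
  sphere <- extrude_region(mask_region(disk), 24L, 47L, 0.1, 0.1)
  expect_equal(aspect_ratio(sphere, "cell"), 1, tolerance = 0.1)
  expect_equal(aspect_ratio(sphere, "nucleus"), 1, tolerance = 0.1)
  # truncation: cut away the top half of the sections
  keep <- names(sphere$regions)[as.integer(names(sphere$regions)) <= 24]
  trunc <- region_stack(sphere$regions[keep], 24L, 0.1, 0.1)
  expect_lt(aspect_ratio(trunc, "cell"), 0.8)
  # over-grouping: duplicate sections stretch Z
  regs2 <- sphere$regions
  extra <- lapply(seq_along(regs2), function(i) {
    r <- regs2[[i]]
    planar_region(r$pixels, r$section + length(regs2), r$shape)
  })
  over <- region_stack(c(regs2, extra), 24L, 0.1, 0.1)
  expect_gt(aspect_ratio(over, "nucleus"), 1.2)
})

test_that("nucleus containment test is inclusive at shared boundaries", {
  cell <- make_cell_stack(25.3, 25.4)
  inside <- make_nucleus(25.1, 25.2)
  expect_true(nucleus_within_cell(cell, inside$stack))
  shifted <- make_nucleus(38.1, 25.2)  # halfway out
  expect_false(nucleus_within_cell(cell, shifted$stack))
  expect_true(nucleus_within_cell(cell, cell))  # identical ROIs: inclusive
})

test_that("intensity extraction sums ROI voxels and normalizes by volume", {
  reg1 <- mask_region(raster_disk(10, 5, 5, 2), 1L)
  reg2 <- mask_region(raster_disk(10, 5, 5, 2), 2L)
  st <- region_stack(list(reg1, reg2), 1L, 0.1, 0.1)
  uni <- image_stack(array(3, c(10, 10, 2)), 0.1, 0.1)
  out <- stack_intensity(st, uni)
  nvox <- stack_voxels(st)
  expect_equal(out$integrated_density, 3 * nvox)
  expect_equal(out$mean_intensity, 3 * nvox / stack_volume(st))
  expect_equal(out$n_voxels, nvox)
  zero <- image_stack(array(0, c(10, 10, 2)), 0.1, 0.1)
  expect_equal(stack_intensity(st, zero)$integrated_density, 0)
  # 3-voxel hand-built toy: exact sum
  toy <- array(seq_len(3 * 3 * 3), c(3, 3, 3))
  ts <- image_stack(toy, 1, 1)
  pr <- planar_region(rbind(c(1, 1), c(2, 2), c(3, 3)), 2L, c(3L, 3L))
  tstack <- region_stack(list(pr), 2L, 1, 1)
  expect_equal(stack_intensity(tstack, ts)$integrated_density,
               toy[1, 1, 2] + toy[2, 2, 2] + toy[3, 3, 2])
})

test_that("record table computes N/C ratios and filters exclude flagged rows", {
  cells <- list(make_cell_stack(25.3, 25.4))
  nuclei <- list(make_nucleus(25.1, 25.2))
  rec <- cell_records(cells, nuclei,
                      channels = list(gfp = image_stack(array(2, c(80, 80, 15)),
                                                        0.1, 0.1)))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$nc_ratio,
               stack_volume(nuclei[[1]]$stack) / stack_volume(cells[[1]]))
  expect_true(rec$nc_ratio > 0 && rec$nc_ratio < 1)
  expect_true("cell_mean_gfp" %in% names(rec))
  expect_true(rec$nucleus_inside)
  # filters drop rows whose flags fail
  rec2 <- rec
  rec2$aspect_ok <- FALSE
  expect_equal(nrow(filter_records(rec2)), 0L)
  expect_equal(nrow(filter_records(rec2, aspect = FALSE)), 1L)
  expect_equal(nrow(cell_records(list(), list())), 0L)
})
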