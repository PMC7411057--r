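test_that("single centred sphere matches analytic volume fraction and is reproducible", {
  ph <- make_solid_spheres(shape = c(64, 64, 64), voxel_size = 2, radius_um = 20,
                           centers = matrix(c(32.5, 32.5, 32.5), 1), seed = 1)
  frac <- cavity_fraction(ph$phase)
  expected <- 4 / 3 * pi * 10^3 / 64^3
  # voxel-centre discretization: within a one-voxel-shell perturbation
  expect_lt(abs(frac - expected), 4 * pi * 10^2 * 0.5 / 64^3)
  ph2 <- make_solid_spheres(shape = c(64, 64, 64), voxel_size = 2, radius_um = 20,
                            centers = matrix(c(32.5, 32.5, 32.5), 1), seed = 1)
  expect_identical(ph$volume$data, ph2$volume$data)
  expect_identical(ph$phase$data, ph2$phase$data)
})

test_that("random sequential addition reaches the target sphere fraction", {
  ph <- make_solid_spheres(shape = c(128, 128, 128), voxel_size = 2,
                           radius_um = 16, fraction = 0.05, seed = 3)
  expect_lt(abs(cavity_fraction(ph$phase) / 0.05 - 1), 0.1)
  # determinism across calls
  ph2 <- make_solid_spheres(shape = c(128, 128, 128), voxel_size = 2,
                            radius_um = 16, fraction = 0.05, seed = 3)
  expect_identical(ph$phase$data, ph2$phase$data)
})

test_that("midpoint threshold of the noiseless grayscale recovers the phase map", {
  ph <- make_voronoi_foam(c(48, 48, 48), 2, n_seeds = 20, wall_um = 4, seed = 5)
  recovered <- binarize(ph$volume, method = "fixed", threshold = 0.5)
  expect_identical(recovered$data, ph$phase$data)
})

test_that("hollow sphere shells have the discretized shell volume and honour preconditions", {
  # outer fraction small enough that exactly one shell is placed
  ph <- make_hollow_spheres(shape = c(64, 64, 64), voxel_size = 1,
                            radius_um = 12, shell_um = 2,
                            outer_fraction = 0.02, seed = 2)
  expect_equal(ph$params$n_spheres, 1)
  material_frac <- 1 - cavity_fraction(ph$phase)
  shell_frac <- 4 / 3 * pi * (12^3 - 10^3) / 64^3
  expect_lt(abs(material_frac / shell_frac - 1), 0.1)
  expect_error(make_hollow_spheres(shape = c(64, 64, 64), voxel_size = 1,
                                   radius_um = 12, shell_um = 12),
               "smaller than the sphere radius")
  expect_error(make_hollow_spheres(shape = c(64, 64, 64), voxel_size = 4,
                                   radius_um = 12, shell_um = 2),
               "finer grid")
  pha <- make_hollow_spheres(shape = c(48, 48, 48), voxel_size = 1,
                             radius_um = 10, shell_um = 2, seed = 1)
  phb <- make_hollow_spheres(shape = c(48, 48, 48), voxel_size = 1,
                             radius_um = 10, shell_um = 2, seed = 2)
  expect_false(identical(pha$phase$data, phb$phase$data))
})

test_that("a two-seed foam is a single planar wall between two cavities", {
  ph <- make_voronoi_foam(c(64, 64, 64), 2, n_seeds = 2, wall_um = 4, seed = 9)
  set.seed(9)
  pts <- matrix(runif(6), ncol = 3)
  pts <- sweep(pts, 2, c(63, 63, 63), `*`) + 1
  # walking from one seed to the other crosses material exactly once
  tt <- seq(0, 1, length.out = 200)
  path <- outer(1 - tt, pts[1, ]) + outer(tt, pts[2, ])
  idx <- pmin(pmax(round(path), 1), 64)
  vals <- ph$phase$data[idx]
  runs <- rle(vals)
  expect_identical(runs$values[runs$values == 0], 0L)
  expect_equal(sum(runs$values == 0), 1)
  expect_equal(sum(runs$values == 1), 2)
})

test_that("overgrown walls are rejected as degenerate", {
  expect_error(make_voronoi_foam(c(48, 48, 48), 2, n_seeds = 400, wall_um = 24,
                                 seed = 1),
               "degenerate foam")
})

test_that("foam mean chord length decreases strictly with seed density", {
  mcls <- vapply(c(8, 30, 100), function(ns) {
    ph <- make_voronoi_foam(c(64, 64, 64), 2, n_seeds = ns, wall_um = 4, seed = 11)
    mean_chord_length(ph$phase, n_lines = 1500, seed = 4)$mcl_um
  }, numeric(1))
  expect_true(all(diff(mcls) < 0))
})

test_that("foam chord lengths are isotropic across the three axes", {
  ph <- make_voronoi_foam(c(128, 128, 128), 2, n_seeds = 150, wall_um = 4,
                          seed = 21)
  set.seed(31)
  axis_mcl <- vapply(1:3, function(ax) {
    n <- 800
    o <- matrix(runif(3 * n, 1, 128), ncol = 3)
    u <- matrix(0, n, 3); u[, ax] <- 1
    lines <- tibble::tibble(line = seq_len(n), ox = o[, 1], oy = o[, 2],
                            oz = o[, 3], ux = u[, 1], uy = u[, 2], uz = u[, 3])
    mean(measure_chords(ph$phase, lines)$chords)
  }, numeric(1))
  expect_lt(max(axis_mcl) / min(axis_mcl) - 1, 0.15)
})

test_that("microCT degradation model is the identity at zero blur and noise", {
  ph <- make_solid_spheres(shape = c(32, 32, 32), voxel_size = 2, radius_um = 8,
                           centers = matrix(c(16, 16, 16), 1), seed = 1)
  out <- add_microct_noise(ph$volume, blur_sigma = 0, noise_sd = 0, seed = 99)
  expect_identical(out$data, ph$volume$data)
})

test_that("noise amplitude is a fraction of contrast and blur preserves the interior mean", {
  const <- volume3d(array(3, dim = c(24, 24, 24)), 2)
  noisy <- add_microct_noise(const, blur_sigma = 0, noise_sd = 0.05, seed = 7)
  expect_lt(abs(sd(noisy$data - 3) / 0.05 - 1), 0.1)  # unit contrast fallback
  # unit-mass symmetric kernel with reflected edges: the volume mean is kept
  ph <- make_voronoi_foam(c(48, 48, 48), 2, n_seeds = 30, wall_um = 4, seed = 2)
  blurred <- add_microct_noise(ph$volume, blur_sigma = 3, noise_sd = 0, seed = 1)
  expect_lt(abs(mean(blurred$data) / mean(ph$volume$data) - 1), 1e-3)
})

test_that("volumes round-trip through TIFF and raw binary with sidecar", {
  ph <- make_voronoi_foam(c(16, 16, 16), 2.5, n_seeds = 5, wall_um = 5, seed = 3)
  tmp_tif <- tempfile(fileext = ".tif")
  write_volume(ph$volume, tmp_tif)
  back <- read_volume(tmp_tif)
  expect_equal(back$voxel_size, 2.5)
  expect_lt(max(abs(back$data - ph$volume$data)), 1e-6)  # 32-bit float pages
  tmp_raw <- tempfile(fileext = ".raw")
  write_volume(ph$phase, tmp_raw)
  back2 <- read_volume(tmp_raw)
  expect_s3_class(back2, "phase_map")
  expect_identical(back2$data, ph$phase$data)
})
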