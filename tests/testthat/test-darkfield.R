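flat_profile <- function(G_plateau = 0, xi_max = 10) {
  correlation_profile(xi_um = c(0, 0.01, xi_max),
                      G = c(1, G_plateau, G_plateau))
}

test_that("monochromatic limits of the forward relation hold exactly", {
  geom <- paper_geom()
  # G identically 1: no structure at any probed length, D = 1
  no_struct <- correlation_profile(c(0, 10), c(1, 1))
  mat1 <- material_model(5e4, 0.005, no_struct)
  expect_equal(mono_darkfield(mat1, 60, geom), 1)
  # sigma * t * (1 - G) = 1 gives D = exp(-1)
  E <- 50; lambda <- energy_to_wavelength(E)
  mat2 <- material_model(1 / (lambda^2 * 0.005), 0.005, flat_profile(0))
  expect_equal(mono_darkfield(mat2, E, geom), exp(-1), tolerance = 1e-12)
  # no extrapolation beyond the profile support
  short <- correlation_profile(c(0, 0.5), c(1, 0.2))
  mat3 <- material_model(5e4, 0.005, short)
  expect_error(mono_darkfield(mat3, 43, geom), "extrapolation")
})

test_that("the G = 0 plateau shows exact inverse-square energy scaling", {
  geom <- paper_geom()
  mat <- material_model(5e4, 0.005, flat_profile(0))
  nl <- -log(mono_darkfield(mat, c(40, 80), geom))
  expect_equal(nl[1] / nl[2], 4, tolerance = 1e-12)
})

test_that("the effective energy exponent lies between 2 and 4 across phantoms", {
  geom <- paper_geom()
  energies <- seq(30, 100, by = 2)
  profiles <- list(
    spheres = {
      ph <- make_solid_spheres(shape = c(64, 64, 64), voxel_size = 2,
                               radius_um = 6, fraction = 0.08, seed = 2)
      projected_profile(autocorrelation_3d(mean_subtract(ph$volume)))
    },
    foam = {
      ph <- make_voronoi_foam(c(64, 64, 64), 2, n_seeds = 40, wall_um = 4,
                              seed = 3)
      projected_profile(autocorrelation_3d(mean_subtract(ph$volume)))
    },
    plateau = flat_profile(0))
  for (prof in profiles) {
    mat <- material_model(5e4, 0.005, prof)
    nl <- -log(mono_darkfield(mat, energies, geom))
    p <- -coef(lm(log(nl) ~ log(energies)))[[2]]
    expect_gte(p, 2 - 1e-6)
    expect_lte(p, 4 + 1e-6)
  }
})

test_that("energy monotonicity: the scattering signal decreases with energy", {
  geom <- paper_geom()
  ph <- make_voronoi_foam(c(48, 48, 48), 2, n_seeds = 25, wall_um = 4, seed = 7)
  prof <- projected_profile(autocorrelation_3d(mean_subtract(ph$volume)))
  mat <- material_model(5e4, 0.005, prof)
  nl <- -log(mono_darkfield(mat, seq(25, 115, by = 1), geom))
  expect_true(all(diff(nl) < 0))
})

test_that("phase stepping simulation and retrieval round-trip exactly", {
  curve <- simulate_stepping_curve(a0 = 1000, visibility = 0.3, phase = 0.7,
                                   n_steps = 7)
  fit <- retrieve_visibility(curve)
  expect_equal(fit$a0, 1000, tolerance = 1e-10)
  expect_equal(fit$visibility, 0.3, tolerance = 1e-10)
  expect_equal(fit$phase, 0.7, tolerance = 1e-10)
  # densely sampled curve: (max - min) / (max + min) is the visibility
  dense <- simulate_stepping_curve(500, 0.42, 1.1, n_steps = 1000)
  I <- dense$intensities
  expect_equal((max(I) - min(I)) / (max(I) + min(I)), 0.42, tolerance = 1e-5)
  # flat curve has zero visibility
  flat <- simulate_stepping_curve(800, 0, 0, n_steps = 7)
  expect_equal(sd(flat$intensities), 0)
  expect_equal(retrieve_visibility(flat)$visibility, 0, tolerance = 1e-12)
  expect_error(simulate_stepping_curve(100, 1.2, 0), "\\[0, 1\\]")
})

test_that("visibility retrieval is nearly unbiased under Poisson counting noise", {
  ests <- vapply(1:500, function(i) {
    curve <- simulate_stepping_curve(a0 = 1e5, visibility = 0.3, phase = 0.7,
                                     n_steps = 7, poisson_seed = 1000 + i)
    retrieve_visibility(curve)$visibility
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.3), 0.01 * 0.3)
})

test_that("dark-field from visibilities divides, clips and validates", {
  expect_equal(darkfield_from_visibilities(0.4, 0.4), 1)
  expect_equal(darkfield_from_visibilities(0.2, 0.4), 0.5)
  expect_warning(D <- darkfield_from_visibilities(0.5, 0.4), "clipping")
  expect_equal(D, 1)
  expect_error(darkfield_from_visibilities(0.2, 0), "positive")
  # inversion of a printed low-bin signal
  expect_equal(round(exp(-1.07), 3), 0.343)
})

test_that("wavelength normalization reproduces the published table entries", {
  expect_equal(round(normalized_logD(1.07, 0.29), 2), 12.72)
  expect_equal(round(normalized_logD(0.13, 0.15), 2), 5.78)
  expect_equal(normalized_logD(0, 0.29), 0)
  expect_error(normalized_logD(1, -1), "positive")
})

test_that("the spectral ratio reproduces the printed quotients", {
  expect_equal(spectral_ratio(1, 1), 1)
  expect_equal(round(spectral_ratio(1.07, 0.36), 2), 2.97)
  expect_equal(round(spectral_ratio(0.50, 0.13), 2), 3.85)
  expect_equal(spectral_ratio(1.07, 0.36, orientation = "high_over_low"),
               0.36 / 1.07)
  expect_error(spectral_ratio(1, 0), "positive")
})

test_that("polychromatic averaging stays within the monochromatic envelope", {
  geom <- paper_geom()
  sp <- simulate_source_spectrum(120, 2)
  vm <- visibility_model(45)
  bin <- energy_bin(23, 64, "low")
  phi_eff <- effective_bin_spectrum(sp, bin, 8)
  ph <- make_voronoi_foam(c(48, 48, 48), 2, n_seeds = 25, wall_um = 4, seed = 7)
  prof <- projected_profile(autocorrelation_3d(mean_subtract(ph$volume)))
  mat <- material_model(5e4, 0.005, prof)
  Dbin <- polychromatic_darkfield(mat, phi_eff, vm, bin, geom)
  Dmono <- mono_darkfield(mat, seq(23, 64, by = 0.5), geom)
  expect_gte(Dbin, min(Dmono))
  expect_lte(Dbin, max(Dmono))
  # sigma0 = 0: no scattering at any energy, D_bin = 1
  mat0 <- material_model(0, 0.005, prof)
  expect_equal(polychromatic_darkfield(mat0, phi_eff, vm, bin, geom), 1)
  # spectrum concentrated at one grid energy reduces to the mono signal
  grid <- seq(23, 64, by = 0.5)
  w <- rep(0, length(grid)); w[grid == 45] <- 1
  delta <- spectral_table(grid, w, "fluence")
  expect_equal(polychromatic_darkfield(mat, delta, vm, bin, geom),
               mono_darkfield(mat, 45, geom), tolerance = 1e-10)
})

test_that("polychromatic weighted mean agrees with the stepping-curve oracle", {
  geom <- paper_geom()
  sp <- simulate_source_spectrum(120, 2)
  vm <- visibility_model(45)
  bin <- energy_bin(23, 64, "low")
  phi_eff <- effective_bin_spectrum(sp, bin, 8)
  ph <- make_voronoi_foam(c(48, 48, 48), 2, n_seeds = 25, wall_um = 4, seed = 7)
  prof <- projected_profile(autocorrelation_3d(mean_subtract(ph$volume)))
  mat <- material_model(5e4, 0.005, prof)
  # oracle: simulate per-energy stepping curves, sum intensities over the
  # spectrum, retrieve the fringe visibility with and without the sample
  grid <- seq(bin$e1, bin$e2, by = 0.5)
  phi_g <- approx(phi_eff$energy_keV, phi_eff$value, grid, rule = 2)$y
  vis_g <- approx(vm$energy_keV, vm$value, grid, rule = 2)$y
  D_g <- mono_darkfield(mat, grid, geom)
  k <- 0:6
  sample_I <- ref_I <- numeric(7)
  for (j in seq_along(grid)) {
    ref_I <- ref_I + phi_g[j] * (1 + vis_g[j] * cos(2 * pi * k / 7))
    sample_I <- sample_I + phi_g[j] * (1 + vis_g[j] * D_g[j] * cos(2 * pi * k / 7))
  }
  D_oracle <- darkfield_from_visibilities(
    retrieve_visibility(sample_I)$visibility,
    retrieve_visibility(ref_I)$visibility)
  Dbin <- polychromatic_darkfield(mat, phi_eff, vm, bin, geom)
  expect_lt(abs(Dbin / D_oracle - 1), 0.01)
})

test_that("sigma0 calibration reproduces a target scattering signal", {
  geom <- paper_geom()
  ph <- make_voronoi_foam(c(48, 48, 48), 2, n_seeds = 25, wall_um = 4, seed = 7)
  prof <- projected_profile(autocorrelation_3d(mean_subtract(ph$volume)))
  s0 <- calibrate_sigma0(prof, target_neg_log_D = 1.07, energy_keV = 43,
                         geom = geom, thickness_m = 0.005)
  mat <- material_model(s0, 0.005, prof)
  expect_equal(-log(mono_darkfield(mat, 43, geom)), 1.07, tolerance = 1e-10)
})
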