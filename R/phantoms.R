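#' Seeded 3D phantom generators for porous two-phase media
#'
#' These generators emulate the structural classes of porous samples used in
#' spectral dark-field studies: dilute solid-sphere phantoms with analytically
#' known autocorrelation and mean chord length, packings of thin-walled hollow
#' glass microspheres, and closed-cell foams built as Voronoi tessellations
#' whose cell walls are material. Every generator returns both a grayscale
#' attenuation volume (two plateau values: material = 1, air = 0) and the
#' exact binary [phase_map()] (cavity = 1), and is fully deterministic for a
#' fixed `seed`.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_size Isotropic voxel edge in micrometres.
#' @param radius_um Sphere radius in micrometres (at least 2 voxels).
#' @param fraction Target volume fraction of the sphere phase, in (0, 1).
#' @param sphere_phase Whether the spheres are `"cavity"` (pores in a solid
#'   matrix, the default) or `"material"` (solid spheres in air).
#' @param centers Optional matrix (n x 3) of sphere centres in continuous
#'   voxel coordinates; bypasses random placement (used for single-sphere
#'   phantoms with exactly known geometry).
#' @param seed Integer seed; all randomness in the call flows from it.
#' @param max_attempts Maximum number of rejection-sampling attempts for
#'   random sequential addition.
#' @param min_fraction Achieved-fraction floor below which placement fails
#'   with an error; by default half the target.
#' @return A list of class `phantom` with elements `volume` ([volume3d()]),
#'   `phase` ([phase_map()]) and `params` (including `achieved_fraction`).
#' @export
#' @examples
#' ph <- make_solid_spheres(shape = c(48, 48, 48), voxel_size = 2,
#'                          radius_um = 8, fraction = 0.05, seed = 1)
#' cavity_fraction(ph$phase)
make_solid_spheres <- function(shape, voxel_size = 2, radius_um = 16,
                               fraction = 0.05,
                               sphere_phase = c("cavity", "material"),
                               centers = NULL, seed = 1L,
                               max_attempts = 20000L,
                               min_fraction = fraction / 2) {
  sphere_phase <- match.arg(sphere_phase)
  shape <- check_shape(shape)
  r <- radius_um / voxel_size
  if (r < 2) abort("sphere radius must be at least 2 voxels.")
  if (is.null(centers)) {
    if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
    centers <- rsa_centers(shape, r, fraction, seed, max_attempts)
  } else {
    centers <- as.matrix(centers)
    attr(centers, "user_supplied") <- TRUE
  }
  random_placement <- is.null(attr(centers, "user_supplied"))
  mask <- array(FALSE, dim = shape)
  for (i in seq_len(nrow(centers))) {
    mask <- paint_ball(mask, centers[i, ], r)
  }
  achieved <- mean(mask)
  if (random_placement && !is.null(min_fraction) && achieved < min_fraction) {
    abort(sprintf(
      "achieved sphere fraction %.4f below the configured minimum %.4f.",
      achieved, min_fraction))
  }
  phase <- if (sphere_phase == "cavity") mask else !mask
  finish_phantom(phase, shape, voxel_size,
                 params = list(kind = "solid_spheres", radius_um = radius_um,
                               n_spheres = nrow(centers), seed = seed,
                               sphere_phase = sphere_phase,
                               achieved_fraction = achieved))
}

#' Hollow microsphere packing phantom
#'
#' Thin spherical shells of material (glass) around air cores, with air also
#' filling the interstitial space — the structure of hollow glass microsphere
#' fillers. Outer spheres are placed by non-overlapping random sequential
#' addition; radii may be drawn from a lognormal distribution.
#'
#' @inheritParams make_solid_spheres
#' @param shell_um Shell thickness in micrometres; must be at least one voxel
#'   and smaller than the radius.
#' @param outer_fraction Target volume fraction occupied by the outer spheres
#'   (cores + shells).
#' @param radius_sdlog Lognormal standard deviation (log scale) of the radius
#'   distribution; 0 gives monodisperse shells.
#' @return A `phantom` list, as for [make_solid_spheres()].
#' @export
make_hollow_spheres <- function(shape, voxel_size = 2, radius_um = 24,
                                shell_um = 4, outer_fraction = 0.3,
                                radius_sdlog = 0, seed = 1L,
                                max_attempts = 20000L) {
  shape <- check_shape(shape)
  if (shell_um >= radius_um) {
    abort("shell thickness must be smaller than the sphere radius.")
  }
  if (shell_um / voxel_size < 1) {
    abort(paste0("shell thinner than one voxel (", shell_um, " um at ",
                 voxel_size, " um/voxel); use a finer grid or a thicker shell."))
  }
  set.seed(seed)
  r_mean <- radius_um / voxel_size
  shell <- shell_um / voxel_size
  vol_total <- prod(shape)
  centers <- matrix(0, 0, 3)
  radii <- numeric(0)
  placed_vol <- 0
  attempts <- 0L
  while (placed_vol / vol_total < outer_fraction && attempts < max_attempts) {
    attempts <- attempts + 1L
    r_i <- if (radius_sdlog > 0) {
      stats::rlnorm(1, meanlog = log(r_mean) - radius_sdlog^2 / 2,
                    sdlog = radius_sdlog)
    } else r_mean
    if (r_i <= shell + 1 || 2 * r_i >= min(shape) - 2) next
    cand <- runif(3, min = 1 + r_i, max = shape - r_i)
    if (nrow(centers) > 0) {
      d2 <- colSums((t(centers) - cand)^2)
      if (any(d2 < (radii + r_i)^2)) next
    }
    centers <- rbind(centers, cand)
    radii <- c(radii, r_i)
    placed_vol <- placed_vol + 4 / 3 * pi * r_i^3
  }
  if (nrow(centers) == 0L) abort("no hollow spheres could be placed.")
  material <- array(FALSE, dim = shape)
  for (i in seq_len(nrow(centers))) {
    material <- paint_ball(material, centers[i, ], radii[i],
                           inner_r = radii[i] - shell)
  }
  finish_phantom(!material, shape, voxel_size,
                 params = list(kind = "hollow_spheres", radius_um = radius_um,
                               shell_um = shell_um, n_spheres = nrow(centers),
                               seed = seed,
                               achieved_fraction = placed_vol / vol_total))
}

#' Closed-cell Voronoi foam phantom
#'
#' A Voronoi tessellation of uniformly random seed points; voxels within half
#' the wall thickness of a cell boundary are material, cell interiors are air
#' cavities. The seed density is the single knob controlling mean cell size
#' and hence the mean chord length of the cavity phase.
#'
#' @inheritParams make_solid_spheres
#' @param n_seeds Number of Voronoi seed points (at least 2).
#' @param wall_um Cell wall thickness in micrometres (at least one voxel).
#' @return A `phantom` list, as for [make_solid_spheres()].
#' @export
make_voronoi_foam <- function(shape, voxel_size = 2, n_seeds = 50,
                              wall_um = 4, seed = 1L) {
  shape <- check_shape(shape)
  if (n_seeds < 2) abort("a foam needs at least 2 Voronoi seeds.")
  if (wall_um / voxel_size < 1) abort("wall thickness must be at least one voxel.")
  set.seed(seed)
  pts <- matrix(runif(3 * n_seeds), ncol = 3)
  pts <- sweep(pts, 2, shape - 1, `*`) + 1   # continuous voxel coords in [1, n]
  # running nearest and second-nearest seed distance per voxel
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xs <- as.double(seq_len(nx)); ys <- as.double(seq_len(ny)); zs <- as.double(seq_len(nz))
  X <- array(xs, dim = shape)
  Y <- array(rep(ys, each = nx), dim = shape)
  Z <- array(rep(zs, each = nx * ny), dim = shape)
  d1 <- array(Inf, dim = shape)
  d2 <- array(Inf, dim = shape)
  for (i in seq_len(n_seeds)) {
    di <- sqrt((X - pts[i, 1])^2 + (Y - pts[i, 2])^2 + (Z - pts[i, 3])^2)
    closer <- di < d1
    d2[closer] <- d1[closer]
    d1[closer] <- di[closer]
    mid <- !closer & (di < d2)
    d2[mid] <- di[mid]
  }
  material <- (d2 - d1) < (wall_um / voxel_size)
  frac_material <- mean(material)
  if (frac_material > 0.9) {
    abort(sprintf(
      "degenerate foam: walls occupy %.0f%% of the volume; reduce seed density or wall thickness.",
      100 * frac_material))
  }
  finish_phantom(!material, shape, voxel_size,
                 params = list(kind = "voronoi_foam", n_seeds = n_seeds,
                               wall_um = wall_um, seed = seed,
                               achieved_fraction = 1 - frac_material))
}

#' Cavity slab phantom
#'
#' A plane-parallel air slab of given thickness centred in a solid block,
#' normal to the chosen axis. Its chord length distribution under isotropic
#' uniform random lines has the closed form \eqn{t/|\cos\theta|}, making it a
#' stereology oracle.
#'
#' @inheritParams make_solid_spheres
#' @param thickness_um Slab thickness in micrometres.
#' @param axis Axis normal to the slab: `"x"`, `"y"` or `"z"`.
#' @return A `phantom` list, as for [make_solid_spheres()].
#' @export
make_slab <- function(shape, voxel_size = 2, thickness_um = 20, axis = "z") {
  shape <- check_shape(shape)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  t_vox <- round(thickness_um / voxel_size)
  n <- shape[ax]
  if (t_vox < 1 || t_vox >= n - 2) abort("slab thickness unrepresentable on this grid.")
  start <- round((n + 1) / 2 - t_vox / 2 + 0.5)
  idx <- start:(start + t_vox - 1L)
  phase <- array(FALSE, dim = shape)
  ind <- list(seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]))
  ind[[ax]] <- idx
  phase[ind[[1]], ind[[2]], ind[[3]]] <- TRUE
  finish_phantom(phase, shape, voxel_size,
                 params = list(kind = "slab", thickness_um = length(idx) * voxel_size,
                               axis = axis, achieved_fraction = mean(phase)))
}

#' MicroCT-like degradation model
#'
#' Applies a Gaussian blur (point-spread surrogate) followed by additive
#' Gaussian noise, emulating the data quality of reconstructed microCT
#' volumes. With `blur_sigma = 0` and `noise_sd = 0` the input is returned
#' unchanged.
#'
#' @param vol A [volume3d()].
#' @param blur_sigma Gaussian blur standard deviation in micrometres.
#' @param noise_sd Noise standard deviation as a fraction of the volume's
#'   grayscale contrast (its value range; a zero-range volume uses unit
#'   contrast so the operation stays defined).
#' @param seed Integer seed for the noise draw.
#' @return A blurred, noisy [volume3d()] on the same grid.
#' @export
add_microct_noise <- function(vol, blur_sigma = 2, noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(vol, "volume3d"))
  if (blur_sigma < 0 || noise_sd < 0) abort("blur_sigma and noise_sd must be >= 0.")
  out <- vol$data
  if (blur_sigma > 0) {
    out <- gaussian_blur3d(out, sigma_vox = blur_sigma / vol$voxel_size)
  }
  if (noise_sd > 0) {
    contrast <- diff(range(vol$data))
    if (contrast == 0) contrast <- 1
    set.seed(seed)
    out <- out + array(rnorm(length(out), sd = noise_sd * contrast), dim = dim(out))
  }
  volume3d(out, vol$voxel_size)
}

# ---- internals ------------------------------------------------------------

check_shape <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) {
    abort("`shape` must be three integers >= 2.")
  }
  shape
}

# voxel-centre membership: voxel (i,j,k) belongs to the ball iff its centre
# lies inside; inner_r carves out a concentric core (shells)
paint_ball <- function(mask, center, r, inner_r = NULL) {
  shape <- dim(mask)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor(center[a] - r))
    hi <- min(shape[a], ceiling(center[a] + r))
    lo:hi
  })
  dx2 <- (rng[[1]] - center[1])^2
  dy2 <- (rng[[2]] - center[2])^2
  dz2 <- (rng[[3]] - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  sel <- d2 <= r^2
  if (!is.null(inner_r) && inner_r > 0) sel <- sel & d2 > inner_r^2
  sub <- mask[rng[[1]], rng[[2]], rng[[3]]]
  mask[rng[[1]], rng[[2]], rng[[3]]] <- sub | sel
  mask
}

# random sequential addition of equal non-overlapping balls, fully inside
rsa_centers <- function(shape, r, fraction, seed, max_attempts) {
  set.seed(seed)
  vol_sphere <- 4 / 3 * pi * r^3
  n_target <- ceiling(fraction * prod(shape) / vol_sphere)
  if (any(shape < 2 * r + 2)) abort("sphere diameter exceeds the grid.")
  centers <- matrix(0, 0, 3)
  attempts <- 0L
  while (nrow(centers) < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- runif(3, min = 1 + r, max = shape - r)
    if (nrow(centers) > 0) {
      d2 <- colSums((t(centers) - cand)^2)
      if (any(d2 < (2 * r)^2)) next
    }
    centers <- rbind(centers, cand)
  }
  if (nrow(centers) < n_target) {
    warn(sprintf("placed %d of %d spheres before max_attempts; achieved fraction ~%.4f.",
                 nrow(centers), n_target,
                 nrow(centers) * vol_sphere / prod(shape)))
  }
  centers
}

finish_phantom <- function(phase_logical, shape, voxel_size, params) {
  phase <- array(as.integer(phase_logical), dim = shape)
  gray <- array(1 - as.double(phase_logical), dim = shape)  # material = 1, air = 0
  structure(list(volume = volume3d(gray, voxel_size),
                 phase = phase_map(phase, voxel_size),
                 params = params),
            class = "phantom")
}

# separable Gaussian blur with reflected edges, kernel truncated at 4 sigma
gaussian_blur3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  k <- max(1L, ceiling(4 * sigma_vox))
  kern <- stats::dnorm(seq(-k, k), sd = sigma_vox)
  kern <- kern / sum(kern)
  for (axis in 1:3) arr <- convolve_axis(arr, kern, axis)
  arr
}

convolve_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- length(a) / n
  dim(a) <- c(n, m)
  k <- (length(kern) - 1L) / 2L
  refl <- c(pmin(pmax(seq(1 - k, n + k), 2 - seq(1 - k, n + k)), 2 * n - seq(1 - k, n + k)))
  pad <- a[refl, , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_along(kern)) {
    out <- out + kern[j] * pad[j:(j + n - 1L), , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}
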