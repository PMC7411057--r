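#' Material model for the dark-field forward relation
#'
#' Bundles the scattering prefactor, sample thickness and correlation profile
#' entering \eqn{-\ln D = \sigma t\,[1 - G(\xi_{corr})]}, where the
#' scattering cross-section is decomposed as \eqn{\sigma = \sigma_0
#' \lambda^2} (the cross-section is proportional to the squared wavelength).
#'
#' @param sigma0 Scattering prefactor per unit thickness and squared
#'   wavelength, in 1/(m·Å²); non-negative.
#' @param thickness_m Sample thickness along the beam in metres.
#' @param profile A `correlation_profile` (see [projected_profile()]).
#' @return A list of class `material_model`.
#' @export
material_model <- function(sigma0, thickness_m, profile) {
  if (sigma0 < 0) abort("`sigma0` must be >= 0.")
  if (thickness_m <= 0) abort("`thickness_m` must be positive.")
  stopifnot(inherits(profile, "correlation_profile"))
  structure(list(sigma0 = sigma0, thickness_m = thickness_m, profile = profile),
            class = "material_model")
}

# G(xi) by linear interpolation; no extrapolation beyond the profile
interp_G <- function(profile, xi_um) {
  if (any(xi_um < min(profile$xi_um) - 1e-12) ||
      any(xi_um > max(profile$xi_um) + 1e-12)) {
    abort("xi outside the correlation profile range; no extrapolation is performed.")
  }
  approx(profile$xi_um, profile$G, xout = xi_um, rule = 2)$y
}

#' Monochromatic dark-field signal
#'
#' \eqn{-\ln D(E) = \sigma_0 \lambda(E)^2\, t\, [1 - G(\xi_{corr}(E))]} with
#' \eqn{\xi_{corr}(E)} from [correlation_length()]. Where the profile's `G`
#' is negative the bracket exceeds 1 and is applied as written. At
#' \eqn{\xi \to 0}, `G(0) = 1` gives `D = 1`: vanishing correlation length
#' probes no structure.
#'
#' @param mat A [material_model()].
#' @param energy_keV Photon energy in keV (vectorised).
#' @param geom An [interferometer_geometry()].
#' @return The dark-field signal `D(E)` in (0, 1]; `-log()` of it is the
#'   scattering signal.
#' @export
mono_darkfield <- function(mat, energy_keV, geom) {
  stopifnot(inherits(mat, "material_model"))
  xi <- correlation_length(energy_keV, geom)
  bracket <- 1 - interp_G(mat$profile, xi)
  lambda <- energy_to_wavelength(energy_keV)
  exp(-mat$sigma0 * lambda^2 * mat$thickness_m * bracket)
}

#' Polychromatic bin-averaged dark-field signal
#'
#' The signal measured in one counting bin is the fluence-and-visibility
#' weighted mean of the monochromatic signals,
#' \eqn{D_{bin} = \int \Phi_{eff} V D(E) dE / \int \Phi_{eff} V dE} — the
#' same weights that define the effective autocorrelation length. The result
#' always lies between the monochromatic extremes over the bin.
#'
#' @inheritParams effective_correlation_length
#' @param mat A [material_model()].
#' @return The bin dark-field signal `D_bin`.
#' @export
polychromatic_darkfield <- function(mat, phi_eff, vis, bin, geom,
                                    grid_step = 0.5) {
  stopifnot(inherits(bin, "energy_bin"))
  grid <- seq(bin$e1, bin$e2, by = grid_step)
  w <- interp_spectrum(phi_eff, grid) * interp_spectrum(vis, grid)
  denom <- trapz(grid, w)
  if (denom <= 0) abort("zero total weight in the energy bin.")
  D <- mono_darkfield(mat, grid, geom)
  trapz(grid, w * D) / denom
}

#' Simulate a phase-stepping intensity curve
#'
#' One grating is stepped over its period in `n_steps` equidistant positions;
#' the recorded intensity is \eqn{I_k = a_0 [1 + V \cos(2\pi k/N + \phi)]},
#' optionally with Poisson counting noise.
#'
#' @param a0 Mean counts per step (positive).
#' @param visibility Fringe visibility in \[0, 1\].
#' @param phase Fringe phase in radians.
#' @param n_steps Number of phase steps (>= 3).
#' @param poisson_seed Integer seed for Poisson noise, or `NULL` for a
#'   noiseless curve.
#' @return A list of class `stepping_curve` with `intensities`, `n_steps`
#'   and `period_fraction` (step positions k/N).
#' @export
simulate_stepping_curve <- function(a0, visibility, phase = 0, n_steps = 7L,
                                    poisson_seed = NULL) {
  if (a0 <= 0) abort("`a0` must be positive.")
  if (visibility < 0 || visibility > 1) abort("visibility must lie in [0, 1].")
  if (n_steps < 3) abort("at least 3 phase steps are required.")
  k <- 0:(n_steps - 1L)
  I <- a0 * (1 + visibility * cos(2 * pi * k / n_steps + phase))
  if (!is.null(poisson_seed)) {
    set.seed(poisson_seed)
    I <- rpois(n_steps, I)
  }
  structure(list(intensities = as.double(I), n_steps = as.integer(n_steps),
                 period_fraction = k / n_steps),
            class = "stepping_curve")
}

#' First-harmonic visibility retrieval from a stepping curve
#'
#' Least-squares retrieval via the discrete Fourier coefficients: the mean
#' gives \eqn{a_0}, the first harmonic gives visibility \eqn{|c_1|/a_0} and
#' phase \eqn{\arg c_1}. Exact on noiseless single-harmonic curves.
#'
#' @param curve A [simulate_stepping_curve()] result, or a bare numeric
#'   vector of intensities.
#' @return A list with `a0`, `visibility` and `phase`.
#' @export
retrieve_visibility <- function(curve) {
  I <- if (inherits(curve, "stepping_curve")) curve$intensities else as.double(curve)
  n <- length(I)
  if (n < 3) abort("at least 3 phase steps are required.")
  a0 <- mean(I)
  if (a0 <= 0) abort("non-positive mean intensity.")
  k <- 0:(n - 1L)
  c1 <- sum(I * exp(-2i * pi * k / n)) * 2 / n
  list(a0 = a0, visibility = Mod(c1) / a0, phase = Arg(c1))
}

#' Dark-field signal from sample and reference visibility
#'
#' \eqn{D = V_{sample} / V_{reference}}: the reduction of fringe visibility
#' caused by small-angle scattering in the sample. Values above 1 (possible
#' under noise) are clipped to 1 with a warning.
#'
#' @param v_sample,v_reference Visibilities; `v_reference` must be positive.
#' @return The dark-field signal `D`.
#' @export
darkfield_from_visibilities <- function(v_sample, v_reference) {
  if (v_reference <= 0) abort("`v_reference` must be positive.")
  if (v_sample < 0) abort("`v_sample` must be >= 0.")
  D <- v_sample / v_reference
  if (D > 1) {
    warn(sprintf("D = %.4f > 1; clipping to 1 (noise can push the ratio above unity).", D))
    D <- 1
  }
  D
}

#' Wavelength-normalized dark-field signal
#'
#' Divides \eqn{-\ln D} by the squared weighted wavelength, removing the
#' \eqn{E^{-2}} scattering cross-section scaling so the remainder should
#' track \eqn{1 - G(\xi)}.
#'
#' @param neg_log_D The scattering signal \eqn{-\ln D} (>= 0).
#' @param lambda_A Weighted wavelength in Angstrom (positive).
#' @return \eqn{-\ln D / \lambda^2} in 1/Å² (vectorised).
#' @export
normalized_logD <- function(neg_log_D, lambda_A) {
  if (any(lambda_A <= 0)) abort("wavelength must be positive.")
  if (any(neg_log_D < 0)) abort("`neg_log_D` must be >= 0.")
  neg_log_D / lambda_A^2
}

#' Spectral dark-field ratio
#'
#' Quotient of the scattering signals of the two energy bins, oriented
#' low over high so that it exceeds 1 and grows with structure size.
#'
#' @param neg_log_D_low,neg_log_D_high Scattering signals of the two bins
#'   (positive).
#' @param orientation `"low_over_high"` (default) or `"high_over_low"`.
#' @return The ratio (vectorised).
#' @export
spectral_ratio <- function(neg_log_D_low, neg_log_D_high,
                           orientation = c("low_over_high", "high_over_low")) {
  orientation <- match.arg(orientation)
  if (any(neg_log_D_high <= 0) || any(neg_log_D_low <= 0)) {
    abort("both bin signals must be positive to form a ratio.")
  }
  r <- neg_log_D_low / neg_log_D_high
  if (orientation == "high_over_low") r <- 1 / r
  r
}

#' Calibrate the scattering prefactor to a target signal
#'
#' Solves \eqn{\sigma_0 = -\ln D_{target} / (\lambda^2 t\,[1 - G(\xi(E))])}
#' so a material model reproduces a chosen scattering signal at one energy.
#'
#' @param profile A `correlation_profile`.
#' @param target_neg_log_D Desired \eqn{-\ln D} at `energy_keV`.
#' @param energy_keV Calibration energy in keV.
#' @param geom An [interferometer_geometry()].
#' @param thickness_m Sample thickness in metres.
#' @return The calibrated `sigma0` in 1/(m·Å²).
#' @export
calibrate_sigma0 <- function(profile, target_neg_log_D, energy_keV, geom,
                             thickness_m) {
  xi <- correlation_length(energy_keV, geom)
  bracket <- 1 - interp_G(profile, xi)
  if (bracket <= 0) abort("1 - G vanishes at the calibration energy; cannot calibrate.")
  lambda <- energy_to_wavelength(energy_keV)
  target_neg_log_D / (lambda^2 * thickness_m * bracket)
}
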