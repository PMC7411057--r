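#' Talbot-Lau interferometer geometry
#'
#' @param d_s_g2 Sample to analyzer-grating distance in metres.
#' @param p_g2 Analyzer grating period in micrometres.
#' @param design_energy Design energy of the interferometer in keV
#'   (informational).
#' @return A list of class `interferometer_geometry`.
#' @export
#' @examples
#' geom <- interferometer_geometry(d_s_g2 = 0.571, p_g2 = 10)
#' correlation_length(43.0, geom)
interferometer_geometry <- function(d_s_g2, p_g2, design_energy = 45) {
  if (d_s_g2 <= 0 || p_g2 <= 0) abort("geometry lengths must be positive.")
  structure(list(d_s_g2 = d_s_g2, p_g2 = p_g2, design_energy = design_energy),
            class = "interferometer_geometry")
}

#' Photon energy to wavelength
#'
#' \eqn{\lambda = hc/E} with \eqn{hc} = 12.3984 keV·Å.
#'
#' @param energy_keV Photon energy in keV (positive; vectorised).
#' @return Wavelength in Angstrom.
#' @export
#' @examples
#' energy_to_wavelength(c(43.0, 80.9))
energy_to_wavelength <- function(energy_keV) {
  if (any(energy_keV <= 0)) abort("energy must be positive.")
  .hc_keV_A / energy_keV
}

#' Autocorrelation length sampled by a grating interferometer
#'
#' The microstructural length scale probed at energy `E` is
#' \eqn{\xi_{corr}(E) = (d_{S,G2}/p_{G2}) \cdot hc/E}: linear in the
#' sample-to-analyzer distance, inverse in the grating period and in the
#' energy.
#'
#' @inheritParams energy_to_wavelength
#' @param geom An [interferometer_geometry()].
#' @return Autocorrelation length in micrometres (vectorised over energy).
#' @export
correlation_length <- function(energy_keV, geom) {
  stopifnot(inherits(geom, "interferometer_geometry"))
  if (any(energy_keV <= 0)) abort("energy must be positive.")
  # d[m] / p[um] * lambda[A]: 1 m/um = 1e6, 1 A = 1e-4 um
  (geom$d_s_g2 * 1e6 / geom$p_g2) * energy_to_wavelength(energy_keV) * 1e-4
}

#' Spectral tables
#'
#' A spectral table is a tibble with columns `energy_keV` (strictly
#' increasing) and `value`, tagged by what the values are: photon fluence
#' (`"fluence"`), effective per-bin fluence (`"effective_fluence"`) or fringe
#' visibility (`"visibility"`, values in \[0, 1\]).
#'
#' @param energy_keV Strictly increasing energy grid in keV.
#' @param value Non-negative values (additionally bounded by 1 for
#'   visibility).
#' @param kind One of `"fluence"`, `"effective_fluence"`, `"visibility"`.
#' @return A tibble of class `spectral_table`.
#' @export
spectral_table <- function(energy_keV, value,
                           kind = c("fluence", "effective_fluence", "visibility")) {
  kind <- match.arg(kind)
  if (length(energy_keV) != length(value)) abort("grids must have equal length.")
  if (any(diff(energy_keV) <= 0)) abort("`energy_keV` must be strictly increasing.")
  if (any(value < 0)) abort("spectral values must be non-negative.")
  if (kind == "visibility" && any(value > 1)) abort("visibility must lie in [0, 1].")
  out <- tibble(energy_keV = as.double(energy_keV), value = as.double(value))
  class(out) <- c("spectral_table", class(out))
  attr(out, "kind") <- kind
  out
}

#' Energy bin of a photon-counting detector
#'
#' Half-open interval `[e1, e2)` in keV, as set by two counting thresholds.
#'
#' @param e1,e2 Bin bounds in keV, `e1 < e2`.
#' @param label Optional short name (e.g. `"low"`, `"high"`).
#' @return A list of class `energy_bin`.
#' @export
energy_bin <- function(e1, e2, label = sprintf("%g-%g keV", e1, e2)) {
  if (!(e1 < e2)) abort("`e1` must be smaller than `e2`.")
  structure(list(e1 = e1, e2 = e2, label = label), class = "energy_bin")
}

trapz <- function(x, y) pracma::trapz(x, y)

# linear interpolation of a spectral table onto a grid; zero outside support
interp_spectrum <- function(tab, grid) {
  approx(tab$energy_keV, tab$value, xout = grid, rule = 2)$y
}

#' Spectrum-weighted effective autocorrelation length
#'
#' For a polychromatic beam the effectively sampled autocorrelation length in
#' an energy bin is the weighted mean
#' \deqn{\langle\xi\rangle_w = \frac{\int_{E_1}^{E_2} \Phi_{eff}(E) V(E) \xi(E)\,dE}
#'   {\int_{E_1}^{E_2} \Phi_{eff}(E) V(E)\,dE},}
#' weighting each energy's \eqn{\xi(E)} by the effective bin fluence and the
#' visibility spectrum. Computed by trapezoidal quadrature on a common
#' interpolated grid.
#'
#' @param phi_eff A [spectral_table()] of (effective) fluence.
#' @param vis A [spectral_table()] of visibility.
#' @param bin An [energy_bin()].
#' @param geom An [interferometer_geometry()].
#' @param grid_step Quadrature grid step in keV.
#' @return The weighted autocorrelation length in micrometres, with
#'   attributes `energy_w_keV` (the equivalent energy \eqn{hc/\langle\lambda\rangle_w})
#'   and `lambda_w_A`.
#' @export
effective_correlation_length <- function(phi_eff, vis, bin, geom,
                                         grid_step = 0.5) {
  stopifnot(inherits(bin, "energy_bin"))
  grid <- seq(bin$e1, bin$e2, by = grid_step)
  if (length(grid) < 2) abort("bin narrower than the quadrature step.")
  w <- interp_spectrum(phi_eff, grid) * interp_spectrum(vis, grid)
  denom <- trapz(grid, w)
  if (denom <= 0) abort("zero total weight in the energy bin.")
  xi <- correlation_length(grid, geom)
  xi_w <- trapz(grid, w * xi) / denom
  lambda_w <- xi_w * 1e4 * geom$p_g2 / (geom$d_s_g2 * 1e6)  # back to Angstrom
  structure(xi_w, energy_w_keV = .hc_keV_A / lambda_w, lambda_w_A = lambda_w)
}

#' Parametric filtered bremsstrahlung source spectrum
#'
#' A Kramers-shaped tube spectrum \eqn{\Phi(E) \propto E\,(kVp - E)} for
#' \eqn{0 < E < kVp}, attenuated by an aluminium filter using tabulated mass
#' attenuation coefficients (log-log interpolated), normalised to unit
#' integral. Zero at and above the tube voltage.
#'
#' @param kvp Tube voltage in kV (maximum photon energy in keV).
#' @param al_filtration_mm Aluminium filter thickness in mm.
#' @param grid_step Energy grid step in keV.
#' @param e_max Upper end of the returned grid in keV.
#' @return A [spectral_table()] of kind `"fluence"`.
#' @export
simulate_source_spectrum <- function(kvp = 120, al_filtration_mm = 2,
                                     grid_step = 0.5, e_max = 150) {
  if (kvp <= 0) abort("`kvp` must be positive.")
  grid <- seq(grid_step, e_max, by = grid_step)
  phi <- pmax(grid * (kvp - grid), 0)
  phi[grid >= kvp] <- 0
  if (al_filtration_mm > 0) {
    mu <- al_mass_atten(grid) * 2.699          # 1/cm
    phi <- phi * exp(-mu * al_filtration_mm / 10)
  }
  total <- trapz(grid, phi)
  if (total > 0) phi <- phi / total
  spectral_table(grid, phi, kind = "fluence")
}

# NIST mass attenuation coefficients for aluminium, cm^2/g, log-log interp
al_mass_atten <- function(energy_keV) {
  e_tab <- c(5, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100, 150, 200)
  mu_tab <- c(193.4, 115.3, 50.33, 26.23, 7.955, 3.441, 1.128, 0.5685,
              0.3681, 0.2778, 0.2018, 0.1704, 0.1378, 0.1223)
  exp(approx(log(e_tab), log(mu_tab), xout = log(pmin(pmax(energy_keV, 5), 200)),
             rule = 2)$y)
}

#' Parametric visibility spectrum of a Talbot-Lau setup
#'
#' Fringe visibility versus energy: a primary peak at the design energy, a
#' multiplicative dip where the gold gratings become transparent below their
#' K-edge (placed at 64 keV by default), and a secondary peak near twice the
#' design energy. All values lie in \[0, 1\]. Measured visibility spectra can
#' be loaded instead with [read_spectrum_csv()].
#'
#' @param design_energy Design energy in keV (primary peak position).
#' @param energies Energy grid in keV.
#' @param v_max Peak visibility at the design energy.
#' @param peak_width Gaussian width (sd, keV) of the primary peak.
#' @param dip_energy,dip_depth,dip_width Position (keV), fractional depth and
#'   width (sd, keV) of the visibility minimum.
#' @param second_peak_frac,second_peak_width Relative amplitude and width of
#'   the secondary peak near `2 * design_energy`.
#' @return A [spectral_table()] of kind `"visibility"`.
#' @export
visibility_model <- function(design_energy = 45,
                             energies = seq(10, 150, by = 0.5),
                             v_max = 0.32, peak_width = 11,
                             dip_energy = 64, dip_depth = 0.8,
                             dip_width = 3,
                             second_peak_frac = 0.65,
                             second_peak_width = 14) {
  if (design_energy <= 0) abort("`design_energy` must be positive.")
  base <- exp(-(energies - design_energy)^2 / (2 * peak_width^2)) +
    second_peak_frac * exp(-(energies - 2 * design_energy)^2 / (2 * second_peak_width^2))
  dip <- 1 - dip_depth * exp(-(energies - dip_energy)^2 / (2 * dip_width^2))
  v <- v_max * base * dip / max(base)
  if (any(v < 0) || any(v > 1)) {
    abort("visibility parameterization left [0, 1]; adjust parameters.")
  }
  spectral_table(energies, v, kind = "visibility")
}

#' Effective spectrum of one counting bin
#'
#' The effective spectrum is the incident spectrum multiplied, energy by
#' energy, with the probability that a photon of that incident energy is
#' recorded inside the bin. The detector response is modelled as a Gaussian
#' of the given FWHM around the incident energy (a one-parameter stand-in for
#' a full calibrated response simulation); `response_fwhm = 0` reduces to a
#' hard truncation of the spectrum to `[e1, e2)`.
#'
#' @param phi A [spectral_table()] of incident fluence.
#' @param bin An [energy_bin()].
#' @param response_fwhm Detector energy response FWHM in keV (>= 0).
#' @return A [spectral_table()] of kind `"effective_fluence"` on the same
#'   grid as `phi`.
#' @export
effective_bin_spectrum <- function(phi, bin, response_fwhm = 0) {
  stopifnot(inherits(bin, "energy_bin"))
  if (response_fwhm < 0) abort("`response_fwhm` must be >= 0.")
  e <- phi$energy_keV
  if (!any(e >= bin$e1 & e < bin$e2)) abort("bin does not overlap the spectrum grid.")
  if (response_fwhm == 0) {
    p_in <- as.numeric(e >= bin$e1 & e < bin$e2)
  } else {
    s <- response_fwhm / (2 * sqrt(2 * log(2)))
    p_in <- stats::pnorm(bin$e2, mean = e, sd = s) -
      stats::pnorm(bin$e1, mean = e, sd = s)
  }
  spectral_table(e, phi$value * p_in, kind = "effective_fluence")
}

#' Read a two-column spectrum CSV
#'
#' Expects a header `energy_keV,value`.
#'
#' @param path CSV file path.
#' @param kind Spectral kind tag, as in [spectral_table()].
#' @return A [spectral_table()].
#' @export
read_spectrum_csv <- function(path, kind = "fluence") {
  df <- utils::read.csv(path)
  if (!all(c("energy_keV", "value") %in% names(df))) {
    abort("spectrum CSV needs columns `energy_keV,value`.")
  }
  spectral_table(df$energy_keV, df$value, kind = kind)
}
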