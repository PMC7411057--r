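#' Subtract the volume mean
#'
#' The autocorrelation analysis operates on density fluctuations
#' \eqn{\Delta\rho = \rho - \langle\rho\rangle}; the output volume has zero
#' mean to machine precision.
#'
#' @param vol A [volume3d()].
#' @return A [volume3d()] with zero mean.
#' @export
mean_subtract <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  volume3d(vol$data - mean(vol$data), vol$voxel_size)
}

#' Normalized 3D autocorrelation of a fluctuation field
#'
#' Computes \eqn{\gamma(r) = F^{-1}[F(\Delta\rho)\,F^*(\Delta\rho)]}
#' normalized by its zero-shift value, so \eqn{\gamma(0) = 1}. The default
#' `zero_pad` boundary embeds the volume in a grid twice each dimension, so
#' the result is the linear (aperiodic) correlation — the finite-volume
#' overlap integral \eqn{\sum_{r'} \Delta\rho(r')\Delta\rho(r'+r)}. The
#' `periodic` mode computes the circular correlation instead and is kept for
#' parity checks.
#'
#' In `zero_pad` mode the estimator can additionally be overlap-corrected
#' (`normalization = "unbiased"`): the raw linear correlation at shift `r`
#' sums over only \eqn{\prod_i (n_i - |r_i|)} voxel pairs, which multiplies
#' the expected correlogram by a triangular window; dividing by the overlap
#' count removes that finite-window damping. The default (`"biased"`) keeps
#' the plain finite-volume integral, whose values are bounded by
#' \eqn{|\gamma| \le 1} (Cauchy-Schwarz) — the unbiased variant may exceed 1
#' at large shifts where few pairs remain.
#'
#' @param delta A zero-mean [volume3d()] (see [mean_subtract()]); a
#'   zero-variance field is rejected.
#' @param boundary `"zero_pad"` (linear correlation, default) or
#'   `"periodic"`.
#' @param normalization `"biased"` (plain overlap sum, default) or
#'   `"unbiased"` (overlap-corrected; `zero_pad` only).
#' @return An object of class `correlation_volume`: a list with `data` (an
#'   origin-centred array of \eqn{\gamma} values over integer shifts
#'   `-(n-1) .. (n-1)` per axis for `zero_pad`), `voxel_size`, and `origin`
#'   (the index of the zero-shift element).
#' @export
autocorrelation_3d <- function(delta, boundary = c("zero_pad", "periodic"),
                               normalization = c("biased", "unbiased")) {
  stopifnot(inherits(delta, "volume3d"))
  boundary <- match.arg(boundary)
  normalization <- match.arg(normalization)
  if (normalization == "unbiased" && boundary != "zero_pad") {
    abort("overlap correction applies to zero_pad boundaries only.")
  }
  x <- delta$data
  if (all(x == x[1])) {
    abort("autocorrelation undefined for zero-variance field.")
  }
  x <- x - mean(x)  # guard against tiny residual mean
  d <- dim(x)
  if (boundary == "zero_pad") {
    dp <- 2L * d
    pad <- array(0, dim = dp)
    pad[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
    F <- fft(pad)
    corr <- Re(fft(F * Conj(F), inverse = TRUE)) / prod(dp)
    # gather shifts -(n-1)..(n-1): shift s lives at index (s mod dp) + 1
    idx <- lapply(1:3, function(a) {
      s <- c(0:(d[a] - 1L), (dp[a] - d[a] + 1L):(dp[a] - 1L)) + 1L
      # order as -(n-1)..(n-1)
      s[c((d[a] + 1L):(2L * d[a] - 1L), 1L:d[a])]
    })
    g <- corr[idx[[1]], idx[[2]], idx[[3]]]
    origin <- d  # element (n, n, n) of the (2n-1)^3 array is zero shift
    if (normalization == "unbiased") {
      ov <- lapply(1:3, function(a) (d[a] - abs(seq(-(d[a] - 1L), d[a] - 1L))) / d[a])
      g <- g / outer(outer(ov[[1]], ov[[2]]), ov[[3]])
    }
  } else {
    F <- fft(x)
    corr <- Re(fft(F * Conj(F), inverse = TRUE)) / prod(d)
    half <- floor(d / 2)
    idx <- lapply(1:3, function(a) {
      ((seq_len(d[a]) - 1L - half[a]) %% d[a]) + 1L
    })
    g <- corr[idx[[1]], idx[[2]], idx[[3]]]
    origin <- half + 1L
  }
  g0 <- g[origin[1], origin[2], origin[3]]
  structure(list(data = g / g0, voxel_size = delta$voxel_size, origin = origin,
                 boundary = boundary),
            class = "correlation_volume")
}

#' @export
print.correlation_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<correlation_volume> %d x %d x %d shifts (%s), voxel %.3g um\n",
              d[1], d[2], d[3], x$boundary, x$voxel_size))
  invisible(x)
}

#' Projected real-space correlation function G(xi)
#'
#' Reduces a 3D correlation volume to the profile the dark-field signal
#' probes: \eqn{\gamma} is summed along the beam axis, the resulting 2D map
#' over perpendicular shifts is normalized by its value at zero perpendicular
#' shift (so `G(0) = 1`), and then averaged over annuli of shift magnitude
#' \eqn{\xi} in the perpendicular plane — the radial average the assumed
#' sample isotropy justifies. Annuli are centred on integer multiples of
#' `bin_width`, so the first nonzero \eqn{\xi} is exactly one voxel.
#'
#' @param gamma A `correlation_volume` from [autocorrelation_3d()].
#' @param beam_axis The projection axis; the convention is `"x"` (first array
#'   dimension).
#' @param bin_width Radial bin width in voxels.
#' @return A tibble of class `correlation_profile` with columns `xi_um`, `G`,
#'   `one_minus_G` and `n_samples` (shift counts per annulus).
#' @export
projected_profile <- function(gamma, beam_axis = "x", bin_width = 1) {
  stopifnot(inherits(gamma, "correlation_volume"))
  ax <- match(match.arg(beam_axis, c("x", "y", "z")), c("x", "y", "z"))
  map <- apply(gamma$data, setdiff(1:3, ax), sum)
  o <- gamma$origin[setdiff(1:3, ax)]
  if (abs(map[o[1], o[2]]) < .Machine$double.eps * prod(dim(gamma$data))) {
    abort("projected map vanishes at zero shift; cannot normalize.")
  }
  map <- map / map[o[1], o[2]]
  d <- dim(map)
  r <- sqrt(outer((seq_len(d[1]) - o[1])^2, (seq_len(d[2]) - o[2])^2, `+`))
  bin <- as.vector(floor(r / bin_width + 0.5))
  sums <- rowsum(as.vector(map), bin)         # rows sorted by numeric bin
  n <- as.vector(rowsum(rep(1L, length(bin)), bin))
  g <- as.vector(sums) / n
  k <- sort(unique(bin))
  correlation_profile(xi_um = k * bin_width * gamma$voxel_size, G = g,
                      n_samples = n)
}

#' Construct a correlation profile
#'
#' Builds a `correlation_profile` tibble from shift magnitudes and G values —
#' usually produced by [projected_profile()], but analytic profiles (e.g. a
#' known sphere correlation) can be supplied to the forward model this way.
#'
#' @param xi_um Strictly increasing shift magnitudes in micrometres, starting
#'   at 0.
#' @param G Correlation values, `G[1]` must be 1.
#' @param n_samples Optional per-bin sample counts.
#' @return A tibble of class `correlation_profile`.
#' @export
correlation_profile <- function(xi_um, G, n_samples = NA_integer_) {
  stopifnot(length(xi_um) == length(G), all(diff(xi_um) > 0), xi_um[1] == 0)
  out <- tibble(xi_um = as.double(xi_um), G = as.double(G),
                one_minus_G = 1 - as.double(G),
                n_samples = as.integer(n_samples))
  class(out) <- c("correlation_profile", class(out))
  out
}

#' Fill the 1 - G column of a correlation profile
#'
#' The dark-field forward relation uses the complement \eqn{1 - G(\xi)}; it
#' starts at 0 and, for samples without long-range order, approaches 1 at
#' large shifts. `G` may legitimately turn negative at large shifts (a
#' consequence of mean subtraction), making \eqn{1 - G > 1}.
#'
#' @param profile A `correlation_profile`.
#' @return The profile with its `one_minus_G` column (re)computed.
#' @export
one_minus_G <- function(profile) {
  stopifnot(inherits(profile, "correlation_profile"))
  profile$one_minus_G <- 1 - profile$G
  profile
}

#' Write a correlation profile to CSV
#'
#' Columns `xi_um,G,one_minus_G,n_samples`.
#'
#' @param profile A `correlation_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "correlation_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
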