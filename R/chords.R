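#' Isotropic uniform random (IUR) test lines
#'
#' Draws lines with direction uniform on the sphere and position uniform on
#' the plane through the volume centre normal to the direction (offsets
#' sampled over a disc containing the volume's projection). Under this
#' mu-randomness the classical mean-intercept identities hold: a convex
#' cavity has mean chord 4V/S, a sphere of diameter d has 2d/3.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param n_lines Number of lines (>= 0).
#' @param seed Integer seed.
#' @return A tibble with columns `line`, `ox, oy, oz` (origin, continuous
#'   voxel coordinates) and `ux, uy, uz` (unit direction).
#' @export
#' @examples
#' cast_random_lines(c(32, 32, 32), n_lines = 3, seed = 1)
cast_random_lines <- function(shape, n_lines, seed = 1L) {
  shape <- check_shape(shape)
  if (n_lines < 0) abort("`n_lines` must be >= 0.")
  set.seed(seed)
  n <- as.integer(n_lines)
  if (n == 0L) {
    return(tibble(line = integer(), ox = double(), oy = double(), oz = double(),
                  ux = double(), uy = double(), uz = double()))
  }
  uz <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - uz^2)
  u <- cbind(ux = s * cos(phi), uy = s * sin(phi), uz = uz)
  # orthonormal basis perpendicular to u
  ref <- cbind(1, 0, 0)
  swap <- abs(u[, 1]) > 0.9
  e1 <- cbind(ifelse(swap, 0, 1), ifelse(swap, 1, 0), 0)
  e1 <- e1 - u * rowSums(e1 * u)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
              u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
              u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
  R <- sqrt(sum(shape^2)) / 2
  a <- runif(n, -R, R)
  b <- runif(n, -R, R)
  ctr <- (shape + 1) / 2
  o <- matrix(ctr, n, 3, byrow = TRUE) + a * e1 + b * e2
  tibble(line = seq_len(n),
         ox = o[, 1], oy = o[, 2], oz = o[, 3],
         ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

#' Measure cavity chords along test lines
#'
#' Each line is sampled at a fixed sub-voxel step (default a quarter voxel);
#' the binary phase is interpolated trilinearly between voxel centres and
#' thresholded at 1/2, so the sampled interface is the smooth iso-surface of
#' the indicator rather than the voxel staircase (whose ~50% larger surface
#' area would fragment grazing chords and bias the mean chord length low).
#' Maximal runs of cavity phase are chords, with length = run count times
#' step. A chord whose run touches the entry or exit face of the volume is
#' excluded (a cavity extending beyond the region of interest would be
#' underestimated), and counted in `n_excluded`.
#'
#' @param pm A [phase_map()].
#' @param lines A tibble of test lines from [cast_random_lines()] (one or
#'   more rows).
#' Chords shorter than `min_chord_vox` voxels are discarded as unresolvable:
#' structure below two voxels cannot be represented on the grid, and the
#' sub-voxel crossings a near-tangent line picks up from the discretised
#' interface are artifacts, not cavities.
#'
#' @param step_frac Sampling step as a fraction of the voxel size.
#' @param chunk Lines processed per vectorised batch.
#' @param min_chord_vox Resolution floor in voxels; accepted chords at least
#'   this long are kept.
#' @return A list with `chords` (micrometres), `n_excluded` (boundary) and
#'   `n_subresolution` (below the resolution floor).
#' @export
measure_chords <- function(pm, lines, step_frac = 0.25, chunk = 256L,
                           min_chord_vox = 2) {
  stopifnot(inherits(pm, "phase_map"))
  if (!all(pm$data %in% c(0L, 1L))) abort("phase map must be binary.")
  d <- dim(pm$data)
  nxy <- d[1] * d[2]
  s <- step_frac  # step in voxel units
  chords <- list()
  n_excluded <- 0L
  n_short <- 0L
  o_all <- as.matrix(lines[, c("ox", "oy", "oz")])
  u_all <- as.matrix(lines[, c("ux", "uy", "uz")])
  n <- nrow(lines)
  for (start in seq(1L, max(n, 1L), by = chunk)) {
    if (n == 0L) break
    ii <- start:min(start + chunk - 1L, n)
    o <- o_all[ii, , drop = FALSE]
    u <- u_all[ii, , drop = FALSE]
    t0 <- rep(-Inf, length(ii)); t1 <- rep(Inf, length(ii))
    ok <- rep(TRUE, length(ii))
    for (a in 1:3) {
      ua <- u[, a]; oa <- o[, a]
      para <- abs(ua) < 1e-12
      lo <- (0.5 - oa) / ua; hi <- (d[a] + 0.5 - oa) / ua
      tl <- pmin(lo, hi); th <- pmax(lo, hi)
      t0 <- ifelse(para, t0, pmax(t0, tl))
      t1 <- ifelse(para, t1, pmin(t1, th))
      ok <- ok & (!para | (oa > 0.5 & oa < d[a] + 0.5))
    }
    ok <- ok & (t1 > t0) & is.finite(t1 - t0)
    if (!any(ok)) next
    o <- o[ok, , drop = FALSE]; u <- u[ok, , drop = FALSE]
    t0 <- t0[ok]; t1 <- t1[ok]
    m <- floor((t1 - t0) / s + 0.5)
    keep <- m >= 1
    if (!any(keep)) next
    o <- o[keep, , drop = FALSE]; u <- u[keep, , drop = FALSE]
    t0 <- t0[keep]; m <- as.integer(m[keep])
    nk <- length(m)
    lid <- rep.int(seq_len(nk), m)
    off <- sequence(m)
    tt <- t0[lid] + (off - 0.5) * s
    px <- o[lid, 1] + tt * u[lid, 1]
    py <- o[lid, 2] + tt * u[lid, 2]
    pz <- o[lid, 3] + tt * u[lid, 3]
    # trilinear interpolation of the phase indicator between voxel centres,
    # thresholded at 1/2: samples the marching-cubes-style smooth interface
    # instead of the voxel staircase, whose inflated surface would fragment
    # grazing chords and bias the MCL low
    x0 <- pmin(pmax(as.integer(floor(px)), 1L), d[1] - 1L)
    y0 <- pmin(pmax(as.integer(floor(py)), 1L), d[2] - 1L)
    z0 <- pmin(pmax(as.integer(floor(pz)), 1L), d[3] - 1L)
    fx <- pmin(pmax(px - x0, 0), 1)
    fy <- pmin(pmax(py - y0, 0), 1)
    fz <- pmin(pmax(pz - z0, 0), 1)
    base <- x0 + (y0 - 1L) * d[1] + (z0 - 1L) * nxy
    pd <- pm$data
    v <- (1 - fx) * (1 - fy) * (1 - fz) * pd[base] +
         fx * (1 - fy) * (1 - fz) * pd[base + 1L] +
         (1 - fx) * fy * (1 - fz) * pd[base + d[1]] +
         fx * fy * (1 - fz) * pd[base + 1L + d[1]] +
         (1 - fx) * (1 - fy) * fz * pd[base + nxy] +
         fx * (1 - fy) * fz * pd[base + 1L + nxy] +
         (1 - fx) * fy * fz * pd[base + d[1] + nxy] +
         fx * fy * fz * pd[base + 1L + d[1] + nxy]
    ph <- as.integer(v >= 0.5)
    # one sentinel (value 2) before each line's samples and one at the end
    vals <- rep.int(2L, length(ph) + nk + 1L)
    cm <- cumsum(m)
    vals[(cm[lid] - m[lid]) + off + lid] <- ph
    r <- rle(vals)
    runs <- which(r$values == 1L)
    if (length(runs) == 0L) next
    touching <- r$values[runs - 1L] == 2L | r$values[runs + 1L] == 2L
    n_excluded <- n_excluded + sum(touching)
    acc <- r$lengths[runs[!touching]]
    resolved <- acc * s >= min_chord_vox - 1e-9
    n_short <- n_short + sum(!resolved)
    acc <- acc[resolved]
    if (length(acc)) chords[[length(chords) + 1L]] <- acc * s * pm$voxel_size
  }
  list(chords = if (length(chords)) unlist(chords) else numeric(0),
       n_excluded = n_excluded, n_subresolution = n_short)
}

#' Mean chord length of the cavity phase
#'
#' Aggregates cavity chords over a set of IUR test lines into a chord length
#' distribution and its mean (MCL) with standard error — the stereological
#' airspace-size measure used for lung parenchyma and porous foams.
#'
#' @inheritParams measure_chords
#' @param n_lines Number of IUR test lines.
#' @param seed Integer seed for the line set.
#' @return An object of class `chord_distribution`: list with `chords` (um),
#'   `mcl_um`, `mcl_se_um`, `n_chords`, `n_lines`, `n_excluded`, `seed`.
#' @export
mean_chord_length <- function(pm, n_lines = 10000L, seed = 1L,
                              step_frac = 0.25, chunk = 256L,
                              min_chord_vox = 2) {
  stopifnot(inherits(pm, "phase_map"))
  lines <- cast_random_lines(dim(pm$data), n_lines, seed)
  res <- measure_chords(pm, lines, step_frac = step_frac, chunk = chunk,
                        min_chord_vox = min_chord_vox)
  if (length(res$chords) == 0L) {
    abort("no interior cavity chords; enlarge the volume or n_lines.")
  }
  structure(list(chords = res$chords,
                 mcl_um = mean(res$chords),
                 mcl_se_um = sd(res$chords) / sqrt(length(res$chords)),
                 n_chords = length(res$chords),
                 n_lines = as.integer(n_lines),
                 n_excluded = res$n_excluded,
                 n_subresolution = res$n_subresolution,
                 seed = as.integer(seed)),
            class = "chord_distribution")
}

#' @export
print.chord_distribution <- function(x, ...) {
  cat(sprintf("<chord_distribution> MCL = %.2f um (SE %.2f), %d chords from %d lines (%d excluded at boundary)\n",
              x$mcl_um, x$mcl_se_um, x$n_chords, x$n_lines, x$n_excluded))
  invisible(x)
}

#' Threshold segmentation of a grayscale volume
#'
#' Splits a grayscale attenuation volume into cavity (below threshold — air
#' attenuates less) and material. The default threshold maximises the
#' between-class variance of the volume histogram (Otsu); a fixed threshold
#' can be given instead.
#'
#' @param vol A [volume3d()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value for `method = "fixed"`.
#' @return A [phase_map()] with cavity = 1 below the threshold.
#' @export
binarize <- function(vol, method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  method <- match.arg(method)
  v <- as.vector(vol$data)
  if (method == "otsu") {
    if (diff(range(v)) == 0) abort("degenerate histogram: volume is constant.")
    thr <- otsu_threshold(v)
  } else {
    if (is.null(threshold)) abort("`threshold` required for method = 'fixed'.")
    thr <- threshold
  }
  phase <- array(as.integer(vol$data < thr), dim = dim(vol$data))
  if (length(unique(as.vector(phase))) < 2L) {
    if (method == "otsu") abort("thresholding produced a single phase.")
    # fixed thresholds may legitimately select everything / nothing;
    # return a degenerate map by bypassing the two-phase check
    return(structure(list(data = phase, voxel_size = vol$voxel_size),
                     class = "phase_map"))
  }
  phase_map(phase, vol$voxel_size)
}

# maximise between-class variance over a 256-bin histogram
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  breaks[which.max(sigma_b) + 1L]
}
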