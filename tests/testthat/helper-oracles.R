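# direct-sum (triple loop over shifts) linear correlation oracle, normalized
# at zero shift; independent of the FFT path it checks
brute_force_gamma <- function(x) {
  overlap_sum <- function(s) {
    d <- dim(x)
    i1 <- pmax(1, 1 - s); i2 <- pmin(d, d - s)
    if (any(i2 < i1)) return(0)
    a <- x[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3], drop = FALSE]
    b <- x[(i1[1] + s[1]):(i2[1] + s[1]),
           (i1[2] + s[2]):(i2[2] + s[2]),
           (i1[3] + s[3]):(i2[3] + s[3]), drop = FALSE]
    sum(a * b)
  }
  c0 <- overlap_sum(c(0, 0, 0))
  f <- function(sx, sy, sz) overlap_sum(c(sx, sy, sz)) / c0
  f
}

# isotropic Gaussian random field on a periodic grid: white noise filtered by
# a Gaussian kernel of sd `sigma` voxels; its autocorrelation is the Gaussian
# exp(-r^2 / (4 sigma^2))
gaussian_random_field <- function(n, sigma, seed) {
  set.seed(seed)
  wn <- array(rnorm(n^3), dim = c(n, n, n))
  fr <- c(0:(n %/% 2), (-(n %/% 2) + 1):(-1))
  k1 <- exp(-2 * pi^2 * sigma^2 * (fr / n)^2)
  K <- outer(outer(k1, k1), k1)
  Re(fft(fft(wn) * K, inverse = TRUE) / n^3)
}

# binary ellipsoid phantom with semi-axes (in voxels) at the grid centre
ellipsoid_phase <- function(shape, semi, voxel_size = 1) {
  ctr <- (shape + 1) / 2
  X <- array(seq_len(shape[1]), dim = shape)
  Y <- array(rep(seq_len(shape[2]), each = shape[1]), dim = shape)
  Z <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  inside <- ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
    ((Z - ctr[3]) / semi[3])^2 <= 1
  phase_map(array(as.integer(inside), dim = shape), voxel_size)
}

paper_geom <- function() interferometer_geometry(d_s_g2 = 0.571, p_g2 = 10,
                                                 design_energy = 45)
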