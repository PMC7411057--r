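#' 3D scalar volumes and binary phase maps
#'
#' `volume3d()` wraps a 3D numeric array of attenuation (or electron-density
#' proxy) values together with its isotropic voxel size. `phase_map()` wraps a
#' binary 3D array with the convention cavity/air = 1, material = 0. Axes
#' follow the interferometer convention `(x, y, z)` where `x` is the beam
#' direction and `z` the sensitivity direction of the grating setup.
#'
#' @param data A 3D numeric array; for `phase_map()` all values must be 0 or 1
#'   and both phases must be present.
#' @param voxel_size Edge length of one (isotropic) voxel in micrometres.
#' @return An object of class `volume3d` (resp. `phase_map`): a list with
#'   elements `data` and `voxel_size`.
#' @export
#' @examples
#' v <- volume3d(array(runif(8^3), dim = c(8, 8, 8)), voxel_size = 2)
#' dim(v$data)
volume3d <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  if (any(dim(data) < 2L)) {
    abort("all three dimensions must be at least 2 voxels.")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    abort("`voxel_size` must be a single positive number (micrometres).")
  }
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "volume3d")
}

#' @rdname volume3d
#' @export
phase_map <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1))) {
    abort("a phase map must contain only 0 (material) and 1 (cavity).")
  }
  if (length(u) < 2L) {
    abort("a phase map must contain at least one voxel of each phase.")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    abort("`voxel_size` must be a single positive number (micrometres).")
  }
  storage.mode(data) <- "integer"
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "phase_map")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, voxel %.3g um, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.phase_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<phase_map> %d x %d x %d voxels, voxel %.3g um, cavity fraction %.3f\n",
              d[1], d[2], d[3], x$voxel_size, mean(x$data)))
  invisible(x)
}

#' Cavity volume fraction of a phase map
#'
#' @param pm A [phase_map()].
#' @return Fraction of voxels labelled cavity (1).
#' @export
cavity_fraction <- function(pm) {
  stopifnot(inherits(pm, "phase_map"))
  mean(pm$data)
}

sidecar_path <- function(path) paste0(sub("\\.(tiff?|raw|bin)$", "", path), ".json")

#' Read and write volumes as TIFF stacks or raw binary with a JSON sidecar
#'
#' Volumes are written as multi-page TIFF stacks (one page per x-slice,
#' 32-bit float) or as little-endian raw doubles, together with a JSON
#' sidecar `<stem>.json` recording `{voxel_size_um, shape, axes,
#' phase_convention}`.
#'
#' @param vol A [volume3d()] or [phase_map()].
#' @param path Output file; extension `.tif`/`.tiff` selects TIFF, anything
#'   else raw binary.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a `volume3d` (or `phase_map` if the sidecar says the payload is binary).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("volume3d", "phase_map")))
  d <- dim(vol$data)
  is_phase <- inherits(vol, "phase_map")
  meta <- list(voxel_size_um = vol$voxel_size, shape = d, axes = "xyz",
               phase_convention = if (is_phase) "cavity=1" else "grayscale")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    # one page per x-slice; tiff stores matrices, scale to float as-is
    pages <- lapply(seq_len(d[1]), function(i) {
      m <- vol$data[i, , , drop = TRUE]
      storage.mode(m) <- "double"
      m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(as.double(vol$data)), con, size = 8, endian = "little")
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = d)
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
    arr <- array(v, dim = d)
  }
  if (identical(meta$phase_convention, "cavity=1")) {
    phase_map(array(as.integer(round(arr)), dim = d), meta$voxel_size_um)
  } else {
    volume3d(arr, meta$voxel_size_um)
  }
}
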