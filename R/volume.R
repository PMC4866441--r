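#' 3D volume container
#'
#' A `gmrid_volume` wraps a 3D numeric array together with its voxel geometry.
#' The flattened volume is the length-`n` intensity vector on which the global
#' filter operates; the canonical linearization used everywhere in the package
#' is R's native array vectorization (1-based, first axis fastest), exposed
#' through [vol_index()] and [vol_coords()].
#'
#' @param data a 3D numeric array of finite intensities.
#' @param voxel_size physical voxel spacing per axis in mm (length 1 or 3).
#' @return an object of class `gmrid_volume` with fields `data`, `shape`,
#'   `voxel_size` and the cached `intensity_range`.
#' @examples
#' v <- as_volume(array(runif(27), c(3, 3, 3)))
#' v$shape
#' @export
as_volume <- function(data, voxel_size = c(1, 1, 1)) {
  if (inherits(data, "gmrid_volume")) return(data)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_contract("volume data must be a 3D array, got %s dimension(s)",
                  paste(length(dim(data)), collapse = "x"))
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop_contract("volume contains non-finite intensities")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(
    list(data = data,
         shape = dim(data),
         voxel_size = as.numeric(voxel_size),
         intensity_range = range(data)),
    class = "gmrid_volume")
}

#' @export
print.gmrid_volume <- function(x, ...) {
  cat(sprintf("<gmrid_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

#' Number of voxels in a volume
#' @param vol a [as_volume()] object.
#' @export
n_voxels <- function(vol) prod(vol$shape)

#' Linear index / coordinate conversion
#'
#' The canonical bijection between voxel coordinates `(i, j, k)` (1-based)
#' and the linear index used for the flattened intensity vector. The first
#' axis varies fastest, matching R's array storage, so
#' `vol$data[idx] == vol$data[i, j, k]`.
#'
#' @param shape integer vector of length 3.
#' @param coords integer matrix with 3 columns (or length-3 vector).
#' @param idx vector of linear indices in `[1, prod(shape)]`.
#' @return `vol_index` returns linear indices; `vol_coords` an n-by-3 matrix.
#' @export
vol_index <- function(shape, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  stopifnot(ncol(coords) == 3L)
  if (any(coords < 1L) || any(t(coords) > shape))
    stop_contract("coordinates out of range for shape %s",
                  paste(shape, collapse = "x"))
  (coords[, 1L] - 1L) +
    (coords[, 2L] - 1L) * shape[1L] +
    (coords[, 3L] - 1L) * shape[1L] * shape[2L] + 1L
}

#' @rdname vol_index
#' @export
vol_coords <- function(shape, idx) {
  n <- prod(shape)
  if (any(idx < 1L) || any(idx > n))
    stop_contract("linear index out of range [1, %d]", n)
  z <- idx - 1L
  i <- z %% shape[1L]
  j <- (z %/% shape[1L]) %% shape[2L]
  k <- z %/% (shape[1L] * shape[2L])
  cbind(i, j, k) + 1L
}

#' Read a 3D volume from disk
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) through RNifti, or the package's plain
#' text format (`.nvol`, see [write_volume()]). Data are promoted to double
#' precision for all internal computation.
#'
#' @param path path to an existing volume file.
#' @return a [as_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop_contract("volume file does not exist: %s", path)
  if (grepl("\\.nvol$", path)) return(read_nvol(path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_contract("unsupported format: expected a 3D volume, got %dD data", length(d))
  if (is.complex(img))
    stop_contract("unsupported format: complex-valued data")
  pix <- attr(img, "pixdim")
  vs <- if (!is.null(pix) && length(pix) >= 3L) abs(pix[1:3]) else
    RNifti::pixdim(img)[1:3]
  vs[!is.finite(vs) | vs <= 0] <- 1
  as_volume(array(as.numeric(img), dim = d), voxel_size = vs)
}

#' Write a 3D volume to disk
#'
#' NIfTI output is stored as float32 (internal computation stays double);
#' the `.nvol` plain text format stores full doubles and round-trips
#' bit-exactly, which the test fixtures rely on.
#'
#' @param vol a [as_volume()] object.
#' @param path destination ending in `.nii`, `.nii.gz` or `.nvol`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_contract("parent directory does not exist: %s", dir)
  if (grepl("\\.nvol$", path)) return(write_nvol(vol, path))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size
  ok <- tryCatch({RNifti::writeNifti(img, path, datatype = "float"); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop_contract("could not write volume to %s", path)
  invisible(path)
}

# Plain text volume format: a self-describing ASCII container used for tiny
# fixtures. Line 1: "NVOL1"; line 2: shape; line 3: voxel size; then one
# intensity per line in full (17 significant digit) precision, canonical order.
read_nvol <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L || lines[1L] != "NVOL1")
    stop_contract("unsupported format: %s is not an NVOL1 file", path)
  shape <- as.integer(strsplit(lines[2L], "\\s+")[[1L]])
  vs <- as.numeric(strsplit(lines[3L], "\\s+")[[1L]])
  if (length(shape) != 3L)
    stop_contract("unsupported format: expected a 3D shape, got %dD", length(shape))
  vals <- as.numeric(lines[-(1:3)])
  if (length(vals) != prod(shape))
    stop_contract("corrupt NVOL1 file: %d values for shape %s",
                  length(vals), paste(shape, collapse = "x"))
  as_volume(array(vals, dim = shape), voxel_size = vs)
}

write_nvol <- function(vol, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_contract("could not open %s for writing", path))
  on.exit(close(con))
  writeLines(c("NVOL1",
               paste(vol$shape, collapse = " "),
               paste(sprintf("%.17g", vol$voxel_size), collapse = " "),
               sprintf("%.17g", as.vector(vol$data))), con)
  invisible(path)
}

# Rescale intensities to [0, 1] by the volume's own min/max; returns the
# rescaled vector plus the affine needed to restore the original units.
# Constant volumes map to all zeros with scale 1.
rescale01 <- function(vol) {
  rng <- vol$intensity_range
  span <- rng[2] - rng[1]
  if (span <= 0) span <- 1
  list(y = (as.vector(vol$data) - rng[1]) / span, offset = rng[1], scale = span)
}

restore01 <- function(y, scaling) y * scaling$scale + scaling$offset
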