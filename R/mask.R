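#' Voxel mask over a 3D grid
#'
#' A `voxel_mask` fixes the voxel universe for all downstream operations:
#' the grid dimensions, the set of in-mask voxel coordinates, and the
#' bijection between in-mask coordinates and the column index of every
#' trials-by-voxels feature matrix. Columns are ordered by the grid's
#' linear (column-major) order, so a mask built from an array and the
#' voxel values extracted with `array[mask_array != 0]` always agree.
#'
#' @param x Either a 3D logical/numeric array (non-zero entries are
#'   in-mask) or an integer vector of length 3 giving grid dimensions, in
#'   which case every voxel of the grid is in the mask.
#' @return An object of class `voxel_mask` with fields `shape` (grid
#'   dimensions), `coords` (an `n_voxels` x 3 integer matrix of 1-based
#'   voxel coordinates in linear order), `index_array` (integer array
#'   mapping a coordinate to its column index, 0 outside the mask) and
#'   `n_voxels`.
#' @examples
#' m <- voxel_mask(c(4, 4, 3))
#' m$n_voxels
#' @export
voxel_mask <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    shape <- dim(x)
    inside <- which(x != 0)
  } else if (is.numeric(x) && length(x) == 3L) {
    shape <- as.integer(x)
    if (any(shape < 1L)) stop("mask dimensions must be positive")
    inside <- seq_len(prod(shape))
  } else {
    stop("`x` must be a 3D array or a length-3 dimension vector")
  }
  if (length(inside) == 0L) stop("mask contains no voxels")
  coords <- arrayInd(inside, .dim = shape)
  storage.mode(coords) <- "integer"
  index_array <- array(0L, dim = shape)
  index_array[inside] <- seq_along(inside)
  structure(
    list(shape = as.integer(shape), coords = coords,
         index_array = index_array, n_voxels = length(inside)),
    class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> grid %s, %d in-mask voxels\n",
              paste(x$shape, collapse = " x "), x$n_voxels))
  invisible(x)
}

#' @export
as_tibble.voxel_mask <- function(x, ...) {
  tibble(voxel = seq_len(x$n_voxels),
         x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3])
}

# in-mask column indices of given coordinate rows; 0 when outside mask
mask_lookup <- function(mask, coords) {
  ok <- coords[, 1] >= 1L & coords[, 1] <= mask$shape[1] &
    coords[, 2] >= 1L & coords[, 2] <= mask$shape[2] &
    coords[, 3] >= 1L & coords[, 3] <= mask$shape[3]
  out <- integer(nrow(coords))
  out[ok] <- mask$index_array[coords[ok, , drop = FALSE]]
  out
}
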