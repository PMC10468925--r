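#' @useDynLib wmhpenumbra, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Volumes are plain 3D arrays (numeric or logical) on a common grid; physical
# geometry travels separately as `voxel_mm`, a scalar (isotropic) or length-3
# spacing in millimetres.

as_spacing <- function(voxel_mm) {
  if (!is.numeric(voxel_mm) || !length(voxel_mm) %in% c(1L, 3L) ||
      any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("'voxel_mm' must be 1 or 3 positive finite numbers (mm)")
  if (length(voxel_mm) == 1L) rep(as.numeric(voxel_mm), 3L) else as.numeric(voxel_mm)
}

check_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("'", name, "' must be a 3D array")
  invisible(x)
}

check_same_grid <- function(...) {
  vols <- list(...)
  dims <- lapply(vols, dim)
  ref <- dims[[1L]]
  for (d in dims)
    if (!identical(as.integer(d), as.integer(ref)))
      stop("input volumes are not on a common grid: ",
           paste(vapply(dims, function(x) paste(x, collapse = "x"), ""),
                 collapse = " vs "))
  invisible(ref)
}

as_mask <- function(x, name = deparse(substitute(x))) {
  check_volume(x, name)
  if (is.logical(x)) {
    if (anyNA(x)) stop("'", name, "' contains NA")
    return(x)
  }
  if (anyNA(x) || any(!x %in% c(0, 1)))
    stop("'", name, "' must be binary (0/1 or logical)")
  array(x != 0, dim = dim(x))
}

#' Euclidean distance map to a binary mask
#'
#' Computes, for every voxel, the exact Euclidean distance in millimetres to
#' the nearest voxel of `mask` (0 inside the mask), using the separable
#' squared-distance transform of Felzenszwalb and Huttenlocher. This is the
#' geometric primitive behind concentric NAWM layer construction: binning this
#' map at 1-mm steps yields the successive shells around a lesion mask.
#'
#' @param mask logical or 0/1 3D array; must contain at least one `TRUE` voxel.
#' @param voxel_mm voxel spacing in mm, scalar (isotropic) or length 3.
#' @param squared if `TRUE`, return squared distances (mm^2); exact integers at
#'   1-mm isotropic spacing, which downstream binning exploits.
#' @return numeric 3D array of (squared) distances, same dimensions as `mask`.
#' @examples
#' m <- array(FALSE, c(8, 8, 8)); m[1, 1, 1] <- TRUE
#' d <- euclidean_distance_map(m, 1)
#' d[4, 5, 1]  # == 5 (3-4-5 triangle)
#' @export
euclidean_distance_map <- function(mask, voxel_mm = 1, squared = FALSE) {
  mask <- as_mask(mask)
  sp <- as_spacing(voxel_mm)
  if (!any(mask)) stop("empty mask: distance map is undefined")
  d2 <- .edt_squared(as.logical(mask), as.integer(dim(mask)), sp)
  out <- if (squared) d2 else sqrt(d2)
  array(out, dim = dim(mask))
}

#' Morphological dilation of a mask by a Euclidean ball
#'
#' Dilates with a ball structuring element of the given radius in voxels
#' (isotropic), implemented through the exact distance transform: a voxel is in
#' the dilated mask iff its Euclidean distance to the mask is at most `radius`.
#' Used for the partial-volume exclusion of GM/CSF ("dilated by 2 voxels").
#'
#' @param mask logical or 0/1 3D array.
#' @param radius_voxels non-negative dilation radius in voxel units.
#' @return logical 3D array.
#' @export
dilate_mask <- function(mask, radius_voxels) {
  mask <- as_mask(mask)
  if (!is.numeric(radius_voxels) || length(radius_voxels) != 1L || radius_voxels < 0)
    stop("'radius_voxels' must be a single non-negative number")
  if (radius_voxels == 0 || !any(mask)) return(mask)
  d2 <- .edt_squared(as.logical(mask), as.integer(dim(mask)), c(1, 1, 1))
  array(d2 <= radius_voxels^2 + 1e-9, dim = dim(mask))
}

# 26-connected (or 6-connected) one-step binary dilation by shifting; cheap on
# cropped arrays, used for adjacency queries and component labelling.
shift_dilate <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  out <- mask
  offs <- neighbour_offsets(connectivity)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    src <- list(valid_range(dm[1], -o[1]), valid_range(dm[2], -o[2]),
                valid_range(dm[3], -o[3]))
    dst <- list(valid_range(dm[1], o[1]), valid_range(dm[2], o[2]),
                valid_range(dm[3], o[3]))
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] | mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

valid_range <- function(n, off) {
  if (off >= 0) seq_len(n - off) + off else seq_len(n + off)
}

neighbour_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g[rowSums(abs(g)) == 1L, , drop = FALSE]
  else if (connectivity == 18L) g[rowSums(abs(g)) <= 2L, , drop = FALSE]
  else if (connectivity == 26L) g
  else stop("'connectivity' must be 6, 18 or 26")
}

# Bounding box of TRUE voxels, padded, as index ranges; NULL for empty masks.
mask_bbox <- function(mask, pad = 1L) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  dm <- dim(mask)
  lapply(1:3, function(a)
    seq.int(max(1L, min(w[, a]) - pad), min(dm[a], max(w[, a]) + pad)))
}
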