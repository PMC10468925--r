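#' Layer-mask configuration
#'
#' @param n_layers number of concentric NAWM shells (default 15).
#' @param layer_mm shell thickness in mm (default 1).
#' @param pv_exclusion_voxels radius (voxels) of the ball dilation applied to
#'   the GM and CSF masks before subtracting them from the layers, reducing
#'   partial-volume contamination (default 2).
#' @return object of class `layer_config`.
#' @export
layer_config <- function(n_layers = 15L, layer_mm = 1, pv_exclusion_voxels = 2L) {
  if (n_layers < 1L) stop("'n_layers' must be >= 1")
  if (layer_mm <= 0) stop("'layer_mm' must be > 0")
  if (pv_exclusion_voxels < 0) stop("'pv_exclusion_voxels' must be >= 0")
  structure(list(n_layers = as.integer(n_layers), layer_mm = layer_mm,
                 pv_exclusion_voxels = as.integer(pv_exclusion_voxels)),
            class = "layer_config")
}

#' Concentric NAWM layer masks around a lesion class
#'
#' Layer `k` is the set of voxels whose Euclidean distance `d` to the class
#' mask satisfies `(k-1)*layer_mm < d <= k*layer_mm`, minus every WMH voxel of
#' any class, the ventricles, and the GM and CSF masks dilated by
#' `pv_exclusion_voxels` voxels. Binning a single distance transform realizes
#' the layer-growing procedure in which the lesion and all previous layers are
#' merged before each 1-mm outward step, and guarantees that layers of
#' neighbouring same-class lesions never overlap: each voxel belongs to the
#' bin of its distance to the nearest lesion.
#'
#' Inputs must be on a 1-mm isotropic grid scaled by `layer_mm`; in practice
#' `voxel_mm` must be isotropic, and layers are exact Euclidean shells.
#'
#' @param class_mask binary mask of the lesion class the layers grow from.
#' @param all_wmh_mask binary mask of all WMH voxels (every class, including
#'   excluded clusters); must contain `class_mask`.
#' @param ventricle_mask,gm_mask,csf_mask binary exclusion masks.
#' @param cfg a [layer_config()].
#' @param voxel_mm isotropic voxel spacing in mm.
#' @return object of class `layer_mask_set`: `class_label` (attached by
#'   callers), `layer_index` (integer volume, 0 outside, 1..n_layers in the
#'   shells) and `config`.
#' @export
build_layers <- function(class_mask, all_wmh_mask, ventricle_mask,
                         gm_mask, csf_mask, cfg = layer_config(),
                         voxel_mm = 1) {
  class_mask <- as_mask(class_mask)
  all_wmh_mask <- as_mask(all_wmh_mask)
  ventricle_mask <- as_mask(ventricle_mask)
  gm_mask <- as_mask(gm_mask)
  csf_mask <- as_mask(csf_mask)
  check_same_grid(class_mask, all_wmh_mask, ventricle_mask, gm_mask, csf_mask)
  sp <- as_spacing(voxel_mm)
  if (max(sp) - min(sp) > 1e-9)
    stop("layer construction requires an isotropic grid; got spacing ",
         paste(signif(sp, 6), collapse = " x "))
  if (!any(class_mask)) stop("empty class mask: no layers to build")
  if (any(class_mask & !all_wmh_mask))
    stop("'class_mask' must be a subset of 'all_wmh_mask'")
  if (cfg$n_layers * cfg$layer_mm > min(dim(class_mask) * sp))
    warning("layer extent exceeds the grid; outer layers may be empty")

  d <- euclidean_distance_map(class_mask, sp[1])
  # half-open bins ((k-1)*h, k*h]; ceiling() with a tolerance one part in 1e9
  # of a layer so distances landing exactly on a bin edge stay in the inner bin
  k <- ceiling(d / cfg$layer_mm - 1e-9)
  k[d <= 0] <- 0L
  k[k > cfg$n_layers] <- 0L
  excl <- all_wmh_mask | ventricle_mask |
    dilate_mask(gm_mask, cfg$pv_exclusion_voxels) |
    dilate_mask(csf_mask, cfg$pv_exclusion_voxels)
  k[excl] <- 0L
  structure(list(layer_index = array(as.integer(k), dim = dim(class_mask)),
                 config = cfg, voxel_mm = sp[1]),
            class = "layer_mask_set")
}

#' Whole-brain NAWM mask
#'
#' Normal-appearing white matter: the WM mask minus all WMH voxels and minus
#' the GM/CSF masks dilated by the configured partial-volume exclusion. By
#' default penumbral tissue (the 15 shells) is retained, matching a
#' whole-brain reference; `exclude_within_mm` carves out everything within
#' that distance of any WMH so the reference contains no penumbral signal —
#' on small phantoms, where the shells are a sizeable fraction of WM, this is
#' the appropriate reference (see the methods vignette).
#'
#' @param wm_mask binary white-matter mask.
#' @param all_wmh_mask binary mask of all WMH voxels.
#' @param gm_mask,csf_mask binary masks for partial-volume exclusion.
#' @param cfg a [layer_config()].
#' @param voxel_mm isotropic voxel spacing in mm.
#' @param exclude_within_mm `NULL`, or a distance in mm: voxels closer than
#'   this to any WMH are removed from the reference.
#' @return logical volume.
#' @export
nawm_mask <- function(wm_mask, all_wmh_mask, gm_mask, csf_mask,
                      cfg = layer_config(), voxel_mm = 1,
                      exclude_within_mm = NULL) {
  wm_mask <- as_mask(wm_mask)
  all_wmh_mask <- as_mask(all_wmh_mask)
  gm_mask <- as_mask(gm_mask)
  csf_mask <- as_mask(csf_mask)
  check_same_grid(wm_mask, all_wmh_mask, gm_mask, csf_mask)
  sp <- as_spacing(voxel_mm)
  out <- wm_mask & !all_wmh_mask &
    !dilate_mask(gm_mask, cfg$pv_exclusion_voxels) &
    !dilate_mask(csf_mask, cfg$pv_exclusion_voxels)
  if (!is.null(exclude_within_mm) && any(all_wmh_mask)) {
    d <- euclidean_distance_map(all_wmh_mask, sp[1])
    out <- out & d > exclude_within_mm
  }
  if (!any(out)) stop("NAWM mask is empty")
  out
}

#' @export
print.layer_mask_set <- function(x, ...) {
  counts <- tabulate(x$layer_index[x$layer_index > 0L], nbins = x$config$n_layers)
  cat("NAWM layer masks:", x$config$n_layers, "shells of", x$config$layer_mm,
      "mm\n  voxels per layer:", paste(counts, collapse = " "), "\n")
  invisible(x)
}
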