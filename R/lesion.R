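#' Binarize a probability map
#'
#' @param prob 3D array with values in `[0, 1]`.
#' @param threshold binarization threshold in `(0, 1)`; the rule is inclusive
#'   (`prob >= threshold`).
#' @return logical 3D array.
#' @export
binarize_probability <- function(prob, threshold = 0.5) {
  check_volume(prob, "prob")
  if (anyNA(prob) || any(prob < 0) || any(prob > 1))
    stop("input error: probability values must lie in [0, 1]")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must be a single number in (0, 1)")
  array(prob >= threshold, dim = dim(prob))
}

#' Label connected components of a binary mask
#'
#' Flood-fill labelling at the requested neighbourhood order (6, 18 or 26);
#' operates on the mask's bounding box, so cost scales with lesion size, not
#' grid size. Labels are contiguous from 1 in first-voxel (column-major) order.
#'
#' @param mask logical or 0/1 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer 3D array, 0 outside the mask.
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- as_mask(mask)
  labels <- array(0L, dim = dim(mask))
  bb <- mask_bbox(mask, pad = 0L)
  if (is.null(bb)) return(labels)
  sub <- mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  sublab <- array(0L, dim = dim(sub))
  nxt <- 0L
  repeat {
    seed_idx <- which(sub & sublab == 0L)
    if (!length(seed_idx)) break
    nxt <- nxt + 1L
    comp <- array(FALSE, dim = dim(sub))
    comp[seed_idx[1L]] <- TRUE
    repeat {
      grown <- shift_dilate(comp, connectivity) & sub & sublab == 0L
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    sublab[comp] <- nxt
  }
  labels[bb[[1]], bb[[2]], bb[[3]]] <- sublab
  labels
}

#' Split WMH clusters into periventricular and deep classes
#'
#' Connected WMH clusters that overlap, or are adjacent to (at the same
#' neighbourhood order used for labelling), the lateral-ventricle mask are
#' periventricular; all others are deep — the "continuity to ventricle" rule.
#'
#' @param wmh_mask binary WMH mask.
#' @param ventricle_mask binary lateral-ventricle mask on the same grid.
#' @param connectivity neighbourhood order for both component labelling and
#'   ventricle adjacency (default 26).
#' @return object of class `lesion_set`: `labels` (integer volume, one id per
#'   cluster) and `class_of` (character vector, `"PV"`, `"DEEP"` or
#'   `"EXCLUDED"`, indexed by cluster id).
#' @export
split_pv_deep <- function(wmh_mask, ventricle_mask, connectivity = 26L) {
  wmh_mask <- as_mask(wmh_mask)
  ventricle_mask <- as_mask(ventricle_mask)
  check_same_grid(wmh_mask, ventricle_mask)
  labels <- label_components(wmh_mask, connectivity)
  n <- max(labels)
  if (n == 0L)
    return(structure(list(labels = labels, class_of = character(0),
                          connectivity = as.integer(connectivity)),
                     class = "lesion_set"))
  vent_halo <- shift_dilate(ventricle_mask, connectivity)
  touching <- sort(unique(labels[vent_halo & labels > 0L]))
  class_of <- rep("DEEP", n)
  class_of[touching] <- "PV"
  structure(list(labels = labels, class_of = class_of,
                 connectivity = as.integer(connectivity)),
            class = "lesion_set")
}

#' Reclassify subcortical deep clusters as excluded
#'
#' Deep clusters closer to the grey-matter mask than `margin_mm` (minimum
#' Euclidean voxel-centre distance) are tagged `EXCLUDED`: they take part in no
#' layer or extraction step other than the cross-class voxel-exclusion mask.
#' Periventricular clusters are never touched. Set `margin_mm = 0` to keep
#' only clusters actually overlapping GM excluded — with none overlapping,
#' the lesion set is returned unchanged.
#'
#' @param lesions a `lesion_set`.
#' @param gm_mask binary grey-matter mask.
#' @param margin_mm non-negative distance margin in mm.
#' @param voxel_mm voxel spacing in mm.
#' @return the updated `lesion_set`.
#' @export
exclude_subcortical <- function(lesions, gm_mask, margin_mm = 3, voxel_mm = 1) {
  stopifnot(inherits(lesions, "lesion_set"))
  gm_mask <- as_mask(gm_mask)
  check_same_grid(lesions$labels, gm_mask)
  if (margin_mm < 0) stop("'margin_mm' must be >= 0")
  if (!length(lesions$class_of) || !any(lesions$class_of == "DEEP") ||
      !any(gm_mask))
    return(lesions)
  d <- euclidean_distance_map(gm_mask, voxel_mm)
  for (id in which(lesions$class_of == "DEEP")) {
    if (min(d[lesions$labels == id]) <= margin_mm)
      lesions$class_of[id] <- "EXCLUDED"
  }
  lesions
}

#' Binary mask of one lesion class
#'
#' @param lesions a `lesion_set`.
#' @param class_label `"PV"`, `"DEEP"` or `"EXCLUDED"`.
#' @return logical volume (all-`FALSE` when the class has no clusters).
#' @export
class_mask <- function(lesions, class_label) {
  stopifnot(inherits(lesions, "lesion_set"))
  ids <- which(lesions$class_of == class_label)
  out <- array(FALSE, dim = dim(lesions$labels))
  if (length(ids)) out[lesions$labels %in% ids] <- TRUE
  out
}

#' Cluster summary table of a lesion set
#'
#' @param lesions a `lesion_set`.
#' @param voxel_mm voxel spacing in mm.
#' @return data frame: `cluster_id`, `class`, `voxel_count`, `volume_mm3`.
#' @export
lesion_table <- function(lesions, voxel_mm = 1) {
  stopifnot(inherits(lesions, "lesion_set"))
  sp <- as_spacing(voxel_mm)
  n <- length(lesions$class_of)
  counts <- tabulate(lesions$labels[lesions$labels > 0L], nbins = n)
  data.frame(cluster_id = seq_len(n), class = lesions$class_of,
             voxel_count = counts, volume_mm3 = counts * prod(sp),
             stringsAsFactors = FALSE)
}

#' @export
print.lesion_set <- function(x, ...) {
  cat("WMH lesion set:", length(x$class_of), "cluster(s)\n")
  if (length(x$class_of)) {
    tab <- table(factor(x$class_of, levels = c("PV", "DEEP", "EXCLUDED")))
    cat("  PV:", tab[["PV"]], " DEEP:", tab[["DEEP"]],
        " EXCLUDED:", tab[["EXCLUDED"]], "\n")
  }
  invisible(x)
}

#' Classify a subject's WMH lesions
#'
#' Convenience wrapper: binarize the WMH probability map, label clusters,
#' split periventricular/deep by ventricle continuity, and apply the
#' subcortical-distance exclusion.
#'
#' @param seg a segmentation set (as produced by [generate_phantom_subject()]
#'   or [read_segmentation()]).
#' @param threshold WMH probability binarization threshold.
#' @param connectivity neighbourhood order (6, 18 or 26).
#' @param subcortical_margin_mm margin for [exclude_subcortical()]; `NULL`
#'   disables the step.
#' @return a `lesion_set`.
#' @export
classify_lesions <- function(seg, threshold = 0.5, connectivity = 26L,
                             subcortical_margin_mm = 3) {
  wmh <- binarize_probability(seg$wmh_prob, threshold)
  vent <- as_mask(seg$ventricle_mask)
  lesions <- split_pv_deep(wmh, vent, connectivity)
  if (!is.null(subcortical_margin_mm)) {
    gm <- binarize_probability(seg$gm_prob, threshold)
    lesions <- exclude_subcortical(lesions, gm, subcortical_margin_mm,
                                   seg$voxel_mm)
  }
  lesions
}
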