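# Synthetic brain phantom: spherical-shell brain (WM core, GM shell, outer
# CSF), an ellipsoidal lateral-ventricle CSF cavity, and spherical WMH lesions
# either attached to the ventricle (periventricular) or isolated in deep WM.
# Parametric maps follow a radial linear ramp from a lesion value to the NAWM
# baseline, reaching baseline exactly at the configured transition distance;
# a subject-level additive offset (shared by every voxel of a subject's map)
# induces the within-subject correlation that paired tests exploit, and
# i.i.d. Gaussian voxel noise sits on top.

#' Phantom specification
#'
#' Defines the geometry, parameter calibration, ground-truth transition
#' distances and noise structure of a synthetic cohort. Defaults reproduce the
#' published cohort's conditions: n = 42 subjects, lesion and NAWM means from
#' the reference profiles, and true transition distances equal to the reported
#' penumbra extents.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_mm isotropic voxel spacing (mm).
#' @param brain_radius_mm,wm_radius_mm outer brain (GM shell ends) and WM core
#'   radii (mm); GM occupies the shell between them, CSF everything outside.
#' @param ventricle_radii_mm ellipsoid semi-axes (mm) of the ventricle, centred
#'   at `ventricle_center_mm` (defaults to the grid centre).
#' @param ventricle_center_mm optional centre (mm).
#' @param lesions list of lesions, each `list(class = "PV"|"DEEP",
#'   center_mm = <length-3>, radius_mm = <scalar>)`. `NULL` gives one deep and
#'   one periventricular lesion of radius 5 mm.
#' @param parameters character subset of `c("CBF","AD","AK","FA","MD","MK","RD","RK")`.
#' @param baseline named numeric, NAWM baseline per parameter.
#' @param lesion_mean 2 x p matrix (rows `PV`, `DEEP`) of in-lesion means.
#' @param transition_mm 2 x p matrix (rows `PV`, `DEEP`) of ground-truth
#'   transition distances T (mm); the ramp reaches baseline exactly at T.
#' @param voxel_noise_sd named numeric, per-voxel Gaussian SD per parameter.
#' @param subject_sd named numeric, between-subject SD of the additive offset.
#' @param n_subjects number of subjects (>= 2).
#' @param seed RNG seed; subject `i` is generated from a stream derived from
#'   `(seed, i)` so any subject is reproducible in isolation.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         voxel_mm = 1,
                         brain_radius_mm = 44,
                         wm_radius_mm = 38,
                         ventricle_radii_mm = c(8, 12, 8),
                         ventricle_center_mm = NULL,
                         lesions = NULL,
                         parameters = PARAMETERS,
                         baseline = NULL,
                         lesion_mean = NULL,
                         transition_mm = NULL,
                         voxel_noise_sd = NULL,
                         subject_sd = NULL,
                         n_subjects = 42L,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("'grid_shape' must be 3 positive integers")
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || voxel_mm <= 0)
    stop("'voxel_mm' must be a single positive number")
  if (n_subjects < 2L) stop("'n_subjects' must be >= 2")
  parameters <- match.arg(parameters, PARAMETERS, several.ok = TRUE)

  centre <- grid_shape / 2 * voxel_mm
  if (is.null(ventricle_center_mm)) ventricle_center_mm <- centre
  if (is.null(lesions))
    lesions <- list(
      list(class = "DEEP", center_mm = centre + c(24, 0, 0), radius_mm = 5),
      list(class = "PV",   center_mm = centre + c(0, 16, 0), radius_mm = 5))
  for (les in lesions) {
    if (!is.list(les) || !all(c("class", "center_mm", "radius_mm") %in% names(les)))
      stop("each lesion needs fields class, center_mm, radius_mm")
    if (!les$class %in% c("PV", "DEEP")) stop("lesion class must be 'PV' or 'DEEP'")
    if (les$radius_mm <= 0) stop("lesion radius must be positive")
    if (any(les$center_mm - les$radius_mm < 0) ||
        any(les$center_mm + les$radius_mm > grid_shape * voxel_mm))
      stop("geometry error: lesion extends outside the grid")
  }
  if (any(ventricle_radii_mm <= 0) || brain_radius_mm <= 0 || wm_radius_mm <= 0)
    stop("radii must be positive")
  if (wm_radius_mm >= brain_radius_mm)
    stop("'wm_radius_mm' must be smaller than 'brain_radius_mm'")

  defaults <- .phantom_calibration_defaults(parameters)
  if (is.null(baseline)) baseline <- defaults$baseline
  if (is.null(lesion_mean)) lesion_mean <- defaults$lesion_mean
  if (is.null(transition_mm)) transition_mm <- defaults$transition_mm
  if (is.null(voxel_noise_sd)) voxel_noise_sd <- defaults$voxel_noise_sd
  if (is.null(subject_sd)) subject_sd <- defaults$subject_sd
  baseline <- .named_for(baseline, parameters, "baseline")
  voxel_noise_sd <- .named_for(voxel_noise_sd, parameters, "voxel_noise_sd")
  subject_sd <- .named_for(subject_sd, parameters, "subject_sd")
  lesion_mean <- .classmat_for(lesion_mean, parameters, "lesion_mean")
  transition_mm <- .classmat_for(transition_mm, parameters, "transition_mm")
  if (any(transition_mm < 0)) stop("'transition_mm' must be >= 0")
  if (any(voxel_noise_sd < 0) || any(subject_sd < 0))
    stop("noise SDs must be >= 0")

  spec <- structure(list(
    grid_shape = grid_shape, voxel_mm = voxel_mm,
    brain_radius_mm = brain_radius_mm, wm_radius_mm = wm_radius_mm,
    ventricle_center_mm = ventricle_center_mm,
    ventricle_radii_mm = ventricle_radii_mm,
    lesions = lesions, parameters = parameters,
    baseline = baseline, lesion_mean = lesion_mean,
    transition_mm = transition_mm,
    voxel_noise_sd = voxel_noise_sd, subject_sd = subject_sd,
    n_subjects = as.integer(n_subjects), seed = as.integer(seed)
  ), class = "phantom_spec")
  # rasterized invariants: PV lesions touch the ventricle, deep lesions do not
  geom <- phantom_geometry(spec)
  vent_halo <- shift_dilate(geom$ventricle_mask, 26L)
  for (i in seq_along(geom$lesion_masks)) {
    touches <- any(geom$lesion_masks[[i]] & vent_halo)
    cls <- spec$lesions[[i]]$class
    if (cls == "PV" && !touches)
      stop("spec violation: PV lesion ", i, " neither overlaps nor abuts the ventricle")
    if (cls == "DEEP" && touches)
      stop("spec violation: deep lesion ", i, " touches the ventricle")
    if (!any(geom$lesion_masks[[i]]))
      stop("geometry error: lesion ", i, " rasterizes to an empty mask")
  }
  spec
}

.phantom_calibration_defaults <- function(parameters) {
  ext <- reference_extents()
  tm <- matrix(NA_real_, 2, length(parameters),
               dimnames = list(c("PV", "DEEP"), parameters))
  lm <- tm
  for (cl in c("PV", "DEEP"))
    for (p in parameters) {
      tm[cl, p] <- ext$extent_mm[ext$class == cl & ext$parameter == p]
      lm[cl, p] <- reference_cell(cl, "WMH", p, "mean")
    }
  base <- vapply(parameters, function(p) reference_cell("DEEP", "NAWM", p, "mean"), 0)
  # Per-voxel map noise at levels a reader of clinical ASL/DKI maps would call
  # plausible; the subject offset follows the 10x layer-mean-SD convention with
  # a reference shell of ~2000 voxels (see the methods vignette).
  vox <- c(CBF = 3, AD = 1, AK = 0.12, FA = 0.1, MD = 1, MK = 0.12,
           RD = 1, RK = 0.15)[parameters]
  list(baseline = base, lesion_mean = lm, transition_mm = tm,
       voxel_noise_sd = vox, subject_sd = 10 / sqrt(2000) * vox)
}

.named_for <- function(x, parameters, what) {
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(parameters))
    if (length(x) != length(parameters))
      stop("'", what, "' must be named by parameter or match length")
    names(x) <- parameters
  }
  if (!all(parameters %in% names(x)))
    stop("'", what, "' missing entries for: ",
         paste(setdiff(parameters, names(x)), collapse = ", "))
  x[parameters]
}

.classmat_for <- function(x, parameters, what) {
  if (!is.matrix(x) || !all(c("PV", "DEEP") %in% rownames(x)) ||
      !all(parameters %in% colnames(x)))
    stop("'", what, "' must be a matrix with rows PV, DEEP and parameter columns")
  x[c("PV", "DEEP"), parameters, drop = FALSE]
}

# squared scaled distance field for an ellipsoid, on voxel-centre coordinates
.ellipsoid_field <- function(grid_shape, voxel_mm, centre, radii) {
  ax <- lapply(1:3, function(a)
    (((seq_len(grid_shape[a]) - 0.5) * voxel_mm - centre[a]) / radii[a])^2)
  outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
}

#' Rasterize the phantom geometry
#'
#' @param spec a [phantom_spec()].
#' @return list of logical volumes (`wm_mask`, `gm_mask`, `csf_mask`,
#'   `ventricle_mask`, per-lesion masks, per-class WMH masks) plus per-class
#'   Euclidean distance maps in mm used by the map generator.
#' @export
phantom_geometry <- function(spec) {
  gs <- spec$grid_shape; vm <- spec$voxel_mm
  centre <- gs / 2 * vm
  brain2 <- .ellipsoid_field(gs, vm, centre, rep(spec$brain_radius_mm, 3))
  wm2 <- .ellipsoid_field(gs, vm, centre, rep(spec$wm_radius_mm, 3))
  vent2 <- .ellipsoid_field(gs, vm, spec$ventricle_center_mm, spec$ventricle_radii_mm)
  ventricle <- vent2 <= 1
  wm <- (wm2 <= 1) & !ventricle
  gm <- (brain2 <= 1) & (wm2 > 1)
  csf <- ventricle | (brain2 > 1)
  lesion_masks <- lapply(spec$lesions, function(les) {
    m <- .ellipsoid_field(gs, vm, les$center_mm, rep(les$radius_mm, 3)) <= 1
    m & wm  # lesions live in WM; any ventricle overlap is carved away
  })
  classes <- vapply(spec$lesions, `[[`, "", "class")
  class_masks <- lapply(c(PV = "PV", DEEP = "DEEP"), function(cl) {
    sel <- which(classes == cl)
    if (!length(sel)) return(NULL)
    Reduce(`|`, lesion_masks[sel])
  })
  dist_maps <- lapply(class_masks, function(m) {
    if (is.null(m) || !any(m)) return(NULL)
    euclidean_distance_map(m, vm)
  })
  list(wm_mask = wm, gm_mask = gm, csf_mask = csf, ventricle_mask = ventricle,
       lesion_masks = lesion_masks, lesion_classes = classes,
       class_masks = class_masks, dist_maps = dist_maps)
}

.subject_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) * 1000003 + subject_index) %% 2147483647)
}

#' Generate one synthetic subject
#'
#' Produces the co-registered label volumes (tissue probabilities, ventricle
#' mask, WMH probability map) and parametric maps of one phantom subject. At
#' distance d (mm) from a lesion-class mask, a parameter's noise-free value is
#' `baseline + (lesion_mean - baseline) * max(0, 1 - d/T)` (1 inside the
#' lesion), i.e. a monotone linear ramp reaching baseline exactly at `T`;
#' contributions of the two lesion classes add. Deterministic given
#' `(spec$seed, subject_index)`.
#'
#' @param spec a [phantom_spec()].
#' @param subject_index integer in `1..spec$n_subjects`.
#' @param geometry optional precomputed [phantom_geometry()] (identical across
#'   subjects, so cohort loops compute it once).
#' @return list with `seg` (a segmentation set: `wm_prob`, `gm_prob`,
#'   `csf_prob`, `ventricle_mask`, `wmh_prob`, `voxel_mm`), `maps` (named list
#'   of parametric volumes) and `truth` (transition distances, subject offsets,
#'   lesion classes).
#' @export
generate_phantom_subject <- function(spec, subject_index,
                                     geometry = phantom_geometry(spec)) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  if (subject_index < 1L || subject_index > spec$n_subjects)
    stop("'subject_index' must be in 1..n_subjects")
  set.seed(.subject_seed(spec$seed, subject_index))

  wmh <- Reduce(`|`, geometry$lesion_masks)
  seg <- structure(list(
    wm_prob = array(as.numeric(geometry$wm_mask), dim = spec$grid_shape),
    gm_prob = array(as.numeric(geometry$gm_mask), dim = spec$grid_shape),
    csf_prob = array(as.numeric(geometry$csf_mask), dim = spec$grid_shape),
    ventricle_mask = geometry$ventricle_mask,
    wmh_prob = array(as.numeric(wmh), dim = spec$grid_shape),
    voxel_mm = spec$voxel_mm), class = "segmentation_set")

  params <- spec$parameters
  offsets <- stats::rnorm(length(params), 0, spec$subject_sd[params])
  names(offsets) <- params
  nvox <- prod(spec$grid_shape)
  maps <- vector("list", length(params))
  names(maps) <- params
  for (p in params) {
    val <- rep(spec$baseline[p], nvox)
    for (cl in c("PV", "DEEP")) {
      d <- geometry$dist_maps[[cl]]
      if (is.null(d)) next
      T <- spec$transition_mm[cl, p]
      ramp <- if (T <= 0) as.numeric(d <= 0) else pmax(0, 1 - as.vector(d) / T)
      val <- val + (spec$lesion_mean[cl, p] - spec$baseline[p]) * ramp
    }
    val <- val + offsets[p]
    if (spec$voxel_noise_sd[p] > 0)
      val <- val + stats::rnorm(nvox, 0, spec$voxel_noise_sd[p])
    maps[[p]] <- array(val, dim = spec$grid_shape)
  }

  truth <- list(transition_mm = spec$transition_mm,
                subject_offset = offsets,
                lesion_classes = geometry$lesion_classes)
  list(seg = seg, maps = maps, truth = truth, subject_index = subject_index)
}

#' Write one phantom subject to disk
#'
#' Labels are written as unsigned-integer NIfTI volumes, maps as 32-bit float
#' NIfTI, plus a plain-text `truth.txt` key-value sidecar.
#'
#' @param subject output of [generate_phantom_subject()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_phantom_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vm <- subject$seg$voxel_mm
  files <- character(0)
  wr <- function(vol, name, datatype) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)),
                           pixdim = rep(vm, 3), datatype = datatype)
    RNifti::writeNifti(img, path)
    path
  }
  for (nm in c("wm_prob", "gm_prob", "csf_prob", "wmh_prob"))
    files <- c(files, wr(subject$seg[[nm]], nm, "float"))
  files <- c(files, wr(subject$seg$ventricle_mask, "ventricle_mask", "uint8"))
  for (p in names(subject$maps))
    files <- c(files, wr(subject$maps[[p]], paste0("map_", p), "float"))
  truth <- subject$truth
  lines <- c(
    paste0("subject_index=", subject$subject_index),
    paste0("lesion_classes=", paste(truth$lesion_classes, collapse = ",")),
    vapply(names(truth$subject_offset), function(p)
      paste0("offset_", p, "=", format(truth$subject_offset[p], digits = 17)), ""),
    unlist(lapply(rownames(truth$transition_mm), function(cl)
      vapply(colnames(truth$transition_mm), function(p)
        paste0("transition_", cl, "_", p, "=",
               format(truth$transition_mm[cl, p], digits = 17)), "")))
  )
  tf <- file.path(dir, "truth.txt")
  writeLines(lines, tf)
  invisible(c(files, tf))
}
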