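# Independent brute-force oracles and compact phantom geometries shared by
# the module tests. The oracles deliberately avoid every code path they are
# used to check: distances are minima over all mask voxels, layers are binned
# from those distances, and the iterative layer oracle literally merges and
# dilates one step at a time.

# all-pairs Euclidean distance (mm) to the nearest mask voxel
bf_distance <- function(mask, voxel_mm = 1) {
  sp <- if (length(voxel_mm) == 1L) rep(voxel_mm, 3L) else voxel_mm
  dm <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  pts <- arrayInd(seq_len(prod(dm)), dm)
  d2 <- rep(Inf, prod(dm))
  for (r in seq_len(nrow(w))) {
    dd <- ((pts[, 1] - w[r, 1]) * sp[1])^2 +
          ((pts[, 2] - w[r, 2]) * sp[2])^2 +
          ((pts[, 3] - w[r, 3]) * sp[3])^2
    d2 <- pmin(d2, dd)
  }
  array(sqrt(d2), dm)
}

# layer indices by brute-force distance binning ((k-1), k] in mm
bf_layers <- function(class_mask, n_layers, layer_mm = 1, exclude = NULL) {
  d <- bf_distance(class_mask, 1)
  k <- ceiling(d / layer_mm - 1e-9)
  k[d <= 0] <- 0L
  k[k > n_layers] <- 0L
  if (!is.null(exclude)) k[exclude] <- 0L
  array(as.integer(k), dim = dim(class_mask))
}

# literal iterative merge-then-dilate layering: at each 1-mm step the lesion
# and all previous layers are merged and dilated by a 1-voxel Euclidean ball
# (voxels within Euclidean distance 1 of the merged set)
iterative_layers <- function(class_mask, n_layers, exclude = NULL) {
  merged <- class_mask
  out <- array(0L, dim = dim(class_mask))
  for (k in seq_len(n_layers)) {
    dil <- merged | (bf_distance(merged, 1) <= 1 + 1e-9)
    ring <- dil & !merged
    out[ring] <- k
    merged <- dil
  }
  out[class_mask] <- 0L
  if (!is.null(exclude)) out[exclude] <- 0L
  out
}

empty_mask <- function(dm) array(FALSE, dm)

# sphere mask on voxel-centre coordinates (mm)
sphere_mask <- function(dm, centre, radius, voxel_mm = 1) {
  ax <- lapply(1:3, function(a) ((seq_len(dm[a]) - 0.5) * voxel_mm - centre[a])^2)
  outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+") <= radius^2
}

# compact 64^3 phantom: one deep and one periventricular lesion, room for a
# handful of layers; cheap enough for per-test simulation. The lesions sit
# ~16 mm apart, so transitions are capped at 5 mm to keep each lesion's
# neighbourhood free of the other's ramp.
small_phantom_spec <- function(parameters = "CBF", n_subjects = 3L, seed = 1L,
                               lesions = NULL, transition_mm = NULL, ...) {
  centre <- c(32, 32, 32)
  if (is.null(lesions))
    lesions <- list(
      list(class = "DEEP", center_mm = centre + c(13, 0, 0), radius_mm = 3),
      list(class = "PV", center_mm = centre + c(0, 10, 0), radius_mm = 3))
  if (is.null(transition_mm))
    transition_mm <- matrix(5, 2, length(parameters),
                            dimnames = list(c("PV", "DEEP"), parameters))
  phantom_spec(grid_shape = c(64L, 64L, 64L), voxel_mm = 1,
               brain_radius_mm = 30, wm_radius_mm = 26,
               ventricle_radii_mm = c(5, 8, 5),
               lesions = lesions, transition_mm = transition_mm,
               parameters = parameters, n_subjects = n_subjects, seed = seed,
               ...)
}

# deep-lesion-only full-size spec used by recovery checks
deep_phantom_spec <- function(parameters, n_subjects = 42L, seed = 7L, ...) {
  centre <- c(48, 48, 48)
  phantom_spec(lesions = list(list(class = "DEEP",
                                   center_mm = centre + c(24, 0, 0),
                                   radius_mm = 5)),
               parameters = parameters, n_subjects = n_subjects, seed = seed,
               ...)
}

pv_phantom_spec <- function(parameters, n_subjects = 42L, seed = 11L, ...) {
  centre <- c(48, 48, 48)
  phantom_spec(lesions = list(list(class = "PV",
                                   center_mm = centre + c(0, 16, 0),
                                   radius_mm = 5)),
               parameters = parameters, n_subjects = n_subjects, seed = seed,
               ...)
}

# table drawn region-wise from explicit means/SDs with a shared subject effect
make_table <- function(means, sds, n = 42L, rho = 0.5, seed = 1L,
                       class_label = "DEEP", parameter = "CBF") {
  tsp <- cohort_table_spec(means, sds, rho = rho, n_subjects = n, seed = seed)
  generate_cohort_tables(tsp, class_label, parameter)
}
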