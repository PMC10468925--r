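# End-to-end orchestration: classify -> layers -> extract -> penumbra, for
# phantom cohorts, directories of NIfTI volumes, or precomputed tables.

#' Per-subject layer analysis
#'
#' Runs lesion classification, per-class layer construction, NAWM-mask
#' construction and region-mean extraction for one subject's co-registered
#' volumes.
#'
#' @param seg a segmentation set (`wm_prob`, `gm_prob`, `csf_prob`,
#'   `ventricle_mask`, `wmh_prob`, `voxel_mm`).
#' @param maps named list of parametric volumes.
#' @param subject_id identifier for the output rows.
#' @param layer_cfg a [layer_config()].
#' @param threshold probability binarization threshold.
#' @param connectivity neighbourhood order for lesion labelling/adjacency.
#' @param subcortical_margin_mm deep-cluster exclusion margin; `NULL` disables.
#' @param nawm_exclude_within_mm optional distance: NAWM reference excludes
#'   voxels within this distance of any WMH (see [nawm_mask()]).
#' @return list `rows` (subject-layer table rows), `lesions`, `layers`,
#'   `nawm`.
#' @export
subject_layer_analysis <- function(seg, maps, subject_id,
                                   layer_cfg = layer_config(),
                                   threshold = 0.5, connectivity = 26L,
                                   subcortical_margin_mm = 3,
                                   nawm_exclude_within_mm = NULL) {
  lesions <- classify_lesions(seg, threshold, connectivity,
                              subcortical_margin_mm)
  masks <- subject_masks(seg, lesions, layer_cfg, threshold,
                         nawm_exclude_within_mm)
  rows <- extract_subject(maps, lesions, masks$layers, masks$nawm, subject_id)
  list(rows = rows, lesions = lesions, layers = masks$layers,
       nawm = masks$nawm)
}

# layer masks per class plus the NAWM reference, for an already classified
# subject; shared by the per-subject and cached-cohort paths
subject_masks <- function(seg, lesions, layer_cfg, threshold,
                          nawm_exclude_within_mm) {
  gm <- binarize_probability(seg$gm_prob, threshold)
  csf <- binarize_probability(seg$csf_prob, threshold)
  wm <- binarize_probability(seg$wm_prob, threshold)
  vent <- as_mask(seg$ventricle_mask)
  all_wmh <- lesions$labels > 0L
  layers <- list()
  for (cl in c("PV", "DEEP")) {
    cm <- class_mask(lesions, cl)
    if (any(cm))
      layers[[cl]] <- build_layers(cm, all_wmh, vent, gm, csf, layer_cfg,
                                   seg$voxel_mm)
  }
  nawm <- nawm_mask(wm, all_wmh, gm, csf, layer_cfg, seg$voxel_mm,
                    exclude_within_mm = nawm_exclude_within_mm)
  list(layers = layers, nawm = nawm)
}

#' Simulate and analyse a phantom cohort
#'
#' Generates every subject of a [phantom_spec()], runs the full per-subject
#' analysis (classification, layers, extraction) and returns the pooled
#' subject-layer table together with the fitted penumbra scan. The label
#' geometry is identical across phantom subjects, so classification and layer
#' masks are computed once and reused; parametric maps and extraction remain
#' per subject.
#'
#' @param spec a [phantom_spec()].
#' @param layer_cfg a [layer_config()].
#' @param stats_cfg a [stats_config()].
#' @param threshold,connectivity,subcortical_margin_mm see
#'   [subject_layer_analysis()].
#' @param nawm_exclude_within_mm distance (mm) around WMH excluded from the
#'   NAWM reference; defaults to the full layer extent, the appropriate
#'   whole-brain-NAWM surrogate on a compact phantom (methods vignette).
#' @param fit if `FALSE`, return only the table (no statistics).
#' @return list `table`, `fit` (a `penumbra_scan` or `NULL`), `lesions`,
#'   `layers`, `nawm`, `truth`.
#' @export
phantom_study <- function(spec, layer_cfg = layer_config(),
                          stats_cfg = stats_config(),
                          threshold = 0.5, connectivity = 26L,
                          subcortical_margin_mm = 3,
                          nawm_exclude_within_mm =
                            layer_cfg$n_layers * layer_cfg$layer_mm,
                          fit = TRUE) {
  geometry <- phantom_geometry(spec)
  first <- generate_phantom_subject(spec, 1L, geometry)
  lesions <- classify_lesions(first$seg, threshold, connectivity,
                              subcortical_margin_mm)
  masks <- subject_masks(first$seg, lesions, layer_cfg, threshold,
                         nawm_exclude_within_mm)
  tabs <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    subj <- if (i == 1L) first else generate_phantom_subject(spec, i, geometry)
    tabs[[i]] <- extract_subject(subj$maps, lesions, masks$layers, masks$nawm,
                                 sprintf("S%03d", i))
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  list(table = table,
       fit = if (fit) penumbra(table, stats_cfg, layer_cfg$layer_mm) else NULL,
       lesions = lesions, layers = masks$layers, nawm = masks$nawm,
       truth = first$truth)
}

#' Read a subject's volumes from a directory
#'
#' Expects the layout written by [write_phantom_subject()]: `wm_prob`,
#' `gm_prob`, `csf_prob`, `wmh_prob`, `ventricle_mask` and `map_<PARAM>`
#' NIfTI volumes.
#'
#' @param dir subject directory.
#' @return list `seg` (segmentation set) and `maps`.
#' @export
read_segmentation <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(path)) path <- file.path(dir, paste0(name, ".nii"))
    if (!file.exists(path)) stop("missing volume: ", name, " in ", dir)
    img <- RNifti::readNifti(path)
    structure(array(as.numeric(img), dim = dim(img)),
              pixdim = RNifti::pixdim(img))
  }
  wm <- rd("wm_prob")
  vm <- attr(wm, "pixdim")[1]
  seg <- structure(list(
    wm_prob = strip_attrs(wm), gm_prob = strip_attrs(rd("gm_prob")),
    csf_prob = strip_attrs(rd("csf_prob")),
    ventricle_mask = strip_attrs(rd("ventricle_mask")) != 0,
    wmh_prob = strip_attrs(rd("wmh_prob")), voxel_mm = vm),
    class = "segmentation_set")
  map_files <- list.files(dir, pattern = "^map_.*\\.nii(\\.gz)?$")
  params <- unique(sub("^map_", "", sub("\\.nii(\\.gz)?$", "", map_files)))
  maps <- lapply(params, function(p) strip_attrs(rd(paste0("map_", p))))
  names(maps) <- params
  list(seg = seg, maps = maps)
}

strip_attrs <- function(x) array(as.numeric(x), dim = dim(x))

#' Run the configured pipeline
#'
#' Modes: `"phantom"` (simulate a cohort, then analyse), `"image"` (analyse
#' per-subject NIfTI directories) and `"table"` (statistics only, from a
#' subject-layer TSV). Writes the pooled table, per-comparison statistics,
#' boundary results, cohort profile, profile figures and a deterministic run
#' manifest into `out_dir`; any stage error leaves a `FAILED` marker naming
#' the stage.
#'
#' @param config a list or path to a YAML file. Top-level fields: `mode`,
#'   `out_dir`, `seed`, plus optional sections `phantom` (arguments of
#'   [phantom_spec()]), `table` (`path`), `image` (`subject_dirs`), `layers`
#'   ([layer_config()] fields), `classify` (`threshold`, `connectivity`,
#'   `subcortical_margin_mm`), `stats` ([stats_config()] fields) and
#'   `nawm_exclude_within_mm`.
#' @param write_volumes in phantom mode, also write each simulated subject's
#'   NIfTI volumes under `out_dir/subjects/`.
#' @return invisibly, a list with the pooled `table`, the `fit` and the
#'   output paths.
#' @export
run_pipeline <- function(config, write_volumes = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- match.arg(config$mode, c("phantom", "image", "table"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config needs 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(out_dir, "FAILED")
  if (file.exists(failed)) unlink(failed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)), failed)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  layer_cfg <- do.call(layer_config, config$layers %||% list())
  stats_cfg <- do.call(stats_config, config$stats %||% list())
  classify_cfg <- config$classify %||% list()
  threshold <- classify_cfg$threshold %||% 0.5
  connectivity <- classify_cfg$connectivity %||% 26L
  margin <- if ("subcortical_margin_mm" %in% names(classify_cfg))
    classify_cfg$subcortical_margin_mm else 3
  nawm_excl <- config$nawm_exclude_within_mm

  if (mode == "table") {
    table <- stage("read_table", read_layer_table(config$table$path))
  } else if (mode == "phantom") {
    spec_args <- config$phantom %||% list()
    if (!is.null(config$seed)) spec_args$seed <- config$seed
    spec <- stage("phantom_spec", do.call(phantom_spec, spec_args))
    study <- stage("phantom_study",
                   phantom_study(spec, layer_cfg, stats_cfg, threshold,
                                 connectivity, margin,
                                 nawm_exclude_within_mm =
                                   nawm_excl %||%
                                   (layer_cfg$n_layers * layer_cfg$layer_mm),
                                 fit = FALSE))
    table <- study$table
    if (isTRUE(write_volumes)) {
      geometry <- phantom_geometry(spec)
      for (i in seq_len(spec$n_subjects))
        write_phantom_subject(
          generate_phantom_subject(spec, i, geometry),
          file.path(out_dir, "subjects", sprintf("S%03d", i)))
    }
  } else {
    dirs <- config$image$subject_dirs
    if (!length(dirs)) stop("image mode needs config$image$subject_dirs")
    tabs <- vector("list", length(dirs))
    for (i in seq_along(dirs)) {
      sd <- dirs[[i]]
      subj <- stage(paste0("read:", sd), read_segmentation(sd))
      res <- stage(paste0("analyse:", sd),
                   subject_layer_analysis(subj$seg, subj$maps, basename(sd),
                                          layer_cfg, threshold, connectivity,
                                          margin, nawm_excl))
      tabs[[i]] <- res$rows
    }
    table <- do.call(rbind, tabs)
  }

  fit <- stage("penumbra", penumbra(table, stats_cfg, layer_cfg$layer_mm))
  paths <- list(table = file.path(out_dir, "layer_table.tsv"),
                results = file.path(out_dir, "penumbra_results.tsv"),
                comparisons = file.path(out_dir, "comparisons.tsv"),
                profile = file.path(out_dir, "profile.tsv"),
                figures = file.path(out_dir, "profiles.pdf"),
                manifest = file.path(out_dir, "manifest.yaml"))
  stage("write_outputs", {
    write_layer_table(table, paths$table)
    write_results_tables(fit, paths$results, paths$comparisons)
    write_tsv_full(fit$profile, paths$profile)
    plot_profiles(fit, paths$figures)
    write_manifest(config, paths$manifest)
  })
  invisible(list(table = table, fit = fit, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_full <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

write_results_tables <- function(fit, results_path, comparisons_path) {
  s <- summary(fit)$table
  write_tsv_full(s, results_path)
  comp <- do.call(rbind, lapply(fit$results, function(r) {
    cbind(data.frame(class = r$class_label, parameter = r$parameter,
                     rule = r$rule, stringsAsFactors = FALSE),
          r$comparisons[, c("comparison", "t", "df", "p", "significant")])
  }))
  rownames(comp) <- NULL
  write_tsv_full(comp, comparisons_path)
  invisible(NULL)
}

write_manifest <- function(config, path) {
  # out_dir is where the run landed, not part of what it computed; dropping it
  # keeps manifests of identical runs byte-identical
  config$out_dir <- NULL
  info <- list(
    package = "wmhpenumbra",
    version = as.character(utils::packageVersion("wmhpenumbra")),
    config = config)
  yaml::write_yaml(info, path)
  invisible(path)
}

#' Write profile figures for a fitted scan
#'
#' @param fit a `penumbra_scan`.
#' @param file output file; `.pdf` uses the PDF device, anything else the
#'   PNG device.
#' @return the file path, invisibly.
#' @export
plot_profiles <- function(fit, file) {
  if (grepl("\\.pdf$", file)) grDevices::pdf(file, width = 10, height = 8,
                                             onefile = TRUE)
  else grDevices::png(file, width = 1400, height = 1000)
  on.exit(grDevices::dev.off())
  plot(fit)
  invisible(file)
}
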