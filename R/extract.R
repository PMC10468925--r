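#' Mean of a parametric map over a mask
#'
#' @param map numeric volume.
#' @param mask logical or 0/1 volume on the same grid.
#' @return list `value` (arithmetic mean; `NA` when the mask is empty, never a
#'   silent 0) and `n_voxels`.
#' @export
region_mean <- function(map, mask) {
  check_volume(map, "map")
  mask <- as_mask(mask)
  check_same_grid(map, mask)
  n <- sum(mask)
  list(value = if (n > 0L) mean(map[mask]) else NA_real_, n_voxels = n)
}

#' Extract a subject's region means
#'
#' Computes, per lesion class with at least one cluster, the mean of every
#' parametric map over the class's WMH voxels, each NAWM layer, and whole-brain
#' NAWM, in long form. The NAWM rows are repeated per class (identical values)
#' so each class block is self-contained.
#'
#' @param maps named list of parametric volumes.
#' @param lesions a `lesion_set`.
#' @param layers named list (by class, `"PV"`/`"DEEP"`) of `layer_mask_set`s;
#'   classes without lesions may be absent.
#' @param nawm logical whole-brain NAWM mask.
#' @param subject_id identifier written into the rows.
#' @return subject-layer table rows: `subject_id`, `class`, `region`,
#'   `parameter`, `value`, `n_voxels`.
#' @export
extract_subject <- function(maps, lesions, layers, nawm, subject_id) {
  stopifnot(inherits(lesions, "lesion_set"))
  if (!length(maps)) stop("no parametric maps supplied")
  nawm <- as_mask(nawm)
  rows <- list()
  for (cl in c("PV", "DEEP")) {
    cmask <- class_mask(lesions, cl)
    if (!any(cmask)) next
    lset <- layers[[cl]]
    if (is.null(lset))
      stop("class ", cl, " has lesions but no layer masks were supplied")
    region_masks <- c(
      list(WMH = cmask),
      stats::setNames(
        lapply(seq_len(lset$config$n_layers),
               function(k) lset$layer_index == k),
        paste0("L", seq_len(lset$config$n_layers))),
      list(NAWM = nawm))
    for (p in names(maps)) {
      for (rg in names(region_masks)) {
        rm <- region_mean(maps[[p]], region_masks[[rg]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subject_id, class = cl, region = rg, parameter = p,
          value = rm$value, n_voxels = rm$n_voxels, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(subject_id = character(0), class = character(0),
                      region = character(0), parameter = character(0),
                      value = numeric(0), n_voxels = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write / read a subject-layer table
#'
#' Tab-delimited, header row, UTF-8, '.' decimal; values at full precision so
#' written tables round-trip identically.
#'
#' @param table a subject-layer table.
#' @param path file path.
#' @return `write_layer_table` returns `path` invisibly; `read_layer_table`
#'   the table.
#' @export
write_layer_table <- function(table, path) {
  needed <- c("subject_id", "class", "region", "parameter", "value")
  if (!all(needed %in% names(table)))
    stop("table lacks required columns: ",
         paste(setdiff(needed, names(table)), collapse = ", "))
  tbl <- table
  tbl$value <- formatC(tbl$value, digits = 17, format = "g")
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_layer_table
#' @export
read_layer_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  tbl$value <- as.numeric(tbl$value)
  if ("n_voxels" %in% names(tbl)) tbl$n_voxels <- as.integer(tbl$n_voxels)
  tbl
}
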