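#' Statistics configuration for boundary detection
#'
#' @param alpha significance level; the rule is inclusive (`p <= alpha` is
#'   significant), default 0.05.
#' @param sided `"two.sided"` (default), `"greater"` or `"less"`.
#' @param structural_parameters parameters analysed with the adjacent-layer
#'   rule.
#' @param perfusion_parameters parameters analysed with the
#'   layer-versus-whole-brain-NAWM rule.
#' @param correction multiplicity correction over a rule's comparison list:
#'   `"none"` (default, matching the original analysis) or `"holm"`.
#' @return object of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, sided = c("two.sided", "greater", "less"),
                         structural_parameters = c("AD", "AK", "FA", "MD",
                                                   "MK", "RD", "RK"),
                         perfusion_parameters = "CBF",
                         correction = c("none", "holm")) {
  sided <- match.arg(sided)
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)")
  if (length(intersect(structural_parameters, perfusion_parameters)))
    stop("structural and perfusion parameter sets must be disjoint")
  structure(list(alpha = alpha, sided = sided,
                 structural_parameters = structural_parameters,
                 perfusion_parameters = perfusion_parameters,
                 correction = correction),
            class = "stats_config")
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y` and `df = n - 1`.
#' Degenerate differences follow explicit conventions: all differences zero
#' gives `p = 1` (no evidence of any difference); zero variance around a
#' non-zero mean is an error for the caller to handle.
#'
#' @param x,y paired per-subject values, equal length `n >= 2`.
#' @param sided `"two.sided"`, `"greater"` or `"less"`.
#' @return list `t`, `df`, `p`.
#' @export
paired_t <- function(x, y, sided = "two.sided") {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 2L) stop("paired t-test needs at least 2 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values in paired data")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  if (s == 0) {
    if (m == 0) return(list(t = NA_real_, df = df, p = 1))
    stop("degenerate paired t-test: zero variance around a non-zero mean")
  }
  t <- m / (s / sqrt(n))
  p <- switch(sided,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  list(t = t, df = df, p = p)
}

# subjects-by-regions value matrix for one (class, parameter); regions absent
# from the table are absent columns
.region_matrix <- function(table, class_label, parameter) {
  sub <- table[table$class == class_label & table$parameter == parameter, ,
               drop = FALSE]
  if (!nrow(sub)) stop("table has no rows for class ", class_label,
                       ", parameter ", parameter)
  if (anyDuplicated(sub[, c("subject_id", "region")]))
    stop("duplicate (subject, region) rows for class ", class_label,
         ", parameter ", parameter)
  subjects <- unique(sub$subject_id)
  regions <- unique(sub$region)
  m <- matrix(NA_real_, length(subjects), length(regions),
              dimnames = list(subjects, regions))
  m[cbind(match(sub$subject_id, subjects), match(sub$region, regions))] <- sub$value
  m
}

.table_n_layers <- function(region_names) {
  idx <- suppressWarnings(as.integer(sub("^L", "", grep("^L[0-9]+$",
                                                        region_names,
                                                        value = TRUE))))
  if (!length(idx)) stop("table contains no layer regions (L1, L2, ...)")
  max(idx)
}

.scan_comparisons <- function(m, pairs, labels, cfg) {
  res <- data.frame(comparison = labels, t = NA_real_, df = NA_integer_,
                    p = NA_real_, n = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    if (!a %in% colnames(m) || !b %in% colnames(m))
      stop("missing rows for comparison ", labels[i])
    ok <- stats::complete.cases(m[, c(a, b), drop = FALSE])
    if (sum(ok) < 2L)
      stop("fewer than 2 complete subjects for comparison ", labels[i])
    tt <- paired_t(m[ok, a], m[ok, b], cfg$sided)
    res$t[i] <- tt$t; res$df[i] <- tt$df; res$p[i] <- tt$p
    res$n[i] <- sum(ok)
  }
  res$p_used <- if (cfg$correction == "holm")
    stats::p.adjust(res$p, "holm") else res$p
  res$significant <- res$p_used <= cfg$alpha
  res
}

.penumbra_result <- function(class_label, parameter, rule, comparisons,
                             boundary_layer, extent_mm, censored, cfg,
                             layer_mm, n_layers) {
  structure(list(class_label = class_label, parameter = parameter, rule = rule,
                 comparisons = comparisons, boundary_layer = boundary_layer,
                 extent_mm = extent_mm, censored = censored,
                 n_subjects_used = min(comparisons$n),
                 alpha = cfg$alpha, layer_mm = layer_mm, n_layers = n_layers),
            class = "penumbra_result")
}

#' Perfusion boundary rule: each layer versus whole-brain NAWM
#'
#' Scans layers inward-out, testing layer k against whole-brain NAWM with a
#' paired t-test. The first non-significant layer is the outer boundary; the
#' penumbra is the run of consecutive significant layers before it, so
#' `extent_mm = (boundary_layer - 1) * layer_mm`. If every layer differs
#' significantly the extent is censored at `n_layers * layer_mm`. All
#' comparisons are computed and reported, including those beyond the boundary;
#' later re-gains of significance never move the boundary.
#'
#' @param table a subject-layer table.
#' @param class_label `"PV"` or `"DEEP"`.
#' @param parameter parameter to analyse.
#' @param cfg a [stats_config()].
#' @param layer_mm physical layer thickness (mm per layer index).
#' @param extent_convention `"significant_run"` (default): the extent counts
#'   the significant layers before the boundary; `"boundary_layer"`: the
#'   printed extent equals the boundary layer index itself.
#' @return a `penumbra_result`.
#' @export
boundary_vs_nawm <- function(table, class_label, parameter,
                             cfg = stats_config(), layer_mm = 1,
                             extent_convention = c("significant_run",
                                                   "boundary_layer")) {
  extent_convention <- match.arg(extent_convention)
  m <- .region_matrix(table, class_label, parameter)
  if (!"NAWM" %in% colnames(m)) stop("table has no NAWM rows")
  n_layers <- .table_n_layers(colnames(m))
  layers <- paste0("L", seq_len(n_layers))
  res <- .scan_comparisons(m, lapply(layers, function(l) c(l, "NAWM")),
                           paste0(layers, " vs NAWM"), cfg)
  first_ns <- which(!res$significant)[1]
  censored <- is.na(first_ns)
  boundary <- if (censored) NA_integer_ else as.integer(first_ns)
  extent <- if (censored) n_layers * layer_mm
    else if (extent_convention == "significant_run") (boundary - 1) * layer_mm
    else boundary * layer_mm
  .penumbra_result(class_label, parameter, "VS_NAWM", res, boundary, extent,
                   censored, cfg, layer_mm, n_layers)
}

#' Structural boundary rule: adjacent layers
#'
#' Tests every pair of neighbouring layers (L1 vs L2, ..., L14 vs L15) with
#' paired t-tests, inward-out. The first of the two neighbouring layers whose
#' values no longer differ is the outer boundary, so
#' `extent_mm = boundary_layer * layer_mm` (the penumbra spans layers
#' 1..boundary). Used for diffusion metrics, for which comparison against
#' whole-brain NAWM is confounded by the periventricular fibre "location
#' effect". Censored at `n_layers * layer_mm` when every pair differs.
#'
#' @inheritParams boundary_vs_nawm
#' @param extent_convention `"first_of_pair"` (default): extent equals the
#'   boundary layer index; `"preceding"`: extent stops one layer short
#'   (`(boundary_layer - 1) * layer_mm`).
#' @return a `penumbra_result`.
#' @export
boundary_adjacent <- function(table, class_label, parameter,
                              cfg = stats_config(), layer_mm = 1,
                              extent_convention = c("first_of_pair",
                                                    "preceding")) {
  extent_convention <- match.arg(extent_convention)
  m <- .region_matrix(table, class_label, parameter)
  n_layers <- .table_n_layers(colnames(m))
  ks <- seq_len(n_layers - 1L)
  res <- .scan_comparisons(
    m, lapply(ks, function(k) paste0("L", c(k, k + 1L))),
    sprintf("L%d vs L%d", ks, ks + 1L), cfg)
  first_ns <- which(!res$significant)[1]
  censored <- is.na(first_ns)
  boundary <- if (censored) NA_integer_ else as.integer(first_ns)
  extent <- if (censored) n_layers * layer_mm
    else if (extent_convention == "first_of_pair") boundary * layer_mm
    else (boundary - 1) * layer_mm
  .penumbra_result(class_label, parameter, "ADJACENT", res, boundary, extent,
                   censored, cfg, layer_mm, n_layers)
}

#' Maximum structural penumbra extent
#'
#' @param results list of `penumbra_result`s, all from the adjacent-layer rule
#'   and the same lesion class.
#' @return the maximum `extent_mm`.
#' @export
max_structural_extent <- function(results) {
  if (!length(results)) stop("'results' is empty")
  if (inherits(results, "penumbra_result")) results <- list(results)
  rules <- vapply(results, `[[`, "", "rule")
  classes <- vapply(results, `[[`, "", "class_label")
  if (any(rules != "ADJACENT"))
    stop("all results must come from the adjacent-layer rule")
  if (length(unique(classes)) != 1L)
    stop("results mix lesion classes")
  max(vapply(results, `[[`, 0, "extent_mm"))
}

#' Across-subject layer profile
#'
#' @param table a subject-layer table with at least 2 subjects.
#' @return data frame per (class, region, parameter): across-subject `mean`,
#'   `sd` (n-1 denominator), `se = sd/sqrt(n)` and `n`.
#' @export
cohort_profile <- function(table) {
  if (length(unique(table$subject_id)) < 2L)
    stop("cohort profile needs at least 2 subjects")
  agg <- stats::aggregate(value ~ class + region + parameter, data = table,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(class = agg$class, region = agg$region,
                    parameter = agg$parameter,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]),
                    stringsAsFactors = FALSE)
  out$se <- out$sd / sqrt(out$n)
  lev <- c("WMH", paste0("L", 1:15), "NAWM")
  out <- out[order(out$class, out$parameter,
                   match(out$region, lev)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit penumbra extents to a subject-layer table
#'
#' The main estimator: for every (lesion class, parameter) present in the
#' table, applies the perfusion rule (layer vs whole-brain NAWM) to perfusion
#' parameters and the structural rule (adjacent layers) to structural
#' parameters, and assembles the per-comparison statistics, boundary layers,
#' extents and the cohort layer profile into one object.
#'
#' @param table a subject-layer table (from [extract_subject()] rows,
#'   [generate_cohort_tables()], or [read_layer_table()]).
#' @param cfg a [stats_config()].
#' @param layer_mm physical layer thickness in mm.
#' @return object of class `penumbra_scan` with `print`, `summary`, `coef`
#'   and `plot` methods. `coef` returns the extent (mm) per class and
#'   parameter.
#' @examples
#' tsp <- cohort_table_spec(reference_profile("DEEP")$mean[
#'          reference_profile("DEEP")$parameter == "CBF"],
#'        reference_profile("DEEP")$sd[
#'          reference_profile("DEEP")$parameter == "CBF"],
#'        rho = 0.5, n_subjects = 42, seed = 1)
#' fit <- penumbra(generate_cohort_tables(tsp, "DEEP", "CBF"))
#' coef(fit)
#' @export
penumbra <- function(table, cfg = stats_config(), layer_mm = 1) {
  combos <- unique(table[, c("class", "parameter")])
  results <- list()
  for (i in seq_len(nrow(combos))) {
    cl <- combos$class[i]; p <- combos$parameter[i]
    fit <- if (p %in% cfg$perfusion_parameters)
      boundary_vs_nawm(table, cl, p, cfg, layer_mm)
    else if (p %in% cfg$structural_parameters)
      boundary_adjacent(table, cl, p, cfg, layer_mm)
    else next
    results[[paste(cl, p, sep = ".")]] <- fit
  }
  if (!length(results))
    stop("no (class, parameter) combination matched the configured rules")
  structure(list(results = results, profile = cohort_profile(table),
                 config = cfg, layer_mm = layer_mm),
            class = "penumbra_scan")
}

#' @export
print.penumbra_result <- function(x, ...) {
  cat(sprintf("%s %s penumbra (%s rule): extent %g mm%s\n",
              x$class_label, x$parameter,
              if (x$rule == "VS_NAWM") "layer-vs-NAWM" else "adjacent-layer",
              x$extent_mm,
              if (x$censored) " [censored at the layer range]" else
                sprintf(" (boundary layer %d)", x$boundary_layer)))
  invisible(x)
}

#' @export
print.penumbra_scan <- function(x, ...) {
  cat("Penumbra extents (alpha =", x$config$alpha, ", inclusive):\n")
  for (r in x$results) print(r)
  invisible(x)
}

#' @export
coef.penumbra_scan <- function(object, ...) {
  classes <- sort(unique(vapply(object$results, `[[`, "", "class_label")))
  params <- unique(vapply(object$results, `[[`, "", "parameter"))
  m <- matrix(NA_real_, length(classes), length(params),
              dimnames = list(classes, params))
  for (r in object$results) m[r$class_label, r$parameter] <- r$extent_mm
  m
}

#' @export
summary.penumbra_scan <- function(object, ...) {
  rows <- lapply(object$results, function(r)
    data.frame(class = r$class_label, parameter = r$parameter, rule = r$rule,
               boundary_layer = if (is.na(r$boundary_layer)) NA_integer_
                                else r$boundary_layer,
               extent_mm = r$extent_mm, censored = r$censored,
               n_subjects = r$n_subjects_used, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(table = out, alpha = object$config$alpha),
            class = "summary.penumbra_scan")
}

#' @export
print.summary.penumbra_scan <- function(x, ...) {
  cat("Penumbra boundary summary (alpha =", x$alpha, "):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot layer profiles with boundary markers
#'
#' One panel per (class, parameter): layer means with standard-error bars,
#' horizontal solid/dotted reference lines at the whole-brain NAWM mean and
#' mean +/- SE, and an arrow at the boundary layer (absent, with a note, for
#' censored fits).
#'
#' @param x a `penumbra_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.penumbra_scan <- function(x, ...) {
  keys <- names(x$results)
  nk <- length(keys)
  if (nk > 1L) {
    nc <- ceiling(sqrt(nk))
    op <- graphics::par(mfrow = c(ceiling(nk / nc), nc),
                        mar = c(4, 4, 2.5, 0.5))
    on.exit(graphics::par(op))
  }
  for (key in keys) plot_profile_panel(x$profile, x$results[[key]], ...)
  invisible(x)
}

plot_profile_panel <- function(profile, result, ...) {
  cl <- result$class_label; p <- result$parameter
  sel <- profile$class == cl & profile$parameter == p
  prof <- profile[sel, , drop = FALSE]
  layers <- seq_len(result$n_layers)
  lab <- paste0("L", layers)
  mu <- prof$mean[match(lab, prof$region)]
  se <- prof$se[match(lab, prof$region)]
  nawm <- prof[prof$region == "NAWM", , drop = FALSE]
  ylim <- range(c(mu - se, mu + se, nawm$mean + c(-1, 1) * nawm$se),
                na.rm = TRUE)
  graphics::plot(layers, mu, type = "b", pch = 16, ylim = ylim,
                 xlab = "NAWM layer (mm from lesion)", ylab = p,
                 main = sprintf("%s %s (%s)", cl, p, tolower(result$rule)),
                 ...)
  has_bar <- is.finite(se) & se > 0
  if (any(has_bar))
    graphics::arrows(layers[has_bar], (mu - se)[has_bar],
                     layers[has_bar], (mu + se)[has_bar],
                     angle = 90, code = 3, length = 0.03)
  if (nrow(nawm)) {
    graphics::abline(h = nawm$mean, lty = 1)
    graphics::abline(h = nawm$mean + c(-1, 1) * nawm$se, lty = 3)
  }
  if (!result$censored && !is.na(result$boundary_layer)) {
    bx <- result$boundary_layer
    tip <- mu[bx] + se[bx]
    if (is.finite(tip) && abs(ylim[2] - tip) > 0)
      graphics::arrows(bx, ylim[2], bx, tip, col = "red", length = 0.08)
    else graphics::points(bx, mu[bx], col = "red", pch = 17)
  } else {
    graphics::mtext("censored: no boundary within the layer range",
                    side = 3, line = 0, cex = 0.7, col = "red")
  }
  invisible(NULL)
}
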