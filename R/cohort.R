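#' Cohort table specification
#'
#' Sampling model for table-mode simulation: per-subject region means are
#' drawn from a multivariate normal whose marginal means and SDs are given per
#' region (WMH, L1..L15, NAWM) and whose cross-region correlation is an
#' equicorrelation `rho` — the minimal covariance structure producing the
#' within-subject correlation paired tests rely on.
#'
#' @param region_means named numeric over regions `WMH, L1..L15, NAWM` (order
#'   enforced); defaults to a reference profile column.
#' @param region_sds named numeric, same regions, all positive.
#' @param rho equicorrelation, in `(-1/(R-1), 1)` for `R` regions.
#' @param n_subjects number of subjects (>= 2).
#' @param seed RNG seed.
#' @return object of class `cohort_table_spec`.
#' @export
cohort_table_spec <- function(region_means, region_sds, rho = 0.5,
                              n_subjects = 42L, seed = 1L) {
  regions <- REGIONS
  region_means <- .named_for(region_means, regions, "region_means")
  region_sds <- .named_for(region_sds, regions, "region_sds")
  if (any(region_sds <= 0)) stop("parameter error: region SDs must be > 0")
  R <- length(regions)
  if (rho <= -1 / (R - 1) || rho >= 1)
    stop("parameter error: rho must lie in (-1/(R-1), 1)")
  if (n_subjects < 2L) stop("'n_subjects' must be >= 2")
  structure(list(region_means = region_means, region_sds = region_sds,
                 rho = rho, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "cohort_table_spec")
}

#' Simulate a subject-layer table from region-level moments
#'
#' Draws `n_subjects` multivariate-normal vectors over the 17 regions with the
#' specified means, SDs and equicorrelation, and returns them as a long-form
#' subject-layer table for a single lesion class and parameter. Reproducible
#' under the spec's seed.
#'
#' @param tspec a [cohort_table_spec()].
#' @param class_label `"PV"` or `"DEEP"`.
#' @param parameter parameter code the values represent.
#' @return data frame with columns `subject_id`, `class`, `region`,
#'   `parameter`, `value`, `n_voxels` (NA in table mode); regions ordered
#'   WMH, L1..L15, NAWM within subject.
#' @export
generate_cohort_tables <- function(tspec, class_label = c("DEEP", "PV"),
                                   parameter = "CBF") {
  if (!inherits(tspec, "cohort_table_spec"))
    stop("'tspec' must be a cohort_table_spec")
  class_label <- match.arg(class_label)
  regions <- names(tspec$region_means)
  R <- length(regions)
  corr <- matrix(tspec$rho, R, R); diag(corr) <- 1
  L <- chol(corr)
  set.seed(tspec$seed)
  z <- matrix(stats::rnorm(tspec$n_subjects * R), tspec$n_subjects, R) %*% L
  values <- sweep(sweep(z, 2L, tspec$region_sds, "*"), 2L,
                  tspec$region_means, "+")
  data.frame(
    subject_id = rep(sprintf("S%03d", seq_len(tspec$n_subjects)), each = R),
    class = class_label,
    region = rep(regions, times = tspec$n_subjects),
    parameter = parameter,
    value = as.vector(t(values)),
    n_voxels = NA_integer_,
    stringsAsFactors = FALSE
  )
}
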