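test_that("degenerate ramp (T = 0, no noise) leaves everything at baseline", {
  spec <- small_phantom_spec("CBF",
    transition_mm = matrix(0, 2, 1, dimnames = list(c("PV", "DEEP"), "CBF")),
    voxel_noise_sd = c(CBF = 0), subject_sd = c(CBF = 0))
  s <- generate_phantom_subject(spec, 1L)
  geom <- phantom_geometry(spec)
  lesion <- Reduce(`|`, geom$lesion_masks)
  expect_true(all(s$maps$CBF[!lesion] == spec$baseline["CBF"]))
  expect_true(all(s$maps$CBF[lesion] != spec$baseline["CBF"]))
})

test_that("noise-free maps hit the configured lesion and NAWM calibration", {
  # periventricular MD calibration: lesion 15.900, baseline 9.737
  spec <- small_phantom_spec("MD",
    voxel_noise_sd = c(MD = 0), subject_sd = c(MD = 0))
  expect_equal(unname(spec$lesion_mean["PV", "MD"]), 15.900)
  expect_equal(unname(spec$baseline["MD"]), 9.737)
  s <- generate_phantom_subject(spec, 1L)
  geom <- phantom_geometry(spec)
  pv <- geom$class_masks$PV
  expect_equal(mean(s$maps$MD[pv]), 15.900)
  # beyond both transitions nothing but the baseline remains
  beyond <- geom$dist_maps$PV >= spec$transition_mm["PV", "MD"] &
    geom$dist_maps$DEEP >= spec$transition_mm["DEEP", "MD"]
  expect_true(all(abs(s$maps$MD[beyond] - 9.737) < 1e-12))
})

test_that("linear ramp passes through the midpoint at d = T/2", {
  # 0.5-mm grid so voxels exist at exactly half the transition distance
  dm <- c(40L, 40L, 40L)
  centre <- c(10, 10, 10)
  spec <- phantom_spec(grid_shape = dm, voxel_mm = 0.5,
                       brain_radius_mm = 9.5, wm_radius_mm = 8.5,
                       ventricle_radii_mm = c(1.2, 2, 1.2),
                       lesions = list(list(class = "DEEP",
                                           center_mm = centre + c(4.5, 0, 0),
                                           radius_mm = 1.4)),
                       parameters = "CBF",
                       transition_mm = matrix(5, 2, 1,
                         dimnames = list(c("PV", "DEEP"), "CBF")),
                       voxel_noise_sd = c(CBF = 0), subject_sd = c(CBF = 0),
                       n_subjects = 2L, seed = 3L)
  geom <- phantom_geometry(spec)
  s <- generate_phantom_subject(spec, 1L, geom)
  d_bf <- bf_distance(geom$class_masks$DEEP, 0.5)
  expect_equal(max(abs(d_bf - geom$dist_maps$DEEP)), 0)
  at_half <- which(abs(d_bf - 2.5) < 1e-12)
  expect_gt(length(at_half), 0L)
  midpoint <- (spec$lesion_mean["DEEP", "CBF"] + spec$baseline["CBF"]) / 2
  expect_equal(unname(s$maps$CBF[at_half]),
               rep(unname(midpoint), length(at_half)))
})

test_that("subject generation is deterministic and monotone along distance", {
  spec <- small_phantom_spec("FA", n_subjects = 3L, seed = 9L)
  a <- generate_phantom_subject(spec, 2L)
  b <- generate_phantom_subject(spec, 2L)
  expect_identical(a, b)
  c2 <- generate_phantom_subject(spec, 3L)
  expect_false(identical(a$maps$FA, c2$maps$FA))

  # zero noise: values are monotone in d on [0, T] and constant beyond
  spec0 <- small_phantom_spec("FA", voxel_noise_sd = c(FA = 0),
                              subject_sd = c(FA = 0))
  s <- generate_phantom_subject(spec0, 1L)
  geom <- phantom_geometry(spec0)
  d <- geom$dist_maps$DEEP
  far_pv <- geom$dist_maps$PV >= spec0$transition_mm["PV", "FA"]
  T <- spec0$transition_mm["DEEP", "FA"]
  sel <- far_pv & d <= T
  ord <- order(d[sel])
  vals <- s$maps$FA[sel][ord]
  # lesion FA below baseline: values non-decreasing with distance
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(abs(s$maps$FA[far_pv & d >= T] -
                        spec0$baseline["FA"]) < 1e-12))
})

test_that("in-lesion means converge to the calibrated lesion mean", {
  spec <- small_phantom_spec("CBF", n_subjects = 24L, seed = 5L)
  geom <- phantom_geometry(spec)
  deep <- geom$class_masks$DEEP
  means <- vapply(seq_len(spec$n_subjects), function(i)
    mean(generate_phantom_subject(spec, i, geom)$maps$CBF[deep]), 0)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - spec$lesion_mean["DEEP", "CBF"]), 3 * se)
})

test_that("phantom geometry honours the ventricle-contact invariants", {
  spec <- small_phantom_spec("CBF")
  geom <- phantom_geometry(spec)
  halo <- wmhpenumbra:::shift_dilate(geom$ventricle_mask, 26L)
  expect_true(any(geom$class_masks$PV & halo))
  expect_false(any(geom$class_masks$DEEP & halo))
})

test_that("invalid phantom specifications are rejected", {
  centre <- c(32, 32, 32)
  # deep lesion touching the ventricle
  expect_error(small_phantom_spec("CBF", lesions = list(
    list(class = "DEEP", center_mm = centre + c(7, 0, 0), radius_mm = 3))),
    "touches the ventricle")
  # PV lesion nowhere near the ventricle
  expect_error(small_phantom_spec("CBF", lesions = list(
    list(class = "PV", center_mm = centre + c(13, 0, 0), radius_mm = 3))),
    "neither overlaps nor abuts")
  # lesion outside the grid
  expect_error(small_phantom_spec("CBF", lesions = list(
    list(class = "DEEP", center_mm = c(63, 32, 32), radius_mm = 3))),
    "outside the grid")
  expect_error(small_phantom_spec("CBF", n_subjects = 1L), "n_subjects")
})

test_that("cohort tables reproduce the specified moments", {
  prof <- reference_profile("DEEP")
  cbf <- prof[prof$parameter == "CBF", ]
  tsp <- cohort_table_spec(cbf$mean, cbf$sd, rho = 0.5, n_subjects = 5000L,
                           seed = 2L)
  tab <- generate_cohort_tables(tsp, "DEEP", "CBF")
  m <- matrix(tab$value, ncol = 17, byrow = TRUE,
              dimnames = list(NULL, tab$region[1:17]))
  mu <- colMeans(m)
  se <- apply(m, 2, sd) / sqrt(nrow(m))
  expect_true(all(abs(mu - cbf$mean) < 3 * se))
  cm <- cor(m)
  expect_lt(abs(mean(cm[upper.tri(cm)]) - 0.5), 0.03)
})

test_that("cohort tables collapse to the means in the noise-free limit", {
  means <- seq(10, 26, by = 1)
  tab <- make_table(means, rep(1e-12, 17), n = 4L, rho = 0)
  m <- matrix(tab$value, ncol = 17, byrow = TRUE)
  expect_equal(m, matrix(rep(means, 4), ncol = 17, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("cohort tables carry 17 ordered regions per subject", {
  prof <- reference_profile("PV")
  fa <- prof[prof$parameter == "FA", ]
  expect_equal(fa$mean[1], 0.221)   # WMH
  expect_equal(fa$mean[2], 0.309)   # L1
  expect_equal(fa$mean[16], 0.389)  # L15
  expect_equal(fa$mean[17], 0.344)  # NAWM
  tab <- make_table(fa$mean, fa$sd, n = 6L, class_label = "PV",
                    parameter = "FA")
  per_subj <- split(tab$region, tab$subject_id)
  for (rg in per_subj)
    expect_equal(rg, c("WMH", paste0("L", 1:15), "NAWM"))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_table_spec(1:17, rep(1, 17), rho = 1), "rho")
  expect_error(cohort_table_spec(1:17, rep(1, 17), rho = -0.2), "rho")
  expect_error(cohort_table_spec(1:17, c(rep(1, 16), 0)), "SDs must be > 0")
})
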