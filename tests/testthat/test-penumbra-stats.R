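test_that("paired t statistic matches the closed form and its conventions", {
  # d = (1,2,3,4): t = 2.5 / (1.29099.../2) = 3.87298..., df = 3
  r <- paired_t(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(r$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-12)
  expect_equal(r$t, 3.872983, tolerance = 1e-6)
  expect_equal(r$df, 3L)
  ref <- t.test(c(1, 2, 3, 4), c(0, 0, 0, 0), paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  # identical pairs: p = 1 by convention
  expect_equal(paired_t(c(2, 5, 7), c(2, 5, 7))$p, 1)
  # antisymmetry: swapping arguments negates t, two-sided p unchanged
  set.seed(1)
  x <- rnorm(10); y <- rnorm(10)
  a <- paired_t(x, y); b <- paired_t(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # degenerate cases
  expect_error(paired_t(1, 2), "at least 2")
  expect_error(paired_t(c(1, 2), c(0, 1)), "zero variance")
})

test_that("paired t agrees with the reference implementation on 100 fixtures", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:60, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- x + rnorm(n, mean = runif(1, -1, 1))
    mine <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_lt(abs(mine$t - unname(ref$statistic)), 1e-10)
    expect_lt(abs(mine$p - ref$p.value), 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("layer-vs-NAWM rule finds the first non-significant layer", {
  regions <- c("WMH", paste0("L", 1:15), "NAWM")
  base <- 20
  # layers 1..13 shifted by 10 pooled SDs; 14-15 match NAWM in distribution
  means <- c(10, ifelse(1:15 <= 13, base - 10, base), base)
  names(means) <- regions
  tab <- make_table(means, rep(1, 17), n = 42L, seed = 5L)
  fit <- boundary_vs_nawm(tab, "DEEP", "CBF")
  expect_equal(fit$boundary_layer, 14L)
  expect_equal(fit$extent_mm, 13)
  expect_false(fit$censored)
  expect_true(all(fit$comparisons$df == 41L))

  # all layers identical to NAWM: extent 0
  null_tab <- make_table(rep(base, 17), rep(1, 17), n = 42L, seed = 6L)
  fit0 <- boundary_vs_nawm(null_tab, "DEEP", "CBF")
  expect_equal(fit0$boundary_layer, 1L)
  expect_equal(fit0$extent_mm, 0)

  # every layer shifted: censored at 15 mm
  means_all <- c(10, rep(base - 10, 15), base)
  fit15 <- boundary_vs_nawm(make_table(means_all, rep(1, 17), n = 42L,
                                       seed = 7L), "DEEP", "CBF")
  expect_true(fit15$censored)
  expect_equal(fit15$extent_mm, 15)
  expect_true(is.na(fit15$boundary_layer))
})

test_that("adjacent-layer rule finds the first flat neighbouring pair", {
  base <- 0.35
  # strong gradient up to L8, then a plateau L8..L15
  lays <- c(seq(0.20, 0.34, length.out = 8), rep(0.34, 7))
  means <- c(0.18, lays, base)
  tab <- make_table(means, rep(0.005, 17), n = 42L, seed = 8L,
                    parameter = "FA")
  fit <- boundary_adjacent(tab, "DEEP", "FA")
  expect_equal(fit$boundary_layer, 8L)
  expect_equal(fit$extent_mm, 8)

  # all layers identically distributed: first pair already flat, extent 1
  fit1 <- boundary_adjacent(make_table(rep(base, 17), rep(0.01, 17),
                                       n = 42L, seed = 9L, parameter = "FA"),
                            "DEEP", "FA")
  expect_equal(fit1$boundary_layer, 1L)
  expect_equal(fit1$extent_mm, 1)

  # strictly separated consecutive layers: censored at 15
  fitc <- boundary_adjacent(make_table(c(0.1, seq(0.2, 0.9, length.out = 15),
                                         0.5),
                                       rep(0.002, 17), n = 42L, seed = 10L,
                                       parameter = "FA"),
                            "DEEP", "FA")
  expect_true(fitc$censored)
  expect_equal(fitc$extent_mm, 15)
})

test_that("maximum structural extent reproduces the published maxima", {
  mk <- function(extents, class_label) lapply(seq_along(extents), function(i)
    structure(list(class_label = class_label, parameter = names(extents)[i],
                   rule = "ADJACENT", extent_mm = extents[i]),
              class = "penumbra_result"))
  deep <- c(AD = 5, AK = 6, FA = 8, MD = 7, MK = 6, RD = 8, RK = 6)
  pv <- c(AD = 13, AK = 14, FA = 7, MD = 12, MK = 9, RD = 11, RK = 8)
  expect_equal(max_structural_extent(mk(deep, "DEEP")), 8)
  expect_equal(max_structural_extent(mk(pv, "PV")), 14)
  expect_equal(max_structural_extent(mk(c(FA = 8), "DEEP")), 8)
  expect_error(max_structural_extent(c(mk(deep, "DEEP"), mk(pv, "PV"))),
               "mix")
  bad <- mk(deep, "DEEP"); bad[[1]]$rule <- "VS_NAWM"
  expect_error(max_structural_extent(bad), "adjacent-layer")
})

test_that("cohort profile computes mean, SD and SE across subjects", {
  tab <- data.frame(subject_id = c("a", "b"), class = "DEEP", region = "L1",
                    parameter = "CBF", value = c(1, 3), n_voxels = 10L)
  prof <- cohort_profile(tab)
  expect_equal(prof$mean, 2)
  expect_equal(prof$sd, sqrt(2))
  expect_equal(prof$se, 1)

  spec <- small_phantom_spec("CBF", n_subjects = 4L, seed = 12L)
  st <- phantom_study(spec, fit = FALSE)
  p1 <- cohort_profile(st$table)
  shuffled <- st$table[sample(nrow(st$table)), ]
  p2 <- cohort_profile(shuffled)
  expect_equal(p1, p2)
})

test_that("profile of a calibrated synthetic cohort matches its moments", {
  prof <- reference_profile("DEEP")
  mk <- prof[prof$parameter == "MK", ]
  tab <- make_table(mk$mean, mk$sd, n = 5000L, seed = 13L, parameter = "MK")
  cp <- cohort_profile(tab)
  cp <- cp[match(c("WMH", paste0("L", 1:15), "NAWM"), cp$region), ]
  expect_equal(cp$mean[1], 0.846, tolerance = 3 * cp$se[1] / 0.846)
  expect_true(all(abs(cp$mean - mk$mean) < 3 * cp$se))
  expect_equal(mk$mean[c(1, 2, 4, 17)], c(0.846, 0.913, 0.964, 0.910))
})

test_that("shrinking alpha never lengthens an extent", {
  means <- c(10, seq(12, 19.5, length.out = 15), 20)
  tab <- make_table(means, rep(4, 17), n = 42L, seed = 14L)
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  extents_a <- vapply(alphas, function(a)
    boundary_vs_nawm(tab, "DEEP", "CBF", stats_config(alpha = a))$extent_mm, 0)
  extents_b <- vapply(alphas, function(a)
    boundary_adjacent(tab, "DEEP", "CBF",
                      stats_config(alpha = a))$extent_mm, 0)
  expect_true(all(diff(extents_a) <= 0))
  expect_true(all(diff(extents_b) <= 0))
})

test_that("the estimator dispatches rules by parameter and summarises", {
  prof_d <- reference_profile("DEEP")
  cbf <- prof_d[prof_d$parameter == "CBF", ]
  fa <- prof_d[prof_d$parameter == "FA", ]
  tab <- rbind(make_table(cbf$mean, cbf$sd, n = 42L, seed = 15L),
               make_table(fa$mean, fa$sd, n = 42L, seed = 16L,
                          parameter = "FA"))
  fit <- penumbra(tab)
  expect_s3_class(fit, "penumbra_scan")
  expect_setequal(names(fit$results), c("DEEP.CBF", "DEEP.FA"))
  expect_equal(fit$results$DEEP.CBF$rule, "VS_NAWM")
  expect_equal(fit$results$DEEP.FA$rule, "ADJACENT")
  cf <- coef(fit)
  expect_equal(dim(cf), c(1L, 2L))
  s <- summary(fit)$table
  expect_equal(nrow(s), 2L)
  expect_true(all(c("extent_mm", "censored") %in% names(s)))
  expect_output(print(fit), "penumbra")
})
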