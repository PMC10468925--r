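test_that("region means are plain arithmetic means with explicit missingness", {
  dm <- c(8L, 8L, 8L)
  cmap <- array(3.7, dm)
  mask <- sphere_mask(dm, c(4, 4, 4), 2.5)
  expect_equal(region_mean(cmap, mask), list(value = 3.7, n_voxels = sum(mask)))
  expect_true(is.na(region_mean(cmap, empty_mask(dm))$value))
  expect_equal(region_mean(cmap, empty_mask(dm))$n_voxels, 0L)
  set.seed(15)
  rmap <- array(rnorm(prod(dm)), dm)
  rmask <- array(runif(prod(dm)) < 0.3, dm)
  expect_equal(region_mean(rmap, rmask)$value,
               sum(rmap[rmask]) / sum(rmask), tolerance = 1e-12)
})

test_that("mean over a union is the voxel-weighted mean of the parts", {
  set.seed(8)
  dm <- c(10L, 10L, 10L)
  m <- array(rnorm(prod(dm)), dm)
  a <- array(runif(prod(dm)) < 0.2, dm)
  b <- array(runif(prod(dm)) < 0.2, dm) & !a
  ra <- region_mean(m, a); rb <- region_mean(m, b)
  ru <- region_mean(m, a | b)
  expect_equal(ru$value,
               (ra$value * ra$n_voxels + rb$value * rb$n_voxels) /
                 (ra$n_voxels + rb$n_voxels),
               tolerance = 1e-9)
})

test_that("zero-noise extraction reproduces the generative profile", {
  # T = 0: every layer mean equals the baseline exactly
  tm0 <- matrix(0, 2, 1, dimnames = list(c("PV", "DEEP"), "CBF"))
  spec0 <- deep_phantom_spec("CBF", n_subjects = 2L, transition_mm = tm0,
                             voxel_noise_sd = c(CBF = 0),
                             subject_sd = c(CBF = 0))
  st0 <- phantom_study(spec0, fit = FALSE)
  lay0 <- st0$table[grepl("^L", st0$table$region), ]
  expect_true(all(abs(lay0$value - spec0$baseline["CBF"]) < 1e-12))
  expect_true(all(abs(st0$table$value[st0$table$region == "WMH"] -
                        spec0$lesion_mean["DEEP", "CBF"]) < 1e-12))

  # linear ramp, T = 8: layer means strictly monotone towards baseline over
  # L1..L8 and exactly baseline from L9 on
  tm8 <- matrix(8, 2, 1, dimnames = list(c("PV", "DEEP"), "CBF"))
  spec8 <- deep_phantom_spec("CBF", n_subjects = 2L, transition_mm = tm8,
                             voxel_noise_sd = c(CBF = 0),
                             subject_sd = c(CBF = 0))
  st8 <- phantom_study(spec8, fit = FALSE)
  s1 <- st8$table[st8$table$subject_id == "S001", ]
  lay <- s1$value[match(paste0("L", 1:15), s1$region)]
  base <- unname(spec8$baseline["CBF"])
  expect_true(all(diff(lay[1:8]) > 0))  # lesion CBF below baseline: increasing
  expect_true(all(lay[1:8] < base))
  expect_equal(lay[9:15], rep(base, 7), tolerance = 1e-12)
})

test_that("WMH region mean matches the deep-lesion CBF calibration", {
  spec <- deep_phantom_spec("CBF", n_subjects = 2L,
                            voxel_noise_sd = c(CBF = 0),
                            subject_sd = c(CBF = 0))
  st <- phantom_study(spec, fit = FALSE)
  wmh <- st$table[st$table$region == "WMH" & st$table$subject_id == "S001", ]
  expect_equal(wmh$value, 14.212)
})

test_that("extraction is invariant to subject order and tables round-trip", {
  spec <- small_phantom_spec("CBF", n_subjects = 3L, seed = 2L)
  geom <- phantom_geometry(spec)
  subjects <- lapply(1:3, function(i) generate_phantom_subject(spec, i, geom))
  s1 <- subjects[[1]]
  lesions <- classify_lesions(s1$seg)
  masks <- wmhpenumbra:::subject_masks(s1$seg, lesions, layer_config(), 0.5,
                                       NULL)
  rows <- lapply(subjects, function(s)
    extract_subject(s$maps, lesions, masks$layers, masks$nawm,
                    sprintf("S%03d", s$subject_index)))
  fwd <- do.call(rbind, rows)
  rev <- do.call(rbind, rows[3:1])
  key <- function(df) df[order(df$subject_id, df$class, df$region), ]
  expect_equal(key(fwd)$value, key(rev)$value)

  # NAWM rows identical across classes within a subject
  nawm <- fwd[fwd$region == "NAWM", ]
  for (sid in unique(nawm$subject_id))
    expect_equal(length(unique(nawm$value[nawm$subject_id == sid])), 1L)

  path <- tempfile(fileext = ".tsv")
  write_layer_table(fwd, path)
  back <- read_layer_table(path)
  expect_equal(back$value, fwd$value, tolerance = 1e-15)
  expect_identical(back$region, fwd$region)
  # and a second write of the re-read table is byte-identical
  path2 <- tempfile(fileext = ".tsv")
  write_layer_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
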