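test_that("zonal median follows the mean-of-middle-two convention", {
  m <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 2, 3, byrow = TRUE)
  s <- toy_scene(m)
  expect_equal(zonal_median(s, toy_roi(1, 1, 1, 3, nrow_m = 2), "RED"), 0.2)
  expect_equal(zonal_median(s, toy_roi(1, 2, 1, 2, nrow_m = 2), "RED"),
               mean(c(0.2, 0.4))) # even count
  # constant field returns the constant
  sc <- toy_scene(matrix(0.42, 4, 4))
  expect_equal(zonal_median(sc, toy_roi(1, 4, 1, 4, nrow_m = 4), "NIR"), 0.42)
  # no valid pixels: NA with warning, not silent zero
  mna <- matrix(NA_real_, 3, 3)
  expect_warning(v <- zonal_median(toy_scene(mna), toy_roi(1, 2, 1, 2, nrow_m = 3),
                                   "RED"), "no valid")
  expect_true(is.na(v))
})

test_that("zonal statistics ignore nodata and pixels outside the polygon", {
  set.seed(3)
  m <- matrix(runif(100), 10, 10)
  inside <- m[3:6, 3:6]
  m2 <- m
  m2[1, 1] <- NA; m2[10, 10] <- 9 # junk outside the ROI
  roi <- toy_roi(3, 6, 3, 6, nrow_m = 10)
  expect_equal(zonal_median(toy_scene(m2), roi, "RED"), median(inside))
  expect_equal(zonal_cv(toy_scene(m2), roi, "RED"),
               sd(inside) / mean(inside))
  # nodata inside the ROI is excluded from the median
  m3 <- m; m3[3, 3] <- NA
  expect_equal(zonal_median(toy_scene(m3), roi, "RED"),
               median(inside[-1]))
})

test_that("zonal CV matches hand-computed values and is scale invariant", {
  m <- matrix(c(2, 4, 5, 5), 1, 4)
  s <- toy_scene(m)
  expect_equal(zonal_cv(s, toy_roi(1, 1, 1, 2, nrow_m = 1), "RED"),
               sqrt(2) / 3, tolerance = 1e-6)
  expect_equal(zonal_cv(s, toy_roi(1, 1, 3, 4, nrow_m = 1), "RED"), 0)
  s10 <- toy_scene(10 * m)
  expect_equal(zonal_cv(s10, toy_roi(1, 1, 1, 2, nrow_m = 1), "RED"),
               zonal_cv(s, toy_roi(1, 1, 1, 2, nrow_m = 1), "RED"))
})

test_that("vegetation indices reproduce the published formulas", {
  expect_equal(compute_vegetation_index("NDRE", nir = 0.4, rededge = 0.2),
               1 / 3, tolerance = 1e-6)
  expect_equal(compute_vegetation_index("DVI", nir = 0.4, red = 0.1), 0.3)
  expect_equal(compute_vegetation_index("RVI", nir = 0.4, red = 0.1), 4)
  expect_equal(compute_vegetation_index("MCARI", green = 0.2, red = 0.1,
                                        rededge = 0.3), 0.54)
  expect_equal(compute_vegetation_index("TCARI", green = 0.2, red = 0.1,
                                        rededge = 0.3), 0.42)
  expect_equal(compute_vegetation_index("OSAVI", red = 0.1, rededge = 0.3,
                                        nir = 0.4), 0.7534884,
               tolerance = 1e-6)
  expect_equal(compute_vegetation_index("CCII", green = 0.2, red = 0.1,
                                        rededge = 0.3, nir = 0.4),
               0.42 / 0.7534884, tolerance = 1e-6)
  # canonical OSAVI differs from the default variant
  expect_equal(compute_vegetation_index("OSAVI", red = 0.1, rededge = 0.3,
                                        nir = 0.4,
                                        osavi_variant = "standard"),
               1.16 * 0.3 / 0.66, tolerance = 1e-6)
  expect_warning(v <- compute_vegetation_index("RVI", nir = 0.4, red = 0),
                 "denominator")
  expect_true(is.na(v))
})

test_that("NDRE is bounded in [-1, 1] for non-negative reflectances", {
  set.seed(7)
  nir <- runif(200); re <- runif(200)
  v <- compute_vegetation_index("NDRE", nir = nir, rededge = re)
  expect_true(all(v >= -1 & v <= 1))
})

test_that("average resampling preserves constants and block means", {
  sc <- toy_scene(matrix(0.3, 6, 6))
  r <- resample_average(sc, 3)
  expect_equal(dim(r$bands$RED), c(2, 2))
  expect_true(all(r$bands$RED == 0.3))
  s2 <- toy_scene(matrix(c(1, 3, 2, 4) / 10, 2, 2))
  expect_equal(as.numeric(resample_average(s2, 2)$bands$RED), 0.25)
  expect_error(resample_average(s2, 0.5), "upsampling")
})

test_that("resampling conserves the mean at integer ratios and tracks a ramp
           at non-integer ratios", {
  set.seed(11)
  m <- matrix(runif(144), 12, 12)
  r <- resample_average(toy_scene(m), 4)
  expect_equal(mean(r$bands$RED), mean(m), tolerance = 1e-12)
  # non-integer ratio (0.7 cm -> 2.5 cm) against a brute-force
  # area-weight accumulation oracle, plus the analytic ramp to within
  # one source pixel of discretization error
  gsd <- 0.007; tgt <- 0.025
  nc <- 50; nr <- 20
  ramp <- matrix(rep((seq_len(nc) - 0.5) * gsd, each = nr), nr, nc)
  rs <- resample_average(toy_scene(ramp, gsd = gsd, origin = c(0, nr * gsd)),
                         tgt)
  oracle_cell <- function(o) { # 1-D: ramp is constant along rows
    lo <- (o - 1) * tgt; hi <- o * tgt
    num <- den <- 0
    for (i in seq_len(nc)) {
      ov <- min(hi, i * gsd) - max(lo, (i - 1) * gsd)
      if (ov > 0) { num <- num + ov * (i - 0.5) * gsd; den <- den + ov }
    }
    num / den
  }
  full <- floor(nc * gsd / tgt)
  expect_equal(as.numeric(rs$bands$RED[1, seq_len(full)]),
               vapply(seq_len(full), oracle_cell, numeric(1)),
               tolerance = 1e-12)
  centers <- (seq_len(full) - 0.5) * tgt
  expect_equal(as.numeric(rs$bands$RED[1, seq_len(full)]), centers,
               tolerance = gsd / 2)
  # nodata propagates only where all contributors are nodata
  m2 <- matrix(1, 4, 4); m2[1:2, 1:2] <- NA
  r2 <- resample_average(toy_scene(m2 / 2), 2)
  expect_true(is.na(r2$bands$RED[1, 1]) && !anyNA(r2$bands$RED[-1, ]))
})

test_that("feature table has the full cardinality and flags missing plots", {
  tr <- small_trial(seed = 4, n_dates = 2)
  ft <- build_feature_table(tr$scenes, tr$plots[1:3], tr$axis)
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 2 * 3 * 15)
  expect_equal(sort(unique(ft$feature)), sort(feature_names()))
  expect_false(anyNA(ft$value))
  expect_false(anyNA(ft$gdd))
  # a plot fully outside the raster yields 15 missing records per scene
  far <- plot_roi("P999", "VX", 1, 2021,
                  cbind(c(900, 901, 901, 900), c(900, 900, 899, 899)))
  expect_warning(ft2 <- build_feature_table(tr$scenes[1], c(tr$plots[1],
                                                            list(far)),
                                            tr$axis), "P999")
  expect_equal(sum(is.na(ft2$value[ft2$plot_id == "P999"])), 15)
})

test_that("median-then-index equals index-then-median on constant ROIs", {
  bands <- list(BLUE = matrix(0.05, 4, 4), GREEN = matrix(0.2, 4, 4),
                RED = matrix(0.1, 4, 4), REDEDGE = matrix(0.3, 4, 4),
                NIR = matrix(0.4, 4, 4))
  s <- toy_scene(NULL, bands = bands)
  roi <- toy_roi(1, 4, 1, 4, nrow_m = 4)
  meds <- vapply(names(bands), function(b) zonal_median(s, roi, b),
                 numeric(1))
  for (ix in c("DVI", "RVI", "NDRE", "MCARI", "CCII")) {
    direct <- compute_vegetation_index(ix, green = 0.2, red = 0.1,
                                       rededge = 0.3, nir = 0.4)
    from_meds <- compute_vegetation_index(ix, green = meds["GREEN"],
                                          red = meds["RED"],
                                          rededge = meds["REDEDGE"],
                                          nir = meds["NIR"])
    expect_equal(unname(from_meds), direct)
  }
})

test_that("band names from different cameras harmonize; unknowns error", {
  m <- matrix(0.1, 2, 2)
  s <- scene("2022-05-01", list(b444 = m, g560 = m, r650 = m, b717 = m,
                                b842 = m), gsd = 1)
  expect_setequal(names(s$bands), feature_names()[1:5])
  expect_error(scene("2022-05-01", list(uv = m), gsd = 1), "unrecognized")
})

test_that("feature tables round-trip through CSV", {
  tr <- small_trial(seed = 4, n_dates = 2)
  ft <- build_feature_table(tr$scenes, tr$plots[1:2], tr$axis,
                            feature_groups = c("bands", "vi"))
  tf <- tempfile(fileext = ".csv")
  write_feature_table(ft, tf)
  back <- read_feature_table(tf)
  expect_equal(back$value, ft$value, tolerance = 1e-12)
  expect_equal(back$date, ft$date)
})
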