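test_that("simulated weather respects its profile and seed", {
  w <- simulate_weather(5, profile = "constant", mean_t = 10)
  ax <- cumulative_gdd(w, min(w$date), max(w$date))
  expect_equal(ax$gdd, 10 * (1:5))
  expect_identical(simulate_weather(30, seed = 9), simulate_weather(30, seed = 9))
  expect_true(all(simulate_weather(30, seed = 9)$tmax_c >=
                    simulate_weather(30, seed = 9)$tmin_c))
  # simulated annual mean stays near the profile mean
  for (s in 1:5) {
    w <- simulate_weather(365, seed = s)
    daily <- aggregate((tmax_c + tmin_c) / 2 ~ date, w, mean)
    expect_lt(abs(mean(daily[[2]]) - 8), 2)
  }
})

test_that("the degenerate noise-free trial has pure variety yields", {
  cfg <- sim_config(seed = 5, n_varieties = 6, n_reps = 3, sigma_y = 0,
                    beta1 = 0)
  tr <- simulate_trial(cfg, render = FALSE)
  spread <- aggregate(yield_g_m2 ~ variety, tr$yields,
                      function(v) diff(range(v)))
  expect_true(all(spread$yield_g_m2 < 1e-9))
})

test_that("default trials land near the target yield distribution", {
  means <- sds <- numeric(0)
  for (s in 1:3) {
    tr <- simulate_trial(sim_config(seed = s), render = FALSE)
    means <- c(means, mean(tr$yields$yield_g_m2))
    sds <- c(sds, sd(tr$yields$yield_g_m2))
    expect_true(all(tr$yields$yield_g_m2 > 0))
  }
  expect_lt(abs(mean(means) - 535.5), 0.1 * 535.5)
  expect_true(all(sds > 40 & sds < 120))
})

test_that("trial structure matches the design", {
  tr <- small_trial(seed = 2, render = FALSE)
  expect_equal(nrow(tr$yields), 12)
  expect_equal(sum(tr$variety_groups$group == "L"), 3)
  expect_equal(sum(tr$variety_groups$group == "H"), 3)
  expect_length(intersect(
    tr$variety_groups$variety[tr$variety_groups$group == "L"],
    tr$variety_groups$variety[tr$variety_groups$group == "H"]), 0)
  # each replicate contains every variety exactly once (RCBD)
  per_rep <- table(tr$yields$replicate, tr$yields$variety)
  expect_true(all(per_rep == 1))
  # fixed variety effects are honored
  eff <- c(-60, -60, -60, 60, 60, 60)
  tr2 <- simulate_trial(sim_config(seed = 3, n_varieties = 6, n_reps = 4,
                                   variety_effects = eff, sigma_y = 0,
                                   beta1 = 0), render = FALSE)
  vm <- aggregate(yield_g_m2 ~ variety, tr2$yields, mean)
  expect_equal(vm$yield_g_m2, 535.5 + eff)
})

test_that("rendered scenes honor the canopy limits and are reproducible", {
  # bare soil: cover never rises within the season
  cfg0 <- sim_config(seed = 6, n_varieties = 6, n_reps = 2,
                     schedule = c(400, 800), f_mid = 1e6)
  tr0 <- simulate_trial(cfg0)
  em <- default_endmembers()
  for (b in c("RED", "NIR")) {
    v <- roi_vals <- vapply(tr0$plots, function(p)
      zonal_median(tr0$scenes[[1]], p, b), numeric(1))
    expect_true(all(abs(v - em["soil", b]) <
                      3 * cfg0$speckle_sd * em["soil", b]))
  }
  # closed green canopy, no speckle, no rows: exactly the leaf endmember
  cfg1 <- sim_config(seed = 6, n_varieties = 6, n_reps = 2,
                     schedule = c(400, 800), f_mid = -1e6, s_mid = 1e6,
                     speckle_sd = 0, row_amp = 0, chl_scale = 0,
                     pheno_shift_sd = 0)
  tr1 <- simulate_trial(cfg1)
  expect_equal(zonal_median(tr1$scenes[[1]], tr1$plots[[1]], "NIR"),
               em["leaf", "NIR"], tolerance = 1e-12)
  # same seed renders identical scenes
  trA <- small_trial(seed = 7, n_dates = 2)
  trB <- small_trial(seed = 7, n_dates = 2)
  expect_identical(trA$scenes[[2]]$bands, trB$scenes[[2]]$bands)
  # and render_scene itself is idempotent
  expect_identical(render_scene(trA, 1)$bands, trA$scenes[[1]]$bands)
})

test_that("row structure appears at partial cover and fades at closure", {
  cfg <- sim_config(seed = 8, n_varieties = 6, n_reps = 2,
                    schedule = c(350, 1000), speckle_sd = 0,
                    gsd = 0.025) # resolve the 0.125 m rows
  tr <- simulate_trial(cfg)
  p <- tr$plots[[1]]
  early <- roi_pixels(tr$scenes[[1]], p, "RED")
  closed <- roi_pixels(tr$scenes[[2]], p, "RED")
  expect_gt(sd(early), 5 * sd(closed))
})

test_that("simulated NDRE at flowering tracks true yield", {
  cors <- vapply(1:5, function(s) {
    tr <- simulate_trial(sim_config(seed = s))
    fl <- which.min(abs(tr$flight_gdd - 1155))
    ft <- build_feature_table(tr$scenes[fl], tr$plots, tr$axis,
                              feature_groups = "vi")
    ndre <- ft$value[ft$feature == "NDRE"]
    ids <- ft$plot_id[ft$feature == "NDRE"]
    cor(ndre, tr$yields$yield_g_m2[match(ids, tr$yields$plot_id)])
  }, numeric(1))
  expect_gt(mean(cors), 0.5)
  expect_true(all(cors > 0.3))
})

test_that("high-yield plots show higher flowering NDRE than low-yield plots", {
  pvals <- vapply(1:5, function(s) {
    tr <- simulate_trial(sim_config(seed = s + 10))
    fl <- which.min(abs(tr$flight_gdd - 1155))
    ft <- build_feature_table(tr$scenes[fl], tr$plots, tr$axis,
                              feature_groups = "vi")
    nd <- ft[ft$feature == "NDRE", ]
    grp <- tr$yields$group[match(nd$plot_id, tr$yields$plot_id)]
    w <- group_ttest(nd$value[grp == "H"], nd$value[grp == "L"])
    expect_gt(w$t, 0)
    w$p
  }, numeric(1))
  expect_true(all(pvals < 0.05))
})

test_that("in-plot contrast is higher on open canopies than closed ones", {
  tr <- simulate_trial(sim_config(seed = 3, schedule = c(300, 1000)))
  texA <- texture_feature_rasters(tr$scenes[[1]]$bands$RED)
  texB <- texture_feature_rasters(tr$scenes[[2]]$bands$RED)
  for (p in tr$plots) {
    a <- zonal_texture_mean(scene_band(tr$scenes[[1]], texA$CON), p)
    b <- zonal_texture_mean(scene_band(tr$scenes[[2]], texB$CON), p)
    expect_gt(a, b)
  }
})

test_that("trials round-trip through the on-disk input formats", {
  tr <- small_trial(seed = 9, n_dates = 2)
  dir <- tempfile()
  write_trial(tr, dir)
  expect_true(file.exists(file.path(dir, "plots.geojson")))
  plots <- read_plots_geojson(file.path(dir, "plots.geojson"))
  expect_equal(length(plots), length(tr$plots))
  expect_equal(plots[[3]]$polygon, tr$plots[[3]]$polygon)
  expect_equal(plots[[3]]$variety, tr$plots[[3]]$variety)
  scn <- read_scene(list.files(file.path(dir, "scenes"),
                               pattern = "\\.tif$", full.names = TRUE)[1])
  orig <- tr$scenes[[1]]
  expect_equal(scn$gsd, orig$gsd)
  expect_lt(max(abs(scn$bands$RED - orig$bands$RED), na.rm = TRUE), 1e-7)
  expect_equal(is.na(scn$bands$RED), is.na(orig$bands$RED))
})
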