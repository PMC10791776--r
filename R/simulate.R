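#' Synthetic variety-trial configuration
#'
#' Parameters of the synthetic wheat variety trial the simulator renders:
#' a randomized complete block design (varieties x replicates), a flight
#' schedule on the thermal-time axis, a five-band canopy reflectance model
#' (soil/leaf/senesced endmember mixture with row-structure and speckle
#' texture), and a yield model carrying a variety effect plus a
#' canopy-duration term.
#'
#' The yield of plot i of variety v is
#' \deqn{yield_i = \beta_0 + q_v + \beta_1 (G_i - G_{ref}) + \epsilon_i,}
#' where \eqn{q_v} is the variety effect, \eqn{G_i} the mean over flight
#' dates of \eqn{f_i (1 - s_i) c_i} (green canopy duration weighted by
#' chlorophyll), and \eqn{\epsilon_i \sim N(0, \sigma_y)}. Canopy cover f
#' and senescence s are logistic in GDD with a variety-specific phenology
#' shift; chlorophyll c is linked to the same variety effect, which is what
#' makes reflectance yield-informative.
#'
#' @param seed Master seed; all sub-streams (weather, varieties, plots,
#'   pixels) derive from it.
#' @param n_varieties,n_reps Trial dimensions (default 19 x 4 = 76 plots).
#' @param schedule Flight schedule in cumulative GDD (default 19 dates,
#'   300-1700).
#' @param gsd Rendered ground sampling distance, m/pixel.
#' @param plot_len,plot_wid,alley,border Field layout, m.
#' @param row_spacing,row_amp Sowing-row sinusoid period (m) and relative
#'   amplitude (visible only while the canopy is open).
#' @param speckle_sd,speckle_closure Lognormal pixel speckle sdlog and its
#'   fractional reduction at full green cover (canopy closure smooths
#'   texture).
#' @param endmembers 3 x 5 matrix of leaf/senesced/soil reflectances per
#'   band.
#' @param chl_scale,chl_absorb Chlorophyll spread per unit variety effect
#'   and its linear effect on RED/REDEDGE leaf reflectance.
#' @param f_mid,f_scale,s_mid,s_scale Logistic midpoints/scales (GDD) of
#'   cover rise and senescence.
#' @param pheno_shift_sd Between-variety phenology shift SD, GDD.
#' @param sd_variety Variety yield-effect SD, g/m^2.
#' @param variety_effects Optional fixed vector of variety yield effects
#'   (g/m^2, length \code{n_varieties}) overriding the random draw; useful
#'   for experiments that prescribe a group separation.
#' @param plot_effect_sd Within-variety plot-level latent SD (unitless, on
#'   the standardized variety-effect scale).
#' @param beta0,beta1,g_ref,sigma_y Yield model: intercept (g/m^2), canopy
#'   slope (g/m^2 per unit G), reference G, residual SD (g/m^2).
#' @param sowing,harvest Season dates.
#' @param year Year tag.
#' @param k_group Varieties per yield group label.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, n_varieties = 19, n_reps = 4,
                       schedule = seq(300, 1700, length.out = 19),
                       gsd = 0.125, plot_len = 10, plot_wid = 1.85,
                       alley = 0.5, border = 1,
                       row_spacing = 0.125, row_amp = 0.6,
                       speckle_sd = 0.12, speckle_closure = 0.6,
                       endmembers = default_endmembers(),
                       chl_scale = 0.15, chl_absorb = 0.8,
                       f_mid = 550, f_scale = 90,
                       s_mid = 1350, s_scale = 70,
                       pheno_shift_sd = 40, sd_variety = 35,
                       variety_effects = NULL, plot_effect_sd = 0.4,
                       beta0 = 535.5, beta1 = 400, g_ref = NULL,
                       sigma_y = 50,
                       sowing = "2020-10-20", harvest = "2021-08-03",
                       year = 2021, k_group = 3) {
  stopifnot(n_varieties >= 2, n_reps >= 1, all(diff(schedule) > 0),
            gsd > 0, sigma_y >= 0, sd_variety >= 0, pheno_shift_sd >= 0,
            speckle_sd >= 0, all(endmembers >= 0 & endmembers <= 1))
  cfg <- list(seed = seed, n_varieties = n_varieties, n_reps = n_reps,
              schedule = schedule, gsd = gsd, plot_len = plot_len,
              plot_wid = plot_wid, alley = alley, border = border,
              row_spacing = row_spacing, row_amp = row_amp,
              speckle_sd = speckle_sd, speckle_closure = speckle_closure,
              endmembers = endmembers, chl_scale = chl_scale,
              chl_absorb = chl_absorb, f_mid = f_mid, f_scale = f_scale,
              s_mid = s_mid, s_scale = s_scale,
              pheno_shift_sd = pheno_shift_sd, sd_variety = sd_variety,
              variety_effects = variety_effects,
              plot_effect_sd = plot_effect_sd, beta0 = beta0,
              beta1 = beta1, sigma_y = sigma_y,
              sowing = as.Date(sowing), harvest = as.Date(harvest),
              year = year, k_group = k_group)
  # reference canopy term: the schedule-mean green canopy duration of the
  # average variety (c = 1, no phenology shift), so beta0 is the mean yield
  cfg$g_ref <- g_ref %||%
    mean(plogis((schedule - f_mid) / f_scale) *
         (1 - plogis((schedule - s_mid) / s_scale)))
  class(cfg) <- "sim_config"
  cfg
}

#' Default soil/leaf/senesced endmember reflectances
#'
#' Rows leaf/senesced/soil, columns BLUE/GREEN/RED/REDEDGE/NIR. Chosen to
#' reproduce the qualitative band dynamics of a wheat season (dark green
#' canopy, bright senesced straw, intermediate soil), not radiometric
#' truth.
#'
#' @return 3 x 5 numeric matrix.
#' @export
default_endmembers <- function() {
  m <- rbind(leaf = c(0.03, 0.08, 0.04, 0.25, 0.50),
             senesced = c(0.10, 0.20, 0.25, 0.35, 0.40),
             soil = c(0.10, 0.14, 0.18, 0.22, 0.25))
  colnames(m) <- BAND_NAMES
  m
}

#' Simulate hourly weather
#'
#' Annual sinusoid daily mean plus AR(1) day-level noise, expanded to
#' hourly max/min pairs with a diurnal cycle (which averages out exactly in
#' the daily mean). \code{profile = "constant"} gives noise-free constant
#' temperature (useful for closed-form thermal-time checks).
#'
#' @param n_days Number of days.
#' @param seed RNG seed.
#' @param profile \code{"sinusoid"} or \code{"constant"}.
#' @param start First day (Date or coercible).
#' @param mean_t Annual mean (sinusoid) or the constant temperature, deg C.
#' @param amplitude Annual sinusoid amplitude, deg C.
#' @param coldest_doy Day-of-year of the annual minimum.
#' @param noise_sd,ar1 Daily AR(1) noise SD and autocorrelation.
#' @param diurnal_amp Within-day temperature swing amplitude, deg C.
#' @param spread Half-distance between hourly max and min, deg C.
#' @return Data frame \code{date, hour, tmax_c, tmin_c} (24 rows/day).
#' @export
simulate_weather <- function(n_days, seed = 1,
                             profile = c("sinusoid", "constant"),
                             start = "2020-10-20", mean_t = 8,
                             amplitude = 10, coldest_doy = 15,
                             noise_sd = 2, ar1 = 0.7,
                             diurnal_amp = 4, spread = 1) {
  profile <- match.arg(profile)
  stopifnot(n_days >= 1)
  days <- seq(as.Date(start), by = "day", length.out = n_days)
  hours <- 0:23
  if (profile == "constant") {
    base <- rep(mean_t, n_days)
    diurnal <- rep(0, 24)
    spread <- 0
  } else {
    set.seed(seed)
    doy <- as.integer(format(days, "%j"))
    eps <- as.numeric(stats::arima.sim(list(ar = ar1), n_days,
                                       sd = noise_sd * sqrt(1 - ar1^2)))
    base <- mean_t - amplitude * cos(2 * pi * (doy - coldest_doy) / 365) + eps
    diurnal <- diurnal_amp * cos(2 * pi * (hours - 14) / 24)
  }
  data.frame(date = rep(days, each = 24),
             hour = rep(hours, n_days),
             tmax_c = rep(base, each = 24) + rep(diurnal, n_days) + spread / 2,
             tmin_c = rep(base, each = 24) + rep(diurnal, n_days) - spread / 2)
}

#' Simulate a complete synthetic variety trial
#'
#' Generates weather, the thermal axis, the plot map (RCBD: each replicate
#' is one field column with its own random variety order), per-plot latent
#' canopy tracks (cover f, senescence s, chlorophyll c), yields, yield
#' groups, a BBCH-like phenology table and (optionally) a rendered
#' five-band reflectance scene per flight date.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param render Render scenes (default TRUE); with \code{FALSE} only the
#'   tabular/latent parts are produced.
#' @return A \code{sim_trial}: list with \code{cfg}, \code{weather},
#'   \code{axis}, \code{flight_dates}, \code{plots} (list of
#'   \code{plot_roi}), \code{yields}, \code{variety_groups},
#'   \code{phenology}, \code{truth} (latent f, s, c per plot-date) and
#'   \code{scenes}.
#' @export
simulate_trial <- function(cfg = sim_config(), render = TRUE) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config")
  if (cfg$n_varieties < 2 * cfg$k_group)
    stop("need at least ", 2 * cfg$k_group, " varieties for group labels")
  weather <- simulate_weather(
    as.integer(cfg$harvest - cfg$sowing) + 1L, seed = cfg$seed + 101L,
    start = cfg$sowing)
  axis <- cumulative_gdd(weather, cfg$sowing, cfg$harvest)
  if (max(axis$gdd) < max(cfg$schedule))
    stop("season too short: axis tops out at ", round(max(axis$gdd)),
         " GDD, schedule needs ", max(cfg$schedule))
  flight_idx <- unique(vapply(cfg$schedule,
                              function(g) which.min(abs(axis$gdd - g)),
                              integer(1)))
  flight_dates <- axis$date[flight_idx]
  flight_gdd <- axis$gdd[flight_idx]

  # varieties: yield effect, phenology shift
  set.seed(cfg$seed + 202L)
  vnames <- sprintf("V%02d", seq_len(cfg$n_varieties))
  if (is.null(cfg$variety_effects)) {
    q_v <- setNames(rnorm(cfg$n_varieties, 0, cfg$sd_variety), vnames)
    q_scale <- max(cfg$sd_variety, 1e-9)
  } else {
    if (length(cfg$variety_effects) != cfg$n_varieties)
      stop("variety_effects must have length n_varieties")
    q_v <- setNames(as.numeric(cfg$variety_effects), vnames)
    q_scale <- max(sd(q_v), 1e-9)
  }
  shift_v <- setNames(rnorm(cfg$n_varieties, 0, cfg$pheno_shift_sd), vnames)

  # plot map (replicate = field column, random variety order per column)
  set.seed(cfg$seed + 303L)
  plots <- list(); meta <- list()
  H <- 2 * cfg$border + cfg$n_varieties * cfg$plot_wid +
    (cfg$n_varieties - 1) * cfg$alley
  pid <- 0
  for (rep_i in seq_len(cfg$n_reps)) {
    ord <- sample(vnames)
    x0 <- cfg$border + (rep_i - 1) * (cfg$plot_len + cfg$alley)
    for (row in seq_along(ord)) {
      pid <- pid + 1
      ytop <- H - cfg$border - (row - 1) * (cfg$plot_wid + cfg$alley)
      poly <- cbind(c(x0, x0 + cfg$plot_len, x0 + cfg$plot_len, x0),
                    c(ytop, ytop, ytop - cfg$plot_wid, ytop - cfg$plot_wid))
      id <- sprintf("P%03d", pid)
      plots[[pid]] <- plot_roi(id, ord[row], rep_i, cfg$year, poly)
      meta[[pid]] <- data.frame(plot_id = id, variety = ord[row],
                                replicate = rep_i, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)

  # per-plot latent state
  n <- nrow(meta)
  z_v <- q_v[meta$variety] / q_scale
  z_i <- z_v + rnorm(n, 0, cfg$plot_effect_sd)
  c_i <- pmin(pmax(1 + cfg$chl_scale * z_i, 0.4), 1.6)
  shift_i <- shift_v[meta$variety] + rnorm(n, 0, 10)
  fmat <- outer(shift_i, flight_gdd,
                function(d, g) plogis((g - (cfg$f_mid + d)) / cfg$f_scale))
  smat <- outer(shift_i, flight_gdd,
                function(d, g) plogis((g - (cfg$s_mid + d)) / cfg$s_scale))
  G_i <- rowMeans(fmat * (1 - smat) * c_i)

  set.seed(cfg$seed + 404L)
  yield <- cfg$beta0 + q_v[meta$variety] +
    cfg$beta1 * (G_i - cfg$g_ref) + rnorm(n, 0, cfg$sigma_y)
  yield <- pmax(yield, 1) # yields are strictly positive
  yields <- data.frame(meta, year = cfg$year, yield_g_m2 = unname(yield),
                       stringsAsFactors = FALSE)
  vm <- aggregate(yield_g_m2 ~ variety, yields, mean)
  groups <- assign_yield_groups(
    data.frame(variety = vm$variety, mean_yield = vm$yield_g_m2),
    k = cfg$k_group)
  yields$group <- groups$group[match(yields$variety, groups$variety)]

  # BBCH-like phenology track: anchors in GDD, shifted per plot
  anchor_g <- c(250, 500, 628, 945, 1073, 1155, 1387, 1667, 1800)
  anchor_b <- c(10, 25, 32, 45, 55, 65, 75, 85, 92)
  phen <- do.call(rbind, lapply(seq_len(n), function(i) {
    bb <- stats::approx(anchor_g + shift_i[i], anchor_b, xout = flight_gdd,
                        rule = 2)$y
    data.frame(plot_id = meta$plot_id[i], date = flight_dates,
               gdd = flight_gdd, bbch = round(bb), stringsAsFactors = FALSE)
  }))

  truth <- do.call(rbind, lapply(seq_along(flight_dates), function(t) {
    data.frame(plot_id = meta$plot_id, date = flight_dates[t],
               gdd = flight_gdd[t], f = fmat[, t], s = smat[, t],
               c = c_i, stringsAsFactors = FALSE)
  }))

  trial <- structure(
    list(cfg = cfg, weather = weather, axis = axis,
         flight_dates = flight_dates, flight_gdd = flight_gdd,
         plots = plots, yields = yields, variety_groups = groups,
         phenology = phen, truth = truth,
         latent = list(c_i = c_i, shift_i = shift_i, fmat = fmat,
                       smat = smat, meta = meta),
         scenes = NULL),
    class = "sim_trial")
  if (render)
    trial$scenes <- lapply(seq_along(flight_dates),
                           function(t) render_scene(trial, t))
  trial
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf(paste0("<sim_trial> %d varieties x %d reps = %d plots, ",
                     "%d flight dates (%.0f-%.0f GDD)\n"),
              x$cfg$n_varieties, x$cfg$n_reps, nrow(x$yields),
              length(x$flight_dates), min(x$flight_gdd), max(x$flight_gdd)))
  cat(sprintf("  yield mean %.1f g/m2 (sd %.1f); %s rendered\n",
              mean(x$yields$yield_g_m2), sd(x$yields$yield_g_m2),
              if (is.null(x$scenes)) "scenes not" else
                paste(length(x$scenes), "scenes")))
  invisible(x)
}

#' Render one flight date's five-band scene
#'
#' Per-pixel reflectance follows the endmember mixture
#' \code{f_px * ((1 - s) * leaf(c) + s * senesced) + (1 - f_px) * soil},
#' where the pixel-level cover \code{f_px} is the plot's cover modulated by
#' the across-row sowing sinusoid (rows run along the plot's long axis) and
#' the result carries multiplicative lognormal speckle whose amplitude
#' shrinks toward canopy closure. Alleys and border are bare soil; a 0.5 m
#' nodata margin surrounds the field. Deterministic given (seed, date
#' index).
#'
#' @param trial A \code{sim_trial} (scenes may be NULL).
#' @param t Flight date index.
#' @return A \code{\link{scene}}.
#' @export
render_scene <- function(trial, t) {
  cfg <- trial$cfg
  set.seed(cfg$seed + 7919L * t)
  W <- 2 * cfg$border + cfg$n_reps * cfg$plot_len +
    (cfg$n_reps - 1) * cfg$alley
  H <- 2 * cfg$border + cfg$n_varieties * cfg$plot_wid +
    (cfg$n_varieties - 1) * cfg$alley
  margin <- 0.5
  nc <- ceiling((W + 2 * margin) / cfg$gsd)
  nr <- ceiling((H + 2 * margin) / cfg$gsd)
  origin <- c(-margin, H + margin)
  xc <- origin[1] + (seq_len(nc) - 0.5) * cfg$gsd
  yc <- origin[2] - (seq_len(nr) - 0.5) * cfg$gsd
  infield <- outer(yc >= 0 & yc <= H, xc >= 0 & xc <= W, "&")

  em <- cfg$endmembers
  bands <- setNames(vector("list", 5), BAND_NAMES)
  # start from bare soil with speckle
  for (b in BAND_NAMES) {
    m <- matrix(NA_real_, nr, nc)
    m[infield] <- em["soil", b] *
      exp(rnorm(sum(infield), 0, cfg$speckle_sd))
    bands[[b]] <- m
  }
  lat <- trial$latent
  for (i in seq_along(trial$plots)) {
    p <- trial$plots[[i]]
    f <- lat$fmat[i, t]; s <- lat$smat[i, t]; ci <- lat$c_i[i]
    xr <- range(p$polygon[, 1]); yr <- range(p$polygon[, 2])
    cols <- which(xc >= xr[1] & xc <= xr[2])
    rows <- which(yc >= yr[1] & yc <= yr[2])
    if (!length(cols) || !length(rows)) next
    # across-row sinusoid: rows along x, modulation varies with y
    rowmod <- sin(2 * pi * yc[rows] / cfg$row_spacing)
    f_px <- pmin(pmax(f * (1 + cfg$row_amp * (1 - f) * rowmod), 0), 1)
    f_px <- matrix(f_px, length(rows), length(cols))
    sdlog <- cfg$speckle_sd * (1 - cfg$speckle_closure * f_px * (1 - s))
    for (b in BAND_NAMES) {
      leaf <- em["leaf", b]
      if (b %in% c("RED", "REDEDGE"))
        leaf <- max(leaf * (1 - cfg$chl_absorb * (ci - 1)), 0.005)
      val <- f_px * ((1 - s) * leaf + s * em["senesced", b]) +
        (1 - f_px) * em["soil", b]
      val <- val * exp(matrix(rnorm(length(val), 0, 1), nrow(val)) * sdlog)
      bands[[b]][rows, cols] <- val
    }
  }
  scene(trial$flight_dates[t], bands, cfg$gsd, origin, cfg$year)
}

#' Write a simulated trial to disk in the pipeline's input formats
#'
#' Scenes as float TIFF + JSON sidecars under \code{scenes/}, plots as
#' GeoJSON, weather/yield/phenology/ground-truth CSVs.
#'
#' @param trial A \code{sim_trial} with rendered scenes.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_trial <- function(trial, dir) {
  if (is.null(trial$scenes)) stop("trial has no rendered scenes")
  dir.create(file.path(dir, "scenes"), recursive = TRUE, showWarnings = FALSE)
  for (s in trial$scenes)
    write_scene(s, file.path(dir, "scenes",
                             paste0("scene_", format(s$date), ".tif")))
  write_plots_geojson(trial$plots, file.path(dir, "plots.geojson"))
  write.csv(trial$weather, file.path(dir, "weather.csv"), row.names = FALSE)
  write.csv(trial$yields, file.path(dir, "yield.csv"), row.names = FALSE)
  write.csv(trial$phenology, file.path(dir, "phenology.csv"),
            row.names = FALSE)
  write.csv(trial$truth, file.path(dir, "truth_synthetic.csv"),
            row.names = FALSE)
  invisible(dir)
}
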