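#' Run configuration for the end-to-end experiment
#'
#' @param scenes_dir Directory of scene TIFFs (+ JSON sidecars).
#' @param plots_file GeoJSON plot file.
#' @param weather_file,yield_file,phenology_file Input CSVs.
#' @param out_dir Optional output directory for result CSVs.
#' @param sowing Sowing date (thermal-time origin).
#' @param base_t Base temperature, deg C.
#' @param texture A \code{\link{texture_config}}.
#' @param cv A \code{\link{cv_config}} (its seed is the run's master seed).
#' @param smoothing_sp Optional fixed spline smoothing parameter.
#' @param window_width Moving-window width (odd).
#' @param tasks Subset of \code{c("regression", "classification")}.
#' @param year Year tag.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(scenes_dir = NULL, plots_file = NULL,
                       weather_file = NULL, yield_file = NULL,
                       phenology_file = NULL, out_dir = NULL,
                       sowing, base_t = 0,
                       texture = texture_config(), cv = cv_config(),
                       smoothing_sp = NULL, window_width = 3,
                       tasks = c("regression", "classification"),
                       year = NULL) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  structure(list(scenes_dir = scenes_dir, plots_file = plots_file,
                 weather_file = weather_file, yield_file = yield_file,
                 phenology_file = phenology_file, out_dir = out_dir,
                 sowing = as.Date(sowing), base_t = base_t,
                 texture = texture, cv = cv, smoothing_sp = smoothing_sp,
                 window_width = window_width, tasks = tasks, year = year),
            class = "run_config")
}

#' Load and validate pipeline inputs
#'
#' Reads scenes (sorted by date), plots, weather, yields and phenology;
#' validates that every plot has a yield record and overlaps every scene's
#' extent. Fails fast naming the offender.
#'
#' @param cfg A \code{\link{run_config}} with file paths set.
#' @return List \code{scenes, plots, weather, yields, phenology}.
#' @export
load_inputs <- function(cfg) {
  for (p in c(cfg$plots_file, cfg$weather_file, cfg$yield_file))
    if (!file.exists(p)) stop("input file not found: ", p)
  tifs <- list.files(cfg$scenes_dir, pattern = "\\.tif$", full.names = TRUE)
  if (!length(tifs)) stop("no scene TIFFs in ", cfg$scenes_dir)
  scenes <- lapply(tifs, read_scene)
  scenes <- scenes[order(vapply(scenes, function(s) as.numeric(s$date),
                                numeric(1)))]
  plots <- read_plots_geojson(cfg$plots_file)
  weather <- read_weather_csv(cfg$weather_file)
  yields <- read_yield_csv(cfg$yield_file)
  miss <- setdiff(vapply(plots, function(p) p$plot_id, character(1)),
                  yields$plot_id)
  if (length(miss))
    stop("yield table missing plot id(s): ", paste(miss, collapse = ", "))
  for (s in scenes) {
    d <- dim(s$bands[[1]])
    xr <- c(s$origin[1], s$origin[1] + d[2] * s$gsd)
    yr <- c(s$origin[2] - d[1] * s$gsd, s$origin[2])
    for (p in plots) {
      px <- range(p$polygon[, 1]); py <- range(p$polygon[, 2])
      if (px[1] < xr[1] - 1e-9 || px[2] > xr[2] + 1e-9 ||
          py[1] < yr[1] - 1e-9 || py[2] > yr[2] + 1e-9)
        stop("plot ", p$plot_id, " outside scene extent on ",
             format(s$date))
    }
  }
  phenology <- if (!is.null(cfg$phenology_file) &&
                   file.exists(cfg$phenology_file))
    read.csv(cfg$phenology_file, stringsAsFactors = FALSE) else NULL
  if (!is.null(phenology)) phenology$date <- as.Date(phenology$date)
  list(scenes = scenes, plots = plots, weather = weather, yields = yields,
       phenology = phenology)
}

#' Map a BBCH rating to a phenology-stage label
#'
#' Decade binning: 20-29 tillering (TI), 30-39 stem elongation (SE), 40-49
#' booting (BO), 50-59 heading (HE), 60-69 flowering (FL), 70-79 early
#' grain filling (EF), 80-99 grain filling/ripening (GF); below 20
#' pre-tillering (PRE).
#'
#' @param bbch Numeric BBCH rating(s), 0-99.
#' @return Character stage label(s).
#' @export
stage_of_bbch <- function(bbch) {
  if (any(is.na(bbch)) || any(bbch < 0 | bbch > 99))
    stop("BBCH ratings must lie in 0-99")
  cut(bbch, c(-1, 19, 29, 39, 49, 59, 69, 79, 99),
      labels = c("PRE", "TI", "SE", "BO", "HE", "FL", "EF", "GF")) |>
    as.character()
}

#' Phenology stage of a plot at a date
#'
#' Looks up the BBCH rating in a phenology table (columns \code{plot_id},
#' \code{date}, \code{bbch}) and maps it through
#' \code{\link{stage_of_bbch}}.
#'
#' @param phenology Phenology table.
#' @param plot_id Plot identifier.
#' @param date Date.
#' @return Stage label.
#' @export
stage_of_gdd <- function(phenology, plot_id, date) {
  row <- phenology[phenology$plot_id == plot_id &
                     phenology$date == as.Date(date), ]
  if (!nrow(row)) stop("phenology track does not cover plot ", plot_id,
                       " on ", format(date))
  stage_of_bbch(row$bbch[1])
}

# stage label at a date by the median BBCH across plots
stage_of_date <- function(phenology, date) {
  sub <- phenology[phenology$date == as.Date(date), ]
  if (!nrow(sub)) return(NA_character_)
  stage_of_bbch(round(median(sub$bbch)))
}

#' Run the full feature x date x strategy x task experiment
#'
#' The end-to-end sweep: thermal axis, feature extraction (15 features),
#' spline smoothing, the three temporal assembly strategies, random-forest
#' CV evaluation for every combination, per-date correlation matrices and
#' H-vs-L Welch t-tests, and a per-feature summary (season-mean and
#' season-best metric with the phenology stage of the best date). All
#' randomness derives from \code{cfg$cv$seed}; re-running with the same
#' inputs and seed reproduces every number.
#'
#' @param inputs Either the list returned by \code{\link{load_inputs}} or a
#'   \code{sim_trial} (its scenes, plots, weather, yields and phenology are
#'   used directly).
#' @param cfg A \code{\link{run_config}} (paths may be NULL when
#'   \code{inputs} is in memory).
#' @return A \code{uav_experiment}: list with \code{features} (the
#'   single-date and smoothed feature tables), \code{results} (one row per
#'   feature x date x strategy x task), \code{correlations},
#'   \code{ttests}, \code{summary} and \code{manifest}. Result CSVs are
#'   written when \code{cfg$out_dir} is set.
#' @export
run_experiment <- function(inputs, cfg) {
  t0 <- Sys.time()
  if (inherits(inputs, "sim_trial")) {
    scenes <- inputs$scenes
    if (is.null(scenes)) stop("sim_trial has no rendered scenes")
    plots <- inputs$plots
    weather <- inputs$weather
    yields <- inputs$yields
    phenology <- inputs$phenology
  } else {
    scenes <- inputs$scenes; plots <- inputs$plots
    weather <- inputs$weather; yields <- inputs$yields
    phenology <- inputs$phenology
  }
  last_date <- max(as.Date(vapply(scenes, function(s) format(s$date),
                                  character(1))))
  axis <- cumulative_gdd(weather, cfg$sowing, last_date,
                         base_t = cfg$base_t)
  table <- build_feature_table(scenes, plots, axis, cfg$texture)
  table$strategy <- "single"
  smoothed <- smooth_feature_table(table, sp = cfg$smoothing_sp)
  smoothed$strategy <- "smoothed"
  dates <- sort(unique(table$date))
  feats <- unique(table$feature)

  yvec <- setNames(yields$yield_g_m2, yields$plot_id)
  if (!"group" %in% names(yields)) {
    vm <- aggregate(yield_g_m2 ~ variety, yields, mean)
    gr <- assign_yield_groups(
      data.frame(variety = vm$variety, mean_yield = vm$yield_g_m2))
    yields$group <- gr$group[match(yields$variety, gr$variety)]
  }
  labeled <- yields[yields$group %in% c("L", "H"), ]
  lvec <- setNames(labeled$group, labeled$plot_id)

  strategies <- c("single", "smoothed", "window")
  res <- list(); ri <- 0
  combo <- 0
  for (task in cfg$tasks) {
    for (strat in strategies) {
      for (f in feats) {
        for (di in seq_along(dates)) {
          combo <- combo + 1
          dm <- switch(strat,
            single = single_date_matrix(table, f, dates[di]),
            smoothed = {
              m <- single_date_matrix(smoothed, f, dates[di])
              m$strategy <- "smoothed"; m
            },
            window = moving_window_matrix(table, f, di,
                                          width = cfg$window_width))
          cvc <- cfg$cv
          cvc$seed <- cfg$cv$seed + combo # per-combination sub-stream
          row <- if (task == "regression") {
            er <- cv_rf_regression(dm, yvec, cvc)
            data.frame(task = task, feature = f, strategy = strat,
                       date = dates[di], gdd = er$gdd, n = er$n,
                       mtry = er$mtry, metric = "rmse",
                       mean = er$mean_rmse, sd = sd(er$folds$rmse),
                       mean_r2 = er$mean_r2,
                       n_folds = nrow(er$folds), seed = cvc$seed)
          } else {
            dml <- dm
            keep <- dml$plot_id %in% names(lvec)
            dml$X <- dml$X[keep, , drop = FALSE]
            dml$plot_id <- dml$plot_id[keep]
            er <- cv_rf_classification(dml, lvec, cvc)
            data.frame(task = task, feature = f, strategy = strat,
                       date = dates[di], gdd = er$gdd, n = er$n,
                       mtry = er$mtry, metric = "accuracy",
                       mean = er$mean_accuracy, sd = sd(er$folds$accuracy),
                       mean_r2 = NA_real_,
                       n_folds = nrow(er$folds), seed = cvc$seed)
          }
          ri <- ri + 1
          res[[ri]] <- row
        }
      }
    }
  }
  results <- do.call(rbind, res)

  correlations <- lapply(dates, function(d)
    correlation_matrix(table, d, yvec))
  names(correlations) <- format(dates)

  tt <- list(); ti <- 0
  for (f in feats) for (d in dates) {
    sub <- table[table$feature == f & table$date == d, ]
    vh <- sub$value[sub$plot_id %in% labeled$plot_id[labeled$group == "H"]]
    vl <- sub$value[sub$plot_id %in% labeled$plot_id[labeled$group == "L"]]
    vh <- vh[!is.na(vh)]; vl <- vl[!is.na(vl)]
    if (length(vh) >= 2 && length(vl) >= 2) {
      w <- group_ttest(vh, vl)
      ti <- ti + 1
      tt[[ti]] <- data.frame(feature = f, date = d, t = w$t, p = w$p)
    }
  }
  ttests <- do.call(rbind, tt)

  # summary: season-mean and season-best metric per feature x strategy x task
  summ <- do.call(rbind, lapply(split(results,
      list(results$task, results$strategy, results$feature), drop = TRUE),
    function(g) {
      best <- if (g$metric[1] == "rmse") which.min(g$mean)
              else which.max(g$mean)
      stage <- if (!is.null(phenology))
        stage_of_date(phenology, g$date[best]) else NA_character_
      data.frame(task = g$task[1], feature = g$feature[1],
                 strategy = g$strategy[1], metric = g$metric[1],
                 season_mean = mean(g$mean), best = g$mean[best],
                 best_date = g$date[best], best_gdd = g$gdd[best],
                 best_stage = stage)
    }))
  rownames(summ) <- NULL

  manifest <- list(
    seed = cfg$cv$seed,
    config_hash = config_hash(cfg),
    n_scenes = length(scenes), n_plots = length(plots),
    n_features = length(feats), n_dates = length(dates),
    n_results = nrow(results),
    warnings = NA_integer_,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- structure(list(features = rbind(table, smoothed),
                        results = results, correlations = correlations,
                        ttests = ttests, summary = summ,
                        manifest = manifest),
                   class = "uav_experiment")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(cfg$out_dir, "results.csv"),
              row.names = FALSE)
    write.csv(summ, file.path(cfg$out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(ttests, file.path(cfg$out_dir, "ttests.csv"),
              row.names = FALSE)
    write_feature_table(out$features,
                        file.path(cfg$out_dir, "features.csv"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.uav_experiment <- function(x, ...) {
  cat(sprintf(paste0("<uav_experiment> %d result rows (%d features x %d ",
                     "dates x strategies x tasks), seed %d\n"),
              nrow(x$results), x$manifest$n_features, x$manifest$n_dates,
              x$manifest$seed))
  invisible(x)
}

# stable hash of a config: canonical (key-sorted) JSON -> md5
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  plain <- canon(rapply(unclass(cfg), function(v)
    if (inherits(v, "Date")) format(v) else v, how = "replace"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Metric-vs-thermal-time curves
#'
#' Plots the per-date mean CV metric of selected features for one task and
#' strategy against GDD (base graphics), one line per feature.
#'
#' @param experiment A \code{uav_experiment}.
#' @param task \code{"regression"} or \code{"classification"}.
#' @param strategy \code{"single"}, \code{"smoothed"} or \code{"window"}.
#' @param features Features to draw (default: all present).
#' @return Invisibly, the plotted subset of the results table.
#' @export
plot_metric_curves <- function(experiment, task = "regression",
                               strategy = "single", features = NULL) {
  r <- experiment$results
  r <- r[r$task == task & r$strategy == strategy, ]
  if (!is.null(features)) r <- r[r$feature %in% features, ]
  if (!nrow(r)) stop("no results for this task/strategy")
  feats <- unique(r$feature)
  cols <- grDevices::hcl.colors(length(feats), "Dark 3")
  ylab <- if (r$metric[1] == "rmse") "CV RMSE (g/m2)" else "CV accuracy"
  graphics::plot(range(r$gdd), range(r$mean), type = "n",
                 xlab = "GDD (deg C day)", ylab = ylab,
                 main = paste(task, "-", strategy))
  for (i in seq_along(feats)) {
    g <- r[r$feature == feats[i], ]
    g <- g[order(g$gdd), ]
    graphics::lines(g$gdd, g$mean, col = cols[i])
  }
  graphics::legend("topright", legend = feats, col = cols, lty = 1,
                   cex = 0.6, ncol = 2)
  invisible(r)
}
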