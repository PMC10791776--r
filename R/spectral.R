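#' Zonal median reflectance of a plot
#'
#' Median over the valid (non-nodata) pixels of one band whose centers fall
#' inside the plot polygon (on-edge centers count as inside). With an even
#' pixel count the mean of the two middle values is returned (the
#' \code{stats::median} convention).
#'
#' @param scn A \code{\link{scene}}.
#' @param roi A \code{\link{plot_roi}}.
#' @param band Canonical band name.
#' @return Median reflectance, or \code{NA} (with a warning) when the ROI
#'   contains no valid pixel.
#' @export
zonal_median <- function(scn, roi, band) {
  v <- roi_pixels(scn, roi, band)
  if (!length(v)) {
    warning("no valid ", band, " pixels for plot ", roi$plot_id,
            " on ", format(scn$date))
    return(NA_real_)
  }
  median(v)
}

#' Zonal coefficient of variation of a plot
#'
#' Sample standard deviation (n-1 denominator) divided by the mean of the
#' valid in-ROI pixel values; dimensionless. Used for contrast-based
#' selection of the texture base band.
#'
#' @inheritParams zonal_median
#' @return CV, or \code{NA} when fewer than 2 valid pixels or zero mean.
#' @export
zonal_cv <- function(scn, roi, band) {
  v <- roi_pixels(scn, roi, band)
  if (length(v) < 2) return(NA_real_)
  m <- mean(v)
  if (m == 0) return(NA_real_)
  sd(v) / m
}

#' Vegetation indices from band reflectances
#'
#' Computes one of the five pipeline indices from (plot-median) band
#' reflectances:
#' \itemize{
#'   \item DVI = NIR - Red
#'   \item RVI = NIR / Red
#'   \item NDRE = (NIR - Rededge) / (NIR + Rededge)
#'   \item MCARI = ((Rededge - Red) - 0.2 (Rededge - Green)) (Rededge / Red)
#'   \item CCII = TCARI / OSAVI with
#'     TCARI = 3 ((Rededge - Red) - 0.2 (Rededge - Green) (Rededge / Red))
#'     and, in the default \code{"paper"} variant,
#'     OSAVI = (1 + 1.16) (NIR - Red) / (NIR + Rededge + 0.16).
#' }
#' The \code{"standard"} OSAVI variant uses the canonical
#' (1 + 0.16) (NIR - Red) / (NIR + Red + 0.16).
#'
#' Indices are computed median-first: extract plot-median band values, then
#' apply the formula.
#'
#' @param name One of \code{"DVI","RVI","NDRE","MCARI","CCII"} (also
#'   \code{"TCARI"}, \code{"OSAVI"} for the CCII components).
#' @param green,red,rededge,nir Band reflectances (vectors allowed).
#' @param osavi_variant \code{"paper"} (default) or \code{"standard"}.
#' @return Index value(s); \code{NA} with a warning on zero denominators.
#' @export
#' @examples
#' compute_vegetation_index("NDRE", nir = 0.4, rededge = 0.2) # 1/3
compute_vegetation_index <- function(name, green = NA, red = NA,
                                     rededge = NA, nir = NA,
                                     osavi_variant = c("paper", "standard")) {
  osavi_variant <- match.arg(osavi_variant)
  name <- toupper(name)
  guard <- function(num, den, what) {
    bad <- !is.na(den) & den == 0
    if (any(bad)) warning("zero denominator in ", what)
    out <- num / den
    out[bad] <- NA_real_
    out
  }
  tcari <- function() 3 * ((rededge - red) -
                           0.2 * (rededge - green) * guard(rededge, red, "TCARI"))
  osavi <- function() {
    if (osavi_variant == "paper")
      (1 + 1.16) * (nir - red) / (nir + rededge + 0.16)
    else
      (1 + 0.16) * (nir - red) / (nir + red + 0.16)
  }
  switch(name,
    DVI = nir - red,
    RVI = guard(nir, red, "RVI"),
    NDRE = guard(nir - rededge, nir + rededge, "NDRE"),
    MCARI = ((rededge - red) - 0.2 * (rededge - green)) *
      guard(rededge, red, "MCARI"),
    TCARI = tcari(),
    OSAVI = osavi(),
    CCII = guard(tcari(), osavi(), "CCII"),
    stop("unknown vegetation index: ", name)
  )
}

#' Aggregate a raster to a coarser GSD by area-weighted averaging
#'
#' Each output pixel is the area-weighted mean of the valid input pixels it
#' overlaps; output pixels whose contributors are all nodata become nodata.
#' Non-integer GSD ratios are handled by exact 1-D overlap weights (the
#' operation is separable). Upsampling is refused.
#'
#' @param scn A \code{\link{scene}}.
#' @param target_gsd Target ground sampling distance, m/pixel
#'   (>= the scene's).
#' @return A new \code{uav_scene} at \code{target_gsd} with the same origin.
#' @export
resample_average <- function(scn, target_gsd) {
  g <- scn$gsd
  if (target_gsd < g - 1e-12) stop("upsampling requested (target_gsd < gsd)")
  if (abs(target_gsd - g) < 1e-12) return(scn)
  d <- dim(scn$bands[[1]])
  wr <- overlap_weights(d[1], g, target_gsd)
  wc <- overlap_weights(d[2], g, target_gsd)
  bands <- lapply(scn$bands, function(m) {
    v <- !is.na(m)
    m0 <- m; m0[!v] <- 0
    num <- wr %*% m0 %*% t(wc)
    den <- wr %*% (v + 0) %*% t(wc)
    out <- num / den
    out[den < 1e-12] <- NA_real_
    out
  })
  scene(scn$date, bands, target_gsd, scn$origin, scn$year)
}

# 1-D overlap-length matrix (n_out x n_in) between input cells of size g
# and output cells of size tg sharing the same origin.
overlap_weights <- function(n_in, g, tg) {
  n_out <- ceiling(n_in * g / tg - 1e-9)
  w <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    lo <- (o - 1) * tg; hi <- o * tg
    i0 <- max(1L, floor(lo / g) + 1L)
    i1 <- min(n_in, ceiling(hi / g + 1e-12))
    for (i in i0:i1) {
      ov <- min(hi, i * g) - max(lo, (i - 1) * g)
      if (ov > 1e-12) w[o, i] <- ov
    }
  }
  w
}

#' Extract the full plot-by-date feature table
#'
#' For every scene x plot: the five band medians, the five vegetation
#' indices computed from those medians (median-first convention), and the
#' five GLCM texture features (ROI mean of the per-pixel texture rasters on
#' the configured base band). The thermal axis attaches cumulative GDD per
#' flight date. Plots without valid pixels in a scene yield missing-flagged
#' records and a warning, not an error.
#'
#' @param scenes List of \code{\link{scene}}.
#' @param plots List of \code{\link{plot_roi}}.
#' @param thermal Optional \code{thermal_axis} for the GDD column.
#' @param texture_cfg A \code{\link{texture_config}}.
#' @param feature_groups Any of \code{"bands"}, \code{"vi"},
#'   \code{"texture"}; restricting groups skips their computation.
#' @param osavi_variant Passed to \code{\link{compute_vegetation_index}}.
#' @return A \code{feature_table}: long data frame with columns
#'   \code{plot_id, date, gdd, feature, value}.
#' @export
build_feature_table <- function(scenes, plots, thermal = NULL,
                                texture_cfg = texture_config(),
                                feature_groups = c("bands", "vi", "texture"),
                                osavi_variant = "paper") {
  feature_groups <- match.arg(feature_groups, several.ok = TRUE)
  rows <- vector("list", length(scenes))
  for (si in seq_along(scenes)) {
    scn <- scenes[[si]]
    gdd <- if (is.null(thermal)) NA_real_ else gdd_at(thermal, scn$date)
    tex <- NULL
    if ("texture" %in% feature_groups)
      tex <- texture_feature_rasters(scn$bands[[texture_cfg$band]],
                                     cfg = texture_cfg)
    per_plot <- lapply(plots, function(p) {
      med <- setNames(rep(NA_real_, 5), BAND_NAMES)
      if (any(c("bands", "vi") %in% feature_groups))
        med <- vapply(BAND_NAMES, function(b)
          suppressWarnings(zonal_median(scn, p, b)), numeric(1))
      if (all(is.na(med)) && any(c("bands", "vi") %in% feature_groups))
        warning("plot ", p$plot_id, " has no valid pixels on ",
                format(scn$date))
      vals <- c()
      if ("bands" %in% feature_groups) vals <- c(vals, med)
      if ("vi" %in% feature_groups) {
        vi <- vapply(VI_NAMES, function(ix) suppressWarnings(
          compute_vegetation_index(ix, green = med["GREEN"], red = med["RED"],
                                   rededge = med["REDEDGE"], nir = med["NIR"],
                                   osavi_variant = osavi_variant)),
          numeric(1))
        vals <- c(vals, vi)
      }
      if ("texture" %in% feature_groups) {
        tx <- vapply(TEXTURE_NAMES, function(f) {
          fr <- scene_like(scn, tex[[f]])
          suppressWarnings(zonal_texture_mean(fr, p))
        }, numeric(1))
        vals <- c(vals, tx)
      }
      data.frame(plot_id = p$plot_id, date = scn$date, gdd = gdd,
                 feature = names(vals), value = unname(vals),
                 stringsAsFactors = FALSE)
    })
    rows[[si]] <- do.call(rbind, per_plot)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

# wrap a single feature matrix in the geometry of an existing scene
scene_like <- function(scn, m) {
  s <- scn
  s$bands <- list(FEAT = m)
  names(s$bands) <- "FEAT"
  class(s) <- "uav_scene"
  s
}

#' Write / read a feature table CSV
#'
#' Long format \code{plot_id,date,gdd,feature,value}; empty value = missing.
#' An optional \code{strategy} column tags temporal processing.
#'
#' @param table A \code{feature_table}.
#' @param path CSV path.
#' @return \code{read_feature_table}: a \code{feature_table}.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  t <- read.csv(path, stringsAsFactors = FALSE)
  t$date <- as.Date(t$date)
  class(t) <- c("feature_table", "data.frame")
  t
}
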