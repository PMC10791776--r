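#' Texture configuration
#'
#' Defaults follow the pipeline's GLCM setup: 5 x 5 kernel, 32 gray levels
#' spanning the raster's 1st-99th percentile, offset distance 1, directions
#' 0/45/90 degrees averaged per feature, computed on the RED band.
#'
#' @param kernel Odd sliding-window size in pixels.
#' @param levels Number of quantization levels N.
#' @param p_lo,p_hi Clip percentiles (0-100) for quantization.
#' @param angles Directions in degrees, subset of \{0, 45, 90\}.
#' @param distance Co-occurrence offset distance in pixels.
#' @param band Base band for texture computation.
#' @param angle_mode \code{"mean_features"} (average the per-direction
#'   feature values) or \code{"pooled"} (pool co-occurrence counts over
#'   directions, then compute features once).
#' @return A list of class \code{texture_config}.
#' @export
texture_config <- function(kernel = 5, levels = 32, p_lo = 1, p_hi = 99,
                           angles = c(0, 45, 90), distance = 1,
                           band = "RED",
                           angle_mode = c("mean_features", "pooled")) {
  angle_mode <- match.arg(angle_mode)
  stopifnot(kernel >= 3, kernel %% 2 == 1, levels >= 2,
            p_lo >= 0, p_hi <= 100, p_lo < p_hi,
            all(angles %in% c(0, 45, 90)), distance >= 1)
  structure(list(kernel = as.integer(kernel), levels = as.integer(levels),
                 p_lo = p_lo, p_hi = p_hi, angles = angles,
                 distance = as.integer(distance), band = band,
                 angle_mode = angle_mode),
            class = "texture_config")
}

#' Percentile-clipped gray-level quantization
#'
#' Clips the raster to its [p_lo, p_hi] percentiles (linear-interpolation
#' quantiles over all valid pixels), then bins linearly into \code{levels}
#' equal-width levels 0..N-1; the top edge maps to N-1. A constant raster
#' (degenerate percentile range) quantizes to all zeros. Nodata propagates.
#'
#' @param m Numeric matrix (NA = nodata).
#' @param levels Number of levels N (>= 2).
#' @param p_lo,p_hi Clip percentiles, 0-100.
#' @return Integer matrix of levels with attributes \code{levels},
#'   \code{p_lo}, \code{p_hi}, \code{clip} (the clip values).
#' @export
percentile_quantize <- function(m, levels = 32, p_lo = 1, p_hi = 99) {
  v <- m[!is.na(m)]
  if (!length(v)) stop("all-nodata raster cannot be quantized")
  cl <- unname(quantile(v, c(p_lo, p_hi) / 100, type = 7))
  q <- matrix(NA_integer_, nrow(m), ncol(m))
  ok <- !is.na(m)
  if (diff(cl) <= 0) {
    q[ok] <- 0L
  } else {
    x <- pmin(pmax(m[ok], cl[1]), cl[2])
    lev <- floor((x - cl[1]) / (cl[2] - cl[1]) * levels)
    lev[lev >= levels] <- levels - 1L # top edge
    q[ok] <- as.integer(lev)
  }
  structure(q, levels = levels, p_lo = p_lo, p_hi = p_hi, clip = cl)
}

# direction -> (drow, dcol) offset at distance d; image row 1 is the top
angle_offset <- function(angle, d = 1) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         stop("unsupported GLCM direction: ", angle))
}

#' GLCM of a single quantized window
#'
#' Counts all pixel pairs inside the window at the offset implied by the
#' direction (0 deg -> (0,+1), 45 deg -> (-1,+1), 90 deg -> (-1,0), scaled
#' by \code{distance}), accumulated symmetrically (each pair in both
#' orders), then normalized to sum 1.
#'
#' @param window Integer matrix of quantized levels, no nodata.
#' @param levels Number of levels N (default: max level + 1).
#' @param angle Direction in degrees: 0, 45 or 90.
#' @param distance Offset distance in pixels.
#' @return N x N matrix P with \code{sum(P) == 1}, symmetric.
#' @export
glcm_from_window <- function(window, levels = max(window) + 1L, angle = 0,
                             distance = 1) {
  if (anyNA(window)) stop("window contains nodata")
  off <- angle_offset(angle, distance)
  nr <- nrow(window); nc <- ncol(window)
  P <- matrix(0, levels, levels)
  for (r in seq_len(nr)) {
    r2 <- r + off[1]
    if (r2 < 1 || r2 > nr) next
    for (c in seq_len(nc)) {
      c2 <- c + off[2]
      if (c2 < 1 || c2 > nc) next
      i <- window[r, c] + 1L; j <- window[r2, c2] + 1L
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
  }
  s <- sum(P)
  if (s == 0) stop("window too small for the requested offset")
  P / s
}

#' Haralick features of a normalized GLCM
#'
#' \itemize{
#'   \item CONTRAST = sum P_ij (i-j)^2
#'   \item CORRELATION = sum P_ij (i-mu)(j-mu) / sigma^2, with mu and
#'     sigma^2 the (identical, by symmetry) marginal mean and variance;
#'     defined as 0 when sigma^2 = 0 (single-level window)
#'   \item DISSIMILARITY = sum P_ij |i-j|
#'   \item ENERGY = sum P_ij^2
#'   \item HOMOGENEITY = sum P_ij / (1 + (i-j)^2)
#' }
#' Indices i, j run over 0..N-1.
#'
#' @param P Normalized (sum 1) GLCM matrix.
#' @return Named numeric vector \code{CON, COR, DIS, ENE, HOM}.
#' @export
haralick_features <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM is not normalized (sum != 1)")
  n <- nrow(P)
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  pm <- rowSums(P)
  mu <- sum((0:(n - 1)) * pm)
  v <- sum((0:(n - 1) - mu)^2 * pm)
  cor <- if (v > 1e-12) sum(P * (i - mu) * (j - mu)) / v else 0
  c(CON = sum(P * (i - j)^2),
    COR = cor,
    DIS = sum(P * abs(i - j)),
    ENE = sum(P^2),
    HOM = sum(P / (1 + (i - j)^2)))
}

#' Sliding-window GLCM texture rasters
#'
#' Quantizes the raster once (whole-raster percentiles), slides a
#' \code{kernel x kernel} window, builds the GLCM per direction and writes
#' the five Haralick features to the window's center pixel (averaging the
#' per-direction feature values, or pooling counts, per
#' \code{angle_mode}). Pixels without a complete all-valid window are
#' nodata.
#'
#' @param m Numeric band matrix (NA = nodata).
#' @param cfg A \code{\link{texture_config}}.
#' @return Named list of five matrices \code{CON, COR, DIS, ENE, HOM}.
#' @export
texture_feature_rasters <- function(m, cfg = texture_config()) {
  if (nrow(m) < cfg$kernel || ncol(m) < cfg$kernel)
    stop("raster smaller than the texture kernel")
  q <- percentile_quantize(m, cfg$levels, cfg$p_lo, cfg$p_hi)
  offs <- do.call(rbind, lapply(cfg$angles, angle_offset, d = cfg$distance))
  storage.mode(offs) <- "integer"
  glcm_texture_cpp(q, cfg$levels, cfg$kernel, offs,
                   cfg$angle_mode == "pooled")
}

#' ROI mean of a texture feature raster
#'
#' Arithmetic mean of the valid feature pixels whose centers fall inside
#' the plot polygon; nodata (border and incomplete-window) pixels are
#' excluded.
#'
#' @param feature_scene A single-band \code{uav_scene} holding a feature
#'   raster (see \code{\link{texture_feature_rasters}}).
#' @param roi A \code{\link{plot_roi}}.
#' @return Mean feature value, or \code{NA} with a warning when no valid
#'   pixel lies in the ROI.
#' @export
zonal_texture_mean <- function(feature_scene, roi) {
  v <- roi_pixels(feature_scene, roi, names(feature_scene$bands)[1])
  if (!length(v)) {
    warning("no valid texture pixels for plot ", roi$plot_id)
    return(NA_real_)
  }
  mean(v)
}

#' Contrast-based selection of the texture base band
#'
#' Ranks bands by the mean zonal coefficient of variation over all plots
#' and scenes (the band with the most within-plot relative variation
#' carries the most texture signal). The returned choice is the configured
#' band (default RED); the CV ranking is always reported alongside.
#'
#' @param scenes List of \code{\link{scene}}.
#' @param plots List of \code{\link{plot_roi}}.
#' @param band Configured choice to return (default \code{"RED"}).
#' @return List with \code{band} (the configured choice), \code{ranking}
#'   (band names, highest mean CV first) and \code{cv} (named mean CVs).
#' @export
select_contrast_band <- function(scenes, plots, band = "RED") {
  stopifnot(length(scenes) >= 1, length(plots) >= 1)
  bands <- Reduce(intersect, lapply(scenes, function(s) names(s$bands)))
  cv <- vapply(bands, function(b) {
    vals <- unlist(lapply(scenes, function(s)
      vapply(plots, function(p) zonal_cv(s, p, b), numeric(1))))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ranking <- names(sort(cv, decreasing = TRUE))
  list(band = band, ranking = ranking, cv = cv)
}
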