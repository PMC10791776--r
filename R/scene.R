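#' Build a multispectral scene
#'
#' A scene is one flight date's reflectance orthomosaic: named band matrices
#' on a common north-up grid. Pixel (r, c) has its center at
#' \code{x = origin[1] + (c - 0.5) * gsd}, \code{y = origin[2] - (r - 0.5) * gsd},
#' where \code{origin} is the top-left corner of the raster. Nodata pixels
#' are \code{NA}.
#'
#' @param date Flight date (Date or coercible).
#' @param bands Named list of equally sized numeric matrices; names are
#'   matched (case-insensitively, with common aliases) onto
#'   BLUE/GREEN/RED/REDEDGE/NIR.
#' @param gsd Ground sampling distance, m/pixel.
#' @param origin Numeric length 2, map coordinates of the raster's top-left
#'   corner.
#' @param year Optional year tag.
#' @return An object of class \code{uav_scene}.
#' @export
scene <- function(date, bands, gsd, origin = c(0, 0), year = NULL) {
  stopifnot(is.list(bands), length(bands) >= 1, gsd > 0)
  names(bands) <- harmonize_band_names(names(bands))
  dims <- vapply(bands, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all bands must share the same grid shape")
  for (b in names(bands)) {
    v <- bands[[b]]
    if (any(v[is.finite(v)] < 0))
      stop("negative reflectance in band ", b)
  }
  structure(list(date = as.Date(date), bands = bands, gsd = gsd,
                 origin = as.numeric(origin),
                 year = year %||% as.integer(format(as.Date(date), "%Y"))),
            class = "uav_scene")
}

# Map camera-specific band labels onto the five canonical names.
harmonize_band_names <- function(nm) {
  lut <- c(blue = "BLUE", b450 = "BLUE", b444 = "BLUE",
           green = "GREEN", g560 = "GREEN",
           red = "RED", r650 = "RED",
           rededge = "REDEDGE", red_edge = "REDEDGE", re = "REDEDGE",
           b730 = "REDEDGE", b717 = "REDEDGE",
           nir = "NIR", b840 = "NIR", b842 = "NIR")
  key <- gsub("[ -]", "_", tolower(nm))
  out <- ifelse(key %in% names(lut), lut[key], toupper(nm))
  unknown <- setdiff(out, BAND_NAMES)
  if (length(unknown))
    stop("unrecognized band name(s): ", paste(unknown, collapse = ", "))
  unname(out)
}

#' @export
print.uav_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<uav_scene> %s: %d x %d px, gsd %.4g m, bands %s\n",
              format(x$date), d[1], d[2], x$gsd,
              paste(names(x$bands), collapse = "/")))
  invisible(x)
}

#' Define a plot region of interest
#'
#' @param plot_id Plot identifier.
#' @param variety,replicate,year Plot identity attributes.
#' @param polygon Two-column matrix of (x, y) vertices in the scene's
#'   coordinate system; must not be self-intersecting.
#' @return An object of class \code{plot_roi}.
#' @export
plot_roi <- function(plot_id, variety, replicate, year, polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3)
    stop("polygon must be a (>= 3) x 2 vertex matrix")
  structure(list(plot_id = as.character(plot_id),
                 variety = as.character(variety),
                 replicate = replicate, year = year, polygon = polygon),
            class = "plot_roi")
}

# Ray-casting point-in-polygon, vectorized over points.
# Boundary rule: a point exactly on an edge counts as inside.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    dx <- xj - xi; dy <- yj - yi
    scale <- max(1, abs(dx) + abs(dy))
    cross <- (px - xi) * dy - (py - yi) * dx
    on <- abs(cross) <= 1e-9 * scale &
      px >= min(xi, xj) - 1e-9 & px <= max(xi, xj) + 1e-9 &
      py >= min(yi, yj) - 1e-9 & py <= max(yi, yj) + 1e-9
    onedge <- onedge | on
    crosses <- ((yi > py) != (yj > py)) &
      (px < xi + (py - yi) * dx / ifelse(dy == 0, Inf, dy))
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | onedge
}

#' Pixel values of one band inside a plot polygon
#'
#' Returns the values of all pixels whose centers fall inside the ROI
#' polygon (center rule; on-edge centers count as inside). Nodata pixels
#' are dropped unless \code{keep_na = TRUE}.
#'
#' @param scn A \code{\link{scene}}.
#' @param roi A \code{\link{plot_roi}}.
#' @param band Canonical band name.
#' @param keep_na Keep NA (nodata) pixel values.
#' @return Numeric vector (possibly empty).
#' @export
roi_pixels <- function(scn, roi, band, keep_na = FALSE) {
  if (!band %in% names(scn$bands))
    stop("band ", band, " not present in scene ", format(scn$date))
  m <- scn$bands[[band]]
  nr <- nrow(m); nc <- ncol(m)
  g <- scn$gsd; o <- scn$origin
  poly <- roi$polygon
  # restrict to the polygon's bounding box in pixel space
  cmin <- max(1L, floor((min(poly[, 1]) - o[1]) / g - 0.5) + 1L)
  cmax <- min(nc, ceiling((max(poly[, 1]) - o[1]) / g + 0.5))
  rmin <- max(1L, floor((o[2] - max(poly[, 2])) / g - 0.5) + 1L)
  rmax <- min(nr, ceiling((o[2] - min(poly[, 2])) / g + 0.5))
  if (cmin > cmax || rmin > rmax) return(numeric(0))
  cc <- rep(cmin:cmax, each = rmax - rmin + 1L)
  rr <- rep(rmin:rmax, times = cmax - cmin + 1L)
  px <- o[1] + (cc - 0.5) * g
  py <- o[2] - (rr - 0.5) * g
  keep <- point_in_polygon(px, py, poly)
  vals <- m[cbind(rr[keep], cc[keep])]
  if (keep_na) vals else vals[!is.na(vals)]
}

#' Write / read a scene as TIFF + JSON sidecar
#'
#' Bands are stored as a multi-page 32-bit TIFF. TIFF samples live in
#' [0, 1], so each band is affinely rescaled into [0, 0.99] (about 2e-10
#' resolution at reflectance scale) with the per-band offset/span recorded
#' in the JSON sidecar \code{<path>.json}, together with the geotransform,
#' band names and date. Nodata is a sentinel near 1 and maps back to
#' \code{NA}.
#'
#' @param scn A \code{uav_scene}.
#' @param path Output TIFF path.
#' @return \code{write_scene}: the path, invisibly. \code{read_scene}: a
#'   \code{uav_scene}.
#' @export
write_scene <- function(scn, path) {
  offs <- numeric(0); spans <- numeric(0)
  pages <- lapply(scn$bands, function(m) {
    v <- m[is.finite(m)]
    off <- if (length(v)) min(v) else 0
    span <- if (length(v) && max(v) > off) max(v) - off else 1
    offs <<- c(offs, off); spans <<- c(spans, span)
    enc <- (m - off) / span * 0.99
    enc[!is.finite(m)] <- 0.999999
    enc
  })
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  meta <- list(date = format(scn$date), gsd = scn$gsd, origin = scn$origin,
               year = scn$year, bands = names(scn$bands),
               offset = offs, span = spans)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bands <- setNames(lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    out <- m / 0.99 * meta$span[i] + meta$offset[i]
    out[m > 0.995] <- NA_real_
    out
  }), meta$bands)
  scene(meta$date, bands, meta$gsd, meta$origin, meta$year)
}

#' Write / read plot ROIs as GeoJSON
#'
#' Plots are stored as a FeatureCollection of Polygons with properties
#' \code{plot_id, variety, replicate, year}.
#'
#' @param plots List of \code{plot_roi}.
#' @param path GeoJSON file path.
#' @return \code{write_plots_geojson}: the path, invisibly.
#'   \code{read_plots_geojson}: list of \code{plot_roi}.
#' @export
write_plots_geojson <- function(plots, path) {
  feats <- lapply(plots, function(p) {
    ring <- rbind(p$polygon, p$polygon[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(plot_id = p$plot_id, variety = p$variety,
                           replicate = p$replicate, year = p$year),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plots_geojson
#' @export
read_plots_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop(path, " is not a GeoJSON FeatureCollection")
  lapply(gj$features, function(f) {
    pr <- f$properties
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    # drop the closing vertex
    if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
    plot_roi(pr$plot_id, pr$variety, pr$replicate, pr$year, poly)
  })
}
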