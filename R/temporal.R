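#' Single-date design matrix
#'
#' One column: the feature's value at one flight date, one row per plot
#' with a non-missing value (missing plots are dropped with a warning).
#'
#' @param table A \code{feature_table}.
#' @param feature Feature name.
#' @param date Flight date.
#' @return A \code{design_matrix}: list with the numeric matrix \code{X}
#'   (rownames = plot ids), \code{plot_id}, \code{date}, \code{gdd},
#'   \code{feature} and \code{strategy = "single"}.
#' @export
single_date_matrix <- function(table, feature, date) {
  date <- as.Date(date)
  sub <- table[table$feature == feature & table$date == date, ]
  if (!nrow(sub)) stop("date ", format(date), " not present for ", feature)
  miss <- is.na(sub$value)
  if (any(miss))
    warning(sum(miss), " plot(s) missing ", feature, " on ", format(date),
            ": dropped")
  sub <- sub[!miss, ]
  if (!nrow(sub)) stop("no plot has a value for ", feature, " on ",
                       format(date))
  X <- matrix(sub$value, ncol = 1,
              dimnames = list(sub$plot_id, paste0(feature, "_t0")))
  structure(list(X = X, plot_id = sub$plot_id, date = date,
                 gdd = sub$gdd[1], feature = feature, strategy = "single"),
            class = "design_matrix")
}

#' P-spline smoothing of one feature series on the GDD axis
#'
#' Fits a penalized cubic B-spline (P-spline, second-order difference
#' penalty, one basis function per observation) to the (GDD, value)
#' observations of one plot x feature series and returns fitted values at
#' the original GDD points. The smoothing parameter is chosen by
#' generalized cross-validation unless fixed via \code{sp}. Missing values
#' are ignored in fitting and imputed in the output. Series with fewer
#' than 4 observations are returned unsmoothed with a warning.
#'
#' @param gdd Strictly increasing numeric vector of thermal times.
#' @param value Feature values (may contain NA).
#' @param sp Optional fixed smoothing parameter (\code{sp = 0} gives an
#'   unpenalized regression-spline interpolant).
#' @return Numeric vector of smoothed values on the same GDD grid.
#' @export
smooth_series <- function(gdd, value, sp = NULL) {
  stopifnot(length(gdd) == length(value), !is.unsorted(gdd, strictly = TRUE))
  ok <- !is.na(value)
  if (sum(ok) < 4) {
    warning("fewer than 4 observations: series returned unsmoothed")
    return(value)
  }
  df <- data.frame(g = gdd[ok], y = value[ok])
  k <- min(sum(ok), 40L) # one basis function per observation, capped
  fit <- mgcv::gam(y ~ s(g, k = k, bs = "ps", m = c(2, 2)), data = df,
                   method = "GCV.Cp", sp = sp)
  as.numeric(predict(fit, newdata = data.frame(g = gdd)))
}

#' Smooth every plot x feature series of a feature table
#'
#' Applies \code{\link{smooth_series}} per (plot, feature) on the GDD axis
#' and returns a feature table of the same shape with smoothed values.
#'
#' @param table A \code{feature_table} with a valid \code{gdd} column.
#' @param sp Optional fixed smoothing parameter passed through.
#' @return A \code{feature_table} with smoothed \code{value}s.
#' @export
smooth_feature_table <- function(table, sp = NULL) {
  out <- table
  key <- interaction(table$plot_id, table$feature, drop = TRUE)
  for (lev in levels(key)) {
    idx <- which(key == lev)
    idx <- idx[order(table$gdd[idx])]
    out$value[idx] <- suppressWarnings(
      smooth_series(table$gdd[idx], table$value[idx], sp = sp))
  }
  out
}

#' Moving-window design matrix
#'
#' Columns are the feature at the previous, current and following flight
#' dates (width 3 by default). At the first and last date the out-of-range
#' neighbor is clamped to the nearest existing date (column duplication),
#' so every date yields a full-width matrix; with
#' \code{drop_endpoints = TRUE} those dates return \code{NULL} instead.
#' Plots with any missing entry are dropped (complete-case).
#'
#' @param table A \code{feature_table}.
#' @param feature Feature name.
#' @param date_index Index of the center date in the sorted date vector.
#' @param width Odd window width (default 3).
#' @param drop_endpoints Drop dates whose window would be clamped.
#' @return A \code{design_matrix} with \code{strategy = "window"}, or
#'   \code{NULL} if the date is a dropped endpoint.
#' @export
moving_window_matrix <- function(table, feature, date_index, width = 3,
                                 drop_endpoints = FALSE) {
  stopifnot(width %% 2 == 1, width >= 1)
  dates <- sort(unique(table$date))
  if (!length(dates)) stop("feature table has no dates")
  if (date_index < 1 || date_index > length(dates))
    stop("date_index out of range")
  h <- (width - 1) / 2
  idx <- (date_index - h):(date_index + h)
  if (drop_endpoints && (any(idx < 1) || any(idx > length(dates))))
    return(NULL)
  idx <- pmin(pmax(idx, 1L), length(dates)) # clamp at the season edges
  sub <- table[table$feature == feature & table$date %in% dates[idx], ]
  wide <- lapply(seq_along(idx), function(i) {
    s <- sub[sub$date == dates[idx[i]], c("plot_id", "value")]
    names(s)[2] <- paste0(feature, "_t", i - 1 - h)
    s
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "plot_id"), wide)
  keep <- complete.cases(merged)
  merged <- merged[keep, ]
  if (!nrow(merged)) stop("no plot has complete data for ", feature,
                          " around date ", format(dates[date_index]))
  X <- as.matrix(merged[, -1, drop = FALSE])
  rownames(X) <- merged$plot_id
  ctr <- table[table$feature == feature & table$date == dates[date_index], ]
  structure(list(X = X, plot_id = merged$plot_id,
                 date = dates[date_index], gdd = ctr$gdd[1],
                 feature = feature, strategy = "window"),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %s @ %s (%s): %d plots x %d column(s)\n",
              x$feature, format(x$date), x$strategy, nrow(x$X), ncol(x$X)))
  invisible(x)
}
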