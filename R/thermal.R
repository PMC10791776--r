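#' Daily mean temperature above a base temperature
#'
#' Averages the hourly midpoints of maximum and minimum temperature over the
#' 24 hours of one day and subtracts the base temperature:
#' \deqn{Tmean_d = \sum_h [(maxT_{d,h} + minT_{d,h})/2 - baseT] / 24.}
#' Negative results are returned as-is unless \code{clamp = TRUE}.
#'
#' @param tmax,tmin Numeric vectors of length 24, hourly maximum and minimum
#'   temperature in degree Celsius.
#' @param base_t Base temperature in degree Celsius (default 0, the winter
#'   wheat convention).
#' @param clamp If \code{TRUE}, a negative daily mean is clamped to 0.
#' @param day Optional label used in error messages.
#' @return Daily mean temperature above base, degree Celsius.
#' @export
#' @examples
#' daily_mean_temp(rep(12, 24), rep(8, 24)) # 10
daily_mean_temp <- function(tmax, tmin, base_t = 0, clamp = FALSE, day = NULL) {
  lab <- if (is.null(day)) "" else paste0(" for day ", day)
  if (length(tmax) != 24L || length(tmin) != 24L)
    stop("need exactly 24 hourly records", lab, " (got ", length(tmax), ")")
  if (anyNA(tmax) || anyNA(tmin))
    stop("missing hourly temperatures", lab)
  if (any(tmax < tmin))
    stop("maxT < minT", lab)
  tm <- sum((tmax + tmin) / 2 - base_t) / 24
  if (clamp) max(tm, 0) else tm
}

#' Cumulative growing degree-days
#'
#' Accumulates \code{\link{daily_mean_temp}} over calendar days to build a
#' thermal-time axis \eqn{GDD = \sum_{d=1}^{n} Tmean_d}. Accumulation starts
#' at zero at \code{start} (conventionally the sowing date); each day in
#' \code{[start, end]} then contributes its daily mean.
#'
#' @param weather Data frame with columns \code{date}, \code{hour} (0-23),
#'   \code{tmax_c}, \code{tmin_c}; 24 rows per day.
#' @param start,end First and last day to accumulate (Date or coercible).
#' @param base_t Base temperature, degree Celsius.
#' @param clamp Clamp negative daily means to 0 (off by default, i.e. cold
#'   days subtract thermal time).
#' @return A \code{thermal_axis}: data frame with columns \code{date},
#'   \code{tmean} and cumulative \code{gdd}, plus attributes \code{base_t}
#'   and \code{start}. A zero-day span gives an empty axis.
#' @export
cumulative_gdd <- function(weather, start, end, base_t = 0, clamp = FALSE) {
  start <- as.Date(start); end <- as.Date(end)
  weather$date <- as.Date(weather$date)
  if (end < start) {
    ax <- data.frame(date = as.Date(character()), tmean = numeric(),
                     gdd = numeric())
    return(structure(ax, base_t = base_t, start = start,
                     class = c("thermal_axis", "data.frame")))
  }
  days <- seq(start, end, by = "day")
  have <- unique(weather$date)
  missing_days <- days[!days %in% have]
  if (length(missing_days))
    stop("weather coverage gap, missing dates: ",
         paste(format(missing_days), collapse = ", "))
  tmean <- vapply(days, function(d) {
    rec <- weather[weather$date == d, ]
    rec <- rec[order(rec$hour), ]
    daily_mean_temp(rec$tmax_c, rec$tmin_c, base_t = base_t, clamp = clamp,
                    day = format(d))
  }, numeric(1))
  ax <- data.frame(date = days, tmean = tmean, gdd = cumsum(tmean))
  structure(ax, base_t = base_t, start = start,
            class = c("thermal_axis", "data.frame"))
}

#' Look up cumulative GDD for given dates
#'
#' @param axis A \code{thermal_axis} from \code{\link{cumulative_gdd}}.
#' @param dates Dates to look up.
#' @return Numeric vector of cumulative GDD (NA for dates off the axis).
#' @export
gdd_at <- function(axis, dates) {
  axis$gdd[match(as.Date(dates), axis$date)]
}

#' Normalize grain yield to a standard moisture content
#'
#' Converts a fresh mass per area at a measured wet-basis moisture fraction
#' (mass of water / fresh mass) to the equivalent mass at a target moisture
#' (grain-trade standard 14 percent):
#' \code{mass * (1 - moisture) / (1 - target)}.
#'
#' @param fresh_mass_g_m2 Fresh grain mass per area, g/m^2.
#' @param moisture_fraction Measured wet-basis moisture, in [0, 1).
#' @param target_moisture Target moisture fraction (default 0.14).
#' @return Normalized yield, g/m^2.
#' @export
normalize_yield_moisture <- function(fresh_mass_g_m2, moisture_fraction,
                                     target_moisture = 0.14) {
  if (any(moisture_fraction < 0) || any(moisture_fraction >= 1))
    stop("moisture_fraction must be in [0, 1)")
  if (any(fresh_mass_g_m2 < 0))
    stop("negative grain mass")
  fresh_mass_g_m2 * (1 - moisture_fraction) / (1 - target_moisture)
}

#' Label low- and high-yielding varieties
#'
#' The k varieties with the lowest mean yield are labeled "L", the k with
#' the highest mean yield "H", all others "none". Ties are broken by variety
#' name (ascending) so the labeling is deterministic.
#'
#' @param variety_means Data frame with columns \code{variety} and
#'   \code{mean_yield}, or a named numeric vector.
#' @param k Number of varieties per group (default 3).
#' @return Data frame \code{variety}, \code{mean_yield}, \code{group} with
#'   \code{group} in \{"L", "H", "none"\}, in the input's variety order.
#' @export
assign_yield_groups <- function(variety_means, k = 3) {
  if (is.numeric(variety_means) && !is.null(names(variety_means)))
    variety_means <- data.frame(variety = names(variety_means),
                                mean_yield = as.numeric(variety_means))
  v <- as.character(variety_means$variety)
  m <- variety_means$mean_yield
  if (anyDuplicated(v)) stop("duplicated variety names")
  if (any(!is.finite(m))) stop("non-finite variety means")
  if (length(v) < 2 * k)
    stop("need at least ", 2 * k, " varieties, got ", length(v))
  ord <- order(m, v) # tie-break by name
  group <- rep("none", length(v))
  group[ord[seq_len(k)]] <- "L"
  group[ord[seq(length(v) - k + 1, length(v))]] <- "H"
  data.frame(variety = v, mean_yield = m, group = group,
             stringsAsFactors = FALSE)
}

#' Read an hourly weather CSV
#'
#' Expected columns: \code{date} (ISO), \code{hour} (0-23), \code{tmax_c},
#' \code{tmin_c}.
#'
#' @param path File path.
#' @return Data frame suitable for \code{\link{cumulative_gdd}}.
#' @export
read_weather_csv <- function(path) {
  w <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "hour", "tmax_c", "tmin_c")
  if (!all(need %in% names(w)))
    stop("weather CSV must have columns ", paste(need, collapse = ", "))
  w$date <- as.Date(w$date)
  if (any(w$tmax_c < w$tmin_c)) stop("weather CSV has rows with maxT < minT")
  w
}

#' Read a plot yield CSV
#'
#' Accepts either pre-normalized \code{yield_g_m2} or the pair
#' \code{fresh_mass_g_m2} + \code{moisture_fraction}, in which case yields
#' are normalized to 14 percent moisture.
#'
#' @param path File path.
#' @param target_moisture Moisture fraction used for normalization.
#' @return Data frame with at least \code{plot_id, variety, replicate, year,
#'   yield_g_m2}.
#' @export
read_yield_csv <- function(path, target_moisture = 0.14) {
  y <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "variety", "replicate", "year")
  if (!all(need %in% names(y)))
    stop("yield CSV must have columns ", paste(need, collapse = ", "))
  if (!"yield_g_m2" %in% names(y)) {
    if (!all(c("fresh_mass_g_m2", "moisture_fraction") %in% names(y)))
      stop("yield CSV needs yield_g_m2 or fresh_mass_g_m2 + moisture_fraction")
    y$yield_g_m2 <- normalize_yield_moisture(y$fresh_mass_g_m2,
                                             y$moisture_fraction,
                                             target_moisture)
  }
  y
}
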