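#' Assign sites to nominal nitrogen-deposition zones
#'
#' Deterministic geographic classification reflecting global histories of
#' atmospheric nitrogen deposition. Zones, in order of precedence:
#' \describe{
#'   \item{high}{central Europe (45-60 N, 15 W-45 E) plus the eastern USA
#'     (23.5-50 N, 100-60 W).}
#'   \item{mid}{mainly eastern Asia (0-45 N, 70-150 E).}
#'   \item{low_south}{the Southern Hemisphere (lat < 0).}
#'   \item{low_north}{remaining Northern-Hemisphere sites: western North
#'     America (lon < -100), the boreal zone (> 50 N in North America,
#'     > 60 N elsewhere). Northern-Hemisphere sites outside all of the above
#'     are also labelled low_north, with a warning, since the nominal zones
#'     do not close the partition.}
#' }
#' Box edges are inclusive at the lower bound and exclusive at the upper;
#' west longitudes and south latitudes are negative.
#'
#' @param lat Latitude, decimal degrees N, in \[-90, 90\].
#' @param lon Longitude, decimal degrees E, in \[-180, 180\].
#' @param quiet Suppress the unclassified-site warning.
#' @return Character vector with values in
#'   `c("high", "mid", "low_north", "low_south")`.
#' @examples
#' assign_zone(50, 10)    # "high"  (central Europe)
#' assign_zone(30, 110)   # "mid"   (eastern Asia)
#' assign_zone(-35, 150)  # "low_south"
#' @export
assign_zone <- function(lat, lon, quiet = FALSE) {
  check_finite(lat, "lat")
  check_finite(lon, "lon")
  if (any(lat < -90 | lat > 90)) stop("'lat' outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("'lon' outside [-180, 180]")
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  in_box <- function(lat0, lat1, lon0, lon1)
    lat >= lat0 & lat < lat1 & lon >= lon0 & lon < lon1
  high <- in_box(45, 60, -15, 45) | in_box(23.5, 50, -100, -60)
  mid <- in_box(0, 45, 70, 150)
  south <- lat < 0
  # North America taken as lon in [-170, -50) for the boreal/western rules
  na_lon <- lon >= -170 & lon < -50
  low_n <- (na_lon & lon < -100) | (na_lon & lat >= 50) | (!na_lon & lat >= 60)
  zone <- character(n)
  zone[south] <- "low_south"
  zone[!south & high] <- "high"
  zone[!south & !high & mid] <- "mid"
  rest <- !south & !high & !mid
  zone[rest & low_n] <- "low_north"
  leftover <- rest & !low_n
  if (any(leftover)) {
    if (!quiet)
      warning(sum(leftover), " Northern-Hemisphere site(s) outside all ",
              "nominal zone definitions; assigned to 'low_north'")
    zone[leftover] <- "low_north"
  }
  zone
}

#' Cumulative nitrogen deposition over a trailing window
#'
#' Sums annual deposition over the `window` years ending at (and including)
#' each target year: cumulative inputs, not single-year rates, are what
#' influence ecosystem properties.
#'
#' @param years Integer years of the annual series.
#' @param ndep Annual deposition, g N m-2 yr-1, same length as `years`.
#' @param target_years Years for which to return the trailing sum.
#' @param window Window length in years. Default 20.
#' @param partial Policy for windows not fully covered by the series:
#'   `"error"` (default) or `"scale"` (mean of available years times
#'   `window`, flagged).
#' @return data.frame with columns `year`, `ndep_cum` (g N m-2 per window)
#'   and `partial` (logical flag).
#' @examples
#' cumulative_n(1946:2015, rep(0.85, 70), 2000) # 17 g N m-2 per 20 yr
#' @export
cumulative_n <- function(years, ndep, target_years, window = 20,
                         partial = c("error", "scale")) {
  partial <- match.arg(partial)
  stopifnot(length(years) == length(ndep), window >= 1)
  check_finite(ndep, "ndep")
  o <- order(years)
  years <- years[o]; ndep <- ndep[o]
  if (anyDuplicated(years)) stop("duplicate years in deposition series")
  res <- lapply(target_years, function(y) {
    idx <- years > (y - window) & years <= y
    k <- sum(idx)
    if (k == 0L)
      stop("deposition series has no coverage of the ", window,
           "-year window ending ", y)
    if (k < window) {
      if (partial == "error")
        stop("deposition series covers only ", k, " of ", window,
             " years ending ", y,
             " (use partial = \"scale\" to extrapolate)")
      c(sum(ndep[idx]) / k * window, TRUE)
    } else {
      c(sum(ndep[idx]), FALSE)
    }
  })
  m <- do.call(rbind, res)
  data.frame(year = as.integer(target_years), ndep_cum = m[, 1],
             partial = as.logical(m[, 2]))
}

#' Convert cumulative deposition to an annual rate in kg N per hectare
#'
#' 1 g N m-2 = 10 kg N ha-1, so x g N m-2 accumulated over `window` years
#' equals x * 10 / window kg N ha-1 yr-1 (e.g. 17 g N m-2 per 20 yr is
#' 8.5 kg N ha-1 yr-1).
#'
#' @param ndep_cum Cumulative deposition, g N m-2 per `window` years.
#' @param window Window length, years. Default 20.
#' @return Deposition rate, kg N ha-1 yr-1.
#' @export
ndep_rate_kg_ha_yr <- function(ndep_cum, window = 20) {
  check_finite(ndep_cum, "ndep_cum")
  stopifnot(window > 0)
  ndep_cum * 10 / window
}

#' Zone labels and cumulative deposition for a site table
#'
#' @param sites data.frame with `site_id`, `lat`, `lon`.
#' @param ndep_table data.frame with `site_id`, `year`, `ndep`
#'   (g N m-2 yr-1).
#' @param target_years Years for which cumulative deposition is needed;
#'   defaults to all years present per site.
#' @param window,partial Passed to [cumulative_n()].
#' @return list with `sites` (plus `zone` column) and `ndep_cum`
#'   (`site_id`, `year`, `ndep_cum`, `partial`).
#' @export
build_ndep_covariates <- function(sites, ndep_table, target_years = NULL,
                                  window = 20, partial = "error") {
  stopifnot(all(c("site_id", "lat", "lon") %in% names(sites)),
            all(c("site_id", "year", "ndep") %in% names(ndep_table)))
  sites$zone <- assign_zone(sites$lat, sites$lon)
  per_site <- lapply(split(ndep_table, ndep_table$site_id), function(d) {
    ty <- if (is.null(target_years)) d$year[d$year >= min(d$year) + window - 1]
          else target_years
    cbind(site_id = d$site_id[1L],
          cumulative_n(d$year, d$ndep, ty, window, partial))
  })
  ndep_cum <- do.call(rbind, per_site)
  rownames(ndep_cum) <- NULL
  list(sites = sites, ndep_cum = ndep_cum)
}
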