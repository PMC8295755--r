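#' Read monthly station precipitation from CSV
#'
#' Column contract: \code{station_id}, \code{latitude}, \code{longitude},
#' \code{year}, \code{month}, \code{precip_mm}.
#'
#' @param path CSV file path.
#' @return data frame of class \code{station_table}.
#' @export
read_station_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "latitude", "longitude", "year", "month", "precip_mm")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("station CSV missing columns: ", paste(miss, collapse = ", "))
  validate_stations(out)
}

validate_stations <- function(stations) {
  if (any(stations$precip_mm < 0, na.rm = TRUE)) stop("negative precipitation")
  dup <- duplicated(stations[c("station_id", "year", "month")])
  if (any(dup)) stop("duplicate (station, year, month) rows")
  class(stations) <- c("station_table", "data.frame")
  stations
}

#' Interpolate station precipitation to a site by inverse distance weighting
#'
#' Monthly values from surrounding weather stations are combined with weights
#' proportional to great-circle distance raised to \code{-power}. A target
#' within \code{zero_tol} metres of a station receives that station's series
#' verbatim. Months reported by no station are missing in the output.
#'
#' @param stations a \code{station_table} (see [read_station_csv()]).
#' @param site_lat,site_lon target coordinates in decimal degrees.
#' @param power positive IDW exponent; 2 is conventional.
#' @param zero_tol coincidence tolerance in metres.
#' @return data frame \code{year}, \code{month}, \code{precip_mm} on the full
#'   monthly grid spanned by the stations.
#' @export
idw_interpolate <- function(stations, site_lat, site_lon, power = 2,
                            zero_tol = 1) {
  if (!nrow(stations)) stop("no stations supplied")
  if (power <= 0) stop("power must be positive")
  meta <- unique(stations[c("station_id", "latitude", "longitude")])
  d <- geosphere::distHaversine(
    cbind(meta$longitude, meta$latitude), c(site_lon, site_lat))
  names(d) <- meta$station_id
  grid <- expand.grid(
    month = 1:12,
    year = seq(min(stations$year), max(stations$year)))[, c("year", "month")]
  if (any(d < zero_tol)) {
    hit <- meta$station_id[which.min(d)]
    s <- stations[stations$station_id == hit, c("year", "month", "precip_mm")]
    out <- merge(grid, s, by = c("year", "month"), all.x = TRUE)
  } else {
    w <- d^(-power)
    st <- stations[!is.na(stations$precip_mm), , drop = FALSE]
    st$w <- w[st$station_id]
    agg <- stats::aggregate(cbind(num = precip_mm * w, den = w) ~ year + month,
                            data = st, FUN = sum)
    agg$precip_mm <- agg$num / agg$den
    out <- merge(grid, agg[c("year", "month", "precip_mm")],
                 by = c("year", "month"), all.x = TRUE)
  }
  out <- out[order(out$year, out$month), c("year", "month", "precip_mm")]
  rownames(out) <- NULL
  out
}
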