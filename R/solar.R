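# Solar geometry: sunrise/sunset per site-date and the four analysis windows.
#
# Sunrise/sunset use the NOAA solar-position equations evaluated at local
# solar noon, with sunrise/sunset defined at solar zenith 90.833 deg
# (standard atmospheric refraction plus the solar radius), i.e. the values
# in common civil sunrise tables.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Solar declination (radians) and equation of time (minutes) at Julian day jd.
.solar_params <- function(jd) {
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + T * (36000.76983 + 0.0003032 * T)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  Mr <- deg2rad(M)
  C <- sin(Mr) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * T) +
    sin(3 * Mr) * 0.000289
  omega <- deg2rad(125.04 - 1934.136 * T)
  lambda <- deg2rad(L0 + C - 0.00569 - 0.00478 * sin(omega))
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps <- deg2rad(eps0 + 0.00256 * cos(omega))
  decl <- asin(sin(eps) * sin(lambda))
  y <- tan(eps / 2)^2
  L0r <- deg2rad(L0)
  eqtime <- 4 * rad2deg(
    y * sin(2 * L0r) - 2 * e * sin(Mr) +
      4 * e * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr)
  )
  list(decl = decl, eqtime = eqtime)
}

#' Sunrise and sunset for a site and date
#'
#' Computes civil sunrise and sunset (solar zenith 90.833 degrees) from the
#' NOAA solar-position equations, returned as timezone-aware timestamps in
#' the site's civil local time.
#'
#' @param lat latitude in decimal degrees (positive north). Must satisfy
#'   `abs(lat) < 66.5`; polar day/night is not supported.
#' @param lon longitude in decimal degrees (positive east).
#' @param date a `Date` (or string coercible to one).
#' @param tz Olson timezone name of the site, e.g. `"Europe/London"`.
#' @return a data.frame with columns `date`, `sunrise`, `sunset`
#'   (POSIXct in `tz`). Vectorised over `date`.
#' @examples
#' solar_times(55.87, -4.29, as.Date("2020-03-20"), "Europe/London")
#' @export
solar_times <- function(lat, lon, date, tz = "Europe/London") {
  if (abs(lat) >= 66.5) {
    stop("unsupported latitude ", lat,
         ": polar day/night possible, sunrise/sunset undefined")
  }
  date <- as.Date(date)
  # JD at 00:00 UT, evaluated at approximate local solar noon
  jd0 <- as.numeric(date) + 2440587.5
  noon_guess <- (720 - 4 * lon) / 1440
  sp <- lapply(jd0 + noon_guess, .solar_params)
  decl <- vapply(sp, `[[`, numeric(1), "decl")
  eqtime <- vapply(sp, `[[`, numeric(1), "eqtime")
  latr <- deg2rad(lat)
  cosH <- cos(deg2rad(90.833)) / (cos(latr) * cos(decl)) -
    tan(latr) * tan(decl)
  if (any(abs(cosH) > 1)) {
    stop("sun does not rise/set on ", paste(date[abs(cosH) > 1], collapse = ", "))
  }
  ha <- rad2deg(acos(cosH))
  noon_min <- 720 - 4 * lon - eqtime
  sunrise_min <- noon_min - 4 * ha
  sunset_min <- noon_min + 4 * ha
  midnight_utc <- as.POSIXct(as.numeric(date) * 86400,
                             origin = "1970-01-01", tz = "UTC")
  sunrise <- midnight_utc + sunrise_min * 60
  sunset <- midnight_utc + sunset_min * 60
  attr(sunrise, "tzone") <- tz
  attr(sunset, "tzone") <- tz
  data.frame(date = date, sunrise = sunrise, sunset = sunset)
}

#' Build the four diel analysis windows for one site-day
#'
#' The onset window is the 6 h between 4 h before and 2 h after sunrise;
#' the end window the 8 h between 4 h before and 4 h after sunset. The
#' diurnal window is 10:00-16:00 local clock time and the nocturnal window
#' 22:00 on the focal date to 02:00 the next day (keyed to the night-of
#' date). All windows are half-open `[start, end)`.
#'
#' @param solar_day one row from [solar_times()] carrying `date`, `sunrise`,
#'   `sunset`.
#' @param tz site timezone used to anchor the clock windows.
#' @return a list of four `c(start, end)` POSIXct pairs: `onset`, `end`,
#'   `diurnal`, `nocturnal`.
#' @export
build_windows <- function(solar_day, tz = "Europe/London") {
  stopifnot(nrow(solar_day) == 1L)
  sr <- solar_day$sunrise
  ss <- solar_day$sunset
  mid <- local_midnight(solar_day$date, tz)
  w <- list(
    onset = c(sr - 4 * 3600, sr + 2 * 3600),
    end = c(ss - 4 * 3600, ss + 4 * 3600),
    diurnal = c(mid + 10 * 3600, mid + 16 * 3600),
    nocturnal = c(mid + 22 * 3600, mid + 26 * 3600)
  )
  if (w$onset[2] > w$end[1]) {
    warning("onset and end windows overlap on ", format(solar_day$date),
            " (short sunrise-sunset gap); estimates may be ambiguous")
  }
  w
}

#' Time of an event relative to a solar anchor, in hours
#'
#' Positive values mean the event occurred after the anchor (e.g. activity
#' onset after sunrise); negative values before it.
#'
#' @param event,anchor POSIXct timestamps (same timezone).
#' @return numeric hours, `(event - anchor) / 3600`.
#' @export
relative_time <- function(event, anchor) {
  as.numeric(difftime(event, anchor, units = "hours"))
}
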