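#' Solar position from the Spencer day-angle Fourier series
#'
#' Declination and equation of time from the day-angle Fourier series;
#' zenith from \code{cos(theta) = sin(phi) sin(delta) + cos(phi) cos(delta)
#' cos(h)}; azimuth clockwise from north (south = 180), resolved to the
#' morning/afternoon quadrant by the sign of the hour angle. No atmospheric
#' refraction correction (sub-0.3 degree accuracy suffices for radiation
#' partitioning and trait retrieval).
#'
#' @param lat_deg,lon_deg site latitude/longitude in degrees (east positive).
#' @param doy day of year (1-366).
#' @param decimal_hour clock time as a decimal hour.
#' @param time_ref "utc" (apply the +lon/15 longitude correction and the
#'   equation of time to obtain apparent solar time) or "local_solar"
#'   (decimal_hour already is apparent solar time).
#' @return list with zenith_deg, azimuth_deg, declination_deg,
#'   equation_of_time_min, hour_angle_deg.
#' @export
solar_position <- function(lat_deg, lon_deg, doy, decimal_hour,
                           time_ref = c("utc", "local_solar")) {
  time_ref <- match.arg(time_ref)
  if (abs(lat_deg) > 90) stop("|latitude| > 90")
  g <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eot_min <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                         0.014615 * cos(2 * g) - 0.04089 * sin(2 * g))
  ast <- if (time_ref == "utc")
    decimal_hour + lon_deg / 15 + eot_min / 60 else decimal_hour
  h <- 15 * (ast - 12)                      # degrees, negative before noon
  phi <- lat_deg * pi / 180
  hr <- h * pi / 180
  cz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(hr)
  cz <- pmin(pmax(cz, -1), 1)
  zen <- acos(cz)
  sz <- sin(zen)
  az <- if (sz < 1e-9) 180 else {
    ca <- (sin(decl) - cz * sin(phi)) / (sz * cos(phi))
    a0 <- acos(pmin(pmax(ca, -1), 1)) * 180 / pi
    if (h <= 0) a0 else 360 - a0
  }
  list(zenith_deg = zen * 180 / pi,
       azimuth_deg = az %% 360,
       declination_deg = decl * 180 / pi,
       equation_of_time_min = eot_min,
       hour_angle_deg = h)
}

#' Psychrometric state of moist air
#'
#' FAO-56 psychrometrics: Tetens saturation vapor pressure, slope of the
#' saturation curve, latent heat of vaporization linear in temperature,
#' psychrometric constant from Cp and pressure, air density from the ideal
#' gas law with virtual temperature.
#'
#' @param Ta air temperature (K).
#' @param RH relative humidity (percent, 0-100).
#' @param u wind speed (m s-1).
#' @param pressure air pressure (kPa).
#' @param Rs_inst instantaneous solar irradiance (W m-2), optional.
#' @param Rs_daily_mean daily-mean solar irradiance (W m-2), optional.
#' @return list of class \code{meteo_state}: the inputs plus es, ea, VPD
#'   (kPa), Delta (kPa K-1), gamma (kPa K-1), lambda (J kg-1),
#'   rho (kg m-3), Cp (J kg-1 K-1), rho_cp (J m-3 K-1).
#' @export
meteo_state <- function(Ta, RH, u = 2, pressure = 101.3,
                        Rs_inst = NA_real_, Rs_daily_mean = NA_real_) {
  if (any(RH < 0 | RH > 100)) stop("RH outside [0, 100]")
  Tc <- Ta - 273.15
  es <- 0.6108 * exp(17.27 * Tc / (Tc + 237.3))
  ea <- es * RH / 100
  Delta <- 4098 * es / (Tc + 237.3)^2
  lambda <- (2.501 - 0.002361 * Tc) * 1e6
  Cp <- 1013
  gamma <- Cp * pressure / (0.622 * lambda) / 1000  # kPa K-1
  Tv <- Ta / (1 - 0.378 * ea / pressure)            # virtual temperature
  rho <- 1000 * pressure / (287.04 * Tv)
  structure(list(Ta = Ta, RH = RH, u = u, pressure = pressure,
                 Rs_inst = Rs_inst, Rs_daily_mean = Rs_daily_mean,
                 es = es, ea = ea, VPD = es - ea, Delta = Delta,
                 gamma = gamma, lambda = lambda, rho = rho, Cp = Cp,
                 rho_cp = rho * Cp),
            class = "meteo_state")
}

#' Clear-sky diurnal irradiance weights
#'
#' Relative weights for integrating an hourly quantity over the daylight
#' period: weight proportional to max(0, cos zenith) times a clear-sky
#' transmittance constant, zero whenever the sun is below the horizon,
#' normalized to sum to one over the day.
#'
#' @param lat,lon site coordinates (degrees).
#' @param doy day of year.
#' @param step_min time step in minutes; must divide 1440.
#' @param transmittance clear-sky atmospheric transmittance (default 0.75).
#' @return data.frame with decimal_hour (UTC), zenith_deg, azimuth_deg,
#'   cos_zenith, irradiance_Wm2 (top-of-atmosphere 1367 W m-2 scaled by
#'   transmittance and cos zenith) and weight (sums to 1).
#' @export
clear_sky_profile <- function(lat, lon, doy, step_min = 30,
                              transmittance = 0.75) {
  stopifnot(1440 %% step_min == 0)
  hours <- seq(step_min / 2, 1440 - step_min / 2, by = step_min) / 60
  sp <- lapply(hours, function(h) solar_position(lat, lon, doy, h, "utc"))
  zen <- vapply(sp, `[[`, numeric(1), "zenith_deg")
  azi <- vapply(sp, `[[`, numeric(1), "azimuth_deg")
  cz <- pmax(0, cos(zen * pi / 180))
  cz[zen >= 90] <- 0
  irr <- 1367 * transmittance * cz
  w <- if (sum(cz) > 0) cz / sum(cz) else cz
  data.frame(decimal_hour = hours, zenith_deg = zen, azimuth_deg = azi,
             cos_zenith = cz, irradiance_Wm2 = irr, weight = w)
}
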