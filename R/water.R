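#' Crop water stress index from actual and potential ET
#'
#' CWSI = 1 - ETa/ETp, clamped to [0, 1] with a flag (actual marginally
#' above potential is treated as measurement noise).
#'
#' @param ET_a actual evapotranspiration (mm day-1).
#' @param ET_p potential evapotranspiration (mm day-1), > 0.
#' @return list with value in [0, 1], raw (unclamped) and flag.
#' @export
cwsi <- function(ET_a, ET_p) {
  if (any(ET_p <= 0)) stop("ET_p must be positive")
  raw <- 1 - ET_a / ET_p
  val <- pmin(pmax(raw, 0), 1)
  list(value = val, raw = raw,
       flag = ifelse(raw < 0 | raw > 1, "clamped", ""))
}

#' Effective rainfall rule
#'
#' Half of the rainfall counts for a single event-day with strictly more
#' than 10 mm; smaller events contribute nothing.
#'
#' @param daily_rain_mm non-negative daily rainfall (mm), vectorized.
#' @return effective rainfall (mm).
#' @export
effective_rainfall <- function(daily_rain_mm) {
  stopifnot(all(daily_rain_mm >= 0))
  ifelse(daily_rain_mm > 10, daily_rain_mm / 2, 0)
}

#' Monthly crop-coefficient calendar for mature almond
#'
#' April 0.70, May 0.95, June 1.09, July 1.15, August 1.17,
#' September 1.12.
#'
#' @return named numeric vector (month number -> Kc).
#' @export
almond_kc_calendar <- function() {
  c("4" = 0.70, "5" = 0.95, "6" = 1.09, "7" = 1.15, "8" = 1.17, "9" = 1.12)
}

#' Daily irrigation water balance
#'
#' ETc = max(0, ETo x Kc(month) - effective rainfall) per day, with season
#' totals.
#'
#' @param dates Date vector.
#' @param ETo daily reference evapotranspiration (mm).
#' @param rainfall daily rainfall (mm).
#' @param kc_calendar named vector month -> Kc
#'   (default \code{\link{almond_kc_calendar}}).
#' @return list with \code{daily} (data.frame date, ETo, Kc, rainfall,
#'   P_eff, ETc) and \code{totals} (ETc_mm, ETo_Kc_mm, P_eff_mm).
#' @export
water_balance <- function(dates, ETo, rainfall,
                          kc_calendar = almond_kc_calendar()) {
  stopifnot(length(dates) == length(ETo), length(ETo) == length(rainfall))
  mon <- as.character(as.integer(format(as.Date(dates), "%m")))
  if (!all(mon %in% names(kc_calendar)))
    stop("month outside the Kc calendar: ",
         paste(unique(mon[!mon %in% names(kc_calendar)]), collapse = ", "))
  Kc <- unname(kc_calendar[mon])
  P_eff <- effective_rainfall(rainfall)
  ETc <- pmax(0, ETo * Kc - P_eff)
  daily <- data.frame(date = as.Date(dates), ETo = ETo, Kc = Kc,
                      rainfall = rainfall, P_eff = P_eff, ETc = ETc)
  list(daily = daily,
       totals = c(ETc_mm = sum(ETc), ETo_Kc_mm = sum(ETo * Kc),
                  P_eff_mm = sum(P_eff)))
}

#' Water productivity
#'
#' Kernel yield per unit of water evapotranspired over the stated period.
#'
#' @param kernel_yield kernel yield (kg per tree).
#' @param ET_a_period_mm actual evapotranspiration total over the period
#'   (mm), > 0.
#' @return WP (kg mm-1).
#' @export
water_productivity <- function(kernel_yield, ET_a_period_mm) {
  if (any(ET_a_period_mm <= 0)) stop("period ET must be positive")
  stopifnot(all(kernel_yield >= 0))
  kernel_yield / ET_a_period_mm
}
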