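#' Shuttleworth-Wallace resistance network for potential conditions
#'
#' Aerodynamic terms reuse the neutral-stability log-profile and in-canopy
#' attenuation machinery of \code{\link{tseb_resistances}}: r_a_a is the
#' reference-to-canopy-source aerodynamic resistance, r_a_s the
#' soil-to-source resistance, r_a_c the bulk leaf boundary-layer resistance
#' divided between the two leaf sides (r_x / 2). The bulk canopy stomatal
#' resistance is r_s_c = rst_min / (2 LAI); potential conditions use a
#' non-limiting wet soil surface (r_s_s = 0 by default).
#'
#' @param meteo meteo_state.
#' @param LAI leaf area index, > 0.05.
#' @param h_c canopy height (m).
#' @param leaf_width mean leaf width (m).
#' @param rst_min minimum stomatal resistance (s m-1, default 100).
#' @param r_s_s_wet soil surface resistance (s m-1, default 0).
#' @param z_u,z_T measurement heights (m).
#' @return list of class \code{sw_resistances}: r_a_a, r_a_c, r_a_s,
#'   r_s_c, r_s_s.
#' @export
sw_resistances <- function(meteo, LAI, h_c, leaf_width = 0.05,
                           rst_min = 100, r_s_s_wet = 0,
                           z_u = h_c + 2, z_T = h_c + 2) {
  if (LAI <= 0.05) stop("LAI at or below the 0.05 floor")
  rs <- tseb_resistances(meteo, LAI, h_c, z_u, z_T, leaf_width,
                         H_current = 0)      # neutral stability
  structure(list(r_a_a = rs$r_ah, r_a_c = rs$r_x / 2, r_a_s = rs$r_s,
                 r_s_c = rst_min / (2 * LAI), r_s_s = r_s_s_wet),
            class = "sw_resistances")
}

#' Shuttleworth-Wallace potential evapotranspiration
#'
#' The standard two-source combination: Penman-Monteith-form terms for the
#' canopy and the soil,
#' PM_c = (Delta A + (rho Cp VPD - Delta r_a_c A_s)/(r_a_a + r_a_c)) /
#' (Delta + gamma (1 + r_s_c/(r_a_a + r_a_c))) (and symmetrically for the
#' soil), blended by the resistance weights C_c, C_s. The daily value uses
#' the same irradiance-ratio upscaling as the actual-ET model.
#'
#' @param meteo meteo_state (Delta, gamma, VPD, rho_cp; Rs_inst and
#'   Rs_daily_mean for the daily value).
#' @param Rn,Rn_s total and soil net radiation (W m-2), Rn > 0.
#' @param G soil heat flux (W m-2).
#' @param rs sw_resistances.
#' @return list of class \code{sw_fluxes}: PM_c, PM_s, C_c, C_s, LE_p
#'   (W m-2), ET_p (mm day-1, NA without daily irradiance), A, A_s.
#' @export
sw_potential_et <- function(meteo, Rn, Rn_s, G, rs) {
  if (is.null(meteo$Delta) || is.null(meteo$gamma) || is.null(meteo$VPD))
    stop("meteo must provide Delta, gamma and VPD")
  stopifnot(Rn > 0)
  D <- meteo$Delta; g <- meteo$gamma; rcp <- meteo$rho_cp
  A <- Rn - G
  A_s <- Rn_s - G
  PM_c <- (D * A + (rcp * meteo$VPD -
                      D * rs$r_a_c * A_s) / (rs$r_a_a + rs$r_a_c)) /
    (D + g * (1 + rs$r_s_c / (rs$r_a_a + rs$r_a_c)))
  PM_s <- (D * A + (rcp * meteo$VPD - D * rs$r_a_s * (A - A_s)) /
             (rs$r_a_a + rs$r_a_s)) /
    (D + g * (1 + rs$r_s_s / (rs$r_a_a + rs$r_a_s)))
  R_a <- (D + g) * rs$r_a_a
  R_c <- (D + g) * rs$r_a_c + g * rs$r_s_c
  R_s <- (D + g) * rs$r_a_s + g * rs$r_s_s
  C_c <- 1 / (1 + R_c * R_a / (R_s * (R_c + R_a)))
  C_s <- 1 / (1 + R_s * R_a / (R_c * (R_s + R_a)))
  LE_p <- C_c * PM_c + C_s * PM_s
  ET_p <- if (!is.na(meteo$Rs_daily_mean) && !is.na(meteo$Rs_inst) &&
              meteo$Rs_inst > 50)
    upscale_daily(LE_p, meteo$Rs_inst, meteo$Rs_daily_mean, meteo$lambda)
  else NA_real_
  structure(list(PM_c = PM_c, PM_s = PM_s, C_c = C_c, C_s = C_s,
                 LE_p = LE_p, ET_p = ET_p, A = A, A_s = A_s),
            class = "sw_fluxes")
}
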