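STEFAN_BOLTZMANN <- 5.670374419e-8
VON_KARMAN <- 0.41
GRAVITY <- 9.81

#' Net radiation over the composite surface
#'
#' Rn = (1 - albedo) Rs + eps_a sigma Ta^4 - eps_s sigma T_rad^4 with the
#' Brutsaert clear-sky air emissivity eps_a = 1.24 (10 ea / Ta)^(1/7) and
#' surface emissivity 0.98.
#'
#' @param Rs_inst incoming shortwave irradiance (W m-2), >= 0.
#' @param albedo surface shortwave albedo.
#' @param Ta air temperature (K).
#' @param ea actual vapor pressure (kPa).
#' @param T_rad composite radiometric surface temperature (K).
#' @param emissivity_surface surface emissivity (default 0.98).
#' @param emissivity_air override for the air emissivity (default NULL =
#'   Brutsaert).
#' @return net radiation (W m-2).
#' @export
net_radiation <- function(Rs_inst, albedo, Ta, ea, T_rad,
                          emissivity_surface = 0.98,
                          emissivity_air = NULL) {
  stopifnot(Rs_inst >= 0)
  eps_a <- if (is.null(emissivity_air))
    1.24 * (10 * ea / Ta)^(1 / 7) else emissivity_air
  (1 - albedo) * Rs_inst + eps_a * STEFAN_BOLTZMANN * Ta^4 -
    emissivity_surface * STEFAN_BOLTZMANN * T_rad^4
}

#' Partition net radiation between canopy and soil
#'
#' Beer-law extinction through the canopy:
#' Rn_s = Rn exp(-kappa LAI / sqrt(2 cos theta_s)), Rn_c = Rn - Rn_s.
#'
#' @param Rn total net radiation (W m-2).
#' @param LAI leaf area index.
#' @param zenith_deg solar zenith angle (degrees), < 90.
#' @param kappa extinction coefficient for net radiation (default 0.45).
#' @return list with Rn_c and Rn_s.
#' @export
partition_net_radiation <- function(Rn, LAI, zenith_deg, kappa = 0.45) {
  if (zenith_deg >= 90) stop("zenith >= 90 in daytime radiation partitioning")
  stopifnot(is.finite(Rn), LAI >= 0)
  Rn_s <- Rn * exp(-kappa * LAI / sqrt(2 * cos(zenith_deg * pi / 180)))
  list(Rn_c = Rn - Rn_s, Rn_s = Rn_s)
}

#' Soil heat flux as a fraction of soil net radiation
#'
#' @param Rn_s net radiation reaching the soil (W m-2).
#' @param c_G fraction in [0, 0.5] (default 0.35, midday).
#' @return G (W m-2).
#' @export
soil_heat_flux <- function(Rn_s, c_G = 0.35) {
  stopifnot(c_G >= 0, c_G <= 0.5)
  c_G * Rn_s
}

# Businger-Dyer stability correction functions
psi_m <- function(zeta) {
  ifelse(zeta >= 0, -5 * zeta, {
    x <- (1 - 16 * pmin(zeta, 0))^0.25
    2 * log((1 + x) / 2) + log((1 + x^2) / 2) - 2 * atan(x) + pi / 2
  })
}
psi_h <- function(zeta) {
  ifelse(zeta >= 0, -5 * zeta, {
    x <- (1 - 16 * pmin(zeta, 0))^0.25
    2 * log((1 + x^2) / 2)
  })
}

#' TSEB resistance network
#'
#' Aerodynamic resistance from Monin-Obukhov similarity with Businger-Dyer
#' stability corrections (roughness d = 0.65 h_c, z_om = 0.125 h_c,
#' z_oh = z_om / 7); soil boundary-layer resistance from the wind speed
#' just above the surface after exponential in-canopy attenuation; bulk leaf
#' boundary-layer resistance r_x = (C'/LAI) sqrt(leaf_width / u(d + z_om)).
#'
#' @param meteo meteo_state (uses u, Ta, rho_cp).
#' @param LAI leaf area index, > 0.05.
#' @param h_c canopy height (m).
#' @param z_u,z_T measurement heights of wind and temperature (m), > h_c;
#'   default h_c + 2.
#' @param leaf_width mean leaf width (m, default 0.05).
#' @param H_current sensible heat flux for the stability state (W m-2);
#'   0 gives the neutral limit.
#' @param a_s,b_s soil-resistance coefficients (defaults 0.004, 0.012).
#' @param C_prime bulk boundary-layer coefficient (default 90 s^1/2 m-1).
#' @return list of class \code{resistance_set}: r_ah, r_s, r_x, u_star,
#'   u_canopy_top, u_soil, u_dz, L_MO, flag.
#' @export
tseb_resistances <- function(meteo, LAI, h_c, z_u = h_c + 2, z_T = h_c + 2,
                             leaf_width = 0.05, H_current = 0,
                             a_s = 0.004, b_s = 0.012, C_prime = 90) {
  if (LAI <= 0.05) stop("LAI at or below the 0.05 floor")
  stopifnot(z_u > h_c, z_T > h_c)
  u <- max(meteo$u, 0.5)               # wind floor
  d <- 0.65 * h_c
  z_om <- 0.125 * h_c
  z_oh <- z_om / 7
  k <- VON_KARMAN
  flag <- ""
  # friction velocity and Obukhov length, one pass given H_current
  L <- Inf
  u_star <- k * u / log((z_u - d) / z_om)
  if (H_current != 0) {
    for (it in 1:10) {
      L <- -meteo$rho_cp * u_star^3 * meteo$Ta /
        (k * GRAVITY * H_current)
      denom <- log((z_u - d) / z_om) - psi_m((z_u - d) / L)
      if (!is.finite(denom) || denom <= 0) { flag <- "neutral_fallback"
        L <- Inf; u_star <- k * u / log((z_u - d) / z_om); break }
      u_star_new <- k * u / denom
      if (abs(u_star_new - u_star) < 1e-6) { u_star <- u_star_new; break }
      u_star <- u_star_new
    }
  }
  zeta_T <- if (is.finite(L)) (z_T - d) / L else 0
  r_ah <- (log((z_T - d) / z_oh) - psi_h(zeta_T)) / (k * u_star)
  # in-canopy wind profile
  u_hc <- u_star / k * log((h_c - d) / z_om)
  a_att <- 0.28 * LAI^(2 / 3) * h_c^(1 / 3) * leaf_width^(-1 / 3)
  u_soil <- u_hc * exp(-a_att * (1 - 0.1 / h_c))
  u_dz <- u_hc * exp(-a_att * (1 - (d + z_om) / h_c))
  r_s <- 1 / (a_s + b_s * u_soil)
  r_x <- (C_prime / LAI) * sqrt(leaf_width / u_dz)
  structure(list(r_ah = r_ah, r_s = r_s, r_x = r_x, u_star = u_star,
                 u_canopy_top = u_hc, u_soil = u_soil, u_dz = u_dz,
                 L_MO = L, flag = flag),
            class = "resistance_set")
}

#' Series resistance network given canopy and soil temperatures
#'
#' In-canopy air temperature is the resistance-weighted mean
#' T_ac = (Ta/r_ah + Ts/r_s + Tc/r_x) / (1/r_ah + 1/r_s + 1/r_x);
#' H_c = rho Cp (Tc - T_ac)/r_x, H_s = rho Cp (Ts - T_ac)/r_s, and their sum
#' equals rho Cp (T_ac - Ta)/r_ah identically.
#'
#' @param Ta,Tc,Ts air, canopy and soil temperatures (K).
#' @param r_ah,r_s,r_x resistances (s m-1).
#' @param rho_cp volumetric heat capacity of air (J m-3 K-1).
#' @return list with T_ac, H_c, H_s, H.
#' @export
tseb_series_network <- function(Ta, Tc, Ts, r_ah, r_s, r_x, rho_cp) {
  T_ac <- (Ta / r_ah + Ts / r_s + Tc / r_x) /
    (1 / r_ah + 1 / r_s + 1 / r_x)
  H_c <- rho_cp * (Tc - T_ac) / r_x
  H_s <- rho_cp * (Ts - T_ac) / r_s
  list(T_ac = T_ac, H_c = H_c, H_s = H_s, H = H_c + H_s)
}

#' Two-source energy balance with observed component temperatures
#'
#' Iterates resistances (Monin-Obukhov stability from the current sensible
#' heat flux), the series-network in-canopy air temperature and the
#' component sensible heat fluxes until H changes by less than 0.1 W m-2
#' (max 50 iterations; non-convergence falls back to the neutral-stability
#' solution with a flag). Latent heat is the energy-balance residual per
#' source: LE_c = Rn_c - H_c, LE_s = Rn_s - G - H_s. Negative component
#' fluxes are retained and flagged, not redistributed.
#'
#' @param Tc,Ts canopy and soil temperatures (K), in [250, 340].
#' @param meteo meteo_state at acquisition (needs Rs_inst for Rn unless Rn
#'   is supplied).
#' @param LAI leaf area index (ground-measured preferred).
#' @param h_c canopy height (m).
#' @param zenith_deg solar zenith angle (degrees).
#' @param Rn net radiation (W m-2); default computed by
#'   \code{\link{net_radiation}} from meteo with \code{albedo} and the
#'   composite radiometric temperature \code{f_cover Tc + (1-f_cover) Ts}.
#' @param f_cover fractional canopy cover for the composite temperature.
#' @param albedo surface albedo (default 0.2).
#' @param kappa,c_G,leaf_width,z_u,z_T,a_s,b_s,C_prime model constants, see
#'   \code{\link{tseb_resistances}} / \code{\link{partition_net_radiation}} /
#'   \code{\link{soil_heat_flux}}.
#' @return list of class \code{energy_fluxes}: Rn, Rn_c, Rn_s, G, H, H_c,
#'   H_s, LE, LE_c, LE_s, T_ac, ET_inst, ET_day (daily value requires
#'   Rs_daily_mean in meteo; NA otherwise), resistances, iterations, flag.
#' @export
solve_tseb <- function(Tc, Ts, meteo, LAI, h_c, zenith_deg,
                       Rn = NULL, f_cover = 0.5, albedo = 0.2,
                       kappa = 0.45, c_G = 0.35, leaf_width = 0.05,
                       z_u = h_c + 2, z_T = h_c + 2,
                       a_s = 0.004, b_s = 0.012, C_prime = 90) {
  stopifnot(Tc >= 250, Tc <= 340, Ts >= 250, Ts <= 340)
  if (is.null(Rn)) {
    T_rad <- (f_cover * Tc^4 + (1 - f_cover) * Ts^4)^0.25
    Rn <- net_radiation(meteo$Rs_inst, albedo, meteo$Ta, meteo$ea, T_rad)
  }
  part <- partition_net_radiation(Rn, LAI, zenith_deg, kappa)
  G <- soil_heat_flux(part$Rn_s, c_G)
  H <- 0
  flag <- ""
  converged <- FALSE
  for (it in 1:50) {
    rs <- tseb_resistances(meteo, LAI, h_c, z_u, z_T, leaf_width,
                           H_current = H, a_s = a_s, b_s = b_s,
                           C_prime = C_prime)
    net <- tseb_series_network(meteo$Ta, Tc, Ts, rs$r_ah, rs$r_s, rs$r_x,
                               meteo$rho_cp)
    if (abs(net$H - H) < 0.1) { H <- net$H; converged <- TRUE; break }
    H <- net$H
  }
  if (!converged) {
    flag <- "stability_nonconvergence"
    rs <- tseb_resistances(meteo, LAI, h_c, z_u, z_T, leaf_width,
                           H_current = 0, a_s = a_s, b_s = b_s,
                           C_prime = C_prime)
    net <- tseb_series_network(meteo$Ta, Tc, Ts, rs$r_ah, rs$r_s, rs$r_x,
                               meteo$rho_cp)
    H <- net$H
  }
  LE_c <- part$Rn_c - net$H_c
  LE_s <- part$Rn_s - G - net$H_s
  LE <- LE_c + LE_s
  if (LE_c < 0 || LE_s < 0)
    flag <- paste0(flag, if (nzchar(flag)) ";", "negative_component_LE")
  et <- et_instant(LE, meteo$lambda)
  et_d <- if (!is.na(meteo$Rs_daily_mean) && !is.na(meteo$Rs_inst) &&
              meteo$Rs_inst > 50)
    upscale_daily(LE, meteo$Rs_inst, meteo$Rs_daily_mean, meteo$lambda)
  else NA_real_
  structure(list(Rn = Rn, Rn_c = part$Rn_c, Rn_s = part$Rn_s, G = G,
                 H = H, H_c = net$H_c, H_s = net$H_s,
                 LE = LE, LE_c = LE_c, LE_s = LE_s, T_ac = net$T_ac,
                 ET_inst = et$value, ET_day = et_d,
                 resistances = rs, iterations = it,
                 flag = paste0(flag, et$flag)),
            class = "energy_fluxes")
}

#' Instantaneous evapotranspiration from latent heat flux
#'
#' ET_inst = 3600 LE / (lambda rho_w) in mm h-1 with rho_w = 1000 kg m-3
#' (so numerically 3600 LE / lambda). Negative LE (condensation) returns 0
#' with a flag.
#'
#' @param LE latent heat flux (W m-2).
#' @param lambda latent heat of vaporization (J kg-1), > 0.
#' @return list with value (mm h-1) and flag.
#' @export
et_instant <- function(LE, lambda) {
  stopifnot(lambda > 0)
  if (LE < 0) list(value = 0, flag = "condensation")
  else list(value = 3600 * LE / lambda, flag = "")
}

#' Daily evapotranspiration by irradiance-ratio upscaling
#'
#' ET_day = (LE / Rs_inst) Rs_daily_mean 86400 / lambda (mm day-1): the
#' instantaneous latent-heat-to-irradiance ratio is assumed conserved over
#' the day.
#'
#' @param LE latent heat flux at acquisition (W m-2).
#' @param Rs_inst instantaneous solar irradiance (W m-2), > 50.
#' @param Rs_daily_mean 24-h mean solar irradiance (W m-2).
#' @param lambda latent heat of vaporization (J kg-1).
#' @return ET_day (mm day-1).
#' @export
upscale_daily <- function(LE, Rs_inst, Rs_daily_mean, lambda) {
  if (Rs_inst <= 50) stop("Rs_inst <= 50 W m-2: irradiance ratio unstable")
  (LE / Rs_inst) * Rs_daily_mean * 86400 / lambda
}
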