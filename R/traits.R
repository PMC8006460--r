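#' Spectral vegetation indices from the six-band camera
#'
#' NDVI = (R872 - R682)/(R872 + R682); GNDVI = (R872 - R571)/(R872 + R571);
#' MCARI = [(R710 - R682) - 0.2 (R710 - R571)] R710/R682;
#' NDRE = (R872 - R710)/(R872 + R710);
#' MSRre = (R872/R710 - 1)/sqrt(R872/R710 + 1).
#' Zero denominators yield NA plus a flag rather than an error.
#'
#' @param R_515,R_571,R_682,R_710,R_781,R_872 surface reflectances in (0, 1]
#'   (vectors allowed).
#' @return data.frame with ndvi, gndvi, mcari, ndre, msrre, flag.
#' @export
vegetation_indices <- function(R_515, R_571, R_682, R_710, R_781, R_872) {
  safe <- function(num, den) ifelse(abs(den) < 1e-12, NA_real_, num / den)
  ndvi <- safe(R_872 - R_682, R_872 + R_682)
  gndvi <- safe(R_872 - R_571, R_872 + R_571)
  mcari <- ((R_710 - R_682) - 0.2 * (R_710 - R_571)) * safe(R_710, R_682)
  ndre <- safe(R_872 - R_710, R_872 + R_710)
  ratio <- safe(R_872, R_710)
  msrre <- ifelse(is.na(ratio) | ratio < -1, NA_real_,
                  (ratio - 1) / sqrt(ratio + 1))
  flag <- ifelse(is.na(ndvi) | is.na(gndvi) | is.na(mcari) | is.na(ndre) |
                   is.na(msrre), "zero_denominator", "")
  data.frame(ndvi = ndvi, gndvi = gndvi, mcari = mcari, ndre = ndre,
             msrre = msrre, flag = flag, stringsAsFactors = FALSE)
}

#' Ellipsoidal canopy extinction coefficient
#'
#' K(chi, theta) = sqrt(chi^2 + tan^2 theta) /
#' (chi + 1.744 (chi + 1.182)^-0.733).
#'
#' @param chi ellipsoidal leaf-angle distribution parameter (1 = spherical).
#' @param zenith_deg beam zenith angle (degrees).
#' @return extinction coefficient (dimensionless).
#' @export
extinction_coefficient <- function(chi, zenith_deg) {
  th <- zenith_deg * pi / 180
  sqrt(chi^2 + tan(th)^2) / (chi + 1.744 * (chi + 1.182)^(-0.733))
}

#' Ellipsoidal parameter from average leaf angle
#'
#' Inverts Campbell's approximation ALA(rad) = 9.65 (3 + chi)^-1.65.
#'
#' @param ala_deg average leaf inclination angle (degrees).
#' @return chi.
#' @export
chi_from_leaf_angle <- function(ala_deg) {
  (ala_deg * pi / 180 / 9.65)^(-1 / 1.65) - 3
}

#' Norman-Jarvis gap-fraction model (LAI <-> PAR transmittance)
#'
#' Inverse: LAI = [(1 - 1/(2K)) fb - 1] ln(tau) / (A (1 - 0.47 fb)) with the
#' ellipsoidal extinction K(chi, theta) and the absorptivity polynomial
#' A = 0.283 + 0.785 a - 0.159 a^2. Forward is the exact algebraic inverse;
#' fiPAR = 1 - tau.
#'
#' @param direction "forward" (LAI -> tau, fiPAR) or "inverse" (tau -> LAI).
#' @param value LAI (forward) or PAR transmittance tau (inverse).
#' @param zenith_deg solar zenith angle (degrees).
#' @param fb beam fraction of incident PAR in [0, 1] (default 0.85,
#'   clear sky).
#' @param chi leaf-angle parameter (default 1, spherical).
#' @param absorptivity leaf absorptivity for PAR (default 0.9).
#' @return list with LAI, tau, fiPAR, K, A, flag ("clipped" when a negative
#'   inverse LAI was floored at 0).
#' @export
gap_fraction_model <- function(direction = c("forward", "inverse"), value,
                               zenith_deg = 0, fb = 0.85, chi = 1,
                               absorptivity = 0.9) {
  direction <- match.arg(direction)
  stopifnot(fb >= 0, fb <= 1)
  K <- extinction_coefficient(chi, zenith_deg)
  A <- 0.283 + 0.785 * absorptivity - 0.159 * absorptivity^2
  num_fac <- (1 - 1 / (2 * K)) * fb - 1
  den_fac <- A * (1 - 0.47 * fb)
  flag <- ""
  if (direction == "inverse") {
    tau <- value
    if (any(tau <= 0 | tau > 1)) stop("tau must be in (0, 1]")
    lai <- num_fac * log(tau) / den_fac
    if (any(lai < 0)) { lai <- pmax(lai, 0); flag <- "clipped" }
  } else {
    lai <- value
    stopifnot(all(lai >= 0))
    tau <- exp(lai * den_fac / num_fac)
  }
  list(LAI = lai, tau = tau, fiPAR = 1 - tau, K = K, A = A, flag = flag)
}

#' Daily intercepted PAR fraction from an hourly hedgerow model
#'
#' The hedgerow casts a shadowed ground fraction
#' S(t) = min(1, (w + h tan(theta_s) |sin(az_sun - az_row)|) / row_spacing);
#' hourly interception is f(t) = S(t) (1 - p) with canopy porosity p. The
#' porosity is solved in closed form so the simulated interception at solar
#' noon equals the observed instantaneous value, then the diurnal course is
#' integrated with clear-sky irradiance weights.
#'
#' @param hedge_height,hedge_width canopy hedge dimensions (m).
#' @param row_azimuth_deg row direction, clockwise from north.
#' @param row_spacing distance between rows (m), default 5.
#' @param fiPAR_noon_obs observed instantaneous intercepted fraction at noon
#'   in [0, 1).
#' @param lat,lon,doy site and date for the solar course.
#' @param step_min integration step (minutes).
#' @return list with porosity, fiPAR_d, profile (hourly data.frame), flag
#'   ("porosity_clipped" when the observation exceeds the geometric maximum).
#' @export
daily_fipar <- function(hedge_height, hedge_width, row_azimuth_deg,
                        fiPAR_noon_obs, lat, lon, doy,
                        row_spacing = 5.0, step_min = 30) {
  stopifnot(fiPAR_noon_obs >= 0, fiPAR_noon_obs < 1,
            hedge_height > 0, hedge_width > 0, hedge_width <= row_spacing)
  prof <- clear_sky_profile(lat, lon, doy, step_min)
  shadow_frac <- function(zen, az) {
    tn <- ifelse(zen >= 90, Inf, tan(zen * pi / 180))
    pmin(1, (hedge_width + hedge_height * tn *
               abs(sin((az - row_azimuth_deg) * pi / 180))) / row_spacing)
  }
  S <- shadow_frac(prof$zenith_deg, prof$azimuth_deg)
  S[prof$zenith_deg >= 90] <- 0
  noon <- which.max(prof$weight)       # step closest to solar noon
  if (S[noon] <= 0) stop("degenerate geometry: no shadow at noon")
  flag <- ""
  p <- 1 - fiPAR_noon_obs / S[noon]
  if (p < 0) { p <- 0; flag <- "porosity_clipped" }
  if (p > 1) p <- 1
  f <- S * (1 - p)
  fiPAR_d <- sum(f * prof$weight)
  prof$shadow_fraction <- S
  prof$fiPAR <- f
  list(porosity = p, fiPAR_d = fiPAR_d, profile = prof, flag = flag)
}

# ---- radiative-transfer surrogate and inversion --------------------------

#' Parameter ranges for reflectance-model simulation
#'
#' Leaf structure/chemistry and canopy ranges used to build the training
#' set for trait inversion (units: Cab, Car ug cm-2; Cw, Cdm g cm-2;
#' LAI m2 m-2; leaf angle degrees).
#'
#' @return named list of c(min, max) ranges.
#' @export
rt_default_ranges <- function() {
  list(N_leaf = c(1.2, 2.2), Cab = c(0, 90), Car = c(0, 40),
       Cbrown = c(0, 1), Cw = c(0.003, 0.011), Cdm = c(0.003, 0.011),
       LAI = c(0, 6), average_leaf_angle_deg = c(30, 80),
       hotspot = c(0.1, 0.5))
}

#' Default soil reflectance spectrum for the six bands
#' @return numeric vector of length 6.
#' @export
rt_default_soil <- function() c(0.121, 0.163, 0.192, 0.319, 0.373, 0.363)

# per-band surrogate coefficients: asymptotic leaf reflectance and
# absorption weights for chlorophyll, water and dry matter
rt_surrogate_coefs <- function() {
  list(rho_inf = c(0.35, 0.45, 0.40, 0.50, 0.55, 0.56),
       k_ab = c(2.5, 1.6, 3.0, 1.2, 0.10, 0.05),
       k_w = c(0.05, 0.05, 0.05, 0.10, 0.15, 0.25),
       k_dm = c(0.10, 0.10, 0.10, 0.10, 0.20, 0.30))
}

#' Forward canopy reflectance model (built-in surrogate)
#'
#' A compact turbid-medium surrogate for a full leaf+canopy radiative
#' transfer code, exposed behind a pluggable contract: leaf reflectance per
#' band is an asymptotic spectrum attenuated exponentially by chlorophyll,
#' water, dry matter and brown pigment; the canopy mixes leaf and soil
#' spectra through exp(-2 K LAI) with the ellipsoidal extinction
#' K(chi(ALA), theta_s). The companion truth is fiPAR = 1 - exp(-K LAI).
#' A full radiative-transfer implementation may replace this function
#' behind the same signature.
#'
#' @param params named list: N_leaf, Cab, Car, Cbrown, Cw, Cdm, LAI,
#'   average_leaf_angle_deg, hotspot (all within \code{rt_default_ranges});
#'   N_leaf, Car and hotspot are accepted for interface completeness but do
#'   not enter the surrogate.
#' @param zenith_deg solar zenith angle (degrees).
#' @param soil soil reflectance spectrum (6 values).
#' @return list with reflectance (6 values), fiPAR, K.
#' @export
rt_forward <- function(params, zenith_deg = 21.81, soil = rt_default_soil()) {
  rng <- rt_default_ranges()
  for (nm in names(rng)) {
    v <- params[[nm]]
    if (is.null(v) || v < rng[[nm]][1] - 1e-9 || v > rng[[nm]][2] + 1e-9)
      stop("parameter ", nm, " missing or outside its range")
  }
  cf <- rt_surrogate_coefs()
  rho_leaf <- cf$rho_inf * exp(-cf$k_ab * params$Cab / 100 -
                                 cf$k_w * params$Cw * 100 -
                                 cf$k_dm * params$Cdm * 100 -
                                 0.3 * params$Cbrown)
  K <- extinction_coefficient(
    chi_from_leaf_angle(params$average_leaf_angle_deg), zenith_deg)
  t2 <- exp(-2 * K * params$LAI)
  list(reflectance = rho_leaf * (1 - t2) + soil * t2,
       fiPAR = 1 - exp(-K * params$LAI), K = K)
}

#' Simulate a reflectance training set
#'
#' Uniform independent sampling of every parameter over its range, forward
#' simulation per sample. Reproducible by seed.
#'
#' @param n_samples number of simulations.
#' @param seed RNG seed.
#' @param ranges parameter ranges (\code{rt_default_ranges}).
#' @param zenith_deg,soil scene configuration passed to \code{forward}.
#' @param forward forward model function with the \code{\link{rt_forward}}
#'   signature.
#' @return list with params (data.frame), reflectance (n x 6 matrix),
#'   fiPAR (vector).
#' @export
rt_simulate <- function(n_samples, seed = 42, ranges = rt_default_ranges(),
                        zenith_deg = 21.81, soil = rt_default_soil(),
                        forward = rt_forward) {
  set.seed(seed)
  par <- as.data.frame(lapply(ranges, function(r)
    stats::runif(n_samples, r[1], r[2])))
  refl <- matrix(NA_real_, n_samples, 6)
  fip <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    fw <- forward(as.list(par[i, ]), zenith_deg = zenith_deg, soil = soil)
    refl[i, ] <- fw$reflectance
    fip[i] <- fw$fiPAR
  }
  list(params = par, reflectance = refl, fiPAR = fip)
}

#' Train per-trait inversion regressors on simulated spectra
#'
#' One many-to-one regressor per target (LAI and fiPAR) mapping the six
#' standardized band reflectances to the trait. Default engine is a
#' single-hidden-layer feed-forward network (20 units, deterministic seed);
#' a k-nearest-neighbor engine is selectable for fully deterministic tests.
#'
#' @param n_samples training-set size (>= 100; the operational default is
#'   1e5, scaled down in tests).
#' @param seed RNG seed for sampling and network initialization.
#' @param engine "nnet" or "knn".
#' @param hidden hidden units for the network engine.
#' @param k neighbors for the knn engine (default 1: exact memorization of
#'   the training set, fully deterministic).
#' @param ranges,zenith_deg,soil,forward passed to \code{\link{rt_simulate}}.
#' @return object of class \code{inversion_model}: per-target fits, input
#'   normalization constants, training ranges, n_samples, seed, engine and
#'   forward-model tag.
#' @export
rt_train <- function(n_samples = 100000, seed = 42,
                     engine = c("nnet", "knn"), hidden = 20, k = 1,
                     ranges = rt_default_ranges(), zenith_deg = 21.81,
                     soil = rt_default_soil(), forward = rt_forward) {
  engine <- match.arg(engine)
  if (n_samples < 100) stop("n_samples < 100")
  sim <- rt_simulate(n_samples, seed, ranges, zenith_deg, soil, forward)
  x <- sim$reflectance
  mu <- colMeans(x); sdv <- apply(x, 2, stats::sd)
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  targets <- list(LAI = sim$params$LAI, fiPAR = sim$fiPAR)
  t_range <- lapply(targets, range)
  fits <- list()
  for (nm in names(targets)) {
    y <- targets[[nm]]
    if (engine == "nnet") {
      set.seed(seed + 1)
      ysc <- (y - t_range[[nm]][1]) / diff(t_range[[nm]])
      fits[[nm]] <- nnet::nnet(xs, ysc, size = hidden, linout = TRUE,
                               decay = 1e-4, maxit = 500,
                               MaxNWts = 5000, trace = FALSE)
    } else {
      fits[[nm]] <- list(x = xs, y = y, k = k)
    }
  }
  structure(list(fits = fits, engine = engine, mu = mu, sd = sdv,
                 target_range = t_range, n_samples = n_samples, seed = seed,
                 hidden = hidden, k = k, zenith_deg = zenith_deg,
                 soil = soil,
                 forward_tag = if (identical(forward, rt_forward))
                   "surrogate-v1" else "external"),
            class = "inversion_model")
}

knn_predict <- function(fit, xs) {
  apply(xs, 1, function(q) {
    d <- sqrt(colSums((t(fit$x) - q)^2))
    mean(fit$y[order(d)[seq_len(fit$k)]])
  })
}

#' Predict traits from mean grid-cell reflectances
#'
#' @param model inversion_model from \code{\link{rt_train}}.
#' @param reflectance numeric vector of 6 reflectances in [0, 1], or a
#'   matrix with 6 columns (one row per tree).
#' @return data.frame with LAI and fiPAR, clipped to the training range of
#'   each target.
#' @export
rt_predict <- function(model, reflectance) {
  x <- if (is.matrix(reflectance)) reflectance else matrix(reflectance, 1)
  stopifnot(ncol(x) == 6)
  if (any(x < 0 | x > 1)) stop("reflectance outside [0, 1]")
  if (any(rowSums(abs(x)) == 0))
    stop("all-zero reflectance is not a physical spectrum")
  xs <- sweep(sweep(x, 2, model$mu), 2, model$sd, "/")
  out <- lapply(names(model$fits), function(nm) {
    r <- model$target_range[[nm]]
    p <- if (model$engine == "nnet")
      as.numeric(stats::predict(model$fits[[nm]], xs)) * diff(r) + r[1]
    else knn_predict(model$fits[[nm]], xs)
    pmin(pmax(p, r[1]), r[2])
  })
  names(out) <- names(model$fits)
  as.data.frame(out)
}

#' Serialize an inversion model to JSON
#'
#' Stores weights (or the kNN training table), normalization constants,
#' target ranges, seed and forward-model tag; \code{rt_model_from_json}
#' rebuilds a model whose predictions are identical.
#'
#' @param model inversion_model.
#' @param path output path (.json).
#' @return invisibly the path.
#' @export
rt_model_to_json <- function(model, path) {
  ser <- list(engine = model$engine, mu = model$mu, sd = model$sd,
              target_range = model$target_range,
              n_samples = model$n_samples, seed = model$seed,
              hidden = model$hidden, k = model$k,
              zenith_deg = model$zenith_deg, soil = model$soil,
              forward_tag = model$forward_tag)
  ser$fits <- lapply(model$fits, function(f) {
    if (model$engine == "nnet") list(wts = f$wts, n = f$n)
    else list(x = f$x, y = f$y, k = f$k)
  })
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname rt_model_to_json
#' @export
rt_model_from_json <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- list()
  for (nm in names(ser$fits)) {
    f <- ser$fits[[nm]]
    if (ser$engine == "nnet") {
      skel <- matrix(0, 2, f$n[1])
      fits[[nm]] <- nnet::nnet(skel, c(0, 1), size = f$n[2], linout = TRUE,
                               Wts = f$wts, maxit = 0, MaxNWts = 5000,
                               trace = FALSE)
      fits[[nm]]$wts <- f$wts
    } else {
      fits[[nm]] <- list(x = as.matrix(f$x), y = f$y, k = f$k)
    }
  }
  structure(list(fits = fits, engine = ser$engine, mu = ser$mu, sd = ser$sd,
                 target_range = ser$target_range, n_samples = ser$n_samples,
                 seed = ser$seed, hidden = ser$hidden, k = ser$k,
                 zenith_deg = ser$zenith_deg, soil = ser$soil,
                 forward_tag = ser$forward_tag),
            class = "inversion_model")
}

# ---- empirical trait regression ------------------------------------------

#' Stepwise multiple regression of a trait on VIs and canopy volume
#'
#' Forward selection (p-to-enter 0.05 on the new coefficient's t test) with
#' backward removal (p-to-remove 0.10), ordinary least squares at each step.
#' Ties between equally significant candidates break toward the lower
#' column index.
#'
#' @param y response vector (LAI or daily intercepted fraction).
#' @param candidates data.frame of candidate predictors (vegetation indices,
#'   canopy volume).
#' @param p_enter,p_remove entry/removal thresholds.
#' @return object of class \code{trait_equation}: intercept, coefficients,
#'   r_squared, rmse (residual standard error, n - k - 1 denominator),
#'   flag ("intercept_only" when nothing enters).
#' @export
stepwise_regression <- function(y, candidates, p_enter = 0.05,
                                p_remove = 0.10) {
  keep <- stats::complete.cases(y, candidates)
  y <- y[keep]; candidates <- candidates[keep, , drop = FALSE]
  if (length(y) < 10) stop("need >= 10 complete observations")
  sel <- character(0)
  nms <- names(candidates)
  repeat {
    changed <- FALSE
    # forward step
    pool <- setdiff(nms, sel)
    if (length(pool) > 0) {
      pvals <- vapply(pool, function(v) {
        d <- cbind(data.frame(y = y), candidates[c(sel, v)])
        fit <- stats::lm(y ~ ., data = d)
        cf <- summary(fit)$coefficients
        if (v %in% rownames(cf)) cf[v, 4] else 1
      }, numeric(1))
      best <- which(pvals < p_enter)
      if (length(best) > 0) {
        # lower column index wins ties (and near-ties from duplicates)
        ord <- order(pvals[best], match(pool[best], nms))
        sel <- c(sel, pool[best][ord[1]])
        changed <- TRUE
      }
    }
    # backward step
    if (length(sel) > 1) {
      d <- cbind(data.frame(y = y), candidates[sel])
      cf <- summary(stats::lm(y ~ ., data = d))$coefficients
      pv <- cf[intersect(sel, rownames(cf)), 4]
      worst <- names(pv)[which.max(pv)]
      if (max(pv) > p_remove) { sel <- setdiff(sel, worst); changed <- TRUE }
    }
    if (!changed) break
  }
  if (length(sel) == 0) {
    fit <- stats::lm(y ~ 1)
    eq <- trait_equation(intercept = stats::coef(fit)[[1]],
                         coefficients = numeric(0))
    eq$flag <- "intercept_only"
  } else {
    d <- cbind(data.frame(y = y), candidates[sel])
    fit <- stats::lm(y ~ ., data = d)
    cf <- stats::coef(fit)
    eq <- trait_equation(intercept = cf[[1]], coefficients = cf[-1])
  }
  s <- summary(fit)
  eq$r_squared <- s$r.squared
  eq$rmse <- s$sigma
  eq
}

#' Linear trait equation over vegetation indices and canopy volume
#'
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector (names drawn from NDVI, GNDVI,
#'   MCARI, NDRE, MSRre, Volume).
#' @return object of class \code{trait_equation}.
#' @export
trait_equation <- function(intercept, coefficients) {
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 r_squared = NA_real_, rmse = NA_real_, flag = ""),
            class = "trait_equation")
}

#' @export
print.trait_equation <- function(x, ...) {
  terms <- if (length(x$coefficients) > 0)
    paste(sprintf("%+.4g %s", x$coefficients, names(x$coefficients)),
          collapse = " ") else ""
  cat(sprintf("trait_equation: y = %.4g %s  (R2 = %.3g, RMSE = %.3g)\n",
              x$intercept, terms, x$r_squared, x$rmse))
  invisible(x)
}

#' Evaluate a trait equation
#'
#' @param eq trait_equation.
#' @param values named list or data.frame providing every named input.
#' @return list with value (floored at 0) and flag ("floored" when the raw
#'   evaluation was negative).
#' @export
apply_trait_equation <- function(eq, values) {
  vals <- as.list(values)
  missing <- setdiff(names(eq$coefficients), names(vals))
  if (length(missing) > 0) stop("missing inputs: ",
                                paste(missing, collapse = ", "))
  raw <- eq$intercept
  for (nm in names(eq$coefficients))
    raw <- raw + eq$coefficients[[nm]] * unlist(vals[[nm]])
  flag <- ifelse(raw < 0, "floored", "")
  list(value = pmax(raw, 0), flag = flag)
}

#' Reference almond trait calibrations
#'
#' Multi-date almond calibrations of LAI and daily intercepted PAR fraction
#' against vegetation indices and net canopy volume (m3):
#' LAI = 0.49 + 1.98 NDRE - 1.06 NDVI + 0.03 Volume;
#' fiPARd = -0.24 + 0.62 GNDVI + 6.95 MCARI + 1.19 NDRE - 0.65 NDVI +
#' 0.01 Volume.
#'
#' @return named list of two trait_equation objects (lai, fipar_d).
#' @export
almond_trait_equations <- function() {
  list(lai = trait_equation(0.49, c(NDRE = 1.98, NDVI = -1.06,
                                    Volume = 0.03)),
       fipar_d = trait_equation(-0.24, c(GNDVI = 0.62, MCARI = 6.95,
                                         NDRE = 1.19, NDVI = -0.65,
                                         Volume = 0.01)))
}
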