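#!/usr/bin/env Rscript
# Traits stage: vegetation indices, radiative-transfer trait inversion
# (network trained on simulated spectra), hourly-interception daily fiPAR,
# and a stepwise empirical calibration of LAI on VIs + canopy volume.

suppressPackageStartupMessages(library(orchardet))

scene <- load_scene("scratch/scene")
st <- run_structure(scene)
tr <- run_traits(scene, st)
write.csv(tr$traits, "results/traits.csv", row.names = FALSE)
rt_model_to_json(tr$model, "results/inversion_model.json")

ok <- !is.na(tr$traits$LAI_rt_canopy)
rmse <- sqrt(mean((tr$traits$LAI_rt_canopy[ok] -
                     scene$truth$LAI_true[ok])^2))
cat(sprintf("RT inversion (n = %d training spectra): canopy LAI RMSE %.2f over %d trees\n",
            tr$model$n_samples, rmse, sum(ok)))
cat(sprintf("daily intercepted fraction spans %.2f-%.2f (porosity %.2f-%.2f)\n",
            min(tr$traits$fiPAR_d, na.rm = TRUE),
            max(tr$traits$fiPAR_d, na.rm = TRUE),
            min(tr$traits$porosity, na.rm = TRUE),
            max(tr$traits$porosity, na.rm = TRUE)))

# empirical calibration against the generator truth (the synthetic stand-in
# for ground LAI), candidates = five VIs + net canopy volume
cand <- data.frame(NDVI = tr$traits$ndvi, GNDVI = tr$traits$gndvi,
                   MCARI = tr$traits$mcari, NDRE = tr$traits$ndre,
                   MSRre = tr$traits$msrre,
                   Volume = st$structure$volume_net)
eq <- stepwise_regression(scene$truth$LAI_true, cand)
cat("stepwise LAI calibration: ")
print(eq)
capture <- c(intercept = eq$intercept, eq$coefficients,
             R2 = eq$r_squared, RMSE = eq$rmse)
write.csv(data.frame(term = names(capture), value = unname(capture)),
          "results/lai_stepwise_equation.csv", row.names = FALSE)
cat("traits in results/traits.csv; calibration in results/lai_stepwise_equation.csv\n")
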