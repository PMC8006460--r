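#!/usr/bin/env Rscript
# Simulate one synthetic airborne campaign over the rootstock trial:
# clear-sky diurnal weather for a late-July acquisition plus the orchard
# scene bundle (DSM/DTM, six reflectance bands, thermal layer, tree and
# truth tables). Rasters go to scratch/ (large), tables to results/.

suppressPackageStartupMessages(library(orchardet))

seed <- 42
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

weather <- generate_weather(doy = 205, lat = 41.5, lon = 0.85, seed = seed)
cat(sprintf("acquisition: DOY %d, %.2f h UTC, zenith %.2f deg\n",
            weather$doy, weather$acquisition_hour, weather$zenith_deg))
cat(sprintf("air %.1f C, VPD %.2f kPa, Rs %.0f W/m2 (daily mean %.0f)\n",
            weather$meteo$Ta - 273.15, weather$meteo$VPD,
            weather$meteo$Rs_inst, weather$meteo$Rs_daily_mean))

config <- orchard_config(seed = seed)
scene <- generate_orchard(config, weather, seed = seed)
save_scene(scene, "scratch/scene")
write.csv(scene$truth, "results/truth.csv", row.names = FALSE)
write.csv(weather$table, "results/weather.csv", row.names = FALSE)

cat(sprintf("scene: %d trees, %d x %d multispectral px, %d x %d thermal px\n",
            nrow(scene$trees), nrow(scene$bands$bands[[1]]$values),
            ncol(scene$bands$bands[[1]]$values),
            nrow(scene$thermal$values), ncol(scene$thermal$values)))
cat(sprintf("imposed stress spans %.2f-%.2f; canopy Tc - Ta spans %.1f-%.1f K\n",
            min(scene$truth$stress), max(scene$truth$stress),
            min(scene$truth$Tc_true) - weather$meteo$Ta,
            max(scene$truth$Tc_true) - weather$meteo$Ta))
cat("bundle written to scratch/scene; truth and weather tables in results/\n")
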