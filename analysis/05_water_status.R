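#!/usr/bin/env Rscript
# Water-status stage: CWSI per tree, its relation to the imposed stress,
# a seasonal irrigation water balance, and water productivity under a
# synthetic yield-vigor assumption.

suppressPackageStartupMessages(library(orchardet))

scene <- load_scene("scratch/scene")
st <- run_structure(scene)
tr <- run_traits(scene, st, model = rt_model_from_json(
  "results/inversion_model.json"))
en <- run_energy(scene, st, tr)
ws <- run_water_status(en, scene)
write.csv(ws, "results/water_status.csv", row.names = FALSE)

ok <- !is.na(ws$CWSI)
cat(sprintf("CWSI spans %.2f-%.2f over %d trees\n",
            min(ws$CWSI[ok]), max(ws$CWSI[ok]), sum(ok)))
cat(sprintf("Spearman(imposed stress, CWSI) = %.3f\n",
            cor(ws$stress[ok], ws$CWSI[ok], method = "spearman")))
cat(sprintf("Spearman(imposed stress, Tc - Ta) = %.3f\n",
            cor(ws$stress[ok], ws$Tc_minus_Ta[ok], method = "spearman")))

# seasonal irrigation requirement for a dry July-August with two rain events
dates <- seq(as.Date("2018-07-01"), as.Date("2018-08-31"), by = "day")
set.seed(scene$config$seed)
eto <- round(runif(length(dates), 4.5, 7.0), 1)
rain <- rep(0, length(dates)); rain[c(20, 45)] <- c(14, 8)
wb <- water_balance(dates, eto, rain)
write.csv(wb$daily, "results/water_balance.csv", row.names = FALSE)
cat(sprintf("season ETc %.0f mm = ETo x Kc %.0f mm - effective rain %.0f mm\n",
            wb$totals["ETc_mm"], wb$totals["ETo_Kc_mm"],
            wb$totals["P_eff_mm"]))

# water productivity: synthetic kernel yield proportional to unstressed
# transpiration capacity (documented stand-in, no field yields exist here)
period_et <- ws$ET_a[ok] * 60          # ~60-day mid-season window, mm
yield <- 2 + 6 * (1 - ws$stress[ok]) * scene$truth$LAI_true[ok] /
  max(scene$truth$LAI_true)
wp <- water_productivity(yield, period_et)
cat(sprintf("synthetic water productivity %.3f-%.3f kg/mm (median %.3f)\n",
            min(wp), max(wp), median(wp)))
cat("tables in results/water_status.csv and results/water_balance.csv\n")
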