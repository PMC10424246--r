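#!/usr/bin/env Rscript
# Printability of the cell-medium bioink through a 250 um valve nozzle.
#
# The medium's measured viscosity, surface tension, density and droplet
# velocity are not published, so the profile is computed for a documented
# water-like medium (culture media are dilute aqueous solutions). The
# regime conclusions — gravity negligible (Bo < 1) and no significant
# splashing (K_sp < 57.7) — are the analysis surface; the reported
# configuration's K_sp of 5.1 is classified alongside.

suppressPackageStartupMessages(library(aliprint))
dir.create("results", showWarnings = FALSE)

spec <- water_like_medium(droplet_velocity = 2)
prof <- printability_profile(spec)
print(spec)
print(prof)

# gravimetric sizing example: 1000 droplets weighing 10 mg at ~1000 kg/m3
dv <- droplet_volume(1.0e-5, 1000, 1000)
cat(sprintf("\nPer-droplet volume %.1f nl, equivalent diameter %.0f um\n",
            dv$volume * 1e12, dv$diameter * 1e6))

cat(sprintf("Reported splashing parameter 5.1 classifies as splashing: %s\n",
            is_splashing(5.1)))

out <- as.data.frame(prof)
out$droplet_volume_nl <- dv$volume * 1e12
out$droplet_diameter_um <- dv$diameter * 1e6
write.csv(out, "results/printability_profile.csv", row.names = FALSE)
cat("\nWrote results/printability_profile.csv\n")
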