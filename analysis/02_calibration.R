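#!/usr/bin/env Rscript
# Stage 2: fit internal-standard calibration curves in both media, derive
# LOD/LOQ from the blank statistics, and assess the matrix effect by slope
# comparison.

suppressPackageStartupMessages(library(carbrisk))
dat <- "results/data"

solv <- fit_calibration(read_calibration_csv(file.path(dat, "calibration_solvent.csv")))
matr <- fit_calibration(read_calibration_csv(file.path(dat, "calibration_matrix.csv")))
blanks <- read_blank_csv(file.path(dat, "blanks.csv"))
limits <- lod_loq(blanks, solv)
me <- matrix_effect(matr, solv)

print(solv)
cat(sprintf("LOD = %.4g ug/kg, LOQ = %.4g ug/kg (LOQ/LOD = %.4f)\n",
            limits[["lod"]], limits[["loq"]], limits[["loq"]] / limits[["lod"]]))
print(me)

jsonlite::write_json(
  list(solvent = list(slope = solv$slope, intercept = solv$intercept,
                      r_squared = solv$r_squared),
       matrix = list(slope = matr$slope, intercept = matr$intercept,
                     r_squared = matr$r_squared),
       lod_ug_per_kg = limits[["lod"]], loq_ug_per_kg = limits[["loq"]],
       matrix_effect_percent = me$me_percent,
       matrix_effect_class = me$classification),
  "results/calibration_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote results/calibration_report.json\n")
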