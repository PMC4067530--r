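#!/usr/bin/env Rscript
# Derived biophysical constants of the ParABS segregation system: spring
# constants of chromosomal loci, force estimates for the translocating
# partition complex, the optimal ATP-hydrolysis time, cellular
# concentrations, and geometric bounds on a hypothetical ParA filament.

suppressPackageStartupMessages(library(dnarelay))
dir.create("results", showWarnings = FALSE)

rows <- list()
add <- function(quantity, value, units) {
  rows[[length(rows) + 1]] <<- data.frame(quantity = quantity,
                                          value = value, units = units)
}

k_long <- sigma_to_kspring(0.064)
k_short <- sigma_to_kspring(0.038)
add("spring constant, long axis", report_signif(k_long$k_pN_per_nm, 1),
    "pN/nm")
add("spring constant, short axis", report_signif(k_short$k_pN_per_nm, 1),
    "pN/nm")
add("k_sp/kT at sigma = 60 nm",
    report_signif(sigma_to_kspring(0.06)$k_over_kT_um2, 2), "um^-2")

add("drag force at 0.003 um/s",
    report_signif(drag_force(v = 0.003, D = 1e-4)$force_pN, 1), "pN")
add("elastic tether force", elastic_force(0.001, 60)$force_pN, "pN")

opt <- optimal_hydrolysis_time(sigma = 0.06, D = 1e-4)
add("optimal tether attachment time", opt$attachment_time_s, "s")
add("optimal hydrolysis rate", report_signif(opt$rate_per_s, 1), "s^-1")

add("in-vivo DNA concentration",
    report_signif(dna_concentration(4e6, 650, 2.5e-13), 2), "mg/ml")
add("diffusing ParB",
    molecules_to_concentration(moles = 0.2e-21, volume_fL = 0.25), "uM")
add("ParA", molecules_to_concentration(moles = 0.3e-21, volume_fL = 0.25),
    "uM")
add("parS-associated ParB (local)",
    molecules_to_concentration(moles = 1e-21, volume_fL = 0.002), "uM")

fb <- filament_length_bounds(90)
add("max nucleoprotein filament", round(fb$nucleoprotein_nm), "nm")
add("max linear filament", round(fb$linear_nm), "nm")

add("effective D of DNA-bound dimers at 1 ms (upper)",
    effective_D_at_timescale(1.5e-3, 1e-3, alpha = 0.4), "um^2/s")
add("effective D of DNA-bound dimers at 1 ms (lower)",
    effective_D_at_timescale(0.25e-3, 1e-3, alpha = 0.4), "um^2/s")

tab <- do.call(rbind, rows)
write.csv(tab, "results/derived_constants.csv", row.names = FALSE)
print(tab, row.names = FALSE)
message("\nThe drag estimate (0.1 pN) and the elastic estimate (0.06 pN) ",
        "agree within a factor of two: one or two chromosomal tethers ",
        "suffice to drive the observed translocation speed.")
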