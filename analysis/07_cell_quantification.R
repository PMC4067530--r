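#!/usr/bin/env Rscript
# Cell-level scoring: the GFP-ParB partition fraction from segment
# profiles, the bimodal autofluorescence split, and the aspect-ratio
# decompaction profile along the cell.

suppressPackageStartupMessages(library(dnarelay))
dir.create("results", showWarnings = FALSE)
seed <- 1L

# partition fraction across cells with 80% of signal in the focus
set.seed(seed)
fracs <- vapply(1:50, function(i) {
  g <- gen_segment_profile(focus_fraction = 0.8, noise_frac = 0.05,
                           seed = seed + i)
  partition_fraction(g$data$fluorescence, g$data$area)
}, numeric(1))
message(sprintf("partition fraction: %.3f +- %.3f (construction truth 0.80)",
                mean(fracs), sd(fracs)))

# bimodal split of normalized fluorescence: autofluorescent vs expressing
set.seed(seed + 1)
vals <- c(rnorm(400, 1, 0.25), rnorm(600, 4, 0.8))
bim <- fit_bimodal_gaussian(vals)
message(sprintf("autofluorescence mean %.2f, expressing mean %.2f (truth 1, 4)",
                bim$means[1], bim$means[2]))

# decompaction along the cell: stretched complexes mid-cell, compact at poles
set.seed(seed + 2)
n <- 300
pos <- runif(n)
stretch <- ifelse(pos > 0.35 & pos < 0.85, 2.2, 1.1)
ars <- vapply(seq_len(n), function(i) {
  g <- gen_elliptical_region(n_points = 300, sd_major = stretch[i],
                             sd_minor = 1, seed = seed + 100 + i)
  aspect_ratio(g$data)$aspect_ratio
}, numeric(1))
prof <- decompaction_profile(pos, ars)
write.csv(prof, "results/decompaction_profile.csv", row.names = FALSE)
print(prof, row.names = FALSE)

out <- list(partition_fraction_mean = mean(fracs),
            partition_fraction_sd = sd(fracs),
            autofluorescence_mean = bim$means[1],
            expressing_mean = bim$means[2],
            mixture_weights = bim$weights)
jsonlite::write_json(out, "results/cell_quantification.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
message("\nDecompacted (AR > 1.5) complexes concentrate away from the ",
        "poles, where tether forces act during translocation.")
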