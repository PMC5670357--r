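#!/usr/bin/env Rscript

# Step 2: run the full synthetic study and tabulate every circadian
# parameter per animal and per group.
#
# For each animal the DD arm yields the free-running period (chi-square
# periodogram), the wavelet period-variability index V, interdaily
# stability, intradaily variability, and the alpha/rho partition; the
# jet-lag arm yields phase angles before and after the shift, the LD
# period and the diurnal activity share. Group means +/- SEM and Student's
# t contrasts are written alongside.

suppressMessages(library(circact))

config <- read_study_config("results/study_config.yaml")
rep <- suppressMessages(suppressWarnings(run_study(config)))

write.csv(rep$per_animal, "results/per_animal.csv", row.names = FALSE)
write.csv(rep$group_summary, "results/group_summary.csv", row.names = FALSE)
write.csv(rep$tests, "results/group_tests.csv", row.names = FALSE)

print(rep)

g <- rep$group_summary
pick <- function(grp, m) g$mean[g$group == grp & g$metric == m]
cat(sprintf(
  "\nFindings: tau %.2f vs %.2f h, IS %.2f vs %.2f, IV %.2f vs %.2f (sham vs implanted-like)\n",
  pick("sham", "tau"), pick("implanted", "tau"),
  pick("sham", "IS"), pick("implanted", "IS"),
  pick("sham", "IV"), pick("implanted", "IV")))
cat(sprintf("%d per-animal analysis failures\n", length(rep$failures)))
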