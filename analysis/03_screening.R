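#!/usr/bin/env Rscript
# Screening statistics: CV profiles, optimal screening concentration,
# tolerance ranking, parent pair, and pairwise significance annotation.
#
# Reads the simulated trial (run 01_simulate.R first) and writes the
# screening report under results/.

suppressPackageStartupMessages(library(kscreen))

obs <- read_trial_table("results/trial.csv")
design <- read_design("results/design.yaml")
summ <- summarize_treatments(obs)

prof <- cv_profile(summ)
opt <- optimal_concentration(prof, reference = design$reference_concentration)
readr::write_csv(prof, "results/cv_profile.csv")
readr::write_csv(relative_traits(summ, design), "results/relative_traits.csv")

cat("Per-trait CV argmax / argmin concentrations (mg/L):\n")
print(as.data.frame(opt$per_trait), row.names = FALSE)
cat(sprintf("Consensus optimal screening concentration: %g mg/L\n\n",
            opt$consensus))

ranking <- rank_tolerance(summ, design)
pair <- select_parent_pair(ranking)
cat("Tolerance ranking (overall score = mean per-trait rank; lower = more tolerant):\n")
print(as.data.frame(ranking), digits = 3, row.names = FALSE)
cat(sprintf("\nSelected parent pair: %s (tolerant) x %s (sensitive), theta = %.2f%s\n",
            pair$tolerant, pair$sensitive, pair$theta_used,
            if (pair$relaxed) " (relaxed)" else ""))

sig <- significance_table(obs, c(pair$tolerant, pair$sensitive), design)
stars <- tidyr::pivot_wider(sig[, c("trait", "concentration", "stars")],
                            names_from = "concentration",
                            values_from = "stars")
cat("\nSignificance stars (paired t on relative values, tolerant - sensitive):\n")
print(as.data.frame(stars), row.names = FALSE)

jsonlite::write_json(
  list(optimal_concentration = opt$consensus, per_trait = opt$per_trait,
       ranking = ranking, tolerant = pair$tolerant,
       sensitive = pair$sensitive, significance = sig),
  "results/screening.json", auto_unbox = TRUE, digits = NA)
cat("\nWrote results/cv_profile.csv, relative_traits.csv, screening.json\n")
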