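#!/usr/bin/env Rscript
# Parameter-recovery experiment.
#
# Re-runs the whole pipeline over 50 independent seeds and asks how often
# it recovers (a) the planted optimal screening concentration and (b) the
# planted extreme varieties as the selected parent pair. This is the
# package's own power check: under the default study conditions both
# should be recovered in at least 90% of trials.

suppressPackageStartupMessages(library(kscreen))

design <- trial_design(sprintf("V%02d", 1:12))
params <- generator_params(design$varieties)
truth <- planted_truth(params, design)
planted_tol <- names(which.max(params$s))
planted_sen <- names(which.min(params$s))

rows <- lapply(1:50, function(seed) {
  obs <- generate_trial(design, params, seed = seed)
  summ <- summarize_treatments(obs)
  opt <- optimal_concentration(cv_profile(summ),
                               reference = design$reference_concentration)
  pair <- select_parent_pair(rank_tolerance(summ, design))
  tibble::tibble(seed = seed, consensus = opt$consensus,
                 tolerant = pair$tolerant, sensitive = pair$sensitive,
                 opt_ok = identical(opt$consensus, truth$consensus),
                 pair_ok = pair$tolerant == planted_tol &
                   pair$sensitive == planted_sen)
})
res <- dplyr::bind_rows(rows)
dir.create("results", showWarnings = FALSE)
readr::write_csv(res, "results/recovery.csv")

cat(sprintf("Planted optimum %g mg/L recovered in %d/50 seeds (%.0f%%).\n",
            truth$consensus, sum(res$opt_ok), 2 * sum(res$opt_ok)))
cat(sprintf("Planted pair (%s, %s) recovered in %d/50 seeds (%.0f%%).\n",
            planted_tol, planted_sen, sum(res$pair_ok), 2 * sum(res$pair_ok)))
cat("Wrote results/recovery.csv\n")
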