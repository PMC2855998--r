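#!/usr/bin/env Rscript
# Stage 6: headline summaries over the packaged printed tables.

suppressPackageStartupMessages(library(bmadex))

t2 <- load_table2()
d <- direction_split(t2)
cc <- cross_contrast_concordance(t2)
rho <- spearman_fold_correlation(t2$fold_rm_hn, t2$fold_rm_pm)
ages <- group_age_summary(load_table1())

cat(sprintf("signature: %d probe-set rows\n", nrow(t2)))
cat(sprintf("direction split: %d higher in RM, %d higher in HN\n",
            d[["n_higher_ref"]], d[["n_higher_other"]]))
cat(sprintf("PM/HN sign concordance: %d of %d; discordant: %s\n",
            cc$n_concordant, nrow(t2),
            paste(cc$discordant$symbol, collapse = ", ")))
cat(sprintf("overlap with the prior probe-set list: %d rows flagged\n",
            prior_overlap(t2)))
cat(sprintf("Spearman rho, RM:HN vs RM:PM folds: %.3f\n", rho))
cat("\ncohort ages:\n")
print(ages)

write.table(ages, "results/cohort_ages.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
lines <- c(
  "# Headline summary",
  "",
  sprintf("- signature rows: %d", nrow(t2)),
  sprintf("- higher in RM: %d; higher in HN: %d",
          d[["n_higher_ref"]], d[["n_higher_other"]]),
  sprintf("- PM expression in the HN direction: %d/%d (discordant: %s)",
          cc$n_concordant, nrow(t2),
          paste(cc$discordant$symbol, collapse = ", ")),
  sprintf("- prior-list overlap: %d", prior_overlap(t2)),
  sprintf("- Spearman rho of fold spectra: %.3f", rho),
  sprintf("- mean ages: RM %.1f, HN %.1f, PM %.0f",
          ages$mean_age[ages$group == "RM"],
          ages$mean_age[ages$group == "HN"],
          ages$mean_age[ages$group == "PM"]))
writeLines(lines, "results/summary.md")
cat("\nwrote results/summary.md\n")
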