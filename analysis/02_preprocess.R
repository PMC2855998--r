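#!/usr/bin/env Rscript
# Stage 2: the study's two preprocessing rules.
#
# Probes with fewer than 20% Present calls across all samples are removed;
# every sample is then rescaled to a mean intensity of 200 (the only
# normalisation applied - no background correction, no quantile step).

suppressPackageStartupMessages(library(bmadex))

em <- read_expression_matrix("results/simulated_expression.tsv",
                             "results/simulated_detection.tsv")
filt <- filter_detection(em, min_detect_frac = 0.20)
em2 <- rescale_samples(filt$matrix, target_mean = 200)

write_expression_matrix(em2, "results/preprocessed_expression.tsv",
                        "results/preprocessed_detection.tsv")
writeLines(filt$removed_probe_ids, "results/removed_probes.txt")

cat(sprintf("removed %d probes with <20%% detectable hybridisation; %d retained\n",
            length(filt$removed_probe_ids), nrow(em2$intensities)))
cat(sprintf("per-sample mean intensity after rescaling: %.6f\n",
            mean(colMeans(em2$intensities))))
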