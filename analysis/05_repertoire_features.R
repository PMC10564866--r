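#!/usr/bin/env Rscript
# Stage 5: build the repertoire feature panels for the gut compartment
# and compare eART vs lART: Fisher 2x2 per categorical (feature, level)
# parameter, Welch t for continuous ones, volcano table with unadjusted
# p < 0.05 flags plus BH-adjusted values, and the IgA/IgG ratio per group.

library(repgut)

outdir <- "results/features"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

pass <- read_rearrangements("results/annotated/rearrangements_pass.tsv")
gut <- pass[pass$compartment == "gut", ]
panel_e <- build_feature_panel(gut[gut$group == "eART", ])
panel_l <- build_feature_panel(gut[gut$group == "lART", ])
cmp <- compare_repertoires(panel_e, panel_l)
write.table(cmp, file.path(outdir, "feature_comparison.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("tested %d repertoire parameters (%d categorical, %d continuous)\n",
            nrow(cmp), sum(cmp$test == "fisher_2x2"),
            sum(cmp$test == "welch_t")))
cat(sprintf("%d parameters significant at unadjusted p < 0.05\n",
            sum(cmp$significant)))
sig <- cmp[cmp$significant, c("feature", "level", "effect", "p", "bh_p")]
if (nrow(sig) > 0) print(sig, row.names = FALSE)

for (g in c("eART", "lART")) {
  cat(sprintf("IgA/IgG ratio (gut, %s): %.2f\n", g, iga_igg_ratio(gut, g)))
}
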