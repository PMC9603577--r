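#!/usr/bin/env Rscript
# Step 2 — threshold classification and three-tool consensus tiering.
#
# Reads the canonical score table from step 1, recomputes every tool's
# categorical call from the published thresholds, tiers each substitution by
# the HumDiv/HumVar/PROVEAN panel vote count (P3/P2/B2/B3), and exports the
# tier table plus the 20 x 300 heatmap matrix (wild-type cells ".").

suppressPackageStartupMessages(library(cdkl5sat))

scores <- read_score_table("results/scores.tsv")
domain <- read_protein_fasta("results/synthetic_domain.fasta")

tiers <- tier_table(scores) # panel: humdiv + humvar + provean
write.table(tiers, "results/tiers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

s <- tier_summary(tiers)
write.table(s, "results/tier_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Consensus tier distribution over", nrow(tiers), "substitutions:\n")
print(s)
cat("Pathogenic (P3+P2):", sum(s$pct[s$tier %in% c("P3", "P2")]),
    "%  benign (B2+B3):", sum(s$pct[s$tier %in% c("B2", "B3")]), "%\n")

mat <- build_heatmap(tiers, domain$residues)
write_heatmap_tsv(mat, "results/heatmap.tsv")
cat("Wrote results/tiers.tsv, results/tier_summary.tsv, results/heatmap.tsv\n")
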