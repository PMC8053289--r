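#!/usr/bin/env Rscript
# Stage 3: NB Wald differential expression.
#
# Median-of-ratios size factors and trend-shrunk dispersions are estimated
# once on the filtered matrix; the five pairwise contrasts of the design
# (CC vs RR and each F1 vs each parent) are then tested and BH-adjusted.

suppressPackageStartupMessages(library(hetexpr))

bundle <- file.path("results", "bundle")
counts <- read_counts(file.path(bundle, "counts.tsv"))
samples <- read_sample_table(file.path(bundle, "samples.csv"))
kept <- read.delim(file.path("results", "kept_genes.tsv"))$gene_id

de <- run_comparisons(counts[kept, ], samples)
sf <- attr(de, "size_factors")
cat("size factors:\n")
print(round(sf, 3))
cat("dispersion trend: a0 =", round(attr(attr(de, "dispersions"),
                                         "trend")[["a0"]], 4),
    " a1 =", round(attr(attr(de, "dispersions"), "trend")[["a1"]], 4), "\n\n")

for (nm in names(de)) {
  n_deg <- length(deg_genes(de[[nm]]))
  cat(sprintf("%-10s %5d DEGs (padj < 0.05) of %d genes\n",
              nm, n_deg, nrow(de[[nm]])))
  write.table(de[[nm]], file.path("results", paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
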