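#!/usr/bin/env Rscript
# Stage 4: expression inheritance patterns.
#
# Every DEG of a cross (union over its three contrasts) is assigned one of
# twelve pattern classes and grouped into additive, dominant or
# overdominant inheritance; the nonadditive share per cross and the
# class table of nonadditive genes shared by both crosses are reported.
# Recovery against the planted ground truth closes the loop.

suppressPackageStartupMessages(library(hetexpr))

resdir <- "results"
rd <- function(f) read.delim(file.path(resdir, f))
fpkm_df <- rd("fpkm.tsv")
fpkm <- as.matrix(fpkm_df[, -1]); rownames(fpkm) <- fpkm_df$gene_id
kept <- rd("kept_genes.tsv")$gene_id
samples <- read_sample_table(file.path(resdir, "bundle", "samples.csv"))
means <- group_mean_fpkm(fpkm[kept, ], samples)

de <- lapply(c(CC_vs_RR = "de_CC_vs_RR.tsv", CR_vs_CC = "de_CR_vs_CC.tsv",
               CR_vs_RR = "de_CR_vs_RR.tsv", RC_vs_CC = "de_RC_vs_CC.tsv",
               RC_vs_RR = "de_RC_vs_RR.tsv"), rd)

calls <- list(
  CR = classify_cross(de$CC_vs_RR, de$CR_vs_CC, de$CR_vs_RR, means, "CR"),
  RC = classify_cross(de$CC_vs_RR, de$RC_vs_CC, de$RC_vs_RR, means, "RC"))

for (cr in names(calls)) {
  write.table(calls[[cr]], file.path(resdir, paste0("calls_", cr, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
summary <- rbind(summarize_modes(calls$CR), summarize_modes(calls$RC))
write.table(summary, file.path(resdir, "mode_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(summary[, c("cross", "n_universe", "n_additive", "n_dominant",
                  "n_overdominant", "n_unclassified", "nonadditive_pct")],
      row.names = FALSE)

sh <- shared_nonadditive(calls$CR, calls$RC)
write.table(sh$class_table, file.path(resdir,
                                      "shared_nonadditive_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nnonadditive genes shared by both crosses:", nrow(sh$genes), "\n")
print(head(sh$class_table, 6), row.names = FALSE)

# recovery against the planted truth
truth <- rd(file.path("bundle", "ground_truth.tsv"))
truth <- truth[truth$gene_id %in% kept, ]
mode_of <- c(CONSERVED = "CONSERVED", ADDITIVE = "ADDITIVE",
             DOMINANT_HIGH = "DOMINANT", DOMINANT_LOW = "DOMINANT",
             OVERDOMINANT_UP = "OVERDOMINANT",
             OVERDOMINANT_DOWN = "OVERDOMINANT")
cat("\nplanted-mode recovery (CR):\n")
for (m in c("ADDITIVE", "DOMINANT", "OVERDOMINANT")) {
  planted <- truth$gene_id[mode_of[truth$mode] == m]
  called <- calls$CR$mode[match(planted, calls$CR$gene_id)]
  cat(sprintf("  %-13s %5.1f%% of %d planted genes\n", m,
              100 * mean(!is.na(called) & called == m), length(planted)))
}
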