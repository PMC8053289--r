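#!/usr/bin/env Rscript
# Stage 5: mid-parent heterosis of the phenotypic traits.
#
# For each trait and each cross, H% is the relative deviation of the F1
# mean from the mid-parent value; significance comes from the one-sample
# t-test of the F1 values against the (fixed) mid-parent.

suppressPackageStartupMessages(library(hetexpr))

pheno <- read_phenotypes(file.path("results", "bundle", "phenotypes.csv"))
tb <- heterosis_table(pheno)
write.table(tb, file.path("results", "heterosis.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("mid-parent heterosis per trait and cross:\n")
for (i in seq_len(nrow(tb))) {
  cat(sprintf("  %-16s %s  N=%-3d H%% = %+7.2f  t = %+7.2f  p = %.3g [%s]\n",
              tb$trait[i], tb$cross[i], tb$N[i], tb$H_percent[i], tb$t[i],
              tb$p[i], tb$tier[i]))
}
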