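#!/usr/bin/env Rscript
# Stage 2: FPKM and the two gene filters.
#
# Genes with a mean FPKM below 1 across all samples lack the statistical
# power for differential testing and are removed; sex-linked (Z/W) genes
# are removed because the sequenced individuals are all female and the
# crosses differ systematically on the sex chromosomes.

suppressPackageStartupMessages(library(hetexpr))

bundle <- file.path("results", "bundle")
counts <- read_counts(file.path(bundle, "counts.tsv"))
annot <- read_annotation(file.path(bundle, "annotation.tsv"))

fpkm <- compute_fpkm(counts, annot)
flt <- filter_genes(fpkm, annot, min_mean_fpkm = 1,
                    sex_chromosomes = c("Z", "W"))

cat("genes in:", nrow(counts), "\n")
cat("removed: ", nrow(flt$removed), "\n")
print(table(flt$removed$reason))
cat("retained for differential analysis:", length(flt$kept), "\n")

dir.create("results", showWarnings = FALSE)
write.table(data.frame(gene_id = rownames(fpkm), round(fpkm, 6),
                       check.names = FALSE),
            file.path("results", "fpkm.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = flt$kept),
            file.path("results", "kept_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(flt$removed, file.path("results", "removed_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
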