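#' Read a gene-level count matrix from TSV
#'
#' First column is the gene id; remaining columns are samples with integer
#' fragment counts.
#'
#' @param path TSV file.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  validate_counts(m)
  m
}

#' Write a count matrix as TSV
#' @param counts integer matrix, genes x samples.
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample table (sample_id, group) from CSV
#' @param path CSV file with columns `sample_id`, `group`.
#' @return data.frame.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("sample table needs columns sample_id, group")
  }
  bad <- setdiff(unique(df$group), GROUPS)
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  df
}

#' Read the gene annotation (gene_id, chromosome, length_bp) from TSV
#' @param path TSV file.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chromosome = "character"))
  if (!all(c("gene_id", "chromosome", "length_bp") %in% names(df))) {
    stop("annotation needs columns gene_id, chromosome, length_bp")
  }
  if (any(df$length_bp <= 0)) stop("annotation length_bp must be > 0")
  df
}

#' Read an individual-level phenotype table from CSV
#' @param path CSV with columns `individual_id`, `group`, then traits.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "group") %in% names(df))) {
    stop("phenotype table needs columns individual_id, group")
  }
  if (anyDuplicated(df$individual_id)) {
    stop("phenotype table has duplicated individual ids")
  }
  df
}

# structural checks shared by every statistical stage
validate_counts <- function(counts, samples = NULL) {
  if (nrow(counts) > 0 &&
      (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))) {
    stop("count matrix needs unique gene ids as rownames")
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("count matrix needs unique sample ids as colnames")
  }
  if (any(counts < 0)) stop("count matrix has negative cells")
  if (any(counts != round(counts))) stop("count matrix has non-integer cells")
  if (!is.null(samples)) {
    if (!all(colnames(counts) %in% samples$sample_id)) {
      stop("samples missing from sample table: ",
           paste(setdiff(colnames(counts), samples$sample_id), collapse = ", "))
    }
  }
  invisible(TRUE)
}

# group factor aligned to count-matrix columns
sample_groups <- function(counts, samples) {
  validate_counts(counts, samples)
  idx <- match(colnames(counts), samples$sample_id)
  setNames(samples$group[idx], colnames(counts))
}

#' Compute FPKM from a count matrix
#'
#' FPKM for gene g in sample s is
#' `counts_gs * 1e9 / (column_total_s * length_g)`, with the column total
#' taken as the sum of assigned fragments in the analyzed matrix.
#'
#' @param counts integer matrix, genes x samples.
#' @param annot annotation data.frame covering every gene
#'   (`gene_id`, `length_bp`).
#' @return numeric matrix of FPKM values, same shape as `counts`.
#' @export
compute_fpkm <- function(counts, annot) {
  validate_counts(counts)
  missing <- setdiff(rownames(counts), annot$gene_id)
  if (length(missing)) {
    stop("annotation missing for genes: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  }
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero column total for sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  len <- annot$length_bp[match(rownames(counts), annot$gene_id)]
  fpkm <- sweep(counts * 1e9 / len, 2, totals, "/")
  dimnames(fpkm) <- dimnames(counts)
  fpkm
}

#' Apply the expression and sex-chromosome gene filters
#'
#' A gene is removed iff its mean FPKM across all samples is strictly below
#' `min_mean_fpkm`, or its chromosome is one of `sex_chromosomes`. Each
#' removal carries a reason code (`LOW_EXPR`, `SEX_LINKED`, or both joined
#' with `;`). Kept and removed gene ids partition the input.
#'
#' @param fpkm FPKM matrix from [compute_fpkm()].
#' @param annot annotation data.frame.
#' @param min_mean_fpkm removal threshold on the mean FPKM (strict `<`).
#' @param sex_chromosomes chromosome labels treated as sex-linked.
#' @return list with `kept` (character vector) and `removed`
#'   (data.frame gene_id, reason).
#' @export
filter_genes <- function(fpkm, annot, min_mean_fpkm = 1,
                         sex_chromosomes = c("Z", "W")) {
  if (nrow(fpkm) == 0) stop("empty FPKM matrix")
  mean_fpkm <- rowMeans(fpkm)
  chrom <- annot$chromosome[match(rownames(fpkm), annot$gene_id)]
  low <- mean_fpkm < min_mean_fpkm
  sex <- chrom %in% sex_chromosomes
  reason <- ifelse(low & sex, "LOW_EXPR;SEX_LINKED",
                   ifelse(low, "LOW_EXPR",
                          ifelse(sex, "SEX_LINKED", NA_character_)))
  removed <- data.frame(gene_id = rownames(fpkm)[low | sex],
                        reason = reason[low | sex],
                        stringsAsFactors = FALSE)
  list(kept = rownames(fpkm)[!(low | sex)], removed = removed)
}

#' Per-group mean FPKM
#' @param fpkm FPKM matrix.
#' @param samples sample table.
#' @return matrix genes x groups of mean FPKM.
#' @export
group_mean_fpkm <- function(fpkm, samples) {
  grp <- samples$group[match(colnames(fpkm), samples$sample_id)]
  groups <- intersect(GROUPS, unique(grp))
  out <- vapply(groups, function(g) {
    rowMeans(fpkm[, grp == g, drop = FALSE])
  }, numeric(nrow(fpkm)))
  if (nrow(fpkm) == 1L) out <- matrix(out, nrow = 1,
                                      dimnames = list(rownames(fpkm), groups))
  out
}
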