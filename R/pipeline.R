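#' Build and validate a pipeline configuration
#'
#' Exactly one of `inputs` (paths to real data files) or `simulation`
#' (a [simulation_spec()]) must be provided.
#'
#' @param outdir output directory.
#' @param simulation optional `sim_spec`; when given, the synthetic bundle
#'   is generated under `outdir/inputs` and analyzed.
#' @param inputs optional named list of paths: `counts`, `annotation`,
#'   `samples`, and optionally `phenotypes`, `gene_sets`.
#' @param seed integer seed recorded in the manifest (the synthetic
#'   route derives all randomness from the spec's own seed).
#' @param padj_threshold DEG cutoff on the BH-adjusted p.
#' @param fpkm_threshold expression filter threshold (mean FPKM, strict <).
#' @param fdr_threshold enrichment significance cutoff.
#' @param sex_chromosomes chromosome labels removed as sex-linked.
#' @param require_parental_de_for_dominance see [classify_gene()].
#' @param enrich_mode mode filter used for the enrichment stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            simulation = NULL,
                            inputs = NULL,
                            seed = 1L,
                            padj_threshold = 0.05,
                            fpkm_threshold = 1,
                            fdr_threshold = 0.05,
                            sex_chromosomes = c("Z", "W"),
                            require_parental_de_for_dominance = FALSE,
                            enrich_mode = "nonadditive") {
  if (is.null(simulation) == is.null(inputs)) {
    stop("provide exactly one of `simulation` or `inputs`")
  }
  for (th in c(padj_threshold, fpkm_threshold, fdr_threshold)) {
    if (!is.numeric(th) || th <= 0) stop("thresholds must be positive")
  }
  if (padj_threshold > 1 || fdr_threshold > 1) {
    stop("p-value thresholds must be <= 1")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation, "sim_spec"))
  if (!is.null(inputs)) {
    need <- c("counts", "annotation", "samples")
    if (!all(need %in% names(inputs))) {
      stop("inputs must name: ", paste(need, collapse = ", "))
    }
    for (f in unlist(inputs)) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
  }
  structure(list(outdir = outdir, simulation = simulation, inputs = inputs,
                 seed = as.integer(seed),
                 padj_threshold = padj_threshold,
                 fpkm_threshold = fpkm_threshold,
                 fdr_threshold = fdr_threshold,
                 sex_chromosomes = sex_chromosomes,
                 require_parental_de_for_dominance =
                   require_parental_de_for_dominance,
                 enrich_mode = enrich_mode),
            class = "pipeline_config")
}

write_tsv <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, digits))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full reciprocal-cross analysis pipeline
#'
#' Stage order: (optional) simulate -> FPKM -> gene filter -> size factors
#' and dispersions -> five pairwise comparisons -> inheritance
#' classification of both crosses -> mode summaries and shared-gene
#' report -> gene-set enrichment (if gene sets present) -> phenotype
#' heterosis (if phenotypes present). All outputs are plain-text TSV/CSV
#' under `config$outdir`; a JSON manifest records file MD5 hashes, the
#' seed, thresholds and stage timings. The same config reproduces
#' identical result files.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    tick(stage)
    res
  }
  outputs <- character(0)
  emit <- function(df, name, digits = NULL) {
    p <- write_tsv(df, file.path(outdir, name), digits = digits)
    outputs <<- c(outputs, p)
    p
  }

  # --- inputs ---
  pheno <- NULL; sets <- NULL
  if (!is.null(config$simulation)) {
    indir <- file.path(outdir, "inputs")
    run_stage("simulate", write_fixture_bundle(indir, config$simulation))
    counts <- read_counts(file.path(indir, "counts.tsv"))
    annot <- read_annotation(file.path(indir, "annotation.tsv"))
    samples <- read_sample_table(file.path(indir, "samples.csv"))
    pheno <- read_phenotypes(file.path(indir, "phenotypes.csv"))
    sets <- read_gmt(file.path(indir, "gene_sets.gmt"))
  } else {
    counts <- run_stage("read_inputs", read_counts(config$inputs$counts))
    annot <- read_annotation(config$inputs$annotation)
    samples <- read_sample_table(config$inputs$samples)
    if (!is.null(config$inputs$phenotypes)) {
      pheno <- read_phenotypes(config$inputs$phenotypes)
    }
    if (!is.null(config$inputs$gene_sets)) {
      sets <- read_gmt(config$inputs$gene_sets)
    }
  }

  # --- expression + filter ---
  fpkm <- run_stage("fpkm", compute_fpkm(counts, annot))
  flt <- run_stage("filter",
                   filter_genes(fpkm, annot,
                                min_mean_fpkm = config$fpkm_threshold,
                                sex_chromosomes = config$sex_chromosomes))
  emit(data.frame(gene_id = flt$kept), "kept_genes.tsv")
  emit(flt$removed, "removed_genes.tsv")
  kept_counts <- counts[flt$kept, , drop = FALSE]
  kept_fpkm <- fpkm[flt$kept, , drop = FALSE]
  emit(data.frame(gene_id = rownames(kept_fpkm), kept_fpkm,
                  check.names = FALSE), "fpkm.tsv", digits = 6)

  # --- differential expression ---
  de <- run_stage("diffexpr",
                  run_comparisons(kept_counts, samples,
                                  padj_threshold = config$padj_threshold))
  for (nm in names(de)) emit(de[[nm]], paste0("de_", nm, ".tsv"))
  deg_counts <- vapply(de, function(d) length(deg_genes(d, config$padj_threshold)),
                       integer(1))

  # --- inheritance classification ---
  means <- group_mean_fpkm(kept_fpkm, samples)
  calls <- run_stage("classify", list(
    CR = classify_cross(de$CC_vs_RR, de$CR_vs_CC, de$CR_vs_RR, means,
                        cross = "CR", alpha = config$padj_threshold,
                        require_parental_de_for_dominance =
                          config$require_parental_de_for_dominance),
    RC = classify_cross(de$CC_vs_RR, de$RC_vs_CC, de$RC_vs_RR, means,
                        cross = "RC", alpha = config$padj_threshold,
                        require_parental_de_for_dominance =
                          config$require_parental_de_for_dominance)))
  emit(calls$CR, "calls_CR.tsv")
  emit(calls$RC, "calls_RC.tsv")
  summaries <- rbind(summarize_modes(calls$CR), summarize_modes(calls$RC))
  emit(summaries, "mode_summary.tsv")
  shared <- shared_nonadditive(calls$CR, calls$RC)
  emit(shared$genes, "shared_nonadditive_genes.tsv")
  emit(shared$class_table, "shared_nonadditive_classes.tsv")
  tick("summaries")

  # --- enrichment ---
  enr <- NULL
  if (!is.null(sets)) {
    enr <- run_stage("enrichment",
                     enrich_nonadditive(calls$CR, calls$RC, sets,
                                        universe = flt$kept,
                                        mode_filter = config$enrich_mode,
                                        fdr_threshold = config$fdr_threshold))
    emit(enr$CR, "enrichment_CR.tsv")
    emit(enr$RC, "enrichment_RC.tsv")
    emit(data.frame(set = enr$shared_significant),
         "enrichment_shared_significant.tsv")
  }

  # --- phenotype heterosis ---
  het <- NULL
  if (!is.null(pheno)) {
    het <- run_stage("heterosis", heterosis_table(pheno))
    emit(het, "heterosis.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hetexpr")),
    seed = config$seed,
    thresholds = list(padj = config$padj_threshold,
                      fpkm = config$fpkm_threshold,
                      fdr = config$fdr_threshold),
    sex_chromosomes = config$sex_chromosomes,
    deg_counts = as.list(deg_counts),
    nonadditive_pct = setNames(as.list(summaries$nonadditive_pct),
                               summaries$cross),
    has_enrichment = !is.null(enr),
    has_phenotypes = !is.null(het),
    files = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    stage_seconds = timings)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable summary report of a pipeline run
#'
#' Renders per-comparison DEG counts, per-cross mode counts and
#' percentages, the shared-gene class table, top enrichment rows and the
#' phenotype heterosis table as text. Sections whose inputs were absent
#' are marked absent; an incomplete output directory yields a partial
#' report with warnings.
#'
#' @param outdir the pipeline output directory.
#' @return character vector of report lines (also written to
#'   `report.txt`).
#' @export
report_summary <- function(outdir) {
  lines <- c("Reciprocal-cross expression inheritance report",
             strrep("=", 47))
  mpath <- file.path(outdir, "manifest.json")
  if (file.exists(mpath)) {
    man <- jsonlite::read_json(mpath)
    lines <- c(lines, paste0("seed: ", man$seed), "")
    lines <- c(lines, "DEGs per comparison (padj < threshold):")
    for (nm in names(man$deg_counts)) {
      lines <- c(lines, sprintf("  %-10s %d", nm, man$deg_counts[[nm]]))
    }
  } else {
    warning("manifest.json missing; partial report")
    lines <- c(lines, "(manifest missing)")
  }
  spath <- file.path(outdir, "mode_summary.tsv")
  if (file.exists(spath)) {
    sm <- read.delim(spath)
    lines <- c(lines, "", "Inheritance modes per cross:")
    for (i in seq_len(nrow(sm))) {
      lines <- c(lines, sprintf(
        "  %s: universe %d | additive %d | dominant %d | overdominant %d | unclassified %d | nonadditive %.2f%%",
        sm$cross[i], sm$n_universe[i], sm$n_additive[i], sm$n_dominant[i],
        sm$n_overdominant[i], sm$n_unclassified[i], sm$nonadditive_pct[i]))
    }
  } else {
    warning("mode_summary.tsv missing; partial report")
  }
  cpath <- file.path(outdir, "shared_nonadditive_classes.tsv")
  if (file.exists(cpath)) {
    ct <- read.delim(cpath)
    lines <- c(lines, "", "Shared nonadditive genes, class shares:")
    if (nrow(ct) == 0) {
      lines <- c(lines, "  (none shared)")
    } else {
      for (i in seq_len(nrow(ct))) {
        lines <- c(lines, sprintf("  %s class %-4s n=%d (%.2f%%)",
                                  ct$cross[i], ct$class[i], ct$n[i],
                                  ct$pct[i]))
      }
    }
  }
  for (cr in c("CR", "RC")) {
    epath <- file.path(outdir, paste0("enrichment_", cr, ".tsv"))
    if (file.exists(epath)) {
      et <- read.delim(epath)
      lines <- c(lines, "", paste0("Top enrichment rows (", cr, "):"))
      for (i in seq_len(min(3, nrow(et)))) {
        lines <- c(lines, sprintf("  %-24s k=%d/%d p=%.3g FDR=%.3g",
                                  et$set[i], et$k[i], et$K[i],
                                  et$pvalue[i], et$fdr[i]))
      }
    } else if (cr == "CR") {
      lines <- c(lines, "", "Enrichment: absent (no gene sets provided)")
    }
  }
  hpath <- file.path(outdir, "heterosis.tsv")
  if (file.exists(hpath)) {
    ht <- read.delim(hpath)
    lines <- c(lines, "", "Phenotype heterosis:")
    for (i in seq_len(nrow(ht))) {
      lines <- c(lines, sprintf(
        "  %-16s %s  N=%d  H%% = %+.2f  t=%.2f df=%d p=%.3g [%s]",
        ht$trait[i], ht$cross[i], ht$N[i], ht$H_percent[i], ht$t[i],
        ht$df[i], ht$p[i], ht$tier[i]))
    }
  } else {
    lines <- c(lines, "", "Phenotype heterosis: absent (no phenotypes provided)")
  }
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(lines)
}
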