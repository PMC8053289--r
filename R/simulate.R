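#' @importFrom stats rnbinom rpois rnorm runif median var pnorm pt qnorm
#'   phyper setNames complete.cases lm coef p.adjust t.test
#' @importFrom utils read.delim read.csv write.csv write.table head
NULL

GROUPS <- c("CC", "RR", "CR", "RC")

PLANT_MODES <- c("CONSERVED", "ADDITIVE", "DOMINANT_HIGH", "DOMINANT_LOW",
                 "OVERDOMINANT_UP", "OVERDOMINANT_DOWN")

#' Specification for the reciprocal-cross count simulator
#'
#' Builds and validates the full parameterization of the synthetic
#' expression study: a four-group design (parental lines CC and RR, F1
#' reciprocal crosses CR and RC) with negative-binomial counts and a known,
#' planted inheritance mode for every gene.
#'
#' Planted modes and their group-mean geometry (on the count scale):
#' \describe{
#'   \item{CONSERVED}{all four group means equal the gene baseline.}
#'   \item{ADDITIVE}{CC and RR differ by `parental_log2fc`; F1 means are the
#'     arithmetic mid-parent `(CC + RR) / 2`.}
#'   \item{DOMINANT_HIGH / DOMINANT_LOW}{F1 means equal the higher / lower
#'     parental mean.}
#'   \item{OVERDOMINANT_UP / OVERDOMINANT_DOWN}{F1 means lie beyond the
#'     higher / lower parent by `overdominant_log2_offset` log2 units.}
#' }
#'
#' Counts for sample s, gene g are drawn NB with mean
#' `libsize_factor_s * group_mean_g` and variance `mu + dispersion * mu^2`.
#'
#' A `sex_linked_fraction` of genes is placed on chromosomes Z/W and a
#' disjoint `low_expr_fraction` is forced below the expression filter; both
#' are drawn from the CONSERVED pool so that filtering never removes genes
#' carrying planted signal.
#'
#' @param seed integer RNG seed; same spec + same seed reproduces the
#'   simulated study exactly.
#' @param n_genes number of genes.
#' @param n_per_group replicates per group, a single count or a named vector
#'   over CC, RR, CR, RC.
#' @param class_proportions named fractions over the six planted modes;
#'   must sum to 1.
#' @param baseline_log2_mean_range interval for the per-gene baseline
#'   log2 mean count.
#' @param parental_log2fc log2 effect size between CC and RR for
#'   non-conserved genes (which parent is higher is randomized per gene).
#' @param overdominant_log2_offset log2 excess of the F1 beyond the nearer
#'   parent for overdominant genes.
#' @param dispersion NB dispersion alpha in `var = mu + alpha * mu^2`;
#'   0 gives Poisson counts.
#' @param libsize_factor_range per-sample library-size multipliers are drawn
#'   log-uniformly from this interval.
#' @param sex_linked_fraction fraction of genes assigned to Z/W.
#' @param low_expr_fraction fraction of genes with baseline forced below the
#'   FPKM filter threshold.
#' @return an object of class `sim_spec` (a validated list).
#' @export
simulation_spec <- function(seed = 1L,
                            n_genes = 2000L,
                            n_per_group = c(CC = 6L, RR = 6L, CR = 6L, RC = 6L),
                            class_proportions = c(CONSERVED = 0.70,
                                                  ADDITIVE = 0.10,
                                                  DOMINANT_HIGH = 0.06,
                                                  DOMINANT_LOW = 0.06,
                                                  OVERDOMINANT_UP = 0.04,
                                                  OVERDOMINANT_DOWN = 0.04),
                            baseline_log2_mean_range = c(3, 10),
                            parental_log2fc = 2,
                            overdominant_log2_offset = 1,
                            dispersion = 0.05,
                            libsize_factor_range = c(0.7, 1.4),
                            sex_linked_fraction = 0.05,
                            low_expr_fraction = 0.10) {
  if (length(n_per_group) == 1L) {
    n_per_group <- setNames(rep(as.integer(n_per_group), 4L), GROUPS)
  }
  if (!all(GROUPS %in% names(n_per_group))) {
    stop("n_per_group must be named over CC, RR, CR, RC (or be a scalar)")
  }
  n_per_group <- as.integer(n_per_group[GROUPS])
  names(n_per_group) <- GROUPS
  if (any(n_per_group < 1L)) {
    stop("zero replicates per group: every group needs at least one sample")
  }
  if (!all(PLANT_MODES %in% names(class_proportions))) {
    stop("class_proportions must be named over: ",
         paste(PLANT_MODES, collapse = ", "))
  }
  class_proportions <- class_proportions[PLANT_MODES]
  if (any(class_proportions < 0)) stop("class_proportions must be >= 0")
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 (got ", sum(class_proportions), ")")
  }
  if (parental_log2fc < 0 || overdominant_log2_offset < 0) {
    stop("negative effect sizes are not allowed: parental_log2fc and ",
         "overdominant_log2_offset must be >= 0")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_genes < 1) stop("n_genes must be positive")
  stopifnot(length(baseline_log2_mean_range) == 2L,
            diff(baseline_log2_mean_range) >= 0,
            length(libsize_factor_range) == 2L,
            all(libsize_factor_range > 0))
  if (sex_linked_fraction < 0 || sex_linked_fraction > 1 ||
      low_expr_fraction < 0 || low_expr_fraction > 1) {
    stop("sex_linked_fraction and low_expr_fraction must be in [0, 1]")
  }
  if (sex_linked_fraction + low_expr_fraction > class_proportions[["CONSERVED"]]) {
    stop("sex_linked_fraction + low_expr_fraction must not exceed the ",
         "CONSERVED proportion (filter-target genes are drawn from the ",
         "conserved pool)")
  }
  structure(list(seed = as.integer(seed),
                 n_genes = as.integer(n_genes),
                 n_per_group = n_per_group,
                 class_proportions = class_proportions,
                 baseline_log2_mean_range = baseline_log2_mean_range,
                 parental_log2fc = parental_log2fc,
                 overdominant_log2_offset = overdominant_log2_offset,
                 dispersion = dispersion,
                 libsize_factor_range = libsize_factor_range,
                 sex_linked_fraction = sex_linked_fraction,
                 low_expr_fraction = low_expr_fraction),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Reciprocal-cross simulation spec\n")
  cat("  genes:", x$n_genes, " seed:", x$seed, "\n")
  cat("  replicates:", paste(names(x$n_per_group), x$n_per_group,
                             sep = "=", collapse = " "), "\n")
  cat("  planted modes:",
      paste(names(x$class_proportions), x$class_proportions,
            sep = "=", collapse = " "), "\n")
  cat("  parental log2FC:", x$parental_log2fc,
      " overdominant offset:", x$overdominant_log2_offset,
      " dispersion:", x$dispersion, "\n")
  invisible(x)
}

# F1 mean on the count scale for one planted mode
.f1_mean_for_mode <- function(mode, mean_cc, mean_rr, od_offset) {
  hi <- pmax(mean_cc, mean_rr)
  lo <- pmin(mean_cc, mean_rr)
  switch(mode,
         CONSERVED = mean_cc,
         ADDITIVE = (mean_cc + mean_rr) / 2,
         DOMINANT_HIGH = hi,
         DOMINANT_LOW = lo,
         OVERDOMINANT_UP = hi * 2^od_offset,
         OVERDOMINANT_DOWN = lo * 2^(-od_offset),
         stop("unknown mode: ", mode))
}

#' Simulate a reciprocal-cross count matrix with planted inheritance modes
#'
#' Draws NB (or Poisson, at dispersion 0) fragment counts for the four-group
#' design described by a [simulation_spec()], together with a gene
#' annotation (chromosome, exonic length) and the ground truth needed to
#' score every downstream stage.
#'
#' @param spec a `sim_spec`.
#' @return a list of class `cross_sim` with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples.}
#'     \item{samples}{data.frame with `sample_id`, `group`.}
#'     \item{annotation}{data.frame with `gene_id`, `chromosome`,
#'       `length_bp`.}
#'     \item{truth}{data.frame with the planted mode, per-group true means,
#'       chromosome and the low-expression flag per gene.}
#'     \item{libsize_factors}{the per-sample multipliers used.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  gene_id <- sprintf("g%05d", seq_len(ng))

  # planted mode per gene: deterministic counts per mode (largest remainder)
  n_mode <- floor(spec$class_proportions * ng)
  rem <- ng - sum(n_mode)
  if (rem > 0) {
    frac <- spec$class_proportions * ng - n_mode
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_mode[add] <- n_mode[add] + 1L
  }
  mode <- sample(rep(names(n_mode), times = n_mode))

  conserved_idx <- which(mode == "CONSERVED")
  n_sex <- round(spec$sex_linked_fraction * ng)
  n_low <- round(spec$low_expr_fraction * ng)
  pick <- sample(conserved_idx, n_sex + n_low)
  sex_idx <- pick[seq_len(n_sex)]
  low_idx <- setdiff(pick, sex_idx)

  chromosome <- sample(as.character(1:28), ng, replace = TRUE)
  if (n_sex > 0) chromosome[sex_idx] <- sample(c("Z", "W"), n_sex, replace = TRUE)

  length_bp <- sample(200:10000, ng, replace = TRUE)
  baseline <- 2^runif(ng, spec$baseline_log2_mean_range[1],
                      spec$baseline_log2_mean_range[2])
  # forced-low genes: tiny baseline and long genes, so mean FPKM < 1 safely
  if (n_low > 0) {
    baseline[low_idx] <- runif(n_low, 0.02, 0.2)
    length_bp[low_idx] <- sample(2000:5000, n_low, replace = TRUE)
  }

  up_parent <- sample(c("CC", "RR"), ng, replace = TRUE)
  half <- spec$parental_log2fc / 2
  hi <- baseline * 2^half
  lo <- baseline * 2^(-half)
  mean_cc <- ifelse(mode == "CONSERVED", baseline,
                    ifelse(up_parent == "CC", hi, lo))
  mean_rr <- ifelse(mode == "CONSERVED", baseline,
                    ifelse(up_parent == "RR", hi, lo))
  mean_f1 <- vapply(seq_len(ng), function(i) {
    .f1_mean_for_mode(mode[i], mean_cc[i], mean_rr[i],
                      spec$overdominant_log2_offset)
  }, numeric(1))

  group <- rep(GROUPS, times = spec$n_per_group)
  sample_id <- unlist(lapply(GROUPS, function(g) {
    paste0(g, "_", seq_len(spec$n_per_group[[g]]))
  }), use.names = FALSE)
  ns <- length(sample_id)
  lsf <- exp(runif(ns, log(spec$libsize_factor_range[1]),
                   log(spec$libsize_factor_range[2])))
  names(lsf) <- sample_id

  group_mean <- cbind(CC = mean_cc, RR = mean_rr, CR = mean_f1, RC = mean_f1)
  counts <- matrix(0L, nrow = ng, ncol = ns,
                   dimnames = list(gene_id, sample_id))
  for (j in seq_len(ns)) {
    mu <- lsf[j] * group_mean[, group[j]]
    counts[, j] <- as.integer(if (spec$dispersion == 0) {
      rpois(ng, lambda = mu)
    } else {
      rnbinom(ng, mu = mu, size = 1 / spec$dispersion)
    })
  }

  truth <- data.frame(gene_id = gene_id,
                      mode = mode,
                      up_parent = up_parent,
                      mean_CC = mean_cc,
                      mean_RR = mean_rr,
                      mean_CR = mean_f1,
                      mean_RC = mean_f1,
                      chromosome = chromosome,
                      low_expr = seq_len(ng) %in% low_idx,
                      stringsAsFactors = FALSE)
  structure(list(counts = counts,
                 samples = data.frame(sample_id = sample_id, group = group,
                                      stringsAsFactors = FALSE),
                 annotation = data.frame(gene_id = gene_id,
                                         chromosome = chromosome,
                                         length_bp = as.integer(length_bp),
                                         stringsAsFactors = FALSE),
                 truth = truth,
                 libsize_factors = lsf,
                 spec = spec),
            class = "cross_sim")
}

#' Read a simulation spec back from the YAML written by
#' [write_fixture_bundle()]
#' @param path YAML file.
#' @return a validated `sim_spec`.
#' @export
read_simulation_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path)
  y <- yaml::read_yaml(path)
  simulation_spec(seed = y$seed, n_genes = y$n_genes,
                  n_per_group = unlist(y$n_per_group),
                  class_proportions = unlist(y$class_proportions),
                  baseline_log2_mean_range = y$baseline_log2_mean_range,
                  parental_log2fc = y$parental_log2fc,
                  overdominant_log2_offset = y$overdominant_log2_offset,
                  dispersion = y$dispersion,
                  libsize_factor_range = y$libsize_factor_range,
                  sex_linked_fraction = y$sex_linked_fraction,
                  low_expr_fraction = y$low_expr_fraction)
}

#' Simulate an individual-level phenotype table
#'
#' Draws normal trait values per individual around planted per-group means,
#' so the planted mid-parent heterosis
#' `H = (mean_F1 - midparent) / midparent` is recoverable by the heterosis
#' stage.
#'
#' @param means planted per-group means: a named numeric vector over the
#'   groups for a single trait, or a numeric matrix / data.frame with one
#'   row per trait (rownames = trait names) and one column per group.
#' @param sd residual standard deviation: a scalar, or shaped like `means`.
#' @param n_per_group individuals per group (scalar or named vector).
#' @param seed integer RNG seed.
#' @param trait trait name used when `means` is a vector.
#' @return data.frame with `individual_id`, `group` and one column per
#'   trait.
#' @export
simulate_phenotypes <- function(means, sd = 1, n_per_group = 20L,
                                seed = 1L, trait = "trait") {
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(trait, names(means)))
  }
  means <- as.matrix(means)
  groups <- colnames(means)
  if (is.null(groups) || length(groups) == 0L) stop("empty group list")
  if (any(sd < 0)) stop("sd must be >= 0")
  sdm <- if (is.null(dim(sd))) {
    matrix(sd, nrow = nrow(means), ncol = ncol(means),
           dimnames = dimnames(means))
  } else as.matrix(sd)
  if (length(n_per_group) == 1L) {
    n_per_group <- setNames(rep(as.integer(n_per_group), length(groups)),
                            groups)
  }
  set.seed(as.integer(seed))
  rows <- lapply(groups, function(g) {
    n <- n_per_group[[g]]
    vals <- vapply(rownames(means), function(tr) {
      rnorm(n, mean = means[tr, g], sd = sdm[tr, g])
    }, numeric(n))
    if (n == 1L) vals <- matrix(vals, nrow = 1,
                                dimnames = list(NULL, rownames(means)))
    df <- data.frame(individual_id = paste0(g, "_", seq_len(n)),
                     group = g, stringsAsFactors = FALSE)
    cbind(df, as.data.frame(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# default planted phenotype scenario for fixture bundles: body weight and
# breast muscle mass with negative mid-parent heterosis, RC more negative
# than CR as observed in broiler x layer crosses
default_phenotype_scenario <- function() {
  mp_bw <- (1000 + 600) / 2
  mp_bm <- (180 + 80) / 2
  means <- rbind(
    body_weight_g   = c(CC = 1000, RR = 600,
                        CR = mp_bw * (1 - 0.15), RC = mp_bw * (1 - 0.20)),
    breast_muscle_g = c(CC = 180, RR = 80,
                        CR = mp_bm * (1 - 0.42), RC = mp_bm * (1 - 0.50)))
  sd <- rbind(body_weight_g = rep(80, 4), breast_muscle_g = rep(15, 4))
  colnames(sd) <- colnames(means)
  list(means = means, sd = sd, n_per_group = 20L)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Materializes one simulated study as the plain-text files every pipeline
#' stage consumes: counts TSV, annotation TSV, sample CSV, phenotype CSV, a
#' small GMT gene-set collection (one positive-control set drawn from
#' planted nonadditive genes plus random sets), the per-gene ground truth
#' TSV, and the spec itself as YAML.
#'
#' @param outdir output directory (created if needed).
#' @param spec a `sim_spec`.
#' @param phenotypes optional list with `means`, `sd`, `n_per_group` as in
#'   [simulate_phenotypes()]; defaults to a negative-heterosis growth-trait
#'   scenario.
#' @return invisibly, a data.frame manifest (file, path, md5).
#' @export
write_fixture_bundle <- function(outdir, spec = simulation_spec(),
                                 phenotypes = default_phenotype_scenario()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  sim <- simulate_counts(spec)

  paths <- c(counts = file.path(outdir, "counts.tsv"),
             annotation = file.path(outdir, "annotation.tsv"),
             samples = file.path(outdir, "samples.csv"),
             phenotypes = file.path(outdir, "phenotypes.csv"),
             gene_sets = file.path(outdir, "gene_sets.gmt"),
             ground_truth = file.path(outdir, "ground_truth.tsv"),
             spec = file.path(outdir, "sim_spec.yaml"))

  write_counts(sim$counts, paths[["counts"]])
  write.table(sim$annotation, paths[["annotation"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(sim$samples, paths[["samples"]], row.names = FALSE, quote = FALSE)

  pheno <- simulate_phenotypes(phenotypes$means, phenotypes$sd,
                               phenotypes$n_per_group,
                               seed = spec$seed + 1L)
  write.csv(pheno, paths[["phenotypes"]], row.names = FALSE, quote = FALSE)

  # gene sets: one positive control preferentially from planted nonadditive
  # genes, plus random background sets (RNG state continues from the
  # simulate_counts() seed, so the bundle is a pure function of the spec)
  nonadd <- sim$truth$gene_id[sim$truth$mode %in%
                                c("DOMINANT_HIGH", "DOMINANT_LOW",
                                  "OVERDOMINANT_UP", "OVERDOMINANT_DOWN")]
  all_genes <- sim$truth$gene_id
  sets <- list(planted_nonadditive = sample(nonadd, min(50L, length(nonadd))))
  for (i in 1:5) {
    sets[[paste0("random_set_", i)]] <- sample(all_genes, 40L)
  }
  attr(sets, "descriptions") <- setNames(
    c("synthetic positive control", rep("synthetic background", 5)),
    names(sets))
  write_gmt(sets, paths[["gene_sets"]])

  write.table(sim$truth, paths[["ground_truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  spec_list <- unclass(spec)
  spec_list$n_per_group <- as.list(spec_list$n_per_group)
  spec_list$class_proportions <- as.list(spec_list$class_proportions)
  spec_list$phenotype_means <- apply(phenotypes$means, 1, as.list,
                                     simplify = FALSE)
  yaml::write_yaml(spec_list, paths[["spec"]])

  manifest <- data.frame(file = names(paths),
                         path = unname(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  invisible(manifest)
}
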