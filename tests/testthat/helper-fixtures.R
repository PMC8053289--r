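# shared fixtures, computed lazily once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# planted mode -> inheritance mode expected from the classifier
mode_of_planted <- c(CONSERVED = "CONSERVED", ADDITIVE = "ADDITIVE",
                     DOMINANT_HIGH = "DOMINANT", DOMINANT_LOW = "DOMINANT",
                     OVERDOMINANT_UP = "OVERDOMINANT",
                     OVERDOMINANT_DOWN = "OVERDOMINANT")

# the default synthetic study, analyzed end to end through the package
default_analysis <- function() {
  cached("default_analysis", {
    sim <- simulate_counts(simulation_spec(seed = 1L))
    fpkm <- compute_fpkm(sim$counts, sim$annotation)
    flt <- filter_genes(fpkm, sim$annotation)
    kc <- sim$counts[flt$kept, ]
    kf <- fpkm[flt$kept, ]
    de <- run_comparisons(kc, sim$samples)
    means <- group_mean_fpkm(kf, sim$samples)
    calls_cr <- classify_cross(de$CC_vs_RR, de$CR_vs_CC, de$CR_vs_RR,
                               means, cross = "CR")
    calls_rc <- classify_cross(de$CC_vs_RR, de$RC_vs_CC, de$RC_vs_RR,
                               means, cross = "RC")
    truth_kept <- sim$truth[sim$truth$gene_id %in% flt$kept, ]
    list(sim = sim, fpkm = fpkm, flt = flt, counts = kc, kept_fpkm = kf,
         de = de, means = means, calls_cr = calls_cr, calls_rc = calls_rc,
         truth_kept = truth_kept)
  })
}

# a strong-effect study: well-expressed genes, so every planted effect is
# comfortably detectable
strong_analysis <- function() {
  cached("strong_analysis", {
    spec <- simulation_spec(seed = 7L, n_genes = 1000L,
                            baseline_log2_mean_range = c(7, 11),
                            sex_linked_fraction = 0,
                            low_expr_fraction = 0)
    sim <- simulate_counts(spec)
    fpkm <- compute_fpkm(sim$counts, sim$annotation)
    de <- run_comparisons(sim$counts, sim$samples)
    means <- group_mean_fpkm(fpkm, sim$samples)
    calls_cr <- classify_cross(de$CC_vs_RR, de$CR_vs_CC, de$CR_vs_RR,
                               means, cross = "CR")
    list(sim = sim, de = de, means = means, calls_cr = calls_cr)
  })
}

# an all-conserved (null) study
null_analysis <- function() {
  cached("null_analysis", {
    spec <- simulation_spec(
      seed = 11L,
      class_proportions = c(CONSERVED = 1, ADDITIVE = 0, DOMINANT_HIGH = 0,
                            DOMINANT_LOW = 0, OVERDOMINANT_UP = 0,
                            OVERDOMINANT_DOWN = 0),
      sex_linked_fraction = 0, low_expr_fraction = 0)
    sim <- simulate_counts(spec)
    de <- run_comparisons(sim$counts, sim$samples)
    list(sim = sim, de = de)
  })
}

# fraction of planted genes of one inheritance mode recovered by the calls
recovery_rate <- function(calls, truth, target_mode) {
  planted <- truth$gene_id[mode_of_planted[truth$mode] == target_mode]
  called <- calls$mode[match(planted, calls$gene_id)]
  mean(!is.na(called) & called == target_mode)
}

# construct a minimal inheritance_calls table from mode/class vectors
make_calls <- function(modes, cross = "CR", classes = NULL) {
  n <- length(modes)
  if (is.null(classes)) {
    classes <- c(ADDITIVE = "I", DOMINANT = "II", OVERDOMINANT = "III",
                 UNCLASSIFIED = "NONE")[modes]
  }
  structure(
    data.frame(gene_id = sprintf("%s_gene%05d", cross, seq_len(n)),
               cross = rep(cross, n), class = unname(classes),
               mode = modes,
               mean_CC = rep(1, n), mean_RR = rep(2, n),
               mean_F1 = rep(1.5, n),
               padj_PP = rep(0.01, n), padj_F1_CC = rep(0.01, n),
               padj_F1_RR = rep(0.01, n), stringsAsFactors = FALSE),
    class = c("inheritance_calls", "data.frame"))
}

# independent brute-force BH step-up oracle (kept naive on purpose)
bh_oracle <- function(p) {
  obs <- which(!is.na(p))
  x <- p[obs]
  m <- length(x)
  out <- rep(NA_real_, length(p))
  if (m == 0) return(out)
  o <- order(x)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * x[o[j]] / j, numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  out[obs] <- adj
  out
}

# independent hypergeometric upper-tail oracle by direct enumeration
hyper_tail_oracle <- function(k, K, N, n) {
  js <- k:min(n, K)
  js <- js[js >= 0 & (n - js) <= (N - K)]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
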