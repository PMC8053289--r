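two_group_samples <- function(nA, nB, groups = c("CC", "RR")) {
  data.frame(sample_id = c(paste0(groups[1], "_", seq_len(nA)),
                           paste0(groups[2], "_", seq_len(nB))),
             group = rep(groups, c(nA, nB)), stringsAsFactors = FALSE)
}

test_that("median-of-ratios size factors match hand computations", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(estimate_size_factors(m), c(s1 = 1, s2 = 1))

  m2 <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-4)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-10)

  # invariant to gene order
  perm <- m2[c(3, 1, 2), ]
  expect_equal(estimate_size_factors(perm), sf)

  # no gene nonzero in all samples
  m3 <- matrix(c(0L, 5L, 5L, 0L), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(estimate_size_factors(m3), "pseudo-reference")
})

test_that("size factors agree with an independent median-of-ratios tool", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  m <- matrix(rnbinom(200 * 8, mu = 100, size = 10), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:8)))
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("dispersion estimation is calibrated on Poisson and NB truth", {
  set.seed(31)
  n <- 50
  samples <- two_group_samples(n, n)
  mu <- 2^runif(400, 4, 9)
  pois <- t(vapply(mu, function(m) rpois(2 * n, m), numeric(2 * n)))
  dimnames(pois) <- list(sprintf("g%03d", seq_along(mu)), samples$sample_id)
  sf <- setNames(rep(1, 2 * n), samples$sample_id)
  a0 <- estimate_dispersions(pois, sf, samples)
  expect_lte(median(a0), 0.01)

  nb <- t(vapply(mu, function(m) rnbinom(2 * n, mu = m, size = 5),
                 numeric(2 * n)))
  dimnames(nb) <- dimnames(pois)
  a2 <- estimate_dispersions(nb, sf, samples)
  expect_equal(median(a2), 0.2, tolerance = 0.3)

  # constant gene: zero variance, floored, never NaN
  const <- rbind(pois, constg = rep(50L, 2 * n))
  ac <- estimate_dispersions(const, setNames(rep(1, 2 * n),
                                             colnames(const)), samples)
  expect_false(anyNA(ac))
  expect_true(all(ac >= 1e-8))
})

test_that("Wald test is exact on the null identity and symmetric", {
  # identical per-sample counts in the two groups -> log2FC 0, p = 1
  set.seed(13)
  base <- matrix(rpois(50 * 3, 80), nrow = 50)
  m <- cbind(base, base)
  dimnames(m) <- list(sprintf("g%02d", 1:50),
                      c(paste0("CC_", 1:3), paste0("RR_", 1:3)))
  samples <- two_group_samples(3, 3)
  sf <- estimate_size_factors(m)
  disp <- setNames(rep(0.05, nrow(m)), rownames(m))
  de <- wald_test(m, sf, disp, samples, "CC", "RR")
  expect_equal(de$log2FoldChange, rep(0, 50), tolerance = 1e-8)
  expect_equal(de$pvalue, rep(1, 50), tolerance = 1e-6)

  # swapping the groups negates the fold change and preserves p
  an <- default_analysis()
  sf2 <- attr(an$de, "size_factors")
  d2 <- attr(an$de, "dispersions")
  w1 <- wald_test(an$counts, sf2, d2, an$sim$samples, "CC", "RR")
  w2 <- wald_test(an$counts, sf2, d2, an$sim$samples, "RR", "CC")
  expect_equal(w1$log2FoldChange, -w2$log2FoldChange, tolerance = 1e-10)
  expect_equal(w1$pvalue, w2$pvalue, tolerance = 1e-10)
})

test_that("planted fold changes are recovered without material bias", {
  an <- default_analysis()
  tr <- an$truth_kept
  de <- an$de$CC_vs_RR
  nonc <- tr$mode != "CONSERVED"
  true_lfc <- log2(tr$mean_CC / tr$mean_RR)[nonc]
  est <- de$log2FoldChange[match(tr$gene_id[nonc], de$gene_id)]
  # orient every gene toward its planted +2 parental contrast
  expect_equal(mean(est * sign(true_lfc)), 2, tolerance = 0.15 / 2)
})

test_that("null simulation is calibrated and finds no DEGs beyond FDR", {
  nl <- null_analysis()
  p <- nl$de$CC_vs_RR$pvalue
  frac <- mean(p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  for (cmp in names(nl$de)) {
    expect_lte(length(deg_genes(nl$de[[cmp]])),
               0.05 * nrow(nl$sim$counts))
  }
})

test_that("rescaling one sample leaves Wald statistics nearly unchanged", {
  an <- default_analysis()
  counts <- an$counts
  scaled <- counts
  scaled[, 1] <- as.integer(round(scaled[, 1] * 3))
  sf1 <- estimate_size_factors(counts)
  sf3 <- estimate_size_factors(scaled)
  # the rescaled sample's factor moves by ~c relative to the others
  expect_equal(unname((sf3[1] / sf3[2]) / (sf1[1] / sf1[2])), 3,
               tolerance = 0.02)
  samples <- an$sim$samples
  d1 <- estimate_dispersions(counts, sf1, samples)
  d3 <- estimate_dispersions(scaled, sf3, samples)
  w1 <- wald_test(counts, sf1, d1, samples, "CC", "RR")
  w3 <- wald_test(scaled, sf3, d3, samples, "CC", "RR")
  big <- which(abs(w1$stat) > 2)
  expect_lt(median(abs(w3$stat[big] / w1$stat[big] - 1)), 0.02)
})

test_that("BH adjustment matches the step-up formula and its oracles", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # missing values are excluded from m
  expect_equal(bh_adjust(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))

  set.seed(19)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    p[sample(length(p), size = rbinom(1, 2, 0.3))] <- NA
    adj <- bh_adjust(p)
    expect_identical(adj, bh_oracle(p))
    expect_equal(adj[!is.na(p)],
                 p.adjust(p[!is.na(p)], method = "BH"))
    # monotone non-decreasing in p-rank, and >= p
    ord <- order(p, na.last = NA)
    expect_true(all(diff(adj[ord]) >= -1e-15))
    expect_true(all(adj >= p, na.rm = TRUE))
  }
})

test_that("the five standard comparisons run as a unit", {
  an <- default_analysis()
  expect_named(an$de, c("CC_vs_RR", "CR_vs_CC", "CR_vs_RR",
                        "RC_vs_CC", "RC_vs_RR"))
  # strong parental effects: nearly all planted non-conserved genes are
  # DEGs between the parental lines
  tr <- an$truth_kept
  nonc <- tr$gene_id[tr$mode != "CONSERVED"]
  degs <- deg_genes(an$de$CC_vs_RR)
  expect_gte(mean(nonc %in% degs), 0.90)

  # missing group is a named error
  s2 <- an$sim$samples[an$sim$samples$group != "RC", ]
  expect_error(run_comparisons(an$counts[, s2$sample_id], s2), "RC")

  # empty matrix after filtering: five empty tables, no crash
  empty <- an$counts[integer(0), ]
  res <- run_comparisons(empty, an$sim$samples)
  expect_length(res, 5L)
  expect_true(all(vapply(res, nrow, integer(1)) == 0L))
})
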