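test_that("single-gene classification follows the rule precedence", {
  # dominance: F1 indistinguishable from the high parent, different from
  # the low parent
  d <- classify_gene(100, 10, 95, 0.001, 0.5, 0.001)
  expect_equal(d$mode, "DOMINANT")
  expect_equal(d$class, "II")

  # overdominance: significantly above both parents
  o <- classify_gene(100, 10, 150, 0.001, 0.01, 0.001)
  expect_equal(o$mode, "OVERDOMINANT")
  expect_equal(o$class, "III")

  # additivity: between significantly different parents, different from both
  a <- classify_gene(100, 10, 55, 0.001, 0.01, 0.01)
  expect_equal(a$mode, "ADDITIVE")
  expect_equal(a$class, "I")

  # nothing significant
  u <- classify_gene(100, 10, 55, 1, 1, 1)
  expect_equal(u$mode, "UNCLASSIFIED")
  expect_equal(u$class, "NONE")

  # overdominance below both parents, parents not significantly different
  ob <- classify_gene(50, 52, 10, 0.8, 0.001, 0.001)
  expect_equal(ob$mode, "OVERDOMINANT")
  expect_equal(ob$class, "VIII")

  # missing padj counts as not significant
  dn <- classify_gene(100, 10, 95, 0.001, NA, 0.001)
  expect_equal(dn$mode, "DOMINANT")

  # degenerate exactly equal means with a significant contrast
  dg <- classify_gene(50, 50, 95, 0.001, 0.9, 0.001)
  expect_equal(dg$mode, "UNCLASSIFIED")

  # optional stricter dominance: parental difference also required
  ds <- classify_gene(100, 10, 95, 0.9, 0.5, 0.001,
                      require_parental_de_for_dominance = TRUE)
  expect_equal(ds$mode, "UNCLASSIFIED")
})

test_that("swapping the parents mirrors the class but preserves the mode", {
  mirror <- c(I = "XII", XII = "I", II = "IX", IX = "II", IV = "XI",
              XI = "IV", III = "VI", VI = "III", VII = "X", X = "VII",
              V = "V", VIII = "VIII", NONE = "NONE")
  set.seed(23)
  for (i in 1:300) {
    mcc <- runif(1, 0, 100); mrr <- runif(1, 0, 100)
    mf1 <- runif(1, 0, 150)
    p <- runif(3)^2
    a <- classify_gene(mcc, mrr, mf1, p[1], p[2], p[3])
    b <- classify_gene(mrr, mcc, mf1, p[1], p[3], p[2])
    expect_identical(b$mode, a$mode)
    expect_identical(b$class, unname(mirror[a$class]))
  }
})

test_that("cross classification covers exactly the DEG universe", {
  an <- default_analysis()
  calls <- an$calls_cr
  degs <- unique(c(deg_genes(an$de$CC_vs_RR), deg_genes(an$de$CR_vs_CC),
                   deg_genes(an$de$CR_vs_RR)))
  expect_setequal(calls$gene_id, degs)
  expect_identical(anyDuplicated(calls$gene_id), 0L)
  # partition: the four modes account for every universe gene
  sm <- summarize_modes(calls)
  expect_identical(sm$n_additive + sm$n_dominant + sm$n_overdominant +
                     sm$n_unclassified, sm$n_universe)
  expect_equal(sm$frac_additive + sm$frac_dominant + sm$frac_overdominant +
                 sm$frac_unclassified, 1, tolerance = 1e-9)
  # classification is a pure function of its inputs
  again <- classify_cross(an$de$CC_vs_RR, an$de$CR_vs_CC, an$de$CR_vs_RR,
                          an$means, cross = "CR")
  expect_identical(again, calls)
  # mismatched universes are refused
  expect_error(classify_cross(an$de$CC_vs_RR[-1, ], an$de$CR_vs_CC,
                              an$de$CR_vs_RR, an$means, "CR"),
               "mismatched")
})

test_that("planted dominant and overdominant genes are recovered on a strong-effect study", {
  st <- strong_analysis()
  expect_gte(recovery_rate(st$calls_cr, st$sim$truth, "DOMINANT"), 0.90)
  expect_gte(recovery_rate(st$calls_cr, st$sim$truth, "OVERDOMINANT"), 0.90)
})

test_that("an all-conserved study yields only a false-positive-level universe", {
  nl <- null_analysis()
  means <- group_mean_fpkm(compute_fpkm(nl$sim$counts, nl$sim$annotation),
                           nl$sim$samples)
  calls <- classify_cross(nl$de$CC_vs_RR, nl$de$CR_vs_CC, nl$de$CR_vs_RR,
                          means, cross = "CR")
  expect_lte(nrow(calls), 0.05 * nrow(nl$sim$counts))
})

test_that("all three modes are recovered exactly in the near-noiseless limit", {
  # one planted gene per mode against a conserved background
  spec <- simulation_spec(seed = 15L, n_genes = 50L, dispersion = 0,
                          baseline_log2_mean_range = c(7, 10),
                          class_proportions = c(CONSERVED = 0.94,
                                                ADDITIVE = 0.02,
                                                DOMINANT_HIGH = 0.02,
                                                DOMINANT_LOW = 0,
                                                OVERDOMINANT_UP = 0.02,
                                                OVERDOMINANT_DOWN = 0),
                          sex_linked_fraction = 0, low_expr_fraction = 0)
  sim <- simulate_counts(spec)
  de <- run_comparisons(sim$counts, sim$samples)
  means <- group_mean_fpkm(compute_fpkm(sim$counts, sim$annotation),
                           sim$samples)
  calls <- classify_cross(de$CC_vs_RR, de$CR_vs_CC, de$CR_vs_RR, means, "CR")
  expect_equal(recovery_rate(calls, sim$truth, "ADDITIVE"), 1)
  expect_equal(recovery_rate(calls, sim$truth, "DOMINANT"), 1)
  expect_equal(recovery_rate(calls, sim$truth, "OVERDOMINANT"), 1)
})

test_that("mode summaries reproduce printed-count proportion arithmetic", {
  # 3617 nonadditive of a 5243-gene universe -> 68.99%
  cr <- make_calls(rep(c("DOMINANT", "OVERDOMINANT", "ADDITIVE"),
                       c(3324, 293, 5243 - 3617)), cross = "CR")
  expect_equal(summarize_modes(cr)$nonadditive_pct, 68.99)
  # 4257 nonadditive of 5587 -> 76.19% (100 * 4257/5587 = 76.1947)
  rc <- make_calls(rep(c("DOMINANT", "OVERDOMINANT", "ADDITIVE"),
                       c(3851, 406, 5587 - 4257)), cross = "RC")
  expect_equal(summarize_modes(rc)$nonadditive_pct, 76.19)
  # zero nonadditive and the empty summary
  expect_equal(summarize_modes(make_calls(rep("ADDITIVE", 10)))$nonadditive_pct, 0)
  empty <- summarize_modes(make_calls(character(0)))
  expect_identical(empty$n_universe, 0L)
})

test_that("shared nonadditive genes and their class shares are tabulated", {
  # no overlap -> empty report
  a <- make_calls(rep("DOMINANT", 5), cross = "CR")
  b <- make_calls(rep("DOMINANT", 5), cross = "RC")
  expect_identical(nrow(shared_nonadditive(a, b)$genes), 0L)

  # 31 shared genes: 24 of one class in CR (77.42%), 19 of one in RC (61.29%)
  ids <- sprintf("shared%02d", 1:31)
  cr <- make_calls(rep("DOMINANT", 31), cross = "CR",
                   classes = rep(c("IV", "II"), c(24, 7)))
  rc <- make_calls(rep("DOMINANT", 31), cross = "RC",
                   classes = rep(c("II", "IX"), c(19, 12)))
  cr$gene_id <- ids; rc$gene_id <- ids
  sh <- shared_nonadditive(cr, rc)
  expect_identical(nrow(sh$genes), 31L)
  tab <- sh$class_table
  expect_equal(tab$pct[tab$cross == "CR" & tab$class == "IV"], 77.42)
  expect_equal(tab$pct[tab$cross == "RC" & tab$class == "II"], 61.29)

  # restriction to a named gene set
  sh2 <- shared_nonadditive(cr, rc, restrict_to = ids[1:10])
  expect_identical(nrow(sh2$genes), 10L)
})
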