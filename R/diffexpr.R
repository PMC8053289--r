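#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes
#' (genes with nonzero counts in every sample) of the ratio of the sample's
#' count to the gene's geometric mean across samples. Factors are not
#' rescaled afterward.
#'
#' @param counts integer matrix, genes x samples.
#' @return named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  validate_counts(counts)
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    stop("no gene has nonzero counts in all samples; consider a ",
         "pseudo-reference fallback on a filtered matrix")
  }
  logc <- log(counts[all_pos, , drop = FALSE])
  log_geo <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(median(x - log_geo)))
  setNames(sf, colnames(counts))
}

# parametric mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted by
# iterated least squares with outlier trimming; both coefficients clamped
# at >= 0 so the trend is a valid dispersion for any mean
fit_dispersion_trend <- function(mu, alpha_raw) {
  use <- which(mu >= 1 & alpha_raw > 1e-8)
  fallback <- function() {
    a0 <- if (length(use)) median(alpha_raw[use]) else 1e-2
    c(a0 = max(a0, 1e-8), a1 = 0)
  }
  if (length(use) < 10) return(fallback())
  m <- mu[use]; a <- alpha_raw[use]
  keep <- rep(TRUE, length(use))
  co <- NULL
  for (it in 1:3) {
    fit <- tryCatch(lm(a ~ I(1 / m), subset = keep), error = function(e) NULL)
    if (is.null(fit)) return(fallback())
    co <- coef(fit)
    pred <- pmax(co[1] + co[2] / m, 1e-8)
    ratio <- a / pred
    keep <- ratio > 1e-4 & ratio < 15
    if (sum(keep) < 10) break
  }
  a0 <- max(co[[1]], 1e-8)
  a1 <- max(co[[2]], 0)
  c(a0 = a0, a1 = a1)
}

#' Per-gene NB dispersion estimates with trend shrinkage
#'
#' Gene-wise method-of-moments estimates on size-factor-normalized counts,
#' `alpha_g = max(0, (s2_g - mu_g) / mu_g^2)`, where `s2_g` pools the
#' within-group sample variances and `mu_g` is the overall normalized mean.
#' Gene-wise values are then shrunk toward a fitted parametric trend
#' `alpha(mu) = a0 + a1/mu` with weight `shrink_weight`, and floored at
#' 1e-8. All-zero genes receive the trend asymptote.
#'
#' @param counts integer matrix, genes x samples.
#' @param sf size factors from [estimate_size_factors()].
#' @param samples sample table mapping samples to groups.
#' @param shrink_weight weight on the trend in the shrunk estimate
#'   (0 = pure gene-wise, 1 = pure trend).
#' @return named numeric vector of dispersions, with the trend coefficients
#'   in attribute `trend`.
#' @export
estimate_dispersions <- function(counts, sf, samples, shrink_weight = 0.5) {
  grp <- sample_groups(counts, samples)
  tab <- table(grp)
  if (any(tab < 2)) {
    stop("need >= 2 samples per group for dispersion estimation")
  }
  norm <- sweep(counts, 2, sf[colnames(counts)], "/")
  mu <- rowMeans(norm)
  groups <- names(tab)
  ss <- 0
  for (g in groups) {
    sub <- norm[, grp == g, drop = FALSE]
    gm <- rowMeans(sub)
    ss <- ss + rowSums((sub - gm)^2)
  }
  s2 <- ss / (ncol(norm) - length(groups))  # pooled within-group variance
  alpha_raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  trend <- fit_dispersion_trend(mu, alpha_raw)
  alpha_tr <- ifelse(mu > 0, trend[["a0"]] + trend[["a1"]] / mu,
                     trend[["a0"]])
  alpha <- (1 - shrink_weight) * alpha_raw + shrink_weight * alpha_tr
  alpha[mu == 0] <- alpha_tr[mu == 0]
  alpha <- pmax(alpha, 1e-8)
  names(alpha) <- rownames(counts)
  attr(alpha, "trend") <- trend
  alpha
}

# Fisher-scoring fit of a per-group NB log-mean with known dispersion and
# log(size factor) offsets; vectorized across genes. Returns the fitted
# log mean phi, the total IRLS weight W = sum mu/(1+alpha*mu), and a
# convergence flag per gene.
fit_nb_group_logmean <- function(y, sf, alpha, maxit = 100L, tol = 1e-10) {
  ng <- nrow(y)
  zero <- rowSums(y) == 0
  phi <- log(pmax(rowSums(y) / sum(sf), 1e-8))
  conv <- zero  # all-zero genes sit at the floor, counted as done
  for (it in seq_len(maxit)) {
    act <- which(!conv)
    if (!length(act)) break
    mu <- exp(phi[act]) %o% sf
    denom <- 1 + alpha[act] * mu
    score <- rowSums((y[act, , drop = FALSE] - mu) / denom)
    W <- rowSums(mu / denom)
    step <- score / pmax(W, 1e-12)
    step <- pmin(pmax(step, -5), 5)  # damp early overshoot
    phi[act] <- phi[act] + step
    conv[act] <- abs(step) < tol
  }
  mu <- exp(phi) %o% sf
  W <- rowSums(mu / (1 + alpha * mu))
  list(phi = phi, W = W, converged = conv, zero = zero)
}

#' Negative-binomial Wald test between two groups
#'
#' Fits, per gene, the NB GLM with log link, intercept + group indicator
#' design and log size-factor offsets (equivalently one fitted log mean per
#' group, by Fisher scoring), with the dispersion fixed at the supplied
#' estimate. The Wald statistic is `beta / SE(beta)` for the group
#' contrast, with a two-sided p-value from the standard normal; the log2
#' fold change is group A over group B.
#'
#' @param counts integer matrix, genes x samples.
#' @param sf size factors.
#' @param dispersions per-gene dispersions.
#' @param samples sample table.
#' @param groupA,groupB group labels; the reported fold change is A over B.
#' @return data.frame of class `de_result`: gene_id, baseMean,
#'   log2FoldChange, lfcSE, stat, pvalue, padj. Non-converged genes carry
#'   NA p-values and are excluded from the BH m.
#' @export
wald_test <- function(counts, sf, dispersions, samples, groupA, groupB) {
  grp <- sample_groups(counts, samples)
  for (g in c(groupA, groupB)) {
    if (sum(grp == g) < 2) stop("group ", g, " needs >= 2 samples")
  }
  iA <- which(grp == groupA)
  iB <- which(grp == groupB)
  alpha <- dispersions[rownames(counts)]
  empty <- data.frame(gene_id = character(), baseMean = numeric(),
                      log2FoldChange = numeric(), lfcSE = numeric(),
                      stat = numeric(), pvalue = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE)
  if (nrow(counts) == 0) return(structure(empty, class = c("de_result", "data.frame")))

  fitA <- fit_nb_group_logmean(counts[, iA, drop = FALSE], sf[iA], alpha)
  fitB <- fit_nb_group_logmean(counts[, iB, drop = FALSE], sf[iB], alpha)

  beta <- fitA$phi - fitB$phi
  se <- sqrt(1 / pmax(fitA$W, 1e-12) + 1 / pmax(fitB$W, 1e-12))
  stat <- beta / se
  pval <- 2 * pnorm(-abs(stat))
  ok <- fitA$converged & fitB$converged & !(fitA$zero | fitB$zero)
  both_zero <- fitA$zero & fitB$zero
  # both groups empty: no information, keep the zero contrast but NA p
  stat[!ok] <- NA_real_
  pval[!ok] <- NA_real_
  beta[both_zero] <- 0

  norm <- sweep(counts[, c(iA, iB), drop = FALSE], 2,
                sf[c(iA, iB)], "/")
  out <- data.frame(gene_id = rownames(counts),
                    baseMean = rowMeans(norm),
                    log2FoldChange = beta / log(2),
                    lfcSE = se / log(2),
                    stat = stat,
                    pvalue = pval,
                    padj = bh_adjust(pval),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("de_result", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: with m the number of non-missing p-values and p(i) the i-th
#' smallest, the adjusted value is `min_{j >= i} (m * p(j) / j)`, capped at
#' 1. Missing values are excluded from m and returned as NA.
#'
#' @param pvalues numeric vector of p-values in [0, 1]; NA allowed.
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  obs <- !is.na(pvalues)
  p <- pvalues[obs]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin((m * p[o]) / (m:1)))[ro]
    out[obs] <- adj
  }
  out
}

# the five pairwise contrasts of the reciprocal-cross design
STANDARD_COMPARISONS <- list(
  CC_vs_RR = c("CC", "RR"),
  CR_vs_CC = c("CR", "CC"),
  CR_vs_RR = c("CR", "RR"),
  RC_vs_CC = c("RC", "CC"),
  RC_vs_RR = c("RC", "RR"))

#' Run the five standard reciprocal-cross comparisons
#'
#' Estimates size factors and trend-shrunk dispersions once on the full
#' (post-filter) matrix, then performs the NB Wald test for CC vs RR and
#' the four F1-vs-parent contrasts on the shared gene universe. A gene is a
#' DEG in a comparison iff its BH-adjusted p-value is below `padj_threshold`.
#'
#' @param counts post-filter integer count matrix.
#' @param samples sample table; all four groups must be present.
#' @param shrink_weight dispersion shrinkage weight, see
#'   [estimate_dispersions()].
#' @param padj_threshold DEG threshold recorded in the result attribute.
#' @return named list of five `de_result` data.frames, with size factors
#'   and dispersions in attributes.
#' @export
run_comparisons <- function(counts, samples, shrink_weight = 0.5,
                            padj_threshold = 0.05) {
  grp <- sample_groups(counts, samples)
  missing <- setdiff(GROUPS, unique(grp))
  if (length(missing)) {
    stop("missing group(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(counts) == 0) {
    res <- lapply(STANDARD_COMPARISONS, function(ab) {
      wald_test(counts, setNames(rep(1, ncol(counts)), colnames(counts)),
                numeric(0), samples, ab[1], ab[2])
    })
    return(res)
  }
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, samples,
                               shrink_weight = shrink_weight)
  res <- lapply(STANDARD_COMPARISONS, function(ab) {
    wald_test(counts, sf, disp, samples, ab[1], ab[2])
  })
  attr(res, "size_factors") <- sf
  attr(res, "dispersions") <- disp
  attr(res, "padj_threshold") <- padj_threshold
  res
}

#' DEG gene ids of one comparison
#' @param de a `de_result`.
#' @param padj_threshold adjusted-p cutoff.
#' @return character vector of gene ids with `padj < padj_threshold`.
#' @export
deg_genes <- function(de, padj_threshold = 0.05) {
  de$gene_id[!is.na(de$padj) & de$padj < padj_threshold]
}
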