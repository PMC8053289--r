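MODES <- c("ADDITIVE", "DOMINANT", "OVERDOMINANT", "UNCLASSIFIED")

# Internal 12-class numeral table. The mode-level grouping is fixed:
# additive = I, XII; dominant = II, IV, IX, XI; overdominant = III, V, VI,
# VII, VIII, X. Within a mode the numeral encodes the geometry:
#   additive:      I  = CC above RR, F1 between;  XII = RR above CC
#   dominant:      II = F1 matches CC, CC high;   IV = F1 matches CC, CC low
#                  IX = F1 matches RR, RR high;   XI = F1 matches RR, RR low
#   overdominant (F1 above both):  III = CC > RR;  V = parents similar
#                  (parental contrast not significant); VI = RR > CC
#   overdominant (F1 below both):  VII = CC > RR; VIII = parents similar;
#                  X = RR > CC
# Swapping the CC and RR columns mirrors the numeral (I<->XII, II<->IX,
# IV<->XI, III<->VI, VII<->X; V and VIII are self-mirrored) and always
# preserves the mode.
CLASS_MODE <- c(I = "ADDITIVE", XII = "ADDITIVE",
                II = "DOMINANT", IV = "DOMINANT", IX = "DOMINANT",
                XI = "DOMINANT",
                III = "OVERDOMINANT", V = "OVERDOMINANT",
                VI = "OVERDOMINANT", VII = "OVERDOMINANT",
                VIII = "OVERDOMINANT", X = "OVERDOMINANT")

#' Classify one gene's expression-inheritance pattern
#'
#' Uses the per-group mean expression (FPKM) and the three adjusted
#' p-values of the cross's comparisons — parent vs parent (PP), F1 vs CC
#' and F1 vs RR — to assign one of twelve pattern classes and an
#' inheritance mode. Rules, evaluated in precedence order:
#'
#' 1. OVERDOMINANT: F1 significantly different from both parents and its
#'    mean outside the parental range (above both or below both).
#' 2. DOMINANT: F1 significantly different from exactly one parent (not
#'    significantly different from the other).
#' 3. ADDITIVE: parents significantly different, F1 mean strictly between
#'    the parental means, and F1 significantly different from both parents.
#' 4. otherwise UNCLASSIFIED.
#'
#' Missing adjusted p-values (e.g. a non-converged fit) are treated as not
#' significant. Exactly equal means where an ordering is needed are
#' degenerate and yield UNCLASSIFIED.
#'
#' @param mean_cc,mean_rr,mean_f1 per-group mean expression (>= 0).
#' @param padj_pp,padj_f1cc,padj_f1rr adjusted p-values for parent vs
#'   parent, F1 vs CC, and F1 vs RR.
#' @param alpha significance threshold.
#' @param require_parental_de_for_dominance if TRUE, a dominance call
#'   additionally requires `padj_pp < alpha`.
#' @return list with `class` (roman numeral or "NONE") and `mode`.
#' @export
classify_gene <- function(mean_cc, mean_rr, mean_f1,
                          padj_pp, padj_f1cc, padj_f1rr,
                          alpha = 0.05,
                          require_parental_de_for_dominance = FALSE) {
  stopifnot(mean_cc >= 0, mean_rr >= 0, mean_f1 >= 0)
  sig <- function(p) !is.na(p) && p < alpha
  s_pp <- sig(padj_pp); s_cc <- sig(padj_f1cc); s_rr <- sig(padj_f1rr)
  unclass_call <- list(class = "NONE", mode = "UNCLASSIFIED")

  hi <- max(mean_cc, mean_rr); lo <- min(mean_cc, mean_rr)
  if (s_cc && s_rr && (mean_f1 > hi || mean_f1 < lo)) {
    up <- mean_f1 > hi
    cls <- if (!s_pp) {
      if (up) "V" else "VIII"
    } else if (mean_cc > mean_rr) {
      if (up) "III" else "VII"
    } else if (mean_rr > mean_cc) {
      if (up) "VI" else "X"
    } else {
      return(unclass_call)  # significant PP with exactly equal means
    }
    return(list(class = cls, mode = "OVERDOMINANT"))
  }
  if (xor(s_cc, s_rr) && (!require_parental_de_for_dominance || s_pp)) {
    if (mean_cc == mean_rr) return(unclass_call)
    matches_cc <- !s_cc  # the parent the F1 is NOT different from
    cls <- if (matches_cc) {
      if (mean_cc > mean_rr) "II" else "IV"
    } else {
      if (mean_rr > mean_cc) "IX" else "XI"
    }
    return(list(class = cls, mode = "DOMINANT"))
  }
  if (s_pp && s_cc && s_rr && mean_f1 > lo && mean_f1 < hi) {
    cls <- if (mean_cc > mean_rr) "I" else "XII"
    return(list(class = cls, mode = "ADDITIVE"))
  }
  unclass_call
}

#' Classify every DEG of one cross
#'
#' The cross's DEG universe is the union of genes with adjusted p below
#' `alpha` in any of its three comparisons (parent vs parent, F1 vs CC,
#' F1 vs RR); every universe gene receives exactly one call.
#'
#' @param de_pp,de_f1cc,de_f1rr `de_result` tables for CC-vs-RR,
#'   F1-vs-CC and F1-vs-RR (the F1 tables' fold-change direction is not
#'   used, only the adjusted p).
#' @param fpkm_means genes x groups matrix of mean FPKM (from
#'   [group_mean_fpkm()]) containing columns CC, RR and the cross.
#' @param cross "CR" or "RC".
#' @param alpha significance threshold.
#' @param require_parental_de_for_dominance see [classify_gene()].
#' @return data.frame of class `inheritance_calls`: gene_id, cross, class,
#'   mode, mean_CC, mean_RR, mean_F1, padj_PP, padj_F1_CC, padj_F1_RR.
#' @export
classify_cross <- function(de_pp, de_f1cc, de_f1rr, fpkm_means,
                           cross = c("CR", "RC"), alpha = 0.05,
                           require_parental_de_for_dominance = FALSE) {
  cross <- match.arg(cross)
  tabs <- list(PP = de_pp, F1_CC = de_f1cc, F1_RR = de_f1rr)
  ids <- lapply(tabs, function(d) sort(d$gene_id))
  if (length(unique(ids)) != 1L) {
    stop("mismatched gene ids across the three comparison tables")
  }
  universe <- sort(unique(unlist(lapply(tabs, deg_genes,
                                        padj_threshold = alpha))))
  missing <- setdiff(universe, rownames(fpkm_means))
  if (length(missing)) {
    stop("FPKM means missing for genes: ", paste(head(missing, 5),
                                                 collapse = ", "))
  }
  need <- c("CC", "RR", cross)
  if (!all(need %in% colnames(fpkm_means))) {
    stop("fpkm_means must contain columns ", paste(need, collapse = ", "))
  }
  getp <- function(d, g) d$padj[match(g, d$gene_id)]
  out <- data.frame(gene_id = universe,
                    cross = rep(cross, length(universe)),
                    class = character(length(universe)),
                    mode = character(length(universe)),
                    mean_CC = fpkm_means[universe, "CC"],
                    mean_RR = fpkm_means[universe, "RR"],
                    mean_F1 = fpkm_means[universe, cross],
                    padj_PP = getp(de_pp, universe),
                    padj_F1_CC = getp(de_f1cc, universe),
                    padj_F1_RR = getp(de_f1rr, universe),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    call <- classify_gene(out$mean_CC[i], out$mean_RR[i], out$mean_F1[i],
                          out$padj_PP[i], out$padj_F1_CC[i],
                          out$padj_F1_RR[i], alpha = alpha,
                          require_parental_de_for_dominance =
                            require_parental_de_for_dominance)
    out$class[i] <- call$class
    out$mode[i] <- call$mode
  }
  rownames(out) <- NULL
  structure(out, class = c("inheritance_calls", "data.frame"))
}

#' Summarize inheritance modes for one cross
#'
#' Counts and fractions of additive, dominant, overdominant and
#' unclassified calls, plus the nonadditive share
#' `(dominant + overdominant) / universe * 100`, rounded to 2 decimals.
#'
#' @param calls an `inheritance_calls` data.frame for one cross.
#' @return one-row data.frame: cross, n_universe, per-mode counts and
#'   fractions, nonadditive_pct.
#' @export
summarize_modes <- function(calls) {
  cross <- if (nrow(calls)) unique(calls$cross) else NA_character_
  if (length(cross) > 1) stop("summarize_modes expects calls from one cross")
  n <- nrow(calls)
  cnt <- setNames(vapply(MODES, function(m) sum(calls$mode == m),
                         integer(1)), MODES)
  frac <- if (n > 0) cnt / n else setNames(rep(0, length(MODES)), MODES)
  nonadd <- if (n > 0) {
    round(100 * (cnt[["DOMINANT"]] + cnt[["OVERDOMINANT"]]) / n, 2)
  } else 0
  data.frame(cross = cross, n_universe = n,
             n_additive = cnt[["ADDITIVE"]],
             n_dominant = cnt[["DOMINANT"]],
             n_overdominant = cnt[["OVERDOMINANT"]],
             n_unclassified = cnt[["UNCLASSIFIED"]],
             frac_additive = frac[["ADDITIVE"]],
             frac_dominant = frac[["DOMINANT"]],
             frac_overdominant = frac[["OVERDOMINANT"]],
             frac_unclassified = frac[["UNCLASSIFIED"]],
             nonadditive_pct = nonadd,
             stringsAsFactors = FALSE)
}

#' Nonadditive genes shared by both crosses
#'
#' Intersects the nonadditive (dominant or overdominant) genes of the CR
#' and RC call lists, optionally restricted to a named gene set, and
#' tabulates each cross's class frequencies among the shared genes
#' (percentages to 2 decimals).
#'
#' @param calls_cr,calls_rc `inheritance_calls` for the two crosses.
#' @param restrict_to optional character vector of gene ids (e.g. one gene
#'   set) to intersect with.
#' @return list with `genes` (data.frame gene_id, class_CR, class_RC) and
#'   `class_table` (data.frame cross, class, n, pct).
#' @export
shared_nonadditive <- function(calls_cr, calls_rc, restrict_to = NULL) {
  nonadd <- function(calls) {
    calls$gene_id[calls$mode %in% c("DOMINANT", "OVERDOMINANT")]
  }
  shared <- intersect(nonadd(calls_cr), nonadd(calls_rc))
  if (!is.null(restrict_to)) shared <- intersect(shared, restrict_to)
  shared <- sort(shared)
  genes <- data.frame(gene_id = shared,
                      class_CR = calls_cr$class[match(shared,
                                                      calls_cr$gene_id)],
                      class_RC = calls_rc$class[match(shared,
                                                      calls_rc$gene_id)],
                      stringsAsFactors = FALSE)
  tab <- function(cls, cross) {
    if (!length(cls)) {
      return(data.frame(cross = character(), class = character(),
                        n = integer(), pct = numeric(),
                        stringsAsFactors = FALSE))
    }
    t <- sort(table(cls), decreasing = TRUE)
    data.frame(cross = cross, class = names(t), n = as.integer(t),
               pct = round(100 * as.integer(t) / length(cls), 2),
               stringsAsFactors = FALSE)
  }
  class_table <- rbind(tab(genes$class_CR, "CR"), tab(genes$class_RC, "RC"))
  rownames(class_table) <- NULL
  list(genes = genes, class_table = class_table)
}
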