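#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors, with per-set descriptions in
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(
    vapply(parts, `[[`, character(1), 2), nm)
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors; optional `descriptions`
#'   attribute (named character vector).
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance in a fixed universe: with N universe genes, K of
#' them in the set, a query of size n and overlap k, the p-value is the
#' upper tail `P(X >= k)` of the hypergeometric distribution. BH adjustment
#' is applied across all tested sets — within namespaces if the GMT
#' descriptions define more than one (e.g. GO vs KEGG), else globally.
#'
#' @param query character vector of gene ids; ids outside the universe are
#'   dropped with a warning.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param universe character vector of background gene ids (deduplicated).
#' @param min_set_size sets with fewer than this many universe genes are
#'   skipped.
#' @return data.frame sorted by p: set, namespace, k, K, n, N, pvalue, fdr,
#'   genes (comma-separated overlap).
#' @export
hypergeom_enrich <- function(query, sets, universe, min_set_size = 3) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  desc <- attr(sets, "descriptions")
  ns <- if (!is.null(desc)) unname(desc[names(sets)]) else
    rep(NA_character_, length(sets))
  rows <- lapply(seq_along(sets), function(i) {
    inset <- intersect(sets[[i]], universe)
    K <- length(inset)
    if (K == 0 || K < min_set_size) return(NULL)
    hit <- intersect(query, inset)
    k <- length(hit)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = names(sets)[i], namespace = ns[i],
               k = k, K = K, n = n, N = N, pvalue = p,
               fdr = NA_real_,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), namespace = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), pvalue = numeric(), fdr = numeric(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  nspaces <- unique(out$namespace[!is.na(out$namespace)])
  if (length(nspaces) > 1) {
    for (s in unique(out$namespace)) {
      idx <- if (is.na(s)) is.na(out$namespace) else
        !is.na(out$namespace) & out$namespace == s
      out$fdr[idx] <- bh_adjust(out$pvalue[idx])
    }
  } else {
    out$fdr <- bh_adjust(out$pvalue)
  }
  out <- out[order(out$pvalue, out$set), ]
  rownames(out) <- NULL
  out
}

#' Enrichment of nonadditive (or dominant / overdominant) genes per cross
#'
#' Builds the per-cross query from the inheritance calls with the requested
#' mode filter, runs [hypergeom_enrich()] against the shared universe, and
#' reports the gene sets significant (FDR below `fdr_threshold`) in each
#' cross and in both.
#'
#' @param calls_cr,calls_rc `inheritance_calls` for the two crosses.
#' @param sets gene-set collection.
#' @param universe background gene ids (typically the post-filter
#'   expressed autosomal genes).
#' @param mode_filter "nonadditive" (dominant + overdominant), "dominant",
#'   "overdominant", or "additive".
#' @param fdr_threshold significance cutoff on the BH FDR.
#' @param min_set_size see [hypergeom_enrich()].
#' @return list with per-cross tables `CR`, `RC`, and
#'   `shared_significant` (set names with FDR < threshold in both crosses).
#' @export
enrich_nonadditive <- function(calls_cr, calls_rc, sets, universe,
                               mode_filter = c("nonadditive", "dominant",
                                               "overdominant", "additive"),
                               fdr_threshold = 0.05, min_set_size = 3) {
  mode_filter <- match.arg(mode_filter)
  wanted <- switch(mode_filter,
                   nonadditive = c("DOMINANT", "OVERDOMINANT"),
                   dominant = "DOMINANT",
                   overdominant = "OVERDOMINANT",
                   additive = "ADDITIVE")
  query_of <- function(calls) calls$gene_id[calls$mode %in% wanted]
  res <- list(CR = hypergeom_enrich(query_of(calls_cr), sets, universe,
                                    min_set_size = min_set_size),
              RC = hypergeom_enrich(query_of(calls_rc), sets, universe,
                                    min_set_size = min_set_size))
  sig <- function(tab) tab$set[!is.na(tab$fdr) & tab$fdr < fdr_threshold]
  res$shared_significant <- intersect(sig(res$CR), sig(res$RC))
  res
}
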