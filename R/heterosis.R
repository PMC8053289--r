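#' Mid-parent heterosis of a trait
#'
#' Heterosis is the relative deviation of the F1 mean from the mid-parent
#' value `MP = (PM + PF) / 2`:
#' `H = (mean(F1) - MP) / MP`, reported both as a fraction and as a
#' percentage (`H_percent = 100 * H`).
#'
#' @param f1_values trait values of the F1 individuals (NA dropped).
#' @param pm_mean,pf_mean means of the maternal and paternal lines.
#' @return list with `n`, `f1_mean`, `pm_mean`, `pf_mean`, `mp`,
#'   `h_fraction`, `h_percent`.
#' @export
heterosis_percent <- function(f1_values, pm_mean, pf_mean) {
  f1 <- f1_values[!is.na(f1_values)]
  if (!length(f1)) stop("no F1 values")
  mp <- (pm_mean + pf_mean) / 2
  if (mp == 0) stop("mid-parent value is zero; heterosis undefined")
  h <- (mean(f1) - mp) / mp
  list(n = length(f1), f1_mean = mean(f1), pm_mean = pm_mean,
       pf_mean = pf_mean, mp = mp, h_fraction = h, h_percent = 100 * h)
}

#' Mid-parent heterosis with its t significance test
#'
#' The t statistic treats the parental means as fixed and tests the F1 mean
#' against the mid-parent value: with H entered as a fraction,
#' `t = H * (PM + PF) * sqrt(N) / (2 * s)`, where `s` is the F1 sample
#' standard deviation — algebraically a one-sample t-test of the F1 values
#' against MP, `t = (mean(F1) - MP) * sqrt(N) / s`, with `df = N - 1` and a
#' two-sided p-value. Tiers: `ns` (p >= 0.05), `P<0.05`, `P<0.01`.
#'
#' @inheritParams heterosis_percent
#' @return list extending [heterosis_percent()] with `sd`, `t`, `df`, `p`,
#'   `tier`.
#' @export
heterosis_t_test <- function(f1_values, pm_mean, pf_mean) {
  est <- heterosis_percent(f1_values, pm_mean, pf_mean)
  f1 <- f1_values[!is.na(f1_values)]
  if (length(f1) < 2) stop("need N >= 2 F1 values for the t-test")
  s <- sqrt(sum((f1 - est$f1_mean)^2) / (length(f1) - 1))
  if (s == 0) {
    warning("zero F1 standard deviation; t is infinite, p reported as 0")
    t_stat <- if (est$f1_mean == est$mp) 0 else sign(est$f1_mean - est$mp) * Inf
    p <- if (t_stat == 0) 1 else 0
  } else {
    t_stat <- est$h_fraction * (est$pm_mean + est$pf_mean) *
      sqrt(est$n) / (2 * s)
    p <- 2 * pt(-abs(t_stat), df = est$n - 1)
  }
  tier <- if (p < 0.01) "P<0.01" else if (p < 0.05) "P<0.05" else "ns"
  c(est, list(sd = s, t = t_stat, df = est$n - 1L, p = p, tier = tier))
}

#' Heterosis table over all traits and both crosses
#'
#' For every trait column and each cross (CR, RC), computes the mid-parent
#' heterosis and its significance, with the parental means taken from the
#' CC and RR individuals. Rows with a missing group or insufficient data
#' are skipped with a warning.
#'
#' @param traits phenotype data.frame with columns `individual_id`,
#'   `group`, then numeric trait columns.
#' @param trait_cols trait columns to analyze; defaults to every numeric
#'   column after the two id columns.
#' @param by column name to stratify by (e.g. `"sex"`), or NULL.
#' @return data.frame: trait, cross, N, F1_mean, PM_mean, PF_mean, MP,
#'   H_percent, t, df, p, tier (plus the stratum column when `by` is set).
#' @export
heterosis_table <- function(traits, trait_cols = NULL, by = NULL) {
  if (!all(c("individual_id", "group") %in% names(traits))) {
    stop("phenotype table needs columns individual_id, group")
  }
  if (!is.null(by)) {
    if (!by %in% names(traits)) stop("stratification column not found: ", by)
    strata <- split(traits, traits[[by]])
    out <- do.call(rbind, lapply(names(strata), function(s) {
      tb <- heterosis_table(strata[[s]][, setdiff(names(traits), by)],
                            trait_cols = trait_cols)
      if (nrow(tb)) cbind(setNames(data.frame(s), by), tb) else NULL
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(trait_cols)) {
    cand <- setdiff(names(traits), c("individual_id", "group"))
    trait_cols <- cand[vapply(traits[cand], is.numeric, logical(1))]
  }
  rows <- list()
  for (tr in trait_cols) {
    vals <- traits[[tr]]
    grp <- traits$group
    pm <- vals[grp == "CC" & !is.na(vals)]
    pf <- vals[grp == "RR" & !is.na(vals)]
    if (!length(pm) || !length(pf)) {
      warning("trait ", tr, ": missing parental group, skipped")
      next
    }
    for (cross in c("CR", "RC")) {
      f1 <- vals[grp == cross & !is.na(vals)]
      if (length(f1) < 2) {
        warning("trait ", tr, ", cross ", cross,
                ": fewer than 2 F1 values, skipped")
        next
      }
      est <- heterosis_t_test(f1, mean(pm), mean(pf))
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, cross = cross, N = est$n,
        F1_mean = est$f1_mean, PM_mean = est$pm_mean,
        PF_mean = est$pf_mean, MP = est$mp,
        H_percent = est$h_percent, t = est$t, df = est$df, p = est$p,
        tier = est$tier, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = character(), cross = character(), N = integer(),
               F1_mean = numeric(), PM_mean = numeric(),
               PF_mean = numeric(), MP = numeric(), H_percent = numeric(),
               t = numeric(), df = numeric(), p = numeric(),
               tier = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
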