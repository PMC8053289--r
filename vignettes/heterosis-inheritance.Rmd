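---
title: "Heterosis and expression inheritance in reciprocal crosses: methods"
author: "hetexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterosis and expression inheritance in reciprocal crosses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetexpr)
```

# The design and the questions

`hetexpr` analyzes a four-group reciprocal-cross design: two purebred
parental lines — here labelled CC (a broiler-type sire line) and RR (a
layer-type dam line) — and the two F1 crosses obtained by swapping the
direction of the cross (CR and RC). Two questions drive the analysis:

1. **Phenotype**: does the F1 deviate from the mid-parent expectation
   (heterosis), and is the deviation significant? Growth traits in
   broiler × layer crosses often show *negative* heterosis.
2. **Transcriptome**: for genes differentially expressed among the groups,
   is the F1 expression *additive* (intermediate between the parents),
   *dominant* (matching one parent), or *overdominant* (outside the
   parental range)? The nonadditive share (dominant + overdominant) is the
   headline quantity per cross.

# Mid-parent heterosis

For a trait with F1 values $F_{1i}$ ($i = 1 \dots N$) and parental means
$\bar P_M$, $\bar P_F$, the mid-parent value is
$MP = (\bar P_M + \bar P_F)/2$ and

$$H = \frac{\bar F_1 - MP}{MP}, \qquad H\% = 100\,H.$$

Significance uses a t statistic that treats the parental means as fixed
constants:

$$t = \frac{H\,(\bar P_M + \bar P_F)\sqrt{N}}{2 s},$$

with $s$ the F1 sample standard deviation. Substituting $H$ shows this is
algebraically the one-sample t-test of the F1 values against $MP$:
$t = (\bar F_1 - MP)\sqrt N / s$, with $N-1$ degrees of freedom and a
two-sided p-value. The test suite verifies this equivalence against
`t.test(..., mu = MP)` at $10^{-10}$ on random instances, and checks the
null rejection rate by simulation.

Two numerical decisions are worth stating:

* **$H$ enters the t statistic as a fraction, not a percentage.** The
  formula is dimensionally consistent only then; using $H\%$ would inflate
  $t$ by a factor of 100.
* **$df = N - 1$, parental means fixed.** The statistic carries no
  parental variance term, so the parents contribute no degrees of freedom.
  This makes the test slightly anticonservative when parental samples are
  small; it is the convention the field uses for this statistic.
* Two-sided p-values, because negative and positive heterosis are both
  reported, with significance tiers at 0.05 and 0.01.

Degenerate inputs: an all-equal F1 sample (zero SD) yields an infinite
$t$ flagged with a warning and $p = 0$; $MP = 0$ is an error since $H$ is
then undefined.

# Expression preprocessing

Counts are gene-level fragment counts (genes × samples). Expression is
summarized as FPKM,
$\mathrm{FPKM}_{gs} = 10^9 \, c_{gs} / (T_s \, L_g)$ with $T_s$ the
sample's total assigned fragments and $L_g$ the exonic gene length. The
denominator uses the column totals of the analyzed matrix, the only total
recoverable from a count matrix.

Two filters precede testing, mirroring standard practice for this design:

* genes with mean FPKM across **all** samples strictly below 1 (low
  information, unstable dispersion estimates);
* genes on the sex chromosomes Z/W ("sex-linked" is operationalized as
  chromosomal location, the only reproducible reading), because the
  sequenced individuals are female and the crosses differ systematically
  in sex-chromosome ancestry.

Filtering is idempotent and order-independent, and each removal carries a
reason code.

# Differential expression

The DE stage is a deliberately compact negative-binomial Wald pipeline —
median-of-ratios size factors, method-of-moments dispersions shrunk to a
parametric trend, and a two-group NB GLM Wald test — rather than a wrapper
around a full-featured DE package. This keeps every formula visible and
testable by simulation; it is *not* a bit-compatible clone of any existing
tool, and its acceptance surface is calibration against planted truth, not
agreement with another implementation (an independent median-of-ratios
implementation is, however, used as a cross-check in the tests).

* **Size factors.** For samples $s$,
  $\hat s_s = \mathrm{median}_g \, c_{gs} / (\prod_s c_{gs})^{1/n}$ over
  genes positive in all samples; factors are not rescaled afterwards.
* **Dispersions.** On normalized counts, the gene-wise estimate is
  $\hat\alpha_g = \max\!\big(0, (s^2_g - \bar\mu_g)/\bar\mu_g^2\big)$ with
  $s^2_g$ the pooled within-group variance. Gene-wise values are shrunk
  with weight 0.5 toward a fitted trend $\alpha(\mu) = a_0 + a_1/\mu$
  (iterated least squares with outlier trimming, coefficients clamped at
  zero, floor $10^{-8}$). The weight is configurable; 0.5 balances the
  small per-group replication (n = 5–6) against gene-specific signal.
  All-zero genes receive the trend value.
* **Wald test.** With the intercept + group-indicator design and log
  size-factor offsets, the NB GLM separates per group; each group's log
  mean is fitted by Fisher scoring with the dispersion held fixed. The
  contrast $\hat\beta$ has
  $SE = (1/W_A + 1/W_B)^{1/2}$, $W_g = \sum_{i \in g} \mu_i/(1+\alpha\mu_i)$,
  $z = \hat\beta / SE$, two-sided p from the standard normal, and
  $\log_2\!FC = \hat\beta/\ln 2$. Non-converged fits are flagged, their
  p set missing and excluded from the multiple-testing m.
* **BH adjustment** is the classic step-up with cumulative-min
  enforcement, capped at 1; missing p-values are excluded from m.

The five contrasts of the design are CC vs RR and each F1 vs each parent.
A gene is a DEG in a contrast iff its adjusted p < 0.05. Independent
filtering and outlier refitting are intentionally omitted: the FPKM filter
already removes the genes they target, and neither is specified for this
analysis.

# Inheritance classification

For one cross, the DEG universe is the union of DEGs over its three
contrasts (parent vs parent, F1 vs CC, F1 vs RR). Each universe gene is
assigned by rules evaluated in precedence order on the group-mean FPKM and
the three adjusted p-values:

1. **Overdominant** — F1 significantly different from both parents and its
   mean outside the parental range;
2. **Dominant** — F1 significantly different from exactly one parent;
3. **Additive** — parents significantly different, F1 strictly between
   them, and significantly different from both;
4. otherwise **unclassified**.

The precedence makes the map a pure function: the textual rules overlap
(an F1 between significantly different parents, significant against both,
would otherwise match nothing unambiguously; an F1 equal to one parent
with a significant parental contrast could read as dominance or loose
additivity). Requiring additivity to be significant against *both*
parents separates genuine intermediacy from noise among DEGs; the cost of
that choice is quantified below. Missing adjusted p-values count as not
significant; exactly tied means where an ordering is needed are degenerate
and go to unclassified. A configurable flag additionally requires the
parental contrast for dominance calls (off by default — the standard rule
does not require it).

The twelve pattern classes refine the three modes by geometry (which
parent is higher, and which side the F1 falls on). The grouping is fixed —
additive = {I, XII}, dominant = {II, IV, IX, XI}, overdominant = {III, V,
VI, VII, VIII, X} — and the within-mode numeral assignment is an internal
documented table (see `classify_gene`): mirror-symmetric under swapping
the parents, with V/VIII reserved for overdominance over statistically
indistinguishable parents. Mode-level results are the quantitative
surface; the numerals serve reporting (e.g. class shares among shared
nonadditive genes).

The per-cross summary reports counts and fractions per mode and the
nonadditive percentage to two decimals; `shared_nonadditive()` intersects
the nonadditive genes of both crosses (optionally within a gene set) and
tabulates each cross's class shares.

# Gene-set enrichment

Over-representation uses the upper-tail hypergeometric test
$P(X \ge k)$ with universe N, set size K, query size n and overlap k,
BH-adjusted across sets — within namespaces when the GMT description
field defines more than one (GO and KEGG collections are conventionally
adjusted separately), else globally. The universe is the post-filter
expressed autosomal gene set: enrichment among nonadditive genes must be
judged against the genes that could have been tested, not the whole
genome. Sets are flat gene lists; term hierarchies and pathway topology
are out of scope, and no database content is bundled — collections are
user-supplied GMT files. Sets with fewer than 3 universe genes are
skipped by default.

# The synthetic-data generator

Every stage is testable without external data through a generator that
plants known truth. A `simulation_spec()` fixes the seed, gene count,
replication (default 6 per group, matching the real design's 5–6), the
mix of planted modes, effect sizes, NB dispersion
($\mathrm{Var} = \mu + \alpha\mu^2$), library-size factors, and the
fractions of sex-linked and forced-low-expression genes.

Defaults and their reasoning:

* **30% non-conserved genes** (10% additive, 12% dominant, 8%
  overdominant, dominance-heavy as observed in this kind of cross),
  parental effect $\log_2\!FC = 2$, overdominant offset 1 — strong,
  detectable effects typical of divergent-line comparisons.
* **Dispersion $\alpha = 0.05$** — mid-range for bulk RNA-seq of
  homogeneous tissue from related individuals; per-group biological
  variability is not reported for the motivating study, so this is an
  explicit, configurable choice.
* **Baseline log2 mean counts uniform on [3, 10]**, spanning weakly to
  highly expressed genes at a desk-scale library size (2,000 genes,
  ~4×10^5 fragments per sample).
* **Library-size factors log-uniform on [0.7, 1.4]** to exercise
  normalization.
* Sex-linked (5%) and forced-low (10%) genes are drawn from the
  *conserved* pool, disjointly, so the expression filters never remove
  planted signal and recovery is well defined on the post-filter
  universe.
* CR and RC are planted with identical means and sampled independently;
  asymmetric planting is possible by construction but not the default.

The phenotype generator draws normal trait values around planted group
means; the default bundle plants negative heterosis for body weight
(−15% CR, −20% RC) and breast-muscle mass (−42% CR, −50% RC) with RC more
negative than CR, and 20 individuals per group — magnitudes and ordering
chosen to resemble published broiler × layer crosses.

What the generator does **not** emulate: batch effects beyond library
size, outlier samples, correlated genes, length biases, zero inflation,
or parent-of-origin asymmetries. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under the stated model,
not that real data meet that model.

# Problem sizes and calibration results

The test suite and the acceptance script run entirely on synthetic
studies at desk scale: 2,000 genes × 24 samples for the default bundle
and the null calibration, 1,000 genes for the strong-effect study, 10,000
replicates for the heterosis null, 1,000 random instances for the
algebraic-equivalence and BH-oracle checks. These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerances.

On the default bundle the package recovers planted dominant genes at
~99% and overdominant genes at ~88%, with ≤5% false nonadditive calls
among conserved genes; the Wald null type-I fraction is ~0.05 and the
planted parental $\log_2\!FC = 2$ is recovered with bias well under 0.15.

**A known limitation — additive recovery.** Additive genes sit at the
arithmetic mid-parent, so their weaker F1-vs-parent contrast is only
$|\log_2\!FC| = \log_2(2.5/4) \approx 0.68$ when the parents differ by
$\log_2\!FC = 2$. With $\alpha = 0.05$ and n = 6 the per-group Fisher
weight is bounded by $n/\alpha$, giving a minimum SE of ≈0.19 log2 units
for that contrast — a hard power ceiling of roughly 88% even for
infinitely expressed genes, and ~75% averaged over the default expression
range. Because the classification rules send an additive gene with one
non-significant F1 contrast to *dominance*, additive recovery on the
default bundle is ~72–77% (seed-dependent), not the ≥85% achieved by the
other modes. This is a property of the rules and the design's replication,
not of the implementation: plugging the true dispersion into the Wald
test changes recovery by only ~3 points, and in the near-noiseless limit
(dispersion → 0, well-expressed genes) all modes are recovered exactly.
Practically: with ~6 replicates per group, reported *additive* fractions
are conservative and the dominant fraction absorbs the shortfall.

# Reproducing the analysis

The numbered scripts under `analysis/` run the stages on the default
synthetic study and write their tables under `results/`;
`analysis/00_run_all.R` runs the same chain through `run_pipeline()`,
which also writes a manifest with file hashes so reruns can be verified
to be identical. `scripts/acceptance.R` recomputes the headline
quantities from scratch for any seed.

```{r, eval = FALSE}
spec <- simulation_spec(seed = 1L)
cfg <- pipeline_config("results/pipeline", simulation = spec)
run_pipeline(cfg)
writeLines(report_summary("results/pipeline"))
```
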