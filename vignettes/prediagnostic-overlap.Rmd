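---
title: "Comparing prediagnostic and clinical-stage blood transcriptome markers"
author: "prediagmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing prediagnostic and clinical-stage blood transcriptome markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prediagmeta)
```

## The scientific question

Genes differentially expressed in blood drawn years before a chronic
lymphocytic leukemia (CLL) diagnosis may mark disease susceptibility, early
biological effects along the causal pathway, or — when the disease is
already present subclinically — the disease itself. One way to distinguish
these readings is to ask whether the prediagnostic markers coincide with
the markers seen in patients at the clinical stage. `prediagmeta`
implements that comparison end to end: it harmonizes heterogeneous
clinical case–control expression studies, pools them gene by gene with a
random-effects meta-analysis, analyzes a prediagnostic cohort gene by gene
with linear mixed models, classifies every gene on the common universe
into a nine-category direction/significance taxonomy, tests whether the
overlap between the two arms could be chance, and characterizes the
resulting gene sets (principal components versus time to diagnosis,
gene-set enrichment, driver-gene lookup).

Because the underlying cohort data are not public, the package ships a
synthetic-data module that generates both arms with known gene-level
ground truth, so the entire pipeline can be exercised, calibrated and
validated without any external download.

## Harmonization

Clinical studies arrive as probe-level matrices from different platforms
with unknown preprocessing. Two steps make them comparable:

1. **Rank-based inverse normal transformation (INT).** Each gene's values
   are replaced by Blom normal scores,
   $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, with mid-ranks for ties.
   The transform is applied per gene across the samples of one study. The
   axis is a genuine design choice — per-array normalization is equally
   conceivable — and we default to per-gene because every downstream
   statistic compares case with control distributions gene-wise; the
   per-sample mode remains available (`int_axis = "sample"`). A constant
   vector has no information beyond ties and maps to all-zero scores with
   a warning.
2. **Probe-to-gene collapsing.** When several probes assay one gene, the
   per-sample gene value is the median across probes. Normalization comes
   first, collapsing second; the reverse order is *not* equivalent and is
   deliberately not offered as an equality.

Only genes measured in every contributing study enter the meta-analysis
(the *common universe*); the intersection is computed after collapsing and
is order-independent.

## The clinical arm: gene-wise random-effects meta-analysis

For one gene in one study with case values $x_1$ ($n_1$ samples) and
control values $x_2$ ($n_2$), the standardized mean difference with
Hedges' small-sample correction is

$$ d = J\,\frac{\bar x_1 - \bar x_2}{s_\text{pooled}}, \qquad
   J = 1 - \frac{3}{4(n_1+n_2-2) - 1}, \qquad
   v = \frac{n_1+n_2}{n_1 n_2} + \frac{d^2}{2(n_1+n_2)}. $$

Study effects are pooled by DerSimonian–Laird random effects: with fixed
weights $w_i = 1/v_i$, Cochran's
$Q = \sum_i w_i (d_i - \bar d_\text{FE})^2$ is referred to
$\chi^2_{S-1}$, the between-study variance is the moment estimator
$\hat\tau^2 = \max\!\big(0, (Q - (S-1)) / (\sum w_i - \sum w_i^2/\sum
w_i)\big)$, and the pooled effect uses weights $w_i^* = 1/(v_i +
\hat\tau^2)$ with a two-sided normal test on $\mu/\mathrm{se}(\mu)$.
Genes with a zero pooled SD in a study are excluded from that study only.
Bonferroni significance is $p < 0.05/G$ with $G$ the universe size. A
peripheral-blood sensitivity analysis is available through
`tissue_filter = "blood"`.

Estimator choices (Hedges $g$ rather than Cohen $d$; DL rather than REML
$\tau^2$; normal rather than Knapp–Hartung inference) follow the
classical defaults of expression meta-analysis frameworks of this kind;
they are assumptions, not derivations, and are centralized in
`standardized_effect()` and `dl_random_effects()`.

**A calibration caveat the tests make explicit.** Under a simulated
complete null (no effects, $\tau = 0$, six studies), the DL z-test is
systematically *conservative*: the fraction of genes with $p < 0.05$ is
about 3–4% rather than 5%, and a Kolmogorov–Smirnov test against
uniformity fails at 2000 genes. This is a well-known small-$S$ property
of the moment estimator — whenever $Q$ fluctuates above $S-1$,
$\hat\tau^2 > 0$ inflates the pooled standard error — and is reproduced
by direct simulation of the formulas outside the package. The Cochran-$Q$
p-values themselves are uniform under homogeneity, and the mixed-model
arm is well calibrated; the corresponding acceptance assertions for the
meta arm document the conservatism rather than hide it. Practically this
means the clinical arm errs on the side of fewer false positives.

## The prediagnostic arm: per-gene linear mixed models

For each gene of the (collapsed, INT-transformed) cohort matrix the model
is

$$ y = \beta_0 + \beta_\text{case}\,\text{case} + X\gamma
     + u_\text{isolation} + u_\text{hybridization} + u_\text{labeling}
     + \varepsilon, $$

with fixed covariates $X$ (age, sex, country, experimental phase, BMI in
the simulated cohort) and independent random intercepts for the three
batch-date factors, estimated by REML (lme4). The case coefficient is
tested with a two-sided Wald z-test; with ~480 samples the normal
reference is accurate. Cases are coded 1 so $\beta_\text{case} > 0$ means
upregulation in future cases. For speed one model template is estimated
and refit per gene (`lme4::refit()`), which is the standard per-gene
strategy and changes results only at optimizer-restart precision
(~1e-7).

Boundary handling follows a continuity contract: when a random-intercept
variance estimates at zero the gene is refit with that component removed,
down to ordinary least squares when all three vanish, so the reported fit
equals the reduced model exactly. Non-converged genes keep their row with
a missing p-value and still count in the Bonferroni denominator
$G_\text{pre}$ (the genes *attempted*) — a conservative, reproducible
universe. Note that REML may legitimately estimate a small positive batch
variance even when the generating variance is zero; exact OLS equality is
therefore guaranteed (and tested) for cohorts without batch structure,
not for every finite-sample fit.

## Overlap classification

Each arm contributes a symbol per gene: `+` (nominally significant,
effect up), `-` (nominally significant, effect down), `o` (otherwise);
the label writes the clinical symbol first: `++`, `--`, `+o`, `-o`,
`o+`, `o-`, `+-`, `-+`, `oo`. Two significance tiers are tracked
orthogonally for the concordant labels: *Bonferroni-concordant* (at
least one arm Bonferroni, the other at least nominal, same direction) and
*nominal-concordant* (both nominal, same direction); genes reaching
Bonferroni in neither arm also carry a `null_finding` roll-up flag. A
nominally significant effect of exactly zero has no direction and is
tie-broken to `o` with a warning.

Overlap significance uses a Fisher exact test on the 2×2 of per-arm
significance within the common universe, at both tiers. The default is
the one-sided enrichment (hypergeometric upper tail), matching the
directional hypothesis that the two arms share markers; the two-sided
variant is available (`sided = "two"`), and the published count table
happens to give the same p either way. Degenerate margins return $p = 1$
by convention. Concordance of the two arms' full result rankings is
summarized by the Spearman correlation of signed $-\log_{10} p$ scores
(sign = effect direction; $p = 0$ is capped at magnitude 320 with a
warning).

`summarize_category_counts()` recomputes, from a category-count table
alone, the clinical-marker replication percentage, the Bonferroni-tier
2×2 and its Fisher p, and the directional Venn layers; the packaged
reference table (`reference_category_counts()`) encodes the printed
counts of the published CLL comparison, whose per-arm totals do not fully
reconcile with the category cells (111 vs 116 on the clinical side), so
the explicit totals are stored alongside the cells and used for the
margins.

## Downstream characterization

- **PCA.** The cohort matrix restricted to a gene set (the similar
  `++`/`--` set, and the prediagnostic-exclusive `o+`/`o-` set) is
  gene-wise centered and unit-scaled; components come from the SVD over
  all samples (cases and controls together). Components explaining more
  than 5% of total variance are retained, examining at most the first
  ten. Sign is fixed deterministically (loading sums positive); when a
  signed statement about disease progression is needed, PC1 is oriented
  toward the case signal first.
- **Time to diagnosis.** Among cases, each retained component score is
  regressed on time to diagnosis (days) with the prediagnostic fixed
  covariates. Whether the published analysis adjusted for the full
  covariate set is ambiguous; we default to the full set and expose the
  choice.
- **Enrichment.** One-sided hypergeometric tests per gene set
  (GMT input), Bonferroni-corrected over the sets with a non-empty
  universe intersection; the universe is the full common gene universe
  with sets intersected, rather than the union of set members — simpler
  and stated. For enriched sets, the composition across the four signal
  roll-up categories inside versus outside the set is compared with a
  Fisher exact test (all-empty categories dropped; fewer than two
  non-empty categories skips the test with a flag).
- **Drivers.** A plain driver-gene list is annotated with presence in the
  universe, per-arm significance and category label; absent genes are
  reported absent and excluded from rate denominators.
- **Correlation structure.** As a descriptive check,
  `gene_correlation_structure()` orders the gene–gene correlation matrix
  of the similar + prediagnostic-exclusive union by average-linkage
  clustering; no formal cluster test is attached.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` fixes the study conditions. Defaults: nine clinical
studies (six peripheral blood, two bone marrow, one lymph node) of 30
cases and 30 controls each; a prediagnostic cohort of 39 future cases and
438 controls; case follow-up uniform on 1–17 years. Each gene belongs to
one planted class (`shared_up/down`, `prediag_only_up/down`,
`clinical_only_up/down`, `dissimilar`, `null`), by default 4% of genes
per concordant axis pair, 1% dissimilar and 87% null.

Effect magnitudes are standardized (units of the within-group SD):
`delta_clinical = 1.2` and `delta_prediag_max = 1.5` at the moment of
diagnosis. These are deliberately large: a cohort of 39 cases can only
have produced hundreds of genome-wide-significant prediagnostic markers,
as the published study reports, if per-gene standardized effects
approach or exceed 1. Between-study heterogeneity adds
`Normal(0, tau^2)` (default `tau = 0.2`) to the per-study true effect of
clinical-signal genes only, so heterogeneity concentrates where effects
exist. The prediagnostic case signal is scaled by a progression weight
$g(t)$: linear $1 - t/t_\max$ by default, or exponential
$\exp(-t/t_\text{med})$ — the true functional form of signal growth is
unknown, both are offered, and nothing downstream depends on the choice
beyond the planted monotonicity. Time is configured in years and stored
in days (×365.25).

Nuisance structure mirrors what the mixed model must absorb: per-gene
fixed-covariate coefficients (`covariate_effect_sd = 0.1`) on two
continuous and three categorical stand-ins (the published covariate set
enters no formula, so generic stand-ins suffice), and per-gene random
intercepts (`batch_sd = 0.3`) for three batch-date factors with 8/8/4
levels. Batch intercepts are drawn independently per gene, matching the
per-gene model's assumption. Platform heterogeneity is emulated by 1–3
probes per gene with additive per-probe offsets (`probe_offset_sd =
0.25`, removed exactly by the rank transform — which is why collapsing
must follow normalization) and by omitting 10% of genes per study, which
forces a non-trivial universe intersection (nine studies retain ~39% of
genes).

What the simulator does *not* emulate: raw platform file formats,
intensity-dependent or spatial array artifacts, correlated gene modules
(genes are independent given the planted class), non-Gaussian noise, and
confounding of case status with batch. Passing tests therefore show the
statistical machinery is correct and calibrated under the assumed model,
not that the pipeline is robust to every pathology of real microarray
data.

## Numerical choices and problem sizes

Tolerances: variance components below 1e-8 count as zero (continuity
contract); refit-based per-gene estimates are reproducible to ~1e-5;
hand-rolled exact tests agree with full enumeration to 1e-9. Degenerate
inputs (constant genes, degenerate margins, missing times) return flagged
or conventional values rather than errors wherever a pipeline run should
survive them, and errors with named offenders where it should not
(sample mismatches, empty universes).

The shipped validation runs use sizes chosen to make Monte-Carlo error
small relative to the assertions while keeping a full run on one CPU in
minutes: calibration at 2000 genes (six studies; cohort 39+438), effect
recovery at six studies of 50+50 with ≥200 planted genes, label recovery
at 800 genes under default conditions, progression recovery over 50
replicate cohorts of 400 genes, and 1000 replicate universes for the
overlap type-I check (universe 10 000, where the exact test's
discreteness — which can only make it conservative — no longer dominates
the rejection rate).

## Known limitations

- The DL z-test conservatism at small $S$ discussed above.
- Gene symbols are matched case-sensitively; no alias resolution.
- The meta-analysis pools two-group contrasts only; covariate-adjusted
  clinical models are out of scope.
- Matching in the prediagnostic design is handled through fixed
  covariates, not conditional likelihoods.
- Figures are deliberately minimal; the package's outputs are tables and
  a machine-readable report.
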