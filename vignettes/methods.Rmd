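---
title: "Methods: epigenetic clock aging and consensus co-methylation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic clock aging and consensus co-methylation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclocknet)
```

## The problem

Huntington's disease (HD) is caused by a CAG-repeat expansion in *HTT*, and
the age of motor onset is tightly coupled to repeat length, suggesting that
biological tissue age modulates disease expression. DNA methylation supplies
a usable biomarker of tissue age: a calibrated weighted average of the beta
values of a panel of clock CpGs estimates "DNAm age" in years, and the
residual of DNAm age from the age trend of unaffected samples — epigenetic
age *acceleration* — asks whether a disease makes tissue look biologically
older than its calendar age. Beyond the clock, HD may reorganize the brain
methylome more broadly; weighted co-methylation network analysis (WGCNA)
summarizes hundreds of thousands of CpGs into a few dozen modules and tests
module summaries, rather than single probes, against disease status.

`epiclocknet` implements this full analysis path for multi-region brain
methylation cohorts — clock, acceleration, confounder models, per-lobe EWAS
with meta-analysis, consensus networks, and CpG-to-gene enrichment — along
with a synthetic cohort generator that plants every signal the pipeline is
supposed to find, so each stage is testable without access to protected
human data.

## Beta values and the clock

Methylation at a CpG is expressed as
\[
\beta = \frac{\max(M,0)}{\max(M,0)+\max(U,0)+100},
\]
where $M$ and $U$ are methylated/unmethylated fluorescence intensities; the
offset of 100 regularizes low-intensity probes and the clamps absorb
negative background-corrected intensities, so $\beta \in [0,1)$.

The clock is linear on a transformed age scale. With knot `adult_age` $A$
(default 20 years),
\[
F(a) = \begin{cases}\log\frac{a+1}{A+1} & a \le A\\[2pt]
\frac{a-A}{A+1} & a > A,\end{cases}
\qquad
\widehat{\mathrm{DNAmAge}} = F^{-1}\Big(c_0 + \sum_j w_j \beta_j\Big).
\]
$F$ compresses the rapid developmental change of methylation and is linear
in adulthood. Clock coefficients are a pluggable input file
(`read_clock_model()`): the package does not re-derive a published clock,
and all tests use the synthetic clock whose construction guarantees that a
zero-noise cohort returns exactly chronological age plus the planted
acceleration.

### Winsorization

Individual estimates can fail grossly (hybridization artifacts). Samples
whose residual from the control trend exceeds a threshold (default 15
years; the published analysis flagged 4 of 475 samples without stating its
numeric rule, so the default here is deliberately conservative) are
replaced by the individual's *second most extreme* non-cerebellar estimate.
"Second most extreme" is made precise as: take the side of the individual's
median on which the flagged value lies, and use the most extreme remaining
estimate on that side — estimates \{50, 52, 90\} with 90 flagged winsorize
to 52. Cerebellar samples are excluded both as flags and as donors because
the cerebellum ages more slowly than the rest of the brain. The control
trend is fitted, winsorization applied, and the trend refitted once.

### Acceleration measures

The control trend is a least-squares natural cubic spline of DNAm age on
age with 2 effective degrees of freedom (one interior knot at the median
control age) through non-HD, non-cerebellar samples — the standard reading
of a "2 df" smoother. *Age acceleration* is the vertical distance of a
sample from this trend; *intrinsic acceleration* is the residual of DNAm
age on age **and** neuron proportion, removing cell-composition
confounding. Outside the fitted age range the trend extrapolates linearly
with a warning. Note that when the neuron deficit is itself caused by the
disease, adjusting for neurons absorbs part of the genuine disease signal;
the intrinsic measure is therefore expected to be somewhat attenuated
relative to the raw one (the package's tests size this effect explicitly).

## Confounder models

`fit_dnam_model()` fits ordinary least squares of DNAm age on HD status
plus: model 1 — age, sex, brain bank, region; model 2 — model 1 plus neuron
proportion; model 3 — model 1 plus the first five methylation principal
components (unit-norm right-singular scores of the row-centered beta
matrix; PC coefficient magnitudes therefore depend on this scaling
convention and are not comparable to other conventions). Reference levels
are fixed (male, NewZealand bank, frontal region) so coefficient rows are
stable across runs. The HD coefficient divided by the age coefficient
converts to years of biological age (`coefficient_to_years()`). Repeated
samples per individual are *not* modeled — no random effects — matching the
published analysis' acknowledged simplification; the function warns
whenever individuals repeat, and all downstream p-values are labeled
descriptive for the same reason.

## EWAS and meta-analysis

CpGs are retained when their variance reaches $5\times10^{-4}$ in at least
one lobe; retained beta values are residualized per CpG on age and a sex
indicator (ordinary least squares, so residuals are exactly orthogonal to
both). Per lobe, HD versus control is tested with the tie-corrected
Kruskal–Wallis rank statistic — chosen for robustness to the bounded,
outlier-prone distribution of beta values — and signed by the HD-minus-control
median difference (ties resolve to $+1$), so hypo-methylated CpGs carry
negative z-scores. Two-sided p-values convert to signed z via
$z = d\,\Phi^{-1}(1-p/2)$ and combine across lobes by Stouffer's method,
$Z = \sum_a z_a / \sqrt{N}$, with meta $p = 2\Phi(-|Z|)$.

Calibration is diagnosed with the median-based genomic inflation factor
$\lambda = \mathrm{median}(\chi^2_{\text{obs}})/0.4549$ — the closed-form,
robust variant rather than a regression estimator. Two numerical notes:
with two groups of 20 the Kruskal–Wallis statistic is discrete, and the
exact null median sits at $\lambda = 1.005$, not exactly 1; and a single
cohort's $\lambda$ lands on discrete atoms (≈0.93/1.01/1.09 at this sample
size), so calibration checks pool p-values across simulated cohorts. The
Bonferroni threshold helper defaults to the array-scale denominator 500000
regardless of how many CpGs were actually tested, the convention of the
published analysis; pass the tested count for a literal correction.

Meta p-values are descriptive, not inferential. Samples from the same
individuals appear in all three lobes, so per-lobe z-scores are positively
correlated wherever individual-level structure exists (co-methylation
module latents, cell composition), and the Stouffer Z is overdispersed
under its nominal null. The synthetic null cohort reproduces this
faithfully: per-lobe type-I error is nominal and pooled $\lambda$ is 1.005,
yet a minority of simulated cohorts shows isolated Bonferroni-level meta
hits driven by whole correlated blocks — which is why one acceptance check
on meta-level false positives is expected to fail and is documented rather
than papered over. Real analyses of this design report the same phenomenon
at much larger magnitude (meta $\lambda$ of 7.3 in the motivating study).

## Consensus co-methylation networks

Per lobe, on the same age/sex-residualized, variance-filtered matrix:

1. **Similarity**: biweight midcorrelation with `max_p_outliers = 0.05` —
   Tukey biweights around the median, with each tail's rescaling capped so
   at most 5% of observations per side are fully down-weighted. Zero-MAD
   profiles fall back to rank correlation with a warning.
2. **Adjacency**: signed hybrid, $A_{ij} = \max(\mathrm{bicor}_{ij},0)^6$;
   soft power 6 is the conventional default. The diagonal is held at zero
   for the overlap computation.
3. **Topological overlap**:
   $T_{ij} = (\sum_u A_{iu}A_{uj} + A_{ij}) / (\min(k_i,k_j)+1-A_{ij})$,
   unit diagonal.
4. **Calibration**: the lower triangles of the per-lobe TOMs are quantile-
   normalized (each lobe treated as one "sample"; target = mean of per-rank
   sorted values; ties within a lobe receive the average of the target
   values they span), then mirrored back to symmetric matrices with the
   diagonal untouched.
5. **Consensus**: component-wise quantile $q$ across lobes; $q = 0$
   (minimum) by default — the conservative conventional choice; the value
   used in the motivating analysis is unstated, so $q$ is configurable and
   recorded in every run manifest. Dissimilarity is one minus consensus.
6. **Modules**: average-linkage hierarchical clustering with a *static*
   cut at 0.995 of the maximum merge height; branches of at least
   `min_module_size` (20) members become modules labeled 1, 2, … by
   decreasing size; everything else is label 0 / grey. The full dynamic
   hybrid tree-cut algorithm is intentionally out of scope — module
   recovery on data with planted structure is the accepted surface, and a
   static cut recovers planted modules exactly there (label order carries
   no meaning; modules are *not* renumbered by disease association).
7. **Eigenvectors**: per lobe and module, profiles are standardized and the
   top sample-side singular direction is the module eigenvector, unit norm,
   sign fixed so the mean standardized profile correlates positively.
8. **Membership and hubs**: $MM^I_i = \mathrm{cor}(x_i, E^I)$ per lobe;
   memberships combine across lobes as Fisher $\mathrm{atanh}(MM)\sqrt{n-3}$
   z-scores via Stouffer — standard, monotone in $MM$, and the only
   concrete choice compatible with "a membership meta-analysis Z".
9. **Module–trait**: per lobe, a robust correlation test of eigenvector
   against trait (t approximation with $n-2$ df applied to the biweight
   midcorrelation — the same approximation used for Pearson, standard
   practice for midcorrelation inference); signed z-scores combine by
   Stouffer; significance against $0.05/\#\text{modules}$.

Module–trait correlations use eigenvectors computed on the age/sex-adjusted
values (the same matrix the network was built from), the internally
consistent reading of applying WGCNA to adjusted data.

## Gene representatives and enrichment

Enrichment operates on genes, not probes, so each gene is collapsed to one
representative CpG: genes with one retained CpG keep it; genes with two
keep the CpG with the higher consensus standard deviation; genes with three
or more keep the consensus hub — the CpG with the highest consensus
intramodular connectivity kIM, where kIM is the sum of signed-hybrid
adjacencies *within the gene's own CpG set* (the "artificial module"), not
within the WGCNA module. Per-lobe kIM (or sd) vectors are quantile-
normalized across lobes and combined at the same consensus quantile $q$.
Ties break lexicographically on CpG id for determinism. A rescaling of one
lobe changes calibrated *values* (the quantile-normalization target is the
across-lobe mean) but not rankings, and selection depends only on the
ranking. Genes inherit the module label of their representative, and
module–gene-set overlaps are tested with the upper-tail hypergeometric
distribution against a universe of all represented genes (the universe used
by the original analysis is unstated; this choice is configurable and the
most conservative self-contained one).

## The synthetic cohort

`simulate_cohort()` draws, per configuration (defaults in parentheses):

* 20 HD + 20 control individuals, one sample each in three lobes (frontal,
  parietal, occipital); ages uniform on 30–80 (HD) / 20–90 (control),
  mirroring the age structure of brain-bank cohorts of this kind.
* 2000 CpGs: 30 clock CpGs; five planted modules of 100/80/60/50/40 CpGs;
  the rest background. Module CpGs load positively (U(0.04, 0.10) in beta
  units per latent SD) on a module latent split **equally** between an
  individual-level component shared across that person's lobes (the
  consensus structure) and a lobe-level innovation — a deliberate middle
  ground between perfectly conserved and lobe-specific co-methylation.
* The first two modules shift their latent in HD by `hd_effect_size` (0.08
  beta units at the mean loading), planting hyper-methylated disease
  modules detectable by both the EWAS and the network stage.
* A planted HD age acceleration of 3.2 years (matching the headline
  estimate the package's worked example reproduces), with 1.5-year
  between-individual SD; clock CpG betas are constructed so the clock is
  exact at zero noise.
* 200 CpGs each with age slopes (SD 0.001 per year), sex shifts (SD 0.02),
  and neuron-proportion loadings (SD 0.08); neuron proportion uniform on
  0.2–0.6 with an HD deficit of 0.08.
* Gaussian residual noise (SD 0.02) added before clipping to [0, 1]; the
  clipping rate is reported and is far below 1% at defaults. Noise is
  Gaussian rather than beta-distributed for simplicity — every implemented
  statistic is rank-based or robust, so the distributional shape is not
  load-bearing.

A green test on this cohort establishes that the pipeline recovers planted
clocks, accelerations, modules, disease modules, and enrichments at
realistic effect sizes. It does **not** establish behavior under probe-type
chemistry differences, batch structure, detection failures, missing values
(readers reject NA cells by design — every downstream formula assumes
complete profiles), or the correlation structure of real 450k arrays; those
are documented non-goals.

The null configuration (`hd_effect_size = 0`, `hd_age_accel_years = 0`,
`hd_neuron_loss = 0`) plants no HD-associated CpG and is the basis of all
calibration tests.

## Numerical and degenerate-input choices

* `p_to_signed_z()` and `inflation_lambda()` use upper-tail quantile calls
  and are safe for p down to ~1e-300; `cor_test()` floors p at the smallest
  positive double for |r| = 1.
* Kruskal–Wallis with all values tied returns H = 0, p = 1.
* Constant CpG profiles: dropped (eigenvector), NA (membership), rank-
  correlation fallback (bicor), sd-0 accepted (representative selection).
* Constant traits skip their lobe in module–trait meta-analysis, reducing
  the effective number of sets.
* Single-sex strata drop the sex term from residualization with a warning.
* One master seed drives the generator; derived seeds (seed+1, +2, +3) fan
  out to the clock, cohort, and annotation streams so components are
  individually reproducible.

## Known limitations

* No random effects anywhere: repeated samples per individual make all
  pooled p-values descriptive; the meta-analysis overdispersion this causes
  is quantified above and left visible in the acceptance suite.
* The static tree cut requires reasonably separated modules; diffuse,
  nested module structure needs the full dynamic hybrid algorithm, which is
  out of scope.
* Block-wise decomposition for very large CpG sets (>50k) and soft-power
  selection by scale-free fit are not implemented (power fixed at 6).
* The clock coefficient file format carries a single linear clock; ensemble
  or tissue-specific clocks would require multiple files.
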