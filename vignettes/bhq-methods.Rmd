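---
title: "Quotient scoring of brain maps and the intervention-study battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quotient scoring of brain maps and the intervention-study battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhqpipe)
```

## The quantity being computed

`bhqpipe` computes Brain Healthcare Quotients (BHQ): IQ-style standardized
scores derived voxelwise from spatially normalized scalar brain maps. For a
map value $x_v$ at voxel $v$ and a normative cohort with voxelwise mean
$\mu_v$ and standard deviation $\sigma_v$,

$$ q_v = 100 + 15\,\frac{x_v - \mu_v}{\sigma_v}. $$

Two modalities are scored. **FA-BHQ** standardizes fractional anisotropy
(FA) maps from diffusion tensor imaging, a white-matter integrity proxy
bounded to $[0,1]$. **GM-BHQ** standardizes head-size-corrected gray-matter
volume: the GM map is smoothed with an 8 mm FWHM Gaussian kernel, divided by
the participant's intracranial volume (ICV, the voxel-sum of the GM, WM and
CSF maps), and the resulting proportional maps define the reference.

Quotient images are then averaged (unweighted) over the voxels of each
atlas region, and the regional quotients are averaged (unweighted) into the
participant's whole-brain score. The per-participant identity
`whole_brain = mean(per_region)` is asserted in the test suite for every
scored participant.

## Scoring choices the literature leaves open

* **SD convention.** The reference field uses the population SD (divide by
  $N$) by default, which makes the defining cohort's voxelwise quotient
  mean exactly 100 and SD exactly 15 — the property that gives the scale
  its meaning ("about 95% of a Gaussian population falls between 70 and
  130"). The sample convention ($N-1$) is a switch
  (`sd_convention = "sample"`) for users who treat the cohort as a sample
  from a wider norm population.
* **Reference pool.** The normative mean/SD images are built from *all*
  scans of all participants at both timepoints by default
  (`reference_pool = "all"`). A pre-only mode is available; it changes the
  scale slightly (post-intervention variance is excluded from the norm) but
  none of the inferential conclusions, since every test downstream is
  invariant to a common affine rescaling of the scores.
* **Mask rule.** Voxels with SD at or below `sd_floor` ($10^{-6}$ by
  default) or mean at or below zero are excluded from the mask instead of
  producing infinities; for nonnegative tissue/FA maps the mean rule drops
  empty background. Regions whose voxels are all masked out are reported
  missing and excluded from the whole-brain mean.
* **Smoothing.** Separable discrete Gaussian with
  $\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$ per axis, converted from mm to
  voxels. Boundaries are handled by whole-sample reflection; with a
  symmetric kernel that operator is symmetric, so constants are invariant
  and total intensity is conserved exactly. FA maps are smoothed at 8 mm
  before referencing by default (configurable to 0 to disable), matching
  the GM stream.

## The synthetic cohort generator

No raw scans are distributed with intervention studies of this kind, so the
package ships a generator whose defaults encode the emulated study
conditions: two randomized groups of 35 healthy middle-aged adults, scanned
pre and post, with a depression-screen exclusion stream (threshold score
16, roughly 20% of recruits), a baseline FA quotient offset of about 2
points (control above intervention), a pre-to-post latent FA improvement of
0.5 points in the intervention group against a -0.4 drift in controls, and
brain-behavior change couplings of .35 magnitude (positive for the
vigor-activity mood subscale, negative for trail-making Part B time).

### Subject-level latent model

The generator is deliberately two-layered. The *latent layer* works in BHQ
points: each participant $i$ has a baseline deviation
$s_i \sim N(0, \texttt{subject\_sd}^2)$ shared across regions, plus
region-by-subject jitter; the pre-to-post change is

$$ \Delta_i = \mu_{g(i)} + a\,u_i + e_i, \qquad
   u_i \sim N(0,1),\; e_i \sim N(0, \sigma_e^2), $$

with $a = \texttt{latent\_loading}\cdot\texttt{change\_sd}$ and
$a^2 + \sigma_e^2 = \texttt{change\_sd}^2$. The same latent factor $u_i$
drives behavioral change in the intervention group,
$\Delta y_i = b\,u_i + f_i$, with $b$ solved from

$$ r = \frac{ab}{\sqrt{(a^2+\sigma_e^2)(b^2+\sigma_f^2)}} $$

so that the population change-score correlation equals the configured
`latent_coupling_r` exactly (this requires $|r| <$ `latent_loading`; the
configuration validator enforces it). Controls receive variance-matched
uncoupled noise, so the groups differ in correlation structure but not in
change variance — which is what makes the between-group Fisher r-to-z
comparison meaningful. All derived constants ($a$, $b$, $\sigma_e$,
$\sigma_f$ per measure) are recorded in the cohort manifest.

Behavioral baselines emulate the instrument properties: mood-state
subscales are rounded, clipped Gaussians on the 0-20 subscale range (the
abbreviated instrument's exact item scoring is not published; we assume
7 items scored 0-4 per subscale and treat the range as a modeling choice,
not a claim about the instrument), and trail-making times are positive
seconds with Part B slower than Part A on average, plus a small practice
effect on Part A in both groups.

### Voxel rendering

The *rendering layer* turns latent regional quotients into voxel lattices:
region base values (FA around 0.35-0.65), plus the latent deviation scaled
by `render_scale` (raw map units per BHQ point), plus iid voxel noise, on
an ellipsoidal brain mask split into connected nearest-seed regions. FA
values are clipped to $[0,1]$ and tissue maps to nonnegative values; tissue
maps are additionally multiplied by a per-participant head-size factor that
the ICV division must remove (a test doubles one participant's tissue maps
and asserts their GM-BHQ is unchanged).

Because voxel noise enters the reference SD, the measured quotient scale is
a deflated affine image of the latent scale, with slope

$$ \kappa = \frac{15c}{\sqrt{c^2 V + g^2 \sigma_v^2}} $$

where $c$ is `render_scale`, $V$ the latent pool variance implied by the
configuration, $\sigma_v$ the voxel noise SD, and $g$ the noise-SD
reduction factor of the smoothing kernel. $\kappa$ is recorded in the
manifest. The formula is exact for interior voxels without smoothing and an
interior approximation under smoothing (kernel support mixes latent values
across region boundaries); the test suite checks the unsmoothed slope
tightly and the smoothed slope loosely, alongside a latent-vs-measured
correlation above .99. Every statistic in the battery (t, F, r, z) is
invariant to this affine map, which the affine-invariance property test
makes explicit.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: balanced
randomization, screening exclusions, baseline offsets, group-specific
change distributions, latent-factor coupling, bounded instrument scores.
It does **not** simulate raw diffusion signal, scanner artifacts,
registration misalignment, T1 contrast, spatial autocorrelation of real
anatomy, or realistic regional geometry. Passing tests therefore validate
the *pipeline* — scoring arithmetic, calibration of the tests, coupling
recovery — not the biological claims of any particular study.

### Monte-Carlo problem sizes

The calibration properties are asserted at the sizes where their
statistical guarantees are crisp while the latent path keeps each replicate
cheap: the interaction test's type-I error over 1000 null cohorts at
n = 35/group (rejection rate must fall in the 95% binomial band around
.05), and recovery of the generating coupling r = .35 over 500 cohorts
(mean realized change correlation within ±.03). These run on the
subject-level latent path (`render_maps = FALSE`); a separate rendered-path
test establishes that the voxel layer is a faithful affine image of that
latent layer, which is what justifies the fast path.

## The statistical battery

All tests are implemented from their formulas and cross-checked in the
suite against independent fitters (`t.test`, `aov` with a subject error
stratum, `cor.test`, `p.adjust`, `chisq.test`, `power.t.test`) — the
external fitters serve as oracles, never as the implementation.

* **Baseline comparisons**: pooled-variance Student t (Welch optional),
  df $= n_1+n_2-2$, sign convention group 2 minus group 1; sex by Pearson
  chi-square without continuity correction.
* **Intervention effect**: the Time-by-Group interaction of the 2x2 mixed
  ANOVA, computed from the within-subject decomposition — with per-subject
  change $d_i$, $SS_{\text{int}} = \sum_g n_g(\bar d_g - \bar d)^2/2$
  against the within-group change variance, $F$ on $(1, N-2)$ df. This
  equals the squared pooled t on change scores; the suite asserts the
  identity to $10^{-8}$ relative error. Effect size: partial
  $\eta^2 = F\,df_1/(F\,df_1 + df_2)$.
* **Within-group change**: paired t on $d_i = \text{pre}_i - \text{post}_i$
  (improvement prints as negative t, as in the tables; magnitudes as in
  text), with Cohen's $d = t/\sqrt{n}$ exactly.
* **Brain-behavior coupling**: Pearson correlation between change scores
  with the $t = r\sqrt{n-2}/\sqrt{1-r^2}$ test; group differences in
  correlations by Fisher's r-to-z,
  $z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)/
  \sqrt{1/(n_1-3)+1/(n_2-3)}$.
* **Multiplicity**: Benjamini-Hochberg step-up over the eight regional
  interaction p-values (the family is configurable).
* **Design**: a-priori sample size for the paired t-test by noncentral-t
  power (smallest $n$ with power $\ge$ target at noncentrality
  $d\sqrt{n}$).

### Flagged reporting discrepancies

Two conventions in published reports of this design do not survive
recomputation, and the package reports both sides rather than silently
picking one:

* **Fisher-z sidedness.** Methods sections typically declare two-sided
  tests, but printed p-values for r-to-z comparisons often match one-sided
  normal tails (e.g. $z = 2.680 \rightarrow p = .004$ one-sided, .007
  two-sided). `fisher_z_compare()` returns both, and the report metadata
  carries a note.
* **BH survival claims.** Regional interaction p-values with minimum
  around .012 over a family of eight cannot all clear .05 after the
  standard step-up ($\min \tilde p \ge 8 \times .012/6 > .05$ whenever
  several members are weaker). The report prints standard BH-adjusted
  values and flags that published "significant after correction" claims at
  such magnitudes are not reproducible with the standard procedure.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(sim = sim_config(seed = 3))
out <- run_end_to_end(cfg, "bhq_run")
res <- attr(out, "results")
res$report$interaction[1:2, c("measure", "F", "p", "partial_eta_sq")]
res$verification          # every printed statistic recomputed from its inputs
```

## Numerical notes and limitations

* Degenerate inputs fail loudly: identical cohorts (zero reference SD
  everywhere), all-zero tissue maps (ICV 0), constant change vectors
  (infinite paired t), $|r| = 1$, zero chi-square margins.
* `benjamini_hochberg()` is stable under input permutation; ties in p
  share an adjusted value.
* The ANOVA implementation handles unbalanced groups (the $F = t^2$
  identity holds for unequal $n$); incomplete pre/post pairs are dropped
  with a warning and logged counts.
* The generator's group balancing retains exactly n_per_group per group
  after screening, topping up when exclusions fall unevenly; recruits are
  assigned to groups before screening, as in the emulated design.
* No covariate adjustment (age, sex, education), no mixed-effects or
  Bayesian variants, no voxelwise inference: these are outside the
  package's scope.
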