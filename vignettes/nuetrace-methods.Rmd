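---
title: "Methods: nitrogen mass balance, seed C:N stoichiometry, and heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrogen mass balance, seed C:N stoichiometry, and heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuetrace)
```

This vignette is the package's account of its statistical methods: the
models, the assumptions behind them, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
decisions that shape edge-case behaviour.

## The mass-balance model

Each plant is a closed three-compartment system at harvest: rosette, stem
(including cauline leaves and empty siliques), and total seeds. Roots are
not part of the budget — they cannot be recovered reliably from dry soil —
so all "total" quantities are aboveground totals, and no uptake-efficiency
index is defined.

For an organ with dry weight $DW$ (mg), nitrogen concentration $N\%$
(mg per 100 mg DW) and $^{15}$N atom percent $A\%$:

$$E\% = A\%_{sample} - A\%_{control}, \qquad
  QtyN = DW \cdot N\%/100, \qquad
  Qty^{15}N = DW \cdot \frac{E\%}{100}\cdot\frac{N\%}{100}.$$

We treat percentages as true fractions so pools are masses in mg; all
allocation fractions, HI, NHI, $^{15}$NHI, NUE and NRE are invariant to
this convention, and NUtE (total DW over total N, mg/mg) becomes a
physically interpretable number of order 20–40 for typical tissue. The
natural-abundance baseline defaults to $A\%_{control} = 0.3660$ and should
be re-measured from unlabelled plants when available.

Assumptions worth stating: the label dose is applied before flowering, so
seed $^{15}$N is remobilized N by construction; enrichment can be slightly
negative on unlabelled tissue through measurement noise, which we keep
(clamping is available via `clamp_enrichment`) but tracer pools are floored
at zero before forming allocation fractions so the fractions stay in
$[0,1]$.

Indices are computed **per plant, then averaged**. Means of ratios and
ratios of means differ by Jensen's inequality; with HI in a denominator the
gap is material (a cell mean of NUE is systematically above
mean(NHI)/mean(HI)). All summaries in `condition_summary()` are means ± SE
of per-plant values, which also determines how degenerate plants are
handled: below the seed-DW guard (default 1 mg — an amount at the weighing
precision limit, far below any real seed lot) NUE and NRE are `NaN`, the
plant is excluded from ratio-index summaries, and counted in
`n_degenerate`. HI, allocations, NHI and NUtE remain defined for such
plants.

## Orthogonal regression and DSC

Seed protein and oil trade off against each other, so seed N% and C% are
strongly negatively correlated and neither is a natural "response"
variable. The stoichiometry line is therefore the **major axis**: the line
through the centroid along the leading eigenvector of the $2\times2$
covariance of (N%, C%), which minimizes the sum of squared perpendicular
distances. The closed form used is

$$b = \frac{S_{cc} - S_{nn} + \sqrt{(S_{cc}-S_{nn})^2 + 4S_{nc}^2}}{2S_{nc}},$$

with the intercept fixed by the centroid. A reduced-major-axis variant
(`method = "rma"`, slope $\mathrm{sign}(S_{nc})\sqrt{S_{cc}/S_{nn}}$) is
exposed because both estimators are in routine use for errors-in-variables
allometry; the major axis is the default because the two variables share
units (percent of DW), so no standardization is applied before fitting.
Tie-breaks are explicit: $S_{nc}=0$ with $S_{nn}=S_{cc}$ (isotropic
scatter) raises a degenerate-fit error rather than picking an arbitrary
axis; a horizontal major axis returns slope 0 and a vertical one slope
`Inf` with a flag.

**DSC** (delta seed composition) is the signed orthogonal distance of a
point from the line. With the vertical gap
$\mathrm{DiffC} = C_0 - (a + bN_0)$ and horizontal gap
$\mathrm{DiffN} = N_0 - (C_0-a)/b$, the magnitude is the altitude of the
right triangle they span:

$$\mathrm{DSC} = \mathrm{sign}(\mathrm{DiffC})\cdot
  \frac{|\mathrm{DiffN}\cdot\mathrm{DiffC}|}
       {\sqrt{\mathrm{DiffN}^2 + \mathrm{DiffC}^2}},$$

which equals the Euclidean point-to-line distance
$|C_0 - a - bN_0|/\sqrt{1+b^2}$ (property-tested to $10^{-9}$). For a
negatively sloped line the two gaps always share a sign; if they ever
disagree (possible only for positive slopes) the sign is taken from DiffC
and the row is flagged. Points above the line — more C at a given N than
the population line predicts — get positive DSC.

Fits are made per experiment × condition, pooling all genotypes, and each
seed lot is scored against the line of its own cell; scoring against a
pooled control line is possible by passing any fit to `dsc()` directly.
Pooling *experiments* into one fit is deliberately not the default:
between-experiment intercept wobble adds variance orthogonal to the line
and can rotate a pooled major axis badly, which is why per-experiment fits
averaged afterwards (as `condition_shifts()` does) are the supported path.

`response_vectors()` summarises each genotype's displacement of mean seed
composition from its control baseline. A condition is labelled
heterogeneous when the circular SD of the vector angles exceeds 60°
(configurable): beyond that, "the stress moves all genotypes the same way"
is no longer a reasonable description, while the threshold is generous
enough that modest angular scatter around a common direction still counts
as homogeneous.

## Variance components and heritability

`anova_components()` partitions the sum of squares of a trait over
genotype, condition, experiment, their interactions, and residual
(`stats::aov`; on the balanced designs the generator produces, all SS types
coincide) and reports each term's share of the total. Variance components
for the genotype-related terms are solved by method of moments from the
balanced random-effects expected mean squares — closed-form, exactly
testable, and unbiased before truncation; negative solutions are truncated
to zero, which keeps $h^2 \in [0,1]$ at the cost of a small upward bias in
near-zero components. REML adds nothing here because the heritability
formula is itself an EMS plug-in. Unbalanced data are accepted with the
mean cell count as $r$ and flagged approximate.

Broad-sense heritability is

$$h^2 = \frac{\sigma^2_{Gen}}
 {\sigma^2_{Gen} + \sigma^2_{G\times C}/n + \sigma^2_{G\times E}/k
  + \sigma^2_{C\times E}/nk + \sigma^2_{G\times C\times E}/nk
  + \sigma^2_{E}/nk}$$

with $n$ the number of experiments and $k$ the number of conditions. Note
the divisor pairing: $\sigma^2_{G\times C}$ (a condition interaction) is
divided by the number of *experiments*. The more common convention divides
each interaction by the number of levels of the factor crossed with
genotype; both are implemented (`divisor_convention = "swapped"` — the
default, matching the formula above — or `"conventional"`), and for the
default design ($n = 4$, $k = 6$) the difference is small.

Two numerical properties of the plug-in deserve a warning. First, $h^2$ is
a ratio of noisy components: with only 8 genotypes the genetic component
has a large sampling SD, and because $h^2$ is concave in it, the *mean of
per-dataset* $h^2$ estimates sits below the $h^2$ of the true components
(Jensen bias ≈ −0.06 at $\sigma^2 = (2,1,1,1,1,4)$, 8×6×4×4). Recovery
should therefore be judged on the components, or on $h^2$ of averaged
components, not on averaged per-dataset $h^2$. Second, a trait that is
constant returns all-zero components and an undefined (`NA`) $h^2$.

Contrasts of each stress against control (`contrast_vs_control()`) use a
linear model with genotype and experiment as additive blocking factors and
estimated marginal means, two-sided, **unadjusted** for multiplicity (the
output carries an `adjust = "none"` attribute); with five stress conditions
a Bonferroni factor of 5 is the user's to apply if desired.

## What the generator emulates — and what it does not

`synthetic_config()` defaults define the study conditions: 8 genotypes
("7", "63", "83", "134", "359", "397", "401", "442"), six post-flowering
conditions, 4 experiments, 4 plants per cell. Control cell means are organ
DW 230/1590/840 mg, N allocation 7/53/40%, ¹⁵N allocation 9/40/51%, a seed
stoichiometry line $C\% = 70.7 - 4.0\,N\%$, and genotype DSC offsets
spanning ±0.5 with three genotypes above the line, three near it, and two
below. Stress profiles scale organ DW and shift allocations the way the
respective stresses act physiologically — low N shrinks everything and
pushes N to seeds; drought spares the rosette; heat is near-sterile (seed
DW multiplier 0.024, ~20 mg seeds, deliberately *above* the 1 mg degenerate
guard) with 95% of N trapped in the stem.

Mechanics and the reasons for them:

- **Dry weights** are log-normal around cell means (biomass is positive and
  right-skewed) with genotype, G×C, G×E, C×E, G×C×E and residual layers on
  the log scale (SDs 0.15/0.05/0.05/0.05/0.05/0.15).
- **Allocation fractions** are the condition targets perturbed
  multiplicatively (log-normal, SD 0.05) and renormalized — additive noise
  would make the near-zero heat shares negative or explosive.
- **Seed composition** places each plant on its cell's line at an N%
  position (genotype baseline 3.80–4.25, condition shifts −0.6…+0.8,
  G×C/G×E/C×E/G×C×E/residual layers with SDs 0.30/0.20/0.10/0.10/0.25,
  residual ≈ 6% CV — a typical elemental-analysis replicate spread) and
  then displaces it orthogonally by the genotype DSC offset plus noise
  (SD 0.15). Genotype N% baselines are deliberately ~uncorrelated with the
  DSC offsets: position along the line and offset from it are independent
  genotype axes, and correlating them tilts every fitted line.
- **The ¹⁵N label** (15 µg excess per plant, the order of magnitude a
  single mL of 10 mM nitrate at 10% enrichment delivers) is split across
  organs by condition-specific remobilization fractions and atom percents
  are *back-computed*, so `plant_indices()` recovers the latent fractions
  exactly (to machine precision), making the isotope tests sharp rather
  than statistical. With `noise_scale = 0` every index equals its
  configured target exactly.

What it does not emulate: correlation between sink size (HI) and tracer
delivery — allocation and DW are drawn independently, so the simulated
mean NRE (~1.7 in control) sits above what positively correlated real data
would give; any mechanistic C/N flux, silique photosynthesis, or
time-resolved remobilization; measurement error structure of a real
elemental analyzer beyond iid noise. Passing recovery tests therefore shows
the estimators are correct for the stated statistical structure, not that
real data satisfy that structure.

One quantitative limitation is worth numbers. With 8 genotypes carrying
persistent orthogonal offsets, each per-cell TLS fit (32 plants) is tilted
by the sampling correlation between the cell's genotype-level N% effects
and the fixed offsets; this floor does not average away with replicates,
and the per-condition mean slope over 4 experiments recovers the configured
slope only to a median absolute error ≈ 0.5 (heavy-tailed: isolated cells
can rotate much further). That matches the between-experiment slope SD
(±0.7) such designs show in practice, and it is why slope-recovery tests
assert the median, not the maximum.

## Sizes and tolerances used by the test suite

Exact identities (mass conservation, NUE·HI = NHI, centroid and
projection properties) are tested at $10^{-9}$ on 1000 random plants or
point/line pairs. The TLS fit is cross-checked against a brute-force
orthogonal-SSE angle search on 200 sets of ≤12 points. Variance-component
recovery uses 500 simulations of the full 8×6×4×4 design; the
DSC-heritability ordering uses 100 simulated datasets plus 100
within-cell genotype permutations. These sizes give Monte-Carlo error
comfortably below the asserted margins while keeping a full run around a
minute; they are package choices and scale up trivially.

## Validation scope

The organ set is enforced strictly (the model is three-compartment by
design), while genotype, condition and experiment are free categorical
labels — the statistics run on any factorial labelling, which is also what
permutation tests rely on. Bounds checked per row: DW ≥ 0; N%, C% and A%
in [0, 100]; N% + C% ≤ 100; (plant, organ) unique. Violations are
rejected with row-addressed messages; nothing is dropped silently.
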