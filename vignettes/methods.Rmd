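---
title: "Methods: diet composition and bioenergetics scores for juvenile Chinook salmon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet composition and bioenergetics scores for juvenile Chinook salmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chinookdiet)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical choices behind the
implementations, and what the synthetic-data generator does and does not
emulate. The running study system is a long-term monitoring design:
subyearling Chinook salmon seined at five fixed tidal-wetland sites in a
large river estuary, February through July over many years, with each
fish's stomach contents identified, counted and blotted-wet-weighed per
taxon.

## Data model and exclusions

A dataset is three flat tables: fish records (site, year, month, fork
length in mm, mass in g, mark status, water temperature at capture, and an
ordinal stomach-fullness category 2–6 that may be missing), prey items (one
row per fish × taxon × life stage, with count ≥ 1 and wet weight in g), and
an energy-density lookup (taxon → kJ per g wet mass, with a default for
unlisted taxa).

Two exclusions precede every analysis: fish with empty stomachs carry no
diet information, and fish of fork length ≥ 100 mm fall outside the
subyearling size range of interest. The 100 mm cutoff is implemented as
`fork_length_mm >= 100` because the largest retained bin is labelled
66–99 mm — 99 is the last included integer length. `apply_exclusions()` is
idempotent and returns a per-rule removal report so counts can be audited
against the sampling design table.

Two length-bin schemes coexist deliberately: the regression models use two
bins (30–65, 66–99 mm; enough fish per cell to estimate a bin effect),
while the ordination uses three (30–59, 60–79, 80–99 mm; finer resolution
is affordable because ordination rows are groups, not model cells). Bins
are inclusive of their printed endpoints and partition [30, 100); for
non-integer lengths the cut sits between a bin's upper printed endpoint and
the next bin's lower one (65.5 mm falls in 30–65).

## Prey-importance indices

Within a group of fish, for each taxon $i$:

$$\%N_i = 100\frac{\sum c_i}{\sum_j \sum c_j},\quad
  \%G_i = 100\frac{\sum w_i}{\sum_j \sum w_j},\quad
  F_i = \frac{\#\{\text{stomachs containing } i\}}{\#\{\text{stomachs}\}},$$

$$IRI_i = F_i\,(\%N_i + \%G_i), \qquad
  \%IRI_i = 100\,IRI_i / \textstyle\sum_j IRI_j.$$

$F$ is a proportion in $[0,1]$ while the compositions are percentages, so
$IRI \in [0, 200]$; $\%IRI$ is the currency used in the diet matrix. Prey
life stages are summed within taxon by default (chironomid larvae, pupae
and emergent adults are one column); a stage-resolved mode
(`stage_resolved = TRUE`) keeps them apart for life-stage questions. The
index is invariant to splitting one prey row into several whose counts and
weights sum to the original, which makes it robust to how a technician
recorded a sample.

## Per-fish foraging scores

* **Instantaneous ration** $IR = \sum w_i / W$: dimensionless stomach
  fullness relative to body mass.
* **Energy ration** $ER = \sum w_i e_i / W$ in kJ per g fish, where $e_i$
  is the taxon's energy density (kJ/g wet mass). When a taxon has no listed
  density the configured default is substituted with a warning — published
  density tables never cover every field taxon, and silently dropping prey
  would bias ER downward.
* **Maintenance metabolism** $J_m = j_m\,e^{d t}\,W$ with defaults
  $j_m = 0.003$ (mass-specific maintenance cost at 0 °C) and $d = 0.68$
  per °C. $J_m$ is carried in abstract model units and only its ratios and
  orderings are interpreted. The default $d = 0.68$ makes $J_m$ grow by
  $e^{0.68} \approx 2$ per degree, which is physiologically implausible for
  a fish (bioenergetics temperature coefficients are typically an order of
  magnitude smaller); it is nonetheless kept as the package default because
  it is the value the analysis is defined with, and it is exposed as an
  ordinary parameter of `metabolism_params()` so users can substitute e.g.
  0.068. None of the package's conclusions depend on the choice: the gamma
  log-link model of $J_m$ absorbs any fixed $d$ into the temperature
  profile, and effect orderings are preserved.

## Multivariate diet comparisons

All multivariate statistics consume a groups × taxa matrix of %IRI values
(rows sum to 100) and are implemented in the package rather than delegated,
so that their tie-breaking, permutation and convergence rules are explicit
and testable. `vegan` serves as an independent cross-check in the test
suite, never as the computational path.

**Bray-Curtis.** $d(a,b) = \sum_i |a_i - b_i| / \sum_i (a_i + b_i)$, with
$d = 0$ for two all-zero rows (a group that ate nothing differs from
nothing). On %IRI rows this is "percentage difference", the standard
dissimilarity for compositional diet data.

**NMDS.** Kruskal stress-1,
$\sqrt{\sum (\hat d_{ij} - d^*_{ij})^2 / \sum \hat d_{ij}^2}$, where
$\hat d$ are configuration distances and $d^*$ their isotonic regression on
the input dissimilarity order (pool-adjacent-violators; Kruskal's primary
tie treatment — tied dissimilarities are ordered by current configuration
distance and left free to differ). Optimisation alternates PAVA with a
SMACOF-style majorisation update using the disparities, accepted through
step-halving so stress-1 never increases across accepted iterations;
convergence is a relative stress change below `tol` (default 1e-6, scale
free because stress-1 is scale invariant). The first start is classical
metric scaling of the dissimilarities; further restarts (default 8) add
seeded Gaussian jitter at a quarter of the start's coordinate SD, and the
best final stress wins. Output is centred and rotated to principal axes, so
solutions are identified up to reflection; tests compare runs by Procrustes
distance, not raw coordinates. Degenerate inputs (all-zero dissimilarities,
fewer than $k+1$ points, asymmetry) are rejected up front; non-convergence
within `max_iter` returns a flagged result rather than an error, because a
slightly unconverged ordination is still plottable.

**ANOSIM.** All off-diagonal dissimilarities are ranked once with average
ranks on ties (deterministic, the standard choice), and
$R = (\bar r_B - \bar r_W) / (n(n-1)/4)$. Permutation p-values shuffle the
group labels and use the add-one estimator $(1 + \#\{R^* \ge R\})/(1 + B)$
so p is never zero; with `exact = TRUE` all distinct label arrangements are
enumerated instead (capped at 200,000 arrangements) and the p-value is the
exact proportion. Pairwise ANOSIM re-ranks each pair's submatrix and
multiplies p by the number of pairs, capped at 1 — plain Bonferroni rather
than Holm, matching the reporting convention the package reproduces. Both a
global test and the pairwise table are exposed, since monitoring reports
use sometimes one, sometimes both.

**SIMPER.** For each between-group row pair, the taxon contribution is
$|a_i - b_i| / \sum_j (a_j + b_j)$; averaging over pairs makes the
contributions sum *exactly* to the mean between-group Bray-Curtis
dissimilarity (an identity the tests check to 1e-9). The head list is the
shortest descending-contribution prefix reaching a cumulative 70 % — the
"taxa that account for more than 70 % of the difference". SIMPER is used
descriptively; no permutation test is attached to it.

**Species vectors.** Each taxon column is least-squares-projected onto the
ordination; strength is the squared multiple correlation, direction the
unit coefficient vector scaled by $\sqrt{R^2}$, and significance a
row-shuffling permutation p (add-one). Constant columns get strength 0 and
p 1.

## Gamma log-link models and effect sizes

IR, ER and Jm are positive, continuous and right-skewed, so they are
modelled as gamma with log link, parameterised by mean $\mu$ and dispersion
$\alpha$: shape $1/\alpha$, scale $\mu\alpha$, variance $\alpha\mu^2$.
Coefficients are fitted by IRLS (for this link/family the working weights
are identically 1), iterated to a relative coefficient change below 1e-12
so refits under row permutation agree to 1e-10; $\alpha$ is then estimated
by maximum likelihood given the fitted means by solving
$\log k - \psi(k) + 1 + \overline{\log(y/\hat\mu) - y/\hat\mu} = 0$ for the
shape $k = 1/\alpha$ (monotone in $\log k$; solved by `uniroot` on a wide
bracket). The coefficient covariance is $\alpha (X^\top X)^{-1}$ and
$AICc = -2\ell + 2k' + 2k'(k'+1)/(n-k'-1)$ with $k'$ counting the
coefficients plus $\alpha$.

The original design's random effect — months nested within years — is
approximated by *fixed* blocking dummies for year (default) or
year × month, selected by AICc in the pipeline. The estimand (factor
marginal means and their contrasts) is preserved at this design's scale,
no variance components need to be reported, and the fit stays a small,
fully testable IRLS. A true random-intercept fit is out of scope.

Rank-deficient designs (an interaction requested for site × month cells
that were never sampled) are handled the way `glm` handles aliasing: the
aliased columns are dropped with a message and the fit proceeds.

**Estimated marginal means** average the linear predictor, for each level
of the target factor, over a reference grid of the *observed distinct
combinations* of the other model factors (including the blocking dummies),
equally weighted. Averaging over observed combinations rather than the full
Cartesian grid drops never-sampled cells automatically; when every cell is
observed the two conventions coincide, which is how the test suite
cross-checks against `emmeans` to 1e-6 on the link scale. Wald 95 % CIs
come from the coefficient covariance; response-scale values are
exponentiated.

**Pairwise comparisons** report link-scale EMM differences with plain 95 %
CIs (no multiplicity adjustment — Bonferroni is applied only to the
ANOSIM side, matching the reporting convention) and Cohen's d: the
difference divided by a population SD. The population SD is not uniquely
defined for a gamma GLM, so the package's default is the model's residual
SD on the link scale, $\sigma_{pop} = \sqrt{\psi'(1/\alpha)}$ (the SD of
$\log x$ for a gamma with dispersion $\alpha$), and the argument is
pluggable. A pair is flagged when the effect-size CI excludes zero. EMM
differences are reported on the link scale.

## The synthetic-data generator

`generator_config()` defaults *are* the study conditions:

* **Design.** Per-(site, month) non-empty fish counts equal the printed
  sampling-design cells exactly (per-site totals 40/444/455/343/83, grand
  total 1365). Each cell's count is spread across 2008–2021 as evenly as
  possible, remainder to the earliest years, since no per-year breakdown is
  published. Empty-stomach fish are added on top at rate 18/1383 — the
  published 18 empties among 1383 processed fish — so exclusions return
  exactly the design.
* **Margins.** Length-bin (30–65 vs 66–99 mm) and mark-status counts per
  site are hit *exactly* by shuffling fixed label vectors over each site's
  fish, because the design-table bookkeeping checks are exact counts, not
  rates. The two margins are shuffled independently, so the real data's
  correlation between being large and being hatchery-marked is *not*
  emulated.
* **Diets.** Each stomach's total prey count is
  $1 + \mathrm{NB}(\mu = 19, k = 2)$ and is split across nine taxa by a
  multinomial whose probabilities are a per-stomach Dirichlet draw from the
  site's concentration vector (total concentration 150: mild
  Dirichlet-multinomial overdispersion). Profiles follow the published
  qualitative structure: *Americorophium*-dominated diets at the three
  downstream sites (Welch and Whites Islands share one profile —
  their diets are reported as near-identical — which also gives the
  test suite an exchangeable site pair), cladoceran-dominated at Campbell
  Slough, dipteran-dominated with more terrestrial insects at Franz Lake.
  Per-item weights are lognormal with taxon-specific medians (5 mg
  amphipods down to 0.15 mg *Daphnia*, log-SD 0.6).
* **Fish.** Fork lengths are uniform within bin; mass follows
  $W = 10^{-5} L^3$ g (a condition-factor-one cube law) with 8 % lognormal
  noise. Temperatures interpolate linearly from per-site February
  endpoints (4.4–10.9 °C across sites) to July endpoints (18.9–23.3 °C)
  with 1 °C noise; 17.5 °C is the rearing-threshold flag.
* **Fullness.** Ordinal categories 2–6 are the quintiles of realised IR
  (fuller stomach, higher category), with 15 % left uncategorised to mirror
  the blanks in real fullness records.
* **Energy densities.** Round placeholder values per taxon (2–5 kJ/g);
  published per-taxon densities are not available in machine-readable form,
  so these are declared by configuration and *not* claimed to match any
  source.

The generator reproduces the design's bookkeeping, the qualitative
between-site diet structure and the scores' distributional shapes. It does
not emulate: interannual prey shifts (e.g. cladocerans only becoming
prevalent after a particular year), the length–mark correlation, prey
availability (so no selectivity analysis is possible), within-site spatial
structure, or day-of-sampling effects. Tests that pass on generated data
therefore demonstrate correctness of the *computations* under the design,
not ecological conclusions about any real estuary.

## Problem sizes and determinism

Every stochastic routine takes a seed and restores the RNG state
(`withr`), so pipeline stages can be re-run in isolation; the pipeline
derives per-stage seeds from one root seed and writes a manifest with file
checksums, making end-to-end runs reproducible byte for byte. The test
suite works at these scales, chosen to make each check sharp but quick:
full-design generation (1365 retained fish) for bookkeeping and recovery
checks over 100 seeds; ANOSIM size calibration over 500 null simulations of
12 samples at 199 permutations; gamma parameter recovery over 200
simulations of n = 500; NMDS reference comparisons on 6–10 point
configurations where the global optimum is reliably found by both
implementations.

## Known limitations

* Fixed blocking dummies approximate, not implement, nested random
  effects; with many years and few fish per year EMM standard errors can
  differ from a mixed model's.
* The EMM reference grid weights observed combinations equally; with
  severely unbalanced designs this is a choice, not the only defensible
  one (`emmeans`-style full-grid weighting coincides only when all cells
  are observed).
* NMDS finds local optima; restarts mitigate but do not guarantee the
  global minimum on large matrices.
* Cohen's d depends on the pluggable $\sigma_{pop}$ convention; values are
  comparable within a convention only.
* The generator's energy densities and prey weights are plausible
  placeholders; ER magnitudes from generated data should not be quoted as
  estuarine values.
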