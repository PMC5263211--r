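---
title: "Genomic assisted selection: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic assisted selection: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gasel)
```

# The problem

In line breeding of autogamous crops, each new cohort of inbred lines is
first observed in a single-location, single-year, *unreplicated*
preliminary yield trial (PYT), and only a selected fraction advances to
replicated multi-environment trials (MET). The PYT-based decision is the
bottleneck: one plot per candidate, field trends, and low heritability for
yield make the phenotype a weak predictor of next-year performance.
`gasel` implements a selection methodology that strengthens this decision
by (i) modeling genomic relationships *within* the preliminary trial
(KBLUP), (ii) predicting candidates genomically from earlier MET cohorts
(GBLUP), and (iii) merging both information sources in a heritability
index, optionally after a sign-change marker pre-selection.

# Models

## Stage one: check-based spatial adjustment

Each trial is analyzed separately. The replicated check plots identify the
model

$$y_{rc} = \mu_{\text{check}(rc)} + \rho_r + \gamma_c + \varepsilon,$$

with sum-to-zero row effects $\rho_r$ and column effects $\gamma_c$ and
i.i.d. plot error $\varepsilon \sim N(0, \sigma^2_e)$, fitted by least
squares on the checks only. Estimated trends are subtracted from every
plot; an unreplicated entry's adjusted value is its BLUE. Its standard
error propagates both the plot error and the uncertainty of the
subtracted trend,

$$\mathrm{se}^2 = \hat\sigma^2_e + \widehat{\mathrm{Var}}(\hat\rho_r + \hat\gamma_c),$$

taken from the check-model coefficient covariance. This matters
downstream: without the second term the stage-two model misattributes
adjustment noise to genotype-by-environment interaction.

Degenerate layouts are handled conservatively. If the checks cannot
support rows *and* columns (fewer residual degrees of freedom than 2),
the model degrades to the single axis with fewer levels, then to check
means only, with a logged message. Rows or columns containing no check
are unadjustable; their effect is set to zero with a warning. Aliased
effects (disconnected check layouts) are zeroed with a warning.

Per-trial heritability is reported in two standard forms, with
$v = \overline{\mathrm{se}^2}$ the mean squared SE of the test entries
and $\hat\sigma^2_G = \max(0, \mathrm{Var}(\text{BLUEs}) - v)$:

* Piepho–Möhring: $h^2 = \sigma^2_G / (\sigma^2_G + \mathrm{MVD}/2)$ with
  $\mathrm{MVD} = 2v$ for unreplicated entries;
* Cullis: $h^2 = 1 - \mathrm{VD}_{\text{BLUP}} / (2\sigma^2_G)$, clipped
  at zero, with $\mathrm{VD}_{\text{BLUP}}$ from the shrinkage-model
  prediction error variance ($2\sigma^2_G v/(\sigma^2_G + v)$ in the
  balanced unreplicated case, where the two forms coincide).

These single-trial moment estimates are *individually* noisy — the error
variance rests on the check degrees of freedom — which is a property of
unreplicated trials, not of the implementation. The test suite therefore
asserts the band 0.15–0.45 for the *replicate mean* of the realized
$h^2$ at a configured 0.3, and uses the stable squared accuracy against
the simulated true breeding values for the convergence check at
$n = 2000$.

Trials with $h^2 > 0.3$ (strict) are forwarded. At desk scale a whole
MET year can fail the gate by estimation noise; `prepare_program_analysis()`
then falls back to using all trials of that year with a warning, so the
year remains analyzable. Preliminary trials are always carried forward —
they are the object of study, and their quality enters through the KBLUP
heritability weight.

## Stage two: across-trial combination

For one year's METs, the stage-one BLUEs follow
$y_{ij} = \mu + g_i + t_j + (gt)_{ij} + e_{ij}$ with fixed line and trial
effects and random interaction $(gt)_{ij} \sim N(0, \sigma^2_{gt})$. The
residual variance is fixed at the squared stage-one standard errors
(inverse-squared-SE weighting). Because stage one delivers exactly one
BLUE per line-by-trial cell, each interaction effect appears in a single
record and the marginal covariance is diagonal,
$\sigma^2_{gt} + \mathrm{se}^2_{ij}$; REML on $\sigma^2_{gt}$ is a smooth
one-parameter problem solved by `optimize()` on the log scale. This is
why the package does not wrap `lme4` here: the residual variance must be
*fixed* at known per-record values, which the diagonal GLS formulation
expresses exactly.

## RR-BLUP, GBLUP and their duality

Marker effects are estimated by ridge-regression BLUP,
$y = Xb + Zu + e$, $u \sim N(0, I\sigma^2_u)$, with markers coded
$-1/0/+1$, recoded to dosages and centered by twice the training allele
frequency. The genomic relationship matrix is

$$K = \frac{WW^\top}{2\sum_k p_k(1-p_k)}, \qquad W_{ik} = Z_{ik} - 2p_k$$

(dosage scale). GBLUP fits $y = Xb + g + e$, $g \sim N(0, K\sigma^2_G)$.
Both are the same model in two parameterizations; with
$\sigma^2_G = c\,\sigma^2_u$, $c$ the normalizer above, predictions agree
identically. This duality is the central internal oracle of the package
and is asserted to $10^{-6}$ on twenty simulated panels.

REML uses the EMMA device: one eigendecomposition of the training block
of $K$ (or of $WW^\top$), after which the profiled criterion is a smooth
function of the shrinkage ratio $\delta = \lambda^2 = \sigma^2_e/\sigma^2_g$,
optimized on $\log\delta \in [-14, 14]$ with tolerance $10^{-10}$.
An optimum within $10^{-3}$ of the interval boundary is flagged
(`boundary = TRUE`); a constant response returns a zero-genetic-variance
fit with $h^2 = 0$ rather than an error. Eigenvalues are clipped at zero;
rank-deficient $K$ is unproblematic. Singular fixed-effect designs are
rejected.

## The Eq.-5 heritability and inbred panels

Throughout, $h^2 = 1/(1 + \lambda^2)$ — the Hofheinz approximation tying
heritability to the fitted shrinkage ratio. One consequence deserves
emphasis: for fully inbred panels the VanRaden-type $K$ has mean diagonal
near 2, so $\sigma^2_g$ is roughly *half* the realized genetic variance
and the Eq.-5 $h^2$ is smaller than the single-plot
$\mathrm{Var(bv)}/(\mathrm{Var(bv)} + \sigma^2_e)$. The parameter-recovery
acceptance criterion therefore simulates from the GBLUP generating model
itself ($g \sim N(0, K\sigma^2_g)$, $\sigma^2_e = \sigma^2_g(1/h^2 - 1)$),
so that the target is the very parameter REML estimates. As an index
*weight* the scale discrepancy is immaterial — both components are scaled
before weighting, and weights act relatively.

## KBLUP

KBLUP is GBLUP machinery applied to a PYT cohort's own adjusted BLUEs with
the grand mean as the only fixed effect. Relationship information lets
single plots borrow strength from relatives: an extreme observation on one
line is shrunk toward its family. Check varieties are excluded — they are
named cultivars, not selection candidates. With $K = I$ KBLUP degenerates
to ordinary shrinkage BLUP and preserves the raw ranking exactly (a test).

## The heritability index and marker selection

GBLUP and KBLUP predictions for the selection candidates are centered and
scaled *over the candidates only*, then merged:

$$\mathrm{GEBV}_{\text{index}} = \mathrm{GBLUP}_s \cdot w_{\text{GBLUP}} +
  \mathrm{KBLUP}_s \cdot w_{\text{KBLUP}},$$

with the respective Eq.-5 heritabilities as weights. Scaling divides by
the standard deviation by default; a literal division by the variance is
available via `method = "variance"` for fidelity to the index's original
description, but standardization is the convention of index selection and
keeps the weights unit-consistent — the default ranking is identical
whenever both components are scaled by the same convention.

Marker pre-selection compares RR-BLUP effects estimated separately on the
MET training set and on the PYT: markers whose effects disagree in sign
are removed before rebuilding $K$ on the GBLUP side only (no benefit
materializes on the KBLUP side, which uses the candidates' own
phenotypes). Zero effects carry no sign evidence and are retained by
default (configurable). Under the null of two independent noise fits the
removal fraction is calibrated at 0.5 (asserted at $M = 1000$ with a
binomial tolerance); refitting the retained panel reduces the residual
discordance when true signal is shared. After selection the GBLUP weight
is inflated to $w_{\text{GBLUP}} = h^2_{\text{GBLUP}}/(1 - |r|)$, $r$ the
correlation between the two prediction sets over the candidates
(affine-invariant, so raw or scaled predictions give the same $r$);
$w_{\text{KBLUP}}$ stays the KBLUP heritability.

## Training design and evaluation

Two-tailed sampling takes the $\lceil n/2\rceil$ highest and
$\lfloor n/2\rfloor$ lowest lines of each year's phenotype distribution
(ties broken by line id). For pairs this provably maximizes the training
variance over all equal-size subsets — verified exhaustively in the
tests. For larger subsets the extreme-tails subset is *not* always the
variance-maximal one (a five-point counterexample exists), so the suite
asserts dominance over the random-sampling expectation there.

The method comparison mirrors the prospective selection decision: for
each selection year $t$ whose cohort is retested in MET year $t+1$, the
retested lines are predicted by each method and correlated with their
next-year across-trial BLUEs. Genomic fits train on three-year
combinations of MET years in which the candidates never occur — their
phenotypes from both the PYT year and the MET are excluded structurally.
Accuracy is the Pearson correlation (predictions are compared against
BLUEs, not ranks). Hit-rate curves report the fraction of the truly
best/worst $q$ of lines recovered in the predicted best/worst $q$, ties
broken by line id.

Leave-one-year-out sampling draws an equal number of lines per training
year, set by the requested fraction of the *smallest* year; this keeps
the paired random/two-tailed arms exactly comparable at the cost of not
exhausting the larger years.

# The simulator: the stated world

The generator emulates the data structure the method assumes, at desk
scale. Defaults and their rationale:

| parameter | default | rationale |
|---|---|---|
| lines/year, years | 120 x 6 | real programs test 150–550 lines/year over 5+ years; 6 years gives the 4-fold three-year-combination geometry |
| families | 25 | pedigree-method programs: many small related families spanning cohorts |
| markers (QTL) | 600 (100) | a GBS panel is ~6.6K after QC; scaled ~10x down for runtime with LD preserved via parental mosaics |
| h² yield / protein | 0.30 / 0.70 | contrasting low/high single-trial heritability traits |
| G×E variance | 0.25 | a quarter of the (unit) genetic variance; strong but not dominant interaction |
| trait means | 60 dt/ha, 14 % | typical winter-wheat scales; genetic SD standardized to 1 |
| spatial trends | sd 0.5/0.5 | visible but sub-residual field gradients |
| checks | 4 x 10 (PYT), 4 x 8 (MET) | ~25% check plots, the density augmented designs need to estimate trends and error |
| carry fraction | 0.40 | retest ratios of roughly 100–150 of 150–550 lines |
| selection | observed PYT yield | reproduces the selection-induced bias between stages |

Genotypes are recombination mosaics of two inbred parental haplotypes per
family (~10 blocks/line, 2% residual heterozygosity) — enough to create
the family-block kinship structure and marker LD the method exploits,
with none of the machinery of a coalescent. QTL effects for the two
traits are bivariate normal (correlation 0.3) and rescaled so the
realized genetic variance is exactly 1, which ties the residual variance
to the target heritability through $\sigma^2_e = (1-h^2)/h^2$. Check
varieties draw their true values from the same distribution as test
lines (a neutral choice; their role is purely structural). The
carry-over fraction between PYT and MET is a free parameter of the
world, not a fitted one.

What the simulator does *not* emulate: chromosome-scale linkage maps,
dominance/epistasis, autoregressive spatial correlation (trends are
additive row+column by construction, matching the analysis model),
multi-trait selection indices, or long-term recurrent selection. A green
stochastic test therefore establishes that the *machinery* produces the
documented orderings in a world with the assumed structure — not that the
magnitudes transfer to any particular breeding program.

# Numerical choices

* REML: `optimize()` on $\log\delta$, interval $[-14, 14]$, tolerance
  $10^{-10}$; stage-two interaction variance on $[-14, 8]$, tolerance
  $10^{-9}$, snapped to 0 at the lower boundary.
* Kinship: symmetrized as $(K + K^\top)/2$; smallest eigenvalue reported,
  not repaired; mean-diagonal sanity band $[0.5, 2.5]$ logged, not
  enforced.
* EM imputation: iterated conditional expectation with a $10^{-8}$
  relative ridge, 50-sweep cap, mean-imputation fallback with a warning;
  imputed values clipped to $[-1, 1]$. Marker-mean imputation is the
  pipeline default (the EM covariance is markers-by-markers and meant for
  modest panels).
* All ties (two-tailed sampling, hit rates, carry-over selection) break
  by line id; every stochastic stage draws from a named substream of one
  master seed, so changing one stage's consumption leaves the others
  untouched.
* Check placement covers every row and column greedily whenever
  geometrically feasible, with randomized tie-breaks — a deterministic
  balanced pattern can disconnect the row-column design (odd/even
  parity), which surfaced during development as an aliased check model.

# Known limitations

* The additive row+column adjustment is a deliberate reduction of
  AIC-selected spatial models with autoregressive residuals; where real
  trials have smooth correlated error surfaces, the check-based additive
  model under-corrects.
* Single-trial heritability estimates from unreplicated trials are noisy
  at realistic check numbers; decisions gated on them (the $h^2 > 0.3$
  filter) are correspondingly unstable at desk scale, hence the fallback.
* The Eq.-5 heritability is a model parameter, not a plot-level
  heritability, and differs from it on inbred panels (see above).
* `fit_rrblup()` forms the $n \times n$ marker cross-product; panels are
  expected to have more markers than lines (the genomic-selection
  regime). For $M \ll n$ a direct ridge solve would be cheaper.
* The simulator's MET trials place each line once per location trial;
  within-trial replication of test lines is not modeled (checks carry
  all replication).
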