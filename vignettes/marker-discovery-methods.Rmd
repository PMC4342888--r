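---
title: "Methods: proteomic marker discovery for hygienic behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic marker discovery for hygienic behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbmarkers)
```

# The problem

Hygienic behavior (HB) is a colony-level social-immunity trait of honey
bees: nurse bees uncap brood cells containing dead or diseased pupae and
remove them. It is scored in the field with the freeze-killed brood assay
as the proportions of killed cells uncapped (U) and removed (R) at 24 h
and 48 h, with `r24` the headline phenotype. `hbmarkers` implements a
quantitative-proteomics pipeline for finding antennal proteins whose
expression across colonies predicts HB, so that marker-assisted selection
can replace repeated field assays. The package covers the experimental
design, the peptide-to-protein processing, the per-protein association
model, the cross-dataset marker ranking with a heritability component,
and the downstream ligand-binding characterization of candidate odorant
binding proteins (OBPs). A synthetic-data suite generates every input
with known ground truth, which is how the package validates itself.

# Triplex block design

Isotopic dimethyl labeling allows three samples per LC-MS/MS run (one
*block*: light/medium/heavy labels). Each colony contributes three
replicate antennal samples. `build_design()` assigns samples to blocks
under the study constraints: a block never holds two samples from the
same colony nor two colonies from the same source population, and each
colony uses each label exactly once (a Latin-square rotation over its
replicates). These constraints keep the HB effect unconfounded with
population and label.

Among valid designs we minimize the sampling variance of the
block-and-label-adjusted HB slope, `1 / SSX`, where `SSX` is the
block-centered sum of squares of the HB covariate over all slots.
Because every colony appears exactly once per label,
`SSX = 3 * sum(x^2) - sum(S_b^2) / 3` with `S_b` the block sums, so the
optimizer simply minimizes the sum of squared block sums — swaps are
evaluated in O(1). The search is random feasible initialization plus
greedy pairwise slot-swap hill climbing with restarts; ties are broken by
a lexicographic block signature so results are reproducible. Instances of
a few hundred colonies converge in under a second; on instances of up to
six colonies the search provably attains the exhaustive optimum (checked
in the test suite). The literal alternative reading of the design goal —
minimizing the within-block variance of HB — is available via
`objective = "within_block_variance"`, but the default maximizes the
power to detect HB effects, which is what an optimized design is for.

```{r design-example}
cols <- simulate_colonies(4, c("ON", "CA1", "SK"), seed = 1)
design <- build_design(cols, hb_variable = "r24", n_restarts = 3, seed = 2)
design
validate_design(design, cols)$ok
```

# From spectra to a protein matrix

`decoy_fdr_filter()` applies the within-block target-decoy rule: the
smallest score threshold at which (decoy hits) / (target hits) is at most
1%, using the plain count ratio (no +1 correction), plus an ions-score
floor of 25 for quantification. `parsimony_group()` reduces accepted
peptides to a non-redundant protein list (Occam's razor): proteins with
identical peptide sets merge, a minimal explaining set is selected, and
subset proteins are absorbed. The selection is solved exactly by branch
and bound when there are at most 25 distinct candidate peptide sets
(greedy set cover seeds the bound and is used above that size); exactness
matters because greedy cover can return one extra group on a few percent
of realistic instances. Label-pair ratios are averaged per protein and
block as arithmetic means of peptide log-ratios — the downstream model
works in logarithms, and log-space averaging is symmetric in label order.

`detection_filter()` keeps proteins seen in at least
`ceiling(0.25 * n_blocks)` blocks (10 of 38 at the study's scale), and
`normalize_quant()` applies the study normalization: log, subtraction of
each protein's within-block mean, then per-label centering and scaling by
the median and median absolute deviation across all proteins and blocks.
The MAD uses the normal-consistency constant 1.4826 (configurable), so
standardized units are comparable to SD units. Note the order of
operations: block means are exactly zero *after the centering step*;
the subsequent per-label affine standardization necessarily shifts them
by tiny label-dependent amounts, which is why the object retains its
`label_stats` — inverting the label transform recovers the exact
zero-mean property, and the test suite checks both identities this way.
Blocks where a protein is present with fewer than three labels are
centered by the mean of the present values (or dropped, by option);
nonpositive intensities and zero label MADs are hard errors.

# Per-protein association

`fit_protein_model()` fits, for each protein,

```
expression ~ HB + label (+ population) + block
```

with block as a random intercept (lme4) and a Wald test on the HB slope.
Two numerical realities shape the implementation:

* After block-mean subtraction, complete-triple data place the block
  variance component exactly on the boundary, where the mixed fit
  degenerates. The model then reduces to a fixed-effects fit in which
  block is absorbed as a fixed factor via within-block demeaning
  (Frisch–Waugh), giving an exact *t* test with residual degrees of
  freedom `n - n_blocks - rank(covariates)`. Counting the absorbed block
  means is essential: ignoring them understates the residual variance
  and inflates the type I error from 5% to roughly 11% at study scale.
  The `auto` engine uses this path directly for standardized
  complete-triple data and the mixed model otherwise; the two agree to
  numerical precision where both apply.
* The three replicate samples of a colony sit in three different blocks,
  and the model (like the study's) carries no colony term. With
  colony-level biological variance `sigma_colony` the replicate errors
  are clustered, and because the optimized design equalizes block means
  of HB, the variance of the HB slope is inflated by approximately
  `(sigma_r^2 + 3 sigma_c^2) / (sigma_r^2 + sigma_c^2)`. Calibration of
  the test statistic itself therefore holds under exchangeable errors
  (`sigma_colony = 0`), which is the setting of the calibration checks;
  under realistic colony variance the per-sample tests are
  anticonservative. This is an inherent property of the block+label-only
  model, documented rather than patched, and it is why the marker
  *ranking* (which aggregates evidence across six datasets and a
  heritability factor) is the primary discovery instrument rather than
  any single dataset's q-values.

`compute_qvalues()` is Benjamini–Hochberg, applied per predictor across
proteins. Wald p-values use the normal approximation under the mixed fit
and the exact *t* under the fixed-effects path; categorical predictors
(population of origin) are tested jointly by F test.

# Marker ranking and selection

For each dataset a protein earns a signed HB factor
`sign_agreement * min(-log10 p, 10) * (1 + min(|effect|, 2)) / 2`:
a statistical factor damped by a biological (effect-magnitude) factor,
negated when the effect direction contradicts the protein's
cross-dataset majority direction. The overall HB correlation score is the
mean factor over the datasets where the protein was quantified plus a
heritability factor `max(0, slope_dam + slope_sire) * w(joint_p)` from
the regression of F1 daughter expression on dam and sire expression
(`w = 1 / 0.5 / 0.25` for joint p below 0.05 / below 0.5 / otherwise).
These functional forms are declared package defaults — unitless,
direction-consistent, and scaled so that strong markers score above 5 —
not transcriptions of the study's supplementary formulas, which are not
printed in the text; every constant is an exposed argument.

Selection takes the union of three routes, each tagged in the output:
`reference_q` (q < 0.1 in the designated multi-population reference
dataset, with a stricter `reference_strict_p` tag at p < 5e-4),
`two_site` (p < 0.05 for *all four* field parameters in *both*
first-year datasets — a protein with missing data at either site fails
the route), and `top_rank` (top k of the correlation score among
proteins quantified in at least 4 of 6 datasets).

# The synthetic-data generator

The generator exists so every stage can be scored against ground truth;
it emulates the statistical structure of the field study, not its
biology:

* **Colonies and phenotypes.** Latent propensity `hb_true` follows a
  wide Beta(1.5, 1.5) by default (the study reports a wide HB range;
  the exact shape is not printed). Two freeze-killed-brood tests a week
  apart perturb the propensity on the logit scale (SD 0.3 per test,
  configurable — colony-level repeatability is not reported, so this is
  a free parameter) and draw cell counts sequentially so that
  `u >= r` and 48 h >= 24 h hold by construction; the two tests are
  averaged.
* **Breeding.** `make_diallel_crosses()` splits parents at the median
  propensity and plans high x high, low x low and hybrid crosses in
  equal thirds (keeping the breeding groups usable as block-design
  "populations"); offspring propensity regresses to the parental mean
  with heritability `h2_behavior` plus segregation noise.
* **Expression.** Per (protein, sample): baseline + population offset +
  `beta * sigma_unit *` standardized propensity + colony effect + block
  offset + label offset + residual. The colony effect splits into an
  additive genetic value — transmitted as the midparent mean plus
  Mendelian segregation noise of variance `h2 * sigma_colony^2 / 2`, so
  additive variance is stationary and the expected dam+sire regression
  slope sum equals `h2` — and an independent environmental part.
  Defaults `sigma_colony = 0.45`, `sigma_resid = 0.6` put roughly a
  third of per-sample biological variance at the colony level, a
  moderate choice for pooled-bee antennal samples; `beta` is expressed
  in per-sample response SD units so planted effects land on the scale
  the standardized matrix is analyzed on.
* **Missingness.** Whole (protein, block) triples drop with probability
  `mcar + (1 - mcar) * plogis(qlogis(base) - w * z(baseline))` —
  a flat completely-at-random component plus abundance-dependent
  censoring that mimics data-dependent acquisition; the default overall
  rate is 25%.
* **PSMs.** Target scores mix a correct and an incorrect normal
  component; decoys draw only from the incorrect one, and the default
  decoy fraction matches the expected incorrect-target count — the
  premise under which decoy counting estimates the FDR. Shared peptides
  and subset proteins exercise the parsimony logic.
* **Titrations.** Saturation curves come from the exact 1:1 quadratic
  equilibrium; competition curves solve the coupled probe/competitor
  equilibria by bracketing plus Newton polish to mass-balance residuals
  below 1e-8 of totals. Fluorescence is linear in bound probe with
  mean-one lognormal noise; a micelle artifact (additive signal above an
  onset concentration) can be enabled to test robustness.

All randomness descends from one integer seed through `split_seeds()`,
so identical seeds give bit-identical outputs. What the generator does
*not* emulate: real spectra, peptide chemistry, retention time, spatial
or temporal field structure, Varroa-specific phenotypes. Passing tests
therefore demonstrate that the statistical machinery behaves as claimed
under the assumed generative model — not that the model captures every
property of real antennal proteomes.

# Binding assays

`fit_saturation()` estimates the probe (1-NPN) dissociation constant
from a saturation titration: fluorescence converts to bound probe
assuming 100% active protein with 1:1 stoichiometry, free ligand is
total minus bound (protein and K_d are comparable here, so depletion is
not negligible), and the Scatchard line `bound/free ~ bound` gives
`K_d = -1/slope`. The unknown plateau is iterated to a fixed point
(relative change < 1e-6, at most 100 iterations) at which the implied
binding capacity equals the total protein. On noiseless data the
recovery is exact to numerical precision across 0.5–10 uM, and the
estimate agrees with a direct nonlinear least-squares fit within 2%.

`find_ic50()` locates the competitor concentration halving the initial
fluorescence by log-linear interpolation (linear when the bracket
includes zero), with censoring to a lower bound when the curve never
reaches half. `kd_from_ic50()` implements the classical conversion
`K_d = IC50 / (1 + [1-NPN] / K_{1-NPN})` — the printed equation read
with conventional grouping, since the literal ungrouped form is not
dimensionally a constant. At this study's concentrations (protein and
probe both 2 uM, K_d of order 1 uM) the closed form is biased upward
about two-fold by ligand depletion, so `fit_competitor()` defaults to
inverting the exact coupled equilibria at the IC50 point — only the
fluorescence *ratio* enters, so the unknown scale cancels — and recovers
a planted 1 uM competitor K_d within a few percent at 2% noise. The
closed form (with free-or-total probe switchable; free is the default,
estimated as `probe_total - bound0/2`) remains available as
`method = "cheng_prusoff"`.

# Numerical and design choices

* Thresholds (1% decoy FDR, ions score 25, 25% detection, q < 0.1,
  p < 0.05 two-site, p < 5e-4 strict, 4-of-6 datasets) are the study's
  printed values, all exposed as arguments.
* BH is the FDR procedure (the study names only "Q-values"); the
  within-block FDR estimator is the plain decoy/target ratio.
* The detection threshold uses the ceiling convention
  (`ceiling(0.25 * 38) = 10`).
* Degenerate cases have defined behavior: constant predictors and
  responses are reported as inestimable/degenerate rather than fitted;
  flat titrations raise a no-binding error; an all-equal HB vector makes
  the design criterion infinite with a warning.
* Problem sizes in the validation suite (36-colony datasets, 500
  proteins, 20 study replicates; 120 colonies for calibration) were
  chosen as the smallest sizes at which the planted effects match the
  study's reported significance scale (per-dataset p well below 1e-3
  for markers).

# Known limitations

* Anticonservativeness under unmodeled colony-level variance (above) is
  the pipeline's main inferential caveat; a colony random effect is a
  natural extension but is deliberately out of scope because the method
  being implemented adjusts for block and label only.
* The dam/sire heritability regression at 60 trios has sampling SD of
  about 0.165 on the slope sum; with `h2 = 0.6` roughly a quarter of
  studies this size will land outside ±0.2 of the truth. The estimator
  is unbiased, but single-study heritability factors should be read as
  noisy weights, not estimates.
* The HB-factor and heritability-factor functional forms are declared
  interpretations (see above), so absolute correlation scores are
  package-specific; only their ranking behavior is validated.
* Greedy set cover applies above 25 candidate peptide sets; minimality
  is guaranteed only below that size (realistic within-study protein
  ambiguity groups are far smaller).
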