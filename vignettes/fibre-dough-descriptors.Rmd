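---
title: "Physico-chemical descriptors of soluble-fibre doughs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physico-chemical descriptors of soluble-fibre doughs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibredough)
library(dplyr)
```

Soluble dietary fibres (fructo-oligosaccharides, inulins, polydextrose)
change wheat-dough rheology and the architecture of the gluten network in
ways that track two molecular properties: how strongly a fibre plasticizes
biopolymers, and how strongly it competes with them for water. `fibredough`
implements the descriptor framework that quantifies both, the sorption model
that measures the water-interaction parameter, feature extraction for the
thermal and mechanical curves those descriptors are regressed against, and
skeleton statistics for gluten-network micrographs. This vignette explains
the models, the tunable parameters, and the design decisions that were
genuinely open.

## The hydrogen-bonding model of plasticization

A carbohydrate plasticizer softens a biopolymer matrix in proportion to the
density of hydrogen-bonding sites it contributes. Not every hydroxyl counts:
intramolecular hydrogen bonds remove some, so the model works with an
*effective* site count per molecule, $N_{OH,s}$. For sugars and their
oligomers this count is encoded in the dry glass transition temperature
through

$$\frac{1}{2}\,\frac{T_g - T_{g,w}}{T_{g\infty} - T_{g,w}}
  = \frac{1}{2} - \frac{1}{N_{OH,s}},$$

with $T_{g,w} = 139\,$K for pure water (which has $N_{OH,w} = 2$) and
$T_{g\infty}$ the glass transition of the reference large polymer of the
compound's family. The closed-form inversion used by `noh_from_tg()` is
$N_{OH,s} = 2(T_{g\infty} - T_{g,w}) / (T_{g\infty} - T_g)$: it equals 2 at
the water limit and diverges as $T_g \to T_{g\infty}$.

$T_{g\infty}$ is a per-family constant. For glucans the maltopolymer/starch
value 475 K applies and reproduces the tabulated site counts of dextrose,
the glucose syrup and polydextrose to the printed precision. For fructans no
single published constant exists in the same form; inverting the relation
against the five well-characterised fructans in the registry gives a tightly
grouped 447.1-448.5 K, so the package adopts **447.5 K** as the fructan
default (`glass_params("fructan")`), exposed for override.

```{r}
noh_from_tg(389)                          # glucose syrup
noh_from_tg(421, glass_params("fructan")) # long-chain inulin
```

The intrinsic plasticizing strength is the site density per molar volume,
$N_{OH,s}/v_s$ with $v_s = M_w/\rho$, reported on the conventional
$10^{-3}\,$mol/cm$^3$ scale (water = 111.1). The packaged registry
(`default_compounds()`) stores the published values as the data of record;
`annotate_compounds()` recomputes them as a validation path. For three
compounds (glucose syrup, dextrose, polydextrose) the published column
differs from the quotient of its own published inputs by up to 0.8 units —
most likely unrounded inputs upstream — so the recomputation check treats
those three at a documentation tolerance rather than the 0.1 used elsewhere.

## Solvent-phase descriptors of a dough

Four numbers summarise a dough's solvent phase:

* $\Phi_{w,eff} = \Phi_w + \sum_i \Phi_{s,i}\,
  \frac{N_{OH,s,i}}{N_{OH,w}}\frac{v_w}{v_{s,i}}$ — the water volume
  fraction plus each dissolved solute's hydrogen-bonding contribution in
  water-equivalent volume;
* $\chi_{eff} = \sum_i \Phi_{s,i}\chi_{s,i} / \sum_i \Phi_{s,i}$ — the
  solute-volume-weighted water interaction parameter (lower = more
  hygroscopic);
* $(N_{OH,s}/v_s)_{eff}$ — the same weighting applied to the site
  densities;
* $\Phi_{flour}$ — the flour-solids volume fraction.

Volumes follow a fixed convention (`phase_volumes()`): the solvent-phase
total comprises added water plus flour moisture (15.5% default), flour
solids and added vital gluten at 1500 kg/m³ (gluten treated as dry), and the
dissolved solutes at their registry densities; salt, yeast and oil are
recorded but excluded. The flour fraction's numerator excludes the added
vital gluten. This convention was validated cell by cell against the
published descriptor block of the twelve packaged recipes: it reproduces the
effective water fraction within 0.0013 and the flour fraction within 0.0008
for eleven of twelve doughs.

The twelfth, the FOS dough, is a documented inconsistency in the source
table rather than a convention failure: a single FOS site density of about
18.4 (instead of the registry value 11.9) reproduces *both* of that row's
otherwise irreproducible printed values, indicating an inconsistent input
upstream. `reproduce_tables()` reports the row as a failing cell on purpose.

```{r}
formulation_params(default_recipes()) |> head(4)
reproduce_tables() |> count(table, pass)
```

## Sorption and the water interaction parameter

Above the mixture glass transition, the water activity of a plasticized
carbohydrate follows the rubbery Flory-Huggins form

$$\ln a_w = \ln\Phi_w + (1 - v_w/v_s)(1 - \Phi_w) + \chi\,(1 - \Phi_w)^2 .$$

`fit_chi()` estimates $\chi$ by least squares **in activity space** (the
sorption balance's error is uniform in $a_w$, not in $\ln a_w$), using only
points with $\Phi_w$ above a cutoff of 0.2 — the volume fraction at which
the mixture glass transition of the common soluble fibres crosses room
temperature, so points below it are glassy and not described by the rubbery
branch. The mixture Tg itself is modelled by the Couchman-Karasz rule
(`tg_mixture()`) with heat-capacity increments defaulting to 1.94 (water)
and 0.5 (carbohydrate) J/(g K); these defaults serve the qualitative
Tg-crossing picture only, no numeric result depends on them. A glassy
free-volume correction is deliberately not implemented: its published form
is not fixed by the material in hand, and fits restricted to the rubbery
branch do not need it. Partially crystalline fibres (long-chain inulin)
simply fit with a larger residual.

One numerical subtlety: for weakly hygroscopic solutes ($\chi \gtrsim 0.6$)
with large molar volumes, the rubbery expression exceeds $a_w = 1$ over a
mid-range band of water fractions — a demixing region no sorption experiment
can populate. Monotonicity of $a_w$ in $\Phi_w$ is guaranteed only for
$\Phi_w \le 1/(2\chi)$, and the synthetic isotherm generator truncates its
$\Phi_w$ grid (nominally 0.25-0.95) to the physically sorbing branch where
the model activity stays below 1.

```{r}
iso <- gen_isotherm(chi_true = 0.84, v_s = 1141, rho_s = 1550,
                    n_points = 20, sigma_aw = 0, seed = 1)
glance(fit_chi(iso, rho_s = 1550, v_s = 1141))
```

## The baking state diagram

Starch gelatinization and gluten thermosetting are treated as Flory
melting-point depression by the effective water fraction:

$$\frac{1}{T_m} = \frac{1}{T_m^0}
 + \frac{R}{\Delta H_u}\frac{v_u}{v_w}\left(\phi - \chi_p \phi^2\right).$$

`melting_temperature()` and `state_diagram()` use configurable parameters
with starch-like defaults ($T_m^0 = 515$ K, $\Delta H_u = 25.9$ kJ/mol,
$v_u = 100$ cm³/mol, $\chi_p = 0.5$) and a softer gluten line. The defaults
are configuration for plotting measured transitions in context, not fitted
constants: no quantitative claim in the package depends on them, and
system-specific parameters should be supplied for quantitative work. The
line is anchored exactly at $T_m^0$ for $\phi = 0$ and is strictly
decreasing for $\chi_p \le 0.5$.

## Curve feature extraction

DSC, DMTA and micro-extension traces are reduced to the standard scalar
features:

* **DSC** (`dsc_features()`): peak = extremum of the baseline-subtracted
  signal (endotherm orientation is a flag; instruments differ); onset =
  intersection of the pre-event baseline tangent with the leading-edge
  tangent at the steepest point. Tangents are local linear fits over a
  5-sample window (configurable). When a run of samples ties for steepest
  slope — a linear leading edge — the window is centred on the middle of
  the run, so it cannot straddle the onset kink; this is the one place the
  implementation prefers a centred tie-break over the lowest-temperature
  one, trading a nominal convention for an unbiased tangent. Curves with no
  event above five times the baseline noise return a sentinel row
  (`found = FALSE`), not an error.
* **DMTA** (`dmta_features()`): values at 28 °C, the tangent-intersection
  structuring onset of G′, values at the onset, the post-onset maximum and
  its temperature, end-of-hold values at 95 °C, and G′max/G′min with the
  minimum taken before the rise. A rise is declared when G′ exceeds twice
  its pre-rise minimum (configurable); flat curves return the sentinel with
  a ratio of exactly 1. Mismatched temperature grids are linearly resampled
  with a warning.
* **Extension** (`extension_features()`): resistance = global force
  maximum; extensibility = displacement at rupture, defined as the force
  maximum immediately preceding the first sample that has dropped by at
  least 50% of the running maximum, required to occur within 3 samples —
  the abruptness requirement distinguishes rupture from gradual decline.

## Gluten-network image statistics

`network_metrics()` starts from a binary mask (Otsu thresholding is applied
when reading grayscale files) and makes no attempt at bit-parity with any
particular GUI tool — the ratio descriptors it feeds are
algorithm-independent quotients. The skeleton comes from two-subiteration
Zhang-Suen thinning; junction pixels are skeleton pixels with three or more
8-neighbours, merged into clusters when adjacent so a thick crossing counts
once; endpoints have exactly one neighbour. Branches are the connected runs
between nodes; their length sums axial steps as 1 and diagonal steps as
$\sqrt 2$, plus the step joining each branch end to its adjacent cluster.
Because the cluster absorbs the centre-adjacent pixel of each incident
branch, a symmetric cross of 15-pixel arms measures 14 per arm — the
decomposition is documented and self-consistent rather than matched to any
external tool. Thinning erodes blunt ends of thick blobs by up to two
pixels, the usual behaviour of this family of algorithms.

Gliding-box lacunarity uses $\Lambda(r) = E[m^2]/E[m]^2$ over all fully
contained $r \times r$ boxes, averaged over $r \in \{2,4,8,16,32\}$ by
default. A full image scores exactly 1; a unit-box checkerboard scores
exactly 2. Because only fully contained boxes enter, the statistic is
exactly translation-invariant only for box sizes within the pattern's
margin to the frame border; invariance tests therefore stop at the box size
the frame supports, while count and length invariances hold unconditionally.

```{r}
star <- gen_network_image(4, 15, 64, seed = 1, rotate = FALSE)
network_metrics(star$img) |> select(n_junctions, n_endpoints, total_length_um,
                                    lacunarity, branching_rate)
```

## Reduced-variable regression

Responses are regressed on the four descriptors after min-max reduction
(`reduce_variables()`), so coefficients share a [0, 1] scale. Backward
elimination (`fit_backward()`) drops the largest-p predictor while any
exceeds `alpha = 0.05` — the package-wide significance convention; the
procedure is deterministic and the drop order is recorded. Normalized
shares $b_k / \sum_j |b_j|$ over the retained set preserve signs and sum to
1 in magnitude. Whether responses enter as replicate-level values or dough
means is the caller's choice; the fit records only what it was given.

Two statistical cautions are built into the test design rather than the
code. First, coefficient recovery is only identifiable on reasonably
conditioned designs: the four descriptors of fibre-substitution recipes are
strongly collinear (the water level drives both the effective water
fraction and the flour fraction), so recovery properties are demonstrated
on seeded uniform designs, and fits on recipe-derived designs should be
read as predictive, not structural. Second, backward elimination at
$\alpha = 0.05$ retains at least one null predictor in a substantial
minority of pure-noise datasets (familywise behaviour); the suite checks
the intercept-only outcome in at least 70% of 200 seeded replicates.

```{r}
set.seed(42)
des <- tibble::tibble(x1 = runif(12), x2 = runif(12),
                      x3 = runif(12), x4 = runif(12))
resp <- gen_response_table(des, b_true = c(3, 2, -1, 0, 0), sigma = 0.01, seed = 2)
fit_backward(resp, "y", c("x1", "x2", "x3", "x4"))
```

## What the synthetic generators do and do not emulate

Every pipeline stage has a seeded generator with known ground truth:
FHFV-shaped isotherms with additive activity noise (instrument-plausible
default $\sigma_{a_w} = 0.005$), recipe grids in the packaged dialect,
linear response tables on reduced designs, star-shaped network masks with
known topology, logistic DMTA curves with an analytic tangent onset
($T_{infl} - 2\,\text{width}$), piecewise-linear DSC endotherms with an
exact construction onset, and extension curves with a known rupture point.
All noise is additive Gaussian (multiplicative for G′, which is
log-scaled); real instruments drift and real gluten networks are not
star-shaped. Passing the recovery tests therefore demonstrates that the
estimators are unbiased and precise under their own model assumptions — it
does not validate the FHFV form, the melting line or the skeleton
decomposition against wet-lab data, which would require the original
measurements.

Problem sizes in the test-suite and recovery studies — 20-point isotherms,
100 Monte-Carlo replicates for the interaction parameter, 200 for the
null-predictor study, 12-dough designs and 48-64 px synthetic masks — were
chosen as the smallest sizes at which the checked properties are stable.

## Known limitations

* The glassy (free-volume) sorption branch is not modelled; fits are
  restricted to the rubbery regime above the $\Phi_w = 0.2$ cutoff.
* Temperature dependence of $\chi$, sorption hysteresis, and crystallinity
  corrections for partially soluble fibres are out of scope.
* State-diagram parameters are configuration with documented defaults, not
  fitted constants.
* Published regression tables from replicate-level dough measurements
  cannot be reproduced without those measurements; the regression engine is
  validated on synthetic data instead.
* Lacunarity values depend on the box-size schedule; comparisons are only
  meaningful at a fixed schedule.
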