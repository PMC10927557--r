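---
title: "Cluster-based diet optimisation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based diet optimisation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietshift)
```

## The problem

National food-based advice is usually derived from the *average* diet of a
population. But populations eat heterogeneously: a shift that is small for
the average consumer can be drastic for a meat-heavy eater and pointless for
a plant-forward one. dietshift implements a two-stage answer: first stratify
a dietary survey into eating-pattern clusters by hierarchical clustering,
then solve, for the total population and for each cluster separately, a
linear programme that finds the *smallest* deviation from that group's own
baseline diet which satisfies nutrient references, food-based dietary
guidelines (FBDGs), per-food acceptability bounds and a greenhouse-gas cap.

## The optimisation model

For a baseline diet with reported mean intakes $w_{rep,i} > 0$ (g/day) over
the $n$ foods the group actually consumes, the decision variables are the
optimised weights $w_{opt,i}$. The relative deviation of food $i$ is

$$RD_i = \frac{w_{opt,i} - w_{rep,i}}{w_{rep,i}},$$

and the objective minimises the total relative deviation
$TRD = \sum_i |RD_i|$, used as a proxy for cultural acceptability (its
per-food average, $ARD = TRD/n$, is the headline similarity statistic). The
absolute value is linearised with the standard split
$w_{opt,i} = w_{rep,i}(1 + d^+_i - d^-_i)$, $d^\pm_i \ge 0$, objective
$\sum_i (d^+_i + d^-_i)$. Because both halves carry cost, an optimum never
holds $d^+_i$ and $d^-_i$ simultaneously positive; `solve_model()` verifies
this by recomputing $\sum_i|RD_i|$ from the weights and insisting it match
the solver objective to 1e-6 relative.

A note on the objective's reading: "total relative deviation" could in
principle be a *signed* sum, but a signed objective would reward arbitrary
reductions in any food and is not a similarity measure; the absolute-value
reading is the one consistent with maximising similarity to the baseline,
and is what this package implements.

Constraints:

* **Energy equality.** $\sum_i w_{opt,i}\, e_i$ equals the baseline energy
  (kcal/day; 1 kcal = 4.184 kJ exactly). Optimised diets are isocaloric with
  their baseline.
* **Dietary reference values (DRVs).** One row per nutrient bound. Where
  limits are sex-specific, the group limit is the sex-count-weighted mean
  $(n_f L_f + n_m L_m)/(n_f + n_m)$ — the natural reading of weighting by
  the population size of the sex groups. Limits expressed as a percentage
  of energy are converted against the fixed baseline energy using Atwater
  factors (4/4/9 kcal per g of carbohydrate/protein/fat, 7 for alcohol);
  the conversion is exact because the energy constraint is an equality.
* **FBDGs.** At least 500 g/day fruit and vegetables, 45 g/day seafood and
  75 g whole grains per 10 MJ; at most 71 g/day red and processed meat.
  Category membership is fractional per food, so composite dishes count
  partially (a meat lasagne contributes a fraction of its weight to
  red/processed meat). The whole-grain bound is scaled with baseline energy
  (equal to optimised energy by construction).
* **Acceptability bounds.** Every food may fall to zero; non-exempt foods
  may rise at most 200 % above baseline ($d^+_i \le 2$). Foods in the
  exempt groups — Pulses, Nuts and seeds, Dairy alternatives, Meat
  alternatives, Vegetable oils — may increase without bound, reflecting
  their role in plant-forward diets and their recent market growth.
* **Climate cap** (optional). Total daily CO2eq at most 1570 g, the level
  consistent with planetary boundaries for climate change; the uncapped and
  capped model families form the standard two-model grid
  (`default_spec_grid()`).

Foods with zero baseline intake are not decision variables: the model
redistributes what a group already eats rather than introducing novel
foods. A consequence worth noting is that exempt groups can only expand
foods the group already consumes at least marginally; at cluster level mean
intakes are virtually never exactly zero, so this is rarely binding.

The LP is solved by the two-phase dense simplex in the recommended `boot`
package, behind a pluggable backend surface. Bounds are passed as explicit
rows; rows are passed *unscaled* because the backend's pivot tolerance
handling is sensitive to row rescaling. On problems of this package's size
(about a hundred variables) solves take milliseconds. Solver output is
never trusted blind: an independent audit recomputes every constraint from
the returned weights (tests insist on 1e-6 relative feasibility), and the
objective is cross-checked against grid-search and analytic oracles on
small instances in the test suite.

## Clustering

Individual diets are summarised as food-group intakes standardised for
individual energy (g/MJ), which removes between-person energy differences
before pattern comparison. Groups consumed by fewer than 75 % of the
population are dropped — zeros from non-consumption would otherwise
dominate the distances — except Pulses and Nuts and seeds, retained as
indicators of climate-friendly, healthy eating. A whole-grain g/MJ column
(fraction-weighted over foods) is appended; whether the original analyses
counted whole-grain *content* or whole-grain-rich *foods* is not
documented, and the content-weighted definition is used here. Each retained
column is z-scored; scaling follows the energy adjustment because the g/MJ
units are the point of that adjustment.

Distances are Canberra:
$d(x,y) = \frac{p}{p_{used}}\sum_{|x_i|+|y_i|>0} \frac{|x_i-y_i|}{|x_i|+|y_i|}$,
with 0/0 coordinates omitted and the sum rescaled — the convention of R's
distance machinery, which the workflows this package mirrors relied on.
Canberra weights proportional differences near zero heavily, which is what
distinguishes "eats little meat" from "eats none". Agglomeration uses
Ward's method in the `"ward.D"` dialect (Lance-Williams update applied to
the dissimilarities as given, no squaring): the classic R workflow passed
Canberra distances straight into Ward linkage, and that is reproduced here;
`"ward.D2"` is available as an option. Ward on non-Euclidean distances can
produce inversions in the merge heights; the result flags them rather than
silently reordering.

The number of clusters is chosen by a three-index majority vote (Dunn
index, mean silhouette width, Calinski-Harabasz pseudo-F; ties toward
smaller k) in `select_k()`. This deliberately replaces a 30-index voting
battery, which is out of scope; the three indices cover the
separation/compactness trade-off from three angles, and on the default
synthetic population the vote reproduces k = 3. That reproduction is a
property of these study conditions, not a universal claim.

## Post-hoc profiling

`compare_clusters()` characterises a partition the way the survey analyses
did: Kruskal-Wallis (midranks, tie-corrected) with Dunn's pairwise z-tests
and Benjamini-Hochberg adjustment for the right-skewed variables (food
groups in g/MJ, dietary CO2eq in g/MJ, income), one-way ANOVA with Tukey's
HSD for age, and Pearson's chi-squared without continuity correction for
the cluster-by-sex table (the correction is a 2x2 device; the table here is
k x 2 with k typically 3). Constant variables are skipped with a notice
rather than an error.

The SHEIA15-style healthy-eating score sums nine intake-to-recommendation
ratios clipped to [0, 1] (range 0-9; low < 4, medium 4-7, high > 7). The
authoritative component list and reference amounts live in survey
documentation this package does not ship; `sheia15_components()` provides
clearly-labelled stand-ins built from the named guideline quantities (four
adequacy components scored as intake/reference, five moderation components
scored as reference/intake so that staying within a limit earns full
credit, which keeps the score monotone in healthier intakes in both
directions).

## The synthetic survey generator

Real survey microdata, climate-database footprints and price scrapes are
external inputs; the generator exists so every stage is testable without
them. It emulates a survey of N adults over 48 foods in the 24 standard
food groups, with three planted archetypes mirroring the observed pattern
split: *classic* (meat- and potato-heavy, low fruit/vegetables), *nutrich*
(nutrient-dense animal foods, nuts, vegetables) and *lowclim*
(plant-forward, pulse-rich, sweet-toothed), in the observed 39/30/31 %
proportions. Default N is 150 — large enough for stable clustering and
rank tests, small enough that the full grid of analyses runs in seconds.

Per individual, group-level gram shares from the archetype are split over a
random subset of foods (60-80 % of each consumed group; rarely-eaten groups
like offal or meat alternatives have low consumption probabilities, which
is what gives the 75 % prevalence filter something to do) and perturbed by
multiplicative lognormal noise with coefficient of variation 0.2. Diet
intakes are positive and right-skewed, which is exactly what a lognormal
multiplicative model produces; the real survey implies no particular
generative model, so this is the stand-in's own assumption. Each diet is
then rescaled to the individual's drawn energy target (mean 2100 kcal/day,
sd 280, sex offsets x0.88/x1.15, truncated at three standard deviations).

Composition values (energy, CO2eq, price, nine nutrients, category
fractions, EAT-Lancet energy splits) are order-of-magnitude realistic for
cooked foods in a Northern-European diet and are jittered mildly per food
item. They were chosen so the synthetic baselines reproduce the qualitative
findings of real Swedish baselines — short on iron, vitamin D, fibre and
carbohydrate energy; over on saturated fat, sodium and added sugars; around
3-3.5 kg CO2eq/day — which makes the optimisation genuinely binding rather
than trivially satisfied. Because an infeasible programme would make every
downstream test vacuous, feasibility is enforced by construction *and*
verified: `generate_population()` runs a feasibility probe (full
nutrient + guideline constraint set with the 1570 g cap on the
population-mean diet) and fails loudly, naming the first violated
constraint, if a draw cannot satisfy it.

What the generator does **not** emulate: real food-composition marginals
and their correlation structure, the long tail of ~1900 distinct survey
items (48 foods means each food carries far more of its group's weight, so
ARD values run higher than in a real survey where deviations dilute over
hundreds of items), within-person day-to-day variation (intakes are diary
means by assumption), and seasonal or regional structure. Passing tests
therefore demonstrate that the machinery is correct under known structure,
not that any particular real population clusters into three patterns.

## Numerical choices

* Active constraints are those within 1e-6 relative of their limit — the
  floating-point operationalisation of "met at exactly 100 %".
* The food-change census counts a food as removed below 0.01 g/day and as
  changed beyond |RD| of 1e-3; all three tolerances are arguments of
  `diet_diagnostics()`.
* Display rounding uses integer percentages and one-decimal ARD (the
  conventional reporting precision) and rounds half away from zero; raw
  values are always retained on the objects.
* Degenerate LPs can have multiple optima; determinism is guaranteed per
  backend and seed, so tests compare objective values, not weight vectors,
  except where the optimum is provably unique.
* Ratios against a zero limit fall back to absolute tolerance; Canberra
  0/0 coordinates are omitted with the p/p_used rescale; a Dunn index with
  all-singleton clusters is +Inf by convention.

## Problem sizes in the checks

The shipped checks run the full pipeline on the 150-individual, 48-food
default population (eight LP solves per run), verify clustering recovery
across 20 generator seeds, compare the solver against brute-force oracles
on instances of up to 3 foods and 8 observations, and estimate the
rank-test false-positive rate from 1000 null replicates — sizes chosen so
the whole suite completes in about a minute while still exercising every
code path at meaningful scale.

## Known limitations

Environmental pressure is greenhouse-gas only — land use, water,
eutrophication and biodiversity are not modelled. Cost is reported, never
constrained. The LP cannot introduce foods absent from a group's baseline.
Cluster-specific energy requirements are taken as each cluster's baseline
mean rather than re-estimated physiological requirements. And the
acceptability proxy is behavioural distance, not measured acceptance.
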