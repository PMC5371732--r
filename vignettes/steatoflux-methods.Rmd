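---
title: "Personalized liver flux modeling in hepatic steatosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized liver flux modeling in hepatic steatosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoflux)
```

## The modeling problem

Hepatic steatosis (HS) — liver fat accumulation — reflects an imbalance
between fatty-acid (FA) uptake, de novo synthesis, oxidation and export by
the liver. `steatoflux` implements a personalized constraint-based analysis
of this balance in the overnight-fasted state: each subject's clinical and
anthropometric variables are translated into exchange bounds for a hepatocyte
metabolic network, the network is solved at steady state
(`S v = 0`, bounds on `v`), and the predicted intracellular fluxes are
correlated across the cohort with the liver-fat percentage and with the net
fat influx (NFI), defined as FA uptake minus FA-equivalent secretion in VLDL
triglyceride.

The scientific claim this machinery probes is that subjects whose livers face
a high FA influx with relatively low VLDL export must oxidize the surplus,
which raises the demand for mitochondrial NAD⁺ (via the transhydrogenase
NNT), for peroxide detoxification (GPX/PRDX), and for glutathione turnover
(GSR and de novo GSH synthesis from glutamate, cysteine and glycine) — and
that the plasma levels of the GSH precursors glycine and serine are
correspondingly depleted with increasing HS.

## The fasting-state boundary model

The liver's fasting inputs are amino acids (AAs), lactate, FAs and glycerol;
its outputs are glucose (gluconeogenesis plus glycogenolysis), ketone bodies,
and the measured VLDL triglyceride and apoB secretion. Per subject:

* **Fat mass** is the measured value when available, otherwise imputed from
  BMI by the linear fit `fat mass (kg) = 1.763 × BMI − 26.75`. Lean mass is
  weight minus fat mass, and `muscle mass = 0.63 × lean − 4.1`. The
  Deurenberg body-fat-percent equation
  (`1.2·BMI + 0.23·age − 10.8·sex − 5.4`, sex 1 = male) is provided as an
  alternative fat-mass source but is *not* the default: at the cohort-mean
  BMI and age it implies roughly twice the fat mass of the BMI regression,
  and the two sources cannot both be right. We expose the choice
  (`fat_mass_from_bmi()` vs `body_fat_percent()`) rather than hide it.
* **FA and glycerol** are released by adipose lipolysis at 1.8 and 0.6
  mmol/h per kg fat mass (a 3:1 molar ratio). About 4 % of the released FA is
  taken up by muscle; this fraction is recorded in the constants but
  deliberately not subtracted, so the full release is presented to the liver.
* **Amino acids** come from three sources. Muscle releases
  0.23 mmol/h per kg muscle mass, distributed so that glutamine + alanine
  carry 60 % of the molar release. Adipose releases AAs in proportion to its
  veno-arterial concentration differences times the adipose blood flow
  (3.5 ml/min per 100 g fat, the midpoint of the measured 3–4 range). The
  remainder up to the urea-derived hepatic AA demand is supplied by the liver
  catabolizing its own protein (autophagy), distributed by the molar AA
  composition of liver protein.
* **The AA demand** is anchored on fasting urinary urea (392 mmol/24 h).
  The published conversion multiplies by the mean AA molar mass
  (136.5 g/mol) and by the mean nitrogen content (1.45 N/AA) to give
  77.6 g AA/day. Taken literally as written (dividing by 1.45), the same
  numbers give 36.9 g/day, and a per-urea-nitrogen accounting (2 N per urea,
  divided by 1.45 N per AA) gives 73.8 g/day. The arithmetic as printed is
  internally inconsistent; we reproduce the published *result* (the
  multiplicative form, default `mode = "printed"`) and ship the
  physiologically motivated alternative behind `mode = "per_urea_nitrogen"`.
  Only the autophagy share — not the muscle or adipose terms — absorbs the
  difference.
* **Lactate** from red blood cells and peripheral tissues totals 80 g/day =
  37 mmol/h.
* **Glucose output** has a lower bound of 16.7 mmol/h (3 g/h) of
  gluconeogenesis plus weight-scaled glycogenolysis (5.5 µmol/kg/min;
  about 5.8 g glucose/h at the cohort-mean 97 kg). **Ketone-body
  secretion** (acetoacetate, β-hydroxybutyrate) has lower bounds of
  0.1 mmol/h each, reflecting the early-fasting state in which
  glycogenolysis still covers most of the brain's demand.
* **VLDL-TG and apoB secretion** are pinned (lower = upper) at the
  subject's measured rates. All other uptakes are closed (fasting), except
  oxygen and a free CO₂/water/urea outlet; a small biliary GSH efflux
  (0.05 mmol/h) represents glutathione turnover.

Two genuinely open choices deserve a note. First, *fixed versus capped
inputs*: the computed FA, glycerol, lactate and AA supplies are applied as
fixed inputs (lower = upper) by default, because in the fasting state these
tissues release at rates the liver does not control — the liver must dispose
of what arrives. Under a pure availability-cap reading (`input_mode =
"bound"`), a flux-sum-minimizing solution would take up only what VLDL
export strictly requires, every subject's oxidative machinery would idle,
and NFI would be nearly zero for everyone; the fixed-input reading is the
one under which the published flux–phenotype correlations are reproducible
at all. Second, *objective handling*: VLDL secretion serves as the model's
objective, and since the measured rate is known we pin it exactly rather
than maximize it; a maximize-then-minimize mode is available through
`maximize_objective()` followed by `minimize_flux_sum(fixed_constraints =)`.

The per-AA profile tables (muscle release fractions, adipose veno-arterial
concentrations, liver protein composition) are not fully published; they
ship as an editable TSV (`inst/extdata/aa_profiles.tsv`) over six explicit
AA species plus a pooled remainder. The muscle rate and adipose
concentrations were calibrated once so that, at the cohort-mean body
composition, the external (muscle + adipose) AA supply is ≈ 35 g/day —
making the autophagy shortfall fall in the expected 40–45 g/day window given
the 77.6 g/day demand — and were not revisited afterwards.

## The reduced hepatocyte network

`build_toy_hepatocyte_network()` returns a ~59-reaction, three-compartment
(cytosol, mitochondria, boundary) reduction of liver central metabolism.
Design choices:

* **H₂O₂ coupling.** Peroxide production is tied stoichiometrically to
  β-oxidation (`ros_yield_per_fa`, default 0.3 mol H₂O₂ per mol C16 FA
  oxidized) and to pooled AA oxidation (`ros_yield_per_aax`, default 0.2).
  The biology implies such a coupling but does not quantify it; both yields
  are explicit free parameters. Their value scales the NNT/GSR/GPX fluxes
  but cancels from correlation coefficients, which is what the analysis
  reports.
* **Redox bookkeeping.** NAD(H), NADP(H) and FAD(H₂) are compartmented;
  NNT is mitochondrial; the oxidative pentose phosphate shunt is the
  alternative cytosolic NADPH source. Removing both NADPH sources makes any
  positive H₂O₂ load infeasible — a structural property the tests assert.
* **Lumped pseudo-metabolites.** A triglyceride equivalent
  (glycerol + 3 C16 FA, 51 carbons) and an apoB pseudo-protein (AAs in liver
  molar ratios) stand in for the lipid and protein diversity of a
  genome-scale model. The VLDL particle is exported as separate TG and apoB
  boundary flows so both measured rates can be pinned independently; the
  TG:apoB ratio of a joint particle is deliberately not fixed.
* **Carbon bookkeeping.** Every metabolite carries a carbon count (cofactor
  couples carry zero; pooled species carry their weighted mean), and every
  internal reaction is carbon-balanced to machine precision, which the test
  suite checks.
* **Subsystem labels.** Reactions are annotated from a closed vocabulary
  covering the interrogated pathways; four auxiliary labels (pentose
  phosphate pathway, TCA cycle, transport, ATP maintenance) were added so
  that supporting reactions are honestly annotated rather than shoehorned
  into a pathway they do not belong to.

Because GPX flux equals the stoichiometric H₂O₂ load, and GSR/NNT follow it
through the GSSG and NADPH balances, the toy network makes the redox fluxes
*nearly deterministic* functions of NFI — the cohort correlations
r(GSR, NFI) and r(NNT, NFI) come out near 1, versus ≈ 0.8 in a genome-scale
model where parallel routes dilute the coupling. The package therefore
asserts the *ordering* r(·, NFI) > r(·, HS) > 0, not the published
magnitudes, which are not reproducible without the study's subject-level
data.

## Solving

All flux computations reduce to linear programs over
`{v : S v = 0, lb ≤ v ≤ ub}`. The package ships its own dense two-phase
primal simplex (`solve_lp()`): upper bounds enter as explicit slack rows,
phase I uses artificial variables, and the pivot rule is Dantzig with an
automatic switch to Bland's rule after 50 consecutive degenerate pivots,
guaranteeing termination. Feasibility and optimality tolerances default to
1e-9 and 1e-6. Infeasible and unbounded problems are reported as statuses,
never as zero vectors. On every packaged network of ≤ 6 reactions the optima
are checked against exhaustive vertex enumeration (`enumerate_vertices()`),
and on random instances against an independent LP implementation.

`minimize_flux_sum()` implements the parsimonious assumption — cells reduce
pathway usage to the minimum consistent with the constraints — by splitting
reversible reactions into nonnegative forward/backward parts and minimizing
the total flux at the pinned exchanges. Alternate optima exist in principle;
because the analysis aggregates to correlation coefficients over exchange-
determined fluxes, the reported quantities are insensitive to the solver's
tie-breaking, and a subsystem-aggregation option in the association table
covers reaction-level degeneracy.

`sample_fluxes()` is a hit-and-run sampler: directions are drawn in the
orthonormal null-space basis of the free columns of `S` (QR-derived), the
feasible segment is computed from the bounds, and a uniform step is taken.
Defaults: 100 warm-up steps, thinning 5, re-projection onto the null-space
slice every 100 steps to suppress numeric drift. Sampling requires finite
bounds; the generic cap is 10⁴ mmol/h (`default_flux_ub`), chosen an order
of magnitude above the largest flux any realistic subject induces.

## The synthetic cohort

The generator defines the study conditions; it is not a tuning knob.

* Subjects are drawn half from a low-HS and half from a high-HS group, each
  clinical variable from a lognormal marginal moment-matched to the
  group mean ± SD (low-HS liver fat 2.8 ± 1.7 %, high-HS 13.4 ± 6.4 %,
  and so on for weight, BMI, glucose, insulin, HOMA-IR, TG, liver enzymes).
  Lognormal marginals keep all quantities strictly positive — so the
  truncation floor the design allows for is inactive in practice — and
  reproduce the group moments exactly in expectation, with the realistic
  right skew of insulin, TG and ALT.
* Cross-variable structure is a Gaussian copula. Each *whole-cohort* target
  correlation (the key one: r = 0.581 between liver fat and VLDL-TG
  secretion; the others are package conventions consistent with the
  reported significant correlates) is converted to a latent within-group
  correlation by solving the exact mixture-of-lognormals moment equation,
  so sample correlations converge to the targets as n grows. A latent
  matrix that fails positive semi-definiteness is an explicit error.
* VLDL secretion moments (0.50 ± 0.20 / 0.72 ± 0.25 mmol TG/h;
  apoB 0.55 ± 0.18 / 0.66 ± 0.22 mmol AA-equivalents/h) are package
  conventions: the units of the measured kinetic outputs are not published,
  and mmol/h is the documented internal standard. Sex is drawn 75:11
  male:female; fat mass is "measured" (BMI regression + residual SD 2.5 kg)
  in a subset and withheld for a 29/73 fraction, mirroring the partial
  availability of body-composition data.
* The plasma metabolome couples each metabolite's log abundance to
  standardized liver fat (negative loadings −0.30…−0.35 for glycine,
  serine, betaine, N-acetylglycine; a shared latent factor brings the
  serine–glycine correlation to 0.77; cysteine and glutamine are null by
  design), with per-metabolite detection probabilities generating missing
  values after the fact. Nothing downstream ever imputes.

What the generator does *not* emulate: platform artifacts (batch effects,
run order), longitudinal structure, measurement error in the clinical
chemistry, or any joint distribution feature beyond pairwise correlations —
the published table reports group-wise moments only, so anything finer is
convention. Passing tests therefore demonstrate that the pipeline recovers
the structure it was told to build in, under realistic noise and
missingness; they do not validate the physiology against real subjects.

## Statistics

Group comparisons use Welch's unequal-variance t-test per metabolite on
log-transformed abundances (`stats::t.test`; an independent closed-form
implementation serves as the test oracle to 1e-9). The log base is a
configurable constant; e is the default and neither signs nor orderings
depend on it. Metabolite–metabolite and metabolite–HS correlations are
pairwise-complete Pearson, computed only at ≥ 30 joint detections (the
published detection rule; configurable, floor 3). Flux–phenotype p-values
use the t-distribution transform of r. No multiple-testing correction is
applied by default, matching the raw P < 0.05 presentation; BH-adjusted
columns can be added with `stats::p.adjust` by the user. The clause about
log transformation "with the minimum observed value" is resolved as:
transform observed values only, never impute — the explicit no-imputation
statement controls. A minimum-imputation variant was considered and
deliberately not implemented, so no code path can fill missing values.

## Problem sizes and determinism

The packaged analyses run at the study scale: 86 subjects, the ~59-reaction
network, 20 randomization repetitions in the control analysis, and 1000
samples per subject in sampling mode (about a minute on one core; the
parsimonious cohort solve takes a few seconds). Every random stage consumes
an explicit integer seed — cohort, metabolome (cohort seed + 1000), solver
sampling, randomized control — and the pipeline manifest records them all;
rerunning a configuration reproduces outputs bit for bit.

## Known limitations

* The toy network's stoichiometric rigidity makes the NFI correlations of
  the redox reactions nearly exact by construction (see above); magnitude
  comparisons against genome-scale results are not meaningful.
* Exchange-bound personalization ignores hormonal regulation, organ
  blood-flow differences beyond the adipose scaling, and the fed state.
* The cohort generator's correlation calibration is exact for the lognormal
  mixture in expectation, but finite-n sample correlations at n = 86 carry
  sampling error of roughly ±0.07–0.1.
* apoB secretion consumes amino acids through a fixed pseudo-protein
  composition; real apoB composition differs from bulk liver protein.
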