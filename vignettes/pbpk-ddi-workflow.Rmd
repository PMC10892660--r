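---
title: "Methods: whole-body PBPK modeling of a CYP3A-mediated DDI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK modeling of a CYP3A-mediated DDI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model underlying `pbpkddi`: its structure
and assumptions, the parameters that matter and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions taken where more than one reasonable
construction existed.

## The problem

Saxagliptin, a DPP-4 inhibitor used in type-2 diabetes, is cleared in
part by CYP3A enzymes (CYP3A2 in rat; CYP3A4/5 in human) and in part
renally. Nicardipine, a calcium-channel blocker likely to be
co-prescribed in patients with diabetes and hypertension, is a potent
competitive CYP3A inhibitor that is itself cleared almost entirely by
the liver. The question the workflow answers is quantitative: by how
much does co-administration raise saxagliptin exposure, in rat — where
the interaction can be measured — and in human, where it must be
extrapolated? A dynamic whole-body model is needed because the
interaction is dominated by the absorption phase, when portal-blood and
liver concentrations of the inhibitor transiently exceed its Ki even
though systemic unbound concentrations never do; a static
`1 + [I]/Ki` screen based on systemic Cmax misses exactly this window.

## Whole-body model structure

Thirteen organs (lung, heart, brain, muscle, adipose, skin, bone,
liver, spleen, kidney, gut wall, gonads, rest-of-body) each carry four
states — vascular plasma, blood cells, interstitial and intracellular
space — plus arterial and venous blood pools, a gut lumen (stomach and
three small-intestine segments, each with dissolved and undissolved
drug), and cumulative bins (metabolized, urine, hepatic elimination,
feces). That is `4 × 13 + 16 = 68` states per compound; a DDI
co-simulation stacks two blocks and couples them only through the
inhibition term.

Blood flow runs venous pool → lung → arterial pool → organs → venous
pool, with gut and spleen draining into the liver (portal vein) and
the liver receiving its own hepatic-arterial flow. Plasma and
blood-cell phases are transported separately (hematocrit 0.45 by
default, overridable).

Sub-compartment exchange is written as permeability–surface-area (PS)
products acting on unbound-concentration differences, with the
partitioned side normalized so that at equilibrium total concentrations
satisfy the organ's Kp:

* plasma ↔ interstitial: PS = 1000/h per mL organ, divided by the
  plasma fraction unbound. The division makes the step
  binding-compensated: capillary endothelium outside the brain is
  fenestrated or discontinuous and equilibrates small molecules within
  seconds regardless of protein binding. Without this compensation a
  highly bound compound's tissue uptake would be limited by its binding
  rather than by any membrane, which for nicardipine (fu = 0.084)
  suppressed hepatic extraction roughly a hundredfold below the
  flow-limited behavior its published kinetics imply. The brain is not
  given a tighter barrier because neither study compound needs one;
  `k_endo_per_h` is overridable per model.
* plasma ↔ blood cells: 500/h per mL of cells, likewise
  binding-compensated, normalized by an erythrocyte partition
  coefficient computed from a fixed red-cell composition.
* interstitial ↔ intracellular: the compound's own cellular
  permeability times a cell surface-area density of 3000 cm² per mL of
  cell volume. This is the permeability-limited step of the model.

All exchange rate constants are capped at `1e5`/h; the cap is purely a
stiffness control and only binds for compounds whose permeability is
already far beyond rate-limiting.

## Partitioning

Tissue-to-plasma partition coefficients use a tissue-composition
scheme: the affinity of a phase mixture is
`f_water + P · f_lipid + 0.37 · f_protein` with `P = 10^logD7.4`, and
`Kp` is the tissue affinity over the affinity of an effective plasma
composition (96% water, 0.35% lipid, protein remainder chosen so the
plasma affinity is exactly 1 at `P = 1`). Using the distribution
coefficient at pH 7.4 folds ionization into the lipophilicity input;
all compartments are treated at pH 7.4 and no intracellular ion
trapping is added (a single basic pKa is carried on each compound for
completeness). The scheme's name is recorded in the result metadata and
any organ's Kp can be overridden verbatim, e.g. with values exported
from another platform. The same composition function supplies the
intracellular partition used by the exchange terms, approximating cell
composition by the organ's overall composition.

## Absorption

Oral doses enter the stomach (dissolved for solutions, undissolved for
tablets) and transit at first-order rates (gastric emptying 2.77/h;
three intestinal segments at 2.0/h rat, 0.9/h human — total
small-intestinal transit ≈ 1.5 h and 3.3 h respectively). Tablets
dissolve along a Weibull curve anchored at 50% dissolved at
`dissolution_time_min`; the anchor convention is recorded and
overridable. Absorption flux from each segment is
`Peff × surface area × dissolved lumen concentration`, into the gut
wall's intracellular space (so gut-wall CYP3A, at 7% of hepatic
relative expression, produces a first-pass contribution). Drug leaving
the last segment is collected in a feces bin. Effective segment surface
areas (240 cm² rat, 7300 cm² human) are bundled defaults representing
mucosal amplification of the cylindrical geometry; they set the
absorbed fraction together with the compound's specific intestinal
permeability. Lumen concentrations under the study doses stay far below
the compounds' solubilities, so dissolution, not solubility, limits
release.

## Clearance processes

* **Enzyme-mediated**: flux = `CLint,app × abundance × Cu_cell / 1000`
  nmol/min, with abundance = reference concentration (pmol/mg
  microsomal protein) × MPPGL (44.8 mg/g rat; 40 mg/g human) × organ
  mass × relative expression (liver 1, gut 0.07, kidney 0.01, lung
  0.005). Rat CYP3A2 at 101 pmol/mg; human CYP3A4/5 at 137/16 pmol/mg
  (standard literature averages, overridable). Metabolism is
  first-order throughout — no Michaelis–Menten saturation.
* **Renal**: a plasma clearance (mL/min/kg) applied to the kidney's
  arterial plasma inflow. Saxagliptin's rat value (38 mL/min/kg)
  exceeds GFR × fu, implying net secretion; the plasma-clearance
  formulation is agnostic to mechanism and, applied to inflowing
  arterial plasma, reproduces the measured clearance exactly without
  being capped by the kidney's own plasma flow.
* **Total hepatic half-life** (nicardipine): first-order loss of
  *total* liver intracellular drug at `ln 2 / t½` (0.62 min rat,
  4.5 min human). The alternative reading — first-order on *unbound*
  intracellular drug — was implemented first and rejected: for a
  compound this highly bound and lipophilic it predicts a systemic
  clearance two orders of magnitude below the flow-limited value that
  nicardipine's published exposure, half-life and high first-pass
  extraction all imply. The total-amount reading reproduces that
  flow-limited behavior directly.

Nicardipine's cellular permeability is carried as printed, 0.09 cm/s.
The alternative reading (0.09 × 10⁻⁶ cm/s, matching the unit of the
saxagliptin row) is selectable via
`read_compound(..., cellular_permeability_unit_hint = "1e-6 cm/s")`,
but is not the default: at 10⁻⁶ scale cellular uptake (≈1/h per mL of
cell water) would become the rate limit for a hepatic elimination
route with a sub-minute intracellular half-life, abolishing both
nicardipine's clearance and the interaction; the literal value is also
consistent with permeability scaling over the five-log-unit
lipophilicity difference to saxagliptin (13 × 10⁻⁶ cm/s at logD −0.7).

## DDI coupling

At every derivative evaluation the victim's enzyme-mediated intrinsic
clearance is rescaled by `1 / (1 + [I]/Ki)`. `[I]` is the
perpetrator's unbound concentration in the same compartment as the
enzyme (liver intracellular for hepatic routes, gut intracellular for
the gut-wall route) — the site-of-action choice; a systemic
`plasma_unbound` source is selectable for comparison with static
reasoning. In the human parameterization inhibition applies to CYP3A4
only (Ki 0.06 µM); CYP3A5 metabolism proceeds uninhibited. In rat a
single CYP3A2 route is inhibited at Ki 0.39 µM. Perpetrator kinetics
are simulated mechanistically in the same system, so the inhibition
window follows its absorption and first-pass profile.

## NCA, evaluation metrics, sensitivity, populations

NCA uses Cmax/Tmax by direct maximum, linear-up/log-down trapezoids
(pure linear selectable), λz by log-linear regression over the terminal
window maximizing adjusted R² (≥3 points, Tmax excluded, manual window
override), `AUC∞ = AUClast + Clast/λz`, and `CL/F = dose/AUC∞`.
Profiles without terminal decline yield flagged `NA`s rather than
guesses. Group summaries are arithmetic mean ± SD with an unpaired
two-sided t-test between two groups; degenerate (zero-variance)
comparisons are flagged with p = 1.

Model evaluation uses MRD (10 to the root-mean-square of log10
concentration residuals — the radical is part of the definition), GMFE
(10 to the mean absolute log10 parameter ratio), predicted/observed
fold classification with 1.25- and 2-fold bands symmetric in log space,
and the conventional adequacy thresholds MRD ≤ 2 and GMFE ≤ 2.

Local sensitivity is one-at-a-time forward perturbation (default +10%;
central differences optional) of dotted parameter paths
(`victim.clint.CYP3A2`, `perpetrator.ki.CYP3A2`,
`physiology.enzyme.CYP3A2`, …), reported as
`SC = (ΔPK/PK)/(Δp/p)` for the victim's Cmax and AUC∞ under
co-administration, ranked by |SC| with a 0.1 sensitivity threshold.

Monte-Carlo prediction intervals draw parameters lognormally with unit
median and user CVs (defaulting to the clearance, fraction-unbound and
dissolution parameters as the varied set — the literature means and
variances behind the original analysis are not published), re-simulate
per subject, and report empirical 2.5/97.5 percentiles; the level is
95% by default and the seed is recorded.

## Synthetic data

`generate_pk_study()` emulates the in vivo study design: per-subject
lognormal inter-individual variability applied through the same
parameter paths, simulation of the assigned arm, sampling on the
study's schedule (0.25–24 h), and residual error (10% proportional +
1 ng/mL additive by default — typical bioanalytical precision), with
optional LLOQ truncation (none by default). `generate_invitro()`
emulates the depletion (0/5/10/20/30 min, triplicate) and inhibition
(9 concentrations, 0–100 µM, triplicate, 0-µM control fixed at 100%)
designs. The generators produce clean parametric noise around the
model's own predictions: they do not emulate chromatographic raw
signals, matrix effects, correlated residuals, dropout, or
between-occasion variability. Recovery tests on these data therefore
demonstrate estimator correctness and pipeline integrity — not that the
model would fit arbitrary real data.

## Numerical choices

* Stiff solver (`deSolve::lsoda`), relative tolerance 1e-8, absolute
  tolerance 1e-10 nmol, fixed 0.01 h output grid; dose times are added
  to the grid and applied as events.
* The Weibull dissolution hazard is capped at 500/h (it diverges at
  t = 0 for shape < 1); the cap touches only the first fraction of a
  second of dissolution. With repeated tablet dosing the hazard clock
  restarts at the most recent oral dose — exact for single doses, an
  approximation if undissolved drug from an earlier tablet remains.
* Exchange rate constants capped at 1e5/h (stiffness control).
* Negative state excursions beyond 1e-6 of the largest state abort the
  simulation; mass balance (states + elimination bins vs cumulative
  dose) is checked in the test suite at 1e-6 relative and holds at
  machine precision.
* Test problem sizes: 24-h single-dose scenarios; property grids run at
  a coarser verified-equivalent solver setting (rtol 1e-6, 0.05 h
  grid); the virtual-study recovery uses 6/7/2 subjects and the
  Monte-Carlo checks 3–12 subjects. These sizes were chosen so the
  whole suite exercises every path in a few minutes on one CPU.

## Known limitations

* Organ-level physiology is a bundled open-literature compilation
  (reference rat 0.25 kg, human 70 kg, linear scaling in body weight);
  it is not asserted to equal any commercial platform's database, and
  acceptance of whole-model outputs is judged by the 2-fold adequacy
  band, not platform-exact replication.
* The composition-based Kp scheme is deliberately simple; for strongly
  lipophilic bases it tends to overestimate deep-tissue partitioning
  (long terminal phases) while leaving clearance-driven exposure
  largely unaffected. Per-organ overrides are the escape hatch.
* No transporters, no mechanism-based or time-dependent inhibition, no
  induction, no enterohepatic recycling, no lymphatic circulation, no
  saturable kinetics, no pediatric/disease populations.
* The dynamic DDI prediction is built from the single-drug models plus
  the in vitro Ki without refitting to co-administration data; it is
  expected to land within the 2-fold band of the reference interaction
  ratio, not to match it exactly.
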