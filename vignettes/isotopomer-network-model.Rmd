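---
title: "An isotopomer network model of 13C label propagation in the Krebs cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An isotopomer network model of 13C label propagation in the Krebs cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcatrace)
```

## The problem

When a uniformly ¹³C-labelled substrate is oxidised, its carbon enters the
Krebs cycle as [1,2-¹³C₂]acetyl-CoA. At isotopic steady state the
mass-isotopologue distributions (M+0 … M+n) of the cycle intermediates,
measured by LC–MS, are a function of a single unknown: the fraction α of
acetyl-CoA entering the cycle that carries the two-carbon label. `tcatrace`
computes that forward map exactly and inverts it by discrepancy
minimisation, converting α into the percent contribution of the labelled
substrate to acetyl-CoA production.

The forward map is not a simple dilution curve, for three positional
reasons:

1. **Positional CO₂ release.** The two carbons lost per turn (at isocitrate
   dehydrogenase and α-ketoglutarate dehydrogenase) are selected by
   position, indiscriminately of mass, and both derive from oxaloacetate —
   never from the acetyl unit that entered that turn (aconitase handles
   citrate stereospecifically; the Ogston effect).
2. **Symmetric-intermediate scrambling.** Succinate and fumarate are
   symmetric, so a labelled chain re-enters malate in either orientation
   with probability ½ each, randomising which labels survive later CO₂
   losses.
3. **Cyclic amplification.** Labelled oxaloacetate recombines with fresh
   (labelled or unlabelled) acetyl-CoA, so every mass shift from M+1 up to
   fully labelled appears over successive turns, even though a single turn
   adds at most 2 amu.

## Model structure

### Atom-transition table

The chemistry is data-driven: a table lists, per composed reaction step,
where each product carbon comes from (a numbered source carbon, or
`ACETYL_C1`/`ACETYL_C2`) and which source carbons leave as CO₂. Four steps
compose one turn over the four tracked intermediates — citrate,
α-ketoglutarate, succinate, malate. The untracked intermediates
(isocitrate, succinyl-CoA, fumarate, oxaloacetate) have labelling
distributions identical to a tracked neighbour and are folded into the
composed steps.

Positional conventions (the positions are bookkeeping slots, fixed once):
oxaloacetate o1 = carboxyl adjacent to the keto carbon, o2 = keto,
o3 = methylene, o4 = distal carboxyl; acetyl a1 = carbonyl, a2 = methyl;
citrate (c1…c6) = (a1, a2, o2, o3, o4, o1) with c6 the central carboxyl;
α-ketoglutarate (k1…k5) = (o4, o3, o2, a2, a1); succinate
(s1…s4) = (o3, o2, a2, a1); malate carries over to oxaloacetate unchanged.
This assignment is the unique one consistent with both positional CO₂
facts: label entering on oxaloacetate carbons 1,2 leaves (one carbon) at
isocitrate dehydrogenase, and label on carbons 3,4 leaves (one carbon) at
α-ketoglutarate dehydrogenase.

Scrambling is encoded as exactly one 50:50 orientation branch at the
succinate → malate step (chain identity vs chain reversal). Applying the
branch at both the succinate-forming and malate-forming steps would be
idempotent on the reachable set and the steady state; a single branch keeps
the matrices sparser. The acetyl alphabet is {0 amu, 2 amu} only — singly
labelled acetyl-CoA is not modelled, and neither are anaplerotic inflows
(pyruvate carboxylation), kinetic rate constants, or explicit back-fluxes;
the iteration index is a relaxation device, not physical time.

### State space

`enumerate_states()` closes the all-unlabelled starting pools under one
turn with both acetyl inputs and all branches. With the built-in table the
reachable space has **60** positional isotopomers (citrate 24,
α-ketoglutarate 16, succinate 8, malate 12); a brute-force reachability
filter over all 2⁶+2⁵+2⁴+2⁴ = 128 candidate bit-tuples, implemented
independently in the test suite, confirms the count. Conventions that
carry a larger state vector — a 78-isotopomer enumeration is in
circulation for this cycle — are not reproducible from the carbon-fate
rules above (for instance, malate isotopomers such as 0101, whose two
chain-end carbons differ and whose two middle carbons also differ, cannot
be formed from any succinate under identity or reversal). The package
therefore reports the enumerated count rather
than forcing agreement, and the table-driven design means an alternative
transition table producing a different state list can be loaded from YAML
without code changes — results are stamped with the table checksum so the
convention in force is always recorded.

Ordering is deterministic: metabolites in cycle order, then the bit-tuple
read as a binary number (carbon 1 most significant). Pool vectors are rows
updated by right-multiplication; each metabolite's slice sums to 1.

### Transition model and steady state

Two row-stochastic matrices are built over the state space — acetyl input
unlabelled and labelled — and combined linearly:
`M(α) = (1 − α)·M_unlabelled + α·M_labelled`. Only the malate → citrate
rows depend on α. One application is a synchronous update: each
metabolite's slice at time T is computed from its predecessor's slice at
T − 1.

The steady state is found by fixed-point iteration from the all-unlabelled
pool with tolerance `1e-12` (max-norm change per step) and a 10 000-step
cap. At this scale (60 states) a machine-precision fixed point costs
milliseconds, which removes tolerance sensitivity from the fits; an
eigen-solution would also work and is used as an independent cross-check in
the tests, not in the API. α = 0 and α = 1 run through the same code path;
their closed-form point masses (all-unlabelled / fully labelled) serve as
test oracles only. Because the update is contractive on the label history
(a surviving label must pass the o2/o3 lineage and the 50:50 scramble each
turn), convergence is geometric; the iteration count is reported on the
result.

### Isotopologue collapse and bifurcation scans

`collapse_isotopologues()` sums each metabolite's state fractions by label
count, giving the M+0…M+n proportions comparable to LC–MS measurements.
`bifurcation_scan()` evaluates the collapse on a regular α grid (default
step 0.001, matching the three-decimal precision at which α is reported
downstream). On that grid the model exhibits — and the tests assert — the
qualitative structure that makes the inverse problem well-posed: M+0
strictly decreasing in α, the fully labelled isotopologue strictly
increasing, and every intermediate isotopologue unimodal with an interior
peak, returning to 0 at α = 1. Only M+0 and the fully labelled channel are
monotone (hence individually invertible); the intermediate channels map one
proportion to two α values, which is why fitting uses the entire
distribution.

## Fitting α

`normalize_measurements()` converts raw peak areas to proportions per
replicate and metabolite, filling unobserved mass shifts with 0. No
natural-abundance correction is applied (and none is simulated): natural
abundance inflates the distributions by an unknown factor inversely related
to the unknown α, so correcting would presuppose the answer. Glutamate is
accepted as a proxy for α-ketoglutarate, with which it interconverts
rapidly. Mass shifts beyond a metabolite's carbon count are a hard error —
they indicate a mis-assigned metabolite — rather than being truncated
silently.

The discrepancy between predicted and observed distributions is the
total-variation distance `½·Σ|p_k − q_k|` averaged with equal weight over
the included metabolites. This is the simplest score that meets both design
anchors — 0 for a perfect fit, 1 for fully disjoint distributions, equal
weighting of all isotopologues — and it is a true metric, which the test
suite checks numerically. The comparison function is exposed
(`tv_distance()`, `discrepancy()`) so an alternative score can be
substituted.

Each replicate is fitted independently: a grid search over
α ∈ {0, `grid_step`, …, 1} (default step 0.001) followed by one
golden-section refinement inside the best grid bracket (absolute tolerance
10⁻⁷, deterministic, ties broken toward smaller α). Replicates are
summarised as mean ± SEM (sd/√n), mirroring per-replicate experimental
designs, and the contribution of a substrate with labelled fraction *f* is
`100·α̂/f`, flagged (not censored) when it exceeds 100%. Which metabolites
enter the fit is the analyst's decision via `included_metabolites`; the
typical reason to drop citrate is that heavy labelling pushes 6+ amu
citrate beyond the detection range, and no numeric threshold exists for
automating that call.

## Synthetic data and the Monte-Carlo oracle

`generate_measurements()` emulates the shape of real inputs: steady-state
proportions at a true α scaled to a total peak area (default 10⁶ arbitrary
units) and perturbed with independent multiplicative log-normal noise per
bin, mean 1, coefficient of variation `noise_cv`. The defaults —
`noise_cv = 0.05`, `n_replicates = 3` — match the replicate structure and a
realistic peak-area CV for the validation experiments the model is used
in. Log-normal noise is a fixture choice (peak areas are positive and
roughly CV-stable), not a claim about any instrument: real data add
natural-abundance structure, correlated ionisation drift, and occasional
missing channels that the generator deliberately does not emulate, so
passing recovery tests demonstrate the inverse problem is well-conditioned
under honest noise, not that every instrument artefact is handled.
Replicates draw from per-replicate substreams derived from one seed, so
tables are byte-identical across runs.

`simulate_molecules()` is the independent oracle for the matrix
formulation: it tracks a cohort of individual molecules through full
turns, sampling the acetyl label and each 50:50 branch per molecule, using
only direct bit-vector operations on the transition table (none of the
enumeration or matrix code). Snapshots are taken at each metabolite stage
of the final turn; with 10⁵ molecules and 200 turns the empirical
distributions agree with the matrix steady state to within total-variation
distance 0.01 per metabolite in the acceptance checks (typically ≲ 0.003).

## Problem sizes and numerical choices

The shipped test and acceptance workloads use: the 0.001 α grid (1001
steady states, each converging in ~100–300 iterations); Monte-Carlo runs of
10⁵ molecules × 200 turns at α ∈ {0.25, 0.5, 0.75}; noiseless recovery at
19 true α values × 5 metabolite-inclusion sets; and 20 seeded noisy
datasets (3 replicates, 5% CV) at α = 0.145. These sizes were chosen so the
recovery experiments estimate bias well below the 0.001 grid resolution
while the full suite completes in minutes on a laptop.

Degenerate inputs are handled explicitly: all-zero metabolites are
rejected by name; empty inclusion sets, out-of-range fractions and
non-converged iterations raise errors carrying the residual; grid ties
resolve toward smaller α so fits are reproducible bit-for-bit.

## Known limitations

* No anaplerosis: significant pyruvate-carboxylase flux adds 3+ amu
  weight the model cannot produce, which shows up as an elevated
  discrepancy score rather than a biased α.
* Acetyl-CoA is assumed 0- or 2-labelled; partially labelled acetyl units
  (e.g. from label recycling) are outside the alphabet.
* The model describes relative distributions at isotopic steady state
  only; it says nothing about absolute fluxes or time-to-steady-state.
* Raw peak areas are compared without natural-abundance correction, so
  fitted α values absorb a small natural-abundance component exactly as
  the measured data do.
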