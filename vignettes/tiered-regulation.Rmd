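---
title: "Tiered regulation of metabolic flux: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered regulation of metabolic flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`fluxtier` asks, for each reaction of a constraint-based metabolic
model, *at which level its flux is regulated* when a cell moves between
growth conditions: transcription (TR), translation (TL),
post-translational modification (PTL), or only indirectly (IR), through
the stoichiometric coupling of its flux to directly regulated reactions.

The underlying flux model is the standard steady-state constraint set:
mass balance `S v = 0` plus finite bounds `v_min <= v <= v_max`.
Condition-specific information enters only through discretized omics:
per sample, each measurement set (all genes' expression; all covered
proteins) is split into tertiles, giving activity levels −1/0/+1.
Protein evidence takes precedence over transcript for covered genes,
except when the two disagree by two levels (+1 vs −1), in which case the
gene is left *unconstrained* — forcing a flux either way on such
contradictory evidence would bias the prediction. Gene levels map to
reactions through Boolean GPR rules, evaluated as min (AND) / max (OR);
an unconstrained gene is propagated with interval semantics: the rule is
evaluated with the gene at −1 and at +1, and the reaction is
unconstrained when the two evaluations differ. This is exact, not a
heuristic.

## Flux prediction

Per condition, reactions whose merged state is +1 (−1) across the
majority of the condition's samples form the high (low) set of an
iMAT-style mixed-integer program: maximise the number of high reactions
carrying at least `epsilon` flux in some direction plus low reactions
within `delta` of zero, subject to `S v = 0` and bounds. The
linearization uses two binaries per high reaction (forward / backward
activation, with big-M constants derived from the bounds) and one binary
per low reaction. The optimum is found by branch-and-bound over an
exact dense-simplex LP relaxation (no LP/MILP backend is assumed; both
solvers are part of the package and the MILP is verified against
exhaustive satisfaction-pattern enumeration in the test suite).

One optimal activity pattern is then fixed into the bounds — satisfied
high reactions keep the direction the optimum chose, which makes the
region convex — and the polytope is sampled with artificial-centering
hit-and-run. The chain runs in an orthonormal null-space basis of `S`,
so every retained sample satisfies mass balance to machine precision;
warmup points are the per-reaction FBA extrema (2n points), the center
is the running mean of visited states, and 100 chain steps separate
retained samples (2,000 samples by default). The sample mean
approximates the condition's flux distribution. iMAT optima are not
unique; the package samples the polytope of exactly one optimum and
records the satisfaction pattern for audit.

## Tier assignment

Reactions are classed per condition by tertiles of |mean flux| (sign is
ignored so a reversible reaction running backwards counts as active).
The assignment is hierarchical and mutually exclusive:

* **TR** — flux class equals the transcript-derived reaction state in at
  least 3 of the condition's 4 replicate samples; the subtype is the
  flux class (TR-high / TR-moderate / TR-low).
* **TL** — not TR, and the protein-derived state matches by the same
  3-of-4 rule; TL-up (TL-down) when the flux/protein class sits above
  (below) the transcript class.
* **PTL** — not TR or TL anywhere, at least one mapped phosphosite, and
  some site's mean intensity series correlates with the predicted flux
  series across the condition × timepoint points with |rho| > 0.6 and
  p < 0.05. The permutation p-value is exact for n ≤ 9 (enumeration of
  all distinct rank arrangements); correlation sign gives the direction
  (activating / inhibiting). No multiple-testing correction is applied
  inside this screen — it is a raw significance filter; the global FDR
  utilities are available separately.
* **SVM extension** — five one-vs-rest SVMs (quadratic polynomial
  kernel, cost 1, class-weight balancing, standardization learned on
  training folds only) trained on the step-1 labels over 13 features:
  reaction-level expression at the 4 samples, predicted flux at 4
  points, reversibility, an integer pathway index, and metabolite /
  substrate / product counts. The pathway index is kept as a single
  ordinal integer for fidelity to the feature list despite its
  statistical awkwardness. A class with fewer than 10 positives is
  skipped. An unassigned reaction is predicted only when exactly one
  classifier fires. Classifiers are trained per condition; on the toy
  network some classes fall below the positive minimum and are skipped —
  the feature-level simulator (`simulate_feature_table`) exercises all
  five at n = 200.
* **IR** — everything left.

## Coupling analysis

Stoichiometric coupling between two reactions is the absolute Spearman
correlation of their fluxes across the ACHR samples (the same sample
sets used for flux prediction; constant-flux reactions are flagged
undefined and excluded, not imputed). Group comparisons use a one-sided
Wilcoxon rank-sum test over all between-group versus within-group
coupling values; bidirectionality enrichment is a hypergeometric upper
tail.

# The synthetic-data generator

The generator emulates the study design the pipeline targets: 3 growth
conditions × 2 timepoints × 2 replicates, full-coverage transcriptomics
(200 genes), partial proteomics (35% of genes), ~15 phosphosites and 10
"measured" fluxes on central-carbon reactions. The toy network (44
reactions, 8 subsystems, 27% bidirectional) contains a glycolysis-like
chain, a pentose-phosphate-like branch, a TCA-like cycle with
anaplerotic shunts, glutaminolysis, lipid and serine branches, and a
second carbon source (pyruvate uptake) so conditions can genuinely
rotate which pathway is active. Pathway capacity bounds are tiered so
that activity classes are separated in magnitude.

The generator works backwards from the analysis: condition profiles
(which pathways are active where) pose iMAT problems with the package's
own machinery, the sampled mean fluxes define activity classes, and
labels are planted compatibly with those classes. Iteration continues
until the emitted world is self-consistent: the activity states the
pipeline will derive from the omics are exactly the states that produced
the truth fluxes, and every label's class is reproduced under a second
independent sampler seed. Labels whose class structure the realized
fluxes cannot support are demoted to IR rather than forced.

Intensities are written on the log2 scale with additive Gaussian noise
(`noise_sd`, default 0.1 — the measurement platforms' noise is not a
published quantity; this is a simulation knob, and the recovery
thresholds are stated at given noise levels). Activity levels map to
anchors 6/8/10 (base 8, step 2), and background genes balance each
sample's tertile counts exactly, so discretization recovers the planted
levels one-to-one at zero noise. TR genes track the flux class at both
transcript and protein level; TL genes track it only at the protein
level, with the transcript shifted one level (up or down); PTL genes are
flat moderate in both layers while a phosphosite tracks the truth flux
series exactly (Spearman ±1 before noise); IR and background genes are
flat moderate. Both timepoints share a condition's flux distribution —
the flux prediction is per condition — so timepoints differ only in
noise.

Design choices worth flagging:

* **A fixed experimental design.** The planted design (labels, truth
  fluxes) derives from a dedicated `design_seed`, fixed by default;
  the `seed` argument varies measurement noise, coverage and decoys.
  Replicate datasets thus share one ground truth and differ as repeated
  measurements would.
* **PTL eligibility.** A PTL reaction is unconstrained in the flux
  prediction (its omics are uninformative), so its activity class must
  be held by the network: the generator only plants PTL on reactions
  whose class is never moderate, whose condition means are separated by
  more than 1 flux unit (so the 6-point rank order is reproducible
  across sampler seeds), and which either run free already or sit in a
  conservation-locked group whose other members are directly
  constrained. On the default design this yields a single PTL reaction;
  the screen's machinery is additionally exercised on constructed series
  in the unit tests.
* **Planted coupling structure.** One member of every pathway chain —
  preferentially a bidirectional one, mirroring the expectation that
  indirect reactions are enriched for reversibility — is reserved as IR
  and never labeled. These reserved reactions are conservation-coupled
  to the direct drivers of their own chain but spread across chains, so
  indirect-to-driver coupling exceeds indirect-to-indirect coupling by
  construction. `coupling_structure_experiment()` measures exactly this
  in the fully profile-constrained world, pooling the three conditions
  into one rank-sum test. On the *pipeline's* default dataset the same
  comparison is directionally positive but not significant: with ~40
  reactions the bulk of reaction pairs is uncoupled on both sides, and
  a pair-level rank-sum cannot resolve the shift that a genome-scale
  network (millions of pairs) resolves easily. The experiment isolates
  the structural claim at the scale where it is testable.
* **Tertile ties.** Values equal to within 1e-8 are treated as tied in
  the discretizer: conservation-locked reactions carry identical flux in
  every sample, and their means differ only by float rounding; the tie
  rule (a tie group straddling a tertile boundary is wholly moderate)
  then fires deterministically in both the generator and the pipeline.
* **What passing tests do not show.** The generator's omics are
  anchor-structured with homoscedastic noise, its proteomics coverage is
  balanced by construction, and its network is small and modular. Real
  data have uneven coverage, correlated noise, batch structure and far
  denser coupling; recovery rates here validate the machinery, not the
  biology of any particular dataset.

# Numerical choices

* Feasibility tolerance 1e-6 flux units throughout; simplex pivot
  tolerance 1e-9 with a Bland-rule fallback against cycling.
* Infinite model bounds are clamped to ±1000 at load (keeps the big-M
  constants finite); reversibility is defined from the bounds, not from
  SBML flags, and the bounds win when the two disagree.
* iMAT defaults ε = 1, δ = 1e-4 (exposed in the configs; no published
  values exist for them).
* ACHR: 2n warmup extrema, running-mean centering, thinning 100,
  2,000 retained samples per condition. These sizes keep a full
  synthetic run around a minute on one core while making the Monte-Carlo
  error of mean fluxes small against the class separation; all are
  config-exposed.
* Unmeasured genes are dropped under OR and under AND (unless all are
  missing, which leaves the rule uninformative) — the treatment of
  unmeasured enzymes as unconstrained.
* Tertile splits at positions ⌈n/3⌉ and n−⌈n/3⌉ with the tie rule
  above; the boundary-tie behaviour is a repo decision, as no published
  tie-breaking rule exists.
* The FDR utility implements the literal per-index filter
  (keep p_i ≤ (i/n)·α at its sorted index) by default, with standard
  Benjamini–Hochberg step-up behind a flag; the literal rule's kept set
  is provably a subset of the step-up set.

# Known limitations

* The MILP solver is exact but dense; it is sized for toy and mid-sized
  models, not genome-scale reconstructions with thousands of reactions.
* Only one iMAT optimum is sampled; alternate optima are acknowledged
  but not enumerated.
* The PTL screen has no kinase or site-function model; a correlated
  decoy site can produce a false positive at the raw p < 0.05 gate.
* Per-condition SVM training on a small model leaves most classifiers
  below the positive minimum; pooling conditions is available but not
  the default.
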