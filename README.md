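# fluxtier

Tiered-regulation analysis of metabolic networks from multi-omics data.

Cancer cells reroute metabolic flux between growth conditions, but the
flux through a reaction can be set at several levels: by transcription of
the catalysing genes, by translation (protein abundance diverging from
mRNA), by post-translational modification (phosphorylation of the
enzyme), or only indirectly, through the stoichiometric coupling of the
reaction to the rest of the network. `fluxtier` implements a four-step
pipeline that assigns each reaction of a constraint-based metabolic model
to one of these tiers by confronting predicted fluxes with discretized
omics layers, and ships a synthetic-data generator with planted ground
truth so that every step can be validated end to end.

## The method

A metabolic network with *m* metabolites and *n* reactions is a
stoichiometric matrix *S* with flux bounds; feasible steady states
satisfy *S·v = 0*, *v*<sub>min</sub> ≤ *v* ≤ *v*<sub>max</sub>.
Per growth condition the pipeline:

1. **Discretizes omics.** Expression and protein intensities are split
   into tertiles per sample (−1 / 0 / +1); protein evidence overrides
   transcript except on hard disagreement (+1 vs −1), which leaves the
   gene unconstrained. Gene states map to reactions through Boolean
   gene–protein–reaction rules (OR → max, AND → min), with unconstrained
   states propagated by interval semantics.
2. **Predicts fluxes (iMAT).** A mixed-integer program maximises the
   number of reactions whose flux agrees with their state (active:
   |v| ≥ ε; inactive: |v| ≤ δ) subject to mass balance and bounds. The
   optimal activity pattern is fixed into the bounds and the resulting
   convex polytope is sampled with artificial-centering hit-and-run
   (2,000 samples); the sample mean approximates the condition's flux
   distribution.
3. **Assigns tiers.** Reactions are classed by |mean flux| tertiles per
   condition. A reaction is **TR** (transcriptionally regulated) when
   its flux class matches its transcript-derived state in ≥3 of the 4
   replicate samples; among the rest, **TL** when the protein-derived
   state matches (TL-up/-down by the transcript disparity); among the
   rest, **PTL** when a mapped phosphosite's intensity series correlates
   with the predicted flux series across conditions and timepoints
   (|Spearman ρ| > 0.6, p < 0.05, exact permutation p at small n).
   Five one-vs-rest SVMs (quadratic kernel, 13 features) extend TR/TL
   labels to reactions that omics coverage left unassigned; a reaction
   is predicted only when exactly one classifier fires.
4. **Analyses coupling.** Pairwise stoichiometric coupling is the
   absolute Spearman correlation of sampled fluxes; the remaining
   indirectly regulated (IR) reactions are tested for preferential
   coupling to direct drivers (one-sided rank-sum) and for enrichment in
   bidirectional reactions (hypergeometric).

## Worked example

```r
library(fluxtier)
report <- run_pipeline(pipeline_config(
  sim = simulation_config(seed = 1, noise_sd = 0.1), seed = 7))
print(report)
```

```
tiered-regulation pipeline report
conditions: c1, c2, c3 
label counts per condition:
           c1 c2 c3
TR         20 19 19
TL          5  5  5
PTL         1  1  1
SVM         2  1  8
unassigned 16 18 11
measured-flux validation: rho = 0.987 (n = 30, p = 9.1e-24)
planted-label recovery: TR 1.00 | TL 1.00 | PTL 1.00
```

Each column is one synthetic growth condition; rows count reactions per
regulatory tier (44 reactions total, counts sum to the model size). The
validation line is the Spearman correlation between predicted mean
fluxes and the simulated "measured" fluxes pooled over conditions; the
recovery line compares assigned tiers against the generator's planted
ground truth. `report$coupling` holds the per-condition coupling
matrices and group comparisons, `report$enrichment` the pathway
enrichment of the TR sets.

A thin command-line front end is included:

```sh
Rscript inst/cli/fluxtier.R simulate --seed 1 --out data_dir
Rscript inst/cli/fluxtier.R run --seed 1 --noise 0.1 --out out_dir
Rscript inst/cli/fluxtier.R validate --model inst/extdata/toy_model.json
```

Models are read from SBML Level 3 (fbc) or a JSON dialect that mirrors
the SBML content field-for-field (see `inst/extdata/toy_model.json`).

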