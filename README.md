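# srnareg

Kinetic modelling and global sensitivity analysis of bacterial
sRNA-mediated post-transcriptional regulation.

Small regulatory RNAs (sRNAs) repress — and occasionally activate — their
target genes by base-pairing with the mRNA, often while it is still being
transcribed. Whether a given sRNA/target pair ends up as a strong
repressor, a weak one, or an activator depends on the interplay of binding
kinetics, RNA stabilities, cotranscriptional termination and translation
rates. `srnareg` is for systems and synthetic biologists who want to
explore that parameter space quantitatively: it implements the mass-action
reaction network, computes its steady states fast enough for
variance-based sensitivity analysis at scale, simulates induction
time-courses, and validates parameter identifiability on synthetic data.

## The model in brief

Seven species — precursor mRNA, mature mRNA, their sRNA complexes, a
truncated (terminated) complex, free sRNA, and protein — evolve under mass
action with 13 rate constants. Transcription is split into initiation
(k_init) and elongation (k_elon), so the sRNA can bind the nascent
precursor (k_on/k_off). A bound precursor is either elongated into a
mature repressed complex, co-degraded (β_ms), or prematurely
terminated/processed at the lumped rate k_coreg; the sRNA can be recycled
from the terminated complex by dissociation. Protein is translated at k_m
from free mature mRNA and k_ms from the complex.

The central read-out is the **protein regulation strength**

> log2( p\*_scenario / p\*_(k_on = 0) )

the steady-state protein level relative to the same cell with sRNA binding
switched off; negative values mean repression. The steady state is
computed by reducing the system to a monotone scalar equation in the free
sRNA level and bisecting its bracket — exact to machine precision,
vectorized over parameter matrices, and cross-checked against stiff ODE
integration in the test suite. Sobol sensitivity indices (Saltelli S1 /
Jansen ST estimators on a Saltelli A/B/AB design, bootstrap confidence
intervals) quantify which rate constants control regulation strength
across the physiological parameter box.

## Worked example

```r
library(srnareg)

## steady-state regulation at the reference (SgrS/ptsG-like) parameters
regulation_strength(default_params())
#> <regulation_result> log2(p/p0) = -1.0340 (repression)
#>   p_scenario = 2.035e+07 AU, p_baseline = 4.167e+07 AU
```

At the reference defaults the sRNA halves protein output (log2 ratio
−1.03, i.e. ~2-fold repression; protein is in arbitrary units).

```r
## which parameters control regulation strength?
d   <- saltelli_design(n_base = 1024, seed = 1)   # 15,360 evaluations
idx <- sobol_indices(d, evaluate_design(d))
head(idx[order(-idx$ST), c("parameter", "S1", "ST")], 5)
#>    parameter     S1    ST
#> 4       k_on 0.2872 0.598
#> 6    k_coreg 0.0388 0.191
#> 5      k_off 0.0684 0.157
#> 12       k_m 0.0466 0.129
#> 3    alpha_s 0.0294 0.127
```

The association rate k_on dominates both directly (S1) and overall (ST);
most other influential parameters act mainly through interactions
(ST >> S1). The output distribution over the sampled box is peaked near
zero and skewed toward repression (`mean(evaluate_design(d)) < 0`).

```r
## parameter recovery from a noisy synthetic induction experiment
ds <- generate_synthetic(default_params(), noise_cv = 0.1, seed = 7)
recover_parameter(ds, "k_on", bounds = c(2.2e-4, 2.2e-2), n_grid = 9)
#> <srna_recovery> k_on = 0.00162084 (objective 0.4093)
```

A single noisy 13-point time course (10% multiplicative noise) recovers
the true k_on = 0.0022 to within ~26% here; across replicates the median
error stays well under 20%.

Induction time-courses for the four mechanistic scenarios (`full`,
`no_recycling`, `translation_only`, `stability_translation`) come from
`simulate_scenario()`; `observe()` collapses them to the experimentally
visible totals (free + complexed molecules). Pipeline wrappers
(`run_steady()`, `run_simulate()`, `run_gsa()`, `run_generate_recover()`,
`run_report()`) write TSV/JSON artifacts plus a full configuration echo; a
thin command-line wrapper lives at `inst/scripts/srnareg.R`.

See the vignette (`vignettes/srna-regulation-model.Rmd`) for the model
assumptions, solver numerics and design choices.

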