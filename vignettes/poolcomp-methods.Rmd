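---
title: "Models and methods behind poolcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcomp)
library(dplyr)
```

poolcomp analyses long-term pooled competition experiments in which a few
hundred barcoded yeast strains are propagated together under serial
dilution, their relative abundances tracked by amplicon sequencing of the
barcodes, and the eventual winners characterised genomically and
phenotypically. This vignette explains the models the package implements,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were open.

## The serial-dilution competition model

A pool is propagated in batch culture with a 1:250 dilution every transfer.
Each dilution-regrowth cycle corresponds to `log2(250) ≈ 7.97`, i.e.
`g = 8` doublings, which is the package-wide default for converting
transfers to generations (23 transfers = 184 generations, 10 transfers =
80). We deliberately standardise on `g = 8` everywhere rather than mixing
rounded and unrounded values; at 91 transfers this gives 728 generations,
comfortably above 700.

`simulate_competition()` summarises each cycle as deterministic selection
followed by a bottleneck:

1. **Selection.** Lineage frequencies update as
   \(f_i \leftarrow f_i e^{g s_i} / \sum_j f_j e^{g s_j}\), where \(s_i\)
   is the per-generation selection coefficient in natural-log units.
   There is no within-cycle model of lag, exponential and saturation
   phases; selection is integrated per cycle. Frequency-dependent fitness
   is intentionally out of scope.
2. **Drift.** If the bottleneck (cells transferred) is finite, the next
   cycle's founding frequencies are a multinomial sample of that many
   cells. The default of \(10^5\) cells is a desk-scale choice that makes
   drift visible in tests while keeping simulations fast; the experiment
   this emulates transfers vastly more cells, and the true effective
   bottleneck is not known, so the parameter is explicit and configurable.
   `bottleneck = Inf` gives the deterministic replicator dynamics used as
   a closed-form oracle in the tests.
3. **Adaptation.** With probability `mutation_rate` per lineage per
   transfer, a lineage founds a beneficial sublineage at frequency
   `1/bottleneck` whose fitness is the parent's plus an exponential
   increment with mean `dfe_mean` (default 0.05). Sublineages are tracked
   internally, but every observable output aggregates them by founding
   barcode, because barcodes — not mutations — are what sequencing reads.

The default wild-strain fitness distribution (`fitness_mixture()`) is a
normal bulk (sd 0.03 per generation) with a 5% exponential right tail
(mean 0.05): pooled natural isolates typically contain many
near-equivalent strains plus a few large-effect outliers, and observed
fitness distributions vary between environments with flatter and more
spiked tails. The exact shape is not critical to any inference; it only
sets the difficulty of the recovery tests.

## The observation model and fitness inference

Sequencing reads for barcode \(b\) at timepoint \(t\) are modelled as
negative binomial with mean \(f_b(t) R_t\) and variance
\(\kappa_t f_b(t) R_t\), where \(R_t\) is the sample's total read count
and \(\kappa_t \ge 1\) the dispersion (\(\kappa = 1\) is Poisson).
`sample_reads()` implements exactly this model via the Gamma–Poisson
construction, so simulation and inference share one likelihood — which is
what makes parameter-recovery experiments meaningful. Dispersion is
applied per timepoint, not per barcode, mirroring the inference side,
which estimates a single noise level per sample from the reference
barcodes.

Six barcoded copies of a neutral laboratory reference strain are spiked
into the pool at a combined 10% (a 9:1 wild:reference mix). They anchor
the analysis twice:

* **Mean fitness.** The reference has fitness 0 by definition, so the
  decay of its summed frequency measures the population mean fitness:
  \(\bar{x} = \ln(F_{ref}(t)/F_{ref}(t')) / (g\,(t'-t))\) per interval
  (`estimate_mean_fitness()`). Anchoring on the reference, rather than
  iterating a self-consistent mean over all lineages, is both what the
  underlying experimental method defines and what breaks the model's
  gauge freedom: adding a constant to every fitness and to \(\bar{x}\)
  leaves the likelihood unchanged, so only reference-relative values are
  identifiable. The test suite verifies this invariance explicitly.
* **Noise.** The reference barcodes are biologically identical, so the
  variance of their per-interval log frequency changes beyond counting
  noise estimates \(\kappa\) (`estimate_dispersion()`): deviations are
  centred on their median and divided by the expected Poisson
  contribution \(\mathrm{mean}_i(1/r_i(t) + 1/r_i(t'))\), floored at 1.
  This deviation-variance estimator is the package's own construction —
  the source method states only that noise is inferred from the reference
  barcodes — and it is calibrated by simulation in the tests (true
  \(\kappa = 4\) recovered within [2.5, 6] over 100 replicates).

`infer_fitness()` then maximises, per barcode, the negative-binomial
likelihood of the whole early trajectory over \((s, f_0)\), with
predicted frequencies
\(f(t_k) = f_0 \exp(g \sum_{j<k}(t_{j+1}-t_j)(s - \bar{x}_j))\).
Numerical choices:

* Optimiser: bounded quasi-Newton (`L-BFGS-B`) on \((s, \log f_0)\),
  bounds \(s \in [-2, 2]\), started from a log-linear regression of
  pseudocounted frequencies on cumulative generations. A finite-difference
  step of \(10^{-6}\) is used for the gradient; the default step is too
  coarse when the regression start already sits near the optimum.
* The initial-guess regression uses pseudocounted frequencies
  (pseudocount 0.5) so zeros are finite; the final likelihood uses raw
  counts.
* Predicted means are clipped below at \(10^{-12} R_t\) to keep the log
  pmf finite.
* Standard errors come from the observed-information diagonal (numerical
  Hessian at the optimum). Over simulated pools, \(\hat{s} \pm 2\,SE\)
  covers the truth for ~90–95% of barcodes.
* Barcodes with all-zero counts in the window are flagged `extinct`;
  optimiser failures are flagged but retain the regression start.

The default fit window is the first six timepoints (transfers 0–5): early
enough that frequency changes reflect standing fitness rather than de
novo adaptation. For later intervals, where sweeps and clonal
interference violate the constant-\(s\) model, `interval_fitness()`
reports the plain log fold change of frequency between two timepoints
(and its per-generation rate), conditioned on non-extinction. Both the
raw change and the rate are emitted because either convention is defensible;
users pick one axis.

With 20 experimental replicates there is a choice between pooling the
likelihood across replicates and combining per-replicate estimates.
`infer_fitness()` fits per replicate (replicates genuinely differ —
different bottenecks of drift, different adaptive events) and
`pool_estimates()` combines them as an inverse-variance-weighted mean,
reporting the unweighted mean alongside.

## Trajectory analytics

* `n99()`/`diversity_series()`: the minimal number of strains whose
  summed frequency reaches 99% — a diversity summary robust to the long
  tail of near-extinct lineages.
* `call_finalists()`: a strain is a finalist if its frequency is ≥ 1% (the
  comparison is inclusive) in at least one replicate at that replicate's
  own last available timepoint — replicates end at different transfers,
  so the rule is evaluated per replicate.
* `top_percentile_set()`: membership in the top fitness percentile uses
  the linear-interpolation quantile (R's default type 7); the method is
  recorded because no convention was prescribed. The percentile is
  computed over all strains with a defined estimate, not only those
  surviving the window — the more inclusive reading.
* `replicate_cv()` uses the sample (n−1) standard deviation.

## Evolved-clone genomics

`filter_variants()` applies, in order: multiallelic removal; removal of
sites that cannot be confidently called in the ancestor; per-record depth
(keep \(5 \le DP \le 2\times\) the sample median — exactly double is
kept, strictly more is removed); genotype quality (keep \(GQ \ge 99\));
and a BED blacklist (mitochondria, telomeres, rDNA, mobile elements,
centromeres, pseudogenes). Each removed record is attributed to the first
rule that caught it, so the filter report is additive. "Cannot be
confidently called in the ancestor" is not an operational definition by
itself; the package operationalises it as the ancestor record failing the
same GQ/depth thresholds or lacking a genotype, and treats it as a
site-level removal.

`classify_variants()` works on alt-allele fractions computed from allele
depths, not genotype calls, because the decision thresholds are stated on
allelic frequency. With `a` the focal clone's fraction and "outside" the
ancestor plus all other clones: `de_novo_het` when \(a \in [0.2, 0.8]\)
(closed) and every outside sample is < 0.2 or > 0.8; `de_novo_hom` when
the focal clone is extreme on the opposite side of all outside samples;
`LOH` when the focal clone is extreme while every outside sample lies
strictly inside (0.2, 0.8). The boundary conventions (closed focal
interval for heterozygous calls, strict interval for LOH) are recorded in
the output's `conventions` attribute since "<" versus "≤" is otherwise
ambiguous. Triploid ancestors need no special casing: expected
heterozygous fractions of 1/3 and 2/3 fall inside (0.2, 0.8). For LOH
events only the resolved allele (reference or alternate homozygote) is
reported; whether the triploid reached it in one or two steps is not
distinguishable from a single genome.

`tally_parallel_genes()` counts clones (not variants) per gene and
(ancestral strain, environment) group, restricted by default to
frameshift and nonsense annotations — the high-impact classes in which
gene-level convergence is detectable against the background of long LOH
tracts. `compare_loh_direction()` labels coincident LOH at a locus as
convergent, divergent or mixed across two groups of clones.

## Karyotyping from read depth

`coverage_profile()` consumes a complete per-base depth table (the
`samtools depth -a` dialect) and computes per-chromosome medians, the
genome median and 1-kb bin means. `call_karyotype()` divides each
chromosome's median by the genome median and rounds to the nearest 0.5
(`round(2x)/2`, exact halves away from zero — "nearest 0.5" does not fix
the tie direction, so the choice is documented); samples whose genome
median is 6 or below are flagged ineligible, the threshold being strictly
"more than six". Mitochondrial and plasmid contigs should be passed via
`exclude` so their copy number does not distort the genome median.

`call_segments()` is invented plumbing: large segmental amplifications
are marked in the source material without a stated method, so the package
uses a transparent run-length rule — at least 20 consecutive 1-kb bins
deviating from the chromosome's baseline ratio by at least 0.4 — with
both parameters exposed. This detects the events of interest (tens of kb
at half-integer copy ratios) and deliberately attempts nothing subtler
(no GC correction, no subclonal mixtures).

## Cytometry and plate phenotypes

Competition assays against a GFP-labelled reference are analysed as:
singlet gating on the forward-scatter area/height ratio in [0.9, 1.03]
(inclusive); a fluorescence threshold calibrated on 100%-GFP and
100%-dark control cultures by minimising their total misclassification
(midpoint of the optimal interval under perfect separation; controls that
separate better with the opposite orientation are rejected as swapped,
and residual misclassification above 40% is rejected as inseparable);
the dark fraction of each sample (flagged below 10,000 events); and
relative fitness as the difference of trapezoid areas under the
dark-fraction-versus-time curves of clone and ancestor. The difference
(not ratio) of AUCs is used so the measure is antisymmetric and zero for
identical series. Threshold calibration uses the fluorescence channel
alone by default; a combined scatter/fluorescence rectangular gate would
need a combining rule that was never specified.

The flocculation score is
\(1 - (OD_{top} - OD_{blank}) / (0.8\,(OD_{bottom} - OD_{blank}))\).
The printed formula's operator precedence is ambiguous; the package reads
0.8 as scaling the denominator, so that a non-flocculant whose top
fraction retains 80% of the bottom density scores 0, and exposes the
alternative reading (`precedence = "product"`) behind a flag with the
choice recorded in the result. Ploidy is classified on the linear scale
defined by haploid and diploid DNA-stain controls, with integer classes
split at midpoints; above 2.5 control units the call is simply "higher".

## What the generator does and does not emulate

`make_pool()` / `simulate_competition()` / `sample_reads()` reproduce the
statistical structure the inference assumes: a 9:1 wild:reference pool of
~300 barcodes, 8 generations per transfer, multinomial drift, occasional
large-effect sublineages, and negative-binomial counts with per-timepoint
dispersion. They do not emulate batch effects between media batches,
PCR-jackpot artefacts beyond the NB dispersion, index cross-talk,
chimeric reads, frequency-dependent interactions, or mating/contamination
— so passing recovery tests demonstrates correctness of the estimators
under the stated model, not robustness to every failure mode of the real
assay. Likewise `make_clone_genomes()` plants events on a scaled-down
genome with uniform background depth — there is no GC bias, mappability
structure or repeat content — and `make_cytometry_events()` draws
two-component log-normal fluorescence with a geometric doublet model.
Stand-ins are synthetic and labelled as such.

## Problem sizes used in the checks

The bundled tests and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes while keeping every estimator in
its asymptotic regime: a 300-strain pool sequenced at \(10^6\) reads per
timepoint with \(\kappa = 2\) over 6 timepoints for fitness recovery
(RMSE ≤ 0.01 per generation for strains with \(f_0 \ge 10^{-4}\));
deterministic dynamics for the finalist/replicator equivalence over 20
seeds; clone genomes of 0.5–1 Mb over 4 chromosomes at 10–30× depth for
variant and karyotype recovery; and \(10^4\)–\(10^5\) events for
cytometry. Fitness recovery uses an infinite bottleneck so that the
measured error isolates the observation model — with a finite bottleneck
the drift contribution would be a property of the design, not the
estimator.

## Known limitations

* The effective bottleneck and saturation density of the real experiment
  are unknown; drift magnitudes in simulation are illustrative.
* The NB dispersion is a single number per sample; barcode-specific
  amplification biases are not modelled.
* The segment caller's 20-bin/0.4-ratio defaults are package choices, not
  community standards; tune them for other genome scales.
* `interval_fitness()` measures change relative to the population mean,
  not relative to the reference, once the reference is too rare to track.
* No sweep-detection statistic is provided; trajectory exports and plots
  are the intended route for inspecting sweeps.
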