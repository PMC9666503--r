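---
title: "Estimating taxon-specific growth from heavy-water qSIP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating taxon-specific growth from heavy-water qSIP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsipr)
```

## The measurement and the model

Quantitative stable isotope probing (qSIP) with H~2~^18^O infers which
members of a soil bacterial community synthesised DNA during an
incubation, and how much. Soil is incubated with isotopically heavy
water; organisms that grow incorporate ^18^O into new DNA, which makes
that DNA denser. After CsCl density-gradient ultracentrifugation the
DNA of each sample is recovered as ~22 fractions spanning the gradient,
and three measurements are made per fraction: its buoyant density
(g mL^-1^), its DNA concentration, and its total 16S rRNA gene copy
number by qPCR. Fractions with enough DNA (above 1.0 ng µL^-1^ by
default) are amplicon-sequenced, giving ASV-level read counts.

The estimator works per taxon *i* and tube:

1. **Absolute abundance per fraction.** Read counts are converted to
   gene copies by scaling each ASV's relative abundance in a fraction
   by the fraction's qPCR total
   (`fraction_absolute_abundance()`).
2. **Weighted-average density (WAD).** The taxon's mean position in the
   gradient is the copy-weighted mean of fraction densities,
   $W_i = \sum_f x_f c_{if} / \sum_f c_{if}$
   (`weighted_average_density()`). A taxon absent from a tube has no
   WAD; the estimate is skipped with a reason code rather than forced.
3. **GC baseline.** Unlabeled DNA density varies with GC content, so
   the unlabeled (^16^O) WAD fixes the taxon's GC fraction through the
   linear calibration $W = 1.646057 + 0.083506\,G$, and with it the
   unlabeled mean nucleotide weight $M = 0.496\,G + 307.691$
   (`gc_from_unlabeled_density()`, `molecular_weight_light()`).
4. **Atom fraction excess.** The labeled molecular weight is the
   unlabeled weight scaled by the density ratio,
   $M_{lab} = M \cdot W_{lab}/W_{light}$, and the ^18^O atom fraction
   excess is
   $A = \frac{M_{lab} - M}{12.07747}\,(1 - 0.002000429)$,
   the weight gain relative to full ^18^O substitution, corrected for
   natural abundance (`atom_fraction_excess_18O()`). $100A$ is the atom
   percent excess (APE).
5. **Linear growth.** Assuming (a) DNA synthesis tracks growth, (b) all
   new DNA carries the ^18^O atom fraction of the soil water, and (c)
   an average of six 16S rRNA gene copies per cell, the fraction of the
   taxon's DNA pool that is new at day $t$ is $p_{new} = A/A_{sat}$,
   the unlabeled pool is $N_{LIGHT} = N_{TOTAL}(1 - p_{new})$, and the
   absolute growth rate is
   $b_i = (N_{TOTAL} - N_{LIGHT})/t$
   (`growth_potential()`). Growth is linear, not exponential, and uses
   only time-$t$ abundances; T0 totals are carried in the outputs for
   turnover interpretation but do not enter $b_i$.

$A_{sat}$ defaults to the labeled soil water's ^18^O atom fraction
(0.7876) minus natural abundance (0.002000429): assumption (b) ties the
labeling ceiling of new DNA to the water, and subtracting natural
abundance keeps the numerator and denominator on the same excess basis.
The water enrichment itself is a configuration input, not a derived
quantity: it is an assay-level measurement that simple two-pool mixing
arithmetic does not reproduce.

Negative $A$ (and hence negative $b_i$) can and does arise from density
noise. Nothing is clamped: truncating at zero would bias every
downstream bootstrap distribution, and statistical significance is the
job of the confidence-interval filter, not of the point estimate.

## Replication, uncertainty, and the activity filter

Estimates rest on three independent replicate microcosms per treatment,
each contributing a T0 ^16^O tube, a T7 ^16^O tube and a T7 ^18^O tube.
Before anything is estimated, an ASV must have been recovered (at least
one read, any sequenced fraction) in **every** replicate of a treatment
(`filter_replicate_presence()`); by default presence is assessed over
the T7 tubes of both isotopes.

Uncertainty is quantified by a replicate-level bootstrap
(`bootstrap_ape()`): each of 1000 iterations resamples the replicate
WADs with replacement, independently on the ^16^O and ^18^O sides,
averages each side, and converts the pair to an APE. The point estimate
is the median of the draws; the 90% interval is their 5th and 95th
percentiles, so `ci_low <= ape_median <= ci_high` holds by
construction. Replicate tubes are the resampling unit because they are
the independent units of the design ($n = 3$); fractions within a tube
are not independent observations of a taxon's density. A taxon is
classified *actively growing* when `ci_low > 0`, strictly: an interval
touching zero is not evidence of growth. By default the unlabeled side
uses the three T7 ^16^O tubes, matching the labeled side's replication;
`light_tubes = "all16O"` additionally admits the T0 tubes into the
baseline.

**Known limitation — small-sample bootstrap calibration.** A percentile
bootstrap on means of three replicates is anti-conservative; this is a
property of the procedure, not of its implementation. Direct Monte
Carlo on normal replicate noise shows ~73% actual coverage for the
nominal 90% interval and a ~12% rate of `ci_low > 0` under a true APE
of zero, and the package's own simulation-based validation
(`truth_recovery_report()`, exercised in the test suite and the
acceptance script) measures the same behaviour end to end: roughly
70–80% coverage and a 10–18% null false-positive rate depending on the
noise realisation. Users comparing activity calls across studies should
treat the 90% label as nominal; increasing replication, not iterations,
is what improves calibration. The bootstrap itself converges correctly:
at 3+3 replicates its percentiles agree with exhaustive enumeration of
all 27 × 27 equally likely resample pairs.

## Comparisons, diversity, and efficiency

*Treatment ratios.* For taxa active under two conditions, the ratio of
their APEs (`ape_ratio_table()`) measures the relative growth
potential; ratios are averaged per phylum (unweighted — every ASV
counts once regardless of abundance) and tested against 1 with a
two-sided Wilcoxon signed-rank test, Benjamini–Hochberg corrected
across the phyla of one comparison (`phylum_ratio_test()`). Each
pairwise comparison is its own BH family, mirroring how such panels are
reported one comparison at a time. Ratios exactly 1 drop out as zero
differences; a phylum with nothing left gets $p = 1$ by convention.
Reporting is restricted to the ten most abundant phyla, ranked by total
read counts (`top_phyla()`); read counts rather than copy-number-scaled
abundances are used because the ranking feeds a reporting filter, not a
quantitative estimate, and the basis is configurable.

*Diversity.* Inverse Simpson diversity ($1/\sum p_i^2$, computed via
vegan) is reported per T7 tube for the total community and for the
qSIP-filtered active subset, on copy-number-scaled abundances pooled
over the tube's sequenced fractions (`diversity_table()`). No
rarefaction is applied; counts enter only as relative abundances scaled
by qPCR totals.

*Growth efficiency.* Gross growth per treatment is $\sum_i b_i t$ over
active taxa — new gene copies over the assay, keeping the linear-growth
convention — and efficiency is gross growth divided by mean CO~2~
efflux (`growth_efficiency()`). The unit
(copies g^-1^ per µg CO~2~ mg^-1^ soil C) is carried as a composite
string; no conversion to biomass carbon is attempted because the
quotient is a proxy, not a calibrated carbon-use efficiency.

## The simulator

`generate_experiment()` is a forward model of the whole assay with
known ground truth, so every inference stage can be validated without
sequencing data. Per taxon it draws a GC content (uniform 0.3–0.7), a
per-treatment true APE from a mixture (point mass at zero with
probability 0.6; otherwise uniform on 0–65 points, covering the range
such assays observe), Dirichlet relative abundances, and lognormal
per-replicate abundance multipliers shared across a replicate's three
tubes. Physically, each taxon's DNA is a two-component Gaussian band in
density: pre-existing DNA at the GC-determined density and new DNA at
the fully labeled density, mixed with weight $p_{new} = APE/(100
A_{sat})$ — exactly the two-pool picture behind assumption (b), which
makes partial labeling testable and the forward model the exact inverse
of the estimator. Bands are integrated over 22 equal-width density bins
(uniform spacing is a simplification; real fraction spacing is
instrument-dependent and configurable), qPCR totals and DNA
concentrations get multiplicative lognormal noise, fractions above the
concentration cutoff receive multinomial reads, and all randomness
descends from one seed through named per-tube substreams.

Default physical settings, chosen once to emulate the assay: band
spread 0.006 g mL^-1^ (equilibrium plus diffusion broadening),
collected range 1.61–1.81 g mL^-1^, 5 µg DNA per tube quantified in a
40 µL post-cleanup resuspension, cutoff 1.0 ng µL^-1^, 10,000 reads
per sequenced fraction, qPCR CV 0.15. Under these, typically 6–11 of
the 22 fractions pass the cutoff (labeled tubes sit at the high end
because isotope incorporation genuinely spreads the community's DNA).

With noise disabled the pipeline recovers planted APE values to better
than 0.01 points (the residue is bin discretisation, about $10^{-3}$
points at these settings), which is the forward–inverse identity the
test suite pins.

What the simulator does **not** emulate: chimeras and primer/
amplification bias, phylogenetic correlation of GC or activity, relic
DNA pools, non-uniform fraction spacing, and between-treatment
differences in the true APE distribution (treatments differ only by
independent draws unless configured otherwise). Passing recovery tests
on simulated data therefore demonstrates correctness of the inference
chain under the model's own physics, not robustness to every artefact
of real amplicon data.

## Numerical and edge-case conventions

- A fraction with zero reads attributes zero copies to every ASV; a
  taxon with zero copies in a tube has an undefined WAD and is skipped,
  never imputed.
- GC estimates outside [0, 1] warn (density outside the calibration
  range) but are not clipped.
- $p_{new} > 1$ (APE above the labeling ceiling, possible under noise)
  warns and is retained.
- Result tables round-trip through TSV at full double precision
  (15 significant digits).
- Validation is total: malformed inputs raise typed errors
  (`qsip_schema_error`, `qsip_referential_error`, ...), and
  non-monotone fraction densities within a tube re-sort rows with a
  warning while leaving fraction indices untouched so count references
  stay valid.
- Densities are restricted to the physically meaningful CsCl window
  [1.55, 1.85] g mL^-1^.

## Validation scale

The package's own validation (test suite and acceptance script) runs
the simulator at 300 taxa for recovery and null studies, 40–120 taxa
for pipeline-level checks, and 1000 bootstrap iterations — the design's
own iteration count. At these sizes a full single-treatment recovery
study takes on the order of a second, and median absolute APE error
among truly active taxa is well under 2 points. The error-degradation
property (estimator error non-decreasing in band spread and qPCR noise)
is checked with the sequencing window held fixed, because under an
active concentration cutoff a *narrower* band concentrates the
community into fewer sequenced fractions and cutoff-truncation bias —
a real effect, worth knowing about — can dominate the comparison.
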