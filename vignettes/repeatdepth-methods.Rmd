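---
title: "Methods: estimating copy number of large tandem-repeat arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating copy number of large tandem-repeat arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatdepth)
```

## The problem

Ribosomal DNA (rDNA) and similar satellite loci exist as tandem arrays of
kilobase-scale units — 7.2 kb in *C. elegans*, 9.1 kb in *S. cerevisiae* —
repeated tens to hundreds of times. Reference assemblies collapse the array
to a single unit, so the copy number of the array is not a genotype a variant
caller reports; it has to be *estimated*, and every available assay estimates
it differently. This package implements the principal estimation routes —
read-coverage ratios from whole-genome sequencing with and without GC-bias
correction, droplet digital PCR (ddPCR), single-molecule molecular inversion
probe (smMIP) capture counting, pulsed-field (CHEF) gel band conversion and
FISH spot intensity — together with the replicate-error statistics used to
compare them, and a synthetic-data generator that produces every input with
known ground truth.

## Relative-read (RR) estimation

With `N_rep` alignment records overlapping the repeat region, `N_tot` mapped
records genome-wide, collapsed genome length `G` and unit length `L`,

```
copy number = (N_rep * G) / (N_tot * L).
```

Counting follows the sequencing workflow this formula comes from: each mate
of a pair is one record, duplicates are retained (identical fragment
coordinates are expected, not artifactual, inside a tandem repeat), no
mapping-quality filter is applied, and a record counts toward a region when
its span overlaps it by at least one base. The counting span and the
denominator unit length are independent parameters, because the worm
workflow counts reads over a 10,735-bp printed span while dividing by the
7,197-bp unit; `estimate_rr()` reproduces that behaviour when given those
constants (`reference_constants("celegans")`).

Two structural properties of this estimator are worth knowing. First, `G` in
the numerator is the *collapsed* genome length while the reads were drawn
from a genome containing `c` copies, so the estimator carries a deflation
factor `G / (G + (c-1)L)` — about 1% for 412 worm-sized units in a 20-Mb
genome, and negligible for real worm or yeast genomes. Second,
overlap-counting admits reads hanging over either region edge, inflating the
count by roughly `(read_length - 1) / (c * L)`. Both effects are visible in
the tests and are part of the estimator's published definition, so they are
left as-is rather than corrected.

## GC-bias correction (GCC)

Tagmentation-based library preparation biases fragment recovery by GC
content. The correction models read starts at reference position `i` as
Poisson with rate `c(i) * lambda(g_i)`, where `g_i` is the GC fraction of a
`W`-base window anchored at `i` and `lambda` is piecewise-constant per GC
bin. `lambda` is fitted on background (non-repeat) positions, where the copy
number is 1, as observed read starts per eligible position per bin. The MLE
for the repeat is then

```
c_hat = (read starts anchored in the repeat) / sum over repeat positions of lambda(g_i).
```

Three modelling choices matter:

* **Strand-aware anchors.** A minus-strand record's forward window extends
  past its fragment's end, so its window GC would be noise. Records on the
  minus strand anchor so their window *ends* at the alignment end, keeping
  the window inside the originating fragment. Without this the fitted
  profile is attenuated and the corrected estimate inherits a several-percent
  bias.
* **Circular repeat windows.** Inside a tandem array, the bases following
  any unit position belong to the next copy; the collapsed reference
  truncates them. Repeat-position windows therefore wrap circularly around
  the unit. With a 500-bp test unit and a 300-bp window, skipping this step
  biases the corrected estimate by tens of percent.
* **Binning.** Window size defaults to 300 bp (the fragment scale, so
  window GC tracks fragment GC), bins are 5% of GC wide, and bins holding
  fewer than 100 eligible positions merge into their nearest populated
  neighbour. None of these values is prescribed by the assay; they are
  package defaults, and the sensitivity that matters (recovery of truth
  under bias) is tested directly.

When the profile is constant the correction collapses to a relative-read
estimate in start-counting form: `c_hat = (repeat start density) /
(background start density)`. This exact identity is the degenerate-case
test for the implementation.

The single-copy audit (`estimate_control_regions()`) applies the RR formula
to each of 29 background control regions with the unit length set to the
region's own length; values far from 1, or a drifting mean, indicate the
kind of library-wide coverage distortion that inflates repeat calls.
`downsample_estimates()` Bernoulli-thins records and re-estimates, to show
how little of the between-library disagreement plain read sampling explains.

## ddPCR

A droplet is positive when it received at least one template molecule, so
with positive fraction `p = k/n` and droplet volume `v` the concentration is
the Poisson zero-class inversion `lambda = -log(1 - p)/v`. The 95% interval
propagates the binomial error of `p` through the log
(`lambda ± 1.96 sqrt(p/(n(1-p)))/v`), the standard normal-approximation
interval droplet readers report. Copy number is the target-to-reference
concentration ratio scaled by the reference locus copies per genome, with
the two channel errors combined assuming independence. A saturated channel
(`k = n`) is an error, not an estimate: the zero class is empty and the
concentration unbounded. Droplet volume defaults to 0.85 nL, the industry
convention, and is always explicit in the configuration.

## smMIP counting

Each molecular inversion probe carries a 12-base UMI, so unique capture
events are distinct (probe, UMI) pairs. A spiked normalization plasmid
carries one variant-marked copy of the repeat target and of each single-copy
target. Per single-copy probe `j`, `P_j = plasmid_j / genomic_j` estimates
plasmids per genome; per repeat probe `m`, `c_m = (genomic_m / plasmid_m) * P`.
Both ratios are within-probe, so per-probe capture efficiency cancels
exactly. Probes are combined by median (robust to one failing probe;
`combine = "mean"` is available — the assay description does not say which
was used). Reads whose diagnostic allele is unreadable are dropped, not
split, and their count logged. Note the plasmids-per-genome ratio is defined
here as plasmid over genomic events; the inverse reading of the assay
description is inconsistent with the stated correction and is not used.

## CHEF conversion

Ladder calibration is piecewise-linear in (migration distance, log size) —
exact at rungs, geometric-mean interpolation between them; gel physics are
not modelled, and a band outside the ladder range is an error ("beyond
ladder resolution"). Copy number is `(size - flanks) / unit_length`,
reported rounded with the unrounded value retained. The worm workflow
subtracts no flanks (the whole excised band is array); the yeast BamHI
workflow subtracts the 8.8-kb and 30.9-kb flanks. Replicate summaries use
the sample (n−1) standard deviation for `CV% = 100·sd/mean`, which is the
convention that reproduces the benchmark tables' printed 3–15% CV range
with median 6%; a single measurement reports `NA`. Minor (sub-population)
bands convert independently and are never averaged into the primary
estimate unless a strain is explicitly flagged as a doublet.

## FISH quantification

Nuclei are segmented by a global Otsu threshold on the DAPI channel plus
3-D connected components (per-slice labelling merged across slices), with
optional marker-based separation of touching nuclei. Foci are 3-D local
maxima exceeding `median + 5·MAD` of their nucleus's intensity
distribution; maxima closer than the integration radius (default `3·psf_sigma`)
merge into the brighter one. Integrated intensity sums a sphere around the
peak and subtracts a background level estimated as the median of
intra-nuclear voxels *outside* all integration spheres — estimating the
background inside the nucleus without excluding the foci contaminates it
with their own tails and breaks intensity linearity. The module is a
*relative* readout: absolute copy numbers require a reference strain, via a
linear rescale, exactly as the imaging assay itself is used. No published
values exist for the original analysis' spot-calling parameters; the
defaults here are declared, not inferred.

## The synthetic-data generator

Every pipeline stage can be driven by `sim_config()` + generators with full
ground truth. What the generator emulates, and what it deliberately does not:

* **Genome**: one chromosome with a single collapsed repeat locus and 29
  single-copy control regions. Background GC is isochore-like — 10-kb blocks
  with GC drawn uniformly from 0.30–0.60 by default — and the repeat unit's
  GC (default 0.55) is settable independently. The heterogeneous background
  matters: a flat-GC background leaves no background positions sharing the
  repeat's GC, making any per-GC-bin correction unidentifiable.
* **Reads**: fragments drawn uniformly from the genome expanded to the true
  copy number; truncated-normal lengths (mean 350, sd 50, bounds
  `[2·read_length, 2000]` — the assay description gives no fragment model);
  paired 75-bp reads. Tagmentation bias is a Gaussian acceptance weight in
  fragment GC, `exp(-(g - 0.40)^2 / (2·0.12^2))` by default — a standard
  stand-in; the magnitude and shape of real Nextera bias are not quantified
  in the benchmark study, so these are free parameters with defaults chosen
  to be plausibly strong (they depress repeat coverage ~40% when the repeat
  GC sits 0.15 above the acceptance optimum). Reads wholly inside the
  repeat are flagged multi-mapping and assigned to the collapsed unit,
  which in a one-locus genome is equivalent to random assignment among
  copies. No sequencing-error or quality model; no PCR-duplicate chemistry.
* **Droplets**: independent Poisson occupancy per channel; no fluorescence
  amplitude model.
* **smMIP**: unique events per probe Poisson(efficiency × template copies),
  with template copies `c` (genomic repeat), 1 (genomic single-copy) and 19
  (plasmid, the 1:19 genome:plasmid molar ratio default); UMIs are random
  12-mers and colliding templates merge on deduplication, as in real data.
* **CHEF**: band migration from inverting the ladder map at
  `copies·unit + flanks`, Gaussian noise on log-size (0.05 log-units by
  default, which lands replicate CVs in the single-digit-percent range
  observed for the assay).
* **FISH**: each cell shows one or two foci (P(two) = 0.76, matching the
  observed 1.76 foci/cell); the two-focus case places them diametrically in
  the nucleus, since the imaged foci are distinct nucleolar organizers;
  total focus intensity is `intensity_per_copy × copies` split randomly;
  foci render as isotropic 3-D Gaussians plus additive noise. No optical
  artifacts, chromatic effects or cell-cycle structure.

Passing tests on these simulations show the estimators recover truth under
the generator's assumptions (uniform or unimodally GC-biased sampling,
ideal alignment to truth coordinates). They do not certify performance on
real libraries, where bias shape, mappability and duplication structure are
richer — which is precisely why the bundled benchmark tables, with their
real cross-method errors, ship alongside.

## Problem sizes and determinism

Parameter-recovery runs use a 20-Mb genome with a 500-bp unit and 500,000
read pairs per library, 20 seeds per condition in the test suite (10 in the
acceptance script); these sizes put the Monte-Carlo error of a mean estimate
well under 1% while keeping a full run in the minutes range on one CPU. FISH
checks use six strains of 100 cells each. All generators are seeded and
byte-reproducible: the same `sim_config()` yields identical FASTA/FASTQ/SAM
bytes and identical tables.

## Known limitations

* The GC model corrects coverage as a function of window GC only; real
  tagmentation bias also has positional and motif components.
* The RR estimator's collapsed-genome deflation is inherent to its printed
  definition and uncorrected (≈1% at the test scale, smaller on real
  genomes).
* The CHEF module converts sizes; it does not call bands from gel images.
* FISH absolute calibration is a linear rescale against a user-supplied
  reference strain; there is no per-cell absolute quantification.
* The command-line surface is the R API itself (the package is an analysis
  library; scripts/acceptance.R shows a complete scripted run).
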