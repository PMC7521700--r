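---
title: "Methods: the 15N biomarker assay and genome-mining models in diazokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 15N biomarker assay and genome-mining models in diazokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazokit)
```

# The functional assay

## Isotope model

A metabolite with $n$ nitrogen atoms whose atoms are independently
$^{15}$N with probability $p$ is observed as a mixture of
isotopologues: the fraction at mass shift $k$ is the binomial mass
$\binom{n}{k} p^k (1-p)^{n-k}$, and each replaced atom moves the mass
up by one unit. `isotopologue_distribution()` implements exactly this;
its mean shift is $np$ and the fractions sum to 1 for every $(n, p)$.
The default mass step is the nominal 1.0 Da; the exact
$^{15}$N–$^{14}$N difference (0.9970 Da) is available through
`sim_config(mass_shift =)` but the nominal step keeps alignment bins
simple and matches how shifted masses are usually described.

The generator assumes one incorporation probability per isolate,
applied uniformly to all of its metabolites. Real incorporation surely
varies across compounds (turnover, pathway distance from fixed
ammonium); we know of no measured distribution to emulate, so the
uniform choice is the simplest defensible one and is stated here
rather than hidden.

## The natural-abundance background

Non-fixing isolates have incorporation probability exactly 0 — but the
generator's default background `natural_15n = 0.0037` gives every
nitrogen atom the natural $^{15}$N abundance in control samples and in
samples of isolates that do not fix. This default is load-bearing, not
cosmetic: the BNF ratio restricts to biomarkers *common to both*
atmospheres (nonzero mean relative intensity in both), and a
mass-shifted isotopologue feature can only be present in a control
sample through the isotopic background. With a strictly zero
background the common set is empty and every isolate's ratio is
undetermined; with the physically correct background the statistic
behaves exactly as intended — non-fixers score $\approx 1$, fixers
score $\gg 1$, monotonically in their incorporation rate. Setting
`natural_15n = 0` is supported for studying that degenerate regime.

A consequence worth stating: recovered fixer ratios are *large*
(tens), because the denominator is the faint natural-abundance signal.
Published per-isolate ratios in the low single digits reflect real
spectra in which control samples carry substantial signal at biomarker
masses (natural $^{13}$C/$^{15}$N envelopes of thousands of co-eluting
compounds, chemical noise, partially N-free biomarkers). The assay's
*decision structure* — ratio $\ge 1$, ordering in incorporation,
grouping — is what the generator verifies, not the absolute scale of
the published ratios, which depends on unreleased raw data.

## Replicate noise and dropout

Replicate intensity noise is multiplicative lognormal with unit mean,
parameterized by its coefficient of variation (`noise_cv`, default
0.1): intensities are positive and heteroscedastic, so additive
Gaussian noise would be the wrong shape. A `detection_floor` (default
0) is applied *after* noise, mimicking peak-picking dropout, which is
how missing features arise in real matrices. Cultures are simulated in
triplicate by default.

## Peak alignment

No published description of the original alignment algorithm is
available at the level of detail needed to re-implement it, so
`align_peaks()` uses a deterministic, order-independent choice that we
document as our own: all peaks from all samples are pooled and sorted
by m/z, and a new feature starts wherever the gap between consecutive
sorted m/z values exceeds the tolerance (single-linkage gap
clustering, default 0.01 Da, configurable in Da or ppm). Two
deliberate details:

* a sample contributes at most one peak per feature — when several
  peaks of one sample fall in a cluster, the peak closest to the
  cluster median m/z stays and the remainder are re-clustered into new
  features (a feature is a single species; one sample cannot
  contribute it twice);
* missing entries are zeros, not `NA`, because the downstream ratio
  statistic sums intensities and absence of signal is naturally 0.

The representative feature m/z is the intensity-weighted mean of its
member peaks. Relative intensities are percentages of each sample's
total raw signal; all-zero samples are left at zero and flagged
instead of producing NaN.

## Feature testing and biomarker selection

Features are tested with a two-sided Welch (unequal-variance) t-test
on raw aligned intensities, pooling all enriched samples against all
control samples across isolates. The original analysis ran a t-test in
an external tool whose transform settings are unreported; we default
to no transform (least assumption) and expose `log_transform` for
log10(x + 1). Degenerate features are defined explicitly: equal means
with zero variance in both groups give p = 1, differing means with
zero variance get a machine-epsilon variance floor (p numerically 0).

Multiple testing uses Benjamini–Hochberg step-up q-values (via
`p.adjust`; the test suite checks them against an independent
brute-force implementation of the step-up definition). Selection is
q ≤ 0.05 *inclusive* and fold change > 1 *strict*, matching the
published wording of each rule. Fold change is the ratio of group mean
raw intensities; when the control mean is exactly zero the denominator
is replaced by (smallest nonzero intensity)/10 — we do not add a
pseudocount to both sides because that would perturb fold changes that
are perfectly well defined.

## The BNF ratio and groups

Per isolate and condition, each biomarker's relative intensity is
averaged over replicates; biomarkers "common to both" conditions are
taken literally as nonzero mean in both (an `include_all` flag
disables the restriction); the common biomarkers are summed per
condition and the ratio is enriched/control. An empty common set or a
zero control sum yields an undetermined ratio (group F) rather than an
infinity.

Group boundaries are published as open intervals (4 > x > 3, ...),
which leaves the boundary points unassigned; we close every interval
on the left (x = 4 → A, 3 → B, 2 → C, 1 → D), consistent with "ratio
greater than or equal to 1" counting as sufficient fixation. The
breaks are configurable in `assign_group()`.

# Genome mining

## Filters

Two filter profiles are preserved exactly as published, including
their asymmetry: the canonical *nif* screen retains hits with model
coverage **≥** 75% and e-value ≤ 1e-9 (both inclusive; the
alternative-*nif* screen relaxes to e ≤ 1e-6, coverage ≥ 85%), while
the carbohydrate screen retains coverage **strictly >** 85% with
e ≤ 1e-9. Coverage of a protein with several domains on one model is
the *union* of the model-coordinate intervals (how much of the model
is matched), with a single-best-domain mode behind a flag; the
original choice is unreported. Likewise the e-value filtered on is the
full-sequence e-value by default, with the per-domain i-Evalue behind
a flag. Filtering is monotone: relaxing either threshold never drops a
retained hit (property-tested).

## Profiles, Dos Santos classes and alternative nitrogenases

Profiles count *unique coding sequences* per gene — a protein with
multiple domains counts once, two paralogs count twice (copy number is
informative: *nifH* duplications are common among confirmed fixers).
DSP/SDS/DSN classification requires all six / some / none of
*nifH, nifD, nifK, nifE, nifN, nifB* and partitions any genome set.
The alternative-nitrogenase partition over the nine genes
(*nifHDK* + *anfDGK* + *vnfDGK*) reports all-nine, Mo-Fe-only,
nifH-only, with an explicit residual category rather than silently
dropping other combinations.

The accession→gene maps ship as editable YAML under `inst/extdata`.
The accession lists follow the published screens, but the
accession-to-gene correspondence is curated here (the screens list
accessions only), and the CAZy/transporter substrate maps are
deliberately labelled as replaceable stand-ins: the original curated
supplementary tables are not part of the main text.

## MinHash genome distance

Sketches are bottom-$s$ MinHash over canonical 31-mers: each k-mer and
its reverse complement are 2-bit packed, the smaller code is hashed
with a seeded 64-bit avalanche mix (MurmurHash3 finalizer, fixed seed
42), hashes are truncated to 53 bits so R doubles store them exactly,
and the $s$ smallest distinct values are kept (default
`sketch_size = 1000`; the original "maximum sketch size" is not
quantified, so the default is our choice). Jaccard similarity between
two genomes is estimated on the bottom-$s$ sketch of their union —
unbiased for bottom sketches — giving a symmetric unit-diagonal JSI
matrix. k is limited to ≤ 31 by the 2-bit packing, which covers the
published k = 31. `exact_jaccard()` is an independent pure-R oracle
(explicit canonical k-mer sets via Biostrings) used to validate the
estimator: at sketch size 1000 on 50 kb genomes mutated at 1% the
estimate tracks the exact Jaccard within 0.05 (observed ≤ 0.02–0.04),
and at full sketch size it equals it exactly.

## Pangenome categories

Genes are classified purely by prevalence across genomes: core
≥ 99%, soft-core [95%, 99%), shell [15%, 95%), cloud [0%, 15%).
The published ranges do not state which end of each interval is
closed; we follow the Roary convention (core closed at 99%, intervals
closed on the left) and expose the three boundaries as arguments.
Counts always sum to the number of genes.

# Problem sizes and what the tests do (and do not) show

The test-suite and acceptance-script simulations use desk-scale sizes
chosen to exercise every code path with comfortable statistical
resolution: 20 isolates (10 fixers on an even incorporation grid
0.3–0.9, 10 non-fixers) × 50 metabolites × triplicates for parameter
recovery; 10 null isolates × 500 features × 20 seeds for
false-discovery behaviour; ten 50 kb genome pairs at 1% mutation for
sketching accuracy; 500 genes × 42 genomes for pangenome
categorization. The null-FDR simulation uses 10 isolates (30 samples
per condition) because the Welch t null is well calibrated at that
group size on lognormal intensities, matching the pooled many-isolate
design the test emulates.

Passing these tests shows that the *procedures* are implemented
correctly and recover planted truth under the stated noise model. It
does not show that any particular published per-isolate number is
reproduced: those depend on unreleased raw spectra and genome data.
The generator also deliberately omits chromatography (retention time),
adducts, charge states, carbon isotope envelopes, and correlated
(batch) noise — so real matrices are harder than synthetic ones, and
tolerance/threshold choices validated here should be re-examined on
real data.

# Known limitations

* Features are (m/z, intensity) pairs only; co-eluting isobars that
  retention time would separate are merged by design.
* Biomarker selection treats every selected feature as an
  N-containing biomarker; no annotation step checks elemental
  composition.
* The shipped substrate maps are stand-ins; real analyses must supply
  their own curation.
* The MinHash implementation targets genome-scale inputs at desk
  scale (it keeps all distinct hashes before truncation); it is not a
  streaming sketcher for metagenome-scale inputs.
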