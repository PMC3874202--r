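---
title: "Methods: quantitative analysis of purified chromatin domains"
author: "chromdom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of purified chromatin domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdom)
```

This vignette is the package's own account of the models and numerical
choices behind its four analysis stages and the simulators that feed
them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. iTRAQ enrichment calling

### Model

An iTRAQ comparison labels a domain purification and a mock (control)
purification with two reporter channels. For protein $p$ in replicate
$r$, the raw ratio is

$$ R_{pr} = \operatorname{median}_{i \in \text{peptides}(p,r)}
   \frac{I^{\text{dom}}_{i}}{I^{\text{ctl}}_{i}}, $$

the background factor is
$g_r = \overline{R_{br}}$ over background proteins $b$ (housekeeping +
ribosomal, which co-purify equally in domain and control and so estimate
the replicate's global labeling/loading bias), and the summary statistic
is the arithmetic mean of $R_{pr}/g_r$ over the replicates in which $p$
was identified, paired with the peptide-count sum over those replicates.

Assumptions: the background set is abundant and unenriched; ratios are
multiplicative-noise quantities (the simulator uses log-normal noise);
identification is peptide-count limited rather than censored by ratio,
so averaging over identified replicates only is unbiased.

### Choices made where the procedure was open

* **Median vs mean peptide aggregation.** The protein-level ratio is the
  median of peptide ratios by default: a single aberrant peptide (shared
  sequence, interference under the precursor) otherwise drags a 2–3
  peptide protein across the calling threshold. The mean is available
  via `aggregation = "mean"`.
* **Arithmetic vs geometric replicate averaging.** "Average" is read
  literally as the arithmetic mean (default); the geometric mean — more
  natural for ratios — is available via `average = "geometric"`. With
  three replicates and moderate noise the two differ far less than the
  distance between the background cluster and the 1.5 threshold.
* **Tier boundaries.** Strict: ratio ≥ 1.5 and ≥ 2 peptides. Relaxed A:
  ratio ≥ 1.5 and ≥ 1 peptide. Relaxed B: ratio **strictly** > 1.0 and
  ≥ 2 peptides. The inclusivity (≥ at 1.5, > at 1.0) follows the
  wording of the criteria; `call_enrichment_tier()` is total and
  monotone in both arguments.
* **Complex rule.** A complex qualifies when ≥ 50 % of its annotated
  subunits pass *any* tier (qualifying tier configurable); averages are
  over identified subunits only, since nothing principled can be imputed
  for subunits that were never observed.
* **Zero intensities.** A peptide with a zero control or domain
  intensity has no defined positive ratio and is dropped; a protein
  whose peptides are all unusable in a replicate is excluded from that
  replicate with a warning rather than given an infinite or zero ratio.

### What passing the recovery test shows

`gen_itraq()` defaults encode the study conditions: 200 background
proteins, 20 spiked at corrected ratio 3.0, three replicates,
peptide-ratio noise CV 0.25, peptide counts $1 + \text{Poisson}(2)$, and
a random per-replicate global bias. Under these conditions strict calls
reach sensitivity ≥ 0.85 and specificity ≥ 0.95 (the acceptance suite
recomputes this). The simulator does **not** model ratio compression
from co-isolation interference, isotope impurity, or missingness
correlated with low abundance, so real-data operating points will be
worse than simulated ones; the test demonstrates correctness of the
pipeline arithmetic and reasonable behaviour of the thresholds, not a
field-calibrated error rate.

## 2. Histone-PTM quantification

### Chemistry and enumeration

Propionylation before trypsin blocks cleavage at lysine, so digestion is
Arg-C-like (after R, never before P — `derivatized_digest()`). Each
lysine carries exactly one state from {propionyl, acetyl,
me1 + propionyl, me2, me3}; the N-terminus is propionylated. Because me2
and me3 block the ε-amine they are treated as non-propionylatable, while
me1 receives a propionyl — standard derivatization chemistry. At the
MS1 level only mass is observed, so positional isomers collapse:
`enumerate_modforms()` enumerates state **multisets** and groups them
into mass bins at 4 decimal places. For the H4 4–17 peptide (4 lysines)
the {prop, ac} alphabet gives 5 bins spaced one CH₂ (14.01565 Da) apart;
the full 5-state alphabet gives $\binom{8}{4} = 70$ multisets collapsing
into 35 mass bins, because a fixed total methyl count weighs the same
however it distributes over sites (e.g. {me1+prop, me2} is isobaric with
{prop, me3}); the test suite checks the bin list against an exhaustive
per-site oracle.

### Recalibration and assignment

* **Calibration model.** With ≥ 2 matched anchors a linear map
  (slope + offset) is least-squares fitted from observed to theoretical
  m/z; with one anchor, offset-only. Both models are provided because
  the instrument drift law is not knowable from centroided data; linear
  is the default since a two-point anchor set determines it exactly and
  it subsumes the offset model. On noise-free synthetic linear drift the
  post-recalibration anchor residuals are < 1e-9 Da (tested).
* **Tolerance.** Peak-to-bin matching uses 0.15 Da — half of a typical
  0.3 Da parent-ion selection window — configurable. Bins closer than
  2 × tolerance cannot be distinguished reliably and are merged into an
  **ambiguity group** (e.g. acetyl vs trimethyl, Δ = 0.0364 Da) and
  quantified jointly; resolving them requires MS/MS, which is out of
  scope. Each group takes the intensity of its nearest owned peak
  within tolerance, else 0; a peak exactly equidistant between two
  groups is an error rather than a silent choice.
* **Proportions.** $\pi_i = I_i / \sum_j I_j$ over the bins of one
  peptide; per spot, then unweighted mean over detected replicas,
  renormalized. Proportions sum to 1 after every stage (tested at
  1e-9). A peptide with no assigned signal is "not detected", never a
  row of zeros.
* **Intensity semantics.** Centroided intensities are consumed as
  given; whether they are heights or areas is upstream processing's
  choice and does not affect the proportion arithmetic.

`gen_maldi()` generates peaks at theoretical m/z under linear drift with
log-normal intensity noise and anchor peaks at twice the peptide's total
intensity. It does not emulate isotope envelopes, matrix clusters or
detector saturation; closure tests therefore validate the
enumeration–recalibration–assignment–normalization chain, not spectral
preprocessing.

## 3. EM nucleosome footprints

### Geometry

Coordinates are 0-based half-open; circular coordinates are modulo the
ring length, and an interval with end < start wraps through the origin.
`to_bp()` multiplies by 3 bp/nm (150 bp ≈ 50 nm) and rounds half-up to
integer bp. `linearize()` maps $x \mapsto (x - \text{cut}) \bmod L$; a
bubble containing the cut site is physically impossible (restriction
enzymes do not cut single-stranded DNA), so such molecules are flagged
unanalyzable — droppable with `drop_unanalyzable = TRUE`. A bubble whose
half-open end coincides with the cut maps its end to $L$, not 0.

### Binning and classification

Size bins are lower-inclusive/upper-exclusive — sub (< 130),
mono [130, 180), intermediate [180, 260), gap [260, 280),
di [280, 360] (upper bound inclusive), supra (> 360 bp) — with
nucleosome equivalents mono → 1, di → 2. The 260–280 bp region sits
between the published intermediate and di ranges; it is kept as an
explicit `gap` bin rather than silently widened into either neighbour,
so no bubble is ever mislabeled by an undocumented convention.

Molecule classes are **emergent**, not a fixed ontology: the key is the
bubble count plus the sorted multiset of (size bin, feature relation)
labels, with relation ∈ {overlaps_feature, upstream, downstream} of the
single configured feature (finer positional granularity is not
recoverable from interval data). Classification is invariant to bubble
listing order and to coordinate shifts that cross no feature boundary
(both tested). `fraction_crosslinked_over_feature()` counts molecules
with no bubble overlapping the feature by ≥ 1 bp (configurable, because
EM boundary precision is limited).

### Simulator

`gen_molecules()` draws a nucleosome configuration per molecule from a
probability catalog; each nucleosome protects 147 bp (the canonical
octamer footprint), protected intervals with linkers below the merge
threshold (default 30 bp — EM cannot resolve short crosslinked linkers;
no measured resolution figure exists, so this is an explicit,
configurable assumption) coalesce into one bubble, and boundaries
receive Gaussian sizing jitter. Two nucleosomes with a 20 bp linker thus
produce a single 147 + 20 + 147 = 314 bp bubble — a di-nucleosome-bin
event, which is why the di bin is wider than twice the mono bin. The
simulator does not model sequence-dependent psoralen preferences or
incomplete crosslinking of naked DNA, the two mechanisms that plausibly
populate the intermediate bin in real data.

## 4. Recovery accounting

* Recovery = $100 \cdot E / CE$, reported unrounded **and** as the
  round-half-up integer (matching tabular presentation; R's default
  banker's rounding would turn 2.5 into 2).
* Fold-excess = domain amount / reference-locus (*PDC1*) amount in the
  same fraction.
* Recombination efficiency: the quotient wording ("recombined divided by
  non-recombined") conflicts with printed values that never exceed
  100 %; the default mode is therefore
  $100 \cdot \text{rec} / (\text{rec} + \text{nonrec})$, with the
  literal quotient available as `mode = "literal"` and clearly labeled
  in the report. Neither reading is asserted as the source's intent.
* Mass-balance QC flags $|P + SUP - CE|/CE > 0.25$; the tolerance
  reflects blot-quantification noise and the flag is advisory, never
  fatal — a purification with a flagged deficit can still have a valid
  recovery.
* Accessibility series are normalized to the cut fraction at the highest
  enzyme amount (by construction 100 % there); ChIP retention is
  $100 \cdot \text{IP} / (\text{input} \times \text{dilution})$.
* Missing quantities ("n.d.") propagate as `NA`, never as zero.

## Problem sizes and determinism

The test suite and acceptance script run simulations at sizes chosen to
make binomial/log-normal sampling error small relative to the assertion
margins while keeping the whole suite in the seconds range: 220 proteins
× 3 replicates for iTRAQ recovery, 100 seeded repeats of 3-spot MALDI
simulations for the proportion MAE, 1,000 random molecules for the EM
oracle-equivalence check and 500 molecules for the occupancy estimate
(binomial SE ≈ 0.02 at p = 0.3, against a 3-SE acceptance band). A
single root seed expands into fixed per-generator substreams
(`chromdom:::substream_seed`), so adding a generator never perturbs
existing fixtures, and identical configurations are bit-for-bit
reproducible.

## Known limitations

* No FDR control across proteins in enrichment calling (none is defined
  for the tiered scheme); the tiers are thresholds, not error rates.
* MS1-level PTM quantification cannot resolve positional isomers or
  acetyl/trimethyl ambiguity groups; ionization-efficiency differences
  between modforms bias proportions in a peptide-specific way the
  pipeline does not correct.
* EM analysis starts from measured contours; segmentation, strand
  identity and incomplete-molecule exclusion happen upstream and their
  selection effects are invisible here.
* The recovery arithmetic is exact but inherits the quantification error
  of the fmole inputs; QC can flag but not repair inconsistent tables.
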