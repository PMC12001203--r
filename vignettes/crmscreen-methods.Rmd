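---
title: "Methods: crude-reaction-mixture screening readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crude-reaction-mixture screening readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

crmscreen implements the computational readout of a crude-reaction-mixture
(CRM) screening campaign: robotic array synthesis produces hundreds to
thousands of unpurified reaction mixtures; LC-MS answers, per mixture,
whether the intended product formed; and crystallographic soaking of the
mixtures lets the protein binding site itself select the active species.
This vignette records the models, parameters and design choices behind each
stage, and what the synthetic-data tests do and do not demonstrate.

## Reaction-array enumeration

An array is defined by building blocks (id, SMILES, role, iteration) and a
route: an ordered list of steps, each a two-component reaction-SMARTS rule
applied over the full factorial of its input sets. A step's inputs are
either block roles or the products of an earlier step (`"@<step_id>"`),
which expresses both linear multi-step routes and branched routes merged by
a final coupling. Structure-level chemistry (parsing, canonicalization,
rule application, fingerprints) is delegated to RDKit through a bundled
Python helper; the package itself owns the enumeration order, provenance
and all mass bookkeeping.

Masses are deliberately *not* taken from the generated product structures.
The product formula of a step is book-kept exactly as
`formula(inputs) - leaving_formula`, and monoisotopic/average masses come
from a fixed isotope table versioned with the package (most-abundant-isotope
masses; proton mass 1.007276 Da for adducts). The test-suite separately
verifies that the structures the rules produce close the same mass balance,
so chemistry errors in a rule surface as closure failures rather than as
wrong expected ions. Rule correctness beyond mass closure is explicitly not
validated: rules are configuration data, and the shipped six iteration
configs reproduce the scale and topology of a real campaign (58/58/64/512/
1024/160 targets; one-step urea and amide arrays, two-step acylation/
sulfonylation arrays, and a branched final iteration) with stylized
building-block series, not the original proprietary block lists.

Racemic building blocks are written with one explicit stereocentre; the
enumerator expands both mirror images and collapses them into a single
product target of identical mass with the enantiomer structures kept in
provenance — mirroring racemic CRMs, where LC-MS cannot distinguish
enantiomers. Where a rule matches several sites of one molecule, the
lexicographically first sanitized product is taken, deterministically; all
site isomers share the same formula, so expected ions are unaffected.

Similarity structure over products uses circular (Morgan) fingerprints,
radius 2, 2048 bits — the de-facto standard parameters — with Tanimoto
similarity and average-linkage agglomeration on `1 - T`. Parameters travel
with the fingerprints and mismatched parameters refuse to compare.

## LC-MS quality control

A run is an rt-ordered list of centroided MS1 spectra read from mzML (via
Bioconductor's mzR; profile-mode data is rejected rather than silently
centroided). The verdict chain is:

1. **TIC** — per-scan summed intensity.
2. **Peak finding** — local maxima filtered by topographic prominence
   (threshold: fraction of the TIC maximum, default 0.05) and base-to-base
   width (default 2 scans). Prominence bases become the half-open peak
   window. A flat trace has no maxima and yields no peaks, so blank runs
   fail QC by construction.
3. **Peak spectrum** — by default the centroids of all scans in the window
   are pooled, clustered on the m/z axis (gaps above half the match
   tolerance split clusters) and summed; summation is robust to apex
   jitter. Apex-only aggregation is available.
4. **Ion matching** — for every (target, adduct) expected ion
   `mz = (M + delta)/|z|`, the most intense signal within tolerance is
   reported with its intensity rank in the whole peak spectrum. The default
   tolerance is an absolute 0.3 Da, appropriate for the unit-resolution
   instruments used for reaction monitoring; a ppm mode exists but is off
   by default. The default adduct list is `[M+H]+` only — positive-mode
   protonation is what defines the "expected molecular ion" in this
   workflow — and is user-extensible.
5. **Verdict** — success iff any peak window contains a within-tolerance
   expected ion. Matches that are not the base peak of their spectrum still
   count as success but are flagged `minor`: manual review of campaign data
   tends to reclassify exactly this category, so it is surfaced rather than
   suppressed.

Reconciliation against human yes/no labels yields TP/TN/FP/FN per sample.
Per-iteration report rows carry the percentage each category represents;
campaign totals average the per-iteration *percentages* (iterations weigh
equally, regardless of size — the convention of the summary tables this
layout reproduces) and sum the counts. Percentages are computed unrounded
and rounded once, half-up, at the printed precision; machine-readable
output always retains the raw values because rounded totals compound error.

## Synthetic LC-MS campaigns

The generator writes labelled mzML campaigns so the QC chain is testable
without instrument data. A spiked run contains its product's `[M+H]+`
species with

* a Gaussian chromatographic profile (`abundance * exp(-(rt-apex)^2/2s^2)`,
  default width s = 4 s on a 2 s scan grid, apex drawn at least 4s inside
  the gradient);
* a carbon-only isotopologue envelope: binomial over the carbon count with
  per-carbon heavy-isotope probability 0.0107 and spacing 1.00336 Da.
  Nitrogen/sulfur isotopes are ignored — adequate for testing ±0.3 Da
  matching, and a documented non-goal beyond it;
* additive Gaussian intensity jitter (default sd 50 counts).

Every run additionally receives decoy signals: per spectrum a
Poisson-distributed number of ions at uniform random m/z with exponential
intensities on the baseline scale (default 500 counts; the default spiked
abundance of 1e4 gives signal-to-baseline 20). The decoy rate is the one
deliberately calibrated constant: 0.5 expected decoys per spectrum over a
50-1050 m/z window makes the run-level probability that noise lands within
0.3 Da of the expected ion about 3% — the level at which real campaign QC
reports false positives from noise. Denser decoy fields (several per
spectrum) would make every run contain hundreds of independent decoy m/z
values and drive the false-positive verdict rate above 25%, which no real
unit-resolution CRM run exhibits.

What the synthetic campaigns do not emulate: chromatographic tailing and
drift, ion suppression, co-eluting isobars, profile-mode peak shapes, and
persistent chemical background at fixed m/z. Passing recall/false-positive
criteria on this generator therefore demonstrates the correctness of the
readout chain under its stated noise model, not instrument-grade
performance.

## Stereochemistry from replicate event maps

When a racemic CRM yields a bound product whose methyl position is
ambiguous, the two candidate enantiomer geometries imply two candidate
methyl-carbon positions bonded to the same ring carbon. The package samples
each map by trilinear interpolation at evenly spaced points along each
candidate C-C bond and summarises a profile by its **mean positive
density** (mean over samples > 0; 0 if none — the reading of "mean positive
density" as positives-only rather than a clamped mean; the alternative is a
config switch). Each replicate structure contributes one (R, S) pair, and a
paired t-test on the differences decides:

* `t = mean(d) / (sd(d)/sqrt(k))`, df = k-1, one-sided upper tail;
* call R if `p < alpha` for R-S, S if the mirror test clears alpha,
  otherwise inconclusive; alpha defaults to 0.01;
* k = 1 is an error: single structures cannot be unambiguously assigned,
  which is the entire point of pooling replicates;
* degenerate inputs (zero variance) are flagged: infinite t with p = 0 for
  a non-zero mean, t = 0 with p = 0.5 otherwise.

Sidedness is genuinely open ("the 1% level" does not say); the default is
one-sided with the direction as the hypothesis under test, recorded in the
output, with a two-sided mode available. Under the one-sided default the
procedure's size is alpha *per direction* (2 alpha for "any call"), which
is what the type-I acceptance check measures: the rate of calling one
designated direction on signal-free maps, compared against alpha = 0.01
with an exact binomial test.

The synthetic map fixture places a Gaussian blob (sd 0.8 Å, approximating a
methyl footprint) at the true methyl position of a 1.54 Å C-C bond, plus
white per-voxel noise. Two geometry choices matter and are deliberate:

* the two candidate directions are **mirror images across a lattice
  plane**, so both probe bonds have identical geometry relative to the
  voxel grid — otherwise interpolation-variance differences between a
  lattice-aligned and a diagonal bond bias the null test toward one call;
* the default grid is fine (64³ voxels at 0.075 Å): with line sampling, the
  information available to the test is the number of independent noise
  degrees of freedom along the bond. At k = 3 the one-sided 1% critical t
  is 6.96, so detecting effect/noise = 4 reliably needs on the order of 20
  effective samples along the bond; a 0.3 Å grid caps this at ~5 and the
  call rate at ~65%. The fixture therefore represents an *oversampled*
  event map, and bond profiles default to 21 sample points so the sampling
  pitch matches the voxel pitch (11 points would discard about half the
  available information; measured recovery drops from ~0.98 to ~0.93).
  Real event maps have spatially correlated noise at the resolution length
  scale, i.e. fewer independent degrees of freedom than white noise on a
  fine grid; recovery rates on this fixture are accordingly an upper bound
  on what identical statistics achieve on real maps.

Maps are read and written as mode-2 (float32) CCP4/MRC with x/y/z axis
order and orthogonal cells (the Cartesian-to-grid transform is the only
place a triclinic extension would slot in); format compliance is
cross-checked against an independent CCP4 implementation in the tests.

## Campaign accounting

Funnel rates divide each stage's successes by the previous stage's
(synthesis attempts → LC-MS-confirmed products → usable datasets →
product-bound structures). Zero denominators yield `NA`, never 0. Raw
fractions are always retained; the two printed precisions seen in campaign
figures (integer and one-decimal, both half-up) are provided as columns
rather than chosen silently.

Resource totals scale per-target manual figures (days, columns/work-ups,
solvent) by target counts and compare them with the automated totals;
years use 365 days/year (which reproduces the conventional 25.68 y from
9372 days). Savings are reported as automated/manual fractions and as the
solvent fold reduction manual/automated. All stored values are unrounded;
rounding happens at render time only.

## Problem sizes and determinism

The shipped tests and the acceptance script use: full enumeration of the
six example iterations (1876 targets, largest array 32 × 32 = 1024); a
100-run simulated campaign (91 scans/run, 50% spiked); 100 seeded
recovery trials and 200 null trials of the k = 3 map experiment (64³
grids). Every random quantity takes an explicit integer seed — there is no
hidden global RNG state, and a given (inputs, seed) pair reproduces
byte-identical mzML and map files.

## Known limitations

* Chemistry validation stops at mass closure; the enumerator will happily
  apply a chemically nonsensical rule that balances its formula.
* One adduct list per route; adduct abundance is not modelled.
* No quantification, retention-time prediction or MS2 support.
* Orthogonal map cells only; line probes (no cylindrical averaging).
* The carbon-only isotope model under-represents envelopes of S/Cl-rich
  products.
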