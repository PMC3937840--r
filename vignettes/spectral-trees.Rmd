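---
title: "Spectral trees, distMS2 and the mzDB library: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral trees, distMS2 and the mzDB library: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iontrees)
```

This vignette explains the models and procedures `iontrees` implements,
the parameters that matter, the numerical choices behind them, and what
the synthetic data used in the test suite does and does not establish
about real measurements.

## 1. The data model

An MS^n scan is a peak list (m/z, intensity) plus the information needed
to place it in a spectral tree: its ms level and its *precursor chain* —
the ordered m/z values of the ancestor ions, MS^1 first. An MS^3 scan
acquired by isolating m/z 867, fragmenting, isolating the product 705 and
fragmenting again has the chain `c(867, 705)`. The chain invariant
(`length(chain) == ms_level - 1`) is enforced at construction
(`msn_scan()`), and the readers reject scans whose chain cannot be
completed rather than guessing.

For mzML/mzXML input (read through mzR) the chain is taken from a
Thermo-style filter string (`"ms3 867.00@cid35.00 705.00@cid35.00"`) when
one is present, because it carries the full chain in a single attribute;
otherwise it is reconstructed by walking precursor-scan references up to
MS^1. Vendor filter-string grammars vary and are not fully documented, so
the parser accepts only the conservative `m@energy` token pattern and
falls back to the reference walk for anything else. The plain-text
*scantable* format (one scan per TSV row, documented in `read_scans()`)
exists so that every analysis can be exercised and reproduced without
binary files.

## 2. Tolerances and peak merging

All m/z comparisons go through a single tolerance abstraction: absolute
(±δ Th; default 0.5, suited to nominal-mass ion-trap data) or relative
(±δ ppm; default 20, suited to Orbitrap-class data). The half-window of a
candidate pair is evaluated at the smaller of the two m/z values, which
makes every predicate symmetric; for merging, the gap between adjacent
sorted peaks is compared against the half-window at the lower member.

Peak merging — used both for consensus spectra across scans and for
centroiding profile data — is greedy single-linkage on the sorted peak
list: adjacent peaks whose gap does not exceed the half-window share a
bin. Each bin emits the **median** of the member m/z values with the
**maximum** (default) or the 95% quantile of member intensities. We chose
single linkage over fixed-grid binning because it has no bin-boundary
artifacts and is independent of input order; the price is that a long
chain of closely spaced peaks can form one wide bin, which at the
default tolerances is rare for centroided small-molecule spectra. The
procedure is idempotent (outputs are separated by more than the
half-window), which the test suite asserts on random inputs. The 95%
quantile uses the standard linear-interpolation definition
(`quantile(type = 7)`); `max` is the default because it is what the
high-resolution centroiding workflow uses. Zero-intensity profile points
are discarded before centroiding — they carry no ion signal and would
only distort bin medians.

## 3. Tree construction and quality control

For one MS^1 bin (root ± half-window) and one sample, all MS^2 scans form
one group (they share the chain `[root]`) and MS^3 scans form one group
per distinct `(root, product)` chain; each group's scans are merged into
a representative spectrum that records `n_scans`. Two QC rules precede
tree construction and deposit:

* scans with base-peak intensity below 100 (arbitrary units) are removed —
  weak spectra show the largest scan-to-scan variation. The threshold is
  a parameter (`min_base_peak`); 100 is the default for ion-trap
  intensities. We apply the rule to MS^2 and MS^3 scans alike for
  consistency, since weak MS^3 scans are noisy for the same physical
  reason.
* across samples, only the tree with the highest number of MS^3 spectra
  is kept (`select_most_branched()`): the most branched tree captures the
  most fragmentation-pathway information. Ties — not addressed by the
  rule itself — are broken deterministically by the larger summed MS^2
  base-peak intensity, then by the smallest sample id.

Trees serialize to the compact text notation used in the literature
(`"248-206 (175, 149), 231"`): MS^2 product ions in descending
representative intensity, each with up to `top_k_ms3_ions` MS^3 products
in parentheses. There is no published intensity cutoff defining "major"
product ions, so the count is an explicit parameter rather than a guess.
The parser accepts both hyphen-minus and the typographic en-dash; the
writer always emits hyphen-minus (machine-safe ASCII). Round numbers are
used because the notation is a nominal-mass convention.

## 4. distMS2

Both spectra are reduced to their `top_n` (default 5) most intense ions
and normalized by the base peak or by the sum of the selected ions
(default **sum**, which bounds the score in [0, 2] and makes scores
comparable across pairs). Ions are matched one-to-one greedily by
increasing |Δm/z| (ties: higher intensity product, then lower m/z), and

d(S₁, S₂) = Σ_matched |I₁ − I₂| + Σ_unmatched I,

with the unmatched sum running over **both** spectra — the variant under
which the score is exactly symmetric. The matching tolerance is the same
δ used everywhere else (0.5 Th / 20 ppm), exposed as a parameter because
no single value suits both resolutions.

Properties, all asserted in the tests: d ≥ 0; d(S,S) = 0 and symmetry
hold *exactly* (same floating-point operations in both directions);
the sum-normalization bound 2 is attained by ion-disjoint spectra. The
triangle inequality fails — tolerance chaining gives the concrete triple
A = {100.0}, B = {100.4}, C = {100.8} with d(A,B) = d(B,C) = 0 but
d(A,C) = 2 — so distMS2 is a quasi-metric and downstream methods must not
assume metricity (classical MDS tolerates this by truncating negative
eigenvalues).

Greedy one-to-one matching is not guaranteed optimal. On sparse spectra
at realistic tolerances (4 ions over m/z 50–1000, 0.5 Th) enumeration
over 1000 random instances finds no case where the greedy pairing differs
from the brute-force optimum; when candidate windows overlap heavily
(ions crowded into a few Th with a wide tolerance) a gap can open, and
one such instance is recorded in the test suite. We keep the greedy
matcher because it is deterministic, O(k² log k) for k ions, and exact in
the regime the method targets.

The baseline metric 1 − r aligns the union of ions (unmatched ions get
intensity 0 in the other spectrum) and computes Pearson's correlation
over the aligned vectors. Alignment is not part of the usual definition
of a correlation distance on spectra; zero-filled union vectors are our
interpretation, documented here, and the natural one for sparse spectra.
A constant aligned vector (e.g. a single shared ion) leaves r undefined
and raises an error rather than returning an arbitrary value.

## 5. LC utilities

XICs sum all peak intensity within the m/z window per MS^1 scan.
Chromatographic peak detection is deliberately simple — moving-average
smoothing (default 5 points) followed by local-maximum picking with
valley-bounded extents — because peak detection is not this package's
contribution; the module boundary allows a wavelet-based detector to be
dropped in. Retention-time statistics report the median with the
[min, max] range and RSD% = 100·sd/mean, using the sample (n−1) standard
deviation; apex RTs collected across samples are the intended input.
MS^2 scans are assigned to the peak whose RT window contains them,
nearest apex on overlap — a deterministic rule for a case the data rarely
disambiguate better.

## 6. High-resolution annotation

Theoretical m/z values are computed from a bundled monoisotopic table
(C, H, N, O, P, S, Na, K, Cl; 6+ decimals) plus adduct arithmetic.
**The electron mass is not included** in ion m/z. This hydrogen-transfer
convention keeps [M+H]⁺ and [M−H]⁻ exactly symmetric about the neutral
mass, and it is the convention under which the package's worked
high-resolution fragment set — the five diagnostic ions of
PI(16:0,18:3) — all fall within 8 ppm of their observed values; with the
electron term included, the sn2 carboxylate ion drifts to ≈9 ppm. Users
comparing against electron-corrected references should be aware of the
~0.00055 Da offset. The five PI fragment compositions shipped in
`pi_16_0_18_3_fragments()` were derived by us from the standard
glycerophospholipid fragmentation nomenclature (acyl carboxylates,
dehydrated inositol-phosphate and glycerophosphate ions, combined
RCOOH + inositol loss); they are a synthetic reference list, not a
database export. The 8 ppm matching window is applied to the absolute
value of the signed ppm error.

## 7. The mzDB library

The library is a single-file SQLite database with the two data tables of
the spectral-tree schema: `experiment` (species, tissue, treatment,
extraction, chromatography, ionization, polarity, collision energy,
pre-processing notes) and `mz` (m/z, optional RT, serialized MS^2/MS^3
representative spectra, annotation). Beyond those two we add only a
`schema_version` guard (no silent migrations) and an `annotation_audit`
table, because annotation is an evolving judgement and previous values
should survive updates. Spectra are stored as compact
`mz:intensity` text (6-decimal m/z), which round-trips within 1e-6
relative — sufficient for both nominal and 20-ppm workflows. Metadata the
schema does not name goes in the free-form notes field; we do not invent
columns. The default duplicate policy for one (experiment, root m/z) is
reject-with-error, with an explicit replace flag, since a study
contributes one tree per nominal ion.

## 8. The synthetic-scan generator

The generator is the test bed's ground truth. It emulates the noise
structure multi-stage data actually show: multiplicative lognormal
intensity noise with a chosen coefficient of variation (lognormal keeps
intensities positive; the mean is corrected to 1 so templates are
unbiased), bounded uniform m/z jitter, and per-peak dropout mirroring the
fact that weak precursors often yield no higher-stage scans. The LC
generator adds Gaussian chromatographic peaks with per-sample apex jitter
and emits MS^2 scans near each apex from the corresponding isomer
template. All draws run under a pinned RNG (Mersenne-Twister, inversion
normals), so fixtures are identical across platforms and sessions and
never stored as files.

Default study conditions used by the clustering checks: four isomer
templates sharing the precursor (nominal m/z 503) and most fragment ions
(341, 323, 221, 179, …) but differing in intensity ratios — the
trihexoside situation where intensity-aware comparison matters — apexes
at 300/336/378/402 s with 4 s across-sample jitter (≈1% RSD), 13 samples
× 4 MS^2 scans per peak (52 spectra per isomer, 208 total), intensity
cv 0.3. On this fixture the mean silhouette of the generator labels in a
2-D MDS embedding is computed for both metrics, and distMS2's exceeds
the 1 − r baseline's; the suite asserts distMS2 > 0.5 and the ordering,
not any tuned value.

What the generator does **not** emulate: chromatographic tailing,
isotope envelopes, adduct co-generation, correlated (structured) noise
between fragments, and real fragmentation chemistry. Passing tests
therefore demonstrate algorithmic correctness and statistical behaviour
under the stated noise model, not instrument fidelity.

## 9. Degenerate inputs and numeric conventions

* Spectra with no positive intensity are *degenerate*: normalization and
  distMS2 raise errors rather than emitting NaN.
* Empty peak lists merge to empty; empty trees serialize to the empty
  string; an empty candidate list annotates to an empty table.
* Intensity ties in top-n selection break toward the lower m/z; all
  orderings used anywhere are total, so results are permutation
  invariant (asserted for grouping).
* Classical MDS truncates negative eigenvalues at zero and zero-pads
  (with a warning) when fewer positive eigenvalues than requested
  dimensions exist.
* m/z is Th throughout; RT is seconds; DIMS scans carry `NA` RT and are
  rejected by RT-dependent operations by name.

## 10. Known limitations

Only MS^1–MS^3 trees are modelled (deeper stages would extend the chain
machinery but have no representation in the tree type); there is no
cross-sample RT alignment — fragmentation-pattern similarity as an
anchor for alignment ("landmark peaks") is noted as future work; no
in-silico fragmentation or external database querying; no charge-state
or isotope-pattern inference (singly charged ions are assumed); the
peak detector is intentionally minimal. Test problem sizes (hundreds of
spectra, tens of scans per tree) were chosen to exercise the statistics
at desk scale; the algorithms are polynomial and run comfortably at
project scale, but the pairwise distance matrix is O(n²) in the number
of spectra and dominates run time for large n.
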