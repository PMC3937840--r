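# iontrees

Spectral trees from multi-stage mass spectrometry for metabolite annotation.

## The problem

Untargeted metabolomics by LC-MS or direct-infusion MS (DIMS) detects
thousands of features characterized only by m/z (and retention time), and
most of them never acquire a chemical identity. Multi-stage mass
spectrometry helps: an electrospray-generated ion can be isolated and
fragmented by collision-induced dissociation to give an MS² spectrum, and
an MS² product ion can be fragmented again to give MS³. The resulting
**spectral tree** (or ion tree) — the MS¹ precursor at the root, its MS²
product-ion spectrum below it, and MS³ spectra of selected MS² products as
branches — carries structural information that complements accurate mass
and retention time. Small molecules yield *sparse* fragmentation spectra (a
handful of ions), so spectral comparison methods developed for peptides
transfer poorly.

`iontrees` is an R toolkit for this setting. It

- reads MS^n scans with their **precursor chains** (the ordered series of
  ancestor ions, e.g. `867 (MS¹) → 705 (MS²)` for an MS³ scan) from
  mzML/mzXML (through Bioconductor's mzR) or from a plain-text scan table;
- groups scans whose chains agree within a tolerance (±0.5 Th for
  nominal-mass ion-trap data, ±20 ppm for high-resolution data) and
  computes **representative spectra**: fragment ions within the tolerance
  are merged at the median of their m/z values with the maximum (or 95%
  quantile) intensity, so all available scans contribute and scan-to-scan
  variation can be assessed;
- builds one ion tree per MS¹ bin and sample, applies quality control
  (scans with base-peak intensity < 100 arbitrary units are discarded;
  across samples, only the tree with the most MS³ spectra is kept), and
  deposits trees in **mzDB**, a two-table SQLite library (`experiment`
  meta-data + `mz` records) supporting distMS2-ranked search and audited
  annotation updates;
- compares sparse MS² spectra with **distMS2** and embeds distance
  matrices by classical multidimensional scaling to resolve co-eluting
  isomers;
- computes theoretical fragment m/z from elemental formulas and adducts
  ([M−H]⁻, [M+K]⁺, ...) for ppm-tolerance annotation, and detects
  neutral-loss series (e.g. repeated losses of 162, hexose − H₂O);
- ships a deterministic synthetic-scan generator so every analysis is
  testable without vendor raw files.

## The distMS2 quasi-metric

Each spectrum is reduced to its *n* most intense ions (default n = 5) and
normalized either by the base peak or by the sum of the selected ions.
With ions matched one-to-one within the m/z tolerance,

    distMS2(S1, S2) = Σ_matched |I1 − I2|  +  Σ_unmatched I

where the second sum runs over the unmatched ions of *both* spectra. The
score satisfies non-negativity, symmetry and d(S, S) = 0, but not the
triangle inequality — a quasi-metric. Under sum normalization it is
bounded by 2, attained when two spectra share no ions. Because it uses
both ion identity and relative intensity, it separates isomeric compounds
with shared fragments better than the correlation-based distance 1 − r
(also provided as a baseline).

## Worked example

```r
library(iontrees)

## a DIMS ion tree: MS2 + three MS3 chains under the precursor m/z 867
scans <- make_msn_scans(templates_tree867(), 5,
                        noise_model(intensity_cv = 0.2, seed = 867))
scans <- qc_filter_spectra(scans, min_base_peak = 100)
tree  <- select_most_branched(build_tree(scans, 867, tol_da(0.5)))
tree
#> <ion_tree> root m/z 867, sample=S1: 1 MS2 node(s), 3 MS3 node(s)
tree_to_text(tree, top_k_ms3_ions = 2)
#> [1] "867-705 (543, 381), 543 (381, 219), 525 (363, 345)"
neutral_loss_series(tree$ms2_nodes[[1]]$peaks, 867, 162, tol_da(0.5))[[1]]
#> 867 -> 705 -> 543   (repeated loss of 162: hexose - H2O)

## sparse-spectrum distance
s1 <- new_peaks(c(100, 150), c(1000, 500))
s2 <- new_peaks(c(100, 160), c(600, 240))
distms2(s1, s2, norm_mode = "base_peak")  # |1-1| + 0.5 + 0.4
#> [1] 0.9
distms2(s1, s2, norm_mode = "sum")        # |2/3-5/7| + 1/3 + 2/7
#> [1] 0.6666667

## high-resolution fragment annotation of PI(16:0,18:3), tol 8 ppm
obs <- new_peaks(c(255.2340, 277.2148, 241.0110, 152.9946, 391.2249),
                 c(100, 90, 80, 70, 60))
annotate_fragments(obs, pi_16_0_18_3_fragments(), tol_ppm = 8)
#>   observed_mz                        label theoretical_mz  ppm_error
#> 1    391.2249 [M-H - sn2 RCOOH - inositol]       391.2250 -0.1290872
#> 2    241.0110     inositol phosphate - H2O       241.0113 -1.3646973
#> 3    152.9946   glycerol-3-phosphate - H2O       152.9953 -4.4767420
#> 4    255.2340             sn1 RCOO- (16:0)       255.2324  6.2482921
#> 5    277.2148             sn2 RCOO- (18:3)       277.2168 -7.0528537
```

The ion tree reads: precursor m/z 867 fragments to 705, 543 and 525; the
MS³ spectrum of 705 shows 543 and 381, and so on — the text line is the
compact notation used to publish such trees. The annotation table shows
every observed high-resolution fragment within 8 ppm of a candidate
composition, sorted by |ppm error|.

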