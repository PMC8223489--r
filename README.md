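# hexpaint

Quantification of hexagonal peptide patterns on DNA origami from DNA-PAINT
single-molecule localization data.

## The problem

DNA origami can display ligands — here TRAIL-mimicking peptides targeting
death receptor 5 — at programmed nanoscale positions, and DNA-PAINT
super-resolution imaging is the standard way to verify that the displayed
pattern matches the design. In DNA-PAINT, dye-labeled imager strands
transiently hybridize to single-stranded docking sites on the origami, so
each peptide-carrying site blinks over thousands of camera frames and can
be localized far below the diffraction limit. What the microscope delivers,
however, is only a long table of localizations. Turning that table into the
quantities of interest — how many of the six designed sites are actually
occupied on each structure, and how far apart the detected sites are —
requires a dedicated analysis chain, which this package implements:

1. **Quality filtering** (`filter_localizations()`): localizations with
   precision > 0.03 camera pixels, ellipticity < 0.1, or photon count more
   than 2 SD above the mean are removed (all three rules evaluated against
   the statistics of the unfiltered table).
2. **Drift correction** (`estimate_drift()`, `apply_drift()`): redundant
   cross-correlation (RCC) — the acquisition is cut into 200-frame
   segments, every pair of segment renderings is cross-correlated with
   sub-pixel peak refinement, and the per-segment offsets are solved
   jointly by least squares, interpolated per frame, and subtracted.
3. **Structure detection** (`detect_rois()`): a 20× oversampled
   rendering is binarized, connected blobs become square ROIs centered on
   the localization-weighted centroid, and ROIs are quality-controlled on
   localization count and temporal span (genuine docking sites blink
   throughout the acquisition; nonspecific stickers do not).
4. **Site calling** (`detect_sites()`): each ROI is rendered at the
   design's oversampling (60–150× depending on pattern size),
   normalized, Gaussian-smoothed, and its local maxima become candidate
   peptide positions; maxima closer than 0.5× the designed spacing are
   merged and only the central cluster of maxima is kept.
5. **Pattern statistics** (`summarize_patterns()`): sites-per-structure
   histogram, site occupancy `mean(min(n_sites, 6)) / 6`, and the
   per-structure mean nearest-neighbor distance (NND). For a complete
   regular hexagon with edge *e* the mean NND equals *e*, so the NND
   distribution directly reports the realized pattern size.

The package also provides the registry of pattern designs (`get_design()`:
W6 … W37 and L6/L11, regular hexagons with edges 5.7–37 nm), a synthetic
DNA-PAINT acquisition simulator with ground truth
(`simulate_acquisition()`) for validating the pipeline, and the wet-lab
arithmetic used alongside the imaging: gel-dosimetry site occupancy
(`gel_occupancy()`) and luminescence viability normalization
(`viability_percent()`).

## Worked example

Simulate a DNA-PAINT acquisition of 20 fully occupied W16 structures
(15.8 nm design spacing) under the default imaging conditions — 12000
frames, 300 ms exposure, 87 nm camera pixels, 10 nM imager, 1 nm
localization precision — and run the full pipeline:

```r
library(hexpaint)

sim <- simulate_acquisition("W16", 20, occupancy = 1, seed = 42)
res <- quantify_pattern(sim$locs, "W16")
print(res$filter_report)
print(res$summary)
```

```
<filter_report> 12136 in, 417 removed (0 precision, 171 ellipticity, 252 photons), 11719 retained
<pattern_summary> W16: 20 ROIs, occupancy estimate 1.000, mean NND 15.58 nm (SD 0.09)
sites per ROI:

 0  1  2  3  4  5  6 
 0  0  0  0  0  0 20 
```

All 20 structures are recovered as ROIs, every ROI yields the full 6
sites (occupancy estimate 1.000), and the mean nearest-neighbor distance
of 15.58 nm reproduces the 15.8 nm design spacing to within 1.4% — the
small shortfall is the expected attraction between neighboring site
images under Gaussian smoothing. On partially occupied samples the same
pipeline recovers the per-site occupancy: the sites-per-ROI histogram
follows the binomial of the true occupancy and `occupancy_estimate`
matches it to within a few percent.

A thin command-line wrapper over these functions is installed at
`inst/scripts/hexpaint-cli.R` (subcommands `filter`, `undrift`,
`detect-rois`, `quantify`, `gel-occupancy`, `viability`).

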