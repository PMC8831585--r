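# mifish

Analysis of combinatorial multi-color DNA FISH (miFISH) experiments in R.

In miFISH, many chromosomal loci are visualized in a **single** hybridization
round by spectral barcoding: each oligo probe targets a ~66 kb locus and is
labelled either with one dye or with two alternating dyes, so the probe's
identity is encoded in the color combination observed at one 3D position.
The reference design covers 16 loci on the q-arm of human chromosome 2 with
6 dyes: the 10 dual-color probes use all C(5,2) = 10 unordered pairs of
AF488/AT542/AF594/AT647N/AF700, and 6 single-color probes use one dye each
(AF790 only here). For a diploid G1 nucleus this predicts 10 dots per
channel for the five dual-combination dyes and 2 dots for AF790.

The package implements the full analysis chain for such data, plus a
ground-truthed simulator used to validate every stage:

* **Simulation** — ellipsoidal nuclei, chromosome-territory chain models of
  the 16 loci (Gaussian steps with sd `scale * gap_Mb^nu`), pixel-integrated
  Gaussian dot rendering with Poisson + Gaussian sensor noise, and bead
  calibration fields with injected chromatic aberrations.
* **Spot detection** — strict 6-connectivity maxima filtered by a
  PSF-matched difference-of-Gaussians response, then two-stage
  maximum-likelihood Gaussian localization (pixel-integrated 2D fit, then a
  1D axial fit), reaching few-tens-of-nm precision that scales as
  sigma/sqrt(N).
* **Chromatic correction** — per-channel 2nd-order lateral polynomial plus a
  constant axial shift, fitted to mutually-matched bead localizations
  against the AT647N reference channel.
* **Nuclei** — Otsu 3D segmentation, G1 gating by integrated DNA intensity,
  and normalized lamina distances `d_E / (d_E + d_C)` from an exact
  anisotropic Euclidean distance transform.
* **Decoding** — k-means homolog clustering, brightest-K candidate
  selection, dual-color pairing under dichroic-dependent co-localization
  thresholds (0.25 / 0.55 µm), the split-dot filter (0.50 µm), brightness
  assignment of single-color probes, a 5 µm outlier filter, and a
  random-allocation null model.
* **Geometry & validation** — natural cubic-spline chromosome traces with
  analytic curvature and normalized peaks, pairwise distance statistics,
  and concordance with Hi-C contact matrices and A/B compartment calls.

## Worked example

```r
library(mifish)

scheme <- build_chr2_scheme()
expected_channel_counts(scheme, n_alleles = 2)
#>  a488   tmr  a594   cy5  a700 ir800
#>    10    10    10    10    10     2

nrow(probe_pair_table(scheme))
#> [1] 120

# simulate, render and decode one diploid G1 cell
scene <- simulate_structures(scheme, 1, seed = 5)[[1]]
dots <- do.call(rbind, lapply(c("a488","tmr","a594","cy5","a700","ir800"),
  function(ch) dog_detect(render_stack(scene, ch, seed = 1), ch,
                          dog_threshold = 5)))
dots$dot_id <- seq_len(nrow(dots))
cl <- cluster_homologs(dots, seed = 3)
alloc <- decode_cluster(cl$dots[which(cl$dots$cluster_id == 1), ], scheme)
table(alloc$status)
#> assigned  missing
#>       15        1
```

The counts are the design expectation per nucleus (10 dots per
dual-combination dye, 2 for AF790); 120 is the number of unordered probe
pairs used in distance/Hi-C comparisons; the decoded cluster recovers 15 of
the 16 probes in this cell — clusters with 13–16 identified probes are the
typical outcome, and losses come from unresolvable same-channel dot pairs.

A full simulated run (`run_pipeline(mifish_config(n_cells = 10))`) writes
`nuclei.csv`, `dots.csv`, `allocations.csv`, `pairwise_distances.csv`,
`structures.csv` and a run log into the configured output directory. A thin
command-line wrapper is installed at `inst/scripts/mifish.R`
(`simulate`, `run-all`, `init-config` subcommands).

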