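# dsbchrom

Break-centered chromatin analysis of Cas9-induced DNA double-strand
breaks (DSBs), in R.

When Cas9 cuts chromatin, the break reorganizes its neighbourhood:
cohesin-driven loop extrusion anchored at the break produces a
cross-shaped "stripe" of contacts in Hi-C maps, the cut acquires
TAD-boundary-like insulation, DNA-end resection loads RPA/RAD51 on a few
kilobases of single-stranded DNA with opposite strand polarity on the two
sides of the cut, and the RAD51 homology search spreads over a broad
(hundreds of kb) chromatin domain that is constrained by TAD boundaries.
`dsbchrom` provides the statistics used to quantify each of these
signatures from binned Hi-C contact matrices and stranded ChIP-seq
coverage, together with a synthetic-data generator that emulates their
statistical structure so every estimator can be validated against a known
injected truth.

It is intended for computational genomicists analysing multi-target
CRISPR ChIP-seq/Hi-C experiments, and for method developers who need a
controlled test bed for break-centered aggregation statistics.

## What it computes

**Differential Hi-C aggregation** (`extract_windows`, `differential_map`):
per-site windows centered on the cut bin and the site-averaged
log2((T + eps)/(U + eps)) map; the break-anchored stripe is the row and
column through the center. Virtual-4C profiles and their treated-minus-
untreated differential (`virtual_4c`, `site_differential_4c`).

**Insulation** (`insulation_score`, `delta_insulation`,
`correlate_enrichment`): the sliding-square score for bin *i* is

    raw(i)  = mean of counts over bins (i-d .. i-1) x (i+1 .. i+d)
    score(i) = log2( raw(i) / chromosome mean of raw )

with d = square/bin (default 500 kb at 25 kb bins). A lower score means
stronger insulation. The per-site damage-induced change dIS (treated −
untreated, averaged over a 50 kb window on the cut) is summarized with a
one-sample t-test, and its drop (−dIS) can be rank-correlated (Spearman,
average ranks) with per-site repair-factor enrichment.

**ChIP meta-profiles and widths** (`meta_profile`, `fit_two_component`):
treated-minus-untreated RPM profiles around cut sites at two scales, and a
two-stage weighted least-squares fit of

    f(x) = c + A_n exp(-x^2 / 2 s_n^2) + A_b exp(-x^2 / 2 s_b^2),  s_n < s_b

reporting each component's FWHM = 2 sqrt(2 ln 2) s: the narrow resection
peak (kb scale) and the broad homology-search domain (hundreds of kb).

**Strand asymmetry** (`strand_asymmetry`): forward-minus-reverse
enrichment, its polarity switch at the cut, and the extent of the
asymmetric region (resection span).

**TAD-boundary statistics** (`boundary_drop`, `band_difference`): the
normalized drop of the broad domain across boundaries 200–700 kb from the
cut (each profile normalized to its cut-proximal mean; drop = 1 − distal
mean), with distance-matched random controls, and distance-band
(−1.5..0.5 / 0.5..1.5 Mb) comparisons between conditions.

**Synthetic data** (`sim_params`, `make_sites`, `simulate_contact_pair`,
`simulate_chip_pair`): Poisson contact maps with power-law distance decay,
TAD blocks, a linearly decaying break-anchored stripe and cross-break
attenuation; stranded ChIP coverage with background + narrow peak + broad
domain, boundary truncation and resection-polarity strand asymmetry.
Every run records a truth object that regenerates the data bit-for-bit.

## Worked example

The bundled demo simulates a 2 × 60 Mb genome with 30 cut sites and runs
every stage:

```r
library(dsbchrom)
cfg <- read_config(system.file("extdata", "demo_config.yaml", package = "dsbchrom"))
cfg$out_dir <- "demo_out"
rep <- run_pipeline(cfg, quiet = TRUE)
print(rep)
```

```
<run_report> seed 7, stages: simulate, hic, insulation, chip, asymmetry, boundary, bands
  insulation: mean dIS -0.747 (p=<2e-16), 100% of sites drop
  widths: narrow 5.89 kb, broad 420 kb
  boundary drop 2.47 (p=2.24e-08) vs control 0.794
```

Reading the numbers:

* mean dIS = −0.747 — Cas9 treatment lowers the insulation score at every
  one of the 30 cut sites (the cut behaves like a de novo TAD boundary);
  the generator injected a cross-break contact attenuation of 0.4.
* narrow FWHM 5.89 kb — the fitted width of the narrow cut-site peak; the
  generator injected a 2.5 kb s.d. component (FWHM 5.887 kb).
* broad FWHM 420 kb — the broad domain fitted on this demo is narrower
  than the injected Gaussian (s.d. 250 kb, FWHM 589 kb) because the demo
  generator truncates it at TAD boundaries, exactly the truncation the
  boundary stage then detects.
* boundary drop 2.47 (p = 2.2e-08) — the enrichment falls sharply when
  crossing a TAD boundary away from the cut; the paired random-site
  control shows the residual smooth-decay level rather than a sharp drop.

The run directory holds every intermediate as plain text: BED6 sites and
boundaries, dense contact-map TSVs, per-strand bedGraphs, profile and
table TSVs, the YAML truth record, and `report.yaml` (byte-identical
across reruns with the same config and seed).

A thin command-line front end with subcommands (`simulate`,
`hic-aggregate`, `insulation`, `chip-profile`, `strand-asym`, `boundary`,
`bands`, `run`) is installed at
`system.file("cli", "dsbchrom.R", package = "dsbchrom")`.

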