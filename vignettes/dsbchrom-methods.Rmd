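---
title: "Methods: break-centered chromatin statistics and their synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: break-centered chromatin statistics and their synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbchrom)
```

`dsbchrom` quantifies how a programmed double-strand break (DSB)
reorganizes its chromatin neighbourhood: break-anchored contact stripes
and gained insulation in Hi-C, a narrow resection footprint and a broad
homology-search domain in repair-factor ChIP-seq, strand asymmetry of the
resected ends, and truncation of the broad domain at TAD boundaries. This
vignette is the package's own account of the models behind each
statistic, the parameters that matter, what the synthetic generator does
and does not emulate, and the design choices that were genuinely open.

## 1. The generative model

All estimators in the package are validated against a generator whose
parameters (`sim_params()`) are the quantities the analyses estimate.

**Contacts.** For one chromosome binned at `contact_bin_size` (default
25 kb), the expected count for bins at separation $s$ is a power law with
an offset,

$$\mu(s) = A \left(\frac{s + s_0}{s_0}\right)^{-\alpha},$$

with $\alpha = 1$ (the classic distance-decay slope of mammalian Hi-C at
the sub-Mb scale) and $s_0$ one bin. TAD structure multiplies same-TAD
pairs by `tad_multiplier` (default 2) and attenuates each pair once per
intervening TAD boundary by `boundary_insulation` (default 0.5). In the
treated condition, each cut site adds a cross-shaped stripe: pairs with
one end in the cut bin and the other within `stripe_extent` $L$ (default
1 Mb, the distance the break-anchored signal spans) gain the factor
$1 + k\,(1 - d/L)$ with `stripe_strength` $k$ (default 2); and pairs whose
ends flank the cut bin are multiplied by `cut_attenuation` (default 0.4),
the cross-break contact loss that makes the cut behave like a de novo
boundary. Counts are independent Poisson draws per upper-triangle bin,
then symmetrized. The linear stripe kernel and the attenuation constant
are stand-ins: the data this emulates show a decaying break-anchored
signal and diminished cross-break contacts without establishing a
functional form.

**ChIP coverage.** Untreated coverage is flat background `background`
reads per `chip_bin_size` bin (defaults 10 reads / 100 bp). Treated
coverage adds, per site, a narrow Gaussian (total mass `narrow_reads`,
s.d. `narrow_sd`, default 2.5 kb — FWHM 5.887 kb, the resection/filament
footprint scale) and a broad Gaussian (mass `broad_reads`, s.d.
`broad_sd`, default 250 kb — FWHM 588.7 kb, the homology-search domain
scale). With `truncate_at_boundaries` the broad component is zeroed
beyond the first TAD boundary on each side of the cut. Within
`resection_span` of the cut (default 1 kb per side) a fraction
`asym_fraction` (default 0.8) of narrow-component reads goes to the
strand matching 3'-resection polarity — forward-dominant on the telomeric
(right) side, reverse-dominant on the centromeric (left) side; the
convention is recorded in the truth object so tests are
convention-independent. Sampling is Poisson per bin per strand. The
Gaussian broad-domain shape is likewise a stand-in; the truncated-Gaussian
choice is what makes "domain width" a well-defined injected truth.

**Depth and the RPM pedestal.** When `depth` is set, each condition's
expected totals are rescaled to that library size before sampling, as if
both libraries were sequenced to a fixed depth. A consequence worth
understanding: because the treated library spends part of its depth on
signal, its *background* RPM is slightly lower than the untreated one, so
treated-minus-untreated RPM profiles sit on a small negative pedestal far
from the cut. This is a real property of subtracted RPM tracks, not an
artifact; at genome scale (signal fraction of reads near zero) the
pedestal vanishes, while on desk-scale genomes it is visible and is
absorbed by the background term of the width fit. The default background
of 10 reads/bin keeps the signal fraction of reads in the 10–25% range
typical of a strong ChIP on the genome sizes used in the tests.

**Seeds.** Every stochastic draw flows from the single integer seed in
`sim_params()`, through per-stream derived seeds; a truth record
(`write_truth()`/`read_truth()`) round-trips losslessly and regenerates
the data bit-for-bit. Noise is pure Poisson — no overdispersion; adding a
negative-binomial option is an extension point, and estimators that pass
under Poisson noise are not thereby validated against overdispersed real
libraries.

## 2. Insulation

The sliding-square score of bin $i$ is the mean count over the square
$(i-d..i-1) \times (i+1..i+d)$, $d$ = `square_size`/bin, normalized as
log2 of the ratio to the chromosome-wide mean of finite raw scores. The
default square of 500 kb at 25 kb bins ($d = 20$) spans the sub-TAD scale
at which the cut's gained insulation is visible; the parameter is exposed
because the analysis that motivated it names the method but not its
window. Masked bins are excluded from each square; a bin whose square is
more than half masked, or within $d$ of a chromosome end, is NaN. The
implementation accumulates plain `sum/length` in storage order so that an
independent double-loop implementation reproduces it bit-for-bit — the
equivalence the test suite asserts on random masked matrices.

Per-site change (`delta_insulation`) averages treated − untreated score
over the bins overlapping a 50 kb window on the cut (2 or 3 bins at
25 kb, depending on phase — all overlapping bins are taken,
deterministically), excludes sites with any NaN bin, and tests the mean
against zero with a one-sample t-test. With identical inputs the t
statistic is undefined and reported as NaN with an explanatory flag
rather than an error.

`correlate_enrichment` pairs the per-site insulation drop with a per-site
enrichment scalar (treated − untreated RPM summed over ±10 kb by default;
the window is a package choice, exposed in the config). Spearman's rho
uses average ranks; the default p-value is the large-sample
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation. A permutation method is
available: exact enumeration up to $n = 9$ (beyond that, $n!$ is
intractable) and a seeded Monte-Carlo permutation above. On the
generator's output this correlation is null by construction — cleavage
efficiency does not modulate the injected signals, so per-site coupling
between insulation drop and enrichment is *not* part of the synthetic
model; the estimator itself is calibrated on Gaussian-copula data with
known rank correlation instead.

## 3. Widths of the narrow peak and the broad domain

The central estimator decision of the package: the source analyses report
peak "widths" without defining an estimator, so `dsbchrom` defines the
width of each component as the FWHM of a fitted Gaussian, and fits the
two components on two scales. A single-scale joint fit is unreliable
here: with a ~100× scale separation the broad component can swallow the
narrow one, and a profile fine enough for a kb-scale peak but long enough
for a Mb-scale domain is enormous. The default two-stage scheme
(`fit_two_component`):

1. **Broad stage** on the coarse profile (≤10 kb bins over ≥±1.5 Mb) with
   the narrow region masked (±3 times the median narrow-width
   initialization): fit $c + A_b e^{-x^2/2\sigma_b^2}$.
2. **Narrow stage** on the fine profile (≤200 bp bins over ≥±15 kb) with
   the broad component and background held fixed: fit
   $c_2 + A_n e^{-x^2/2\sigma_n^2}$, $\sigma_n$ bounded above by
   $\sigma_b$.

Both stages run Levenberg–Marquardt (`minpack.lm::nlsLM`) with
non-negative amplitude bounds, a deterministic five-point multi-start
over the width initialization (fractions of each profile's span), a
1e-8 tolerance and a 500-iteration cap; the best residual wins, so the
fit is a deterministic function of its inputs. Profiles are converted to
per-bp density so the two scales share units. On an exactly flat profile
the Gaussian gradient is singular at zero amplitude; the fit then falls
back to the constant model with zero amplitude and reports convergence.
Standard errors come from the per-stage covariance and are conditional on
the staging (the broad parameters are treated as known in stage 2). A
joint single-stage fit is available behind `two_stage = FALSE`.

Two properties of the *data*, reproduced by the generator, matter when
interpreting fitted widths: (i) boundary truncation shrinks the fitted
broad FWHM below the injected Gaussian's — the width-recovery validation
therefore runs with truncation off, because truncation changes the truth
itself; (ii) sites whose broad domains overlap contaminate each other's
windows, so recovery studies place sites several Mb apart, mirroring the
real sparsity of ~126 sites in a 3 Gb genome.

## 4. Strand asymmetry

The asymmetry profile is forward minus reverse treated-minus-untreated
RPM. The polarity switch is the zero crossing, nearest the cut, of the
3-bin sign-smoothed profile (raw sign flips bin-to-bin in noise). The
extent is the total span of the two contiguous above-threshold lobes
flanking the cut, with the threshold at 10% of the maximum absolute
asymmetry — a free choice (the observable it mirrors is quoted only as
"~2 kb"), exposed in the config; because the asymmetry passes through
zero at the cut itself, the lobes are found separately on each side and
the central gap is included in the span. An identically zero profile
yields extent 0, switch NaN, and a flag. Axes are genomic by default;
per-site flipping by guide-RNA strand is a supported option since
resection polarity is strand-defined.

## 5. Boundary drop and distance bands

For each (cut site, boundary) pair at 200–700 kb, the enrichment profile
over boundary ±100 kb is oriented cut-proximal-left and normalized by its
cut-proximal mean; drop = 1 − distal mean. "Normalized" is undefined in
the source analyses, so this unitless-fraction interpretation is a
package decision, with one stability guard that belongs to it: a ratio of
near-zero means is unbounded, so besides the non-positive-proximal
exclusion, pairs whose proximal mean is below 10% of the group's median
positive proximal mean are excluded and counted. On tracks with signal
everywhere — the regime of real data — the guard excludes nothing.
Random controls are drawn at distances matched to the true site–boundary
distance distribution by inverse empirical CDF, on a random side of a
random site, excluding positions within one flank of any true boundary;
the draw is seeded and deterministic. Distance matching uses the inverse
*empirical* CDF (no interpolation) so the control distances are draws
from exactly the matched distribution.

Band comparisons (`band_difference`) average per-site enrichment within
half-open signed bands (default [−1.5, 0.5) and [0.5, 1.5) Mb — the
half-open convention places a value at exactly +0.5 Mb in the distal
band) and compare two conditions with an unpaired two-sided t-test; the
reported difference is condition B minus condition A.

## 6. What the tests show, and at what sizes

The validation suite runs entirely on synthetic data, at sizes chosen so
the whole suite completes in minutes on one CPU while each study keeps
the statistical structure it needs: null calibration and perturbation
detection on 30–70 Mb chromosomes at 25 kb bins (126 sites for the
detection study, matching the multi-target scale); width recovery on a
30 Mb chromosome with 6 sites ≥4 Mb apart at depth 5e6 over 20 seeds;
asymmetry recovery on 12 Mb with 20 seeds; boundary truncation on
2 × 140 Mb with 36 sites ≥7 Mb apart (sparse occupancy keeps neighbour
TADs signal-free, as in a real genome) with a broad s.d. of 3 Mb so the
Gaussian stand-in is near-flat across the 200–700 kb control range and
the test isolates truncation rather than the stand-in's curvature; band
broadening on 20 Mb over 20 seeds. The demo pipeline uses a 2 × 60 Mb
genome with 30 sites.

Passing these tests shows the estimators recover known truths under the
generator's assumptions — Poisson noise, Gaussian/linear signal shapes,
uniform background, uncoupled per-site effects. It does not show
robustness to overdispersion, mappability structure, copy-number
variation, replicate variability, or matrix balancing, none of which the
generator emulates.

## 7. Other fixed conventions

* Coordinates are 0-based half-open throughout; a cut site is a single bp
  assigned to the bin containing it.
* The log2-ratio pseudocount defaults to 1 count (the ratio is undefined
  on zeros) and is recorded in every aggregate map.
* Contact maps are used as provided (raw or balanced; the tag
  propagates); synthetic maps are raw.
* The center bin (cut self-interaction) is included in aggregates; a mask
  flag exists because protein-bound ends may distort it. Sites whose
  windows overlap another site are kept by default (overlaps are rare at
  realistic sparsity); a filter flag exists.
* Site-centered differential virtual-4C uses the two bins flanking the
  cut as viewpoints, mirroring the left profile so positive distances
  point away from the break, then averaging; a cut-bin viewpoint mode
  exists, and is what the stripe-decay checks use, since the synthetic
  stripe lives entirely in the cut bin's row.
* Contact maps are exchanged as dense TSV with `#key=value` headers;
  coverage as per-strand bedGraph plus a YAML library-size sidecar;
  sites/boundaries as BED6 (cleavage rank in the score column); configs
  and truth records as YAML. Pipeline reports carry no timestamps, so a
  rerun with the same config and seed is byte-identical.

## 8. Known limitations

The boundary-drop ratio is meaningful only where the enrichment track is
positive at the pair's proximal flank; on weak signals the stability
guard can exclude many pairs (the counts are reported). Standard errors
of the two-stage fit understate joint uncertainty. The generator draws
strictly intra-chromosomal contacts and models no sister-chromatid or
trans signal, no replication timing, and no coupling between cleavage
rank and signal strength — per-site rank is carried through the pipeline
but drives nothing in the synthetic model.
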