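---
title: "Profiling mass shifts from open proteomics searches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling mass shifts from open proteomics searches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massshiftr)
```

## The problem

An open (mass-tolerant) database search matches MS/MS spectra to peptides
while allowing a wide precursor mass window, so a peptide can be identified
even when it carries a modification the search did not model. What remains
unexplained is the *delta mass* of each peptide-spectrum match (PSM): the
observed precursor mass minus the theoretical peptide mass. Across a data
set these delta masses concentrate into discrete populations, one per
modification (or combination of modifications), superimposed on noise.

`massshiftr` turns FDR-filtered PSM lists and their fragmentation spectra
into a modification profile: which mass shifts are present, how abundant
each is in each experiment, what known modifications explain each shift,
which residues carry it, how it perturbs the fragmentation spectrum, and
how it moves chromatographic retention time (RT).

## The procedure

`shift_profile()` runs five stages. Each is also exported on its own.

**1. Histogram.** All delta masses (every experiment pooled, unit weight per
PSM) are binned at `bin_width` = 0.0002 Da. Pooling with unit weights is
proportional to averaging per-experiment histograms weighted by their share
of total PSMs, so peak calling is identical. The range is extended by 5 Da
on either side so edge peaks survive smoothing. A small uniform jitter
breaks ties between repeated delta masses and bin boundaries. The histogram
is then smoothed by convolution with a truncated Gaussian kernel spanning
`smoothing_bins` = 5 bins. The kernel sigma is fixed by the requirement
that those 5 bins cover `smoothing_mass_fraction` = 95% of the Gaussian
mass: sigma = (5/2) / qnorm(0.975) ≈ 1.2755 bins; kernel weights are the
per-bin integrals of that Gaussian, renormalized. At the histogram ends the
kernel is re-truncated and renormalized per source bin, so total weight is
conserved exactly — a property the test suite asserts to 1e-9 relative.

**2. Peak calling.** To make descent monotone, adjacent bins are first
grouped into non-overlapping sets spanning `flatten_width` = 0.0010 Da
(5 bins at defaults) and each set is flattened to its minimum. Local maxima
of the flattened vector are candidate apexes. Prominence is measured by
walking outward from the apex while heights are non-increasing; the
shoulder is the height where the descent stops, and prominence is
`(apex - max(shoulders)) / apex`. The raw apex-to-shoulder *ratio* is
always ≥ 1 and could not be compared against a threshold inside (0, 1), so
the normalized drop is used; peaks are called when it exceeds
`prominence_threshold` = 0.3. Candidates are ranked by the signal-to-noise
remainder (SNR): mean bin height in a 0.004 Da window centred on the apex
minus the mean height of the two adjacent 0.005 Da background flanks. The
top `top_n_peaks` = 500 by SNR are retained. Peak boundaries are the bin
edges where the monotone descent ends, clipped to apex ±
`precursor_tol` = 0.01 Da, whichever is closer. Each PSM is assigned to the
peak whose boundaries contain its raw delta mass (nearer apex on overlap),
and counts are normalized to each experiment's PSM total.

Two location summaries are kept per peak: the bin-quantized `apex_mass`,
and `reported_mass`, the mean raw delta mass of the assigned PSMs. The
latter is independent of bin quantization and is the mass printed in
reports and matched during annotation.

**3. Annotation.** Each peak mass is decomposed into at most two components
drawn from: a catalogue of common modification masses shipped with the
package, single-residue insertion/deletion masses for all 20 amino acids,
isotopic-error entries at ±1 and ±2 × `isotope_spacing` (1.00235 Da, the
peptide averagine spacing; the constant is configurable), user-defined
shifts, and signed "misattributed" counterparts of variable modifications
searched upstream (a variable modification assigned during search but
physically absent appears as its negative mass). Matching is staged: an
immediate single-entry match within `annotation_tol` = 0.01 Da; then pairs
of (user shift + any entry); then pairs drawn from the pool of entries
already used in completed single annotations plus the masses of peaks so
far left unannotated, processed in SNR order. With
`prioritize_user_mods = TRUE` any candidate containing a user shift
outranks any that does not; remaining ties go to the smaller absolute
residual, then to fewer components. This staging lets a user-declared
failed alkylation (−57.0215 Da) pull compound artifacts such as −9.0368 Da
(failed alkylation + cysteine trioxidation, +47.9847 Da) out of the
"unannotated" pile.

**4. Localization.** For every assigned PSM with a resolvable spectrum, the
peak's shift is placed on each residue in turn and the PSM is rescored
against its own spectrum with an MSFragger-style hyperscore:
`log10(Nb! · Ny! · max(ΣIb, 1) · max(ΣIy, 1))` over greedily matched singly
charged b/y ions (nearest spectrum peak within the fragment tolerance, each
peak usable once; factorials in log space). A PSM is *localizable* when
some placement matches strictly more fragment ions than the unshifted
baseline. Localization weight is split uniformly across the top-scoring
positions (score ties rather than matched-count ties — the finer of the two
criteria). Per peak and experiment, site weights are summed by residue and
divided by the residue's background frequency; the background is counted
over all localizable PSMs in the data set by default, with unique-peptide
and per-peak (`bin_*`) scopes selectable. This enrichment obeys the
identity that its background-frequency-weighted mean is exactly 1, which
the tests assert for every scope.

**5. Modified/unmodified comparison.** PSMs with |delta mass| <
`unmodified_threshold` = 0.001 Da form an index keyed by (peptide, charge)
within each experiment, capped at `unmodified_cap` = 50 spectra per key by
seeded random subsampling. Each assigned PSM is compared against its
counterparts at the same charge: cosine similarity between intensities
accumulated on a fixed 0.05 Th m/z grid (no binning rule is prescribed for
this comparison upstream, so the grid is explicit and configurable;
square-root intensity transforms are off by default, and precursor peaks
are not stripped), and ΔRT = PSM RT − mean counterpart RT. A PSM in the
zero-shift bin is never compared against itself. Low mean similarity
indicates a non-labile or C-terminal modification; ΔRT near zero flags
in-source losses, which occur after elution and therefore leave RT
unchanged, while genuine sample modifications shift RT.

Counterparts are looked up within the same *experiment* rather than the
same LC-MS run: the run-level restriction is stricter than the input
schema guarantees (run identity is only implicit in spectrum identifiers),
and experiment-level lookup is the coarsest scope that never crosses
processing conditions.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `bin_width` | 0.0002 | Da | resolves sub-millidalton peak separation (e.g. formylation 27.9949 vs dimethylation 28.0313) |
| `jitter_half_width` | 0.0001 | Da | half a bin; breaks boundary ties without blurring structure |
| `smoothing_bins` / `smoothing_mass_fraction` | 5 / 0.95 | bins / – | fixes kernel sigma ≈ 1.2755 bins |
| `prominence_threshold` | 0.3 | – | normalized drop to the higher shoulder |
| `snr_signal_window` / `snr_background_flank` | 0.004 / 0.005 | Da | signal/background averaging windows |
| `top_n_peaks` | 500 | – | peaks sent downstream |
| `precursor_tol` | 0.01 | Da | cap on boundary distance from apex |
| `annotation_tol` | 0.01 | Da | match tolerance, single or pair sums |
| `unmodified_threshold` / `unmodified_cap` | 0.001 / 50 | Da / spectra | unmodified bin and per-peptide cap |
| `fragment_tol` | 20 | ppm | rescoring match tolerance (absolute Da selectable); upstream calibrated tolerances are input data we cannot assume |
| `background_scope` | `dataset_psm` | – | enrichment background population |

A note on the jitter default: a tie-break jitter of ±0.005 Da is 25× the
default bin width and would erase exactly the sub-millidalton structure the
0.0002 Da binning exists to resolve; the package therefore defaults to
±0.0001 Da (half a bin), and the larger value remains selectable via
`jitter_half_width`.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces the statistical structure the method relies
on: discrete delta-mass populations with Gaussian measurement error
(sigma 0.0005 Da, sharp relative to the 0.004 Da SNR window), shifts
implanted on designated residues with configurable site fidelity,
per-peptide base elution with modification-dependent RT offsets plus
Gaussian RT noise, theoretical singly charged b/y spectra with log-normal
fragment intensities treated as a peptide property (so replicate spectra of
the same peptide agree, and the zero-shift peak shows similarity near 1,
with per-spectrum jitter and uniform noise peaks on top), and a shared
peptide pool so unmodified counterparts recur.

The default fixture is 3 experiments × 2,000 PSMs over a 150-peptide
tryptic-like pool (lengths 7–16, charges 2–3), with eight implanted shifts
at frequencies 1.5–5% whose residue targets and RT offsets mirror common
labelling-experiment artifacts: oxidation on Pro, TMT overlabelling,
formylation and phosphorylation on Ser, deamidation on Asn, pre-elution
dehydration and ammonia loss (+450 s), and the failed-alkylation +
trioxidation composite on Cys.

It does **not** emulate: chromatographic peak shape or alignment drift,
charge-state envelopes and higher fragment charges, isotope envelopes,
co-isolation chimeras, TMT reporter ions, or realistic intensity models.
Passing tests therefore demonstrate correctness of the algorithms under
the stated noise model, not performance on real instrument data.

## Numerical choices and degenerate inputs

* Kernel sigma from the inverse-normal quantile (above); kernel integrals
  by `pnorm` differences; edge conservation by per-source renormalization.
  Constant histograms are preserved exactly away from the outer 2·(span/2)
  bins, where edge weight is redistributed inward.
* Block flattening suppresses structure narrower than `flatten_width`; an
  isolated population must span more than one flatten set to be callable.
  The flatten span is tied to the smoothing span (same 0.0010 Da), which
  keeps the two scale-invariant together under `bin_width` changes.
* Greedy fragment matching resolves exact-distance ties toward the lower
  m/z peak; annotation ties resolve by smaller residual, then fewer
  components, then catalogue order. All are deterministic.
* Factorials are computed via `lfactorial`, so large matched-ion counts
  cannot overflow.
* Degenerate inputs: an empty PSM list is an error; a histogram with no
  callable peak yields an empty peak set with a warning and header-only
  reports; an experiment with zero PSMs reports zero counts; a PSM whose
  spectrum is missing stays in the histogram and quantification but is
  excluded from localization and similarity — and, consequently, from the
  localization background (its residues are unobservable for placement, so
  counting them would bias enrichment denominators).
* Reports print masses at 4 decimal places — 3 would round away mass
  differences comparable to `annotation_tol` — and rates at 2; z-scores use
  the sample (n−1) standard deviation, with constant columns mapped to
  zeros.

## Problem sizes used by the test suite

The suite validates peak calling against an exhaustive per-bin enumeration
oracle on 1,000 random histograms of ≤ 200 bins, fragment rescoring against
a direct matcher on 500 random spectra of ≤ 20 peaks, conservation on 100
random histograms, implant recovery on the default 3 × 2,000-PSM fixture,
and residue recovery over 50 fixture seeds of 60 PSMs each. These sizes
give the oracles full coverage of edge cases (plateaus, ties, truncated
windows) while keeping each property's runtime in seconds to a few
minutes.

## Known limitations

Only singly charged b/y ions are scored; c/z ions, a ions and multiply
charged fragments are out of scope, as are multi-site placements of a
single shift, PTMProphet-style localization probabilities, isotope-envelope
deconvolution, RT alignment across runs, site-restriction vetoes during
annotation, and any FDR handling (inputs are assumed pre-filtered).

## A worked run

```{r example}
fx <- generate_dataset(fixture_spec(n_experiments = 2, n_psms = 400,
                                    rng_seed = 11))
exset <- assemble_experiment_set(fx$psm_tables, fx$spectra)
prof <- shift_profile(exset, shift_config(top_n_peaks = 50))
prof
head(prof$global[, c("reported_mass", "n_psms", "annotation",
                     "mean_similarity", "mean_delta_rt", "top_residue")])
```
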