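# massshiftr

Post-processing of **open (mass-tolerant) database search** results in
shotgun proteomics.

An open search identifies a peptide even when it carries an unmodeled
modification; what is left behind is each PSM's **delta mass**
Δm = M_observed − M_theoretical. Across a data set these delta masses form
discrete populations — one per modification or modification combination.
`massshiftr` is for proteomics researchers and pipeline builders who need
to turn FDR-filtered PSM lists (plus their MGF/mzML spectra) into an
interpretable modification profile: which mass shifts are present, their
abundance per experiment, their likely identities, the residues that carry
them, and their spectral and chromatographic signatures.

## What it computes

1. **Delta-mass histogram** — all PSMs pooled at unit weight into
   0.0002 Da bins, extended 5 Da beyond the extremes, tie-break jitter,
   then smoothed with a truncated Gaussian kernel over 5 bins whose sigma
   is set so those bins hold 95% of the kernel mass
   (σ = 2.5 / Φ⁻¹(0.975) ≈ 1.2755 bins). Total weight is conserved exactly.
2. **Peak calling** — bins are block-flattened to local minima for
   monotonicity; local maxima with normalized prominence
   (apex − shoulder)/apex > 0.3 are called, ranked by the signal-to-noise
   remainder SNR = mean(signal window 0.004 Da) − mean(background flanks
   0.005 Da), top 500 retained; boundaries are the descent endpoints
   clipped to apex ± 0.01 Da; PSMs are assigned by boundary containment
   and counts normalized to experiment size.
3. **Annotation** — each peak mass is decomposed into ≤ 2 components from
   a modification catalogue, residue insertions/deletions, isotopic-error
   spacings (±k·1.00235 Da), and user-defined shifts, via staged matching
   (single entry → user + any entry → pairs of previously used
   components), tolerance 0.01 Da, user shifts prioritized.
4. **Localization** — the shift is placed on every residue in turn and the
   PSM rescored against its spectrum with the hyperscore
   log₁₀(N_b!·N_y!·max(ΣI_b,1)·max(ΣI_y,1)) over greedily matched singly
   charged b/y ions; localizable iff some placement beats the unshifted
   matched-ion count; tied sites share weight; residue enrichment =
   (site-weight fraction) / (background residue fraction).
5. **Modified/unmodified comparison** — PSMs with |Δm| < 0.001 Da are
   indexed by (peptide, charge), capped at 50 per key; each modified PSM
   gets a mean grid-cosine spectral similarity and mean ΔRT against its
   counterparts. ΔRT ≈ 0 flags in-source losses; low similarity flags
   non-labile or C-terminal modifications.

Multi-experiment runs call peaks on the aggregate histogram and report
every attribute per experiment and pooled, including a z-scored
experiment × peak profile matrix for batch-effect inspection.

A synthetic-fixture generator (`generate_dataset()`) with a ground-truth
manifest makes the whole pipeline testable offline.

## Worked example

```r
library(massshiftr)

fx    <- generate_dataset(fixture_spec(n_experiments = 2, n_psms = 500,
                                       rng_seed = 11))
exset <- assemble_experiment_set(fx$psm_tables, fx$spectra)
prof  <- shift_profile(exset, shift_config(top_n_peaks = 50))
prof
```

```
Mass-shift profile
  1000 PSMs in 2 experiment(s); 9 peak(s) called
  top mass shifts by PSM count:
       0.0000 Da     732 PSMs  None
     229.1629 Da      51 PSMs  TMT 10-plex
      15.9949 Da      39 PSMs  Oxidation
      27.9950 Da      38 PSMs  Formylation
       0.9840 Da      36 PSMs  Deamidation
     -18.0106 Da      35 PSMs  Dehydration
      79.9662 Da      31 PSMs  Phosphorylation
     -17.0265 Da      22 PSMs  Ammonia loss
```

```r
head(prof$global[, c("reported_mass", "n_psms", "annotation",
                     "mean_similarity", "mean_delta_rt", "top_residue")], 6)
```

```
  reported_mass n_psms  annotation mean_similarity mean_delta_rt top_residue
1     1.445e-05    732        None          0.9779       0.04465        <NA>
2     2.292e+02     51 TMT 10-plex          0.4845     -68.19450           S
3     1.599e+01     39   Oxidation          0.4589     -30.55706           P
4     2.800e+01     38 Formylation          0.4718      66.44864           S
5     9.840e-01     36 Deamidation          0.4899      39.61783           N
6    -1.801e+01     35 Dehydration          0.5461     444.98326           E
```

Reading the rows: the zero-shift peak holds the unmodified PSMs — its
spectra match their own peptide's replicates almost perfectly (similarity
0.98) and its ΔRT is ~0 s. The implanted TMT overlabelling peak
(229.1629 Da) localizes to Ser, elutes ~68 s earlier than its unmodified
counterparts, and its shifted fragment ions depress the cosine similarity
to ~0.48. The dehydration peak shows the +445 s RT shift of a genuine
pre-elution modification — the signature that separates real sample
chemistry from in-source losses. `write_reports(prof, "out/")` writes the
five deterministic TSV reports; localization and similarity tables are
also available per experiment in `prof$localization` and
`prof$comparison`.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/ptm-profiler.R fixtures --out fx --seed 5
Rscript inst/scripts/ptm-profiler.R run \
  --psm fx/psm_exp01.tsv=exp01,fx/psm_exp02.tsv=exp02 \
  --spectra fx/exp01.mgf,fx/exp02.mgf \
  --user-mods "failed alkylation=-57.0215" --out out
```

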