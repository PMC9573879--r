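---
title: "Targeted quantification of protease products in purified organelles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted quantification of protease products in purified organelles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomahaqr)
library(dplyr)
```

## The problem

Intramembrane proteolysis of the amyloid precursor protein (APP) happens
inside the endolysosomal system: BACE1 cleaves the juxtamembrane region to
produce the membrane-tethered fragment CTF-beta, and gamma-secretase then
cuts inside the membrane to release amyloid-beta (A-beta) peptides of
varying length (A-beta 37 through 43). Where exactly each cleavage occurs,
and how inhibitors (BSI, GSI) and modulators (GSM) shift the product
spectrum *within a given organelle*, are questions that bulk assays cannot
answer.

The measurement strategy this package implements couples three ideas:

1. **Half-tryptic reporter peptides.** A peptide with one terminus made by
   an endogenous protease and the other by in-vitro trypsin is a unique,
   sequence-level witness of an in-organelle cleavage event. Each monitored
   cleavage site yields a parent tryptic peptide and two half-tryptic
   products that concatenate exactly to the parent.
2. **Trigger/target multiplexed acquisition.** A synthetic copy of each
   monitored peptide, labelled with a "super-heavy" isobaric reagent
   (TMTsh), is spiked into the sample. It co-elutes with the endogenous,
   TMT-labelled targets but sits at a known precursor m/z offset
   (`n_label_sites * (mass_TMTsh - mass_TMT) / z`). The instrument watches
   MS1 for the trigger, confirms its identity in real time, and only then
   spends expensive SPS-MS3 scans on the target — quantifying all
   multiplexed channels at once from reporter ions.
3. **Knockout-channel background.** Two channels carry material from
   APP-null cells. For every APP-derived peptide their reporter signal
   defines the noise floor, so "the product disappeared under drug X" can
   be stated relative to a measured background rather than zero.

Everything here is driven by a synthetic-data generator with full per-scan
ground truth, so each stage — design, acquisition logic, quantification,
statistics — is testable without any vendor raw files.

## The monitored peptides

`demo_substrate()` is a **synthetic** APP-like construct: the genuine
A-beta region (so the gamma-secretase half-tryptic products are the real
A-beta 29–37/38/39/40/42/43 C-terminal peptides, e.g. `GAIIGLMVGGVVIA` for
A-beta 42) embedded in invented flanking segments that reproduce the
tryptic context of the Swedish-mutant juxtamembrane (`...NL | DAEFR...`),
a transmembrane continuation, and a short tail. It is deliberately not the
real 751-residue isoform; positions in user-supplied proteins are resolved
through `isoform_offset` so sites quoted in isoform numbering work on
fragments.

```{r}
half_tryptic_products(demo_substrate(), 58)   # the A-beta 42 site
build_design(demo_substrate()) |>
  filter(role == "TARGET") |>
  select(peptide_id, sequence, termini, sim_group, amount_amol)
```

Mass arithmetic is monoisotopic throughout (proton 1.007276 Da), with
TMT +229.162 Da and TMTpro +304.207 Da per label site (N-terminus plus
each lysine), static cysteine carbamidomethylation (+57.021 Da) and
optional methionine oxidation (+15.995 Da). The TMTsh reagent's
monoisotopic mass is not public: `mod_table()` deliberately has no default
and errors until the user supplies one. The simulator uses an explicit
stand-in (235.1767 Da, a `sim_params()` field); nothing downstream depends
on its particular value, only on trigger/target arithmetic staying
consistent.

## What the generator emulates — and what it does not

`simulate_run()` produces a scan stream plus ground truth:

* **Abundances.** Each target peptide has a baseline endosomal amount in
  amol (defaults: long A-beta species most abundant at 150–200 amol, short
  ones 60–80 amol, juxtamembrane peptides 300–500 amol, matching the
  regime where half-tryptic species were detectable at a few hundred
  amol). Conditions act multiplicatively through `condition_effects()`:
  BSI doubles the uncleaved parent and sends both BACE1 half-tryptic
  products to background while reducing downstream gamma products
  (juxtamembrane cleavage precedes intramembrane cleavage); GSI sends all
  gamma products to background; GSM roughly doubles A-beta 37/38 while
  sending 39/40/42 to background; lysosomal channels scale everything by
  0.2 (within the several-fold endosome/lysosome difference). Knockout
  channels, and any fully suppressed species, sit at a configurable floor
  (1 amol) — background is a small positive quantity, never exactly zero.
* **Chromatography.** Gaussian elution (sigma 0.1 min); a trigger and its
  target co-elute exactly, which is what the method relies on.
* **Spectra.** Fragment relative intensities are a deterministic
  per-sequence pattern shared by trigger and target (same chemistry);
  interference peaks are injected uniformly at configurable density to
  exercise the purity filter; reporter intensities are the true channel
  abundances mixed through a column-stochastic isotopic impurity matrix.
* **Noise.** Two physically distinct terms, both off at `noise_cv = 0`:
  a single lognormal factor per scan shared by all of its peaks
  (spray/injection fluctuation — it cancels in within-scan ratios, exactly
  as co-migration guarantees on a real instrument), plus independent
  additive detector noise at the scan's noise floor. The floor is also the
  S/N denominator, so "reporter S/N" directly predicts relative precision:
  a channel measured at per-scan S/N 10 carries ~10% uncertainty per scan.
  An earlier draft used independent multiplicative noise per peak; it was
  replaced because it breaks that correspondence.
* **LMW filtration.** Each peptide belongs to a carrier species (free
  ~4.5 kDa A-beta vs ~87 kDa full-length/CTF); `apply_lmw_filtration()`
  rescales abundances by a logistic transmission around the 50 kDa
  cut-off. Filtrate and retentate sum exactly to the input.

Not emulated: ion optics and AGC dynamics (beyond the prescan scaling
rule), FAIMS, chimeric chromatography, retention-time drift, missed or
nonspecific cleavage, and any real biological variance between replicate
channels beyond measurement noise. Passing tests therefore demonstrate
correctness of the *computational* pipeline under a controlled forward
model, not performance on real instrument data.

All randomness descends from one master seed through named substreams
(per scan, per materialisation request), so identical seeds give
byte-identical runs and the engine's on-demand scans are reproducible.

## The acquisition engine

`run_engine()` replays the published real-time cascade offline, iterating
the MS1 stream in order (the instrument "listen/insert" loop is modelled
as synchronous iteration; requested scans are materialised from ground
truth at the request's retention time):

1. MS1 peaks matching a trigger within ±10 ppm, at the right charge, at
   intensity ≥ 5e4 start a cascade (several matches in one cycle are
   serviced in descending intensity; no dynamic exclusion for triggers).
2. A trigger MS2 is inserted and confirmed by real-time peak matching:
   strictly more than 6 theoretical fragments within ±10 ppm ("> 6" read
   as ≥ 7). The confirmed spectrum is stored as the library.
3. A target MS2 is inserted at the label-offset m/z and confirmed against
   the library — both the match count and the intensity rank order are
   checked by default (the prose is ambiguous about whether the count rule
   re-applies; both checks are config-selectable). Rank order is scored as
   a Spearman correlation with threshold 0.9 rather than exact permutation
   equality: with 16+ fragments, any nonzero noise produces adjacent-rank
   swaps, and an instrument rule that failed on those would never fire.
4. SPS candidates are label-carrying b/y ions whose observed relative
   intensity is within ±50% (relative deviation of the library-normalised
   value) and whose purity — own intensity over all signal within a 3 Th
   window — is at least 0.5. The top 10 by intensity are co-isolated
   (the targeted method's count is unstated; 10 mirrors the global
   method's top-10 rule).
5. A 10 ms reporter prescan estimates signal strength; the MS3 injection
   time is `min(5000 ms, 10 ms × AGC_target / prescan_signal)` — the
   vendor formula is unpublished, this proportional rule is a declared
   stand-in with the documented cap and fixed point.

Every decision is logged; tightening any threshold can only reduce the
number of MS3 scans, and tests verify the whole cascade against an
exhaustive brute-force oracle on random runs.

## Quantification

Reporter S/N is extracted from each MS3 scan within ±0.003 Da per channel,
summed per peptide across its qualifying scans, and impurity-corrected by
solving the mixing system (negatives clamp to 0 — vendor convention).
Background per peptide is the mean over knockout channels; condition
statistics use classical two-sided Student's t-tests (the equal-variance
reading of "Student's t-test"; Welch is available).

`normalize_total()` implements equal-loading total-reporter normalisation
and is idempotent, but the demo pipeline does not apply it to the targeted
stream: the published workflow takes loading factors from a parallel
*global* SPS-MS3 analysis, and in a targeted-only stream channel totals
measure biology (a knockout channel would be scaled up by orders of
magnitude), not loading. In the simulation, loading is equal by
construction.

Absolute amounts come from SIM-mode runs: the co-eluting target and
trigger precursor traces are extracted within ±10 ppm and integrated
trapezoidally; `total_amol = (target_area / trigger_area) × spike`. The
total is then apportioned over channels in proportion to corrected,
unnormalised reporter S/N. The source description of this step ("divided
by the relative quantitation") is dimensionally ambiguous; fractional
apportionment is used because it conserves the total exactly.

A species is called **at background** in a condition
(`condition_summary()`) when its mean S/N is within 2-fold of the knockout
background *or* its background-subtracted signal is below 5% of the
background-subtracted vehicle level. The second rule exists because at the
measurement floor the ratio of two near-zero means is dominated by noise
(impurity-correction residuals from adjacent high-signal channels exceed
the floor), making a pure ratio rule ill-posed.

## Enrichment statistics

For organelle-IP proteomics, `enrichment()` computes per-protein log2 fold
change of total-reporter-normalised means (half-minimum pseudocount
guards zero controls), classical t-tests, and adjusted p-values by the
adaptive two-stage Benjamini–Hochberg step-up procedure (first BH pass at
`alpha/(1+alpha)` estimates the null count m0; final adjusted values are
BH × m0/m — implemented here directly and verified against an independent
reference implementation). The enrichment *flag* uses the raw p-value
(log2FC > 1 and p < 0.02), matching how the printed filter pairs the
thresholds; the adjusted p is reported alongside so either reading can be
applied. Quartile summaries per annotation class use type-7 interpolation;
identifier harmonisation for set overlaps uppercases and strips isoform
suffixes, and never drops unmatched ids silently.

On 10,000 simulated null proteins the raw-p type-I error is 0.05 ± 0.01
(mildly conservative under lognormal noise), and detection on
strongly-separated synthetic IP tables reproduces an independent
per-protein loop exactly.

## Problem sizes and numerical choices

The shipped scenario sizes are deliberate: 9 monitored peptides, 11
channels, 0.1-min MS1 intervals over ~9 min of gradient (≈ 90 survey
scans, ≈ 5 MS3 per peptide); the direction-of-effect suite runs 100 seeded
replicates of a combined DMSO/BSI/GSI/GSM/KO design (the source
experiments split BSI/GSI and GSM/GSI across two 11-plexes; one combined
synthetic design exercises every contrast per seed); the engine oracle
comparison uses 100 random small runs. Zero-noise recovery is exact to
1e-6 relative error end-to-end; with noise (cv 0.05) the ensemble RMS
error of per-channel absolute amounts at per-scan reporter S/N > 10 is
2–3% — a single channel at the S/N-10 threshold is itself ~10%-noisy per
scan, which is why the precision statement is about the ensemble, not the
worst channel.

Other numerical conventions: ties in SPS ranking break by intensity;
degenerate t-tests (numerically constant groups) return p = 1 when means
agree and p = 0 otherwise rather than erroring; reporter extraction errors
if windows overlap at the requested tolerance; digestion of an empty
sequence, unknown residue letters, cleavage sites on tryptic boundaries,
singular impurity matrices, and designs without knockout channels are all
explicit errors.

## Known limitations

* The generator's condition effects are multiplicative and noiseless at
  the biology level; real replicate organelle preparations vary far more.
* Scheduled retention times are inputs; there is no RT prediction or
  drift, so the scheduling problem of real targeted methods is untested.
* Protein-level roll-up is a plain sum over PSMs; no parsimony inference.
* The TMTsh mass, the vendor injection-time formula, and the instrument
  noise distributions are stand-ins, clearly parameterised as such.
* mzML export is not provided; the documented columnar TSV pair
  (`write_scans()`) is the interchange format.
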