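---
title: "Spectral screening of small molecules against disordered protein targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral screening of small molecules against disordered protein targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ismsm)
```

## The problem

Intrinsically disordered proteins (IDPs) such as tau lack stable binding
pockets, so structure-based virtual screening has little to grip. The
informational spectrum method (ISM) sidesteps structure entirely: it treats
the primary structure of a biomolecule as a discrete signal of electronic
properties and asks whether two molecules share a *periodicity* in that
signal. Shared spectral components between a protein and its interaction
partners have long been interpreted as a signature of long-range recognition
(effective at roughly 5–1000 Å). `ismsm` implements the extension of this
idea to small molecules: a compound's structure is also rendered as a
one-dimensional signal, so protein–ligand spectral compatibility can be
scored for whole compound libraries at negligible cost per molecule.

## The encoding

Every position of the signal carries an electron–ion interaction potential
(EIIP, in Rydbergs):

$$W = \frac{0.25\,Z^* \sin(1.04\,\pi Z^*)}{2\pi},
\qquad Z^* = \frac{1}{N}\sum_i n_i Z_i,$$

where $Z^*$ is the average quasi-valence number (AQVN) of the molecule or
atomic group: the mean valence-*electron* count per atom ($Z_H = 1$,
$Z_C = 4$, $Z_N = 5$, $Z_O = 6$, ...). For proteins the package defaults to
the classical tabulated per-residue EIIP values shipped in
`inst/extdata/eiip_amino_acids.csv`; a `"computed"` mode derives values from
residue atomic composition through the same two formulas. The two sets do
not coincide (leucine is tabulated as exactly 0 Ry, for instance), and the
provenance travels with the table so downstream results are never ambiguous
about which alphabet they used.

For small molecules, the SMILES string is expanded to explicit-hydrogen form
and traversed in the parser's canonical atom order. Two conventions are
supported because the notion of "atomic group" is genuinely underdetermined:

* **per-group** (default): each heavy atom plus its bonded hydrogens is one
  group; its AQVN feeds the EIIP formula. Benzene becomes six identical
  CH groups at $W(2.5) \approx 0.0946$ Ry.
* **per-atom**: every atom, hydrogens included, contributes
  $W(Z)$ of its own valence-electron count.

Molecules with fewer than two heavy atoms are rejected — a one-point series
has no spectrum.

## Spectra and cross-spectra

The informational spectrum is the amplitude of the DFT of the encoded
series, reported on the normalized frequency grid $f_n = n/L$,
$n = 1..L/2$. Three numerical choices matter:

* **Mean-centering before the transform.** EIIP series have large DC
  offsets; without centering they leak into the low bins and drown real
  peaks.
* **A common grid.** A cross-spectrum multiplies spectra bin-wise, so all
  members must share one grid length $L$. Sequences of different length are
  zero-padded to a shared $L$ — by default the next power of two at or above
  the longest member, and at least 512. Padding (rather than truncation or
  resampling) preserves every series unchanged; the price is that a reported
  peak frequency can shift by about one bin between different grid choices,
  which is why frequency matching is done by nearest bin with a 1-bin
  tolerance, and frequencies print rounded to three decimals (the
  conventional F(0.xxx) notation).
* **S/N as peak over mean.** The signal-to-noise ratio of a frequency is its
  amplitude divided by the mean amplitude of the whole (cross-)spectrum —
  the standard ISM specificity measure. It is undefined (an error) on an
  all-zero spectrum.

Peak extraction takes local maxima (boundary bins included), ranks by
amplitude, breaks ties toward the lower frequency for determinism, and
greedily enforces a minimum bin separation.

The screening workflow derives candidate frequencies three ways, all
reducing to cross-spectra: per-ligand CS against the target, one joint CS
over the target plus all ligands, and a CS across ortholog sequences (a
conserved dominant peak suggests an evolutionarily maintained interaction
region). The union is deduplicated within a 1-bin tolerance, with
provenance and supporting ids kept per entry.

## Localizing the contributing region

Two complementary views localize which residues carry a target frequency:

* **Sliding window** (default length 64, step 1): each window is centered,
  padded, transformed, and the amplitude at the matched bin recorded. A
  window of 64 resolves periodicities down to $F \approx 0.08$ (period
  ~12.5 residues) while keeping residue-scale localization; the parameters
  are configurable because no canonical values exist. The *domain* is the
  contiguous run of windows at or above 70% of the peak response that
  contains the peak (ties to the earlier run), reported as residues from the
  first window's start to the last window's end, 1-based inclusive. BED
  export converts to 0-based half-open explicitly.
* **Morlet CWT** ($\omega_0 = 6$, the standard trade-off between time and
  frequency localization): the scale ladder is logarithmic over ±2 octaves
  around the scale whose Fourier period equals $1/f$, with an odd ladder so
  one row sits exactly on the target scale. Absolute coefficients are cut
  into five quantile bands — band 5 is the top quintile — computed only
  outside the cone of influence (within $\sqrt{2}s$ of an edge), because
  edge effects inflate coefficients; hotspot intervals overlapping the cone
  are flagged rather than silently trusted. *Hotspots* are the residues at
  the target scale with band ≥ 4, merged into sorted intervals.

The transform itself is computed in the Fourier domain (Torrence–Compo
normalization); the unit tests verify it against a direct time-domain
convolution of the analytic Morlet wavelet on interior positions.

## Scoring and ranking

Druglikeness enters through the Drug Score

$$dS = \prod_i \left(\tfrac12 + \tfrac12 s_i\right)\cdot\prod_i t_i,
\qquad s_i = \frac{1}{1 + e^{a p_i + b}},$$

over $p \in \{\log P, \log S, \mathrm{MW}, d\}$ with toxicity weights
$t = 1.0/0.8/0.6$ for none/low/high risk in four categories. The default
$(a, b)$ pairs orient every sigmoid so favorable values score high —
$(1, -5)$ for logP, $(-1, -5)$ for logS, $(0.012, -6)$ for MW (midpoint at
500 Da), $(-1, 0)$ for $d$ — following the descriptor-tool convention these
scores originate from; the alternative literal pairs
$\{1,-5\},\{1,5\},\{0.012,6\},\{1,0\}$ are available via
`drugScoreParams("printed")`, because under them high molecular weight and
high solubility would be *penalized into* $s \approx 0$ for nearly all real
drugs, which we judged to be a sign-convention artifact rather than intent.
The fragment-based druglikeness $d = \sum v_i / n$ is deliberately a
pluggable input (a descriptor-table column or caller-supplied fragment
scores): the reference fragment library behind it is proprietary, and $n$
is caller-defined normalization.

**Total Score** $= dS \times S/N$ ranks library hits; both factors favor
higher values. **Total Score 2** $= (S/N) / d_{\text{centroid}}$ ranks
within ADMET k-means clusters, favoring spectrally specific compounds near
the center of a pharmacokinetic chemotype. Clustering standardizes features
to zero mean and unit variance (constant columns dropped with a warning),
uses a fixed seed (default 42) with best-of-10 restarts for
reproducibility, and measures centroid distances in the standardized space
— raw ADMET features mix units (Da, log-units, binary flags), so raw-space
distances would be dominated by molecular weight. A compound exactly on its
centroid is flagged `rankFirst` rather than scored infinite. The
within/between variance decomposition always closes to 100%.

Screening declares a compound a hit through its *best* frequency (per-
frequency results are all reported); the S/N cutoff defaults to 20,
the lower edge of the range observed for well-behaved drug-like hits, and is
configurable since no canonical threshold exists. Ranking ties break by
compound id, making results independent of library order and
byte-reproducible.

## What the fixtures emulate — and what they do not

All statistical guarantees are stated against seeded synthetic fixtures:

* `makePlantedSequence()` injects $A\cos(2\pi f_0 (m-1))$ plus Gaussian
  noise directly in EIIP space (exact ground truth; generator SNR defined as
  $A/\sigma$), optionally confined to a burst region; a `quantize` mode
  snaps the signal onto the real amino-acid EIIP alphabet to emulate an
  actual protein sequence.
* `makeOrthologFamily()` gives 12 members sharing $f_0$ with independent
  noise and ±10% length jitter — the shape of a mammalian ortholog set with
  one conserved spectral region.
* `makeDecoyLibrary()` emits small random (but always valid) C/N/O/S chain
  SMILES, optionally planting one poly-heteroether "matched ligand" whose
  per-group series is periodic at $f_0$ (its fundamental dominates for
  periods up to ~6 atoms).
* `makeAdmetBlobs()` draws well-separated Gaussian clusters with exactly
  equal pairwise center distances.

The study conditions used throughout the tests and the acceptance script
are: planted-signal SNR 3 (amplitude 0.9, noise 0.3), sequence lengths
400–512, grid 512, 200 recovery trials, 100-seed family and burst baselines,
and 50 screens of 1000 decoys + 1 matched ligand. These are desk-scale
stand-ins chosen to make the statistical properties sharp and fast to
verify.

What passing them does *not* show: real proteins are not stationary
sinusoids plus white noise; real compound libraries are vastly more diverse
than a chain grammar; descriptor and ADMET tables here are synthetic
Gaussians, not predictions for real chemistry. The fixtures validate the
*machinery* — encodings, transforms, peak logic, score algebra, ranking
determinism — not the biological claim that spectral compatibility implies
binding, which only experiments can.

## Degenerate inputs and tie-breaks, in one place

* Constant series: zero spectrum; S/N errors; wavelet map errors.
* All-zero window profile: domain call errors (no domain at that
  frequency).
* Equal-amplitude peaks: lower frequency wins. Equal supra-threshold runs:
  earlier run wins. Equal ranking scores: compound id order.
* Unparseable SMILES in a library: skipped and logged with ids, error only
  if nothing survives; a single-molecule encode propagates the error with
  the offending id.
* Nonstandard residues: strict (error with positions) by default, `"skip"`
  drops them with a per-position message.

## Known limitations

* Grid choice can move a reported frequency by one bin; comparisons across
  grids must go through `matchFrequency()` rather than exact equality.
* The sliding-window domain rule (70% of peak, maximal run) reproduces
  planted regions well, but published interval boundaries from other
  implementations may differ by up to a window length without either being
  wrong.
* Per-compound spectra are length-limited: tiny molecules (2–3 heavy atoms)
  have very coarse spectral support, and their S/N at any single frequency
  is accordingly unstable.
* The CWT hotspot bands are quantiles, so band 5 always covers ~20% of
  non-edge cells even for pure noise — hotspot calls are meaningful only at
  frequencies already supported by cross-spectrum evidence.
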