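---
title: "Models and methods behind wellscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wellscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellscreen)
```

`wellscreen` models a single-clone phage screening platform: bacterial
cells carrying phagemid clones are Poisson-loaded into a microwell array
chip, occupied wells grow clonal phage, antigen-reactive (AR) wells are
identified by fluorescence immunoassay, the matching spots on a
sample-capturing substrate are registered and retrieved, and the retrieved
clones are identified from pooled sequencing reads and confirmed by ELISA.
This vignette records the models, the parameters that matter, the design
decisions that were genuinely open, and what the simulation-based tests do
and do not establish.

## Poisson loading

Per-well cell counts under dilute loading are `N ~ Poisson(λ)` with λ in
cells/well. The package uses three closed forms:

- occupancy `P(N > 0) = 1 − e^{−λ}` (and its inverse
  `λ = −log(1 − p)` in `lambda_for_occupancy()`),
- single-cell purity among occupied wells
  `P(N = 1 | N > 0) = λ e^{−λ} / (1 − e^{−λ})`,
- expected single-cell assays `n_wells · p · P(N = 1 | N > 0)`.

At the standard operating point λ = 0.1 (≈10% occupancy) about 95% of
occupied wells are single-cell and a 113,000-well chip yields >10,000
single-cell assays. `1 − e^{−λ}` is evaluated with `expm1` so the
single-cell limit `λ → 0⁺ → 1` is numerically exact. Library coverage is
reported as the raw ratio `n_screened / complexity` without collision
correction; `expected_unique_clones()` provides the corrected
`C(1 − e^{−n/C})` for comparison but is deliberately not used in headline
numbers, which keeps the reported fraction a simple, assumption-free ratio.

## The degenerate library

A mutagenesis scheme fixes designed heavy-chain positions and their IUPAC
degenerate codons; the default scheme randomises two HCDR1 and three HFR3
residues with RMN/YMY/NNK/MTN/RYN. Complexity is the product of the
per-position variant-set sizes. The nucleotide-level, stop-inclusive
product is 16·8·32·8·16 = 524,288 ≈ 5.2 × 10⁵; the stop-exclusive product
is 5.08 × 10⁵ and the amino-acid-level product 7,200. The package defaults
to nucleotide level with stops included and exposes the alternatives,
because published complexity figures for such libraries are typically
order-of-magnitude statements whose exact counting convention is not
recoverable; none of the package's checks treats complexity as an
exact-match quantity.

The genetic code is the standard table. No amber-suppressor readthrough is
modelled: the identification filters operate at the amino-acid level, where
a TAG-containing segment is an internal stop regardless of host strain.

## What the synthetic generator emulates

The generator produces every input the pipeline consumes, with ground
truth:

- **Chip images.** Wells are uniform disks on a flat background; in
  brightfield, wells image darker than the PDMS and occupied wells carry
  bright cell speckles; fluorescence of a well is the **maximum** over its
  clones' intensities (mixed phage compete for the antigen surface;
  configurable to the sum) plus optional Gaussian pixel noise. Fiducial
  markers are high-contrast crosses at the four chip corners in a stable
  order — the real platform's marker geometry is unspecified, so a minimal
  non-collinear, order-stable design was chosen. Tiles of the configured
  field of view (default 3328 µm) are cut with a configurable overlap
  (default 10%; neither overlap nor marker count is dictated by the
  platform, both are configuration).
- **Disassembly distortion.** A known first-order transform plus optional
  isotropic marker jitter, recorded as ground truth.
- **Reads.** Full constructs (5′ flank + VL + (G4S)₃ linker + VH + 3′
  flank) with per-base substitutions, per-read single-nucleotide
  frameshifts, low-quality reads (mean < Q20) and a reverse-complement
  fraction (default 0.5 — pooled amplicon sequencing is unoriented). The
  wild-type template is synthetic, generated reproducibly from sense
  codons, with designed-position codons drawn from the scheme's own sets
  so the wild type is a legal library member.
- **ELISA plates.** Negative controls ~ Normal(0.15, 0.05) truncated at 0
  (placing the 5-SD threshold at OD 0.4), non-reactive targets from the
  same distribution, reactive targets floored a margin above the nominal
  threshold.

Not emulated: optical point-spread and flat-field structure, well-to-well
growth competition, phage rescue biology, chimeric reads, and base-caller
artefacts beyond per-base quality. Passing tests therefore certify the
*algorithms* against a geometrically and statistically faithful model of
the data, not robustness to every optical or biochemical artefact of real
chips.

## Imaging

Stitching places tiles at their stage positions and resolves overlaps by
last-write with no blending — chosen so that noiseless reconstructions are
pixel-exact and testable; an optional integer-shift cross-correlation
refinement is available when stage positions are unreliable. Pixel
coordinates are 0-based with x rightward and y downward; physical
coordinates are µm from the chip's top-left corner, with pixel centres at
`(j − 0.5)·pixel_size`.

Well detection is grid-phase fitting: the negated brightfield image is
correlated with a disk template (FFT-based), the lattice offset maximising
the summed response at the layout's predicted well centres is searched over
one pitch, and each well is refined to its local response peak with
separable quadratic sub-pixel interpolation. A flat response surface, or
fewer than half the wells showing a clear peak, raises a grid-fit failure.

Fluorescence per well is the mean over a disk of 80% of the well radius
(avoiding partial rim pixels) minus the **median** of a surrounding
annulus — the median is robust to bright neighbours. Occupancy is called
from brightfield interior variance exceeding five times the median
interior variance across wells, a robust blank estimate valid under dilute
loading where most wells are empty.

Hits are wells that are occupied, not edge-truncated, and at or above
`mean + k·SD` of the empty-well fluorescence. The platform's own
fluorescence cutoff is not quantified anywhere recoverable, so the package
adopts k = 5 by analogy with the ELISA confirmation rule, configurable. A
well exactly at the threshold is a hit (`≥`); in addition the signal must
strictly exceed the empty-well mean, a condition that only binds in the
degenerate noiseless case where SD = 0 and signal-free occupied wells
would otherwise tie the threshold. Because the experimental threshold is
unknown, the validation-experiment well counts (thousands of fluorescent
wells across four dilution series) are not reproducible quantities and are
not targeted by any check.

## Registration and retrieval

The "first-order" compensation between pre- and post-disassembly frames is
implemented as the full 6-parameter affine `x′ = Ax + t`, fitted by least
squares from ≥3 non-collinear marker pairs (markers correspond by their
stable ordering; automatic correspondence search is out of scope). An
affine is preferred over a 4-parameter similarity because a peeled
elastomer stretches anisotropically; a similarity mode (closed-form
Procrustes fit) is provided for comparison. Degeneracy guards: |det A| >
10⁻⁶, rank-3 design matrix. With exact markers the fit recovers parameters
to ~10⁻⁹ and sub-µm end-to-end accuracy — far inside a 60 µm well, which
is the platform's implicit requirement; with marker jitter σ the RMS
residual tracks σ.

Retrieval plans visit targets row-major (by substrate y, then x),
convert coordinate differences to stage displacements via calibration
factors (default identity — no instrument constants are assumed), and fill
tubes sequentially at 48 targets/tube.

## Clone identification

Anchors (5′ flank, linker, 3′ flank) are aligned semi-globally to each
read on both strands with match +1, mismatch −1, gap −2 and an 80%
per-anchor identity floor; these are package defaults, as no aligner or
parameters are prescribed by the platform. The orientation with the higher
total score wins; VL spans (flank-5′ end, linker start) and VH (linker
end, flank-3′ start). QC flags: frameshift (segment length not a codon
multiple), defective chain (length outside template ± `length_tol`,
default 0 — designed mutations are substitutions, so any in-frame indel is
defective), internal stop, and low quality (mean Phred < 20 across the two
segments; the threshold is a package default). An indel confined to a
flank or the linker is absorbed by the anchor alignment and the read
remains usable — only variable-chain indels corrupt the clone sequence.

Clone identity is the **amino-acid** VL+VH pair (the filters operate on
amino-acid mismatches); reads merge by that key with read counts summed.
Residues at designed positions are recorded as assignments; a designed
residue outside its codon's translation set counts as unintended — the
conservative reading of "mutations restricted to the randomised residues"
— as does every non-designed difference from wild type, in either chain
(the filter examines both). The strict filter keeps clones with zero
unintended mismatches, the relaxed filter up to two (PCR artefacts).
Mutation-frequency tables are clone-level by default (each clone counts
once), with a read-weighted option.

## ELISA confirmation

Threshold = negative-control mean + k·SD with k = 5, sample SD (n−1
denominator, unspecified by convention and chosen as the standard
estimator); ties call AR. The threshold is computed per plate rather than
fixed at OD 0.4 — with the default control distribution the two coincide —
and the per-plate statistics are reported alongside the calls.

## Pipeline and evaluation conventions

`run_screen()` derives one sub-seed per stochastic stage from the master
seed, so a fixed seed reproduces the manifest byte for byte. Retrieval is
treated as exact: registration accuracy is ~10⁻³ of the well diameter, so
each planned spot yields reads of precisely the clones seeded in its well
(mixed wells yield mixed reads; no chimera resolution is attempted, and
wells that sequence ambiguously simply fail QC).

Two conventions deserve emphasis:

- **`read_error` is per read.** The pipeline configuration models
  consensus-grade reads, where the natural error unit is the fraction of
  reads carrying any error; it is converted internally to the per-base
  substitution rate `1 − (1 − e)^{1/L}` used by `simulate_reads()`, whose
  own contract (binomial per-base errors) is the right primitive level.
- **Recall is against loaded clones.** AR-clone recall is measured against
  reactive clones that were actually seeded into at least one well. At
  λ = 0.1 a finite chip simply never receives some library members; that
  is a property of Poisson sampling, not of the pipeline under test, and
  folding it into recall would make the metric measure the loading
  lottery.

Default problem sizes — a 2,000-well chip (40 × 50, 85 µm pitch at
3.25 µm/px) with a 50-clone, 5-reactive library, ~20 reads per retrieved
spot — were chosen as the smallest configuration in which every funnel
stage is exercised with comfortable statistics (≈200 occupied wells, ≈20
hits, ≈300 pooled reads); closed-form checks run at full chip scale
(113,000 wells) since they cost nothing. The moderate-noise condition used
in end-to-end validation is pixel noise at 5% of the reactive signal and a
0.5% per-read error with 2% frameshift and 2% low-quality reads.

## Known limitations

- The imaging model has no illumination field or PSF, so detection
  performance on real micrographs will be bounded by preprocessing not
  modelled here.
- Occupancy calling assumes dilute loading (median interior variance as
  the blank estimate); at high λ it would need an explicit blank model.
- Marker correspondence relies on ordering; rotated-by-90° chips would
  need a correspondence search.
- The funnel's experimental counts in a real screen depend on wet-lab
  realisations (library composition, growth, retrieval efficiency) that
  the generator parameterises but cannot reproduce; simulated funnels are
  shape-compatible, not count-identical.
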