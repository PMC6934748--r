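---
title: "Designing and evaluating short-amplicon HRM species assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating short-amplicon HRM species assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmelt)
library(dplyr)
```

## The problem

Two closely related, sympatric species that cannot be told apart reliably
by morphology can often be separated by a handful of fixed nucleotide
differences in a standard barcode locus such as mitochondrial COI.
High-resolution melting analysis (HRMA) turns those differences into a
cheap, closed-tube assay: a short PCR amplicon spanning the diagnostic
sites is melted in the presence of a saturating dye, and the temperature
at which the duplex dissociates — read as the peak of the −dF/dT
derivative curve — differs between species whenever the fixed
substitutions change G·C base pairs into A·T. Short amplicons (tens of
base pairs) matter because each variant site then shifts the melting
temperature by a usable fraction of a degree.

`hrmelt` implements the full in-silico counterpart of that workflow:
diagnostic-site discovery, thermodynamic Tm prediction, assay ranking,
melt-curve simulation and interpretation, and throughput reporting.

## Site classification

For a two-species alignment, each column is categorised from the
per-species sets of observed states (`N` and `-` are missing data, never
states):

* **fixed_diagnostic** — both species observed and their state sets are
  disjoint. These columns carry all the diagnostic power.
* **shared_polymorphic** — at least one state occurs in both species.
  This is how we operationalise a plesiomorphy: no outgroup rooting is
  attempted, shared state alone makes a column non-diagnostic. Such sites
  create within-species melt variability.
* **private_polymorphic** — polymorphic, but only one species has data.
* **monomorphic** — everything else.

Substitutions are annotated as transitions (A/G, C/T) or transversions,
and by codon position given the alignment's frame offset. Synonymy is
judged from *observed codon variants only*: a site is synonymous iff no
pair of observed codons differing at exactly that site encodes different
amino acids. This matches how one annotates real alignments — we never
extrapolate to unobserved codon combinations.

The default genetic code is the standard nuclear code (table 1), with the
invertebrate mitochondrial code (table 5) selectable. This choice is
deliberate: for an ATA/ATG third-position transition the standard code
reads Ile vs Met while table 5 reads Met for both, so the familiar
"one non-synonymous Ile↔Met change" description of such a site only
arises under table 1. Selecting table 5 emits a warning that flags
exactly this discrepancy, which is surprising for insect mtDNA but is
the convention the field's alignment viewers default to.

## Thermodynamic model

Duplex stability uses the unified nearest-neighbor parameter set
(SantaLucia 1998): ΔH and ΔS are sums of the ten doublet stacking terms
plus terminal initiation terms (A·T vs G·C ends). Monovalent salt enters
through the entropy correction ΔS[Na⁺] = ΔS + 0.368·(N−1)·ln[Na⁺~eq~],
with magnesium folded into a monovalent equivalent
(Na~eq~ = monovalent + 120·√Mg, in mM). The melting temperature of a
non-self-complementary duplex with equal strands at total concentration
C~T~ is

Tm = 1000·ΔH / (ΔS[Na⁺] + R·ln(C~T~/4)).

Defaults (`thermo_conditions()`): 50 mM monovalent, 2 mM free Mg²⁺,
C~T~ = 0.25 µM, calibration offset 0 °C. These are ordinary PCR-buffer
conditions; they are not meant to reproduce any instrument's absolute
temperature scale.

Two modelling decisions deserve emphasis:

* **Two-state melting.** Amplicons up to ~110 bp are treated as melting
  in a single all-or-none transition; multi-domain statistical-mechanics
  melting is out of scope. Short diagnostic amplicons show single melt
  peaks, which is the regime the model targets.
* **Absolute scale is calibrated, not predicted.** Saturating-dye Tm
  elevation and platform offsets are absorbed into a single additive
  `calibration_offset_C` (`calibrate_offset()` maps a predicted Tm onto
  an observed calibrator peak). Only Tm *differences* between sequences
  are treated as thermodynamic predictions; observed peak temperatures
  (e.g. ~77.0 and ~79.4 °C for the two species on a particular
  instrument) serve as anchors, never as prediction targets.

The equilibrium duplex fraction θ(T) solves the bimolecular two-state
equation a·f² − (2a+2)·f + a = 0 with a = K(T)·C~T~; we use the
numerically stable root f = 2a / (2a + 2 + √(8a+4)) (the discriminant
simplifies exactly, avoiding overflow at large association constants),
so θ(Tm) = 0.5 holds to machine precision.

## Assay design and ranking

`find_candidate_amplicons()` enumerates windows of 40–106 bp (the
short-amplicon regime) containing at least one fixed site, flagging
windows whose terminal 18 bp primer footprints overlap polymorphic
columns. `generate_primer_pairs()` anchors forward primers at the window
start and reverse primers at the end, applying standard composition
rules: length 16–25 nt, predicted primer Tm within 50–62 °C, GC fraction
0.3–0.7, no homopolymer run over 4, and no 3′ terminus on a polymorphic
column (a mismatched 3′ base kills extension, so a polymorphic 3′ column
would make amplification allele-dependent). `in_silico_pcr()` verifies a
pair yields a unique product (≤2 mismatches per primer, exact 3′ match).

`score_and_rank()` excises the amplicon (primer footprints included —
in a 60 bp assay the primers lie inside the translated fragment) from
every haplotype, predicts each Tm, and scores a candidate by its
**minimum between-species ΔTm** over all inter-species haplotype pairs.
The minimum, not the mean, is the relevant statistic: an assay is only
diagnostic if its *closest* pair of heterospecific haplotypes still
separates. Wet-lab ranking would weigh amplification efficiency first;
efficiency cannot be simulated, so the composition rules act as hard
filters and ranking uses ΔTm, breaking ties by shorter amplicon then
smaller start coordinate (a total, permutation-stable order).

## Melt-curve simulation and interpretation

The forward model of the instrument signal is

F(T) = amplitude · θ(T − jitter) · (1 + b₁(T−T₀)) + c₀ + c₁(T−T₀) + ε,

with a gently sloping helix baseline (b₁ = −0.002/°C), a post-melt
baseline (c₀ = 0.05, c₁ = −5·10⁻⁴), per-point Gaussian fluorescence
noise, and a per-specimen Tm jitter (default SD 0.15 °C) representing
well-to-well variation. The acquisition grid is 65–85 °C at 0.05 °C —
twenty acquisitions per degree, a typical plate instrument's
high-resolution melt setting.

One subtlety: the bimolecular transition is slightly asymmetric, so the
maximum of −dθ/dT sits a constant fraction of a degree above the
half-dissociation temperature. Instruments report the derivative peak,
so the simulator shifts the transition by that constant (computed
numerically per amplicon) to make the noiseless *reported peak* coincide
with the amplicon's calibrated Tm. Without this, simulated peaks and
thermodynamic anchors would disagree by a systematic ~0.2 °C.

Interpretation mirrors instrument software:

1. **Normalization** (`normalize_curve()`): straight-line fits to the
   pre-melt (66–68 °C) and post-melt (83–85 °C) windows, fluorescence
   rescaled to the fraction between them, clipped to [−0.05, 1.05].
   Affine-invariant by construction.
2. **Derivative** (`melt_derivative()`): Savitzky–Golay smoothed first
   derivative, negated. The default window (11 points) preserves
   sub-grid peak accuracy on clean curves; `classify_curves()` instead
   uses 41 points (≈2 °C, the order of a short amplicon's transition
   width) because peak *location* under realistic noise is what matters
   for classification.
3. **Peak calling** (`melt_peaks()`): global maximum with 3-point
   parabolic refinement by default; the classification pipeline refines
   with a least-squares quadratic vertex over ±1 °C, which cuts
   peak-position noise by an order of magnitude at the cost of a few
   hundredths of a degree of common-mode bias (common-mode, because
   references and specimens shift together). A 0.5 °C band at each grid
   end is excluded from the search — the filter's one-sided edge fits
   are unreliable there. Bimodal curves record a secondary peak.
4. **Species assignment** (`call_species()`): peaks below `min_height`
   (default 0.1 units/°C, a free parameter since failure criteria are
   instrument-specific) are `failed`; otherwise a specimen is assigned
   to the nearest reference within τ = 0.75 °C provided the gap to the
   next reference is ≥ 0.5 °C, else `ambiguous`. References closer than
   2τ are rejected outright — the assay would not be diagnostic at
   those thresholds. References are by default *measured calibrator
   peaks of known-species controls on the same plate*, which is how
   such assays are actually scored; calibrated predictions can be used
   instead.

`summarize_assay()` tabulates totals and per-sex breakdowns. Percentages
are reported at one and two decimals with half-up rounding (the two
precisions throughput tables are quoted at). Discordance with a prior
morphology label is counted over specimens with a label *and* a
successful unambiguous call, while its percentage denominator is all
labelled specimens in the group — so 30 discordant among 279 labelled
males reads 10.75% / 10.8% regardless of how many labelled males failed.

## The synthetic-data generator

`barcode_spec()` / `make_minibarcode_alignment()` generate the default
conditions every test runs under: a 60 bp in-frame COI-like fragment
(backbone ~35% GC — COI-plausible; no published base composition was
available, so the value is configurable), with

* 4 fixed third-position transitions, G/C in one species and A/T in the
  other (so that species melts higher on every haplotype pair), one of
  them an ATA/ATG codon at the ninth nucleotide — the single
  non-synonymous site under the standard code;
* 4 shared third-position transitions arranged so each species has 3
  haplotypes differing only at shared sites, with skewed frequencies
  (25/12/6 and 13/6/3 across 43 + 22 specimens);
* shared-site patterns chosen analytically so the 3×3 inter-species
  Hamming distances are four 5s and five 6s — mean 5.56 (≈5.6)
  substitutions — while every inter-species pair remains ≥4 G/C units
  apart. The arrangement is forced up to symmetry: over biallelic
  sites, Hamming distances have a rank-1 parity structure, so the four
  odd distances must form a row/column cross.

`cohort_spec()` / `make_cohort()` emulate a plate-scale run: 518
specimens (279 labelled males, 239 unlabelled females), species sampled
at the proportions the successful assignments imply, exactly
round(fail_rate·n) = 9 amplification failures drawn among males only
(the emulated table reports zero female failures), and exactly 30 male
labels flipped — flips are label-only and never touch the species used
to simulate the curve, because they represent morphological
misidentification, not biology.

Each simulated specimen's melt transition is anchored at its species'
calibrator reference temperature (77.0 / 79.4 °C by default) plus
jitter. Predicted within-species haplotype Tm offsets can be added with
`use_haplotype_tm = TRUE` but are off by default: classification against
single per-species reference peaks with τ = 0.75 °C presumes curves
cluster within τ of their reference, and the assignment emulation is
about the scoring logic, not about re-deriving the within-species
spread (which the assay ranking already quantifies on the prediction
side). This is the one place where the generator deliberately simplifies
relative to the physical model; the haplotype-resolved option exists for
studying how within-species variability erodes the assignment window.

All generators are pure functions of spec + seed
(`withr::with_seed()`), so every cohort and alignment in the test suite
is exactly reproducible.

### What passing tests do and do not show

The generator reproduces the *structural* facts of a real two-species
mini-barcode system: site counts and types, haplotype frequencies, mean
divergence, GC-bias direction, cohort composition, failure and
discordance rates. It does **not** simulate sequencing error, indels,
heteroplasmy, nuclear-mitochondrial pseudogenes, heteroduplex formation
(mtDNA is effectively haploid here), dye-binding kinetics, or
multi-domain melting. End-to-end recovery on simulated cohorts therefore
demonstrates that the pipeline's logic is sound under its own forward
model — not that any particular wet assay will achieve the same rates.
Absolute peak temperatures are instrument- and dye-dependent and are
used only as calibration anchors and classifier references.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; codon positions 1/2/3.
* Hamming distances ignore positions where either sequence has `N` or a
  gap; amplicons containing `N` are skipped (with a warning) rather
  than guessed.
* The minimum spanning network uses Kruskal weight classes with an
  exact (ε = 0) tie rule: every edge that joins two components as they
  stood at the start of its weight class is retained; edges whose
  endpoints an equal-weight path has already connected are flagged
  `alternative`. Non-alternative edges always form a minimum spanning
  tree (verified against exhaustive enumeration in the tests); the
  alternatives are what make it a network.
* A single haplotype yields a degenerate, edge-free network with a
  warning; an alignment with no fixed differences is a design error —
  no melt assay can separate the species, and the package says so
  rather than returning an empty ranking.
* Ranking tie-breaks: ΔTm (desc), amplicon length (asc), start (asc).
* Report rounding is half-up at the printed precision, not banker's.

## Problem sizes

The shipped tests and the acceptance script run the full default
geometry: 65-specimen alignments, 60 bp amplicons, and ten independent
518-specimen cohorts (≈2 × 10⁶ simulated fluorescence points per
cohort batch), chosen to exercise the complete plate-scale workflow
while keeping the whole suite comfortably fast on a laptop.

## Known limitations

* The nearest-neighbor model with a single additive calibration cannot
  predict absolute instrument peaks; assays should always be calibrated
  against known-species controls.
* Primer quality screening covers composition rules only — no
  hairpin/dimer ΔG, no degenerate-base support (haplotypes are
  enumerated explicitly instead).
* Peak-based classification ignores curve *shape*; difference-plot
  clustering used by some HRM software is out of scope.
* The two-state assumption will mispredict amplicons long enough to
  melt in domains; keep designs inside the short-amplicon window.
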