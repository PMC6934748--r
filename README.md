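# hrmelt

Design and evaluate **short-amplicon high-resolution melting (HRM)
assays** that distinguish closely related species from a mitochondrial
mini-barcode — the common situation where two sympatric congeners (for
example the saltmarsh planthoppers *Prokelisia marginata* and *P. dolus*
on COI) are near-impossible to tell apart morphologically but differ at a
handful of fixed nucleotide sites.

The idea the package implements: in a species-labelled alignment, find the
columns whose character-state sets are **disjoint between the species**
(fixed diagnostic sites) as opposed to **shared polymorphisms**
(plesiomorphies, which add within-species melt variability but no
diagnosis). A short amplicon (~40–106 bp) spanning the fixed sites melts
at a measurably different temperature in each species when the
substitutions are G·C ↔ A·T, because each base pair contributes to duplex
stability through nearest-neighbor stacking:

- ΔH, ΔS = initiation terms + Σ unified doublet parameters (SantaLucia
  1998), with the entropy salt correction
  ΔS[Na⁺] = ΔS + 0.368·(N−1)·ln[Na⁺_eq];
- Tm(K) = 1000·ΔH / (ΔS[Na⁺] + R·ln(Cₜ/4)) for a non-self-complementary
  duplex at total strand concentration Cₜ;
- a specimen's fluorescence melt curve is the two-state duplex fraction
  θ(T), read out as the −dF/dT derivative peak.

From those pieces the package: classifies sites (category, transition vs
transversion, codon position, synonymy), builds the haplotype minimum
spanning network, enumerates and ranks candidate primer assays by the
**minimum between-species ΔTm** over all haplotype pairs (the worst case
the assay must still resolve), simulates plate-scale cohorts of melt
curves, normalizes/differentiates/peak-calls them, assigns species
against per-species reference peaks, and emits a throughput report
(failed / ambiguous / assigned / discordant-with-morphology, with
percentages at printed precision).

## Worked example

```r
library(hrmelt)
library(dplyr)

# a 60 bp COI-like mini-barcode: 4 fixed third-position transitions
# (G/C in one species, A/T in the other), 4 shared sites, 3 haplotypes
# per species, 65 specimens
aln   <- make_minibarcode_alignment(barcode_spec(seed = 1))
haps  <- collapse_haplotypes(aln)
sites <- classify_sites(aln, c("marginata", "dolus"))
filter(sites, category != "monomorphic") |> count(category)
#>   category           n
#> 1 fixed_diagnostic   4
#> 2 shared_polymorphic 4

pairwise_divergence(haps, c("marginata", "dolus"))
#> Between-species divergence (marginata vs dolus)
#>   mean Hamming distance over 9 haplotype pairs: 5.56
#>   fixed differences: 4

ranked <- score_and_rank(window_primer_pair(aln), haps, thermo_conditions())
glance(ranked)
#>   n_candidates best_min_dtm_C best_amplicon_length best_n_diagnostic_sites
#> 1            1           2.73                   60                       4

tidy(ranked) |> select(haplotype_id, species, count, tm_C)
#>   haplotype_id species   count  tm_C
#> 1 H1           marginata    25  77.2
#> 2 H2           dolus        13  72.0
#> 3 H3           marginata    12  76.4
#> 4 H4           dolus         6  72.6
#> 5 H5           marginata     6  75.7
#> 6 H6           dolus         3  73.0
```

The G/C-biased species melts higher on every haplotype pair; the
worst-case predicted separation (2.73 °C here) is what the ranking
maximizes. Shared polymorphisms spread the within-species Tm by
~0.7–1 °C without closing the between-species gap.

Simulate a high-throughput plate run and score it against per-species
calibrator peaks:

```r
co    <- make_cohort(cohort_spec(seed = 1), ranked[1, ], thermo_conditions())
calls <- classify_curves(co$curves, c(marginata = 79.4, dolus = 77.0))
summarize_assay(calls, co$metadata)
#> High-throughput HRM assay report
#>   total    n=518  failed 9 (1.7%)  ambiguous 0 (0.0%)  discordant 30/279 (10.8% | 10.75%)
#>            assigned: marginata 306, dolus 203
#>   female   n=239  failed 0 (0.0%)  ambiguous 0 (0.0%)
#>            assigned: marginata 138, dolus 101
#>   male     n=279  failed 9 (3.2%)  ambiguous 0 (0.0%)  discordant 30/279 (10.8% | 10.75%)
#>            assigned: marginata 168, dolus 102
```

Every non-failed specimen is assigned unambiguously; the
morphology-discordance row counts specimens whose prior (visual) label
disagrees with the molecular call, over all labelled males.

Plot helpers: `plot_melt_curves()`, `plot_derivative()` (the −dF/dT peak
view), `plot_sites()` (alignment tile view), and `autoplot()` methods for
assay rankings and haplotype networks. A thin command-line front end with
`design` / `classify` / `report` / `simulate` subcommands lives at
`inst/cli/hrmelt.R`.

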