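---
title: "Barcode-based authentication and PCR-RFLP assay design with its2auth"
author: "its2auth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-based authentication and PCR-RFLP assay design with its2auth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2auth)
```

## The problem

Herbal raw materials are traded as dried roots, slices or powders with
no morphology left to identify them by. When a pharmacopoeia admits a
single source species, market material is routinely adulterated — by
congeners with similar medicinal use, and by unrelated look-alike
species. `its2auth` implements a desk workflow for this situation,
centred on a short nuclear barcode (typically ITS2, the second internal
transcribed spacer of nuclear ribosomal DNA):

1. characterize a reference barcode library (lengths, GC content,
   variable sites, haplotypes);
2. quantify divergences with the Kimura 2-parameter (K2P) model and
   assess the *barcode gap*;
3. build neighbor-joining (NJ) trees with bootstrap support and check
   species monophyly;
4. mine *diagnostic characters* — alignment columns fixed in the target
   species and absent everywhere else;
5. turn a diagnostic character that completes a restriction site into a
   species-specific PCR-RFLP assay, engineering a primer mismatch when
   a confounding restriction site spoils the readout;
6. authenticate query sequences (commercial products) by best-match
   identity, diagnostic characters and predicted assay outcome.

A synthetic-data generator reproduces the statistical structure that
this workflow assumes, so that every stage is testable end to end with
a known ground truth and no downloads.

## Distance model

For two aligned sequences, comparable sites are those where both
residues are unambiguous `A/C/G/T`; sites with a gap or an IUPAC
ambiguity code in either member are excluded pair by pair ("pairwise
deletion", the default of the common distance software; a
`deletion = "complete"` flag removes every such column globally
instead, so both conventions can be compared). With transition
proportion $P$ and transversion proportion $Q$ over the $n$ comparable
sites, the K2P distance is

$$d = -\tfrac12 \ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\,\big].$$

Saturation (a non-positive argument of the logarithm or square root)
and empty overlap yield an undefined marker (`NA`) with a recorded
reason, never an exception: a single saturated pair must not abort a
matrix build. The implementation returns the $(n, s, v)$ counts beside
every distance so that summaries can be audited.

A barcode gap is declared for a target species when the minimum
interspecific distance to a comparison scope exceeds the maximum
intraspecific distance. The package reports both numbers and the
boolean, per scope (congeners / adulterants / all).

## Trees

`neighbor_joining()` is a direct Saitou–Nei agglomeration using the
Studier–Keppler criterion
$Q(i,j) = (r-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, with the
standard branch-length formulas. Two numerical policies matter:

* ties in $Q$ are broken by the smallest $(i, j)$ index pair in the
  current label order, making the result deterministic;
* negative branch lengths are clamped to zero and the total clamped
  deficit is kept as an attribute, so non-additivity is visible rather
  than silently absorbed.

Trees are unrooted (`phylo` objects with a basal trifurcation);
`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the K2P matrix and NJ tree per replicate, and maps the
percentage of replicates containing each bipartition onto the
*full-data* topology (the behaviour of the mainstream barcoding GUIs,
rather than a majority-rule consensus). Replicates whose resampled
matrix contains undefined distances are discarded and redrawn, with the
redraw count logged, so the requested number of effective replicates is
honoured. Support values below a display threshold are a rendering
concern only; the data always retain them.

## Diagnostic characters

A column is diagnostic for the target iff every target sequence carries
the same concrete state (a base or the gap state) and no scope sequence
carries — or could, through an ambiguity code, encode — that state.
Ambiguity codes in the scope therefore *conservatively disqualify* a
column. Fixation in the target is required by default because only
fixed characters are stable evidence for authentication; a relaxed mode
(`min_target_fraction < 1`) exists for exploratory use. Positions are
1-based columns of whichever alignment was supplied, and every report
carries a frame label, because positions are meaningless without their
frame. Multi-column indels yield one site per column.

## In-silico PCR-RFLP

Primer binding requires at most `max_mismatch` mismatches (default 1)
and an exact match over the 3'-terminal `clamp` bases (default 3);
ambiguous template bases count as mismatches. Reverse primers are
matched against the minus strand, so their 3' clamp sits at the *left*
edge of the plus-strand footprint. The predicted product overwrites
both primer regions with the primer bases — exactly what the physical
product contains — which is what makes digestion predictions of
mismatch-engineered primers come out right: the engineered base is
propagated into every amplicon.

Restriction sites are found under strict IUPAC semantics (the template
base must be unambiguous and contained in the motif symbol's set: a cut
must be certain). The shipped enzyme table holds Bgl I
(`GCCNNNNNGGC`, cutting after motif base 7, leaving a 3-nt 3'
overhang); the table is an editable config, not an external database
dependency. Fragment lengths are computed from top-strand cuts of the
linear product, matching what a gel shows.

`engineer_primer()` formalizes the mismatch-engineering trick: when a
confounding restriction site lies under the reverse-primer footprint in
the whole genus, it enumerates primer substitutions (fewest first,
then as far from the 3' end as possible) such that (i) every genus
product loses all footprint-overlapping sites, (ii) the primer still
binds every template within the mismatch budget with an intact clamp,
and (iii) no new site is created anywhere in any product. Every
proposal is re-verified closed-loop through the PCR and digestion
code. A site whose only destroyable bases sit inside the clamp is
reported as such in a failure tally instead of being forced.

`select_assay()` composes the pieces: an enzyme qualifies when one of
its motif hits in the target amplicon overlaps a diagnostic character
while non-target amplicons lack the site; designs are ranked clean
first, then engineered by substitution count, then by the minimum
fragment-length contrast against non-target patterns (gel
resolvability).

## Identification and reporting

`identity_percent()` computes a global pairwise alignment (match +1,
mismatch −1, gap −2 per base, free end gaps) and reports
$100 \times \text{matches}/\text{aligned columns}$, excluding terminal
overhangs, rounded half-up to one decimal — the granularity of
best-match reports. `identify()` is an exhaustive nearest-neighbour
search per species with a shared-8-mer prefilter whose only effect is
speed: when the filter would discard every reference it falls back to
the full scan, so results are identical with and without it. Species
tied at the top identity are reported together, never silently broken.

The final call rule: top identity ≥ 99.0% *and* all configured
diagnostic characters matched → species call; ≥ 99.0% without
diagnostic confirmation → genus-level call; otherwise unresolved. The
threshold is configurable; 99.0 reflects the granularity at which a
single substitution over a ~200-bp barcode (≈ 0.5%) still supports a
species call. Products represented by several sequences with different
best matches are flagged as mixtures — mixture detection via multiple
input sequences per product is in scope, chromatogram deconvolution is
not.

## The synthetic-data generator

`simulate_library()` draws a study in the regime this workflow targets:

* ancestral barcode at GC fraction 0.645, default length 211 bp for the
  target (the alignment gains one column for the planted deletion, so
  congeners read 212 bp);
* a genus stem branch (0.05 substitutions/site) shared by target and
  congeners — the shared derived states that make the genus a clade
  relative to distant adulterants;
* per-congener divergence drawn uniformly in 0.5–1.5 × 0.02
  substitutions/site, with at least one barcode substitution enforced
  (a congener is, by definition, a distinct species), emulating a
  0.005–0.06 congeneric range that *breaks* the barcode gap;
* ten adulterants at 0.25 substitutions/site (deliberately below
  realistic between-family divergence, where alignment itself becomes
  unreliable), preserving the gap against distant adulterants;
* intraspecific variation of Poisson(0.65) substitutions per sampled
  individual, giving a mean intraspecific K2P near
  $2 \times 0.65 / 211 \approx 0.006$;
* substitutions follow a K2P process with transition/transversion rate
  ratio $\kappa = 4$, the same model family used for the distances, so
  parameter recovery is interpretable;
* planted features: one diagnostic deletion (barcode column 68), one
  diagnostic substitution placed inside a target-only Bgl I site such
  that the 292-bp amplicon cuts into 168 + 124 bp, conserved primer
  landing sites, and a confounding Bgl I site under the reverse-primer
  footprint shared by the whole genus — destroyable by a single primer
  substitution. Adulterant templates carry a disrupted reverse
  footprint (3' clamp broken), so they fail the species-specific PCR.

Planted features are mutation-protected, and accidental occurrences of
the enzyme motif (expected about twice per library by chance for a
6-fixed-base degenerate motif) are deterministically destroyed, so the
generator's truth ledger is exact: the planted sites are the only
sites. The diagnostic substitution sits at barcode column 125 rather
than further 3': with a 45-bp conserved flank, the 168 + 124 fragment
geometry pins the restriction site to amplicon position 162, and the
diagnostic base must lie inside the motif's fixed bases. Intraspecific
and congener substitutions act on the barcode region only — the flanks
model the conserved ribosomal context that keeps universal primer sites
intact.

`simulate_products()` draws market-style queries: each product is a
random conspecific individual plus private Poisson(0.65) substitutions;
the default composition is 30 products — 2 authentic, 12 congeneric,
15 from five adulterant species and one two-species mixture emitted as
two records under one product id.

What the generator does *not* emulate: rate heterogeneity across sites,
indel processes beyond the single planted deletion, chimeric or
degraded reads, and intragenomic ITS2 polymorphism. Passing the
end-to-end tests therefore demonstrates the correctness of the
machinery under the model's assumptions, not robustness to every
artefact of real trace data.

## Numerical choices and degenerate inputs

* Alignment kernels (pairwise, profile–profile and query-to-profile)
  share one compiled Gotoh routine; ties prefer diagonal moves, then
  gaps in the second sequence, so outputs are deterministic.
* The progressive aligner (match +1, mismatch −1, gap open −5, extend
  −1, UPGMA guide tree) is a *fallback* for unaligned input; a curated
  alignment, when available, is never silently re-aligned.
* Single-sequence alignment input is returned unchanged with a warning;
  single-sample species yield intraspecific summaries with
  `n_pairs = 0` and undefined moments rather than errors.
* GC content excludes gaps and ambiguity codes from numerator and
  denominator; zero unambiguous bases is an error.
* Identity rounding is half-up at one decimal (210/211 → 99.5).
* All run drivers write a manifest (effective configuration + seeds),
  so any run is reproducible from its outputs.

## Problem sizes

The shipped tests and the acceptance script use the default study
conditions: a 109-sequence library (25 target samples, 11 congeners and
10 adulterants at 4 samples each), 200 bootstrap replicates in the
acceptance run, 200 simulated conspecific queries plus a 30-product
market set. The heavier property suites (motif-scanner equivalence on
10^4 random strings, NJ recovery on 4–8-leaf additive matrices) run in
seconds because the kernels are compiled.

## Known limitations

* The built-in progressive aligner is serviceable for the short, highly
  similar barcodes this workflow targets; it is not a general multiple
  aligner and makes no claim against dedicated tools.
* Thermodynamic primer evaluation (melting temperature, dimers,
  hairpins) is out of scope; engineered primers are validated only
  against binding mismatch budgets and restriction-site logic.
* Assay predictions assume clean single-template PCR; competitive
  amplification in mixtures is not modelled.
* Identification is nearest-neighbour by design (top-hit semantics);
  it inherits the reference library's blind spots, and congeners
  closer than the intraspecific spread cannot be separated by distance
  at all — that is precisely what the diagnostic characters and the
  PCR-RFLP assay are for.
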