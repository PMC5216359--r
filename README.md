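# its2auth

Authentication of herbal raw materials against a reference DNA barcode
library, and in-silico design of species-specific PCR-RFLP assays.

Medicinal plants are sold as dried roots, slices and powders; when a
pharmacopoeia admits a single source species, market material is
routinely substituted by congeners or by unrelated look-alike species,
and nothing morphological is left to check. A short nuclear barcode
such as ITS2 solves the problem in two complementary ways, both
implemented here:

* **sequence-based identification** — a curated reference library,
  Kimura 2-parameter (K2P) distances
  `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` (transition proportion `P`,
  transversion proportion `Q`, pairwise deletion of gapped/ambiguous
  sites), barcode-gap assessment (`min inter > max intra`),
  neighbor-joining trees with bootstrap support, and best-match
  identification of query sequences;
* **character-based assays** — mining of diagnostic characters
  (alignment columns fixed in the target species and absent in all
  others, substitutions or single-column indels) and, where such a
  character completes a restriction site (e.g. Bgl I,
  `GCCNNNNNGGC`), an in-silico PCR-RFLP assay: species-specific
  primers, digestion prediction, and mismatch-engineered primers that
  destroy confounding restriction sites shared by the whole genus.

A first-class synthetic-data generator (`simulate_library()`,
`simulate_products()`) reproduces the statistical structure the
workflow assumes — shallow target variation (mean intraspecific K2P
about 0.006), gap-breaking congeners (0.005–0.06), distant adulterants,
planted diagnostic characters and enzyme sites with an exact truth
ledger — so the whole pipeline is testable offline.

## Worked example

```r
library(its2auth)

lib   <- simulate_library(synthetic_config(seed = 1))
aln   <- lib$truth$alignment_barcode
D     <- distance_matrix(aln)                     # K2P, pairwise deletion

species_summary(D, lib$table, "target")           # intraspecific spread
#> mean 0.0054, max 0.0193 over 300 pairs

barcode_gap(D, lib$table, "target", scope = "adulterant")
#> max_intra 0.0193, min_inter 0.2117, gap_present TRUE

diagnostic_sites(aln, lib$table, "target")
#>   position target_state other_states  type
#> 1       68            -            G indel
#> 2      125            C            T   snp
```

The deletion at column 68 and the substitution at column 125 are fixed
in the target and absent from every congener and adulterant; the
substitution completes a Bgl I site present only in the target. Assay
design finds the confounding genus-wide Bgl I site under the
reverse-primer footprint and removes it with a one-base primer
substitution:

```r
res <- run_design(lib$records, aln, lib$table, "target",
                  fwd = lib$truth$fwd,
                  rev_footprints = list(lib$truth$rev_footprint_target_template),
                  aln_offset = lib$config$flank_length)
res$status                       #> "engineered"  (one substitution)
gel_schematic(res$designs[[1]])
#> species                  PCR      fragments (bp)
#> target                   +        168+124
#> congener_01              +        293
#> adulterant_01            -        no product
```

Only the target is both amplified and cut (292 bp into 168 + 124 bp);
congeners amplify but stay uncut; distant adulterants give no product.
Query products are then authenticated by best match, diagnostic
characters and predicted assay outcome:

```r
sites <- diagnostic_sites(aln, lib$table, "target")
q <- simulate_products(lib, composition = c(target = 1, congener_01 = 1,
                                            adulterant_01 = 1), seed = 3)
out <- run_identify(q$records, lib$records, lib$table, "target",
                    design = res$designs[[1]], sites = sites, aln = aln)
out$report[, c("product_id", "identified", "identity", "diagnostics",
               "specific_pcr", "rflp", "final_call")]
#>   product_id    identified identity diagnostics specific_pcr rflp    final_call
#> 1        Y01        target     99.7       match            +    +        target
#> 2        Y02   congener_01     99.7    mismatch            +    -   congener_01
#> 3        Y03 adulterant_01    100.0    mismatch            -  N/A adulterant_01
```

`run_stats()`, `run_tree()`, `run_design()`, `run_identify()` and
`run_simulate()` drive the same stages with on-disk TSV/JSON/Newick
outputs and a manifest per run.

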