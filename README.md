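# citruskit

Tools for building and evaluating **target cultivar-specific DNA
identification kits** from retrotransposon insertion polymorphisms, of the
kind used to police breeders' rights for Japanese citrus: given a panel of
dominant (presence/absence) markers scored across a reference set of
cultivars, find the smallest marker combination unique to a target cultivar
and simulate the multiplex-PCR strip assay that detects it.

The package covers the whole computational workflow:

1. **Simulation** of transposon-display sequencing libraries with known
   ground truth (`simulate_landscape()`, `generate_reads()`): 150 bp reads
   beginning with a retrotransposon end tag, followed by the genomic flank
   of the insertion site, with adapter remnants, substitution errors, PCR
   duplicates and a two-point read-quality mixture.
2. **Preprocessing** (`preprocess_reads()`): 5' tag removal, adapter
   trimming, mean-QV >= 30 filtering, trimming to a fixed 50 bp, and
   collapsing any sequence seen >= 10 times to a single representative.
3. **Clustering** (`cluster_reads()`): a deterministic greedy
   seeded-Hamming clusterer (8-mer seed, <= 2 mismatches to the
   representative) that groups 50-mers into one cluster per insertion site
   and tallies per-cultivar read counts.
4. **Genotyping** (`call_presence()`): the read-fraction rule — an
   insertion is absent from a cultivar when its cluster holds < 0.1% of
   that cultivar's reads — plus screens for cultivar-specific
   (`screen_specific()`) and polymorphic (`screen_polymorphic()`) markers.
5. **Marker-set selection** (`minimal_and_set()`, `greedy_and_set()`,
   `verify_uniqueness()`): the AND identification rule. A set S identifies
   target t iff every marker in S is present in t and no other cultivar
   carries all of S; the exhaustive solver returns the smallest such S
   (equivalently, a minimum set cover in which each chosen marker "covers"
   the cultivars lacking it).
6. **Kit simulation** (`design_kit()`, `predict_bands()`, `diagnose()`):
   assembles the marker set with the *rbcL* chloroplast positive control
   onto a four-line chromatographic printed-array strip (C-PAS4), checks
   fragment-size separation for gel compatibility, predicts band patterns,
   and returns a `target` / `non_target` / `invalid` verdict per sample.

The published genotype table for 26 Japanese citrus cultivars x 14 markers
and the matching marker metadata (fragment sizes, source families) ship as
plain-text fixtures (`citrus_genotypes()`, `citrus_markers()`,
`citrus_kits()`).

## Worked example

```r
library(citruskit)

gm <- citrus_genotypes()          # 26 cultivars x 14 markers
screen_specific(gm)
#> # A tibble: 3 × 2
#>   marker    cultivar
#>   <chr>     <chr>
#> 1 IND141-l  Rinoka
#> 2 Tcs2-CL68 Ehimekashidai28go
#> 3 Tcs2-CL80 Himekoharu

minimal_and_set(gm, "Asumi")
#> <marker_set> target 'Asumi': {Cp0419-s, IND214-s} (size 2, unique, exhaustive)

kit <- citrus_kits()[["Kanpei"]]
predict_bands(kit, gm, "Kanpei")$band_count
#> [1] 4
diagnose(predict_bands(kit, gm, "Kanpei"))
#> [1] "target"
```

Three markers are cultivar-specific on their own, so three of the eight
kit targets need a single marker beside the control; 'Asumi' needs the
two-marker combination above; on its own strip, 'Kanpei' develops all four
bands (three markers + control) while every non-target cultivar develops
at most three.

A simulated round trip — library generation through genotyping — recovers
the simulated truth exactly when reads are error-free:

```r
ls  <- simulate_landscape(26, 100, specific_fraction = 0.1, seed = 1)
cfg <- sim_config(depth = 50, error_rate = 0, seed = 1)
col <- preprocess_reads(generate_reads(ls, cfg),
                        preprocess_params(retro_tag = cfg$retro_tag))
gm2 <- call_presence(cluster_reads(col))
glance(gm2)
#> # A tibble: 1 × 4
#>   n_cultivars n_markers n_specific n_polymorphic
#>         <int>     <int>      <int>         <int>
#> 1          26       100         10            93
```

`run_pipeline(pipeline_config(...))` chains all stages and writes TSV/JSON
outputs with checksums; `inst/scripts/citruskit.R` exposes the same stages
as shell subcommands (`simulate`, `preprocess`, `cluster`, `genotype`,
`select`, `kit`, `diagnose`, `run-all`).

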