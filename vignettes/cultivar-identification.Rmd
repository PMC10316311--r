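---
title: "Cultivar identification from retrotransposon insertion polymorphisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cultivar identification from retrotransposon insertion polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citruskit)
```

## The problem

New fruit cultivars are valuable intellectual property, and inspectors need
a fast yes/no answer to "is this sample cultivar X?". Because closely
related cultivars descend from repeated crosses among a narrow set of
ancestors, a single DNA polymorphism unique to the target often does not
exist; what does exist is a small *combination* of dominant
presence/absence markers that only the target carries. citruskit implements
the full computational chain behind such identification kits: discovering
insertion-site markers from transposon-display sequencing, scoring a binary
genotype matrix, finding minimal discriminating marker combinations, and
simulating the multiplex-PCR strip assay that deploys them.

The markers are of two kinds: InDel polymorphisms (scored by PCR amplicon
size) and LTR retrotransposon insertion sites of the citrus Copia-type
families CIRE1, Tcs1 and Tcs2. A retrotransposon insertion creates a
dominant marker: element-anchored PCR amplifies the flanking genomic
sequence in carriers and nothing in non-carriers, so each site is scored 1
(present) or 0 (absent) per cultivar.

## The identification rule

All marker sets use a pure conjunction (AND) rule. A set $S$ identifies
target cultivar $t$ in matrix $G \in \{0,1\}^{C \times M}$ iff

$$G_{t,m} = 1 \;\forall m \in S \quad\text{and}\quad
  \forall c \neq t\; \exists m \in S: G_{c,m} = 0.$$

Absences in the target are never used for discrimination: a missing band
cannot be distinguished from a failed reaction, which is also why every kit
carries a positive-control marker (the chloroplast *rbcL* gene, present in
all citrus) whose failure invalidates the assay rather than excluding the
sample. `minimal_and_set()` searches set sizes $k = 1, 2, \dots$
exhaustively (candidates are the target-present markers, excluding the
positive control and all-present columns, which can exclude no cultivar)
and returns the lexicographically smallest minimum-size solution, so
results are deterministic. This is a set-cover problem — each chosen marker
"covers" the cultivars lacking it — so `greedy_and_set()` provides the
classical greedy approximation for panels too large to enumerate
(hundreds of markers); the exhaustive solver is the default and is
exact for desk-scale panels (the default `max_k = 4` reflects the
four-line strip: at most three markers plus the control).

On the packaged 26-cultivar table, ties do occur: two Tcs2 markers
(`Tcs2-CL55_M`, `Tcs2-CL55_E`) share one presence column, so 'Mihaya'
has two equally small sets and the solver returns the lexicographically
first. The published kits are therefore built from the published marker
assignments (`citrus_kits()`), not from solver output.

## From reads to genotypes

**Read model.** `generate_reads()` emulates single-end 150 bp
transposon-display reads: a retrotransposon end tag (20 bp by default),
then the insertion site's genomic flank, then — when the insert is short —
adapter remnant and poly-A fill. Only read 1 is simulated: the analysis
uses a fixed 50 bp of flank, which read 2 cannot add to. Barcoding is
represented by per-cultivar FASTQ files; demultiplexing, fragment-level
size selection and indel errors are out of scope.

**Preprocessing.** The chain is `trim_tag()` → `trim_adapter()` →
`quality_filter()` → `fixed_length_trim()` → `collapse_duplicates()`.
Choices worth stating:

* *Adapter matching* trims at the leftmost full-adapter occurrence; exact
  always, and at most one mismatch when the adapter is at least 8 bp.
  Partial overhangs shorter than the adapter are not trimmed — harmless,
  since only the first 50 bp are analysed.
* *Quality* is filtered on the mean read QV (threshold 30). Filtering tools
  offer several modes (mean, minimum, windowed); the mean is used because
  it is deterministic and directly testable against the simulator's
  two-point QV mixture (pass 38 / fail 20, 90% pass by default).
* *Duplicate collapsing* reduces any 50-mer seen 10 or more times to
  multiplicity 1; below 10, the original multiplicity is kept. "Identical"
  means exact string equality. The operation is idempotent.

**Clustering.** The clusterer is a deterministic greedy stand-in for
self-alignment clustering: distinct 50-mers are processed in descending
total multiplicity (lexicographic tie-break); each joins the
earliest-founded cluster whose representative shares at least one exact
8-mer and lies within Hamming distance 2, else it founds a new cluster.
The (8, 2) defaults mirror the tile-size-8 / one-off-2 parameterisation
customary for this task; score-type settings of alignment tools have no
direct analog here and are absorbed into these two knobs. Representatives
are the highest-multiplicity members, so with realistic error rates the
error-free centre of each site anchors its cluster. Reads are clustered in
a single orientation: transposon-display reads share the element-anchored
orientation, so no reverse-complement matching is needed.

**Presence calling.** For cultivar $c$ and cluster $s$,
$$G_{c,s} = 0 \iff \frac{\mathrm{reads}(c,s)}{\mathrm{total}(c)} < 0.1\%,$$
with the boundary case (exactly 0.1%) scored present — the absence rule is
a strict inequality. Fractions are computed on post-collapse multiplicities
(clustering happens after collapsing, so cluster counts are post-collapse),
and `total(c)` is the cultivar's own library total for the family being
analysed, not the pooled run. Raising the threshold can only turn
presences into absences (monotonicity, property-tested). Cultivars with no
reads at all are scored all-absent with a warning rather than an error.

## Kit simulation

`design_kit()` places the positive control on line 1 and the markers on
subsequent lines by descending fragment size — an invented but fixed
convention, since strips do not dictate line order. Two physical
constraints are enforced: at most four lines (C-PAS4), and pairwise
fragment-size separation of at least `min_separation` (default 30 bp) so
the same primers stay resolvable on a 2% agarose gel; the published sizes
satisfy 30 bp comfortably (minimum observed gap 34 bp) while the paper
states the non-overlap requirement only qualitatively. Amplification is
modelled as deterministic given the genotype — primer-concentration tuning
and hybridization chemistry are wet-lab matters outside the model.
`diagnose()` partitions every line subset into exactly one of `invalid`
(control absent), `target` (all lines present) or `non_target`.

## Simulator defaults and what they do (and do not) show

Defaults, chosen once to mirror a realistic transposon-display experiment:
flank length 130 bp (tag + flank fills the read, as expected after 500–1000
bp size selection), depth 50 reads per present site, substitution rate
0.001, PCR duplicate copies $1 + \mathrm{Pois}(2)$, specific-site fraction
0.1 (typical of the three citrus retrotransposon libraries, whose
cultivar-specific fractions are 10/93, 24/276 and 19/174), and background
off-target fraction 0 — no published per-library off-target rate exists, so
background is opt-in rather than guessed. Flanks are rejection-sampled so
every pair differs at more than twice the mismatch budget over the first
50 bp, making cluster identity unambiguous; generation fails loudly if the
requested site count cannot be separated at the requested flank length.

With errors and background disabled, the pipeline recovers the simulated
truth matrix *exactly* — that is the end-to-end test, run at 26 cultivars ×
100 sites × depth 50 (about 180k reads, a deliberately desk-sized library;
the real libraries run to $10^8$ reads). Passing it shows the bookkeeping
is right, not that the thresholds are optimal for real data: real libraries
add chimeric reads, uneven amplification, shared k-mer structure between
genuine sites and mapping artefacts, none of which the generator emulates.
The 0.1% rule and the (8, 2) clustering knobs should be re-examined before
applying the pipeline to new sequencing data.

## Numerical and degenerate-input choices

* Lexicographic tie-breaks everywhere use C-locale byte order, so results
  do not depend on the session locale.
* A single-cultivar landscape forces every site present (a site absent
  everywhere would not exist).
* `collapse_duplicates()` rejects ragged-length input (trim first);
  `cluster_reads()` likewise requires one uniform length of at least the
  seed k-mer size.
* An empty read set flows through the whole pipeline and yields an empty
  genotype matrix with a warning, not an error.
* Duplicated marker columns in a genotype TSV are collapsed only when
  bitwise identical (the published table duplicates `Cp0419-s` under two
  kits); conflicting duplicates are an error naming the column.
* The duplicated `Cp0419-s` is printed with different fragment sizes under
  its two kits (371 bp and 246 bp); kit assembly therefore resolves sizes
  per kit target rather than per marker, and the genotype-level metadata
  carries no size for such markers.

## Worked example

```{r example}
gm <- citrus_genotypes()
glance(gm)
minimal_and_set(gm, "Kanpei", max_k = 3)
kit <- citrus_kits()[["Kanpei"]]
tidy(predict_bands(kit, gm, "Kanpei"))
diagnose_all(kit, gm) |> dplyr::count(band_count, verdict)
```

```{r plot, fig.width = 7, fig.height = 5}
autoplot(gm)
```

## Known limitations

The minimal sets depend on the marker panel: on the pooled 14-marker table
'Kanpei' admits a two-marker set, while against a broader screening panel
(185 published InDel markers plus all insertion sites) three markers are
needed — panels must match before comparing set sizes. The exhaustive
solver is exponential in `max_k` and intended for desk-scale panels; the
greedy solver scales but may overshoot the minimum. The simulator's
duplicate model is a plain integer multiplier without PCR family
structure, and indels are not simulated, so adapter/tag matching never has
to absorb length changes.
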