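---
title: "Evidence-based annotation updating: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based annotation updating: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotweave)
```

## The problem

Draft-genome annotations of non-model organisms — the cricket
*Gryllus bimaculatus* is the motivating case, with its `GBI_`-prefixed gene
identifiers — typically under-annotate isoform diversity, split single
transcription units into multiple gene models, and miss loci entirely.
Deep RNA-seq aligned to the genome and assembled into sample-specific
transcripts (StringTie-style GTF output) carries the evidence needed to
repair all three defects. annotweave implements the repair as a
deterministic, auditable procedure: classify every assembled transcript
against the reference, plan a set of update actions, apply them, and
account for what was done. Downstream, it also owns the bookkeeping that
such an update feeds: assembly summary statistics, the distribution of
merge sizes, gene-level reconciliation of transcript-mode BUSCO results,
and threshold-based summaries of differential-expression tables.

## Transcript classification

Each evidence transcript receives exactly one class code from a fixed
decision ladder; the first matching rule wins:

1. **EXACT** — a same-strand reference transcript has an identical intron
   chain. The chain is the ordered list of intron coordinates, so the ends
   of the terminal exons are deliberately ignored: RNA-seq evidence rarely
   pins transcription start and end sites, and requiring them would reject
   biologically identical structures. A single-exon transcript (which has
   no chain) is EXACT when a single-exon reference transcript shares at
   least a 0.8 reciprocal exonic overlap — a conventional single-exon
   equivalence cutoff, exposed as `single_exon_frac`.
2. **SPANS_MULTIPLE** — same-strand exonic overlap with two or more
   distinct reference genes. This is the gene-joining evidence, and it
   deliberately outranks isoform evidence: a transcript that bridges two
   genes usually also shares introns with at least one of them.
3. **NOVEL_ISOFORM** — multi-exon, shares at least one intron (both
   coordinates) with exactly one reference gene, but no identical chain.
4. **CONTAINED** — the chain is a contiguous sub-chain of a reference
   transcript's chain, or a single-exon transcript lies wholly inside a
   reference exon.
5. **EXONIC_OVERLAP_ONLY** — same-strand exonic overlap with one gene but
   no shared intron.
6. **OPPOSITE_STRAND** — exonic overlap only with genes on the other
   strand.
7. **INTERGENIC** — no exonic overlap at all.

Two structural decisions matter throughout. First, "touching" a gene
always means exon-to-exon base overlap, never genomic-span overlap;
without this, a gene nested inside another gene's long intron would be
joined to its host by any transcript of the host. Second, strand `"."` is
permitted only on single-exon transcripts (intron chains are
strand-dependent) and is treated as compatible with both strands.

A consequence of the ladder worth stating explicitly: any multi-exon
transcript whose chain is a sub-chain of a reference chain necessarily
shares introns with that gene, so rule 3 claims it before rule 4 can.
`CONTAINED` is therefore only ever reached by single-exon fragments inside
a reference exon. Such fragments carry no splicing structure absent from
the annotation, which is why the planner discards them rather than
instantiating truncated isoforms.

The classifier is backed by a `data.table::foverlaps()` interval join plus
hashed intron-chain lookup; its contract is that it equals the obvious
quadratic algorithm — the test suite compares it against an exhaustive
pairwise comparator on every fixture.

## Planning and applying the update

* **Isoform addition.** `NOVEL_ISOFORM` transcripts are grouped per target
  gene into `ADD_ISOFORM` actions. The gene keeps its identifier and its
  attributes byte-for-byte; the inserted transcript is renamed
  `<gene_id>.tN` with `N` the next free index, because the evidence
  assembler's own identifiers (`STRG.*`) are meaningless in the updated
  annotation.
* **Merging.** Every `SPANS_MULTIPLE` result contributes edges between the
  reference genes it touches, and the connected components of that graph
  (computed by union-find) become `MERGE` actions. Transitive closure is
  the point: a single cDNA fragment rarely spans eleven loci, but a chain
  of pairwise-spanning fragments can join eleven neighbors, and observed
  merge-size distributions have exactly that long tail. The merged gene
  receives a fresh identifier; the absorbed genes' transcripts keep their
  identifiers verbatim (so provenance remains traceable), the joining
  evidence transcripts come in as new isoforms, and the subunits'
  annotation text is concatenated `";"`-joined in ascending genomic order
  of the subunits — a deterministic order that reads left to right on the
  scaffold.
* **Novel genes.** Surviving `INTERGENIC` transcripts are clustered by
  mutual same-strand exonic overlap (union-find again); each cluster
  becomes one `NEW_GENE` action holding all its transcripts. Single-exon
  intergenic fragments shorter than `min_novel_single_exon_len`
  (default 200 nt) are discarded first: mapping artifacts and incompletely
  assembled fragments concentrate in exactly that class, and 200 nt is
  short enough that no plausible protein-coding or regulatory novel locus
  is lost. The threshold is configuration, not policy.
* **Discards.** `EXACT` (already annotated), `EXONIC_OVERLAP_ONLY`
  (ambiguous, no splice support), `OPPOSITE_STRAND` (no antisense rule is
  implemented — a conservative choice, since spurious antisense fragments
  are a known assembler failure mode), and `CONTAINED` (see above) are
  counted but never instantiated.

New gene identifiers are `GBIG_` plus a zero-padded six-digit counter,
assigned sequentially in genomic order of the actions, skipping any
identifier already present in the reference. The numbering offset is
configurable and defaults to 0; reproducing any particular historical
numbering seed is out of scope — determinism is the requirement.

Two invariants tie the whole procedure together and are enforced by tests:
the **gene-count law** `n_out = n_ref − Σ_k (k−1)·merges_k + n_novel` on
fixtures where no other effect interferes, and **idempotence** — re-running
the update with its own output as the reference yields zero actions,
because every instantiated transcript now classifies `EXACT` and every
discarded class stays discarded.

## BUSCO reconciliation

Transcript-mode BUSCO marks a gene's isoforms as `Duplicated` hits, which
misstates completeness at the gene level. `reconcile_gene_level()` maps
every `Complete`/`Duplicated` hit to its gene through a transcript-to-gene
map: one distinct gene means complete-single (isoform duplication
collapses), two or more mean complete-duplicated. Complete outranks
fragmented — a BUSCO with both kinds of hits is complete — which is the
standard BUSCO precedence; re-scoring fragmented-versus-complete from the
best isoform's HMM score is deliberately not attempted, status precedence
only. Percentages are `100·count/n_total` rounded half-up to two decimals.
The reconciliation can only collapse duplications: merging two genes in
the map never converts a single into a duplicate (tested as a property).

## Differential-expression summaries

The negative-binomial model fit is upstream (DESeq2); this package owns
what is done with its output table:

* significance: `padj < 0.1` and `|log2FC| > 0.6`, both strict. The FDR
  direction is exposed as `padj_max` and the fold cutoff as `lfc_min`.
* fold bins: "4-fold or greater" is inclusive, `|log2FC| >= 2`.
  Percentages print as integers unless the exact value terminates at one
  decimal (15/24 prints as 62.5, 13/14 as 93).
* top tables: among significant genes, `baseMean >= 70` filters low
  expression, ranking is by fold change with lexicographic gene-id
  tie-break, and BLAST annotations with E-value above 1e-10 are labelled
  `NSS` (no significant similarity).
* volcano preparation: adjusted p-values below 1e-10 are clamped to 1e-10
  so extreme points stay on-scale; the four point categories are exactly
  the four quadrants of the two thresholds.
* ranked export: `baseMean >= 100`, two columns (gene, log2FC), sorted by
  fold change — the shape ranked-list enrichment tools ingest. Enrichment
  terms tagged `both` are copied into both the up and the down list before
  downstream semantic clustering.

## The synthetic-data generator

`make_annotation_pair()` lays reference genes left to right on
`Scaffold1`, separated by gaps larger than twice the maximum intron
length, and plants evidence transcripts per class: exact copies with
ragged terminal ends, novel isoforms that keep the first intron and bridge
the rest with a novel exon, merge groups realized as chains of
pairwise-spanning transcripts (so closure is actually exercised; a group
of k genes yields k−1 spanning transcripts), novel-gene clusters and
sub-threshold 120 nt fragments on `Scaffold2` where they are trivially
intergenic, and antisense fragments over pool genes. Scaffold naming
follows the draft-genome convention. Everything derives from one seed and
the generators restore the session RNG state.

`make_de_tables()` plants per-day significant sets, their ≥4-fold
subsets, and a cross-day overlap structure; every planted value sits at
least 0.01 away from each threshold boundary, because boundary semantics
are tested by explicit cases, not by luck. `make_busco_table()` realizes
planted gene-level categories as transcript-level rows, including
isoform-level duplications that must collapse.

What passing tests on these fixtures shows: the classification ladder,
closure, accounting, reconciliation and thresholding are implemented
exactly as specified. What it does not show: behavior on real alignments
with soft-clipping, overlapping loci, fusion artifacts or
expression-dependent assembly dropout — none of which the generator
emulates.

Problem sizes used by the test suite are the package's own choice of
scale: scenario fixtures of roughly 15–100 reference genes, 25 randomized
parameter-recovery scenarios, a merge-distribution scenario with the full
set of merge sizes (including an 11-gene chain) at one-fiftieth of the
observed instance counts, a 1,013-ortholog BUSCO set, and
three DE tables of ~2,300 genes each. The full-scale published outputs
(74,090 transcripts from 28,637 genes) are not reproducible from fixtures
— they require the original aggregate alignment and draft genome — so the
suite verifies the arithmetic the update reports on top of those inputs,
plus the two invariants above, at fixture scale.

## Numerical and degenerate-input choices

* Reported ratios use round-half-up (with a 1e-9 epsilon absorbing
  floating-point representation just below a .5 boundary), matching how
  summary tables conventionally print; base R's `round()` would give
  round-half-even.
* Ties everywhere break lexicographically (matched transcript choice,
  top-table ordering, ranked export), making every output a pure function
  of its input.
* Empty evidence, empty plans, genes on unknown scaffolds, and all-missing
  BUSCO sets are all defined, not errors; an empty annotation set cannot
  be summarized (no statistics are definable) and that is an error.
* GTF parsing treats exon features as authoritative; optional
  gene/transcript header lines must agree with the exon-derived extents or
  parsing fails — silent disagreement is how annotation corruption
  propagates.

## Known limitations

* No gene *splitting*: evidence that one annotated gene is two
  transcription units is not acted on, so published gene counts that
  include such rules will not be exactly reproduced by the stated actions.
* No antisense gene instantiation, and only the four GFFcompare-like
  relationship groups the update consumes are distinguished; finer codes
  (intronic containment on the same strand, polymerase run-on fragments)
  are folded into their nearest group here.
* The single-exon 0.8 reciprocal-overlap cutoff and the 200 nt novel-locus
  floor are field conventions, not fitted quantities; both are exposed as
  configuration.
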