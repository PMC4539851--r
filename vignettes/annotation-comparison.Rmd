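---
title: "Comparing and merging bacterial genome annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and merging bacterial genome annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annocompare)
```

## The model

`annocompare` treats a genome annotation as a set of closed genomic
intervals — one per CDS, tRNA, rRNA or ncRNA feature — each carrying a
strand, an optional product description and pseudogene/frameshift flags.
Nothing else from the GenBank record is used: no sequence, no evidence
qualifiers. The comparison question is purely structural and lexical: do two
annotation methods (AMs) call the same gene at the same place, and what do
they each say it does?

Two genes from different annotations of the same genome match when they lie
on the same replicon and strand and their ends agree closely enough:

* **identical**: equal start and stop.
* **similar**: every end deviation is at most `offset` × (length of the
  shorter gene), the feature types agree, and — for CDS — both genes are in
  the same reading frame. The frame is the mod-3 phase of the
  translation-initiation end: `start %% 3` on the plus strand, `stop %% 3` on
  the minus strand, so a shared stop codon with a shifted start still counts
  as the same frame, while a 1 bp start shift does not.
* **unique with overlap**: any other same-strand overlap. This includes
  *short overlaps* (deviations beyond the offset), feature-type mismatches,
  and in-offset CDS overlaps in different frames; the last group is also
  reported as *relative frameshifts*, since neither AM flagged a frameshift
  but the two gene models are incompatible at the codon level.
* **unique without overlap**: no same-strand shared base pair.

The pairwise similarity score is the matched fraction of the pooled gene
set, `2·(Identical + Similar)/(Total_x + Total_z)·100`, which is symmetric,
equals 100 exactly for self-comparison, and is insensitive to which
annotation is called the reference.

### One-to-one matching

An AM may place several gene models over one reference gene, so statuses are
assigned under a one-to-one matching rather than per overlapping pair.
Candidate pairs (same replicon, same strand, ≥ 1 shared bp, found with
`IRanges::findOverlaps`) are ranked by status (identical before similar
before unique-with-overlap), then by total end deviation, then by shared
base pairs, then by partner coordinates and identifiers; pairs are accepted
greedily while both genes are unmatched. The final coordinate/identifier
tie-breaks make the matching fully deterministic. Genes left unmatched are
unique-without-overlap, even if they touch an already-consumed partner —
under this convention the four status buckets exactly partition each
annotation, which is the identity the reference report relies on
(identical + similar + FN_short + FN_none = reference total, and the FP
analogue for the query). The test suite checks the greedy matcher against an
exhaustive all-pairs brute-force implementation of the same preference order
on hundreds of random annotations.

### Pseudogene propagation

When an identical or similar pair has exactly one member flagged as a
pseudogene, the flag is copied to the other member (never removed), and the
pipeline repeats the pairwise sweep until a fixpoint so that flags travel
across AMs transitively. Short-overlap pairs do not propagate: two gene
models that disagree on the gene's extent are not treated as the same gene.

## Multi-annotation clustering and the extended views

With three or more annotations, genes are grouped into clusters built from
the pairwise identical/similar matches under a **clique rule**: a gene joins
a cluster only if it matches every current member, with at most one gene per
annotation, seeded greedily in input-annotation order. The alternative —
transitive chaining — would let a drifting series of borderline matches
merge unrelated genes into one cluster; the clique rule guarantees that
every pair inside a cluster satisfies the similarity conditions, which is
exactly the property the merged annotation claims for its genes. Because
matching is one-to-one per annotation pair, the greedy clique growth is
deterministic and every gene lands in exactly one cluster, so cluster sizes
conserve the pooled gene count and the support-set (Venn) region totals per
label equal that annotation's gene count.

The extended views follow directly:

* **EA** — clusters with support ≥ 2. Representative coordinates come from
  the reference member if the cluster has one, else from the first-listed
  supporting annotation: the input order is read as the user's trust order.
  All member descriptions are kept verbatim with their AM labels; no attempt
  is made to reconcile conflicting descriptions, as free-text comparison of
  product names is out of scope by design. A merged gene is *functional* iff
  at least one member description classifies as functional, which is the
  mechanism by which the EA raises the functional fraction above every
  individual input.
* **unique** — support-1 clusters, grouped by source AM.
* **EUA** — the concatenation of EA and unique, so `|EUA| = |EA| + |unique|`
  is asserted on every run.
* **EUA_clean** — EUA minus pseudogenes and frameshifted genes (including
  propagated flags); idempotent.
* **complemented per-AM views** — each AM's own gene set in which an orphan
  member of a support-≥ 2 cluster is re-labelled functional when another
  member supplies a function. The exact rule behind this view is a declared
  interpretation: it re-labels, never re-coordinates.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `offset` | 0.02 | end-deviation tolerance as a fraction of the shorter gene's length; 0.02 is the conventional 2 % used for "significant" overlap |
| `patterns` | see `default_product_patterns()` | case-insensitive substrings defining hypothetical and conserved-hypothetical products |
| `first_is_reference` | `TRUE` | score every other annotation against the first-listed one |

Raising `offset` can only move pairs from unique-with-overlap to similar,
never the reverse; this monotonicity is tested over
`{0, 0.01, 0.02, 0.05, 0.10}`.

Product classification is purely lexical. The hypothetical lexicon
(`"hypothetical protein"`, `"uncharacterized"`, `"unknown function"`,
`"predicted protein"`, `"hypothetical"`; conserved:
`"conserved hypothetical"`, `"domain of unknown function"`, `"DUF"`) is
deliberately explicit and replaceable rather than an undocumented heuristic;
no database lookup of conserved genes is attempted. Conserved hypotheticals
count inside the hypothetical (orphan) side of every split, and are also
reported separately in the per-annotation statistics.

## Numerical and degenerate-input choices

* **Rounding.** All printed percentages use half-up rounding to two decimals
  (`round_half_up()`), not R's round-half-to-even, because the published
  tables this mirrors use decimal half-up arithmetic. A machine-epsilon
  guard absorbs binary representation error.
* **Coordinates.** GenBank 1-based inclusive throughout; GFF3 shares the
  convention, so export applies no shift. Partial-location markers (`<`,
  `>`) are stripped; partiality is not modelled.
* **Discontiguous genes.** `join(...)` locations keep their segments but
  compare on the outer span, and are excluded from frame checks (their frame
  is undefined at the span level). A segment crossing the replicon origin is
  normalised per-segment.
* **Feature types.** Only CDS, tRNA, rRNA and ncRNA are modelled; tmRNA,
  misc_RNA and bare `gene` features are skipped and counted in a
  `skipped_features` attribute. Type-mismatched overlaps can never be
  identical or similar.
* **Empty inputs.** A GenBank file with records but no features yields a
  zero-gene annotation; a file with no records at all is an error. The
  similarity score of two empty annotations is undefined and raises an
  error; percentages of an empty view are reported blank.
* **Per-end offset test.** Each end deviation is compared to
  `offset × Lmin` independently (not their sum) — the most literal reading
  of "start and stop positions deviating no more than the offset".
* **Overlap counting.** The per-annotation statistic counts overlapping
  *genes* (genes involved in ≥ 1 internal overlap), not overlapping pairs.

## The synthetic-data generator

`generate_annotation()` packs non-overlapping genes (CDS lengths are codon
multiples between 300 and 1500 bp; realistic tRNA/rRNA/ncRNA lengths; ~85 %
CDS; ~30 % hypothetical products) onto one replicon with a minimum
intergenic gap of 150 bp, deterministically per seed.
`perturb_annotation()` then emulates AM disagreement with disjoint gene
sets: in-offset end shifts (intended status *similar*; codon-multiple shifts
for CDS so the frame survives), beyond-offset shifts (*unique with
overlap*), 1 bp frame-breaking shifts of the translation-start end (*unique
with overlap* + relative frameshift), dropped genes (reference-unique),
inserted genes (query-unique), plus pseudogene and product rewrites that do
not move coordinates. Every shift moves an end inward, so perturbed genes
never collide with neighbours and each variant gene has exactly one
defensible intended status, recorded in a truth log.

What passing on these fixtures shows — and what it does not: the matcher,
score, clustering and extension algebra are exact on inputs whose true
correspondence is known and unambiguous. Real annotations additionally
contain dense operon-style overlaps, shared stop/shifted start models at
saturating density, partial genes at contig edges and inconsistent replicon
naming; the matcher's behaviour there is defined (and deterministic) but not
validated against a curated truth, because none is bundled. Test problem
sizes (50–100 genes per annotation, hundreds of seeds) were chosen as the
smallest scale at which every perturbation class occurs several times per
fixture.

## Known limitations

* Start/stop positions are never corrected, and no judgment is made about
  which AM is biologically right; conflicting descriptions are listed, not
  reconciled.
* Matching is greedy, not globally optimal; the documented preference order
  is the specification, and the brute-force oracle in the tests implements
  the same order.
* Replicon identity is taken from the LOCUS name; annotations using
  different replicon naming schemes must be renamed upstream (the error
  message says so).
* The Venn output is the textual region-count table; the optional plots are
  simple base-graphics charts, not true proportional Venn diagrams.
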