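---
title: "Quantifying mitogenome architectural evolution with mgorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitogenome architectural evolution with mgorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgorder)
```

## The model

`mgorder` treats a mitogenome as a circular, strand-signed sequence of gene
labels drawn from a 40-symbol vocabulary: 13 protein-coding genes, 22 tRNAs
(the two leucine and two serine tRNAs distinguished as trnL1/trnL2 and
trnS1/trnS2 by the standard anticodon designation), 2 rRNAs, the control
region (CR), the light-strand replication origin (OL), and an open `extra`
class for unmappable features. Repeated copies of a label are distinguished
only by encounter order from the anchor, never by sequence identity: the
pipeline works on annotations alone and makes no nucleotide-level claims.

Two observationally equivalent genomes should compare as equal, so every
order is reduced to a canonical representative of its equivalence class
under rotation and under reflection-with-strand-flip:

* **Reading direction** is chosen so the majority of protein-coding genes
  lie on the plus strand. Mitochondrial protein-coding genes are almost all
  heavy-strand encoded (nad6 is the lone exception in the typical
  vertebrate arrangement), so this recovers the conventional orientation
  and guards against reverse-annotated submissions. If there is no
  majority, the orientation with fewer minus-strand genes wins, then the
  lexicographically smaller serialization — an arbitrary but deterministic
  convention that only matters for synthetic inputs.
* **Anchor**: the linearization starts at trnF, the tRNA conventionally
  flanking the control region in vertebrates; if trnF is absent the chain
  falls back to rrnS, then to the lexicographically smallest token. With
  several anchor copies, the rotation with the smallest serialization wins.
* Reflection equivalence never merges genuinely distinct biology here —
  published comparisons never score a genome against its mirror — but it
  makes ingestion robust to annotation pipelines that report the opposite
  strand.

Canonical orders are serialized as one-line strings
(`trnF,rrnS,...,trnT,-trnP,CR,CR.2`), and *gene rearrangement types* are
equivalence classes of samples under exact canonical equality, numbered by
descending member count.

## Two rearrangement metrics

**Neighbor scheme** (alignment-free). Every gene of the query contributes
the number of its two strand-signed adjacencies (predecessor, successor)
absent from the reference's adjacency set: 0, 1 or 2. Adjacencies are
compared by signed token with copy indices ignored, so a duplicated copy is
scored against every placement of that token in the reference; a gene with
no reference counterpart necessarily scores 2. The genome score RS is the
per-gene sum. Because each broken adjacency is counted at both of its
genes, a single remote translocation scores 6 (2 on the moved gene, 1 on
each of the four flanking genes), and RS is symmetric whenever gene content
matches.

**Aligned scheme** (breakpoint-partitioned). The circle is first cut at two
junctions chosen after the replication/transcription organisation of the
vertebrate mitogenome — (CR → trnF) and (trnN → OL inside the WANCY
cluster) — into two linear intervals. When a junction is absent from a
derived order, the cut falls back to "after the left token", then "before
the right token", and the fallback used is reported; this is what places
the Neobatrachian LTP cluster in the first interval. Genes within each
interval are aligned to the reference's columns (same token, nearest
relative rank, earliest reference column on ties; copies matched within
their interval first). Each gene is then classified:

* *unchanged* — same interval, same relative order, same strand;
* *transposed* — interval changed, or relative order changed;
* *inverted* — strand changed; *transposed+inverted* for both;
* *duplicated/gained* — no reference column; *lost* — no query gene
  (reported on the reference token).

"Relative order changed" needs care. We mark a matched gene as moved unless
it belongs to **every** maximum-length increasing subsequence of reference
ranks taken in query order. A plain longest-increasing-subsequence test is
ambiguous for a swap of two blocks — either block is a valid complement —
whereas the all-maxima rule marks both blocks, matches how curators
describe such swaps (all four genes of a nad6-trnE / cob-trnT interchange
moved), and is symmetric in query and reference, so the transposed gene set
is identical whichever genome serves as reference.

Event weights default to 1 per class (a transposed+inverted gene scores the
sum of both weights); they are exposed because weighting conventions vary
between published tools and any calibration should be explicit, not
hard-coded.

RF tables accumulate per-gene scores over *types*, not samples, by default:
dataset-wide hotspot tables are computed over deduplicated types, and
weighting by sample count is a separate mode (`per_sample = TRUE`). Lost
genes contribute to the reference token's RF. The all-vs-all RS matrix
scores every ordered type pair and needs no global reference.

## Annotation ingest

Readers accept GenBank flat files (LOCUS length; gene/CDS/tRNA/rRNA/
D-loop/rep_origin keys; `complement()` and origin-wrapping two-segment
`join()` locations; `/gene`, `/product`, `/anticodon` qualifiers) and a
per-gene TSV. Coordinates are 1-based inclusive on input, the GenBank
convention; features whose start exceeds their end are flagged as wrapping
the circular origin and their length computed modulo the genome length.

Control regions are frequently unannotated, so every intergenic gap of at
least `min_gap` bases becomes a CR feature, including the wrap-around gap.
The threshold defaults to 250 bp — comfortably shorter than any real
control region (hundreds of bp to several kb) and longer than typical
intergenic spacers (tens of bp) — and is exposed as configuration since no
single value is canonical. Raising the threshold can only remove
detections, a monotonicity the tests enforce. One genuine limitation:
tandem control-region copies merge into a single gap, so gap detection can
never see more than one CR per gap; tandem copies must arrive annotated.

Name standardization maps annotation spellings (ND5/NADH5, COI/cox1,
12S/rrnS, D-loop, tRNA-Phe, ...) onto the vocabulary. Leucine and serine
tRNAs are resolved by anticodon when present (trnL1 = UAG, trnL2 = UAA,
trnS1 = GCU, trnS2 = UGA), else by positional context against the
reference pattern (a leucine tRNA between trnS1 and nad5 is trnL1; between
rrnL and nad1, trnL2), else flagged `leucine-serine-ambiguous`.

Validation emits the standard error taxonomy: `missing-gene` (any of the
37 canonical genes absent; fatal), `abnormal-strand` (strand contradicts
the reference *only when* the unsigned order matches it exactly, so
genuine inversions that also relocate genes are not falsely flagged),
`duplicate-unexpected` (recorded, not fatal), `name-unrecognized`,
`invalid-annotation`. Records failing fatally are flagged and excluded
rather than re-annotated; a hook for an external annotator is deliberately
out of scope.

Taxonomy reconciliation is fully offline: names with `cf.` or `sp.` go to
an unidentified list, hybrids are flagged, an `aff.` qualifier is dropped
before matching, trinomials truncate to binomials; cleaned binomials are
deduplicated and matched against a (family, genus, species-count)
checklist, with a manual mapping table for the remainder and an
`unresolved` listing rather than an error. Coverage is reported against
the checklist exactly as given — per-rank percentages and per-genus
mean/median species coverage — and is invariant to sample duplication.

## Phylogenetic dynamics

Trees are `ape` phylogenies with branch lengths in Myr; node ages are
measured from the present. `edit_tree()` supports pruning taxa (with branch
fusion, preserving the ages of surviving nodes) and grafting tips at
stated attachment ages, for reconciling a published backbone with a
revised family list.

Ancestral types are assigned by exact parsimony, computed as a Sankoff
dynamic program: unit costs reproduce Fitch counts, or a pairwise RS
matrix serves as the cost matrix (the cost of changing from parent state s
to child state t is the RS of t against reference s). The root can be
forced to the type observed at a designated outgroup tip — the
outgroup-based rooting convention for ancestral gene orders — in which
case the program returns the exact minimum conditional on that root.
Top-down tie-breaking prefers the parent's state, then the lowest type id;
both choices favour fewer, later changes and make the output
deterministic.

For the time course, the tree is sliced into half-open 5-Myr intervals
(the oldest closed, so the root is counted; 34 intervals span a 170-Myr
crown). Every node — tips included by default, since they carry observed
types; exclusion is a toggle — contributes the RS of its assigned type
against the reference to the interval containing its age, grouped by
taxon; internal nodes whose descendant tips span several taxa form an
explicit `ancestral` group so the partition always sums to the all-taxa
curve. Cumulative totals run from the oldest slice toward the present and
are therefore non-decreasing. Whether the interval grid should start at
the root age or a round figure is unsettled; the interval count and width
are both configurable. An alternative `branch` mode accumulates the RS
between parent and child types instead of state-vs-reference, for readers
who prefer a change-along-branch interpretation; the default remains
state-vs-reference.

## Richness versus rearrangement

Per-family species richness (from the checklist, not the sampled species —
sampling effort varies too much for sampled counts to measure standing
diversity; both modes exist) is regressed on summed RS by LOESS (tricube
weights, degree 1, span 0.75, direct surface so collinear input is
reproduced exactly). Families with |residual z| > 2 are flagged, signed
toward the axis in excess. The threshold formalizes what is usually an
eyeballed judgement; it is this package's rule, exposed as a parameter.

## The simulator

`simulate_tree()` builds ultrametric multi-family trees by explicit
coalescence: family backbone joins in the deep 55–98% of the root age
(the oldest exactly at the root age, 170 Myr by default), family crowns in
the shallow 15–45%, so families are monophyletic with labeled clades.
`simulate_events()` draws translocations, inversions, duplications,
CR-duplications and losses as independent Poisson processes along each
branch and mutates the circular order event by event from the vertebrate
ground pattern. Defaults follow the qualitative structure reported for
real amphibian datasets — translocation the dominant class (2e-3
events/lineage/Myr), CR duplication prominent (1e-3), generic duplication
5e-4, inversion and loss rare (2e-4 each) — yielding on the order of 0.7
events per root-to-tip path on a 170-Myr tree. Duplications insert in
tandem with probability 0.5 and at a uniform remote site otherwise,
mirroring both tandem CR repeats and remote copy transpositions; a loss
guard (on by default) refuses to delete the last copy of a canonical gene,
since wholesale gene loss is exceptional. Events with no eligible site are
silent no-ops and never logged, so replaying the log from the root pattern
reproduces every node's order bit-exactly — the invariant the recovery
tests rest on. An `event_max_age` confines events to recent slices for
scenarios with a planted onset time.

What the simulator does *not* emulate: sequence evolution, rate
heterogeneity among lineages, duplication-random-loss correlation
structure (each event is independent), or realistic rates estimated from
data. Passing tests therefore demonstrate the pipeline's mechanics —
canonicalization, scoring, inference, slicing — under known truth, not
that real amphibian data will behave as simply. In particular, convergent
tandem CR duplications arise in simulation exactly as they do in nature,
and parsimony will happily (and wrongly) push such homoplasic types below
their true origin; this is a property of parsimony, not a defect of the
implementation, and it is why the time-slicing validation uses
ground-truth node states while inference is validated against exhaustive
minimization separately.

## Numerical choices and problem sizes

Ties everywhere resolve deterministically (documented above per
operation). The exhaustive validation sizes are chosen to finish in
seconds while covering the space that matters: all circular orders of up
to 6 distinct genes for the adjacency oracle (152 orders), all 3^n type
assignments on 4-tip trees plus sampled assignments on 5- and 6-tip trees
for parsimony, 50 replicate 16-tip clades for ancestral recovery, 100
clades for the event-count/RS correlation, and a 1777-sample / 88-type
planted dataset for deduplication. The acceptance script repeats these
from scratch under a caller-supplied seed.

## Known limitations

* Gap-based CR detection cannot separate tandem CR copies (above).
* The neighbor scheme under-scores genes inside clusters that transpose
  as a block (interior adjacencies survive the move), a recognised
  limitation of alignment-free scoring; the aligned scheme is the remedy.
* The automatic interval aligner is greedy; a curated manual alignment
  table can always be supplied and is validated before use.
* Parsimony reports one optimal assignment under documented tie-breaks,
  not the full set of most-parsimonious reconstructions.
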