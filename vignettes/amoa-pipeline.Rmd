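---
title: "From raw amoA records to a curated database, taxonomy and molecular signatures"
author: "amoatax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw amoA records to a curated database, taxonomy and molecular signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amoatax)
```

## The problem

Archaeal ammonia oxidisers (AOA, class *Nitrososphaeria*) are routinely
surveyed through PCR amplicons of the *amoA* gene, the marker encoding
subunit A of ammonia monooxygenase. Public repositories hold tens of
thousands of such fragments, and they are dirty in predictable ways:
ambiguous bases, wrong orientations, frameshifts from sequencing indels,
premature stop codons, truncated amplicons, and a large load of PCR
chimeras. `amoatax` implements, as reusable R functions, the computational
chain that turns such a corpus into a curated gene database with OTUs, a
reproducible support-based taxonomy, consensus-tree selection, per-gene
molecular signatures and hierarchical habitat profiles. A seeded
synthetic-data generator produces every input with known ground truth, so
the whole chain is testable end to end without downloads.

## Curation model

All analyses work in a common coding frame of 591 columns (197 codons), the
longest coding region shared by the common *amoA* amplicons. Curation is a
fixed cascade:

1. **Alphabet screen** — records containing anything outside `ACGT` are
   removed (`screenAlphabet`).
2. **Six-frame extraction** (`extractInFrame`) — both orientations and all
   three offsets are scanned for the longest stop-free codon run; partial
   codons are trimmed. Fragments under 194 codons (582 nt) are rejected:
   the floor admits up to three biological codon deletions against the
   591-nt frame. Ties between equally long fragments prefer the forward
   strand, then the lower frame offset. A stop-free window with no stop at
   either end is accepted as an open fragment.
3. **Frameshift screen** (`screenFrameshifts`) — the fragment is globally
   aligned (affine gaps, opening 10 / extension 2) to its nearest reference
   by shared 8-mer count; any gap run whose length is not a multiple of
   three fails the gene, and more than three whole-codon indels fails it
   too. When the fragment and its nearest reference have equal length and
   at least 80% column identity the alignment is skipped, because the
   affine-gap optimum is then gapless.
4. **Global trim** (`globalTrim`) — survivors are fixed to exactly 591
   frame columns; sub-582-nt fragments are excluded; shorter survivors are
   padded with frame gaps as columnar bookkeeping.

Rejection reasons are observable, not oracular: a truncated record always
fails as `short` (length pre-check), while premature-stop and frameshift
corruptions surface as `no-orf` at extraction or as `frameshift` at the
alignment screen, depending on whether the damaged record happens to retain
an alternative-frame open window of 582 nt or more. Tests assert this
documented mapping together with zero false accepts and zero false
rejections on registry-labelled data.

Real-world alignments (MAFFT and back-translation in the original
workflow) are out of scope: the package accepts externally aligned input
and treats the frame as columnar bookkeeping.

## Chimera screening

The screen is reference-based. The trusted database is assembled by three
admission rules — dereplicated multiplicity of at least five; full-length
identity of at least 99% to two or more other sequences including one from
an independent study; or genome derivation (a flagged input) — and then
clustered at 97% identity so no two members are more similar than that.

Each query is scored against a two-parent (bimera) model. With candidates
gated at 80% query identity and ranked by shared 8-mers, every ordered
candidate pair `(A, B)` and breakpoint `b` defines the model
`M(A,B,b) = A[1..b] + B[b+1..L]`; the search keeps the model matching the
query at the most columns (ties: smallest `b`, then lexicographic pair).
Writing `mQM` for the query's matches to the best model and `mQT` for its
matches to the better of the two reported parents `T`,

* divergence `d = 100 (mQM − mQT) / L`;
* the vote score `h` is computed on the *informative* columns — those where
  the model and `T` disagree. Per side of the breakpoint, `Y` counts
  query-matches-model columns, `N` query-matches-`T`, `A` neither, and
  `h_side = Y / (Y + 8 N + 0.5 A)`; `h` is the minimum over sides that have
  informative columns (a side without any cannot veto), and 0 if no column
  is informative.

A query is chimeric iff `d ≥ 1.7` and `h ≥ 0.10`, the thresholds
established for this marker. The informative-column restriction is this
package's own scorer contract: counting every agreeing column as an
abstention would drive `h` toward zero even for a perfect bimera and make
the published threshold meaningless. Note the applicability domain the 80%
gate implies: a bimera whose minor parent contributes a fraction `f` of
columns is only scorable while parent divergence stays below
`0.2 / (1 − f)`; with breakpoints in the central 60% of columns this is
0.25. A whitelist re-admits verified false positives, and the verdict table
carries an empty `external_label` slot for a second-opinion method so
union/intersection filtering can be reproduced organisationally. A
branch-length outlier report (`branchLengthOutliers`) supports the manual
tree-inspection step; nothing is removed automatically.

## OTU clustering

`pairwiseDistances` defines distance as one minus the fraction of matching
columns, by default excluding columns gapped in either sequence from both
numerator and denominator (gap handling differs across program versions;
this policy is fixed and documented rather than inferred).
`averageNeighbour` is agglomerative average-linkage clustering: merge while
the smallest average inter-cluster distance is at most `1 − identity`,
with ties broken by the lowest distance then lexicographic cluster labels
(a cluster is labelled by its smallest member id). The representative is
the medoid, ties lexicographic — reproducible where "first seen" would not
be. 96% identity is the working OTU level, 97% the reference-database
level, 99% the near-duplicate level. `assignToOtus` maps new sequences to
the best representative at a strict `≥ 0.96` identity and reports the
assignable fraction.

## Taxonomy from dual branch supports

A `SupportTree` carries an ultrafast-bootstrap and an SH-aLRT percentage on
every internal branch. `collapseUnsupported` contracts every branch with
UFBoot `< 95` **or** SH-aLRT `< 85` (both boundaries inclusive: a branch at
exactly 95/85 survives); children re-attach to the grandparent and keep
their own lengths — the contracted branch length is dropped.

`assignRanks` then walks the collapsed tree from seeded order clades (an
anchor leaf per order prefix: NC, NS, NT, NP). Within a named clade, the
maximal supported subclades with at least three leaves are rank-eligible;
a new rank level opens only when at least two eligible subclades must be
distinguished, otherwise the clade is terminal. Labels are Greek letters at
level 1 and integers deeper (`NP-α-2.2.2.1` style), assigned in descending
order of stem branch length starting from the longest. The original
procedure only fixes the first label by the longest branch; this package
orders *all* siblings that way and breaks ties by larger leaf count, then
the lexicographically smallest member id, so labelling is fully
deterministic. Exactly-two-leaf subclades are named `<parent>-IS`
(incertae sedis; `-IS2`, `-IS3`... when several). Singleton leaves carry
the parent's name. Manual overrides force a rank onto listed monophyletic
clades — the mechanism behind the four long-branch exceptions of the
original taxonomy — even where the redundancy rule would suppress it.
Leaves outside every seeded order go to one reserved incertae-sedis bucket.

`classifyGene` places new sequences by nearest representative at `≥ 96%`
identity, falling back to the deepest taxon covering all representatives
within a relaxed radius (default 90%), else `unclassified` — an
identity-based stand-in for likelihood placement, which is out of scope.
`exportTaxonomy`/`importTaxonomy` round-trip the taxonomy losslessly
through an annotated Newick (`name|ufboot/shalrt` node labels) and a flat
TSV.

## Tree certainty and congruence

`internodeCertainty` scores each internal bipartition of a focal tree
against a candidate set: with `f1` its frequency across the trees, `f2` the
frequency of its strongest observed conflict, `p_i = f_i/(f1+f2)`,
`IC = 1 + p1 log2 p1 + p2 log2 p2`, negated when the conflict is the more
frequent. Frequencies count trees, not bootstrap replicates; a branch with
no observed conflict scores 1; multifurcations contribute only resolved
branches. `selectBestTree` sums IC into tree certainty and returns the
argmax (ties flagged and broken by the lexicographically smallest Newick
serialisation). `sharedCladeCongruence` classifies each reference-tree
clade as congruent (monophyletic in the focal tree), compatible
(monophyletic once leaves absent from the reference are ignored) or
conflicting; the compatibility rule is a formal proxy for the expert
judgment used on real data and is labelled as such in the report.

## Molecular signatures

GC and purine content are percentages on the coding strand (purine on the
sense strand is a fixed convention here). The effective number of codons
uses Wright's estimator: per synonymous family,
`F = (n Σ p_i² − 1)/(n − 1)` for `n ≥ 2`, and
`Nc = 2 + 9/F̄2 + 1/F̄3 + 5/F̄4 + 3/F̄6` over the redundancy classes of the
standard code (the 3-codon class is Ile; Met, Trp and stops are excluded),
capped into [20, 61]. When a class has no usable family or a non-positive
mean, the uniform-usage expectation `1/k` substitutes — `chips`-style
behaviour is version-dependent, so the contract is made explicit.

The global codon adaptation index scores genes against
relative-adaptiveness weights `w_c = f_c / max f` within each family.
Fixed mode pools the reference counts once; the default iterative mode
re-fits weights while keeping the top-scoring half of the references until
the set reaches `max(1%, 5)` members or the weights stabilise (tolerance
`1e-6`), which converges to the dominant codon bias of the reference set —
validated by recovering the biased subpopulation from a 90/10 mixture, not
by matching any external tool's schedule. Codons unseen within an observed
family get the pseudo-weight `0.5/max count` (avoiding log 0); unobserved
families are skipped in the geometric mean.

Per-OTU summaries report the deviation of each OTU mean from the global
average, where the global average is the unweighted mean over OTU means so
large OTUs cannot dominate; single-gene OTUs report SD 0. Gene-versus-
genome relationships use ordinary least squares with a residual table for
external diagnostics.

## Habitat profiles

Annotations live on a category forest rooted at broad habitats (marine,
soils-sediments, freshwater, estuarine-coastal, salt lakes, hot springs,
host-associated), with depth zones split at 200 m and pH classes at
6.5/7.5; range categories such as `acidic-neutral` are explicit sibling
nodes. The level-wise fraction rule: at a node, the denominator counts
sequences assigned at or below any child, *excluding* those whose
annotation stops at the node itself, so broader-only sequences never
distort child fractions. Conflicting duplicate annotations resolve
first-wins with a logged conflict. Counts aggregate per taxon times habitat
(multiplicity-weighted) and export to Krona-style two-column text that
round-trips.

## The synthetic generator

`simConfig`/`simulateAmoaData` generate: a rooted tree of 2 or more order
clades, optionally with 3-8 supported subclades each; dual supports with
true clade stems drawn from the high regime (UFBoot in [95,100], SH-aLRT in
[85,100]) and all other internal branches failing one threshold, the other,
or both, so each threshold is exercised separately; clade ancestors sampled
from GC-targeted codon weights and pinned to their GC target within 0.005
by directed codon resampling (the first two codon positions are largely
fixed by the code, so raw sampling alone cannot reach 0.40 or 0.58);
descendants mutated per branch with a GC-biased replacement kernel that
rejects stop codons — a deliberately simple process, since the pipeline and
not the simulator is the subject; per-OTU members at about 1% divergence
from their representative; bimeras with breakpoints uniform in the central
60% of columns and parent divergence in [0.05, 0.25] (PCR chimeras form
between co-amplified, related templates, and 0.25 keeps both parents of any
central-window bimera inside the scorer's 80% gate); corrupted raw records
(1-2 nt frameshifts away from the termini, premature stops at codons
4-194, truncations to 400-581 nt, random reverse complementing); and
per-clade habitat distributions with a configurable broader-only fraction.
One seed fixes every output bit-identically, and every sequence appears in
exactly one registry (clean, chimera, corrupted).

What the generator does *not* emulate: realistic PCR error spectra,
amplification bias, coalescent-accurate tree shapes, alignment uncertainty
(all sequences share one frame by construction), or rogue taxa. Passing
tests therefore demonstrate the correctness of the algorithms under
controlled conditions, not field performance on arbitrary GenBank input.

## Problem sizes and numerical choices

The shipped checks run at desk scale, chosen to exercise every rule while
keeping the default suite in minutes on one core: clustering oracles on 200
random instances of up to 12 sequences; exhaustive chimera-scorer searches
over up to 10 candidates; tree-certainty recomputation on 8-leaf tree
sets; taxonomy recovery on 50 seeded trees with 4 orders of 3-8 subclades;
chimera sensitivity/specificity on pools of roughly 100 OTU-structured
genes with 10% bimeras across three seeds; and an end-to-end run of about
500 raw sequences. Degenerate inputs are contracts, not accidents: empty
references error, a sub-2-sequence distance matrix warns, a zero
denominator in habitat fractions is flagged undefined rather than zeroed,
and zero-variance regressors error.

## Limitations

Tree inference, likelihood-based placement, branch-length re-estimation
after collapsing, topology tests and external aligners are out of scope by
design; the package consumes their outputs. The chimera scorer is a fully
specified re-interpretation of a tool whose internals the original
workflow tuned but did not restate; its thresholds transfer, but absolute
scores are not comparable across implementations. The compatibility call
in congruence reports is a formal proxy. Habitat categories ship as a
small default forest and are user-extensible.
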