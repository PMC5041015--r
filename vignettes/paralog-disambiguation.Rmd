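---
title: "Methods: context-based paralog disambiguation and signature motifs"
author: "paraSign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-based paralog disambiguation and signature motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraSign)
```

## The annotation problem this package addresses

Similarity-based annotation transfer fails predictably on multigene
families. Whenever one genome encodes two or more members of a family,
those members are paralogs, and paralogs often diverge in function while
remaining highly similar in sequence — sometimes a single active-site
substitution apart. The PTPS fold family is the motivating example: its
subfamilies carry the signature motifs `CxxxHGH`, `CxxxxxHGH` and
`ExxHGH`, act in three different cofactor pathways, and are distinguished
in practice not by overall similarity but by the gene families that
flank them on the chromosome. paraSign automates that curation logic:
flag paralogs, group family members whose gene neighborhoods are
conserved across genomes, derive per-subgroup signature motifs, and
propagate annotations by motif matching.

## The model, stage by stage

### Paralog flagging

A `ParalogFlag` is any (family, genome) pair with two or more members;
plasmids and extra contigs count within their genome. Downgrade reasons
distinguish members whose *own* genome holds paralogs
(`paralog_in_same_genome`) from members of families paralogous only
*elsewhere* (`family_has_paralogs_elsewhere`); same-genome evidence takes
precedence, and every member of a flagged family receives exactly one
reason. The copy-number census over a membership matrix excludes
families with zero members everywhere from the denominator, and reports
the complementary fractions of families that are single-copy in every
genome versus families with at least one paralogous genome.

### Neighborhood grouping

The neighborhood profile of a member is the *set* of neighbor family
labels within `window_k` genes per side on the same contig, truncated at
contig ends. Order, strand and distance are deliberately ignored: the
conserved signal curators use is "the same recognizable families keep
appearing next to these genes in distant genomes", which a label set
captures with the fewest assumptions. Unannotated neighbors are excluded
by default (they carry no cross-genome signal); `includeUnassigned`
admits them under reserved `singleton:` labels for diagnostic use. The
focal family itself never counts as its own context.

Similarity between members is the Jaccard index of their profiles
(0 when both are empty), and subgroups are single-linkage connected
components of the graph with edges at `tau` or above, subject to a
support rule: a subgroup needs at least two members spanning at least
two genomes, otherwise its members are `unplaced`. Single-linkage was
chosen over community detection because it is deterministic, exactly
checkable against a brute-force component oracle, and monotone: raising
`tau` can only refine the partition, never merge subgroups (the built-in
`tauSweep` reports this sensitivity). Subgroup labels `SG1, SG2, ...`
follow the lexicographically smallest member id, so the partition is
invariant under input order. The supporting family set is the
intersection of members' profiles, falling back to labels shared by at
least half the members when losses empty the intersection.

Defaults: `window_k = 5` genes per side (a typical conserved-cassette
span in prokaryotes; there is no canonical value, which is why it is a
flag) and `tau = 0.3` (permissive, because single-linkage only needs one
adequate partner per member, and the sweep exposes the dependence).

### Sequence similarity networks (the negative control)

`pairwiseScores` computes all-vs-all optimal local alignment scores
(BLOSUM62, affine gaps: a gap of length *L* costs 11 + *L*), converted
to bit scores `(λS − ln K)/ln 2` with the standard gapped BLOSUM62-11/1
constants λ = 0.267, K = 0.041, clamped at zero. Bit scores were chosen
over E-value-based scores because they need no database-size convention;
the commonly used alignment-score thresholds 15/25/30 are retained as
named presets, with the caveat that they are approximately — not
exactly — equivalent to scores in E-value units. `thresholdSweep`
evaluates *every* distinct observed score (exact at desk scale) and
reports cluster purity, the number of subgroups split over multiple
clusters, and whether any threshold is simultaneously pure and
split-free. On families whose between-subgroup scores overlap the
within-subgroup range, no such threshold exists — the failure mode that
motivates context-based grouping, reproduced in the test suite on a
constructed score geometry.

### Signature motifs

Subgroup proteins are stacked positionally (`alignSubgroup`): row *i*,
column *j* holds residue *j* of sequence *i*, short rows padded with
gaps. This is the exact alignment for the regime the machinery targets —
subfamily members whose motif occupies homologous positions and whose
length variation is terminal. Internal indels are *not* modelled; for
real families with indels, run any MSA tool and supply its rows as an
`AlignedBlock` directly. (An earlier center-star anchoring scheme based
on pairwise local alignments was evaluated and rejected: when members
share only a short motif, chance off-diagonal local optima reach the
same score range as the true anchor, and a noisy center corrupts the
whole stack.)

`buildPFM` counts residues (plus `X` and gap) per column; relative
frequencies are over all rows, so a gap-heavy column cannot masquerade
as conserved. Information content is `log2 20 − H` over the non-gap
residue distribution, without small-sample correction; an all-gap column
has IC 0 and zero occupancy. `selectMotifWindow` maximizes the summed
*occupancy-weighted* IC over contiguous windows (ties broken leftmost):
weighting by the non-gap fraction is necessary because a column carried
by one row has maximal IC by the unweighted formula, which would pull
windows to ragged block edges. The default width of 16 columns matches
the span of a typical curated signature region.

`deriveConsensusMotif` calls a literal wherever one residue reaches the
conservation threshold (default 0.9, tolerating rare aberrant members),
else the wildcard `x`, then trims terminal wildcards; an all-wildcard
window is a "no signature" error. `buildSignature` adds one refinement
pass: a provisional consensus at 0.6 identifies the motif columns, rows
that disagree at any literal column (mutated motifs, sequences violating
the coordinate frame, wrong start calls) are dropped, and the final
consensus is called on the conforming rows at the user threshold. This
mirrors how curators exclude unclassifiable or truncated sequences
before building logos, and it is what makes exact pattern recovery
robust when a handful of members carry mutated motifs.

`twoSampleLogo` contrasts two equal-width blocks per column and residue
with a Welch *t*-test on per-sequence 0/1 presence indicators. Perfectly
conserved columns have zero variance, so ε = 1e−9 is added inside the
square root; the degrees of freedom fall back to nA + nB − 2 when the
Welch–Satterthwaite expression is undefined. No multiple-testing
correction is applied by default (matching the referenced two-sample
logo convention); Bonferroni over all residue-column tests is available.

### Annotation propagation

`classifyGene` applies a strict precedence: context placement always
wins (evidence `context`, upgraded to `context+motif` with high
confidence when the member also matches its own signature); otherwise a
unique signature match gives a `motif` call (medium confidence); two or
more matches give a `hybrid` call listing all patterns — bifunctional
hybrids such as `CExxHGH` are genuine biology, not errors; no match is
`unresolved` (low confidence), and sequences too short to contain any
signature window carry the note "short, possible wrong start call".
Pattern matching is regex-style with `x` as any-residue wildcard,
reporting all overlapping offsets. A PSSM log-odds score
(`scorePssm`, pseudocount 0.5/20, uniform background) is available as
quantitative supplementary evidence but deliberately does not enter the
decision rule: the field's signatures are literal/wildcard patterns, and
keeping the rule symbolic keeps every call auditable.

The three-level confidence scheme (high / medium / low) is a package
convention; context-only calls sit at medium because the high tier is
reserved for members where two independent evidence types agree.

## What the synthetic generator emulates — and what it does not

`generatePanGenome` plants, per genome, one cassette contig per focal
member: the member flanked by its subgroup's conserved neighbor
families (each lost with probability `gene_loss`, order shuffled with
probability `rearrangement`), with up to one unannotated filler gene per
side; labelled decoy families occupy separate contigs. Proteins are
background-sampled residues with the subgroup motif planted at a
subgroup-specific offset (motifs occupy homologous positions within a
subfamily; indels are out of scope by design), literals mutated
per-position with probability `motif_mutation`. A rejection step
re-samples any protein that accidentally contains *another* subgroup's
pattern, so planted members conform to exactly one signature and hybrids
exist only when constructed deliberately. Half of the genomes (the
`paralog_fraction`) carry members of two or more subgroups — the
workflow's entry point — with a 0.2 chance of a second same-subgroup
copy; the remaining genomes carry a single member.

Default scenario (also the validation scenario): 20 genomes, 3 subgroups
with patterns `CxxxHGH` / `CxxxxxHGH` / `ExxHGH`, 3 context families per
subgroup, `window_k = 5`, 120-residue proteins, mutation 0.02, loss 0.1.
At these sizes the full pipeline runs in seconds on one CPU, which is
the scale all tests and the acceptance script use.

Passing on this generator demonstrates that the machinery is correct,
not that real pan-genomes are this clean. Deliberate simplifications:

* backgrounds are i.i.d. uniform residues (a `background` option takes a
  composition vector), with no phylogenetic correlation between members;
* cassettes sit on their own draft-assembly-style contigs, and
  non-context neighbors are unannotated, so profiles contain essentially
  pure context signal — real chromosomal neighborhoods interleave
  annotated but irrelevant families, which lowers Jaccard similarities
  and makes `tau` a real tuning decision (use `tauSweep`);
* no indels, fusions, or operon rearrangements beyond order shuffling;
* members that lose *all* context genes (probability
  `gene_loss^context_size` each) are honestly unplaced — they enter the
  partition-recovery ARI as singletons and are recovered, if at all, by
  their motif.

## Evaluation conventions

`evaluateRecovery` strips a held-out fraction (default 0.2) of members
of their context, partitions the rest, builds signatures, and annotates
the held-out members by motif alone. Recovered subgroups map onto
planted ones by majority membership. Held-out accuracy is computed over
members that receive a specific subgroup call; `unresolved` (family-
level) calls are abstentions, reported separately as coverage. This
mirrors curation practice, where sequences without a recognizable motif
are re-annotated at family level rather than guessed: with per-literal
mutation 0.02 and four literal positions, about 8% of members carry a
broken motif by construction, and declining to call them is the correct
behavior, not an error. Hybrid calls on held-out members count against
accuracy (planted members are single-subgroup by construction).

## Numerical and degenerate-input conventions

* Jaccard of two empty profiles is 0; `tau` above 1 yields an edgeless
  graph.
* Bit scores are clamped at 0; the score matrix diagonal holds positive
  self-scores.
* ARI of two degenerate partitions (vanishing pair-counting denominator,
  e.g. both all-singletons) is 1 when the partitions are identical, else 0.
* `which.max` tie-breaking makes window selection leftmost and majority
  labels alphabetical-first, everywhere deterministic.
* All generator randomness flows from the mandatory seed; identical
  configurations produce byte-identical files.
* Duplicate gene ids and multi-family gene rows are hard errors (fusion
  genes are out of scope); family rows referencing unknown genes are
  skipped with a counted warning.

## Known limitations

Positional stacking limits signature building to families without
internal indels in the motif region (terminal truncations are tolerated
via the refinement pass); real-data use should feed an external MSA into
`AlignedBlock`. Neighborhood similarity ignores gene order and strand,
discarding signal that operon structure could provide. The SSN bit-score
thresholds are unit-approximate to the commonly quoted E-value-derived
scores. All-vs-all scoring is quadratic and intended for families of at
most a few thousand members. Phylogenetic reconstruction,
gene-tree/species-tree reconciliation and fusion handling are outside
the package's scope.
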