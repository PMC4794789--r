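---
title: "Detecting group-specific conservation in protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting group-specific conservation in protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gentscan)
```

## The problem

An enzyme family such as the nucleotide diphosphate sugar dehydrogenases
(NDP-SDHs) splits into functional groups — UDP-glucose dehydrogenases
(prokaryotic and eukaryotic), GDP-mannose dehydrogenases and
UDP-N-acetyl-mannosamine dehydrogenases — that share a catalytic
mechanism and fold but act on different nucleotide-sugar substrates.
Positions conserved across the whole family mark the shared machinery
(catalytic residues, the Rossmann-fold glycines). Positions conserved
*within one group but not across the family* are candidate
specificity-determining positions: they often sit in the substrate
pocket or at group-specific subunit interfaces. `gentscan` takes a
labeled multiple sequence alignment and finds both kinds of position,
plus conserved motifs and a bootstrapped phylogeny that checks whether
the labels form supported clades.

## Conservation bands

For each column the modal residue fraction is computed **with gaps in
the denominator**, so "invariant" means literally the same residue in
every sequence — the operative meaning when single residues are called
invariant across a family. The three reported bands are 100%
(invariant), 80–99% and 60–79%; both interior boundaries are inclusive
at the lower edge, and band assignment always uses the unrounded
fraction (displayed percentages are rounded half-up separately, so a
98.7% column is shown as 99% but banded by its true fraction).
An all-gap column is `below_60` by definition. Whether a published
count of conserved positions used gap-inclusive or gap-exclusive
denominators is usually unstated; the gap-inclusive convention is this
package's declared choice and is used consistently in reports.

Ambiguity letters (B/Z/X) are accepted on input because real MSF files
contain them; they are tallied as "other" in profiles and are never the
modal residue. Modal ties break alphabetically for determinism.

## The group-entropy score

For a column restricted to a scope (one group, or the whole family),
gaps are removed, the residue counts are smoothed with a pseudocount
$\alpha$ per residue, and the distribution $p$ is scored against a
background $q$:

* `kl` (default): $\mathrm{GE} = \sum_i p_i \log_2 (p_i / q_i)$, the
  Kullback–Leibler divergence from the background; zero exactly when the
  column matches the background.
* `negentropy`: $\log_2 20 - H(p)$; zero exactly when the column is
  uniform.

Both are in bits, non-negative, and reach $\log_2 20 \approx 4.32$ for
an invariant column under a uniform background with $\alpha = 0$. The
score is finally multiplied by $(1 - \text{gap fraction in scope})$, so
indel-dominated columns rank low instead of spuriously high (a column
that is gapped in most of a group tells you about the indel, not about
residue conservation).

The same score function applied to the group-restricted column is the
group entropy GE, applied to the full column the family entropy FE.
Group-specific positions have high GE and low FE — the upper-left
quadrant of a GE-vs-FE scatter (`plot()` on a `gent_scan` draws it).

**Scale caveat.** The historical group-entropy program that inspired
this contrast reports values on an unpublished scale (published tables
reach 12.8, above $\log_2 20$, and assign different scores to columns
with identical group distributions), so absolute published values are
deliberately not reproduced. Rankings and quadrant membership are the
contract; both implemented score functions are exposed behind one
interface so the contrast itself, not a specific formula, carries the
analysis.

### Default cutoffs

`rank_group_specific()` filters columns with FE at or below a cutoff
and sorts by GE; `quadrant_classify()` uses a GE cutoff and an FE
cutoff. The defaults are the **midpoint of each score's observed
range** — the literal quadrant boundaries of the scatter plot. A
percentile default (e.g. the FE median) was considered and rejected: a
column perfectly conserved in a group holding a share $s$ of the family
carries an irreducible family-entropy floor of roughly
$s \log_2(20 s)$ bits (about 1.4 bits when the group is 40% of the
family), which sits *above* the FE median of any alignment dominated by
weakly conserved columns, so a median filter would reject exactly the
positions the scan exists to find. The midrange adapts to alignment
size the same way a percentile would, without that failure mode. Both
cutoffs accept absolute values when the user prefers.

The "common residue" listing for the other groups uses a within-group
frequency threshold of 0.25 (gap-inclusive), which yields the one- or
two-residue entries typical of published group-entropy tables.
$\alpha$ defaults to 0.05 with a uniform background.

## Reference-residue mapping

Published residue identities are quoted on ungapped reference sequences
(e.g. a catalytic Cys260 of a particular structure), while every
internal computation is addressed by 1-based alignment column including
gap columns. `build_reference_map()` holds the bijection between the
two over the non-gap positions of one reference row; reports annotate
each column with the residue numbers of every configured reference.
The round trip is identity on every non-gap reference position and is
property-tested on random gapped alignments.

## Conserved motifs

Motif discovery here is a deterministic conservation-window scan, not
an EM mixture model: windows of configurable widths are scored by the
mean per-column family score (with the same gap down-weighting), and
the highest-scoring non-overlapping windows are selected greedily, ties
to the leftmost start. Window means are computed directly per start
rather than by a cumulative-sum sweep so that windows over identical
columns score exactly equal and tie-breaking stays deterministic.
The consensus pattern writes one token per column: residues at family
frequency ≥ 0.10 in descending frequency, a bare letter for one
residue, a bracketed list for up to 4, and `x` otherwise — the bracket
arity and wildcard usage of published motif tables. The token count
always equals the window length, which is the tested invariant. This
scanner recovers conserved *regions*; it makes no claim to reproduce
any specific motif-discovery program's strings or E-values.

## Phylogeny stage

The tree stage replaces an external pipeline with declared, closed-form
steps:

* **Trimming**: drop columns with family gap fraction above 0.5 (an
  automated-heuristic trimmer is not reproduced; the rule is declared
  and tested instead).
* **Distances**: p-distance over pairwise-ungapped columns, optionally
  with Kimura's correction $-\ln(1 - p - 0.2 p^2)$; arguments where the
  correction is undefined ($p \gtrsim 0.854$) map to a declared ceiling
  of 10.0. Maximum-likelihood protein distances are deliberately not
  re-implemented, which will shift bootstrap values relative to
  analyses that used them.
* **Neighbor joining** via `ape::nj()`, with negative branch-length
  estimates clamped to zero (and messaged). NJ is exact on additive
  matrices; the tests verify recovery of simulated trees up to 12 taxa
  against the path-metric oracle and a least-squares brute force over
  all three topologies at $n = 4$.
* **Bootstrap**: column resampling with replacement, a rebuilt tree per
  replicate, bipartition tallies keyed canonically; a replicate whose
  resample leaves some pair with no comparable columns is skipped and
  the denominator adjusted. Fixed seeds give bit-identical tallies.
* **Consensus**: strict majority rule (count $> R/2$; a split in
  exactly half the replicates is excluded). Majority splits are always
  pairwise compatible, which the tests check exhaustively; supports are
  attached as internal node labels in the newick output.

`group_clade_support()` reports, per group, whether its leaf set is a
bipartition of the consensus, the bootstrap tally of that bipartition,
and the largest fraction of the group inside a pure consensus clade. A
single-sequence group is trivially monophyletic and its support is
reported as not applicable.

## The synthetic generator

`synthetic_spec()` / `generate_alignment()` plant *marginal column
structure* with a per-column truth label, so every stage has a recovery
oracle without any external data. The defaults are the study
conditions of the motivating family: groups of 92/55/38/44 sequences,
600 columns, 18 invariant columns, 20 in the 80–99% band, 52 in the
60–79% band, a handful of group-specific columns per group, and one
gap block per group at the reported loop positions.

Design choices worth knowing:

* Band and background columns plant an **exact modal count** drawn
  uniformly inside their band (background in $[0.30, 0.60)$), so the
  realized band of every column equals its truth label
  deterministically and background columns never leak into the 60%
  band.
* Group-specific columns fix residue $a$ in the target group (then
  corrupt it at the `within_group_noise` rate) and make a different
  residue $b$ *dominant* (default rate 0.40) — not fixed — outside the
  group, with the remainder drawn from the background excluding $b$.
  Residue pairs are biased toward readable exemplars (H/L, R/F, P/E,
  A/G). Dominance rather than fixation mirrors the multi-residue
  "common residue" entries of real group-entropy tables and keeps the
  planted column's family entropy below the quadrant boundary.
* One pseudorandom stream per run: equal seeds give byte-identical
  alignments.
* With `shuffle = FALSE` the planted archetypes are laid out
  contiguously (invariant first), which provides known conserved blocks
  for motif recovery tests.

What the generator does **not** emulate: evolution along a tree (no
substitution model, no rate variation, no correlated columns), realistic
indel processes, or between-group divergence at unplanted columns —
background columns are i.i.d. across the whole family. Consequently,
under the sparse default conditions the pairwise distances carry almost
no group signal and bootstrap clade supports are near zero *by
construction*; passing conservation and GEnt tests on this generator
says nothing about tree recovery. For the phylogeny stage the
reproduction script therefore uses a dense-divergence condition (60
group-specific columns per group), reflecting that the real groups
share only ~20% identity so most real columns are between-group
divergent; under that condition each group is recovered as a
fully supported clade. Equally, perfect recovery on planted columns
shows the scan's machinery is correct, not that real
specificity-determining positions are as cleanly separable as planted
ones.

## Problem sizes and determinism

The test suite runs the noise-sweep recovery experiment at the full
study conditions (229 × 600, noise 0 to 0.5 in steps of 0.1, 10 seeds
per level) and keeps tree oracles at ≤ 12 taxa and bootstrap checks at
R ≤ 100, which keeps the whole suite under a minute on one core. The
reproduction script subsamples 12 sequences per group (48 taxa) for its
R = 200 bootstrap. All randomness flows through explicit seeds; the
pipeline's non-plot artifacts are byte-identical across runs with the
same configuration and seed, verified by checksum in the tests.

## Known limitations

* Identity-based banding only: conservation of physicochemical classes
  (e.g. hydrophobic positions) is not scored.
* The group-entropy scale is this package's own (bits); published
  absolute values from the historical program are not comparable.
* The motif scanner finds contiguous conserved windows; gapped or
  dispersed motifs are out of scope.
* Distance-based trees only (no ML or parsimony); supports depend on
  the declared trimming rule and distance model.
* Group labels are taken as given; the package checks whether they form
  clades but does not relabel outliers.
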