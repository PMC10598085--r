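---
title: "Methods: classifying Clp1-family polynucleotide kinases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying Clp1-family polynucleotide kinases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clp1family)
```

## The problem

Eukaryotic Clp1-family proteins are polynucleotide kinases (PNKs) that
transfer ATP's γ-phosphate to RNA 5′ ends.  The family splits into two
paralogous groups with different biology: the Clp1 group (tRNA splicing,
mRNA 3′-end formation) and the Nol9/Grc3 group (pre-rRNA processing).
Within a genome the family may carry one to several members per group —
products of ancient and lineage-specific duplications — and individual
paralogs can lose PNK activity through degeneration of the kinase domain
while retaining other roles.

`clp1family` implements the comparative-genomics workflow that turns a
set of proteomes into a classified family table:

1. **Homolog search** — seeded local-alignment search with both
   full-length and kinase-domain (Clp1_P) queries, merged without
   duplication; per-species inventories with splicing isoforms collapsed
   to the longest representative.
2. **Representative clustering** — greedy length-sorted clustering at
   70% identity (identical residues over the shorter sequence), with
   required anchor sequences re-added.
3. **Alignment and trees** — progressive multiple alignment, 12-rank
   column conservation, gap trimming, Kimura-corrected distances,
   neighbor joining with nonparametric bootstrap, midpoint rooting.
4. **Domain architecture** — profile (PSSM) scans for known domains and
   de novo discovery of novel conserved domains in unannotated regions.
5. **Classification** — Clp1 vs Nol9/Grc3 split from the kinase-domain
   tree anchored by known members; cross-species "type" clades (t1, t2,
   …) versus per-species letter suffixes (-a, -b, -c); Walker A /
   Walker B / Clasp / Lid motif scanning; activity prediction.

Every stage is testable offline against a synthetic-proteome generator
with planted ground truth.

## Sequence statistics

**Local search.** Alignments are exact affine-gap Smith–Waterman under
BLOSUM62 with gap open 11 / extend 1 (a gap of length $k$ costs
$11 + k$).  We deliberately use exhaustive dynamic programming rather
than a word-seeded heuristic: at desk scale (sequences ≤ ~1,100 aa) the
exact optimum is cheap, and a heuristic could only miss it.  Raw scores
$S$ map to E-values by Karlin–Altschul statistics,
$E = K m n e^{-\lambda S}$, with the standard gapped-BLOSUM62 constants
$\lambda = 0.267$ nats, $K = 0.041$, no composition-based or
effective-length corrections.  Hits must reach $E \le 10^{-4}$ and cover
≥ 30% of the query (single best HSP per target; coverage is measured on
the query).  Identity and similarity percentages divide by the full
alignment length including gap columns; "chemically similar" is
operationalized as substitution score > 0.  Both choices are documented
fixed conventions, as is rounding (not truncating) to integers for
published-style tables.

**Masses.** Molecular weights are sums of standard average
(monomer-minus-water) residue masses plus one water, reported in kDa to
one decimal.  Sequences containing `X` are rejected rather than
approximated.

## Profiles and E-values for domain scans

Known domains are modelled as per-column log-odds profiles built from
seed alignments with background-proportional pseudocounts (total mass 1
per column, distributed as the background frequencies).  The
pseudocount choice matters: with flat add-one counts, an *unobserved*
rare residue such as tryptophan would outscore the residue actually
observed in the seed, because the log-odds denominator is its tiny
background frequency.

A profile's score distribution on unrelated sequences is calibrated
once, at build time: 100 background-random sequences of a reference
length (400 aa) are scored and a Gumbel is fitted by the method of
moments.  At scan time the per-scan tail probability is scaled linearly
to the scanned length and multiplied by the database size, so the
E-value is the expected number of false placements in the whole search
— the same semantics as the profile-search tools this stage mirrors.
With 6 profiles × ~32 proteins per dataset, a fixed per-scan threshold
of $10^{-3}$ would otherwise admit a false decoration every few
datasets by construction.  The scan threshold stays at the conventional
$E \le 10^{-3}$.

## Novel-domain discovery

Regions not covered by any profile hit (≥ 50 aa) are compared
all-versus-all by local alignment; pairs passing the family-search
thresholds ($E \le 10^{-4}$, coverage ≥ 30%) become edges, and
single-linkage components with ≥ 3 members from ≥ 3 species are
reported as novel domains.  Member boundaries are refined to the
*aligned core*: the median start and end of the member's pairwise
aligned spans.  We chose the median-span rule over an MSA-occupancy
rule (keep columns occupied by ≥ 50% of members) after observing that
occupancy cannot trim unrelated flanking residues at all — aligning two
random 12-aa flanks in-line costs ~12 mismatch points, far less than
two affine gap runs, so every flank column stays fully occupied.  The
median of the actual local-alignment spans is also closer to how hit
segments are delimited in practice: a hit starts where the conserved
block starts.  Reported per-domain statistics are mean ± SD of the
refined member lengths.

## Trees, rooting, supports

Distances come from trimmed alignments as Kimura-corrected fraction
differences, $d = -\ln(1 - p - 0.2p^2)$, capped at $p = 0.85$;
uncorrected distances are available by flag.  Trees are standard
neighbor joining; negative branch lengths are clamped to zero with the
deficit moved to the sibling edge.  Maximum-likelihood inference is
deliberately out of scope — externally inferred trees can be imported
as newick and drive all downstream classification.

Bootstrap support is the plain nonparametric column-resampling
bootstrap (support = percentage of replicate NJ trees containing each
bipartition), not an ultrafast approximation; it takes an explicit seed
and is exactly reproducible.

Midpoint rooting places the root halfway along the longest leaf-to-leaf
path; ties between equally long leaf pairs are broken by the
lexicographically smallest label pair, and a midpoint falling exactly
on an internal node attaches the root there through a zero-length edge.
The two deepest root-to-leaf distances agree to $10^{-9}$ by
construction, and the rooting never changes leaf-to-leaf path lengths.

## Conservation ranks

Column conservation uses a 12-rank (0–11) scale over ten
physicochemical property sets (hydrophobic, polar, small, proline,
tiny, aliphatic, aromatic, positive, negative, charged).  Rank 11
(symbol `*`) is a gap-free identical column; rank 10 (symbol `+`) is a
gap-free column whose residues all share an identical property profile;
otherwise the rank is the number of properties common to all residues
present, and any gap caps the rank at 9.

## Group split, types and letters

The kinase-domain (Clp1_P) tree separates the two groups: after
midpoint rooting, the two subtrees under the root are labelled by the
majority group of the anchor leaves they contain, and every leaf
inherits its subtree's label.  If both groups' anchors end up majority
in one subtree the tree does not bipartition the family and the stage
fails loudly rather than guessing.

Within a group, a *type* is a maximal clade that (i) spans at least two
species, (ii) holds at most one member per species — tolerating exactly
one duplicated species, which is flagged — and (iii) shares a domain
architecture signature not shared by another such clade.  Types are
numbered t1…tn by decreasing clade size (ties by alphabetically first
member id); the numbering is therefore stable but arbitrary, and
accuracy against planted truth is measured after optimal label
matching.  Leftover members that co-occur with another leftover member
of the same species get letter suffixes -a, -b, -c in input order;
singletons get no decoration.  A group whose members form one clean
cross-species clade (one member per species) is reported as a single
type covering the group.

## Motifs and activity

Four motifs are scanned in order along the kinase span: Walker A
(`[AG]x(4)GK[ST]`, the P-loop), Walker B (four hydrophobics then two
acidics), Clasp and Lid.  The Clasp and Lid defaults are synthetic
stand-in consensus patterns — the published consensus is in
supplementary material not bundled here — and are user-overridable via
`motif_models()`; the synthetic generator plants exactly these
instances, so a green motif test establishes the scanning machinery,
not the biological consensus.  A protein is predicted **active** only
if all four motifs match *and* the kinase span is ≥ 130 aa; kinase
domains much shorter than the family mean lack the Clasp/Lid region and
with it PNK activity.  The two lines of evidence are combined
conjunctively.  If the kinase domain was not located at all the call is
**unknown**.

## The synthetic world

`simulation_config()` defaults state the world every recovery test and
the acceptance loop run in:

* 8 species on a random coalescent tree scaled to height 1;
* three Clp1-group lineages, each with its own C-terminal replacement
  domain (planted lengths 145 / 150 / 140 aa): t1 is Clasp-ablated
  (inactive), t2 fully intact (active), t3 carries a 100-aa truncated
  kinase domain (inactive by the < 130 aa rule); plus one
  Nol9/Grc3-like lineage (intact, active);
* root-to-leaf expected divergence 0.125 per site, so within-lineage
  pairwise divergence stays around 25%, the regime the recovery
  criteria quote; lineage ancestors sit at 0.15 divergence from the
  shared templates, and the Nol9-branch kinase template at 30% from the
  Clp1 one;
* motif sites are substitution-protected unless ablated, so motif truth
  is exact at every divergence;
* inter-domain linkers and tails are resampled (content and Poisson
  length) on every branch with nonzero divergence: they model
  fast-evolving, unalignable spacer sequence.  This is the regime in
  which "novel conserved domain" is even well-defined — with conserved
  linkers the flanks genuinely belong to the conserved block and no
  boundary rule could recover the planted domain length;
* duplications and losses default to 0 (the emulated family shows a
  clean complement of one member per lineage per species, with rare
  exceptions exercised through explicit configs in tests); isoform
  records appear with probability 0.1 per gene as C-terminally
  truncated copies annotated "isoform"; five composition-shuffled
  decoys per species are the hardest realistic negatives.

What a green recovery test does **not** establish: performance on real
proteomes with compositional bias, repeats, domain shuffling, or
fragmented gene models; correctness of the stand-in Clasp/Lid
consensus; or equivalence with any specific external search tool's
scores.

## Numerical and degenerate-input choices

* All coordinates are 1-based inclusive.
* Deterministic tie-breaks throughout: lexicographic ids for equal
  E-values, clade sizes, and equal-score overlaps (with a warning for
  the latter).
* A group whose members are all identical yields an all-zero distance
  matrix; the pipeline then falls back to a star topology instead of
  failing in midpoint rooting.
* Trimming that would delete every column errors with advice rather
  than returning an empty alignment.
* Every stochastic step (simulation, bootstrap, null calibration) takes
  an explicit integer seed; the same config reproduces byte-identical
  outputs, which the test suite checks by hashing artifacts.

## Known limitations

* The aligner is exact but $O(mn)$; proteome-scale searches (millions
  of sequences) are out of scope by design.
* Profile E-values rest on a moment-fitted Gumbel from 100 null draws;
  the far tail is extrapolated.  The database-size scaling makes the
  operating threshold conservative, but E-values should not be read as
  precise beyond an order of magnitude.
* Progressive alignment has no iterative refinement; across-group
  full-length alignments are noisy, which is why group membership is
  decided on the kinase domain and types are found within groups.
* The type rule tolerates exactly one duplicated species per clade;
  worlds with pervasive recent duplication need the letter-suffix path
  or an explicit config.
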