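---
title: "Multilocus genealogical concordance, hybrid detection, and mating-type segregation with gcpsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus genealogical concordance, hybrid detection, and mating-type segregation with gcpsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcpsr)
```

## The scientific problem

Morphology is a poor guide to species limits in many fungal groups, so
mycologists recognize species where multiple independent gene genealogies
agree — genealogical concordance phylogenetic species recognition (GCPSR).
Once species limits are set by a multilocus species phylogeny, each
single-locus genealogy can be interrogated for *conflict*: a species whose
samples form a clade in the species phylogeny but fail to form a clade in a
given gene genealogy. Scored over all species and loci, conflicts quantify
how much recombination, incomplete lineage sorting, or interspecific
hybridization blurs the species boundaries, and individual samples that
nest with strong support inside another species' clade at one locus are
candidate hybrids.

`gcpsr` implements this analysis end to end for the typical design used in
surveys of closely related fungal species complexes (for example the
yellow morels, *Morchella*, Esculenta Clade): a few dozen species, one to
nine samples per species, and a handful of unlinked loci (mating-type
genes such as *MAT1-1-1*/*MAT1-2-1*, plus anonymous or ribosomal loci),
with per-locus amplification dropout. It also covers the companion
mating-system question: whether single-ascospore isolates carry one
mating-type idiomorph each, segregating 1:1 (heterothallism), or both
(secondary homothallism).

## Data model

* **Locus alignment** — a pre-aligned FASTA per locus over
  `{A, C, G, T, N, -}`; rows are sample ids. IUPAC ambiguity codes other
  than N are mapped to N with a warning, since none of the downstream
  statistics distinguish partial ambiguity.
* **Sample table** — TSV mapping each sample to exactly one species, with
  a 0/1 amplification flag per locus. Failed amplifications are retained
  as `FAILED` rather than dropped, so single-sample (`O`-style) and
  no-data (`N`-style) bookkeeping in the conflict matrix stays exact.
  Voucher/accession strings are free text and deliberately not assumed
  unique (published tables occasionally repeat accessions across rows).
* **Trees** — `ape::phylo` objects; bootstrap supports ride along as
  internal node labels in percent, the RAxML-style convention, both on
  import (`read_newick`) and export.

## Diversity statistics

`nucleotide_diversity` computes π as the mean over unordered sequence
pairs of the per-site difference proportion, comparing only columns where
both sequences carry an unambiguous base (pairwise deletion). No
multiple-hit correction is applied; at the divergences this package
targets (π ≈ 0.02) the correction would be smaller than the sampling
noise, and uncorrected values are what survey tables conventionally
print. `classify_sites` partitions columns into constant,
parsimony-informative (every observed state present at least twice),
singleton-variable (all non-majority states are singletons), and a
remainder category for columns mixing a second common state with
additional singletons. This partition is deliberately exhaustive and
disjoint so the category counts always sum to the column count; note that
the remainder category is populated by columns such as `A,A,T,T,C`, which
some other toolkits count as parsimony-informative.

### Display rounding

Percentages of variable sites are displayed to two decimals by rounding
half-up to three decimals and then half-to-even to two. This successive
display rounding reproduces the formatting conventions of the published
survey tables this package mirrors (for example 120/654 → 18.35% and
158/827 → 19.10%, the latter an exact 19.105 tie resolved to the even
digit); a single-stage rule cannot reproduce both. Conflict percentages
are rounded half-up to one decimal (13/16 → 81.3%), again matching table
conventions; note base R's `round()` would give 81.2.

## Tree building

The native tree builder is neighbor-joining on raw or Jukes–Cantor
distances with pairwise deletion, plus nonparametric bootstrap
(column resampling, seeded, default 1000 replicates) mapped onto the
full-data tree as bipartition percentages. Heavier ML/MP tree searches
are intentionally out of scope — the concordance layer is agnostic to the
tree source, and externally built trees with supports can be imported via
`read_newick`. Numerical conventions:

* taxa are sorted lexicographically before NJ, so tie-breaking is
  deterministic;
* negative NJ branch lengths are clamped to zero with the deficit moved
  to the sister edge;
* internal branches of (numerically) zero length are collapsed into
  polytomies. The collapse matters: sets of identical sequences give NJ
  zero-distance ties that it resolves arbitrarily but deterministically,
  and without the collapse the same arbitrary resolution would recur in
  every bootstrap replicate and earn spurious 100% support;
* bootstrap replicates whose distance matrix is degenerate (a saturated
  pair under JC69, or a pair with no comparable sites) are skipped and
  the support denominator adjusted.

`fitch_score` provides the parsimony criterion for any fixed tree, with
gaps as a genuine fifth state and N as missing data (the union state), so
imported MP trees can be scored on the same footing. Rooting is by
outgroup (keeping edge labels attached to the correct edges) or by
midpoint for loci without a usable outgroup; a non-monophyletic outgroup
roots the tree on the edge best separating outgroup from ingroup, with a
warning.

## Conflict scoring and hybrid flagging

`build_conflict_matrix` scores each (species, locus) cell as `NO_DATA`
(zero amplified samples), `SINGLE_SAMPLE` (one), or, with two or more,
`CONFLICT` exactly when the amplified samples fail to be monophyletic in
that locus' rooted gene tree. Two points follow the field's practice:
conflict is failure of monophyly only — an intact species clade placed
differently than in the species phylogeny is *not* a conflict — and the
topological test is applied to the tree as given, so weakly supported
breaks count, just as they do when conflicts are read off published
trees. Per-locus conflict percentages use only the
`CONFLICT`/`NO_CONFLICT` cells in the denominator.

`flag_hybrids` looks for two supported-discordance patterns at a
configurable support threshold (default 95%, the conventional bar for
claiming hybridization):

* **Foreign nesting** — sample *s* of species X sits in a clade with
  support ≥ 95 whose other members all belong to other species, each such
  host species present with *all* of its amplified samples, while X's
  remaining samples form a clade excluding *s*. The completeness
  requirement on hosts, and the intactness requirement on X's remainder,
  suppress the mirror-image false calls that otherwise arise on the
  donor species' own samples.
* **Species merger** — the amplified samples of two species jointly form
  a supported clade while neither species alone is even topologically
  monophyletic: the pattern left by two recently diverged species sharing
  (near-)identical sequences at a locus. Requiring *topological*
  non-monophyly (not merely support below threshold) keeps ordinary
  resolved sister species with middling supports from being merged.

A clade mixing three or more host species yields a single call listing
all hosts rather than one call per host pair.

`compare_genealogies` restricts two trees to their shared leaves and
reports supported bipartitions that are shared versus incompatible (all
four side-intersections non-empty), the standard split-compatibility
test, for locus-against-locus comparisons.

## Mating-type analysis

Idiomorphs are called from amplicon lengths: 708 bp (± 15 bp) is
*MAT1-1-1* evidence and 869–880 bp (± 15 bp) is *MAT1-2-1* evidence,
windows that a gel can resolve; a tolerance that would let the windows
overlap is rejected. Segregation among single-ascospore isolates is
tested against Binomial(n, ½) with an exact two-sided p-value defined by
tail distance, `P(|X − n/2| ≥ |n11 − n/2|)`, summed directly — exact
rather than chi-square because spore panels are small (n ≈ 20), and
stated explicitly because "two-sided exact" differs between ecosystems.
For the symmetric null this equals R's `binom.test`. Reproductive modes
follow the evidence hierarchy: any spore carrying both idiomorphs ⇒
putative secondary homothallism; single-typed spores of both types with
1:1 not rejected (α = 0.05) ⇒ heterothallism; no spores but parent tissue
carrying both idiomorphs ⇒ presumed heterothallism; anything else ⇒
indeterminate, with the reason recorded.

## The synthetic-data generator

Every stage is testable without external data through a simulator whose
defaults emulate the survey design above:

* **Species tree** — Yule topology; divergence times re-spaced to a
  basal-divergence-plus-radiation shape (root at the full height,
  remaining nodes evenly spaced up to 0.6 × height). Two consequences
  drove this choice over raw birth-process times: every species pair is
  separated by a guaranteed minimum divergence, so no pair is
  statistically invisible at realistic locus lengths; and pooled π over a
  dense sample of the clade realizes close to the nominal height — about
  0.02 at the defaults, the magnitude such surveys report. An optional
  `min_species_divergence` floor makes the closest pair's divergence
  explicit for high-signal designs.
* **Gene trees** — the species tree with each species tip replaced by a
  within-species coalescent subtree of depth `height ×
  within_species_scale` (default 0.02, i.e. intraspecific variation two
  orders below interspecific). Planted events act on gene-tree topology,
  giving exact ground truth: a *tip transfer* regrafts one sample inside
  the donor species' subtree at one locus; a *clade merge* replaces two
  species by a single zero-depth subtree, so their sequences come out
  identical at that locus. Dropout removes (sample, locus) leaves, is
  recorded in the truth ledger, and never hits samples named in events at
  the event locus.
* **Sequences** — HKY85 (transition/transversion ratio κ, default 2;
  arbitrary base frequencies), simulated site by site from an
  eigendecomposition of the normalized rate matrix; branch lengths are in
  expected substitutions/site. HKY was chosen as the minimal model with a
  transition bias knob; the analysis layer never assumes the generating
  model.
* **Truth** — the expected conflict matrix and expected hybrid calls are
  derived deterministically from the realized gene trees (all true clades
  treated as fully supported), so truth always describes what is
  topologically detectable, whatever the seed.

All randomness flows from one master seed through fixed per-stage
derivations; identical configurations give byte-identical outputs.

What the generator does **not** emulate: coalescent-with-migration
population processes (events are topological grafts), indels (alignments
are generated gap-free; gap handling is exercised by hand-built
fixtures), rate variation across sites or loci, and base-compositional
heterogeneity. Passing the end-to-end tests therefore shows that the
inference machinery recovers planted topological signal at realistic
divergences — not that it is robust to alignment error or model
misspecification in real data.

## Validation strategy and problem sizes

The test suite checks each scoring primitive against an independent
brute-force oracle: π against direct pairwise counting (up to 8
sequences), site classification against per-column enumeration, monophyly
against exhaustive clade scans (up to 12 leaves), Fitch length against
exhaustive internal-state minimization (5 taxa), NJ against random
additive matrices, and split incompatibility against the
four-intersection rule. The end-to-end study uses 8 species × 4 samples,
four 800-site loci, height 0.05 with a 0.05 divergence floor, 100
bootstrap replicates, and three planted events (two tip transfers and one
merge); hybrid flagging at the 95% threshold recovers exactly the planted
calls, and an event-free control yields zero conflicts. Segregation
testing is checked against closed forms, against `binom.test`, and for
type-I error over 10,000 simulated 1:1 panels. These sizes keep the whole
suite under a minute of compute while leaving the statistical checks
enough resolution (3·SE bands) to fail on real regressions.

## Known limitations

* Conflict scoring is topological; on poorly resolved gene trees it will
  count weakly supported breaks as conflicts, exactly as manual reading
  of such trees does. Use the bootstrap-aware hybrid flags, not raw
  conflict counts, for claims about gene flow.
* NJ is a distance method; for very short internal branches its
  gene-tree estimates are noisier than ML. Import externally built trees
  where that matters.
* The species-merger rule requires the merged pair to be jointly
  monophyletic with support; a merge additionally disturbed by other
  events at the same locus may fall back to foreign-nesting calls or
  plain conflicts.
* One published-style table quirk is intentional: strict tallies of a
  transcribed conflict-state matrix can disagree with a table's printed
  totals (the F1-style column); the package always reports the strict
  tally of the states it is given.
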