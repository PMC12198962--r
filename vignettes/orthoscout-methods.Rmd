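---
title: "Feature architecture-aware targeted ortholog search: models and methods"
author: "orthoscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature architecture-aware targeted ortholog search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design choices behind
`orthoscout`, in the spirit of a methods section: what is computed, under
which assumptions, and where the open design decisions were settled.

## 1. The search model

`orthoscout` performs a *targeted* ortholog search: one seed protein, one
taxon collection, no pre-computed orthology resource. The workflow has two
phases.

**Phase 1 — dynamic core-group compilation.** The aim is a small,
taxonomically diverse set of orthologs (the *core group* C, from *primer
taxa* P) that trains a profile HMM sensitive enough for the full search.
Diversity is enforced taxonomically: taxa are visited by increasing
taxonomic distance from the seed taxon, and after a taxon contributes a
member, it and all taxa within `min_dist` of it (or of the seed taxon) are
removed from the candidate pool. Candidates are ranked by

\[ \frac{AS(c_0, c_i)}{AS(c_0, c_0)} + \frac{1}{2}\left(FAS(c_0 \to c_i) +
FAS(c_i \to c_0)\right) \in [0, 2], \]

which balances sequence similarity (alignment-score ratio to the seed)
against feature-architecture conservation in both directions. Ties are
broken toward the taxonomically closer candidate, then lexicographically
by protein id for determinism.

**Phase 2 — full search.** The final profile HMM scores every protein of
every search taxon; hits above a bit threshold are validated by the
reciprocity criterion (section 4), the per-taxon representative minimizes
Kimura distance to the seed, and co-orthologs are kept while their
distance to the representative does not exceed the representative-to-seed
distance. Every retained ortholog is annotated with bidirectional FAS
scores.

## 2. Taxonomic distance and the rank ladder

The package works on a ranked taxonomy (NCBI-style node table). The
*taxonomic distance* between two leaves is the index, on the fixed ladder
species (0) < genus (1) < family (2) < order (3) < class (4) < phylum (5)
< kingdom (6) < superkingdom (7), of their lowest *ranked* common
ancestor; unranked intermediate nodes are skipped upward. Leaves whose
only common ancestor is an unranked root above the superkingdoms are at
distance 7, so the default upper pruning bound (`max_dist =
"superkingdom"`) excludes nothing. This rank-ladder definition was chosen
(over node or edge counts) because the user-facing bounds `min_dist` /
`max_dist` are expressed as ranks; it makes them exact statements about
where divergence may lie.

The lower bound deliberately excludes leaves whose lowest ranked common
ancestor with the reference *is* the `min_dist` rank: two species of the
same genus diverged *within* the genus, so at the default `min_dist =
"genus"` the seed's congeners (and the seed taxon itself) leave the primer
pool. This reading keeps the documented consequence — primer taxa are
pairwise at least `min_dist` apart — and matches the intended effect of
the bound (no two primer taxa from one genus). `min_dist = "species"`
excludes nothing.

Equidistant taxa are visited in a random order drawn from an explicit
integer seed (`rng_seed`, advanced by one per iteration), so every run is
reproducible; the global RNG state of the session is saved and restored
around each draw.

## 3. Sequence comparison

* **Alignment.** Global (Needleman–Wunsch) alignment under BLOSUM62 with
  affine gap penalties, opening 10 and extension 1 per gap position —
  conventional protein-search defaults. A gap of length L costs
  10 + L. Pairwise alignment is delegated to `Biostrings`; the test suite
  checks it against an independent dynamic-programming oracle.
* **AS ratio.** Alignment score of candidate vs. seed divided by the seed
  self score. Under matrices with a maximal diagonal the self alignment is
  gap-free, so the self score is the diagonal sum; the ratio is ≤ 1 for
  homologous pairs and equals 1 only for identical sequences.
* **Kimura distance.** The standard protein log-correction
  d = −ln(1 − p − 0.2p²) of the mismatch fraction p (gap columns
  excluded). Saturated pairs (argument ≤ 0, p ≳ 0.854) are flagged by
  returning `Inf`, which loses every minimum-distance comparison.
* **Core-group alignment.** An internal deterministic progressive aligner:
  UPGMA guide tree over pairwise 3-mer distances (the cheap guide-tree
  distance of progressive aligners), then profile–profile dynamic
  programming with average BLOSUM62 column scores and a linear gap penalty
  of 8. UPGMA (rather than neighbor joining) was chosen because `hclust`
  yields the merge order directly and the contract — deterministic,
  equal-length rows, gap removal recovers the inputs — does not depend on
  the guide-tree method. An `aligner` hook accepts any external function
  mapping named sequences to named gapped rows, for users who prefer a
  dedicated MSA tool; column-for-column reproduction of any particular
  external aligner is a non-goal.

## 4. Profile HMM

The profile HMM is a Plan-7-like model (match/insert/delete per column,
flanking inserts that emit from the background, so the model is global in
its match columns and local in the sequence). Design choices:

* **Match columns**: alignment columns with ≤ 50% gaps.
* **Emissions**: residue counts with a Laplace pseudocount (weight 1 by
  default) over the 20-letter alphabet; `X` residues are ignored in
  counting and score log-odds 0 when scored.
* **Transitions**: counts smoothed with a *sparse prior* scaled by the
  same pseudocount weight — match→match 0.9, match→insert/delete 0.05
  each, insert and delete splits 0.5/0.5. A flat Laplace count here would
  put probability 0.5 on match→match in a single-row model and cost ~1 bit
  per column, making a freshly initialized model unable to recover its own
  training sequence; the sparse prior is the standard remedy.
* **Scoring**: forward-algorithm log-odds in bits against a fixed
  background (Robinson–Robinson amino-acid frequencies); a Viterbi variant
  exists and is dominated by the forward score by construction. The DP
  kernel is compiled (Rcpp). Hits require ≥ 10 bits by default — the
  threshold is a significance proxy, configurable; E-value calibration
  against database size is out of scope.
* **Reciprocity.** The reference species defaults to the seed species.
  A candidate is accepted if its best global-alignment hit in the
  reference proteome is the core ortholog, or if the Kimura distance
  between the core ortholog and that best hit is smaller than between the
  candidate and the best hit ("evolutionary distance" is Kimura distance
  on global alignments — the only distance the workflow defines).

Trained models serialize to a versioned JSON layout
(`orthoscout-phmm-1`), so a model library can be re-used to extend
profiles with new taxa without re-training.

## 5. Feature-architecture similarity (FAS)

Architectures are ordered lists of typed, namespaced feature instances
(e.g. `PFAM:PF00759`, `TM:helix`) with 1-based residue coordinates,
consumed from JSON; running annotation tools is out of scope. The
similarity score implemented here is this package's own surrogate with the
contract of the published FAS measure: asymmetric, in [0, 1], 1 for
identical architectures, 0 exactly when no reference feature type occurs
in the query. For each type t of the *reference*:

\[ s(t) = \frac{\min(n_{ref}(t), n_{qry}(t))}{n_{ref}(t)} \cdot
   \frac{1 + \bar{o}(t)}{2}, \]

where \(\bar{o}(t)\) is the mean over reference instances of the best
Jaccard overlap with a query instance of the same type, computed on
length-normalized coordinates (orthologs differ in length). The overall
score is the weight-averaged \(s(t)\) over reference types (default
weight 1 per namespace). Averaging over *reference* types only is the
source of the asymmetry: a query carrying every reference feature scores
1 forward even when it carries extras, while the extras depress the
backward score. The positional term maps perfect overlap to 1 and is
bounded below by ½ so that sharing a type always contributes — otherwise
a shared type at disjoint positions would be indistinguishable from an
absent type. Coverage asymmetries dominate positional ones by design;
resolving overlapping same-namespace features by an optimal
non-overlapping path (as dedicated architecture scorers do) is not
attempted.

## 6. Profiles, filtering, embedding

* `filter_by_fas()` applies a threshold to FAS_F, FAS_B or their mean;
  filtering is idempotent and monotone in the threshold.
* `binarize()` drops records with FAS below 0.3 (mean mode by default —
  the direction is configurable because a single published direction is
  not canonical) and encodes presence as "at least one retained record".
  A record at exactly the threshold is kept ("below" excludes only <).
* `embed_profiles()` places taxa in 2-D by repertoire similarity:
  principal coordinates of Jaccard distances between binary rows, with an
  optional seeded non-metric MDS refinement (vegan). A pair of all-zero
  rows is at distance 0, zero vs. non-zero at 1. The contract asserted by
  tests is what downstream use relies on: determinism under a fixed seed,
  identical rows map together, disjoint repertoires separate, and
  permutation of rows only permutes coordinates. Non-linear
  neighbor-graph embeddings (e.g. UMAP) can be substituted on the same
  binary matrix; re-implementing one here is a non-goal.
* `select_paralog_representative()` approximates a duplication's origin
  as the closest relative of the seed species where one target protein is
  ortholog to ≥ 2 paralogous seeds, and keeps the seed with the most
  orthologs under a focal lineage (ties by id).

## 7. Contamination and HGT flags

Given a similarity hit table (qseqid, sseqid, staxid, bitscore) and a
contig map: the query's self-hit is excluded; hits within 10% of the best
remaining bit score (per-hit margin) vote by their lowest common ancestor;
an assignment off the species-to-root path is *foreign*. A foreign gene is
a *contamination* when its contig is shorter than the unweighted mean
contig length of the assembly **and** all existing direct neighbors
(ordinal predecessor/successor; single-gene contigs satisfy this
vacuously — short single-gene contigs are the canonical contamination
signature) are foreign too; other foreign genes are flagged *horizontally
acquired*. Queries are the longest isoform per gene (ties by id). Strand
is carried but unused. Classification is a pure function of the flags and
the contig map.

## 8. The synthetic scenario generator

`generate_scenario()` produces everything the pipeline consumes plus a
ground-truth table, from one integer seed. The default scenario — the one
the recovery tests run on — is 16 eukaryote species (2 classes × 1 order ×
2 families × 2 genera × 2 species) plus 2 bacterial outgroup species, 20
gene families, ~60-residue proteins. These sizes keep a whole-pipeline
replicate (20 core compilations + full search) around a minute on one
core while still exercising every distance class of the rank ladder.

Sequences evolve by i.i.d. residue substitution: each tree edge carries a
substitution probability of 0.05 per site and rank level crossed, so
identity decays monotonically with taxonomic distance (a tested property)
— roughly 90% identity between congeners, ~55% across superkingdoms. No
indels are generated by default, which keeps alignment-based oracles exact
while the pipeline logic (profiles, reciprocity, distances) is fully
exercised. Planted events per family: loss in a random 10% of non-seed
taxa; an extra post-speciation duplicate (in-paralog) with probability
0.1; one family pair duplicated on the eukaryote stem with the bacteria
retaining a single pre-duplication copy (the oracle for the
paralog-consistency property); one horizontal transfer of a bacterial copy
into a random eukaryote; three contaminant genes from bacterial donors on
short single-gene contigs of one focal taxon, with matching hit-table and
contig-map fixtures; architecture gain/loss events at rate 0.1. Five
decoy proteins per proteome keep hit discrimination honest.

What the generator does *not* emulate — indel-rich divergence, rate
heterogeneity, real domain databases, fragmented assemblies — bounds what
passing tests show: they validate the algorithmic contracts (selection,
pruning, stopping, reciprocity, filtering, flag rules) and end-to-end
recovery under a clean substitution process, not performance on real
proteomes.

## 9. Numerical and degeneracy conventions

* Score comparisons in the compilation use a 1e−9 tolerance; the hard
  stopping rule accepts |total − 2| ≤ 1e−9.
* All argmax/argmin operations break ties deterministically
  (distance, then lexicographic id), so outputs are invariant under taxon
  processing order and worker partitioning (tested with 1 vs. 4 workers).
* A single-sequence "alignment" is its own one-row MSA; a model trained on
  it has one match state per residue.
* Empty reference architectures score FAS 1 (nothing to recover); a
  missing annotation is treated as an empty architecture.
* Proteomes without hits, taxa without proteomes, and empty cells simply
  produce no records; per-taxon failures in the full search are logged
  and skipped without aborting the run.

## 10. Known limitations

* The FAS surrogate preserves the published contract, not the published
  algorithm; absolute FAS values are comparable within `orthoscout` runs
  only.
* The profile HMM has no Dirichlet mixture priors or E-value calibration;
  bit thresholds are heuristic.
* The internal progressive aligner is adequate for small core groups
  (≤ ~10 sequences); large or indel-rich groups should use the `aligner`
  hook.
* The reciprocity check aligns the candidate against the full reference
  proteome; for very large proteomes a pre-filter would be advisable.
* Contamination flags implement positional heuristics; phylogenetic
  confirmation of transfers (gene-tree tests) is out of scope.
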