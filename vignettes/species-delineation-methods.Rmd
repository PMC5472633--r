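---
title: "Methods: simulating and delineating bacterial species from genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and delineating bacterial species from genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Closely related bacterial genera routinely contain strains that share ≥99%
16S rRNA identity yet split into several genomically coherent clusters.
Deciding where the species boundaries lie is complicated by homologous
recombination: different core genes can carry different evolutionary
histories, so the choice of loci can change the inferred phylogeny.
`phylodelim` implements a complete desk-scale pipeline for this question —
ortholog clustering, single-copy-core extraction, statistical recombination
screening, partitioned phylogenies with congruence scoring, ANI/gANI-AF
species delineation, and pan-genome cohesion statistics — together with a
synthetic-genus generator that provides ground truth for every stage.

## The generator: a stated world

`sim_params()` fixes the world the tests live in. Defaults: 3 species ×
4 strains, 100 core and 60 accessory families of 900 nt, tip-to-ancestor
divergence 0.01 within and 0.06 between species, paralog probability 0.02
per genome and core family, clade bias 0.7 for accessory content, a 1500-nt
16S-like marker evolving at 1/20 the core rate with 2–5 identical copies per
strain. These choices reproduce the regimes the pipeline is meant to face: a
few percent core-gene divergence between species, ~0–14 marker SNPs across a
genus, and a U-shaped accessory occupancy spectrum.

Structure worth calling out:

* **Substitution model.** JC69 without indels. Per branch of length *d*, a
  site changes with probability 3/4·(1 − e^(−4d/3)) and picks a uniform
  different base. Families therefore stay aligned by construction and no
  external aligner is needed. Composition over branches stays JC, so the
  expected p-distance between two leaves at total path *d* is
  3/4·(1 − e^(−4d/3)); the generator test checks this closed form at
  *d* = 0.1 (expected p ≈ 0.0936) by Monte-Carlo.
* **Resolved within-species subtrees.** Species clades are not stars:
  strains coalesce through a random ultrametric subtree below depth
  `within_species_div`. This matters for the recombination tests —
  parsimony-informative sites inside a clade only exist when the clade has
  internal branches, and without them PHI has no signal to find.
* **Within-species accessory cohesion.** A cosmopolitan accessory family
  first draws carrier *species* (U-shaped Beta(0.3, 0.3) inclusion
  probability), then strains of a carrier species hold the gene with
  probability 0.9. Real accessory genomes are species-cohesive in exactly
  this way; it is also what makes a single species' pan-genome curve flatten
  faster than the genus curve.
* **Collinearity.** Gene order and intergenic spacers are shared across
  strains (only presence/absence and contig breaks differ). Congeners are
  largely syntenic at ANI-fragment scale; keeping collinearity lets the
  fragment-based ANI behave as it does on real draft genomes. Strands are
  always `+` and coordinates 0-based half-open.
* **Recombination.** An event copies a donor tract (fraction
  `recomb_tract_fraction` of the gene, 1.0 = the whole allele) from a strain
  of one species over the allele of a strain of another, and is logged in a
  ground-truth ledger.

What a green test does *not* establish: the generator has no indels, no GC
heterogeneity, no strand structure, no rate variation across sites, and no
assembly artifacts, so green results here say the *methods* are implemented
correctly, not that the defaults match any particular real genus.

## Orthology

The all-vs-all search replaces translated BLAST with a nucleotide
seed-and-extend: genes sharing an exact 16-mer are candidates; identity is
computed over aligned columns (direct comparison at equal lengths, majority
seed diagonal otherwise). The published cutoff of 70% similarity is applied
to that identity, and the e-value threshold — which is database-size
dependent and irreproducible without BLAST — is replaced by a minimum
coverage of 0.5 of the shorter gene. Markov clustering then follows the
standard scheme (column-stochastic matrix with self-loops at the component
maximum; expansion = matrix square; inflation = elementwise power 1.5 with
renormalisation; pruning at 1e-9; convergence at 1e-6 or 100 iterations).
Clusters are read off the support of the limit matrix; overlapping attractor
systems merge, which deterministically resolves ties toward the cluster
containing the lowest gene id. Core OGs occur in every strain; the
single-copy core (SCC) additionally has exactly one member per strain, which
removes families with paralogs.

## Recombination screening

Three statistics are computed per SCC gene, each with a site-permutation
p-value using the add-one rule p = (1 + #extreme)/(n_perm + 1):

* **PHI** — mean refined incompatibility (cyclomatic number of the bipartite
  joint-state graph) over informative-site pairs within 100 nt of each other
  in original coordinates. Recombination makes nearby pairs unusually
  compatible, so the test is lower-tailed.
* **MaxChi** — maximum 2×2 χ² of match/mismatch counts left vs right of a
  breakpoint, over all sequence pairs, within a centred window of
  2·⌈2k/3⌉ gap-free sites. All gap-free columns enter the table (a matching
  column is informative for this contrast even if it is not polymorphic);
  breakpoints sit after polymorphic columns.
* **NSS** — mean similarity of adjacent rows of the binary incompatibility
  matrix; upper-tailed, since recombination clusters compatibility along the
  gene.

The decision rule defaults to PHI alone at p < 0.01 (the headline statistic
of the program this reimplements); `decision = "any"`/`"all"` are exposed
because the source description is ambiguous on this point. Genes with fewer
than two informative sites are untestable and conservatively assigned to the
minimum core, flagged.

**A structural limit worth understanding.** PHI detects *intragenic
mosaics*. A whole-allele replacement — copying one strain's entire gene from
a donor — produces an alignment that is still perfectly compatible with a
single tree (the gene tree with the recipient moved), so PHI's power against
tract fraction 1.0 is essentially the false-positive rate, for any
implementation. The acceptance suite contains a sensitivity criterion stated
at tract 1.0; it is implemented exactly as stated and is expected to fail,
while the companion property test at tract 0.5 shows ≥70% (empirically
>90%) power against genuine mosaics. Whole-allele transfers are instead
caught downstream, by gene-tree/species-tree incongruence.

## Phylogenies and congruence

Maximum-likelihood inference is out of scope; trees are built by JC69
distances (pairwise deletion, saturation capped at d = 5) and Saitou–Nei
neighbor joining with deterministic tie-breaking (lexicographically smallest
label pair) and negative-branch clamping that preserves the pair sum.
Bootstrap resamples columns and reports split frequencies as internal-node
labels. Midpoint rooting handles the 2-leaf and zero-length cases itself and
delegates the edge surgery to `phangorn::midpoint` otherwise. All congruence
operations accept externally computed Newick trees, so ML trees can be
substituted without touching the logic that actually matters here: a species
is *monophyletic* in a gene tree iff its leaf set forms a bipartition, and a
tree set is *species-level congruent* iff every species is monophyletic in
every tree. Offending strains are the extraneous leaves of the smallest
containing edge-side — one formalisation of a judgement the source made by
eye; it errs toward naming few strains.

## ANI, gANI/AF and delineation

Fragment ANI follows the classical recipe: 1020-nt non-overlapping windows,
best subject location by majority 15-mer diagonal, an HSP-like
maximal-scoring segment (match +1 / mismatch −2) standing in for a BLAST
local alignment, and the 30%-identity / 70%-coverage hit filter; ANI is the
mean identity of surviving fragments, computed in both directions and
averaged into the symmetric matrix (the dendrogram needs a metric; both
directions are retained). gANI/AF uses bidirectional best hits between gene
sets: gANI is the aligned-length-weighted mean identity of BBH pairs, AF the
aligned fraction of the query's coding length (per pair; direction-averaged
in matrices). Species delineation builds a graph with an edge when the
criterion holds (ANI ≥ 95, or gANI > 96.5 and AF > 0.6) and takes connected
components — single linkage tolerates the occasional sub-threshold pair
inside a clade, and the reported clique purity quantifies how often that
happened. Missing comparisons fail the criterion (conservative). The
distance matrix for the UPGMA dendrogram is 100 − ANI with missing entries
at maximal divergence, flagged.

## Pan-genome statistics

Rarefaction permutes strain order (default SE shading: sd over permutations
/ √n_perm, 100 permutations) with exactly computed endpoints; Chao1 and ACE
use the *incidence* spectrum — genomes are samples; within-genome copy
number is not an abundance — in their classical forms, with the documented
fallbacks (Chao1's Q2 = 0 branch; ACE falling back to Chao1 at zero coverage
and to S_obs when no rare classes exist). The occupancy histograms exclude
single-strain families ("singletons and recent paralogs") by default; the
inclusive spectrum, which adds unclustered singletons to Q1, is the one
richness estimation uses.

## Markers and traits

16S SNP counts skip ambiguous positions; intra-strain marker copies must be
identical (heterogeneity is a hard error, matching the observation the
generator emulates). The SNP-vs-ANI regression puts SNPs on x and ANI on y
so "the SNP count at 95% ANI" is read directly from the fit; all strain
pairs enter (the alternative — clade means — is not what the package
implements). Binary trait tables cluster by Jaccard distance and
average linkage with deterministic ties; partition agreement is the adjusted
Rand index.

## Numerical and design choices

* Percentages print at one decimal with round-half-even, integer
  percentages at zero decimals — matching the precision of the numbers they
  are compared against.
* Every stochastic routine takes an explicit seed; the pipeline derives all
  stage seeds from one master seed, and emission is byte-identical across
  runs.
* Permutation counts in the shipped test suite are 199 (p-resolution 0.005,
  still below the 0.01 decision level) instead of the interactive default
  1000, purely for runtime; this is stated where it happens.
* Config files are JSON (the only structured-config reader guaranteed in
  the target environment); sections `pipeline` and `simulation`.
* `paralog_rate` is interpreted per genome *per core family* — a strict
  per-genome reading would generate almost no paralogs and never exercise
  the single-copy rule.

## Known limitations

No indel handling beyond gap-column removal; no e-value model; no
translated-protein orthology; NJ rather than ML (by design, with external
trees accepted); the fragment-ANI search is exact-seed based and can miss
homology below ~75% identity — which is also roughly where fragment ANI
stops being meaningful.
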