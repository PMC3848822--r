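---
title: "Comparative mining of biosynthetic gene cluster families with bgcfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mining of biosynthetic gene cluster families with bgcfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcfam)
library(dplyr)
```

## The problem

Actinomycetes and related bacteria encode most of their secondary
metabolites — antibiotics, siderophores, pigments, signalling molecules —
in contiguous biosynthetic gene clusters (BGCs). Genome mining finds
these clusters from signature enzymes (polyketide synthase ketosynthase
domains, NRPS condensation domains, lanthipeptide cyclases, and so on),
but comparing clusters *between* genomes is hard, particularly for PKS
and NRPS systems whose modular, repetitive domains defeat naive sequence
comparison. `bgcfam` implements a comparative workflow that works at the
level of genes and ortholog groups instead of raw sequence:

1. call clusters from significant signature-enzyme hits with a
   six-gene window rule;
2. tally cluster classes per genome, counting hybrid clusters once per
   class;
3. compute a whole-genome similarity matrix from ortholog groups with a
   min-copy counting rule;
4. group each genus's clusters into gene cluster families (GCFs) by
   homolog-content similarity;
5. summarise family conservation as histograms and delineate cluster
   boundaries from the drop in conserved gene content;
6. screen for phosphonate biosynthesis by the PepM motif and summarise
   candidate lanthipeptide precursors as a position-frequency matrix.

Every stage is a plain function over tibbles, so stages compose with the
pipe and intermediate results are ordinary data frames.

## Cluster calling: the six-gene window rule

The unit of distance is the **gene ordinal**, not the nucleotide
coordinate: genes on each replicon are sorted by start coordinate and
numbered `0..N-1` (`read_gene_table()`). A cluster is seeded at every
significant signature hit and extended six genes (`window = 6`) to
either side; a further hit within the window joins the same cluster and
re-initiates the count, and the final bounds are the outermost hits
plus the window, clipped at replicon ends. A six-gene extension is a
deliberate compromise: longer extensions pull in divergent flanking
neighbourhoods that add noise to cluster comparisons, while shorter ones
leave too few genes to compare.

Two readings of "a further hit within the window" are defensible, and
both are implemented (`join_rule`):

* `hit_in_window` (default): the next hit lies within `window` genes of
  the previous hit;
* `extensions_overlap`: the two hits' window extensions overlap (gap of
  at most `2 * window`).

Under the default reading, two separately chained hits can still end up
with overlapping extended ranges. Because a cluster is one genomic
locus, such chains are merged (`merge_overlapping_extensions = TRUE`),
which also makes cluster ranges on a replicon provably disjoint. With
merging on, the two readings coincide in the partition they induce;
they differ only when merging is disabled, which is supported for
inspection but leaves overlapping ranges. Replicons are treated as
linear even when biologically circular — no wrap-around rule is
defined, so windows clip at the ends; this is conservative and
reproducible. Ties between genes with identical start coordinates are
broken by end coordinate, then locus tag.

Plasmids are excluded by default (`include_plasmids = FALSE`), driven
by a `replicon_type` annotation: plasmid content turns over quickly and
skews long-term comparisons. Sequence-based plasmid detection is out of
scope.

Hybrid clusters (for example an NRPS/PKS hybrid) carry their full class
set and are never split; in the census (`class_census()`) each cluster
increments every class it contains by one, so an NRPS/PKS hybrid counts
once as NRPS and once as PKS, and class counts may exceed the cluster
count (reported separately). `nrps_pks_ratio()` pools the three PKS
types in its denominator.

Signature-hit significance is defined by a per-model cutoff table
supplied as configuration (`default_model_cutoffs()` is the bundled
table used by the simulator); hits below cutoff are retained but
flagged, and only significant hits may enter cluster calling. PKS
models also hit fatty-acid synthases; when a FAS-score table is
available, `resolve_fas_conflicts()` drops PKS hits on genes that score
higher against the FAS model than the PKS model. Whether to use
dedicated FAS models or a score comparison was an open choice; the
score-comparison rule is simple, symmetric and needs no extra model.

## Whole-genome similarity: the min-copy rule

From an OrthoMCL-style grouping of all proteins, the shared-gene count
between genomes $i$ and $j$ is

$$S_{ij} = \sum_{g \in \text{groups}} \min(c_{ig},\, c_{jg})$$

where $c_{ig}$ is the number of genes of genome $i$ in group $g$: when
one genome has two copies and the other four, the pair shares two. The
similarity fraction divides by one genome's gene count,
$F_{ij} = S_{ij} / G_j$ with $j$ the *column* genome, so every pair has
two similarity values. A reduced genome (hundreds of genes) therefore
shows a uniformly high column — nearly all its genes are found in other
genomes — while the largest genome's column is uniformly low. The
identity $F_{ij} G_j = F_{ji} G_i$ holds exactly and is asserted in the
tests at $10^{-12}$.

Two numerical choices: genes absent from every group (singletons) count
toward $G$ but never toward $S$, because OrthoMCL output omits
singletons; and the diagonal is *fixed* at 1 rather than computed, since
computing it from groups would make self-similarity artifactually below
1 for exactly that reason. Display order can be set from a phylogeny
(`set_genome_order()` reads newick leaf order) and the matrix is
written as TSV (`write_heatmap_table()`) or drawn with `autoplot()`.

## Gene cluster families

Published comparative studies have grouped similar clusters with a mix
of manual tools — phylogenetic inspection and whole-locus alignments.
`bgcfam` replaces that manual procedure with a single defined,
reproducible statistic, which is the central methodological decision of
the package. The content similarity of two clusters is

$$\mathrm{sim}(c_1, c_2) =
  \frac{|\text{shared homolog groups (min-copy)}|}
       {\min(n_{\text{genes}}(c_1),\, n_{\text{genes}}(c_2))}$$

The `min` denominator (containment, rather than Jaccard) is chosen so
that a small cluster wholly contained in a larger one scores 1: family
members that have undergone large-scale expansions or contractions
still group together. A `jaccard` option is provided. Families are the
connected components of the graph with an edge wherever similarity
reaches `threshold` (default 0.5) **and** the class sets intersect; the
class requirement stops unrelated clusters chaining through shared
transporter or regulatory genes. Singletons become size-1 families, and
a genome may contribute several members to one family (multi-copy
families occur in real genera, e.g. a lanthipeptide cluster present
twice or four times per genome).

No published numeric cutoff exists for calling two clusters "the same
family"; 0.5 is a proxy validated only on synthetic truth, where
within-family content similarity is near 1 and between-family
similarity near 0, and the planted partition is recovered with Rand
index 1.0. On real data the threshold matters and should be explored;
`group_families()` is deliberately cheap to rerun.

`conservation_histogram()` bins a class's families by size — the
histogram `{1: 3, 4: 1}` reads "three unique clusters and one family
found four times".

## Boundary delineation

Within a family, the biosynthetic core travels together across genomic
backgrounds while flanking genes differ. `delineate_boundaries()`
scores every gene of a member cluster by the fraction of *other*
members whose content contains its homolog group, then trims the
cluster to the maximal contiguous run of genes with conservation
`>= min_fraction` (default 0.8) containing the member's signature
hits. Three details are pinned down explicitly:

* signature-hit genes are always treated as conserved (they define the
  family);
* if a member's hits fall in different conserved runs, the trimmed
  range spans from the start of the first hit's run to the end of the
  last hit's run — hits of one cluster are never separated;
* `min_fraction = 0` returns the full called range.

Size-1 families are refused: with no second genomic context the
boundary is undefined (a cluster inside a large well-conserved region
has the same problem — its "conserved run" extends past any sensible
boundary, and such cases should be reported as undetermined rather than
trimmed). A flanking gene coincidentally shared by all members stays
inside the boundary; this is documented behaviour, not a defect — the
method measures conservation, not biosynthetic function.

## Phosphonates and lanthipeptide precursors

Phosphoenolpyruvate mutase (PepM), the entry enzyme of phosphonate
biosynthesis, carries an invariant EDK-X(5)-NS motif.
`scan_pepm_motif()` scans proteins position by position (the test suite
holds it against an independent regular-expression oracle) and emits
phosphonate-class hits that enter cluster calling exactly like pHMM
hits. Note that in large proteomes short motifs match by chance
(roughly $20^{-5}$ per position for the spacer-constrained part), so
the screen is off by default in `run_bgc_pipeline()` and should be
combined with homology evidence on real data.

Lanthipeptide precursors are short peptides whose Cys/Ser/Thr residues
form lanthionine rings. `extract_candidate_precursors()` uses an
intentionally simple heuristic — length at most 120 residues, at least
2 cysteines, at least one serine or threonine, signature (cyclase)
genes excluded — because no published, automatable definition exists;
all three parameters are exposed. On random short proteins the residue
filter passes often, so counts from this heuristic are indicative, not
definitive. `build_pfm()` tabulates per-position residue counts over
the (externally aligned, if necessary) precursor set; the consensus
breaks ties alphabetically with the gap symbol last, and `tidy()`
reports per-column information content in bits against a uniform
20-letter background.

## Ribosomal-protein supermatrix

For tree-based display ordering, `select_single_copy_groups()` picks
homolog groups that (a) contain a reference-genome gene annotated as
one of the 41 classical ribosomal proteins
(`ribosomal_protein_names()`; patterns are case-insensitive and
word-bounded so L1 does not match L11) and (b) are strictly single-copy
in every genome. `concatenate_alignments()` joins per-gene alignments
into one sequence per genome in sorted-group order, so shuffled input
yields identical output; alignment itself and tree inference are
external (any aligner/FastTree), and only a resulting newick is read
back for leaf order. Genes are aligned individually and then
concatenated, never the reverse.

## The synthetic genus

`simulate_genus()` generates the test bed: `n_genomes` genomes, each a
single chromosome of roughly `genes_per_genome` backbone genes of which
a fraction `core_fraction` belong to core homolog groups (single-copy
in every genome, shuffled order per genome) and the rest are private
accessory genes. Planted cluster families are inserted between evenly
sized backbone chunks with `window` private flanking genes on each
side, so that (by construction) hits of different clusters are farther
apart than twice the window and called clusters map one-to-one onto
planted ones. Family members share dedicated homolog groups; hybrid
families carry two signature genes of different classes within one
window; lanthipeptide families carry planted 40-residue precursors with
two invariant cysteines, an invariant threonine and an LD motif, and
their non-precursor neighbours are made long so the length filter has
an unambiguous truth. Scores in the emitted hit table always exceed the
bundled cutoffs. With `neighborhood_randomization = FALSE` the flanks
are instead shared within a family, producing conserved neighbourhoods
(useful for testing that boundary trimming then cannot shrink to the
core).

The default spec — 5 genomes of 1,900–2,100 backbone genes, 70% core,
12 planted clusters in 7 families including one 3-member and one
4-member family, two unique NRPS/PKS hybrids, and one
precursor-carrying lanthipeptide cluster — is sized like a small
bacterial genus and exercises every pipeline feature at once. The
simulation is a deterministic function of the spec including its seed;
equal seeds give byte-identical emitted files.

What the simulator does *not* emulate — and hence what green tests do
not show about real data: there is no sequence evolution (proteins are
random strings except planted features), no gradual family divergence
(within-family content is identical, between-family content disjoint,
so any threshold in (0, 1] separates them), no annotation error, no
assembly fragmentation, and no horizontally transferred partial
clusters. The simulator validates the machinery, not the biological
thresholds.

```{r demo}
sim <- simulate_genus(genus_spec(seed = 1))
hits <- annotate_hits(sim$hits, sim$genes)
clusters <- call_clusters(hits, sim$genes)
fam <- group_families(clusters, sim$genes, sim$groups)
family_summary(fam)
conservation_histogram(fam, "PKS1")
nrps_pks_ratio(class_census(clusters))
```

## Problem sizes, defaults and limitations

| parameter | default | meaning |
|---|---|---|
| `window` | 6 genes | extension to either side of a hit |
| `join_rule` | `hit_in_window` | closest literal reading of window joining |
| `merge_overlapping_extensions` | `TRUE` | clusters are single loci |
| `threshold` | 0.5 | family edge cutoff on content similarity |
| `similarity_method` | `containment` | nested clusters score 1 |
| `min_fraction` | 0.8 | conservation needed to stay inside a boundary |
| `include_plasmids` | `FALSE` | plasmids skew long-term comparisons |
| `max_len`, `min_cys`, `min_ser_thr` | 120, 2, 1 | precursor heuristic |

The test suite runs the window-rule oracle on 500 random hit
configurations (up to 200 genes, 20 hits), the similarity invariants on
100 random group sets of 3 genomes, the full default genus once, and
smaller 3–4 genome genera for family, boundary and precursor recovery;
these sizes make the properties sharp while keeping a full run of the
suite in the low minutes on one CPU.

Known limitations: cluster calling depends entirely on the supplied
hit table and cutoffs (no de-novo detection); families are not linked
across genera; boundary delineation needs at least two genomic
contexts and inherits any error in the family partition; the precursor
heuristic over-collects among genuinely short proteins; and none of
the default thresholds have been calibrated on curated real clusters —
they are the package's documented starting points.
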