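---
title: "Molecular discrimination of tall fescue morphotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular discrimination of tall fescue morphotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fescuephylo)
```

# The problem

Hexaploid tall fescue (*Festuca arundinacea*) comprises three morphotypes -
Continental, Mediterranean and Rhizomatous - that are nearly impossible to
tell apart phenotypically, yet differ in traits (summer dormancy, winter
hardiness) that matter for breeding. Chloroplast sequence variation offers a
clean maternal signal: this package implements the full analysis chain that
turns a multiple alignment of chloroplast amplicons from a panel of
accessions into (i) a classified variant table, (ii) a between-group
similarity index, (iii) diagnostic PCR markers that separate Continental from
Mediterranean material, (iv) UPGMA trees with bootstrap support and (v)
median-joining haplotype networks with rho-statistic clade ages.

The study system the defaults emulate is a panel of 12 varieties/accessions
in six groups: 2 Continental, 3 Mediterranean and 1 Rhizomatous tall fescue,
plus the relatives *F. pratensis* (2), *F. mairei* (2) and *F. glaucescens*
(2), compared over roughly 20 kb of concatenated chloroplast amplicons.

# Variant calling and the similarity index

`call_variants()` classifies every polymorphic column of a gapped alignment:

* **SNP** - a column with two or more distinct bases among non-gap, non-`N`
  taxa;
* **single-base deletion (`del1`)** - a column gapped in some but not all
  taxa;
* **multi-base indel** - a maximal run of adjacent columns sharing one
  identical gap presence/absence pattern, merged into *one* locus.

The merge rule is what makes the locus count additive: one SNP column is one
locus and one merged indel event is one locus, so SNP + del1 + indel counts
sum to the total. A column can legitimately host both a substitution among
the non-gap taxa and a gap pattern; both records are emitted and flagged
(`overlaps`) rather than silently resolving the ambiguity either way.

Between-group polymorphism uses the **disjoint-allele-set rule**: a locus
counts toward a pair of groups only when the two groups share no allele at
that locus (a fixed difference). `N` states are dropped from allele sets
first, so missing data can never manufacture a difference. The similarity
index is then

$$S(a,b) = 1 - \frac{n_{\text{between}}(a,b)}{n_{\text{total}}},$$

reported half-up-rounded to two decimals (the printed precision of such
tables), with full precision retained in `comparison_table()` output.

# The synthetic-data generator

All fixtures are generated in code; nothing is downloaded. A
`plant_profile()` names the taxa, their groups, and one row per planted
locus: a class, a *carrier split* (the subset of groups receiving the
derived state), and an indel length. `generate_alignment()` realises the
profile over an i.i.d. uniform A/C/G/T monomorphic background, with planted
spans separated by at least one monomorphic column so adjacent gap runs
never merge. Base composition is deliberately unmodelled - none of the
downstream statistics tested depend on it - and there is no rate
heterogeneity, recombination or sequencing error. Passing tests therefore
demonstrate algorithmic correctness on clean group-structured data, not
robustness to alignment error or intra-group polymorphism in real material.
Multi-base indels are planted as contiguous gap runs in the carrier taxa,
matching the alignment-gap view the caller consumes. Columns gapped in every
taxon cannot arise (the generator never emits them, and `aligned_set()`
rejects them on input).

## The packaged 12-taxon preset

`festuca_profile()` plants 167 loci - 129 SNPs, 25 single-base deletions and
13 multi-base indels of 3-47 bp - over a 20,056-column alignment. The
carrier splits were chosen by integer programming so that the planted
pairwise fixed-difference counts reproduce the published comparison table
wherever that is possible. It is *not* possible everywhere: the published
15-pair table is provably not decomposable into 167 group-level fixed
differences - the constraint system is infeasible for every bipartition
multiset and even for arbitrary multi-state group partitions. That
infeasibility is informative: the real data must have carried within-group
variation or shared alleles that group-monomorphic planting cannot express.
The preset therefore matches 11 of the 15 pairs exactly - including every
pair used in worked examples (117, 103, 42, 2, 5, 100, 45, 101, 102, 106) -
and deviates on four (pratensis/glaucescens 45 vs 44, mairei/Mediterranean
79 vs 57, mairei/glaucescens 101 vs 102, Rhizomatous/Mediterranean 102 vs
105).

Exactly four multi-base indels (32, 3, 47 and 8 bp - the four product-size
differences of the diagnostic chloroplast amplicons) separate the
Continental and Mediterranean groups; the remaining nine sit on splits that
keep the two morphotypes on the same side. A consequence of group-monomorphic
planting is that *any* indel carried jointly by the Mediterranean and
*F. mairei* groups would also separate Continental from Mediterranean, so
the reported "shared indels between Mediterranean and *F. mairei*" of the
original material are represented only by the four diagnostic ones; forcing
six such indels would contradict the four-marker diagnostic count, and the
marker count is the quantity under test.

# Diagnostic markers

`find_diagnostic_indels()` returns indel loci of at least `min_length` bp at
which the two groups carry fixed, different states, with an explicit
`tolerance` for group-inconsistent samples (default 0, the strict rule).
`in_silico_pcr()` performs exact matching of the forward primer on the given
strand and the reverse primer as reverse complement downstream; the product
spans the first base of the forward site through the last base of the
reverse site, the convention under which expected sizes of designed
amplicons are stated. Mismatch and degenerate-base models are deliberately
out of scope - the assay being emulated uses genome-derived primers - and a
primer matching twice raises an ambiguous-amplification error rather than
guessing. `genotype_by_size()` assigns templates to groups by size windows
(`rule` +/- `tolerance`), requiring windows separated by more than twice the
tolerance, and returns `"unknown"` rather than forcing a call.

SSR surveys are emulated as long presence/absence tables (primer x
accession x fragment). `score_ssr_discrimination()` counts fragments fixed
present in one morphotype and absent in the other, again with a sample
tolerance (SSR allele presence in real material is known to be less
consistent than chloroplast markers, so the tolerance is a parameter rather
than a hard-coded zero). The packaged `festuca_ssr_table()` plants 26
discriminating primers among 144 with 1-24 fragments each and exactly 1,212
fragments in total; non-planted primers are repaired after simulation so
that none carries two accidentally fixed fragments, keeping the strict
scorer's count exact by construction.

# Trees

`encode_binary()` supports two encodings, because the natural coding differs
by downstream use:

* `"reference"` - one column per non-reference allele. Row-wise Hamming
  distances equal per-locus difference counts regardless of the reference
  choice; this feeds the haplotype network.
* `"band"` - one presence/absence column per allele, the classic
  allele-as-electrophoretic-band coding for which the Nei-Li/Dice
  coefficient was designed. Under it, every taxon carries exactly one band
  per locus, and for group-monomorphic data the Dice similarity between two
  taxa equals the fraction of loci at which they agree - exactly the
  similarity-index scale. The reference encoding is *not* suitable for Dice:
  a taxon identical to the reference has an all-presence-free row and Dice
  similarity 0 to everything, which scrambles the topology. The Dice/UPGMA
  stage therefore uses `"band"`.

`dice_distance()` implements \(1 - 2a/(2a+b+c)\) with shared absences
excluded by definition; a pair with no presences at all is defined as
similarity 1. Dice is non-metric, so triangle violations are possible and
not asserted anywhere. `tamura_nei_distance()` implements TN93 with
**pairwise deletion** (only columns where both taxa carry unambiguous bases)
and base frequencies estimated per pair from the shared columns. Pairwise
rather than complete deletion is the default because an indel-rich alignment
would otherwise discard most of its columns; saturated pairs raise an error
naming the pair rather than returning `NaN`.

`upgma()` is written in full rather than delegated to `hclust`, for one
reason: deterministic tie-breaking. Ties on the minimum distance are broken
by the lexicographically smallest merged member-label set, so topologies are
reproducible across platforms; the implementation is cross-checked against
average-linkage `hclust`/`phangorn` on tie-free matrices. Node height is
half the merge distance and trees are ultrametric to floating-point
precision. `bootstrap_support()` resamples columns with replacement, rebuilds
the tree per replicate and maps support onto the *original* tree's tip-set
bipartitions (not a consensus tree), matching how per-node percentages are
conventionally displayed.

# Median-joining networks and rho dating

`median_joining()` iterates the epsilon-relaxed minimum spanning network,
quasi-median insertion, and obsolete-vector removal until stable. For binary
characters the quasi-median of a triplet is the per-character majority; DNA
input is binarised per segregating state first (with the caveat that a
truly triallelic character then contributes two binary characters, slightly
inflating distances between the two non-reference states - the packaged
SNP/indel matrices are biallelic, where the binarisation is exact).
Candidate triplets are the mutually connected ones plus pairs sharing an MSN
neighbour; a median is accepted when the star through it is strictly cheaper
than the triplet's own minimum spanning tree. Epsilon defaults to 0 and the
character weight to the conventional uniform 10; scaling all weights by a
constant provably changes nothing, and reported edge weights are unweighted
mutation counts.

One representational choice deserves a note. Inserted median vectors
subdivide the spanning-tree edges they lie on, so the displayed network need
not contain observed-to-observed MST edges *literally* - the three-haplotype
triplet resolves to a star through the median, not a triangle. The guarantee
maintained (and tested by exhaustive MST enumeration) is *display*: every
edge of every minimum spanning tree of the observed haplotypes is realised
as a network shortest path of exactly its Hamming length. A final repair
pass restores a direct link in the rare configurations where median
insertion would otherwise lengthen a displayed path.

`rho_age()` computes rho as the multiplicity-weighted mean shortest-path
mutation count from a designated ancestral node to the descendant
haplotypes, and its dispersion on the shortest-path tree as
\(\mathrm{sd}_\rho = \frac{1}{n}\sqrt{\sum_e l_e n_e^2}\) (edge length
\(l_e\), lineages through the edge \(n_e\)); for a star of \(n\) lineages at
depth \(d\) this reduces to \(\rho = d\), \(\mathrm{sd}_\rho = \sqrt{d/n}\).
Ties among equal-length shortest paths are broken toward smaller node
indices so the tree is deterministic, and reticulation on a used path is
reported as a warning - how the classical desktop implementation resolves
reticulate structures is undocumented, so the package makes its own rule
explicit instead of emulating an unknown. Ages scale linearly with the
mutation rate (years per mutation; the conventional chloroplast calibration
of 20,180 is the default but is an input, not a claim). Ages in My print at
two decimals; stored values are unrounded. The ancestor is always
user-supplied: which network node is ancestral is an interpretive decision
that the package does not automate.

# Pipeline, determinism and problem sizes

`run_pipeline()` executes the enabled stages in dependency order and writes
one artifact per stage (variant TSV, comparison CSV, marker reports, two
Newick trees, network GML and edge list, age TSV) plus a log capturing every
parameter. Identical configuration and seed give byte-identical artifacts;
the GML writer normalises the library banner line to keep that true. All
generator functions save and restore the caller's RNG state, so they are
pure functions of their seed arguments.

Test problem sizes were chosen to exercise every code path at desk scale:
oracle equivalence for the variant caller runs on fifty 10-taxon x
500-column random alignments against an independently written brute-force
scanner; MST display is checked by full Prufer enumeration on sets of up to
seven haplotypes; rho recovery uses two hundred 100-tip star genealogies at
a Poisson mean of 32.29; bootstrap replays use 200 replicates on the full
20,056-column preset. The 1,000-replicate default remains the pipeline's
production setting.

# Known limitations

* The generator plants group-monomorphic variants; within-group
  polymorphism, alignment error, and missing data patterns of real surveys
  are not emulated (single `N`s and per-taxon gaps are handled by the
  caller, but not simulated).
* The published pairwise comparison table cannot be reproduced exactly on
  all 15 pairs by any fixed-difference configuration (see above); the four
  deviating pairs are a property of the published table, not of the
  implementation.
* DNA-state median-joining binarises multiallelic characters, which is exact
  only for biallelic data.
* No maximum-likelihood or Bayesian tree inference, no thermodynamic primer
  checks, and no automated choice of ancestral network nodes.
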