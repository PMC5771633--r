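# fescuephylo

Molecular discrimination of tall fescue (*Festuca arundinacea*) morphotypes
from chloroplast sequence variation and SSR fragment data.

Hexaploid tall fescue comprises three morphotypes — Continental,
Mediterranean and Rhizomatous — that are phenotypically nearly
indistinguishable but differ in summer dormancy and winter hardiness, traits
central to forage breeding. This package implements the analysis chain that
separates them molecularly:

* **Variant calling** from a gapped multiple alignment of chloroplast
  amplicons: SNPs, single-base deletions, and multi-base indels (maximal
  runs of identical gap patterns merged into one locus each).
* **Similarity index** between groups:
  `S(a,b) = 1 − n_between(a,b) / n_total`, where `n_between` counts loci at
  which the two groups' allele sets are disjoint (fixed differences) and
  `n_total` is the total polymorphic locus count.
* **Diagnostic markers**: morphotype-diagnostic indels, in-silico PCR
  product-size prediction by exact primer matching, genotyping by band
  size, and SSR primer scoring for group-discriminating fragments.
* **Trees**: Nei–Li/Dice similarity (`2a/(2a+b+c)`) on binary marker
  matrices and Tamura–Nei (TN93) sequence distances with pairwise deletion,
  clustered by a deterministic UPGMA with column-resampling bootstrap
  support.
* **Networks and dating**: median-joining haplotype networks
  (epsilon-relaxed MSN + quasi-median vectors) and clade ages from the rho
  statistic — the mean mutation count from a designated ancestral node to
  its descendants — scaled by a mutation rate in years per mutation
  (`sd_rho = sqrt(Σ l_e n_e²) / n` on the shortest-path tree).
* **Synthetic data**: every fixture is generated in code with a truth
  table — group-structured alignments with planted variants, amplicon
  template pairs, SSR tables with planted discriminating primers, and star
  genealogies with Poisson mutation counts — so the whole pipeline is
  testable end to end without any external data.

## Worked example

The packaged preset emulates the study conditions: 12 varieties/accessions
in six groups, a 20,056-bp concatenated chloroplast alignment, and 167
planted polymorphic loci (129 SNPs, 25 single-base deletions, 13 multi-base
indels of 3–47 bp).

```r
library(fescuephylo)

prof <- festuca_profile()
sim  <- generate_alignment(prof)
loci <- call_variants(sim$alignment)
loci
#> # A tibble: 167 × 8
#>    locus_id start   end class       length alleles    states   overlaps
#>    <chr>    <int> <int> <chr>        <int> <list>     <list>   <lgl>
#>  1 L001       124   125 snp              1 <chr [12]> <list>   FALSE
#>  4 L004       466   481 indel_multi     15 <chr [12]> <list>   FALSE
#>  ...
```

The group-comparison table reproduces the similarity-index arithmetic; the
closest pairs are the Rhizomatous/Continental/*F. glaucescens* trio, the
most distant is *F. pratensis* vs Mediterranean:

```r
comparison_table(loci, sim$alignment$groups) |> dplyr::arrange(n_polymorphic)
#>   group_a     group_b     n_polymorphic n_total similarity similarity_2dp
#> 1 glaucescens Rhizomatous             2     167      0.988           0.99
#> 2 glaucescens Continental             5     167      0.970           0.97
#> 3 Rhizomatous Continental             5     167      0.970           0.97
#> 4 pratensis   Continental            42     167      0.749           0.75
#> ...                                 117     167      0.299           0.30
```

Exactly four multi-base indels separate the Continental and Mediterranean
morphotypes — the diagnostic markers:

```r
find_diagnostic_indels(loci, sim$alignment$groups,
                       "Continental", "Mediterranean", min_length = 3)
#> # A tibble: 4 × 9
#>   locus_id start   end class       length ...  n_violations discriminating
#> 1 L109     13073 13081 indel_multi      8                 0 TRUE
#> 2 L113     13542 13589 indel_multi     47                 0 TRUE
#> 3 L136     16313 16345 indel_multi     32                 0 TRUE
#> 4 L160     19136 19139 indel_multi      3                 0 TRUE
```

The largest (47 bp) is the NFTCHL45-style assay; on the packaged synthetic
templates the in-silico PCR reproduces the 750 bp / 703 bp product pair
that tells the morphotypes apart on a gel:

```r
fx <- nftchl45_fixture()
in_silico_pcr(fx$templates, fx$primer)
#>   primer             template      product_length forward_start reverse_start
#> 1 NFTCHL45_synthetic Mediterranean            750            30           760
#> 2 NFTCHL45_synthetic Continental              703            30           713
```

A full run — trees with bootstrap support, the haplotype network, clade
ages — is one call:

```r
cfg <- pipeline_config(profile = "festuca", seed = 20180,
                       bootstrap_replicates = 200, out_dir = "bundle",
                       ancestral = "KY-31",
                       descendants = c("Prosper", "Resolute", "FlechaMaxQ",
                                       "PI283312", "PI283313"))
bundle <- run_pipeline(cfg)
tidy(bundle$tables$dice_tree)   # the Mediterranean + F. mairei clade at 100%
autoplot(bundle$tables$network)
```

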