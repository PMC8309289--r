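# fuzzmap

Graphical genotyping and fine mapping of a recessive locus in backcross
populations — an R implementation of the introgression-line route to a
monogenic trait, modelled on the mapping of the peach/nectarine fruit-skin
hairiness locus (*G*) on chromosome 5.

## Who it is for

Breeders and genetics researchers who have (or want to simulate) a BC1
population — a cross of an F1 back to its recurrent parent — genotyped by
resequencing, and who need to walk the classical chain:

```
VCF genotypes ──► parent-informative SNPs (AA × BB screen)
              ──► bin map / graphical genotypes (a = homozygous recurrent,
                                                 h = heterozygous donor)
              ──► introgression fragments and breakpoints
              ──► co-segregation scan  ──►  candidate interval
              ──► recombinant marker panel ──► fine-mapped interval
              ──► genes + co-segregating variants in the interval
              ──► diagnostic-SNP MAS genotyper
```

## The model

In a BC1 every locus is either homozygous for the recurrent-parent allele
(**a**) or heterozygous (**h**), segregating 1:1. With a dominant donor
allele *G* (hairy) over the recurrent *g* (glabrous/nectarine) and complete
penetrance, an individual is hairy ⇔ its causal locus is **h**. The
co-segregation scan therefore returns the maximal genomic intervals where
every individual satisfies

```
hairy      ⇔  state h
non-hairy  ⇔  state a        (missing states are non-informative)
```

and fine mapping closes the interval at the innermost phenotype-discordant
markers flanking the completely linked ones. The MAS rule is the recessive
Punnett-square logic at a diagnostic SNP with alleles `mut` (trait,
recessive; shipped default `T`) and `wt` (dominant; default `G`):
`mut/mut → non-hairy`, anything carrying `wt → hairy`.

A built-in simulator (`simulate_population()`) generates the whole study
design — Haldane crossovers, 1:1 segregation, complete penetrance,
configurable genotyping error and missingness — so the entire pipeline is
testable without any external data. See the vignette
(`vignettes/fine-mapping-backcross.Rmd`) for the modelling choices and
their limits.

## Worked example

```r
library(fuzzmap)

## a 38-offspring BC1 with defaults (8 x 25 Mb chromosomes, causal locus
## at Pp05:15,900,000), written to standard formats and read back
pop   <- simulate_population(genome_spec(), cross_spec(seed = 11))
paths <- emit_fixtures(pop, "bc1_run")
gm    <- read_vcf(paths$vcf)
phen  <- read_phenotypes(paths$phenotypes)

sites <- screen_informative(gm, "parent_recurrent", "parent_nonrecurrent")
imap  <- segment_introgressions(call_bins(recode_offspring(sites, gm),
                                          pop$genome))
ivs   <- cosegregation_scan(imap, phen)
ivs[[1]]
#> <candidate_interval> Pp05:14,900,001-17,000,000 (2099 kb, 38 supporting individuals)
```

The scan localises the causal locus to a ~2.1 Mb interval on chromosome 5
supported by all 38 individuals. Narrowing with the shipped seven-marker
panel and a ten-recombinant genotype table (synthetic — constructed to show
the published bounding pattern):

```r
fine <- fine_map(fine_mapping_example_table(),
                 candidate_interval("Pp05", 14099000, 16721000),
                 recurrent = "Zhongyou No. 4",
                 nonrecurrent = "Baihuashanbitao")
fine
#> <candidate_interval> Pp05:15,760,886-16,242,580 (481 kb, 12 supporting individuals)
fine$evidence$linked_markers
#> [1] "Pp05-SNP-15858687" "Pp05-SNP-15959172"
```

Two markers are completely linked and the interval closes at the flanking
discordant SNPs, 481 kb apart. Finally, the MAS genotyper on the shipped
16-cultivar validation panel:

```r
panel <- peach_cultivar_panel()
mas_concordance(mas_calls(panel$cultivar, panel$genotype, panel$phenotype))
#> <mas_concordance> 16/16 concordant (100.0%)
```

Every `T/T` line is a nectarine and every `G` carrier is hairy: the
diagnostic SNP predicts the phenotype of all 16 cultivars.

A thin command-line wrapper is available at `exec/binmap-finemap`
(`binmap-finemap {simulate|map|finemap|candidates|mas} --config cfg.yaml
[--seed N] [--out DIR]`), driven by the same `cmd_*()` functions.

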