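---
title: "Fine mapping a recessive locus in a BC1 population with fuzzmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine mapping a recessive locus in a BC1 population with fuzzmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzmap)
```

## The genetic setting

fuzzmap implements the classical introgression-mapping route to a monogenic
recessive trait, in the concrete clothing of the peach/nectarine fruit-skin
hairiness locus (*G*). Nectarines (glabrous skin, genotype *g/g*) are
recessive to hairy peaches. A first backcross (BC1) population is built by
crossing an F1 (recurrent nectarine parent × donor peach parent) back to the
recurrent parent. Every BC1 individual then carries, at each locus, either

* two recurrent-parent alleles (coded **a**, "homozygous recurrent"), or
* one recurrent and one donor allele (coded **h**, "heterozygous"),

segregating 1:1, and is hairy exactly when it carries the dominant donor
allele at the causal locus (complete penetrance is assumed throughout).
Mapping then reduces to finding the genomic region where the a/h state of
every individual coincides with its phenotype.

The pipeline has six stages, each usable on its own:

1. **Parental screen** (`screen_informative()`, `recode_offspring()`) —
   keep SNPs homozygous in both parents and differential between them
   (the AA × BB screen), and recode offspring calls onto {a, h, conflict,
   missing}. `conflict` (homozygous donor, impossible in a clean BC1) is a
   first-class flag, never silently coerced; binning treats it as missing
   but `conflict_rate()` reports it, since it is a direct readout of
   genotyping error or off-type individuals.
2. **Graphical genotyping** (`call_bins()`, `segment_introgressions()`) —
   aggregate coded calls into fixed-width bins, call each bin by majority
   vote, and segment each chromosome into alternating introgression
   fragments.
3. **Co-segregation scan** (`cosegregation_scan()`) — all maximal intervals
   where every phenotyped individual is concordant.
4. **Fine mapping** (`fine_map()`) — narrow the interval with a Sanger-typed
   marker panel on recombinant individuals.
5. **Candidate filtering** (`genes_in_interval()`,
   `filter_cosegregating_variants()`) — intersect with GFF3 gene models and
   rank in-interval variants by co-segregation under the recessive model.
6. **MAS genotyping** (`mas_predict()`, `mas_concordance()`,
   `segregation_report()`) — predict phenotype from the diagnostic SNP and
   report concordance and Mendelian segregation.

## The simulator and what it does (not) emulate

`simulate_population()` generates the full study design: two fully
homozygous, fully differential parents; `n_offspring` BC1 individuals; and
observed calls with configurable noise. Its defaults are the study
conditions every test and the acceptance script use:

| parameter | default | rationale |
|---|---|---|
| genome | 8 chromosomes × 25 Mb | the scan's eight-chromosome geography at legible coordinates |
| causal locus | `Pp05:15,900,000` | inside the region the shipped marker panel spans |
| `n_offspring` | 38 | the size of the primary mapping population the workflow is modelled on |
| `recombination_rate` | 1.0 Morgan/chromosome | a standard order of magnitude for a ~25 Mb plant chromosome |
| crossover model | Poisson count, uniform placement (Haldane) | the minimal no-interference model; easy to reason about and test |
| `genotyping_error_rate` | 0 | errors flip a ↔ h symmetrically; no error structure is assumed |
| `missing_rate` | 0 | calls are dropped independently |
| `n_sites` | 1500/chromosome | ≈ 6 informative sites per default 100 kb bin, enough for a robust majority vote |

All simulated sites are parent-informative by construction (the analysis
discards non-informative sites immediately; the readers are exercised on
non-informative input separately). The simulator deliberately does **not**
model read-level data, sequencing depth, crossover interference, residual
donor heterozygosity, selfed/F2 designs, or multi-locus traits. Passing
tests therefore demonstrate correctness of the analysis under a clean BC1
with complete penetrance — not robustness to pedigree errors or depth
artefacts in real resequencing data.

## Numerical and design choices

**Bins.** Default `bin_size` = 100 kb with `min_sites` = 3. A bin's state is
the majority of its non-missing a/h calls; ties or fewer than `min_sites`
calls give a missing bin. There is no HMM smoothing: the bin map mirrors the
manual graphical-genotype comparison this workflow mechanises, and every
rule stays auditable.

**Segmentation.** Maximal runs of equal called state become fragments.
Interior missing runs bounded by equal states join that state; bounded by
opposite states, the breakpoint is placed at the bp midpoint of the missing
run; leading/trailing missing adopts the nearest called state. A chromosome
with no called bin is reported state-unknown, never fabricated. Breakpoints
are reported both as a point (the display boundary) and as the bounding
interval between the last called bin of one state and the first of the next
— the honest resolution of bin-mapped data.

**Definite evidence vs. display.** A bin containing a true crossover is a
mixed bin: its majority call can land on either side, and a sub-bin
introgression sliver can be outvoted entirely. Two consequences are built
in:

* each fragment carries a *core* — its called extent minus one bin at every
  flank that abuts another run (that edge bin may host the crossover);
* bins whose votes disagree ("impure" bins) are excluded from cores
  altogether, because a sliver can only hide where the bin's own votes
  disagree. In error-free data impure bins occur only at true crossovers,
  so exclusion power elsewhere is untouched.

The co-segregation scan excludes only cores. This keeps it *sound*: in
error-free simulations the causal locus is never excluded by a
breakpoint-placement artefact. The cost is resolution — interval bounds are
conservative by up to one bin.

**Multiple concordant regions.** With only ~38 individuals and no crossover
interference, double recombinants occasionally isolate a second, genuinely
concordant region far from the causal locus (in our simulations this
happens in roughly 5 % of populations, with the causal-containing interval
always the widest). The scan returns *all* maximal concordant intervals
ranked by decreasing span rather than silently picking one; degenerate
scans (fewer than two individuals per phenotype class) and whole-chromosome
intervals are flagged.

**Fine-map interval convention.** The narrowed interval is *closed at the
innermost discordant markers* flanking the completely linked run — the
printed width of such an interval is the outer coordinate difference, and
`interval_width_kb()` truncates it to whole kb. When several runs of linked
markers tie for length, the one nearest the prior interval's midpoint is
taken; individuals missing at a boundary marker cannot set a bound; bounds
never move outward from the prior. Marker names like `Pp05-SNP-15760886`
are display names only — the authoritative position is the panel's `pos`
column.

**Candidate ranking.** In-interval variants are ranked by concordance under
the recessive model (non-hairy ⇔ homozygous recurrent allele), then feature
class CDS > intron > UTR-unknown > intergenic (a coding change is the more
parsimonious candidate; without UTR features, "in gene but outside the CDS
hull" cannot be split into UTR vs intron, hence *UTR-unknown*), then
position. Concordance is computed over typed individuals only, with the
typed count reported. No functional-effect prediction is attempted.

**MAS rule.** With `mut` the trait-associated (recessive) allele and `wt`
the wild-type allele, `mut/mut` predicts the recessive phenotype and any
`wt` carrier the dominant one; missing predicts unknown. Allele symbols are
configurable (`mas_alleles()`); the shipped default is T (nectarine) / G
(hairy) — allele labelling is fragile across strands and reports, which is
also why the VCF reader stores REF/ALT exactly as given and never
reconciles strands. `segregation_report()` tabulates observed
hairy:non-hairy counts against the Punnett-square expectation
(e.g. `mut/mut × mut/wt` → 1:1, `mut/wt × mut/wt` → 3:1) with an exact
binomial p-value as a diagnostic only. Parental genotypes inferred from
offspring ratios are hypotheses, never facts: the report prints the
expectation for the *stated* parents only.

## Shipped data

* `peach_cultivar_panel()` — phenotype and diagnostic-SNP genotype for the
  two mapping parents and 14 further cultivars/lines (16 in all; the
  validation panel for the 100 % concordance figure).
* `pp05_marker_panel()` — the seven chromosome-5 SNP markers
  (14,562,747–16,563,677 bp) used for fine mapping.
* `fine_mapping_example_table()` — a *synthetic* ten-recombinant genotype
  table (file `recombinants_pp05_synthetic.tsv`): per-individual
  fine-mapping genotypes are not published, so a constructed table
  reproduces the published bounding pattern — discordances at
  `Pp05-SNP-15760886` and `Pp05-SNP-16242580`, complete linkage at the two
  interior markers — yielding the 481 kb interval.

## Worked example

```{r example, eval = FALSE}
library(fuzzmap)

## simulate the study design and write standard-format fixtures
pop <- simulate_population(genome_spec(), cross_spec(seed = 11))
paths <- emit_fixtures(pop, "bc1_run")

## primary mapping from the VCF
gm <- read_vcf(paths$vcf)
phen <- read_phenotypes(paths$phenotypes)
sites <- screen_informative(gm, "parent_recurrent", "parent_nonrecurrent")
imap <- segment_introgressions(call_bins(recode_offspring(sites, gm),
                                         pop$genome))
ivs <- cosegregation_scan(imap, phen)
ivs[[1]]
#> <candidate_interval> Pp05:14,900,001-17,000,000 (2099 kb, 38 supporting individuals)

## fine mapping with the shipped marker panel
fine <- fine_map(fine_mapping_example_table(),
                 candidate_interval("Pp05", 14099000, 16721000),
                 recurrent = "Zhongyou No. 4",
                 nonrecurrent = "Baihuashanbitao")
interval_width_kb(fine)
#> [1] 481

## MAS on the shipped cultivar panel
panel <- peach_cultivar_panel()
mas_concordance(mas_calls(panel$cultivar, panel$genotype, panel$phenotype))
#> <mas_concordance> 16/16 concordant (100.0%)
```

## Problem sizes used by the tests and acceptance script

The default test suite runs the full scan on populations of 38 offspring
with 1,500 sites per chromosome (100 populations in the end-to-end
recovery check), 50 seeds for the monotone-narrowing property, an
exhaustive equivalence check of the segmenter against a brute-force oracle
on every ≤ 12-bin instance, and a 2,000-offspring population for the
segregation check — sizes chosen so the whole suite completes in a few
minutes on one CPU while keeping every binomial check at 3-standard-error
resolution.

## Known limitations

* Resolution is bounded by `bin_size`: introgression fragments smaller than
  about half a bin can escape detection entirely (their individuals are
  then reported with fewer supporting segments, and the scan's impure-bin
  rule prevents them from corrupting the interval).
* The scan assumes a single causal locus with complete penetrance; under
  genotyping error the soundness guarantee becomes empirical coverage, not
  a certainty.
* The candidate stage handles SNPs only — no structural-variant or
  LTR-insertion detection, although such events are known causes of
  recessive alleles at trichome loci.
* Gene content of a real interval depends on the external annotation used;
  the synthetic gene models shipped by the simulator only guarantee that a
  gene overlaps the causal locus.
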