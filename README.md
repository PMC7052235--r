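# embryoscreen

Trio-based whole-genome variant screening for preimplantation genetic
testing (PGT) embryos, in R.

## The problem

Clinical PGT usually tracks the one familial variant a couple sought
testing for. Whole-genome sequencing of an embryo's trophectoderm biopsy,
analysed jointly with both parents' genomic DNA, can instead screen the
whole genome: every embryo allele is classified by trio comparison as
paternally transmitted, maternally transmitted, or de novo, then graded
for pathogenicity. The catch is that biopsy DNA must be whole-genome
amplified (multiple displacement amplification, MDA), which creates allele
dropout over megabase regions, false heterozygotes with a characteristic
low variant-allele-fraction band (0.08–0.34, peaking near 0.26), and
uneven coverage. `embryoscreen` is the analysis layer of such a workflow,
for bioinformaticians building or evaluating genome-wide PGT pipelines.

## What it implements

- **Six inheritance-mode filter workflows** per embryo — dominant
  heterozygous, recessive homozygous (with carrier and dropout-suspect
  accounting), compound heterozygous (parental-origin phased), X-linked,
  de novo, and a deliberately low-specificity *failsafe* capture of
  actionable-gene hits for manual curation — each split into
  dbSNP-catalogued and novel subfilters, with full pass/fail trails.
- **Pathogenicity grading**: ClinVar class + review stars first; for
  unresolved variants a stacked prediction filter — at least 2 of 6
  predictor algorithms damaging, MPC > 2, CADD > 35 — yields
  `predicted_pathogenic`.
- **MDA-aware de novo gates**: reject VAF < 0.35 (the artifact band), and
  QD > 12 for novel candidates; rejections keep their reasons.
- **Loss-of-heterozygosity segments** (runs of >100 informative sites at
  ≥95% LoH consistency), trio-compared against parental homozygosity;
  pathogenic variants expected from a parent but unreliable in the embryo
  enter an *expected-but-missing ledger* and are phased from the nearest
  informative flanking SNPs (carrier / non-carrier / unresolved — never a
  guess when flanks disagree).
- **Binned trio CNV calling**: 10 kb depth bins, embryo/parent copy
  ratio (> 2.0 duplication, < 0.5 deletion) with Z-scores and four QC
  flags, ClinGen-style dosage-sensitivity annotation, trio inheritance by
  reciprocal overlap, cross-checking recessive CNVs against opposite-
  parent heterozygous SNV/indel hits, and ingestion of external SV calls.
- **Tandem-repeat panel**: the 17 repeat-expansion disease loci, with
  pathogenic-range flagging and exact parent–embryo transmission
  concordance under the best allele assignment.
- **A synthetic trio generator** (first-class, tested): parental germline
  variation at Ts/Tv 2.081, Mendelian transmission with recombination,
  74 de novo SNVs per full-genome equivalent, MDA artifacts (dropout
  regions, false hets with VAF mode 0.26, coverage degraded to 87.5% of
  the genome at ≥20× versus 96.4% for parents), planted CNVs and disease
  conditions — plus a complete ground-truth ledger for every emitted
  genotype.

Everything is tibble-in / tibble-out and pipe-friendly; reports have
`tidy()` / `glance()` methods and `autoplot()`.

## Worked example

```r
library(embryoscreen)

set.seed(7)
fam <- simulate_family(sim_params())   # 2 parents + 3 embryos, 50 Mb genome
emit_family(fam, "family_dir")         # VCF, bedGraphs, pedigree, tables, truth

res <- screen_family("family_dir")
res$summary
#> # A tibble: 12 × 4
#>    category              mean     sd n_embryos
#>    <chr>                <dbl>  <dbl>     <int>
#>  1 carriers             5.33   1.15          3
#>  2 cnv_calls          129.    27.9           3
#>  3 compound_pairs       0.333  0.577         3
#>  4 denovo_rejected      0      0             3
#>  5 denovo_retained      0.333  0.577         3
#>  6 dominant             5.33   1.15          3
#>  7 dropout_suspects     0.333  0.577         3
#>  8 expected_missing     2      2             3
#>  9 failsafe           864    30.8            3
#> 10 loh_segments         3.33   2.52          3
#> 11 recessive_affected   0.333  0.577         3
#> 12 x_linked             0.667  0.577         3
```

Each embryo's report carries per-mode candidate tables. The first embryo's
planted de novo survives both gates with the expected metrics:

```r
res$reports$embryo1$denovo$retained[, c("key", "gene", "grade", "vaf", "qd")]
#>   key              gene  grade        vaf    qd
#> 1 chr4:1850000:A:G ABL1  pathogenic 0.625  20.9
```

and its planted 300 kb homozygous deletion is called, dosage-annotated and
labelled de novo:

```r
dplyr::filter(res$reports$embryo1$cnv$calls, end - start >= 2e5)
#>   chrom   start     end state    mean_ratio inheritance gene   route
#> 1 chr3  6000000 6300000 deletion          0 de_novo     C3G031 report
```

Per-condition status against the generator's truth:

```r
conditions <- unique(fam$truth$conditions[, c("gene", "mode")])
assign_status(res$reports$embryo1, conditions)
#>   gene  mode          status
#> 1 KRT10 dominant_het  unaffected
#> 2 CFTR  recessive_hom unresolved   # causal site inside a dropout region
#> 3 BRCA2 dominant_het  unaffected
#> 4 GLA   x_linked      unaffected
#> 5 PKD1  dominant_het  unaffected
#> 6 SCN1A compound_het  affected
#> 7 ABL1  de_novo       affected
```

The `unresolved` CFTR status is the honest outcome for a biparental
variant inside an embryo-only LoH segment: it is listed in the
expected-but-missing ledger, and single-parent flank phasing cannot
resolve a variant both parents carry.

A thin CLI wraps the same functions:

```sh
embryoscreen simulate --seed 7 --out family_dir
embryoscreen run --dir family_dir
embryoscreen concordance a.vcf b.vcf --pedigree pedigree.tsv --sample embryo1
```

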