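---
title: "Trio-based whole-genome embryo screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based whole-genome embryo screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoscreen)
library(dplyr)
```

## The screening problem

Preimplantation genetic testing (PGT) of IVF embryos conventionally targets
the one familial variant a couple already knows about. Whole-genome
sequencing of a trophectoderm biopsy, jointly analysed with both parents'
genomic DNA ("trio testing"), extends this to genome-wide screening: every
embryo allele can be classified as paternally transmitted, maternally
transmitted, or de novo, and graded for pathogenicity. The difficulty is
that biopsy DNA must be whole-genome amplified by multiple displacement
amplification (MDA), which introduces allele dropout (one haplotype's
evidence vanishes over megabase-scale regions), false heterozygotes from
polymerase errors and misalignment, and uneven coverage. `embryoscreen`
implements the full analysis layer of such a workflow — it consumes a
multi-sample VCF, per-sample depth tracks and external annotations, and is
deliberately agnostic about the upstream aligner and caller.

## Inheritance-mode filters

Six filter workflows run in parallel per embryo, each split into a
dbSNP-catalogued and a not-yet-catalogued (novel) subfilter:

* **Dominant heterozygous** — transmitted alt-bearing calls of qualifying
  grade.
* **Recessive homozygous** — embryo homozygous-alternate with one alternate
  from each parent; heterozygous hits are reported separately as *carrier*
  findings; a homozygote whose parent is confidently homozygous reference
  is a *dropout suspect*, not a disease call.
* **Compound heterozygous** — unordered pairs of heterozygous hits in one
  gene with opposite parental origin (or one inherited plus one retained
  de novo). Pairs involving an ambiguous-origin hit (both parents carry the
  allele) cannot be phased by parental origin and go to a curation list.
* **X-linked** — chrX outside the pseudoautosomal regions; hemizygous males
  and homozygous females are affected, heterozygous females carriers.
  Embryo sex comes from the pedigree, else it is inferred as male when X
  heterozygosity is below 0.1 over at least 200 called X sites.
* **De novo** — alt alleles carried by neither parent, followed by the
  MDA-specific gates below.
* **Failsafe** — every alt-bearing call in a clinically actionable gene at
  read depth above 1, with no genotype-quality, grade or VAF requirement.
  Intentionally low-specificity: its output is a curation worklist, and on
  synthetic data it is a strict superset of every strict filter's output
  restricted to actionable genes.

The strict filters require embryo depth of at least 10 reads (the ">10x"
threshold read literally as `>= 10`) and a genotype quality of at least 20.
The GQ cutoff is our choice of a conventional Q20 — the workflow we follow
defines the failsafe by *omitting* the genotype-quality filter but does not
print the strict filters' cutoff; it is configurable
(`screen_config(gq_min = ...)`).

Every alt-bearing embryo record ends in exactly one accounting bucket —
a candidate list, the carrier list, the dropout-suspect list, the
expected-but-missing ledger, or the rejected list with its full pass/fail
trail — so nothing silently vanishes; this union-exhaustiveness is enforced
by a property test.

## Pathogenicity grading

ClinVar grading comes first: `pathogenic` and `likely_pathogenic` classes
(with review stars carried) are accepted directly; benign classes are
`benign_like`; uncertain, conflicting and unclassified variants fall
through to the stacked prediction filter, which returns
`predicted_pathogenic` only when **all three** stages pass:

1. more than one of the six predictors (SIFT, PolyPhen2 HVAR,
   MutationTaster2, MutationAssessor, FATHMM, FATHMM-MKL) calls the variant
   damaging (implemented as `>= 2`, missing verdicts counting as
   not-damaging);
2. MPC strictly above 2;
3. Phred-scaled CADD strictly above 35.

A missing MPC or CADD fails its stage, so indels — which the six predictors
do not score — can only qualify through ClinVar. Exactly one basis (ClinVar
or prediction) is recorded per variant, and the conjunction is verified by
an exhaustive truth-table test over all damaging-counts and threshold
sides.

## De novo gates under MDA

Embryo heterozygote VAF distributions from MDA material show a false-het
artifact band from 0.08 to 0.34 peaking near 0.26, far below the 0.5
expected of a genomic heterozygote. Two gates suppress these:

* **VAF gate** — de novo candidates with VAF below 0.35 are rejected
  (`>= 0.35` retained; 0.35 itself survives). The threshold is "soft" in
  the sense that rejected candidates are preserved with reasons for the
  curation path, never silently dropped. By default all variant classes
  are gated with the class recorded; deletions longer than 1 bp are known
  to run at higher VAF and can be exempted via
  `screen_config(vaf_gate_classes = "snv")`.
* **QD gate** — quality-by-depth strictly above 12, applied only to the
  novel (non-dbSNP) subfilter; transmitted variants are never QD-gated.

The gates commute and partition their input (property-tested). On
simulated embryos, true de novos at genomic allele fraction 0.5 and 40x
depth survive with sensitivity above 0.95 while artifact FDR stays below
0.05.

## LoH detection and flanking-SNP rescue

For an embryo, the LoH site universe is the set of sites where the two
parents carry different genotypes; a site is LoH-consistent when the
embryo is called homozygous or missing. Maximal runs are assembled by
merging consecutive LoH runs across the smallest interruptions first while
the pooled fraction stays at or above 0.95, and a segment is emitted when
it spans strictly more than 100 sites. Both the total site count and the
LoH-consistent count are reported, since the published description
(">100 and 95% of variants") does not say which is counted — we threshold
on the total. Embryo segments reciprocally overlapping (>= 50%) a parental
homozygosity run are labelled `shared_parental` (inherited homozygosity);
the rest are `embryo_only` — the MDA dropout signature. Recessive
homozygous calls inside an `embryo_only` segment are demoted to dropout
suspects.

Every pathogenic or predicted-pathogenic variant carried by a parent whose
embryo evidence is unreliable — call absent, depth below 10, or inside an
`embryo_only` LoH segment (where a present call has lost one haplotype's
evidence) — enters the *expected-but-missing ledger*. Ledger entries are
phased from the nearest informative flanking SNP on each side (carrier
parent phased heterozygous, other parent homozygous, embryo call
revealing the transmitted haplotype) within a 1 Mb window (configurable;
no published value exists). Status is inferred only when both flanks
agree; discordant flanks — the recombination signature — and single-flank
cases stay `unresolved`. There is deliberately no statistical imputation:
phasing uses single nearest informative SNPs, nothing else, and a
property test asserts rescue never mis-assigns when flanks conflict.
Variants expected from *both* parents cannot be resolved by single-parent
phasing and remain unresolved.

## Binned trio CNV calling

Depth tracks are averaged into 10 kb bins and normalized per sample by
autosomal median depth. For a target sample against its controls (embryo
vs both parents; each parent vs the other):

* copy ratio = target normalized depth / mean control normalized depth,
  divided by the sex-chromosome expectation (a male embryo's X runs at
  half a female's);
* Z-score = target bin against the controls' genome-wide normalized-depth
  distribution (with only two parents, a per-bin Z reference would be
  degenerate);
* four QC flags: `high_control_variation` (control CV above 0.5),
  `low_control_depth` (mean control depth below 10), `low_z_score`
  (|z| below 1.96 — deviation within noise), and `within_regional_iqr`
  (bin depth inside the interquartile range of the surrounding +/-50-bin
  window, computed from non-candidate bins so a broad genuine CNV does not
  flag itself).

Calls are maximal runs of consecutive qualifying bins — duplications at
ratio strictly above 2.0 with positive Z, deletions strictly below 0.5
with negative Z — containing no flagged bin (runs split at any
interruption; no gap tolerance), and requiring mean *control* depth above
5 over the call. We measure the depth criterion on the controls because an
embryo homozygous deletion has near-zero embryo depth by construction; the
criterion asks whether the region is reliably sequenceable. Calls are
annotated against a ClinGen-style dosage table (deletions x
haploinsufficiency, duplications x triplosensitivity; sufficient-evidence
genes are reportable, autosomal-recessive-evidence genes route to a
cross-check against heterozygous SNV/indel candidates from the *other*
parent), and trio-compared by >= 50% reciprocal same-state overlap
(paternal / maternal / ambiguous / de novo). Externally discovered SV
intervals (DEL/DUP/INV/ITX/CTX) are ingested and annotated the same way;
only DEL/DUP enter dosage logic.

Two detection limits are worth stating. A single-copy loss inherited from
a parent who carries the same deletion sits at ratio ~0.67 against
parents-as-controls (the control mean is itself depressed) and is below
the strict 0.5 threshold — a structural property of using the couple as
the reference. And isolated single-bin (10 kb) calls under MDA noise are
mostly stochastic; consumers should filter by size for reporting, as the
acceptance property does (no false call at or above 100 kb).

## Tandem repeats

The default panel is the 17 distinct repeat-expansion disease loci (CBL,
ATN1, ATXN2, ATXN3, JPH3, CACNA1A, DMPK, CSTB, ATXN10, ATXN7, HTT,
PPP2R2B, ATXN1, C9ORF72, FXN, AR, FMR1; some published enumerations list
ATXN1 under the "ataxin 10" name — the panel here is the 17 distinct
genes). Repeat genotypes are consumed as calls (repeat estimation from
reads is out of scope). Each allele is classified against curated
normal / premutation / pathogenic ranges (pathogenic lower bound
inclusive); the shipped ranges are defaults drawn from the clinical
literature and are user-overridable, not diagnostic assertions.
Transmission concordance is exact repeat-count equality under the best of
the two parent-to-allele assignments (a configurable +/-1 tolerance
exists but is off by default, since the assessment is "transmission
exactness"); X-linked loci in male embryos match the single allele
against the maternal alleles only.

## The synthetic trio generator

No sequencing data accompany the study conditions this package targets, so
the generator is a first-class, tested module that produces everything the
pipeline reads, plus a complete ground-truth ledger. Its defaults *are*
the study conditions:

| quantity | default | rationale |
|---|---|---|
| genome | 4 autosomes + chrX, 10 Mb each | desk-scale miniature |
| family variant-site density | 1/800 bp | ~2 het sites/kb/parent, human-like |
| parent depth | NB(mean 46, size 8) | 96.3% of genome >= 20x |
| embryo depth | NB(mean 48, size 3.65) x 50 kb lognormal waves (sdlog 0.2) | 87.5% of genome >= 20x |
| de novo SNVs | 74 per full-genome equivalent, scaled by simulated fraction | documented full-genome default |
| crossovers | Poisson(1) per chromosome | order-one human value |
| artifact false hets | 50/Mb, VAF ~ 0.08 + 0.26 x Beta(10, 5) | mode 0.26 on support [0.08, 0.34] |
| dropout regions | Poisson(3) per genome, 0.5–3 Mb | megabase-scale ADO |
| Ts/Tv | 2.081 | WGS-quality spectrum |

The Beta(10, 5) shape is the unique two-parameter choice placing the mode
of the scaled density at exactly 0.26; observed artifact allele depths are
`round(VAF x depth)`, modelling the amplification-template fraction
directly. The negative-binomial sizes and the wave amplitude were
calibrated analytically, once, to the two coverage fractions above; the
wave region (50 kb) is kept below the 100 kb false-call bound so
amplification waves cannot masquerade as large CNVs. Parental genotypes
are emitted phased (`0|1`) with chromosome-consistent haplotype order,
which is what the flanking-SNP rescue consumes; embryo genotypes are
unphased. Planted conditions can force transmission (`transmit_father =
"alt"`), implemented by flipping the whole chromosome's transmitted-
haplotype labelling so crossover structure and flank phase stay
consistent; a spec a parent cannot satisfy is a fatal error. Background
pathogenic annotations are kept out of the planted-condition genes so each
condition's truth status is attributable to its planted site.

What the generator does **not** emulate: read-level errors (no FASTQ/BAM),
sequence-context mutation spectra beyond Ts/Tv, population allele
frequencies and linkage structure, chimeric MDA molecules, or mosaicism.
Passing tests therefore demonstrate the *logic* of the filters under the
stated statistical structure, not performance on real embryo libraries.

## Numerical and design choices

* Thresholds printed with strict inequalities are implemented strictly
  (QD > 12, MPC > 2, CADD > 35, ratio > 2.0 / < 0.5, segment sites > 100,
  failsafe depth > 1 as `>= 2`); ">10x coverage" is `>= 10` reads.
* Missing QD fails the QD gate; missing VAF fails the VAF gate; both are
  recorded as explicit rejection reasons.
* Variant keys are `chrom:pos:ref:alt` after multiallelic decomposition
  (never dropping alternate alleles) and reference-free parsimony
  left-normalization of indels, so annotation joins are deterministic.
* Coordinates are 1-based inclusive in variant space (VCF convention) and
  0-based half-open in all interval outputs (BED convention).
* LoH run merging is greedy smallest-gap-first; emitted segments are
  maximal in the sense that merging two adjacent emitted segments would
  violate the 95% fraction.
* Pseudoautosomal regions are treated as autosomal. The default
  `par_regions` is empty (the synthetic chrX is a 10 Mb miniature);
  `grch37_par()` supplies GRCh37 coordinates for real data.
* Ambiguous-origin alleles (both parents carry) count as transmitted for
  dominant and recessive purposes but block compound-het auto-calling.

## Problem sizes

The shipped tests simulate the default five-chromosome 50 Mb family
(about 60,000 family variant sites, three embryos) for end-to-end checks,
100 embryos at the unscaled de novo rate for the load calibration, an
eight-chromosome 200 Mb parental genome (about 200,000 SNVs) for the
substitution-spectrum check, and around 10,000 artifact sites for the VAF
mode. These sizes give the stochastic checks comfortable margins (e.g.
the standard error of the de novo mean is about 0.9 against a +/-3
tolerance) while a full test run stays in the minutes range on one core.

## Worked example

```{r example, eval = FALSE}
set.seed(7)
fam <- simulate_family(sim_params())
emit_family(fam, "family_dir")

res <- screen_family("family_dir")
res$summary
tidy(res$reports$embryo1)
autoplot(res$reports$embryo1)

conditions <- dplyr::distinct(fam$truth$conditions[, c("gene", "mode")])
assign_status(res$reports$embryo1, conditions)
```

## Known limitations

* One family per run; no multi-family batch VCFs.
* No mosaicism fraction estimation, imprinting, mitochondrial or polygenic
  modelling.
* Compound-het phase for ambiguous-origin hits is left to curation rather
  than read-backed or population phasing.
* Inherited single-copy CNVs shared with a parent are at the detection
  limit of the parents-as-controls ratio (see above).
* The concordance assessment assumes both call sets share a variant key
  space; lifting array genotypes onto sequence coordinates is external.
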