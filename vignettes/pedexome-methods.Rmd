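---
title: "pedexome: methods, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pedexome: methods, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedexome)
```

## The inheritance-consistency model

`pedexome` treats inheritance-model filtering as a constraint-satisfaction
problem. For a biallelic site and a model $M \in \{AD, AR, XLD, XLR\}$, a
site is *consistent* iff there exists a complete genotype assignment
$g$ over **all** pedigree members — sequenced or not — satisfying:

* **Observation.** $g_i$ equals the observed alt-allele count for every
  sequenced member $i$ with a non-missing call. Missing calls (`./.`) are
  wildcards: exome coverage is uneven, and a genotype hidden by a coverage
  gap must not refute a model. This makes consistency monotone in
  missingness (masking a call can never turn a consistent site
  inconsistent), a property the test suite checks.
* **Mendelian transmission.** Each non-founder receives one gamete from
  each parent ($0 \to \{0\}$, $1 \to \{0,1\}$, $2 \to \{1\}$). On X,
  sons receive only a maternal gamete and daughters the paternal
  hemizygous allele plus a maternal gamete; male X genotypes are
  hemizygous $\{0,1\}$, and pseudo-autosomal regions are treated as X.
  A member with one recorded and one unrecorded parent (the grandson's
  mother here) receives an unconstrained gamete from the unrecorded side.
* **Full penetrance.** Affected ⟺ risk genotype; unaffected ⟺ non-risk.
  Risk genotypes: AD $g \ge 1$ (heterozygous carriers are the observed
  case, but homozygous alt is not excluded by any stated rule); AR
  $g = 2$; XLD hemizygous alt or female $g \ge 1$; XLR hemizygous alt or
  female $g = 2$. Members of unknown affection are constrained by
  transmission only. Phenocopies, reduced penetrance and de-novo events
  inside the pedigree are deliberately not modelled: the deduced-genotype
  logic this reproduces assumes strict genotype–phenotype equivalence.
  Compound heterozygosity under AR is not modelled either (sites are
  treated independently). Founder genotypes carry no frequency prior.

Two implementations coexist by design: an early-exit depth-first search
(`site_matches_model`) and an exhaustive enumerator
(`enumerate_assignments`, capacity-bounded at 15 members) whose
non-emptiness must agree with the matcher. The acceptance suite verifies
this equivalence against a third, independently written brute-force oracle
over every observation vector ($3^k$ per pedigree, including all 243
vectors over the study quintet) for all four models.

Before any per-site matching, structural rules exclude whole scopes:
Y-linkage when any affected member is female; mitochondrial inheritance
when an affected member has an unaffected mother and an affected father
(paternal disease origin); X-linked dominance on male-to-male
transmission. AD and AR are always evaluated, and XLR is retained by
default — per-site genotype logic decides its fate.

## Consequence annotation

Transcript models carry exon intervals (1-based inclusive; BED inputs are
converted from 0-based half-open at the boundary), CDS bounds and the
spliced coding sequence in coding orientation. A coding SNV is classified
by translating the reference and alternate codons with the standard
genetic code; both the modern (`c.695G>T`) and legacy (`c.G695T`) HGVS
coding names plus the protein name (`p.Gly232Val`) are emitted. Indels are
frameshift iff the allele-length difference is not a multiple of 3.
Intronic positions within `splice_window` bases of an exon boundary are
`splicing`; the default window is ±2 bp (the canonical splice
dinucleotide) — the source workflow names "splicing" without stating a
window, so it is configurable. When transcripts overlap, the most severe
consequence is reported and per-transcript detail kept. Stopgain/stoploss
categories extend the printed vocabulary for completeness. A VCF reference
allele disagreeing with the transcript sequence raises a
`reference_mismatch` condition; the pipeline logs and skips such sites.

## The filter cascade

Steps run in the published order: (1) keep exonic/splicing; (2) drop
synonymous **SNVs** (indels bypass this step, matching the dual SNV/indel
accounting); (3) keep conserved-region variants — the conservation step is
a *retention* filter, not an annotation; (4) drop segmental-duplication
overlaps; (5) drop dbSNP members, matched by `(chrom, pos, ref, alt)`
rather than rsID to avoid positional collisions; (6) drop variants with
population MAF ≥ 0.05 (strictly-less-than survives; absent frequency is
retained — absence of evidence of commonness). The subsequent novelty
filter is stricter: *any* frequency entry in either panel, however rare,
marks a known variant. Per-step SNV/indel counts are recorded per model;
the survivor set is provably order-independent (the predicates are
per-site), which the tests exercise by permutation.

The multi-allelic pre-filter requires strictly biallelic records. The
source describes filtering "loci with more than 3 alleles" while reserving
"bi-allelic variants"; the stricter biallelic reading governs here, and
dropped counts are logged.

## Prioritization

Strict consensus deleteriousness requires **all seven** categorical
predictors present and damaging (`C` for PhyloP/GERP++, `D` for the
rest); possibly-damaging (`P`), tolerated, benign, neutral and missing
calls all fail. This is the unique rule that isolates exactly one
candidate on the packaged 19-row predictor fixture. How `P` *should* be
treated is genuinely open — the strict reading is the default, and a
`lenient` flag admits PolyPhen-2 `P` for sensitivity analyses. The control
screen classes any validated variant seen in ≥ 1 screened control as a
polymorphism (panel size is data-driven, not hard-coded at 100);
cosegregation flags a violation when an affected member lacks the variant
or an unaffected member carries it, while carriers of unknown phenotype
are listed as uninformative. Ranking is deterministic:
consensus > family-specific > cosegregates > known disease gene, with an
alphabetical tie-break; Sanger-refuted candidates (calling errors) are
removed before ranking.

## What the synthetic generator emulates — and what it does not

`simulate_family_dataset()` states one fixed world (defaults below) and
derives everything from a single seeded RNG stream:

| parameter | default | rationale |
|---|---|---|
| pedigree | 7 members, 5 sequenced | the studied family structure |
| planted model | AD, heterozygous carriers | the published causal variant |
| planted site | coding position 695, codon 232 `GGG→GTG` | Gly→Val missense |
| `n_background` | 1000 | desk-scale stand-in for the ~16k model-consistent pool |
| MAF prior | Beta(0.2, 2) on [0.001, 0.5] | rare-skewed site-frequency spectrum |
| `genotype_error_rate` | 0 | error is an experimental dial, not a default condition |
| `missing_rate` | 0.01 | typical residual no-call rate at good coverage |
| fractions: exonic .45, synonymous .5, conserved .30, segdup .05, dbSNP .90, 1000G .80, ESP .60 | | a post-calling exome table: an even syn/nonsyn split, most sites already catalogued |
| `n_false_positive` | 2 | the two sequencing-refuted candidates of the study |
| per-predictor damaging probability | 0.3 | mixed predictions dominate real candidate tables |

Founder genotypes are Hardy-Weinberg draws at the variant's MAF and
offspring are produced by Mendelian gamete sampling (verified by
Monte-Carlo against the binomial expectation). Emitted sites are
conditioned on being polymorphic among the sequenced members — joint
calling never emits a site nobody carries — so of 1,000 attempted
background variants roughly 770 appear in the VCF; the unconditional
draw remains available to the calibration test (with the default seed 1,
771 of 1,000 attempted background sites are emitted). Exonic background
variants are placed at real CDS positions whose actual codon change
realizes the desired synonymous/nonsynonymous class, so the annotation
module re-derives the truth rather than trusting a label. Conservation
and segdup truth flags are *recomputed from the emitted intervals*, making
resource/truth disagreement impossible by construction; the planted
site's neighbourhood is excluded from segdup intervals because the truth
contract requires the planted variant to pass every cascade predicate.
False-positive injections carry the planted genotype pattern but are
marked `validated = FALSE`, emulating calls refuted by re-sequencing.

The generator does **not** emulate read-level reality: no coverage/depth
structure, no allele-balance-dependent error, no linkage disequilibrium
between background sites, no indel realization in genomic sequence
context, and no population stratification. A green end-to-end test
therefore establishes that the *filtering logic* behaves as specified on
data with the stated statistical structure — not that the pipeline is
robust to alignment- or calling-stage artifacts, which are out of scope.

## Numerical and interface choices

* Coordinates are genomic 1-based inclusive internally; BED is converted
  at the boundary. Codon arithmetic is exact integer arithmetic
  (`codon = (pos − 1) %/% 3 + 1`), reproducing the four printed
  residue numbers 232, 193, 1169 and 164.
* The frequency threshold uses strict `<` (a variant at exactly 0.05 is
  dropped), matching a "MAF < 0.05 survives" reading.
* Heterozygous-coded male X calls are recoded as alt hemizygotes rather
  than rejected: outside pseudo-autosomal regions they are artifacts, and
  the carrier reading is the conservative one for a filter.
* The pipeline config file is JSON, not YAML: the target environment
  ships no R YAML parser, and jsonlite is already a dependency. Flags
  override file values.
* Determinism: identical seeds give byte-identical simulator output;
  identical inputs give identical reports; ranking has a total order.

## Known limitations

* Full penetrance is a strong assumption; a single phenocopy or
  non-penetrant carrier refutes the true model and the causal site is
  then lost at the inheritance stage (the truth table attributes such
  losses under simulated genotyping error).
* The exhaustive search is exponential in pedigree size; it is bounded at
  15 members, ample for the clinical use case but not for extended kindreds.
* Cosegregation uses a dominant carrier reading; recessive cosegregation
  semantics would need genotype-level (not carrier-level) comparison.
* Splice-site annotation is window-based only; no splicing-strength model.
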