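# pedexome

Pedigree-driven filtering and prioritization of family exome variants in R.

## The problem

In a small family segregating a rare, apparently monogenic disease —
here the motivating case is inherited cardiac conduction disease (CCD),
a progressive failure of the heart's impulse-generating and
impulse-propagating system — whole-exome sequencing of a handful of
relatives yields hundreds of thousands of variant calls, of which exactly
one is the causal mutation. Linkage analysis is powerless at this pedigree
size. `pedexome` implements the discrete filtering strategy that makes such
studies work:

1. **Inheritance-model filtering.** For each biallelic site, keep it only
   if there *exists* a full genotype assignment `g : members → {0,1,2}`
   (hemizygous `{0,1}` for males on X) such that (a) `g` matches every
   observed call, (b) each non-founder's genotype is Mendelian-producible
   from its parents' gametes, and (c) under full penetrance,
   `affected(i) ⟺ risk(g_i)` where the risk genotype is `g ≥ 1` (AD),
   `g = 2` (AR), or the X-linked analogues (XLD/XLR). Structural rules
   first exclude whole model classes (Y if any affected female; MT if the
   disease enters through the father; XLD on male-to-male transmission).
2. **Annotation cascade.** Retain exonic/splicing calls, drop synonymous
   SNVs, keep conserved-region variants, drop segmental-duplication
   artifacts, dbSNP members and variants with population MAF ≥ 0.05, then
   drop anything with *any* reported frequency in the 1000 Genomes or ESP
   panels (novelty filter) — with per-step SNV/indel accounting.
3. **Consensus prioritization.** A candidate is consensus-deleterious only
   if all seven categorical predictors (PhyloP, SIFT, PolyPhen-2, LRT,
   MutationTaster, GERP++, SIFT 2013) call it damaging. Candidates are
   ranked by consensus, family specificity in a healthy control panel,
   cosegregation with the phenotype, and known disease-gene membership.

A seeded synthetic-data generator emulates the post-calling data of a
seven-member pedigree with five sequenced members, a planted causal
variant, background variants at Hardy-Weinberg genotype frequencies,
genotyping error, coverage gaps and injected false-positive calls — so
every stage is testable end to end without any sequence download.

## Worked example

```r
library(pedexome)

ped <- study_pedigree()
applicable_models(ped)$models
#> [1] "AD"  "AR"  "XLR"

# the published family's genotypes at the causal site (alt-allele counts)
s <- site_genotypes("1", 156104651, "G", "T",
                    c(`I-3` = 0, `II-2` = 1, `II-3` = 1, `II-4` = 1,
                      `III-1` = 0))
site_matches_model(s, ped, "AD")
#> [1] TRUE                      # the deceased father is assignable as het

cds_to_codon(695)
#>   codon_index offset
#> 1         232      2          # c.695G>T lands in codon 232: p.Gly232Val

# full simulated run: 1,000 background variants, one planted AD variant
ds  <- simulate_family_dataset(simulation_config(seed = 1))
res <- run_pipeline(dataset = ds, verbose = TRUE)
#> input sites: 771 (0 multi-allelic dropped)
#> model AD: 45 SNVs, 1 indels consistent
#> model AR: 3 SNVs, 0 indels consistent
#> model XLR: 0 SNVs, 0 indels consistent
#> annotated 49 model-consistent sites (0 reference mismatches skipped)
#> cascade survivors (all models): 4
#> novelty filter: 1 known removed, 3 candidates
#> ranked 1 candidates (2 calling errors removed)
res$report$gene[1]
#> [1] "GENE01"                  # the planted causal gene, ranked first
```

The two "calling errors removed" are the injected false-positive calls
(pedigree-consistent in the VCF, refuted by the simulated Sanger
validation), mirroring how sequencing-refuted candidates are discarded in
practice. The packaged 19-candidate predictor fixture reproduces the
published selection: exactly one gene (LMNA) survives strict consensus,

```r
tab <- table4_fixture()
tab$gene[sapply(seq_len(nrow(tab)), function(i)
  consensus_deleterious(do.call(prediction_profile, as.list(tab[i, -1]))))]
#> [1] "LMNA"
rank_candidates(tab, table5_fixture(), study_pedigree(),
                disease_genes = cardiac_disease_genes())$gene[1]
#> [1] "LMNA"
```

## Files the pipeline consumes

PED (6 columns, optional 7th `sequenced`), multi-sample VCF 4.x (GT),
transcript models as TSV + CDS FASTA or BED12 + FASTA, conserved /
segmental-duplication BED (0-based half-open), dbSNP and population
frequency TSVs keyed by `chrom, pos, ref, alt`, categorical prediction
TSV, and an optional validation TSV. `write_dataset()` emits a complete,
mutually consistent set of these from one simulation; `pedexome_cli()`
exposes `simulate` / `inherit` / `run` subcommands, with the pipeline
configured from a JSON file.

See `vignettes/pedexome-methods.Rmd` for the model, its assumptions,
parameter choices and limitations.
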