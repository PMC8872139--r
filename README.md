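# digenicBSA

Forward-genetics mapping of recessive plant mutants, packaged as a tested
R pipeline: digenic segregation analysis, recombinant-based fine mapping,
bulked-segregant delta SNP-index scanning, and candidate-gene triage, plus
a synthetic-data generator that produces every input format the pipeline
consumes together with truth records.

It is aimed at plant geneticists doing map-based cloning: you have a
mutant, segregating F2 / F2:3 populations, pooled re-sequencing of a
near-isogenic line (NIL) pair, gene annotations and an expression table,
and you want to go from observed counts to a short, ranked list of
candidate genes.

## The statistics at the core

**Segregation modelling.** An epistasis model maps each joint genotype
class of a selfed double heterozygote to a phenotype. Under duplicate
recessive epistasis (mutant ⇔ *aa bb*) exact enumeration of the nine
classes gives the F2 ratio wild : mutant = 15 : 1, and, conditioning on
wild-type F2 plants and asking which genotype classes can self to a mutant
progeny, the F2:3 progeny-test ratio segregating : non-segregating =
8 : 7. Observed counts are tested with the Pearson statistic
χ² = Σ (Oᵢ − Eᵢ)² / Eᵢ, Eᵢ = N pᵢ, df = classes − 1. Two reporting
conventions seen in segregation tables (integer-rounded expected counts;
Yates continuity correction) are exposed as flags, both off by default.

**Fine mapping.** Among phenotypic mutants, each heterozygous call at a
marker counts one recombinant chromosome and each non-mutant-parent
homozygote two. The mapping interval is the maximal run of
zero-recombinant markers, bracketed by the nearest markers with events on
each side.

**BSA scan.** For each pool, the SNP index at a site is alt / (alt + ref)
read depth; sites are first passed through GATK-style hard filters
(SNPs fail on QD < 4 ∨ FS > 60 ∨ MQ < 40; indels on QD < 4 ∨ FS > 200 ∨
ReadPosRankSum < −20 ∨ InbreedingCoeff < −0.8; pool genotypes with
GQ < 20 are masked). A sliding window (2 Mb window, 50 kb step, anchored
at coordinate 1) averages the per-site indices, and
Δ(SNP index) = index(MT) − index(WT) per window. Candidate regions are
maximal runs of windows with Δ ≥ threshold (1 in the noiseless limit).

**Triage.** Genes overlapping a candidate region are classified by
codon-level variant effect (strand-aware CDS mapping, standard genetic
code) and by the differential-expression rule p ≤ 0.05 ∧ |log2FC| ≥ 1.
Tier 1 = missense + DEG, tier 2 = exactly one, tier 3 = neither.

## Worked example

Segregation analysis of two crosses of a short-petiole soybean mutant
(650:42 and 420:120 wild:mutant F2 plants) and its progeny test
(93:87 segregating:non-segregating F2:3 lines):

```r
library(digenicBSA)
m <- epistasisModel("duplicate_recessive_mutant")
f2PhenotypeRatio(m)
#   wild mutant
#     15      1
chiSquareGof(c(420, 120), c(3, 1))
# Chi-square goodness of fit: chi2 = 2.222, df = 1, p = 0.136
#   observed: 420:120  expected: 405:135
chiSquareGof(c(93, 87), as.integer(f23ProgenyRatio(m)))
# Chi-square goodness of fit: chi2 = 0.2009, df = 1, p = 0.654
#   observed: 93:87  expected: 96:84
```

So the wide cross fits the digenic 15:1 expectation, the other cross fits
3:1 (one causal locus already fixed in that parent), and the progeny test
confirms 8:7 — two recessive genes.

Candidate triage on the bundled chromosome-11 interval tables:

```r
genes <- exampleTable("chr11_interval_genes")
vars  <- exampleTable("chr11_coding_variants")
eff   <- data.frame(gene_id = vars$gene_id,
                    effect = ifelse(vars$type == "Synonymous",
                                    "synonymous", "missense"))
summarizeVariants(eff)$totals
#  nSnps  nGenes  nMissense  nMissenseGenes  nSynonymous
#     12       6         10               5            2
head(rankCandidates(genes$gene_id, eff,
                    c("Glyma.11g230300", "Glyma.11g230600")), 4)
#           gene_id in_interval missense_count total_cds_snps is_deg tier
# 1 Glyma.11g230300        TRUE              3              3   TRUE    1
# 2 Glyma.11g230600        TRUE              2              3   TRUE    1
# 3 Glyma.11g230000        TRUE              2              2  FALSE    2
# 4 Glyma.11g230200        TRUE              2              2  FALSE    2
```

The two protein-kinase genes carrying missense variants *and* showing
differential expression come out on top — the mapping study's candidates.

A fully synthetic end-to-end run (NIL pools, planted causal gene):

```r
res <- runNilScenario(seed = 3)
res$report[res$report$tier == 1, "gene_id"]   # "toy003"
res$truth$causalGene                          # "toy003"
```

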