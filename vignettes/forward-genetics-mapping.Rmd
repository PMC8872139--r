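---
title: "Mapping recessive plant mutants: segregation models, recombinant counting, and the delta SNP-index scan"
author: "digenicBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive plant mutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digenicBSA)
```

# Scope and model

digenicBSA implements the statistical chain used in map-based cloning of a
recessive plant mutant, from segregation counts to a ranked candidate-gene
list. The motivating setting is a soybean mutant governed by duplicate
recessive epistasis — two unlinked loci, mutant phenotype only when both
are homozygous recessive — but every component is generic over the
registered epistasis models.

The package assumes read alignment and variant calling have already
happened: it consumes marker genotype tables, pooled variant calls with
allele depths and site statistics, gene annotations, CDS sequences and
differential-expression tables. It does not align reads, call variants,
compute FPKM, or run GO/KEGG enrichment.

# Segregation analysis

## Exact enumeration

`enumerateF2()` builds the joint genotype classes of a selfed (double)
heterozygote in integer rational arithmetic: per-locus selfing frequencies
1:2:1 over denominator 4, joint classes over denominator 16. Keeping
numerators as integers makes the normalization Σfᵢ = 1 exact and lets
`f2PhenotypeRatio()` and `f23ProgenyRatio()` reduce phenotype sums to
coprime parts with a deterministic gcd, so 15:1 and 8:7 are derived, never
hard-coded. A *fixed background* (one locus pinned, e.g. a cross to a
parent already homozygous recessive there) collapses the enumeration to
the three classes of the segregating locus — that is how the same digenic
model predicts 3:1 in a cross where one parent carries one of the
recessive alleles.

The progeny-test classification is mechanistic: an F2 wild-type class is
expected to segregate in F2:3 iff selfing that genotype can produce at
least one mutant-phenotype genotype. Under duplicate recessive epistasis
this yields 8 segregating : 7 non-segregating; for a monogenic recessive,
2:1.

## Chi-square conventions

`chiSquareGof()` computes the plain Pearson statistic with expected counts
Eᵢ = N·partᵢ/Σparts and p from the χ² survival function. Published
segregation tables are not always explicit about two details, so both are
flags rather than silent behaviour:

* `roundExpected` — some tables round expected counts to whole plants
  before computing χ². For 650:42 against 15:1 the plain statistic is
  0.039 while the integer-rounded convention gives 0.025 (printed as 0.02,
  p = 0.87). We could not determine which convention produced every
  published value, so the default is the plain statistic
  (`roundExpected = FALSE`) and the rounded convention is opt-in.
* `yates` — the continuity correction, floored at zero deviation. Off by
  default; Yates-corrected values are systematically smaller.

P-values are carried at full precision; any rounding belongs to report
formatting, not to the test.

`classifyInheritance()` automates model selection across crosses: every
candidate model whose p clears `alpha` is "accepted", the max-p model is
reported, and ties break toward fewer loci, then the lexicographically
first name — a deterministic rule, not a statistical claim.

# Fine mapping by recombinant counting

All individuals in a fine-mapping table are phenotypic mutants, hence
homozygous for the mutant-parent allele at the causal locus. What counts
as "one recombination event" is ambiguous in common usage, so
`countRecombinants()` exposes both units: `chromosomes` mode (default)
counts a heterozygote as one recombinant chromosome and a non-mutant-
parent homozygote as two; `individuals` mode counts any non-P2 call once.
Chromosome-mode counts always dominate individual-mode counts. Missing
calls are excluded from the denominator, never imputed.

`delimitInterval()` takes the ordered per-marker counts, finds the maximal
run of zero-recombinant markers, and brackets it with the nearest flanking
markers that show events. With several zero runs, the run with the lowest
total flanking events wins and the ambiguity is flagged; a run touching
the chromosome end yields an open-ended interval with a warning rather
than an invented boundary. The physical span is the inclusive bp
difference between flanking marker positions, treating each marker as a
point coordinate.

# The delta SNP-index scan

## Filters

`applyHardFilters()` reimplements the printed hard-filter expressions
downstream of the caller: SNPs fail on QD < 4 ∨ FS > 60 ∨ MQ < 40, indels
on QD < 4 ∨ FS > 200 ∨ ReadPosRankSum < −20 ∨ InbreedingCoeff < −0.8, and
a pool genotype with GQ < 20 is masked (its depths become missing) without
failing the site. A missing site statistic skips that criterion and flags
the record — the permissive semantics of the upstream tool. Every failing
record carries its reasons, and the run log checks conservation:
records in = records passed + Σ records failed per reason.

## Windows

The SNP index of a pool is alt/(alt+ref) depth, missing when depth is
zero or below `minDepth` (default 0). Windows are anchored at coordinate
1, advance by the step, and include sites by half-open [start, start+W);
defaults are the study conditions W = 2 Mb, step = 50 kb. Window means
are unweighted over the included non-missing site indices — "the average
SNP index of the SNPs" — not depth-weighted. Empty windows and windows
below `minSnps` propagate missing rather than zero; the final partial
window is kept and flagged. Means are computed per window with `mean()`
rather than running sums precisely so that results are bit-identical to a
brute-force recomputation (a property the tests assert on random inputs).

The delta track is Δ = mean(MT) − mean(WT) on the shared grid, and
`callCandidateRegions()` reports maximal runs of Δ ≥ threshold (inclusive,
so a noiseless single window at exactly 1.0 is called); a missing Δ breaks
a run. Lowering the threshold can only grow regions, which the tests check
as a monotonicity property. The threshold defaults to 1 — the expectation
for a NIL pair with a fixed causal block and error-free reads — but with
realistic sequencing error per-window deltas sit just below 1, so analysis
at ~0.9 is the practical choice and is what the parameter-recovery tests
use; a threshold of exactly 1 is documented as fragile off the noiseless
case.

# Candidate triage

`genesInInterval()` uses any-overlap semantics (boundary genes are
conventionally kept in fine mapping) and sorts by gene start.
`classifyEffect()` maps a genomic substitution to its CDS coordinate
across segments (minus-strand genes complement the substituted base),
rewrites the affected codon, and translates with the standard genetic
code; classes are synonymous, missense, nonsense, stop-loss, noncoding,
and splice-adjacent — defined as within 2 bp of a CDS segment boundary,
flagged rather than force-classified, since splice variants are otherwise
out of scope. The independent oracle in the tests re-translates the whole
mutated CDS and must agree on 100% of randomized cases on both strands.

The DEG rule is the printed one — unadjusted p ≤ 0.05 and |log2FC| ≥ 1,
closed inequalities — with an optional Benjamini–Hochberg adjustment left
to the user (`p.adjust`) because the motivating analysis used raw
p-values. Tier assignment is a pure function of (missense ≥ 1, DEG):
both → tier 1, one → tier 2, neither → tier 3, sorted by tier, then
decreasing missense count, then gene id. Homology between candidates is
deliberately outside the ranking.

The bundled example tables include the mapped soybean intervals (15 genes
on chromosome 14, 18 on chromosome 11) and the twelve coding variants of
the chromosome-11 interval. One published amino-acid conversion is spelt
"Val→Aal"; the table keeps the verbatim spelling alongside a normalized
"Val→Ala" column rather than silently correcting it.

# The synthetic-data generator

Because the underlying sequencing data of the motivating study are not
deposited, the generator recreates inputs with the statistical structure
the analysis assumes, with truth records for parameter recovery:

* **F2 / F2:3 populations** (`simulateF2`, `simulateF23Lines`): gametes
  per chromosome with crossovers under no interference, adjacent-position
  recombination fractions from the Haldane map function
  r = (1 − e^(−2d/100))/2. Haldane is the assumption-free default; no
  interference model is claimed. Progeny-test lines are classified
  deterministically (can the genotype self to a mutant?), which matches
  observed classification for any realistic family size.
* **NIL bulk pools** (`simulateNilPools`): one causal block fixed
  alternate in the MT pool and reference in the WT pool; residual
  heterozygous blocks (true frequency 0.5 in both pools) cover 5% of the
  rest of the genome in ~300 kb blocks; the isogenic remainder emits
  nothing. Depth is Poisson around 31 (the study's coverage), alternate
  counts binomial with allele frequency perturbed by a 0.5% error rate,
  and pools of 5 plants mirror the study design. Site statistics
  (QD/FS/MQ/GQ) are synthesized inside passing ranges, except a 2%
  injected fraction with failing QD — only threshold behaviour is under
  test, not a read-level model.
* **Toy genes** (`makeToyGenes`): random 1–3-exon ORFs (start codon, sense
  codons, stop) on both strands, emitted as gene models plus CDS, always
  translating cleanly.
* **DE tables** (`simulateDeTable`): true DEGs with |log2FC| ≥ 2 and
  p ≤ 0.01, nulls with log2FC ~ N(0, 0.3) and uniform p.

All generators are pure functions of their seed. What they deliberately do
**not** emulate: alignment artefacts, depth correlation along the genome,
multi-allelic and structural variation, expression-count overdispersion,
and linkage disequilibrium beyond the simulated map. Passing
parameter-recovery tests therefore show the pipeline's logic is correct
under its own model assumptions, not that real data will be as clean.

# Problem sizes and numerical choices

The test suite runs at desk scale, chosen to keep each property decisive
yet quick: segregation ratios at n = 10,000 simulated individuals (3
binomial SE bands), recombinant-count calibration over 200 seeds of
~570 mutants, interval coverage over 100 seeds of ~500 mutants, window
scans against brute force on 50+ random cases, 1,000 randomized variant
effects against whole-CDS re-translation, and 20-seed parameter-recovery
runs on a 20 Mb chromosome with a 1.5 Mb causal block at 30× depth
(coverage of the true causal midpoint ≥ 95%, end-to-end tier-1 recovery
of the planted gene ≥ 95%).

Numerical conventions collected in one place: exact integer arithmetic
for ratios; coordinates 1-based inclusive at all external interfaces (VCF
and GFF3 convention), half-open arithmetic only inside the window scan;
ties in model selection and zero-run choice broken deterministically;
degenerate ratios (an empty phenotype class) flagged, never dropped;
boundary values pass filters and DEG thresholds exactly as the printed
inequalities dictate (strict for filters, closed for DEG).

# Interfaces and limitations

The exported functions are the interface; `runPipeline()` orchestrates
the stages from a validated configuration list or YAML file (unknown keys
are rejected) and writes the window track (TSV), candidate regions (BED),
the candidate report (TSV) and a replayable run log (JSON with seed and
resolved configuration). Known limitations: no linkage between the two
causal loci is modelled (they are treated as unlinked, as the motivating
cross design implies); no confidence intervals on the SNP index; the
effect classifier handles single-base substitutions only; and marker
physical positions must be supplied — the package never invents them.
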