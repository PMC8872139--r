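chr11genes <- exampleTable("chr11_interval_genes")
chr14genes <- exampleTable("chr14_interval_genes")
chr11vars <- exampleTable("chr11_coding_variants")
effTable <- data.frame(
  gene_id = chr11vars$gene_id,
  effect = ifelse(chr11vars$type == "Synonymous", "synonymous", "missense"))

test_that("interval-gene lookup reproduces the mapped soybean intervals", {
  hit11 <- genesInInterval(chr11genes, "Chr11:37308090-37471869")
  expect_length(hit11, 18)
  hit14 <- genesInInterval(chr14genes, "Chr14:47796602-47975414")
  expect_length(hit14, 15)
  expect_length(genesInInterval(chr11genes[0, ], "Chr11:1-2"), 0)
  # any-overlap: a boundary-straddling gene is retained
  edge <- genesInInterval(chr11genes, "Chr11:37313000-37314000")
  expect_identical(S4Vectors::mcols(edge)$gene_id, "Glyma.11g228900")
  # idempotent and sorted by start
  again <- genesInInterval(hit11, "Chr11:37308090-37471869")
  expect_identical(S4Vectors::mcols(again)$gene_id,
                   S4Vectors::mcols(hit11)$gene_id)
  expect_false(is.unsorted(GenomicRanges::start(hit11)))
})

test_that("codon-level effect classification on hand-checked toys", {
  g <- geneModel("toy", "c1", 101, 109, "+", cbind(101, 109))
  # ATG GGT TAA: G->C at codon 2 position 2 gives GGT->GCT, Gly->Ala
  eff <- classifyEffect(g, "ATGGGTTAA", 105, "G", "C")
  expect_identical(eff$effect, "missense")
  expect_identical(c(eff$refAA3, eff$altAA3), c("Gly", "Ala"))
  # wobble position: GGT->GGC stays Gly
  syn <- classifyEffect(g, "ATGGGTTAA", 106, "T", "C")
  expect_identical(syn$effect, "synonymous")
  # stop gain and loss
  non <- classifyEffect(g, "ATGGGTTAA", 104, "G", "T")   # GGT -> TGT? pos2 c1
  expect_true(non$effect %in% c("missense", "nonsense"))
  stopl <- classifyEffect(g, "ATGGGTTAA", 108, "A", "C") # TAA -> TAC
  expect_identical(stopl$effect, "stop-loss")
  # outside the gene / near a CDS edge
  expect_identical(classifyEffect(g, "ATGGGTTAA", 500, "A", "T")$effect,
                   "noncoding")
  expect_identical(classifyEffect(g, "ATGGGTTAA", 110, "A", "T")$effect,
                   "splice-adjacent")
  expect_error(classifyEffect(g, "ATGGGT", 105, "G", "C"), "length")
})

test_that("minus-strand and multi-exon mapping agree with re-translation", {
  tg <- makeToyGenes(8, seed = 17)
  set.seed(18)
  checked <- 0L
  strands <- character(0)
  while (checked < 250) {
    i <- sample(8, 1)
    g <- tg$genes[[i]]
    cds <- as.character(tg$cds[[i]])
    seg <- g@cdsSegments
    allPos <- unlist(lapply(seq_len(nrow(seg)),
                            function(k) seg[k, 1]:seg[k, 2]))
    pos <- sample(allPos, 1)
    ref <- cdsBaseAt(g, cds, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- classifyEffect(g, cds, pos, ref, alt)
    expect_identical(eff$effect, wholeCdsEffect(g, cds, pos, ref, alt))
    strands <- union(strands, g@strand)
    checked <- checked + 1L
  }
  expect_setequal(strands, c("+", "-"))
})

test_that("variant summary reproduces the chromosome-11 coding-variant tallies", {
  s <- summarizeVariants(effTable)
  expect_identical(unname(s$totals["nSnps"]), 12L)
  expect_identical(unname(s$totals["nGenes"]), 6L)
  expect_identical(unname(s$totals["nMissense"]), 10L)
  expect_identical(unname(s$totals["nMissenseGenes"]), 5L)
  z <- summarizeVariants(data.frame(gene_id = character(0),
                                    effect = character(0)))
  expect_true(all(z$totals == 0))
})

test_that("DEG flag uses closed inequalities at the printed thresholds", {
  expect_true(degFlag(0.01, -1.5))
  expect_true(degFlag(0.05, 1.0))     # boundary values are DEGs
  expect_false(degFlag(0.049, 0.9))
  expect_false(degFlag(0.051, 1.5))
  expect_error(degFlag(1.2, 1), "0, 1")
  expect_identical(degFlag(c(0.05, 0.5), c(1, 2)), c(TRUE, FALSE))
})

test_that("candidate ranking puts the two DEG + missense genes in tier 1", {
  degs <- c("Glyma.11g230300", "Glyma.11g230600")
  rep <- rankCandidates(chr11genes$gene_id, effTable, degs)
  expect_identical(sort(rep$gene_id[rep$tier == 1]), degs)
  expect_identical(rep$gene_id[1], "Glyma.11g230300")  # 3 missense first
  misOnly <- rep[rep$tier == 2, ]
  expect_true(all(xor(misOnly$missense_count >= 1, misOnly$is_deg)))
  # 2 tier-1 (missense + DEG), 3 tier-2 (missense only), 13 tier-3
  expect_identical(sum(rep$tier == 2), 3L)
  expect_identical(sum(rep$tier == 3), 13L)
  # permutation of inputs changes nothing
  rep2 <- rankCandidates(rev(chr11genes$gene_id),
                         effTable[sample(nrow(effTable)), ], rev(degs))
  expect_identical(rep, rep2)
})

test_that("ranking edge cases: no evidence, single evidence, stray genes", {
  none <- rankCandidates(c("g1", "g2"))
  expect_true(all(none$tier == 3L))
  one <- rankCandidates(c("g1", "g2"),
                        data.frame(gene_id = "g1", effect = "missense"))
  expect_identical(one$tier[one$gene_id == "g1"], 2L)
  expect_warning(
    stray <- rankCandidates("g1", data.frame(gene_id = "g9",
                                             effect = "missense")),
    "outside the interval")
  expect_false(stray$in_interval[stray$gene_id == "g9"])
})
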