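dup <- epistasisModel("duplicate_recessive_mutant")
mono <- epistasisModel("monogenic_recessive")

twoLocusMap <- function() {
  mk <- data.frame(name = c("m1", "m2", "m3"),
                   chrom = c("c1", "c1", "c2"),
                   cM = c(0, 30, 0), bp = c(1e5, 3e6, 1e5))
  cl <- data.frame(name = c("L1", "L2"), chrom = c("c1", "c2"),
                   cM = c(10, 40), bp = c(1e6, 4e6), locus = c("1", "2"))
  geneticMap(mk, cl)
}

test_that("generators are pure functions of the seed", {
  map <- twoLocusMap()
  a <- simulateF2(map, 200, dup, seed = 5)
  b <- simulateF2(map, 200, dup, seed = 5)
  expect_identical(genotypeCalls(a$table), genotypeCalls(b$table))
  expect_identical(a$phenotypes, b$phenotypes)
  c <- simulateF2(map, 200, dup, seed = 6)
  expect_false(identical(a$phenotypes, c$phenotypes))

  n1 <- simulateNilPools(chromLengths = c(x = 2e6), causalStart = 5e5,
                         causalEnd = 1e6, seed = 3)
  n2 <- simulateNilPools(chromLengths = c(x = 2e6), causalStart = 5e5,
                         causalEnd = 1e6, seed = 3)
  expect_identical(n1$sites, n2$sites)

  d1 <- simulateDeTable(500, 0.1, seed = 8)
  d2 <- simulateDeTable(500, 0.1, seed = 8)
  expect_identical(d1, d2)

  t1 <- makeToyGenes(4, seed = 2)
  t2 <- makeToyGenes(4, seed = 2)
  expect_identical(as.character(t1$cds), as.character(t2$cds))
})

test_that("simulated F2 populations match Mendelian expectations at n = 10000", {
  map <- twoLocusMap()
  f2 <- simulateF2(map, 10000, dup, seed = 42)
  # mutant fraction within 3 binomial SE of 1/16
  p <- 1 / 16
  expect_lt(abs(mean(f2$phenotypes == "mutant") - p),
            3 * sqrt(p * (1 - p) / 10000))
  # unlinked marker segregates 1:2:1 within 3 SE per class
  calls <- genotypeCalls(f2$table)[, "m3"]
  for (cl in c("P1", "H", "P2")) {
    q <- if (cl == "H") 0.5 else 0.25
    expect_lt(abs(mean(calls == cl) - q), 3 * sqrt(q * (1 - q) / 10000))
  }
  # progeny test: segregating fraction within 3 SE of 8/15
  lines <- simulateF23Lines(f2, dup)
  q <- 8 / 15
  expect_lt(abs(mean(lines$segregating) - q),
            3 * sqrt(q * (1 - q) / nrow(lines)))
  # a line homozygous wild-type at both loci never segregates
  expect_true(all(!lines$segregating[lines$class == "AA:AA"]))
})

test_that("a marker coincident with the causal locus shows no recombination", {
  mk <- data.frame(name = "m0", chrom = "c1", cM = 10, bp = 1e6 + 1)
  cl <- data.frame(name = "L1", chrom = "c1", cM = 10, bp = 1e6,
                   locus = "1")
  map <- geneticMap(mk, cl)
  f2 <- simulateF2(map, 3000, mono, seed = 12)
  mut <- f2$phenotypes == "mutant"
  expect_true(all(genotypeCalls(f2$table)[mut, "m0"] == "P2"))
})

test_that("noiseless NIL pools are fixed and isogenic background is silent", {
  sim <- simulateNilPools(chromLengths = c(x = 1e7), causalStart = 4e6,
                          causalEnd = 5.5e6, errorRate = 0,
                          failFraction = 0, seed = 9)
  s <- sim$sites
  causal <- s$pos >= 4e6 & s$pos <= 5.5e6
  expect_true(any(causal))
  expect_true(all(snpIndex(s$mtRef[causal], s$mtAlt[causal]) == 1))
  expect_true(all(snpIndex(s$wtRef[causal], s$wtAlt[causal]) == 0))
  # every emitted site lies in the causal block or a het block
  inHet <- Reduce(`|`, lapply(sim$truth$hetBlocks, function(b)
    s$chrom == b$chrom & s$pos >= b$start & s$pos <= b$end), rep(FALSE, nrow(s)))
  expect_true(all(causal | inHet))
  # het-block sites hover around index 0.5 in both pools
  expect_lt(abs(mean(snpIndex(s$wtRef[inHet], s$wtAlt[inHet]),
                     na.rm = TRUE) - 0.5), 0.05)
})

test_that("injected low-QD records all fail the hard filters downstream", {
  sim <- simulateNilPools(chromLengths = c(x = 5e6), causalStart = 1e6,
                          causalEnd = 2e6, failFraction = 0.3, seed = 4)
  f <- applyHardFilters(sim$sites)
  injected <- f$pos %in% sim$truth$injectedFailPos
  expect_true(any(injected))
  expect_true(all(!f$filterPass[injected]))
  expect_true(all(grepl("QD", f$filterReasons[injected])))
  expect_true(all(f$filterPass[!injected]))
})

test_that("DE generator: null table yields no true DEGs and few false flags", {
  d0 <- simulateDeTable(2000, degFraction = 0, seed = 14)
  expect_length(d0$truth$degIds, 0)
  flags <- degFlag(d0$table$pvalue, d0$table$log2fc)
  # false positives need p <= 0.05 AND |lfc| >= 1 (3.3 sigma): rare
  expect_lt(mean(flags), 0.005)
})

test_that("DE generator: strong effects are recovered with high recall", {
  recall <- vapply(1:20, function(s) {
    d <- simulateDeTable(500, degFraction = 0.1, lfcEffect = 2, seed = s)
    flags <- degFlag(d$table$pvalue, d$table$log2fc)
    mean(d$truth$degIds %in% d$table$gene_id[flags])
  }, numeric(1))
  expect_gte(mean(recall), 0.95)
})

test_that("toy genes always carry valid ORFs", {
  tg <- makeToyGenes(10, seed = 33)
  for (i in seq_along(tg$genes)) {
    cds <- tg$cds[[i]]
    expect_identical(length(cds) %% 3L, 0L)
    aa <- as.character(Biostrings::translate(cds))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*.", aa))            # no internal stop
    expect_identical(nchar(as.character(cds)), cdsLength(tg$genes[[i]]))
  }
})
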