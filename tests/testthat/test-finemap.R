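mono <- epistasisModel("monogenic_recessive")

makeMutantTable <- function(callCols, markers = NULL) {
  calls <- do.call(cbind, callCols)
  if (is.null(markers))
    markers <- data.frame(name = names(callCols), chrom = "c1",
                          bp = seq_len(ncol(calls)) * 1e6)
  markerGenotypeTable(calls, markers)
}

test_that("bulk profile screening follows the fixed-mutant-bulk rule", {
  prof <- data.frame(marker = c("m1", "m2", "m3"),
                     MT = c("P2", "P1,P2", "P2"),
                     WT = c("P1,P2", "P1,P2", "P2"))
  expect_identical(bsaMarkerScreen(prof), "m1")
  expect_error(bsaMarkerScreen(data.frame(marker = "x", MT = "", WT = "P1")),
               "at least one allele")
})

test_that("an unlinked marker is rarely flagged in simulated 10+10 bulks", {
  map <- mapWithMarkersAt(50)   # 50 cM from the causal locus
  flagged <- 0L
  for (s in 1:200) {
    f2 <- simulateF2(map, 80, mono, seed = 9000 + s)
    mut <- which(f2$phenotypes == "mutant")[1:10]
    wld <- which(f2$phenotypes == "wild-type")[1:10]
    if (anyNA(mut) || anyNA(wld)) next
    prof <- poolProfiles(f2$table, f2$table@individuals[mut],
                         f2$table@individuals[wld])
    flagged <- flagged + (length(bsaMarkerScreen(prof)) > 0)
  }
  expect_lt(flagged / 200, 0.10)
})

test_that("recombinant counting per marker follows the counting mode", {
  tbl <- makeMutantTable(list(
    mA = rep("P2", 42),
    mB = c("H", rep("P2", 41)),
    mC = c("P1", "H", rep("P2", 39), NA)))
  expect_identical(countRecombinants(tbl, "mA")$events, 0L)
  expect_identical(countRecombinants(tbl, "mB")$events, 1L)
  expect_identical(countRecombinants(tbl, "mB", "individuals")$events, 1L)
  cC <- countRecombinants(tbl, "mC")
  expect_identical(cC$events, 3L)           # P1 = 2, H = 1
  expect_identical(cC$individualsCounted, 41L)  # NA excluded
  expect_identical(countRecombinants(tbl, "mC", "individuals")$events, 2L)
  expect_error(countRecombinants(tbl, "nope"), "not present")
})

test_that("counts are permutation-invariant and chromosome mode dominates", {
  set.seed(21)
  for (i in 1:20) {
    n <- 30
    calls <- matrix(sample(c("P1", "P2", "H", NA), n * 3, TRUE,
                           prob = c(.1, .7, .15, .05)), n, 3)
    colnames(calls) <- c("x", "y", "z")
    tbl <- markerGenotypeTable(
      calls, data.frame(name = c("x", "y", "z"), chrom = "c1",
                        bp = c(1, 2, 3) * 1e5))
    perm <- markerGenotypeTable(
      calls[sample(n), ], data.frame(name = c("x", "y", "z"), chrom = "c1",
                                     bp = c(1, 2, 3) * 1e5))
    for (mk in c("x", "y", "z")) {
      a <- countRecombinants(tbl, mk)
      b <- countRecombinants(perm, mk)
      expect_identical(a$events, b$events)
      expect_gte(a$events, countRecombinants(tbl, mk, "individuals")$events)
    }
  }
})

test_that("mean recombinant count matches the binomial expectation and grows with distance", {
  # markers at 0.5025 cM (r = 0.005) and increasing distances
  dists <- c(-50 * log(1 - 2 * 0.005), seq(2, 20, by = 2))
  map <- mapWithMarkersAt(dists)
  totEvents <- numeric(length(dists))
  totChrom <- 0
  for (s in 1:200) {
    f2 <- simulateF2(map, 2292, mono, seed = 100 + s)
    mut <- f2$phenotypes == "mutant"
    sub <- markerGenotypeTable(genotypeCalls(f2$table)[mut, , drop = FALSE],
                               markerInfo(f2$table))
    counts <- countRecombinantsAll(sub)
    totEvents <- totEvents + counts$events
    totChrom <- totChrom + 2 * sum(mut)
  }
  # binomial oracle at the near marker: events ~ Binom(2*nMut, 0.005)
  expN <- totChrom * 0.005
  expect_lt(abs(totEvents[1] - expN), 3 * sqrt(expN * 0.995))
  # monotone increase with genetic distance
  expect_gt(cor(dists, totEvents, method = "spearman"), 0.9)
})

test_that("interval delimitation brackets the zero-recombinant run", {
  counts <- data.frame(marker = c("A", "B", "C"), chrom = "Chr14",
                       bp = c(1e6, 2e6, 3e6), events = c(2L, 0L, 7L))
  iv <- delimitInterval(counts)
  expect_identical(S4Vectors::mcols(iv)$leftMarker, "A")
  expect_identical(S4Vectors::mcols(iv)$rightMarker, "C")
  expect_identical(S4Vectors::mcols(iv)$spanBp, 2e6 + 1)
  expect_identical(S4Vectors::mcols(iv)$zeroMarkers, "B")

  run <- data.frame(marker = paste0("m", 1:4), chrom = "c1",
                    bp = (1:4) * 1e6, events = c(1L, 0L, 0L, 3L))
  iv2 <- delimitInterval(run)
  expect_identical(GenomicRanges::start(iv2), 1000000L)
  expect_identical(GenomicRanges::end(iv2), 4000000L)

  expect_error(delimitInterval(transform(run, events = c(1L, 2L, 1L, 3L))),
               "not bracketed")
  expect_warning(
    open <- delimitInterval(transform(run, events = c(0L, 0L, 1L, 3L))),
    "open-ended")
  expect_true(S4Vectors::mcols(open)$openLeft)

  # two zero runs: the one with lower flanking totals wins
  two <- data.frame(marker = paste0("m", 1:5), chrom = "c1",
                    bp = (1:5) * 1e6, events = c(9L, 0L, 5L, 0L, 1L))
  iv3 <- delimitInterval(two)
  expect_identical(S4Vectors::mcols(iv3)$zeroMarkers, "m4")
  # interval always contains every zero marker of the chosen run
  expect_true(GenomicRanges::start(iv3) <= 4e6 &&
                GenomicRanges::end(iv3) >= 4e6)
})

test_that("delimited intervals cover the true causal position in simulation", {
  # flanking markers far enough to always recombine, near markers tight
  # enough that ~500 mutants usually leave them recombinant-free
  dists <- c(8, 10.29, 10.31, 12)
  map <- mapWithMarkersAt(dists, causalAt = 10.3)
  truthBp <- 1e5 + 10.3e6 + 1
  hits <- 0L
  for (s in 1:100) {
    f2 <- simulateF2(map, 2000, mono, seed = 500 + s)
    mut <- f2$phenotypes == "mutant"
    sub <- markerGenotypeTable(genotypeCalls(f2$table)[mut, , drop = FALSE],
                               markerInfo(f2$table))
    counts <- countRecombinantsAll(sub)
    iv <- tryCatch(suppressWarnings(delimitInterval(counts)),
                   error = function(e) NULL)
    if (!is.null(iv) &&
        GenomicRanges::start(iv) <= truthBp &&
        GenomicRanges::end(iv) >= truthBp)
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
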