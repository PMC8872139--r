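oneSite <- function(...) {
  base <- list(chrom = "c1", pos = 100, ref = "A", alt = "T",
               isIndel = FALSE, wtRef = 10, wtAlt = 10, mtRef = 10,
               mtAlt = 10, QD = 20, FS = 5, MQ = 50, ReadPosRankSum = 0,
               InbreedingCoeff = 0, gqWT = 60, gqMT = 60)
  as.data.frame(modifyList(base, list(...)))
}

test_that("hard filters implement the printed threshold expressions", {
  f <- applyHardFilters(oneSite(QD = 3.9, FS = 10, MQ = 50))
  expect_false(f$filterPass)
  expect_identical(f$filterReasons, "QD")

  expect_true(applyHardFilters(oneSite(QD = 10))$filterPass)
  expect_false(applyHardFilters(oneSite(FS = 60.1))$filterPass)
  expect_false(applyHardFilters(oneSite(MQ = 39.9))$filterPass)
  # boundary values pass (strict inequalities in the filter expression)
  expect_true(applyHardFilters(oneSite(QD = 4, FS = 60, MQ = 40))$filterPass)

  ind <- applyHardFilters(oneSite(isIndel = TRUE, ReadPosRankSum = -25))
  expect_false(ind$filterPass)
  expect_identical(ind$filterReasons, "ReadPosRankSum")
  # SNP-only MQ criterion does not apply to indels; indel FS bound is 200
  expect_true(applyHardFilters(oneSite(isIndel = TRUE, MQ = 10,
                                       FS = 150))$filterPass)
  expect_false(applyHardFilters(oneSite(isIndel = TRUE,
                                        InbreedingCoeff = -0.9))$filterPass)
})

test_that("low GQ masks the pool without failing the site; missing stats flag", {
  f <- applyHardFilters(oneSite(gqWT = 10))
  expect_true(f$filterPass)
  expect_true(f$wtMasked)
  expect_false(f$mtMasked)
  miss <- applyHardFilters(oneSite(QD = NA))
  expect_true(miss$filterPass)     # permissive: missing stat is skipped
  expect_true(miss$statMissing)
})

test_that("filter decisions are order-invariant and every fail has a reason", {
  sites <- randomSiteTable(200, 1e6, seed = 31)
  sites$QD[sample(200, 30)] <- runif(30, 0, 3.9)
  a <- applyHardFilters(sites)
  perm <- sample(200)
  b <- applyHardFilters(sites[perm, ])
  expect_identical(a$filterPass[perm], b$filterPass)
  expect_identical(a$filterReasons[perm], b$filterReasons)
  expect_true(all(nzchar(a$filterReasons[!a$filterPass])))
  fs <- filterSummary(a)
  expect_identical(fs$recordsIn,
                   fs$recordsPassed + sum(fs$failedByReason))
})

test_that("snpIndex is alt fraction with missing-depth semantics", {
  expect_identical(snpIndex(0, 31), 1)
  expect_identical(snpIndex(31, 0), 0)
  expect_identical(snpIndex(10, 10), 0.5)
  expect_true(is.na(snpIndex(0, 0)))
  expect_true(is.na(snpIndex(3, 2, minDepth = 10)))
  expect_error(snpIndex(-1, 5), "negative")
  set.seed(4)
  idx <- snpIndex(rpois(100, 10), rpois(100, 10))
  expect_true(all(idx >= 0 & idx <= 1, na.rm = TRUE))
})

test_that("window scan equals brute-force recomputation on random inputs", {
  set.seed(77)
  for (case in 1:60) {
    n <- sample(0:80, 1)
    len <- sample(5e4:5e5, 1)
    cfg <- scanConfig(windowSize = sample(c(1e4, 2.5e4, 7e4), 1),
                      step = sample(c(2e3, 5e3, 1e4), 1),
                      deltaThreshold = 0.9,
                      minSnps = sample(1:3, 1))
    pos <- sort(sample.int(len, n, replace = TRUE))
    val <- runif(n)
    val[runif(n) < 0.15] <- NA
    mine <- windowScan(pos, val, len, cfg)
    ref <- bruteWindowScan(pos, val, len, cfg)
    expect_identical(mine$nSnps, ref$nSnps)
    expect_identical(mine$start, ref$start)
    expect_identical(mine$end, ref$end)
    expect_equal(mine$mean, ref$mean)      # bitwise-comparable sums
    expect_identical(mine$partial, ref$partial)
  }
  expect_error(windowScan(c(5, 1), c(0, 1), 100, scanConfig(10, 5, 1)),
               "sorted")
})

test_that("single-site and constant tracks behave trivially", {
  cfg <- scanConfig(windowSize = 1e4, step = 1e4, deltaThreshold = 1)
  w <- windowScan(25000, 0.7, 5e4, cfg)
  expect_identical(w$mean, c(NA, NA, 0.7, NA, NA))
  expect_identical(w$nSnps[3], 1L)
  pos <- seq(500, 99500, length.out = 100)
  u <- windowScan(pos, rep(0.5, 100), 1e5, scanConfig(2e4, 5e3, 1))
  expect_true(all(u$mean[u$nSnps > 0] == 0.5))
})

test_that("delta track subtracts pool means on a shared grid", {
  cfg <- scanConfig(1e4, 1e4, 1)
  wt <- windowScan(c(2000, 12000), c(0, 0), 2e4, cfg)
  mt <- windowScan(c(2000, 12000), c(1, 0.4), 2e4, cfg)
  d <- deltaTrack(wt, mt)
  expect_identical(d$delta, c(1, 0.4))
  expect_true(all(abs(d$delta) <= 1, na.rm = TRUE))
  bad <- windowScan(c(2000), c(1), 3e4, cfg)
  expect_error(deltaTrack(wt, bad), "grids")
  same <- deltaTrack(wt, wt)
  expect_true(all(same$delta == 0, na.rm = TRUE))
})

test_that("candidate regions are maximal threshold runs, inclusive", {
  tr <- data.frame(chrom = "c1", start = seq(1, 41, 10),
                   end = seq(10, 50, 10),
                   delta = c(0, 1.0, NA, 1.0, 0.2))
  none <- callCandidateRegions(transform(tr, delta = 0), 1)
  expect_length(none, 0)
  reg <- callCandidateRegions(tr, 1.0)
  expect_length(reg, 2)               # NA breaks the run
  expect_identical(GenomicRanges::start(reg), c(11L, 31L))
  expect_identical(GenomicRanges::end(reg), c(20L, 40L))
  expect_identical(S4Vectors::mcols(reg)$peakDelta, c(1, 1))
})

test_that("lowering the threshold never shrinks called regions", {
  set.seed(13)
  for (i in 1:20) {
    tr <- data.frame(chrom = "c1", start = seq(1, 191, 10),
                     end = seq(10, 200, 10),
                     delta = round(runif(20, -0.2, 1.2), 2))
    tr$delta[runif(20) < 0.1] <- NA
    hi <- callCandidateRegions(tr, 0.9)
    lo <- callCandidateRegions(tr, 0.5)
    if (length(hi) == 0) next
    cov <- GenomicRanges::findOverlaps(hi, lo, type = "within")
    expect_identical(S4Vectors::queryHits(cov), seq_along(hi))
  }
})
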