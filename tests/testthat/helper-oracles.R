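# Independent oracles used across test files. These re-derive expected
# values by brute force, through a different route than the implementation.

# Enumerate all ordered gamete combinations of a selfed (double)
# heterozygote: per locus the two parental alleles combine in 2x2 ordered
# ways, so a two-locus F2 is 16 equally likely ordered genotype
# combinations. Returns phenotype counts under the model's map.
bruteGametePhenotypes <- function(model) {
  gametes1 <- c("A", "a")
  combo <- function() {
    g <- expand.grid(m = gametes1, p = gametes1, stringsAsFactors = FALSE)
    code <- function(m, p) {
      n <- sum(c(m, p) == "a")
      c("AA", "Aa", "aa")[n + 1]
    }
    mapply(code, g$m, g$p)
  }
  if (model@nLoci == 1L) {
    cls <- combo()
  } else if (length(model@fixedBackground)) {
    fb <- model@fixedBackground
    segCls <- combo()
    cls <- if (fb[["locus"]] == "1")
      paste(fb[["genotype"]], segCls, sep = ":")
    else paste(segCls, fb[["genotype"]], sep = ":")
  } else {
    cls <- as.vector(outer(combo(), combo(), paste, sep = ":"))
  }
  table(factor(unname(model@phenoMap[cls]),
               levels = c("wild-type", "mutant")))
}

# Brute-force sliding-window recomputation: explicit loop over windows,
# half-open inclusion, unweighted mean of non-missing values.
bruteWindowScan <- function(positions, values, chromLength, config) {
  W <- config@windowSize; s <- config@step
  starts <- seq(1, chromLength, by = s)
  res <- lapply(starts, function(st) {
    inWin <- positions >= st & positions < st + W
    v <- values[inWin]
    nAll <- sum(inWin)
    m <- if (nAll < config@minSnps || all(is.na(v))) NA_real_
    else mean(v, na.rm = TRUE)
    data.frame(start = st, end = min(st + W - 1, chromLength),
               nSnps = nAll, mean = m,
               partial = (st + W - 1) > chromLength)
  })
  do.call(rbind, res)
}

# Whole-CDS re-translation oracle for variant effect classes.
wholeCdsEffect <- function(gene, cds, pos, ref, alt) {
  cp <- digenicBSA:::.cdsCoord(gene, pos)
  if (is.na(cp)) return(NA_character_)
  altC <- if (gene@strand == "+") alt else digenicBSA:::.complement[[alt]]
  mut <- cds
  substr(mut, cp, cp) <- altC
  tr <- function(x) as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(x), no.init.codon = TRUE)))
  aaR <- strsplit(tr(cds), "")[[1]]
  aaM <- strsplit(tr(mut), "")[[1]]
  d <- which(aaR != aaM)
  if (length(d) == 0) return("synonymous")
  if (aaM[d] == "*") return("nonsense")
  if (aaR[d] == "*") return("stop-loss")
  "missense"
}

# A small genetic map: one causal locus at 0 cM plus markers at the given
# distances (cM) along one chromosome, bp = 1e5 + cM * 1e6.
mapWithMarkersAt <- function(dists, causalAt = 0) {
  mk <- data.frame(name = sprintf("mk%02d", seq_along(dists)),
                   chrom = "c1", cM = dists, bp = 1e5 + dists * 1e6)
  cl <- data.frame(name = "L1", chrom = "c1", cM = causalAt,
                   bp = 1e5 + causalAt * 1e6 + 1, locus = "1")
  geneticMap(mk, cl)
}

randomSiteTable <- function(n, chromLength, seed) {
  set.seed(seed)
  pos <- sort(sample.int(chromLength, n))
  data.frame(chrom = "c1", pos = pos, ref = "A", alt = "T",
             isIndel = FALSE,
             wtRef = rpois(n, 15), wtAlt = rpois(n, 15),
             mtRef = rpois(n, 15), mtAlt = rpois(n, 15),
             QD = runif(n, 5, 30), FS = runif(n, 0, 50),
             MQ = runif(n, 41, 60),
             ReadPosRankSum = runif(n, -3, 3),
             InbreedingCoeff = runif(n, -0.5, 0.9),
             gqWT = sample(30:99, n, TRUE), gqMT = sample(30:99, n, TRUE))
}
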