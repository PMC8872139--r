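#' Haldane map function
#'
#' Recombination fraction between two positions separated by \code{d}
#' centimorgans, assuming crossovers arrive as a Poisson process with no
#' interference: \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param dcM map distance in cM (vectorized, non-negative).
#' @return recombination fractions in [0, 0.5).
#' @export
haldane <- function(dcM) {
  stopifnot(all(dcM >= 0))
  (1 - exp(-2 * dcM / 100)) / 2
}

## One gamete per individual per chromosome: matrix n x m of parental
## origins (0 = P1, 1 = P2) at the ordered cM positions.
.simGametes <- function(n, cM) {
  m <- length(cM)
  g <- matrix(0L, n, m)
  g[, 1] <- rbinom(n, 1L, 0.5)
  if (m > 1) {
    r <- haldane(diff(cM))
    for (j in 2:m) {
      swap <- rbinom(n, 1L, r[j - 1])
      g[, j] <- bitwXor(g[, j - 1], swap)
    }
  }
  g
}

.codeFromDose <- function(d) c("AA", "Aa", "aa")[d + 1L]

#' Simulate an F2 population on a genetic map
#'
#' Gametes are generated per chromosome with crossovers under no
#' interference (Haldane map function between adjacent positions); two
#' independent gametes form each F2 individual. Genotypes are recorded at
#' every map position; phenotypes are assigned from the genotypes at the
#' causal loci through the epistasis model (the mutant-parent allele is
#' the recessive one, so dose 2 at a causal locus is \code{"aa"}).
#'
#' @param map a \code{GeneticMap} whose causal loci cover the model's loci.
#' @param n number of F2 individuals.
#' @param model an \code{EpistasisModel} (no fixed background:
#'   the simulated cross segregates at every causal locus on the map).
#' @param seed integer seed (mandatory; the output is a pure function of
#'   it).
#' @return list: \code{table} (\code{MarkerGenotypeTable} at the marker
#'   positions), \code{phenotypes} (character), \code{causalGenotypes}
#'   (data.frame of per-locus codes), \code{truth} (list with the map,
#'   seed and per-individual causal doses).
#' @export
simulateF2 <- function(map, n, model, seed) {
  validObject(map); validObject(model)
  stopifnot(n >= 1, is.finite(seed))
  set.seed(seed)
  pos <- map@positions
  loci <- sort(unique(pos$causalLocus[!is.na(pos$causalLocus)]))
  need <- as.character(seq_len(model@nLoci))
  if (!all(need %in% loci))
    stop("map must carry causal locus/loci ", paste(need, collapse = ","))

  dose <- matrix(0L, n, nrow(pos))
  for (ch in unique(pos$chrom)) {
    jj <- which(pos$chrom == ch)
    dose[, jj] <- .simGametes(n, pos$cM[jj]) + .simGametes(n, pos$cM[jj])
  }
  colnames(dose) <- pos$name

  causal <- pos$name[match(need, pos$causalLocus)]
  geno <- as.data.frame(lapply(causal, function(nm)
    .codeFromDose(dose[, nm])), col.names = paste0("locus", need))
  cls <- if (model@nLoci == 1L) geno$locus1 else
    paste(geno$locus1, geno$locus2, sep = ":")
  phen <- unname(model@phenoMap[cls])

  mk <- which(is.na(pos$causalLocus))
  calls <- matrix(c("P1", "H", "P2")[dose[, mk, drop = FALSE] + 1L],
                  nrow = n)
  tbl <- markerGenotypeTable(
    calls, data.frame(name = pos$name[mk], chrom = pos$chrom[mk],
                      bp = pos$bp[mk], cM = pos$cM[mk]),
    individuals = sprintf("F2_%05d", seq_len(n)))
  list(table = tbl, phenotypes = phen, causalGenotypes = geno,
       truth = list(seed = seed, map = pos, causalDose = dose[, causal,
                                                             drop = FALSE]))
}

#' Progeny-test F2:3 lines derived from F2 wild-type individuals
#'
#' Each selected F2 wild-type individual is selfed; its line is classified
#' as segregating iff its genotype class can produce at least one
#' mutant-phenotype progeny genotype (deterministic classification — with
#' the family sizes used in progeny tests the expected mutant count in a
#' segregating line is far from zero, so possibility and observation
#' coincide for all practical purposes).
#'
#' @param f2 output of \code{simulateF2}.
#' @param model the \code{EpistasisModel} used for the cross.
#' @param nLines number of wild-type F2 plants to harvest (default all);
#'   the first \code{nLines} in individual order are taken, mirroring
#'   random harvesting of an unordered field population.
#' @return data.frame: individual, genotype class, segregating (logical).
#' @export
simulateF23Lines <- function(f2, model, nLines = NULL) {
  wt <- which(f2$phenotypes == "wild-type")
  if (!is.null(nLines)) wt <- wt[seq_len(min(nLines, length(wt)))]
  geno <- f2$causalGenotypes[wt, , drop = FALSE]
  cls <- if (model@nLoci == 1L) geno$locus1 else
    paste(geno$locus1, geno$locus2, sep = ":")
  seg <- vapply(cls, .selfSegregates, logical(1), model = model,
                USE.NAMES = FALSE)
  data.frame(individual = f2$table@individuals[wt], class = cls,
             segregating = seg, stringsAsFactors = FALSE)
}

#' Simulate near-isogenic bulk-pool variant calls
#'
#' Emulates pool sequencing of a NIL pair differing only around a causal
#' block: inside the block the mutant pool is fixed for the alternate
#' allele and the wild-type pool for the reference; residual heterozygous
#' background blocks (true allele frequency 0.5 in both pools) cover a
#' configurable fraction of the rest of the genome; the isogenic remainder
#' emits no variants. Per site, pool depth is Poisson around
#' \code{meanDepth} and the alternate read count binomial with allele
#' frequency perturbed by the sequencing error rate. Site statistics are
#' synthesized inside passing ranges except for an injected fraction of
#' filter-failing records.
#'
#' @param chromLengths named numeric vector (default one 39.2 Mb
#'   chromosome emulating soybean chromosome 11).
#' @param causalChrom,causalStart,causalEnd causal block (defaults: the
#'   36.26--37.94 Mb region).
#' @param meanDepth mean pool depth (default 31).
#' @param errorRate per-read error rate (default 0.005).
#' @param snpDensity variant sites per bp within variant-bearing blocks
#'   (default 1e-4, one per 10 kb).
#' @param hetFraction fraction of the off-block genome in residual
#'   heterozygous blocks (default 0.05).
#' @param hetBlockSize residual block size in bp (default 3e5).
#' @param failFraction fraction of sites injected with a failing QD
#'   (default 0.02).
#' @param seed integer seed (mandatory).
#' @return list: \code{sites} (pooled variant site table as consumed by
#'   \code{applyHardFilters}/\code{scanDeltaIndex}), \code{truth} (causal
#'   block, het blocks, injected-fail positions, seed),
#'   \code{chromLengths}.
#' @export
simulateNilPools <- function(chromLengths = c(Chr11 = 39.2e6),
                             causalChrom = names(chromLengths)[1],
                             causalStart = 36.26e6, causalEnd = 37.94e6,
                             meanDepth = 31, errorRate = 0.005,
                             snpDensity = 1e-4, hetFraction = 0.05,
                             hetBlockSize = 3e5, failFraction = 0.02,
                             seed) {
  stopifnot(is.finite(seed), causalStart < causalEnd,
            causalEnd <= chromLengths[[causalChrom]])
  set.seed(seed)
  bases <- c("A", "C", "G", "T")

  ## residual heterozygous blocks, placed off the causal block
  hetBlocks <- list()
  for (ch in names(chromLengths)) {
    len <- chromLengths[[ch]]
    offLen <- len - if (ch == causalChrom) (causalEnd - causalStart) else 0
    nb <- floor(hetFraction * offLen / hetBlockSize)
    placed <- 0L; tries <- 0L
    while (placed < nb && tries < 50L * nb) {
      tries <- tries + 1L
      s <- floor(runif(1, 1, len - hetBlockSize))
      e <- s + hetBlockSize - 1
      if (ch == causalChrom && s <= causalEnd && e >= causalStart) next
      clash <- any(vapply(hetBlocks, function(b)
        b$chrom == ch && s <= b$end && e >= b$start, logical(1)))
      if (clash) next
      hetBlocks[[length(hetBlocks) + 1L]] <-
        list(chrom = ch, start = s, end = e)
      placed <- placed + 1L
    }
  }

  blockSites <- function(chrom, start, end, freq) {
    len <- end - start + 1
    k <- rpois(1, len * snpDensity)
    if (k == 0) return(NULL)
    pos <- sort(sample.int(len, min(k, len))) + start - 1
    data.frame(chrom = chrom, pos = pos, trueFreq = freq)
  }
  sites <- do.call(rbind, c(
    list(blockSites(causalChrom, causalStart, causalEnd, 1.0)),
    lapply(hetBlocks, function(b)
      blockSites(b$chrom, b$start, b$end, 0.5))))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  n <- nrow(sites)
  rownames(sites) <- NULL

  sites$ref <- sample(bases, n, replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(bases, r), 1), character(1))
  sites$isIndel <- FALSE

  draw <- function(freq) {
    dp <- rpois(n, meanDepth)
    fObs <- freq * (1 - errorRate) + (1 - freq) * errorRate
    alt <- rbinom(n, dp, fObs)
    cbind(ref = dp - alt, alt = alt)
  }
  wt <- draw(ifelse(sites$trueFreq == 1, 0, sites$trueFreq))
  mt <- draw(sites$trueFreq)
  sites$wtRef <- wt[, "ref"]; sites$wtAlt <- wt[, "alt"]
  sites$mtRef <- mt[, "ref"]; sites$mtAlt <- mt[, "alt"]

  ## site statistics inside passing ranges ...
  sites$QD <- runif(n, 10, 30)
  sites$FS <- runif(n, 0, 10)
  sites$MQ <- runif(n, 50, 60)
  sites$ReadPosRankSum <- runif(n, -2, 2)
  sites$InbreedingCoeff <- runif(n, -0.1, 0.5)
  sites$gqWT <- sample(60:99, n, replace = TRUE)
  sites$gqMT <- sample(60:99, n, replace = TRUE)
  ## ... except an injected failing fraction (QD below threshold)
  failIdx <- which(runif(n) < failFraction)
  sites$QD[failIdx] <- runif(length(failIdx), 0, 3.9)

  list(sites = sites,
       truth = list(causal = list(chrom = causalChrom, start = causalStart,
                                  end = causalEnd),
                    hetBlocks = hetBlocks,
                    injectedFailPos = sites$pos[failIdx],
                    seed = seed),
       chromLengths = chromLengths)
}

#' Simulate a differential-expression table with known truth
#'
#' True DEGs receive \code{|log2FC|} uniform in
#' \code{[lfcEffect, lfcEffect + 2]} with random sign and p-values uniform
#' in \code{[0, 0.01]}; null genes receive log2FC ~ Normal(0, 0.3) and
#' p-values uniform in \code{[0, 1]}.
#'
#' @param nGenes number of genes.
#' @param degFraction fraction of true DEGs in [0, 1] (default 0.1).
#' @param lfcEffect minimum true absolute log2 fold change (default 2).
#' @param seed integer seed (mandatory).
#' @param geneIds optional gene ids (default gene0001...).
#' @return list: \code{table} (gene_id, log2fc, pvalue, mean_expr),
#'   \code{truth} (character vector of true DEG ids, seed).
#' @export
simulateDeTable <- function(nGenes, degFraction = 0.1, lfcEffect = 2,
                            seed, geneIds = NULL) {
  stopifnot(degFraction >= 0, degFraction <= 1, is.finite(seed))
  set.seed(seed)
  if (is.null(geneIds)) geneIds <- sprintf("gene%04d", seq_len(nGenes))
  nDeg <- round(degFraction * nGenes)
  degIdx <- if (nDeg > 0) sample.int(nGenes, nDeg) else integer(0)
  lfc <- rnorm(nGenes, 0, 0.3)
  p <- runif(nGenes)
  lfc[degIdx] <- sample(c(-1, 1), nDeg, replace = TRUE) *
    runif(nDeg, lfcEffect, lfcEffect + 2)
  p[degIdx] <- runif(nDeg, 0, 0.01)
  list(table = data.frame(gene_id = geneIds, log2fc = lfc, pvalue = p,
                          mean_expr = exp(rnorm(nGenes, 3, 1)),
                          stringsAsFactors = FALSE),
       truth = list(degIds = geneIds[sort(degIdx)], seed = seed))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Generate toy multi-exon gene models with valid ORFs
#'
#' Each gene gets a random open reading frame (start codon, sense codons,
#' stop codon) split across 1--3 exons on a randomly chosen strand, laid
#' out left to right along one chromosome with intergenic gaps. The
#' emitted CDS sequence always translates without internal stops.
#'
#' @param n number of genes.
#' @param seed integer seed (mandatory).
#' @param chrom chromosome name.
#' @param startAt genomic coordinate of the first gene.
#' @param gap intergenic gap in bp.
#' @param codonRange range of CDS lengths in codons (including start/stop).
#' @return list: \code{genes} (list of \code{GeneModel}), \code{cds}
#'   (named \code{DNAStringSet} of coding sequences).
#' @export
makeToyGenes <- function(n, seed, chrom = "Chr11", startAt = 1e4,
                         gap = 2e4, codonRange = c(40L, 90L)) {
  stopifnot(is.finite(seed))
  set.seed(seed)
  genes <- vector("list", n)
  cds <- character(n)
  ids <- sprintf("toy%03d", seq_len(n))
  at <- startAt
  for (i in seq_len(n)) {
    nc <- sample(codonRange[1]:codonRange[2], 1)
    orf <- paste0("ATG",
                  paste(sample(.SENSE_CODONS, nc - 2L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1))
    len <- nchar(orf)
    nex <- sample(1:3, 1)
    cuts <- sort(sample(seq_len(len - 1), nex - 1))
    widths <- diff(c(0, cuts, len))
    introns <- if (nex > 1) sample(80:300, nex - 1, replace = TRUE) else
      integer(0)
    segStart <- at + cumsum(c(0, widths[-nex] + introns))
    segStop <- segStart + widths - 1
    strand <- sample(c("+", "-"), 1)
    genes[[i]] <- geneModel(ids[i], chrom, min(segStart), max(segStop),
                            strand, cbind(segStart, segStop),
                            annotation = "toy gene")
    ## segments are stored in genomic order; for minus-strand genes the
    ## coding sequence reads from the last segment backwards
    cds[i] <- orf
    at <- max(segStop) + gap
  }
  cdsSet <- Biostrings::DNAStringSet(cds)
  names(cdsSet) <- ids
  list(genes = genes, cds = cdsSet)
}

#' Genomic CDS base consistent with a toy gene's coding sequence
#'
#' Helper for planting variants: returns the plus-strand base at a genomic
#' position inside the CDS of \code{gene}, derived from the coding
#' sequence.
#'
#' @param gene a \code{GeneModel}.
#' @param cdsSeq its coding sequence.
#' @param pos genomic position within the CDS.
#' @return single plus-strand base.
#' @export
cdsBaseAt <- function(gene, cdsSeq, pos) {
  cp <- .cdsCoord(gene, pos)
  if (is.na(cp)) stop("position ", pos, " is not inside the CDS")
  b <- substr(as.character(cdsSeq), cp, cp)
  if (gene@strand == "+") b else .complement[[b]]
}
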