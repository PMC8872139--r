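## inverse of .cdsCoord: genomic position of a 1-based CDS coordinate
.genomicCoord <- function(gene, cdsPos) {
  seg <- gene@cdsSegments
  widths <- seg[, 2] - seg[, 1] + 1
  total <- sum(widths)
  stopifnot(cdsPos >= 1, cdsPos <= total)
  plusCoord <- if (gene@strand == "+") cdsPos else total - cdsPos + 1
  cum <- cumsum(widths)
  k <- which(plusCoord <= cum)[1]
  before <- if (k == 1) 0 else cum[k - 1]
  seg[k, 1] + (plusCoord - before) - 1
}

## pick a substitution at the given CDS coordinate that yields the wanted
## effect class; returns list(pos, ref, alt) in plus-strand genomic terms
.plantVariant <- function(gene, cdsSeq, cdsPos, want = "missense") {
  pos <- .genomicCoord(gene, cdsPos)
  ref <- cdsBaseAt(gene, cdsSeq, pos)
  for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
    eff <- classifyEffect(gene, cdsSeq, pos, ref, alt)
    if (eff$effect == want) return(list(pos = pos, ref = ref, alt = alt))
  }
  NULL
}

#' Simulate and analyze a complete NIL bulk-pool scenario
#'
#' End-to-end run with planted truth: toy genes are laid out inside (and
#' beyond) a causal block; NIL pools are simulated with the block fixed
#' alternate in the mutant pool; one designated causal gene carries a
#' planted missense variant (fixed in the mutant pool) and is the only
#' differentially expressed gene in the block; background variant sites
#' falling into toy-gene CDS are dropped so coding evidence is exactly the
#' planted one. The pipeline then runs hard filters, the delta SNP-index
#' scan, region calling, gene intersection, effect classification and
#' candidate ranking.
#'
#' @param seed integer seed driving all randomness.
#' @param chromLength chromosome length in bp.
#' @param causalStart,causalEnd causal block.
#' @param nGenesInBlock,nGenesOutside toy genes inside / outside the block.
#' @param config a \code{ScanConfig}; the default threshold 0.9 tolerates
#'   sequencing error (a threshold of exactly 1 is fragile off the
#'   noiseless case).
#' @param ... further arguments to \code{simulateNilPools} (meanDepth,
#'   errorRate, snpDensity, hetFraction, ...).
#' @return list: \code{report} (ranked candidates), \code{regions},
#'   \code{track}, \code{effects}, \code{deTable}, \code{truth} (causal
#'   gene and block), \code{log}.
#' @export
runNilScenario <- function(seed, chromLength = 2e7, causalStart = 9e6,
                           causalEnd = 10.5e6, nGenesInBlock = 6,
                           nGenesOutside = 4,
                           config = scanConfig(deltaThreshold = 0.9), ...) {
  chromLengths <- c(Chr11 = chromLength)
  toys <- makeToyGenes(nGenesInBlock, seed = seed + 1, chrom = "Chr11",
                       startAt = causalStart + 2e5,
                       gap = floor((causalEnd - causalStart - 4e5) /
                                   max(nGenesInBlock, 1)) - 3e3)
  outside <- makeToyGenes(nGenesOutside, seed = seed + 2, chrom = "Chr11",
                          startAt = 1e6, gap = 5e5)
  outside$genes <- lapply(outside$genes, function(g) {
    g@geneId <- sub("^toy", "out", g@geneId); g
  })
  names(outside$cds) <- sub("^toy", "out", names(outside$cds))
  genes <- c(toys$genes, outside$genes)
  cds <- c(toys$cds, outside$cds)
  ids <- vapply(genes, function(g) g@geneId, character(1))
  stopifnot(max(vapply(toys$genes, function(g) g@stop, numeric(1))) <=
              causalEnd - 1e5)

  sim <- simulateNilPools(chromLengths = chromLengths,
                          causalStart = causalStart, causalEnd = causalEnd,
                          seed = seed, ...)
  sites <- sim$sites

  ## keep toy-gene CDS free of background variants, then plant the causal one
  inCds <- rep(FALSE, nrow(sites))
  for (g in genes) {
    seg <- g@cdsSegments
    for (k in seq_len(nrow(seg)))
      inCds <- inCds | (sites$pos >= seg[k, 1] & sites$pos <= seg[k, 2])
  }
  sites <- sites[!inCds, , drop = FALSE]

  causalGene <- toys$genes[[ceiling(nGenesInBlock / 2)]]
  pv <- .plantVariant(causalGene, cds[[causalGene@geneId]], cdsPos = 10L)
  stopifnot(!is.null(pv))
  depth <- list(...)$meanDepth %||% 31
  planted <- data.frame(
    chrom = "Chr11", pos = pv$pos, trueFreq = 1, ref = pv$ref, alt = pv$alt,
    isIndel = FALSE, wtRef = depth, wtAlt = 0L, mtRef = 0L, mtAlt = depth,
    QD = 20, FS = 1, MQ = 55, ReadPosRankSum = 0, InbreedingCoeff = 0.1,
    gqWT = 90, gqMT = 90)
  sites <- rbind(sites, planted)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]

  det <- simulateDeTable(length(ids), degFraction = 0, seed = seed + 3,
                         geneIds = ids)
  deTable <- det$table
  ci <- which(deTable$gene_id == causalGene@geneId)
  deTable$log2fc[ci] <- 2.5
  deTable$pvalue[ci] <- 1e-4

  filtered <- applyHardFilters(sites)
  track <- scanDeltaIndex(filtered, sim$chromLengths, config)
  regions <- callCandidateRegions(track, config@deltaThreshold)

  geneGr <- geneRangesFromTable(data.frame(
    gene_id = ids,
    chrom = vapply(genes, function(g) g@chrom, character(1)),
    start = vapply(genes, function(g) g@start, numeric(1)),
    stop = vapply(genes, function(g) g@stop, numeric(1))))
  intervalGenes <- character(0)
  for (i in seq_along(regions))
    intervalGenes <- union(intervalGenes,
      S4Vectors::mcols(genesInInterval(geneGr, regions[i]))$gene_id)

  passing <- filtered[filtered$filterPass, ]
  effects <- list()
  for (gid in intervalGenes) {
    g <- genes[[match(gid, ids)]]
    seg <- g@cdsSegments
    hit <- passing$chrom == g@chrom &
      Reduce(`|`, lapply(seq_len(nrow(seg)), function(k)
        passing$pos >= seg[k, 1] & passing$pos <= seg[k, 2]))
    for (i in which(hit))
      effects[[length(effects) + 1L]] <-
        classifyEffect(g, cds[[gid]], passing$pos[i], passing$ref[i],
                       passing$alt[i])
  }
  report <- rankCandidates(intervalGenes, effects, deTable)
  list(report = report, regions = regions, track = track,
       effects = effects, deTable = deTable,
       truth = list(causalGene = causalGene@geneId,
                    block = sim$truth$causal, seed = seed),
       log = list(seed = seed, filter = filterSummary(filtered),
                  nRegions = length(regions),
                  nIntervalGenes = length(intervalGenes)))
}

.pipelineKeys <- c("scenario", "seed", "outDir", "scan", "sim", "inputs",
                   "triage")
.scanKeys <- c("windowSize", "step", "deltaThreshold", "minSnps", "minDepth")

#' Run the analysis pipeline from a configuration
#'
#' Orchestrates the stages in order: segregation test (when cross counts
#' are supplied), delta SNP-index scan, and candidate triage, writing
#' intermediate artifacts to \code{outDir}. Two input modes: scenario
#' \code{"nil-pools"} simulates everything from \code{seed}; file mode
#' reads a VCF (plus GFF3 / CDS FASTA / DE table) named under
#' \code{inputs}. Unknown configuration keys are rejected up front, and
#' the run log records the seed, the resolved configuration and in/out
#' record counts at every filter so each stochastic result is replayable.
#'
#' @param config named list, or path to a YAML file with the same
#'   structure. Keys: \code{scenario}, \code{seed}, \code{outDir},
#'   \code{scan} (windowSize, step, deltaThreshold, minSnps, minDepth),
#'   \code{sim} (passed to the scenario), \code{inputs} (vcf, wtSample,
#'   mtSample, gff3, cdsFasta, deTable), \code{triage} (pThreshold,
#'   lfcThreshold).
#' @return list with \code{report}, \code{regions}, \code{track},
#'   \code{log}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .pipelineKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$scan)) {
    bad <- setdiff(names(config$scan), .scanKeys)
    if (length(bad))
      stop("unknown scan key(s): ", paste(bad, collapse = ", "))
  }
  sc <- do.call(scanConfig, config$scan %||% list())
  outDir <- config$outDir

  if (!is.null(config$scenario)) {
    if (config$scenario != "nil-pools")
      stop("unknown scenario '", config$scenario, "'")
    if (is.null(config$seed)) stop("scenario runs require a seed")
    res <- do.call(runNilScenario,
                   c(list(seed = config$seed, config = sc),
                     config$sim %||% list()))
  } else {
    inp <- config$inputs
    if (is.null(inp$vcf)) stop("file mode requires inputs$vcf")
    sites <- readPooledVcf(inp$vcf, inp$wtSample %||% "WT",
                           inp$mtSample %||% "MT")
    chromLengths <- vcfContigLengths(inp$vcf)
    if (length(chromLengths) == 0)
      stop("VCF declares no contig lengths; cannot build the window grid")
    filtered <- applyHardFilters(sites)
    track <- scanDeltaIndex(filtered, chromLengths, sc)
    regions <- callCandidateRegions(track, sc@deltaThreshold)
    effects <- NULL
    deTable <- if (!is.null(inp$deTable)) readDeTable(inp$deTable)
    intervalGenes <- character(0)
    if (!is.null(inp$gff3)) {
      genes <- readGff3Genes(inp$gff3)
      cds <- if (!is.null(inp$cdsFasta)) readCdsFasta(inp$cdsFasta)
      geneGr <- geneRangesFromTable(data.frame(
        gene_id = names(genes),
        chrom = vapply(genes, function(g) g@chrom, character(1)),
        start = vapply(genes, function(g) g@start, numeric(1)),
        stop = vapply(genes, function(g) g@stop, numeric(1))))
      for (i in seq_along(regions))
        intervalGenes <- union(intervalGenes,
          S4Vectors::mcols(genesInInterval(geneGr, regions[i]))$gene_id)
      if (!is.null(cds)) {
        passing <- filtered[filtered$filterPass & !filtered$isIndel, ]
        effects <- list()
        for (gid in intervalGenes) {
          g <- genes[[gid]]
          seg <- g@cdsSegments
          hit <- passing$chrom == g@chrom &
            Reduce(`|`, lapply(seq_len(nrow(seg)), function(k)
              passing$pos >= seg[k, 1] & passing$pos <= seg[k, 2]),
              accumulate = FALSE)
          for (i in which(hit))
            effects[[length(effects) + 1L]] <-
              classifyEffect(g, cds[[gid]], passing$pos[i],
                             passing$ref[i], passing$alt[i])
        }
      }
    }
    tri <- config$triage %||% list()
    report <- rankCandidates(intervalGenes, effects, deTable,
                             tri$pThreshold %||% 0.05,
                             tri$lfcThreshold %||% 1)
    res <- list(report = report, regions = regions, track = track,
                log = list(seed = config$seed,
                           filter = filterSummary(filtered),
                           nRegions = length(regions),
                           nIntervalGenes = length(intervalGenes)))
  }
  res$log$config <- config
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeWindowTrack(res$track, file.path(outDir, "delta_track.tsv"))
    writeRegionsBed(res$regions, file.path(outDir, "candidate_regions.bed"))
    write.table(res$report, file.path(outDir, "candidate_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logOut <- res$log
    logOut$filter$failedByReason <- as.list(logOut$filter$failedByReason)
    jsonlite::write_json(logOut, file.path(outDir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}
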