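#' @import methods
#' @importFrom stats pchisq rbinom rpois runif rnorm setNames
#' @importFrom utils read.csv read.delim write.csv write.table modifyList head tail
NULL

GENOTYPE_CODES <- c("AA", "Aa", "aa")
PHENOTYPE_CLASSES <- c("wild-type", "mutant")
MARKER_CALLS <- c("P1", "P2", "H")

#' Two-locus (or one-locus) epistasis model
#'
#' An \code{EpistasisModel} maps every joint genotype class of a selfed
#' (double) heterozygote to a phenotype class (\code{"wild-type"} or
#' \code{"mutant"}). For a two-locus model the map is total over the nine
#' joint classes \code{AA:AA .. aa:aa}; for a one-locus model over the
#' three classes \code{AA, Aa, aa}. An optional fixed background pins one
#' locus to a single genotype, modelling a cross in which one parent is
#' already homozygous recessive at that locus.
#'
#' @slot name model identifier.
#' @slot nLoci number of segregating loci (1 or 2).
#' @slot phenoMap named character vector: joint genotype class (e.g.
#'   \code{"aa:aa"}) to phenotype class.
#' @slot fixedBackground either \code{character(0)} or
#'   \code{c(locus = "1"|"2", genotype = "AA"|"Aa"|"aa")}.
#' @export
setClass("EpistasisModel",
  representation(
    name = "character",
    nLoci = "integer",
    phenoMap = "character",
    fixedBackground = "character"
  )
)

setValidity("EpistasisModel", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!object@nLoci %in% c(1L, 2L))
    msg <- c(msg, "'nLoci' must be 1 or 2")
  keys <- jointClassKeys(object@nLoci)
  if (!setequal(names(object@phenoMap), keys))
    msg <- c(msg, sprintf("'phenoMap' must be total over the %d genotype classes",
                          length(keys)))
  if (!all(object@phenoMap %in% PHENOTYPE_CLASSES))
    msg <- c(msg, "phenotypes must be 'wild-type' or 'mutant'")
  fb <- object@fixedBackground
  if (length(fb) > 0) {
    if (object@nLoci != 2L)
      msg <- c(msg, "fixed background only meaningful for two-locus models")
    if (!identical(sort(names(fb)), c("genotype", "locus")) ||
        !fb[["locus"]] %in% c("1", "2") ||
        !fb[["genotype"]] %in% GENOTYPE_CODES)
      msg <- c(msg, "fixedBackground must be c(locus = '1'|'2', genotype = 'AA'|'Aa'|'aa')")
  }
  if (length(msg)) msg else TRUE
})

jointClassKeys <- function(nLoci) {
  if (nLoci == 1L) GENOTYPE_CODES
  else as.vector(outer(GENOTYPE_CODES, GENOTYPE_CODES,
                       function(a, b) paste(a, b, sep = ":")))
}

setMethod("show", "EpistasisModel", function(object) {
  cat("EpistasisModel '", object@name, "' (", object@nLoci, " locus",
      if (object@nLoci > 1) "es", ")\n", sep = "")
  mut <- names(object@phenoMap)[object@phenoMap == "mutant"]
  cat("  mutant classes:", if (length(mut)) paste(mut, collapse = ", ")
      else "<none>", "\n")
  if (length(object@fixedBackground))
    cat("  fixed background: locus", object@fixedBackground[["locus"]],
        "=", object@fixedBackground[["genotype"]], "\n")
})

#' Marker genotype table for a mapping population
#'
#' Individuals by ordered markers, with calls coded \code{P1} (homozygous
#' for the non-mutant parent allele), \code{P2} (homozygous mutant-parent),
#' \code{H} (heterozygous), or \code{NA} (missing). Markers on one
#' chromosome must be strictly ordered by physical position.
#'
#' @slot individuals character vector of individual ids (rownames of calls).
#' @slot markers data.frame with columns \code{name}, \code{chrom},
#'   \code{bp}, and optionally \code{cM}.
#' @slot calls character matrix, individuals x markers.
#' @export
setClass("MarkerGenotypeTable",
  representation(
    individuals = "character",
    markers = "data.frame",
    calls = "matrix"
  )
)

setValidity("MarkerGenotypeTable", function(object) {
  msg <- character(0)
  mk <- object@markers
  need <- c("name", "chrom", "bp")
  if (!all(need %in% names(mk)))
    msg <- c(msg, "markers must have columns name, chrom, bp")
  else {
    if (anyDuplicated(mk$name))
      msg <- c(msg, "marker names must be unique")
    bad <- vapply(split(mk$bp, mk$chrom),
                  function(x) is.unsorted(x, strictly = TRUE), logical(1))
    if (any(bad))
      msg <- c(msg, "marker bp positions must be strictly increasing within chromosomes")
  }
  if (nrow(object@calls) != length(object@individuals))
    msg <- c(msg, "calls rows must match individuals")
  if (ncol(object@calls) != nrow(mk))
    msg <- c(msg, "calls columns must match markers")
  vals <- object@calls[!is.na(object@calls)]
  if (!all(vals %in% MARKER_CALLS))
    msg <- c(msg, "calls must be P1, P2, H or NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MarkerGenotypeTable", function(object) {
  cat("MarkerGenotypeTable:", length(object@individuals), "individuals x",
      nrow(object@markers), "markers on",
      length(unique(object@markers$chrom)), "chromosome(s)\n")
  tab <- table(factor(object@calls, levels = MARKER_CALLS), useNA = "always")
  cat("  calls:", paste(sprintf("%s=%d", c(MARKER_CALLS, "NA"), tab),
                        collapse = " "), "\n")
})

#' @rdname MarkerGenotypeTable-class
#' @param calls character matrix of P1/P2/H/NA calls (individuals x markers).
#' @param markers data.frame with name, chrom, bp (and optional cM).
#' @param individuals optional ids; defaults to rownames of \code{calls}.
#' @return a \code{MarkerGenotypeTable}.
#' @export
markerGenotypeTable <- function(calls, markers, individuals = rownames(calls)) {
  if (is.null(individuals))
    individuals <- sprintf("ind%03d", seq_len(nrow(calls)))
  rownames(calls) <- individuals
  colnames(calls) <- markers$name
  new("MarkerGenotypeTable", individuals = individuals,
      markers = as.data.frame(markers), calls = calls)
}

#' @rdname MarkerGenotypeTable-class
#' @param x a \code{MarkerGenotypeTable}.
#' @export
markerInfo <- function(x) x@markers

#' @rdname MarkerGenotypeTable-class
#' @export
genotypeCalls <- function(x) x@calls

#' Hard-filter thresholds for pooled variant calls
#'
#' Mirrors GATK VariantFiltration expressions commonly used for pool-seq:
#' a SNP fails when \code{QD < snpQDmin | FS > snpFSmax | MQ < snpMQmin};
#' an indel fails when \code{QD < indelQDmin | FS > indelFSmax |
#' ReadPosRankSum < indelRPRSmin | InbreedingCoeff < indelICmin}. A
#' per-pool genotype with \code{GQ < gqMin} is masked (treated as missing)
#' without failing the site.
#'
#' @export
setClass("FilterPolicy",
  representation(
    snpQDmin = "numeric", snpFSmax = "numeric", snpMQmin = "numeric",
    gqMin = "numeric",
    indelQDmin = "numeric", indelFSmax = "numeric",
    indelRPRSmin = "numeric", indelICmin = "numeric"
  )
)

setValidity("FilterPolicy", function(object) {
  vals <- c(object@snpQDmin, object@snpFSmax, object@snpMQmin, object@gqMin,
            object@indelQDmin, object@indelFSmax, object@indelRPRSmin,
            object@indelICmin)
  if (length(vals) != 8L || any(!is.finite(vals)))
    "all eight thresholds must be single finite numbers"
  else TRUE
})

#' @rdname FilterPolicy-class
#' @param snpQDmin,snpFSmax,snpMQmin SNP-level thresholds.
#' @param gqMin per-pool genotype-quality floor.
#' @param indelQDmin,indelFSmax,indelRPRSmin,indelICmin indel-level thresholds.
#' @return a \code{FilterPolicy}.
#' @export
filterPolicy <- function(snpQDmin = 4.0, snpFSmax = 60.0, snpMQmin = 40.0,
                         gqMin = 20, indelQDmin = 4.0, indelFSmax = 200.0,
                         indelRPRSmin = -20.0, indelICmin = -0.8) {
  new("FilterPolicy", snpQDmin = snpQDmin, snpFSmax = snpFSmax,
      snpMQmin = snpMQmin, gqMin = gqMin, indelQDmin = indelQDmin,
      indelFSmax = indelFSmax, indelRPRSmin = indelRPRSmin,
      indelICmin = indelICmin)
}

setMethod("show", "FilterPolicy", function(object) {
  cat("FilterPolicy\n",
      sprintf("  SNP fail:   QD < %g | FS > %g | MQ < %g\n",
              object@snpQDmin, object@snpFSmax, object@snpMQmin),
      sprintf("  indel fail: QD < %g | FS > %g | ReadPosRankSum < %g | InbreedingCoeff < %g\n",
              object@indelQDmin, object@indelFSmax, object@indelRPRSmin,
              object@indelICmin),
      sprintf("  pool mask:  GQ < %g\n", object@gqMin), sep = "")
})

#' Sliding-window scan configuration
#'
#' @slot windowSize window width in bp (default 2 Mb).
#' @slot step window increment in bp (default 50 kb).
#' @slot deltaThreshold delta SNP-index call threshold in (0, 1].
#' @slot minSnps minimum SNPs for a window mean to be reported.
#' @slot minDepth minimum pool depth for a site index to be reported.
#' @export
setClass("ScanConfig",
  representation(
    windowSize = "numeric", step = "numeric", deltaThreshold = "numeric",
    minSnps = "integer", minDepth = "numeric"
  )
)

setValidity("ScanConfig", function(object) {
  msg <- character(0)
  if (object@windowSize < 1) msg <- c(msg, "windowSize must be >= 1")
  if (object@step < 1 || object@step > object@windowSize)
    msg <- c(msg, "step must be in [1, windowSize]")
  if (object@deltaThreshold <= 0 || object@deltaThreshold > 1)
    msg <- c(msg, "deltaThreshold must be in (0, 1]")
  if (object@minSnps < 1) msg <- c(msg, "minSnps must be >= 1")
  if (object@minDepth < 0) msg <- c(msg, "minDepth must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ScanConfig-class
#' @param windowSize,step,deltaThreshold,minSnps,minDepth see slots.
#' @return a \code{ScanConfig}.
#' @export
scanConfig <- function(windowSize = 2e6, step = 5e4, deltaThreshold = 1.0,
                       minSnps = 1L, minDepth = 0) {
  new("ScanConfig", windowSize = windowSize, step = step,
      deltaThreshold = deltaThreshold, minSnps = as.integer(minSnps),
      minDepth = minDepth)
}

setMethod("show", "ScanConfig", function(object) {
  cat(sprintf(
    "ScanConfig: window %g bp, step %g bp, delta threshold %g, minSnps %d, minDepth %g\n",
    object@windowSize, object@step, object@deltaThreshold, object@minSnps,
    object@minDepth))
})

#' Gene model with CDS segments
#'
#' Coordinates are 1-based inclusive, GFF3 convention. CDS segments are
#' stored in genomic order regardless of strand; for minus-strand genes the
#' coding sequence runs from the highest-coordinate segment backwards.
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome name.
#' @slot start,stop gene span (1-based inclusive).
#' @slot strand "+" or "-".
#' @slot cdsSegments two-column integer matrix (start, stop), genomic order.
#' @slot annotation free-text functional annotation.
#' @export
setClass("GeneModel",
  representation(
    geneId = "character", chrom = "character",
    start = "numeric", stop = "numeric", strand = "character",
    cdsSegments = "matrix", annotation = "character"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (object@start > object@stop) msg <- c(msg, "start must be <= stop")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  seg <- object@cdsSegments
  if (nrow(seg) > 0) {
    if (ncol(seg) != 2) msg <- c(msg, "cdsSegments must have 2 columns")
    else {
      if (any(seg[, 1] > seg[, 2])) msg <- c(msg, "CDS segment start > stop")
      if (any(seg[, 1] < object@start) || any(seg[, 2] > object@stop))
        msg <- c(msg, "CDS segments must lie within the gene span")
      if (nrow(seg) > 1) {
        o <- order(seg[, 1])
        if (any(seg[o, 1][-1] <= seg[o, 2][-nrow(seg)]))
          msg <- c(msg, "CDS segments must be non-overlapping")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GeneModel-class
#' @param geneId,chrom,start,stop,strand,cdsSegments,annotation see slots.
#' @return a \code{GeneModel}.
#' @export
geneModel <- function(geneId, chrom, start, stop, strand = "+",
                      cdsSegments = cbind(start, stop), annotation = "") {
  seg <- matrix(as.numeric(cdsSegments), ncol = 2,
                dimnames = list(NULL, c("start", "stop")))
  seg <- seg[order(seg[, 1]), , drop = FALSE]
  new("GeneModel", geneId = geneId, chrom = chrom, start = as.numeric(start),
      stop = as.numeric(stop), strand = strand, cdsSegments = seg,
      annotation = annotation)
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s %s:%d-%d(%s), %d CDS segment(s), CDS %d bp\n",
              object@geneId, object@chrom, object@start, object@stop,
              object@strand, nrow(object@cdsSegments),
              cdsLength(object)))
})

#' @rdname GeneModel-class
#' @param gene a \code{GeneModel}.
#' @export
cdsLength <- function(gene) {
  seg <- gene@cdsSegments
  if (nrow(seg) == 0) return(0L)
  as.integer(sum(seg[, 2] - seg[, 1] + 1))
}

#' Genetic map for population simulation
#'
#' Ordered marker and causal-locus positions per chromosome, in both
#' centimorgans (for crossover simulation) and base pairs (for physical
#' interval reporting).
#'
#' @slot positions data.frame with columns \code{name}, \code{chrom},
#'   \code{cM}, \code{bp}, \code{causalLocus} (NA or "1"/"2").
#' @export
setClass("GeneticMap", representation(positions = "data.frame"))

setValidity("GeneticMap", function(object) {
  pos <- object@positions
  need <- c("name", "chrom", "cM", "bp", "causalLocus")
  msg <- character(0)
  if (!all(need %in% names(pos)))
    msg <- c(msg, "positions needs columns name, chrom, cM, bp, causalLocus")
  else {
    byc <- split(pos, pos$chrom)
    if (any(vapply(byc, function(d) is.unsorted(d$cM), logical(1))))
      msg <- c(msg, "cM must be non-decreasing within chromosomes")
    if (any(vapply(byc, function(d) is.unsorted(d$bp, strictly = TRUE),
                   logical(1))))
      msg <- c(msg, "bp must be strictly increasing within chromosomes")
    if (anyDuplicated(pos$name)) msg <- c(msg, "position names must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GeneticMap-class
#' @param markers data.frame with name, chrom, cM, bp.
#' @param causalLoci data.frame with name, chrom, cM, bp, locus ("1"/"2").
#' @return a \code{GeneticMap}.
#' @export
geneticMap <- function(markers, causalLoci) {
  markers$causalLocus <- NA_character_
  causalLoci$causalLocus <- as.character(causalLoci$locus)
  causalLoci$locus <- NULL
  pos <- rbind(markers[c("name", "chrom", "cM", "bp", "causalLocus")],
               causalLoci[c("name", "chrom", "cM", "bp", "causalLocus")])
  pos <- pos[order(pos$chrom, pos$bp), , drop = FALSE]
  rownames(pos) <- NULL
  new("GeneticMap", positions = pos)
}

setMethod("show", "GeneticMap", function(object) {
  pos <- object@positions
  cat("GeneticMap:", sum(is.na(pos$causalLocus)), "markers,",
      sum(!is.na(pos$causalLocus)), "causal locus/loci on",
      length(unique(pos$chrom)), "chromosome(s)\n")
})
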