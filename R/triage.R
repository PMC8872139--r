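#' Genes overlapping a mapping interval
#'
#' Any-overlap semantics: a gene is retained when its span intersects the
#' interval at all (boundary genes in fine mapping are conventionally
#' kept). Results are sorted by gene start.
#'
#' @param genes \code{GRanges} of gene spans with a \code{gene_id}
#'   metadata column (see \code{\link{geneRangesFromTable}}), or a
#'   data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{stop}.
#' @param interval \code{GRanges} of length 1 (e.g. from
#'   \code{delimitInterval}) or "chrom:start-end" string.
#' @return the overlapping subset of \code{genes}, sorted by start.
#' @export
genesInInterval <- function(genes, interval) {
  if (is.data.frame(genes)) genes <- geneRangesFromTable(genes)
  if (is.character(interval)) interval <- GenomicRanges::GRanges(interval)
  hits <- GenomicRanges::findOverlaps(genes, interval, type = "any")
  out <- genes[unique(S4Vectors::queryHits(hits))]
  out[order(GenomicRanges::start(out))]
}

#' Convert an annotation table to gene ranges
#'
#' @param df data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{stop} and optionally \code{annotation}.
#' @return \code{GRanges} with \code{gene_id} (and \code{annotation})
#'   metadata.
#' @export
geneRangesFromTable <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$stop))
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  if (!is.null(df$annotation))
    S4Vectors::mcols(gr)$annotation <- df$annotation
  gr
}

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
          Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
          L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
          S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
          "*" = "*")

## genomic position -> 1-based CDS coordinate (strand-aware); NA if the
## position falls outside every CDS segment.
.cdsCoord <- function(gene, pos) {
  seg <- gene@cdsSegments
  if (nrow(seg) == 0) return(NA_integer_)
  widths <- seg[, 2] - seg[, 1] + 1
  before <- cumsum(c(0, widths))[seq_len(nrow(seg))]  # bp preceding each segment
  k <- which(pos >= seg[, 1] & pos <= seg[, 2])
  if (length(k) == 0) return(NA_integer_)
  plusCoord <- before[k] + (pos - seg[k, 1] + 1)
  if (gene@strand == "+") as.integer(plusCoord)
  else as.integer(sum(widths) - plusCoord + 1)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify the coding effect of a single-base substitution
#'
#' Maps the genomic position to a CDS coordinate (strand-aware; on the
#' minus strand the substituted base is complemented), swaps the base in
#' the affected codon, translates with the standard genetic code, and
#' compares amino acids. Positions outside the CDS are classified
#' \code{noncoding}, or \code{splice-adjacent} when within 2 bp of a CDS
#' segment boundary (intron-side).
#'
#' @param gene a \code{GeneModel}.
#' @param cdsSeq the spliced coding sequence (character or
#'   \code{DNAString}), 5'->3' on the coding strand; its length must equal
#'   the summed CDS segment lengths.
#' @param pos genomic position of the substitution (1-based).
#' @param ref,alt reference and alternate bases on the plus strand.
#' @return list (\code{VariantEffect}): \code{geneId}, \code{pos},
#'   \code{cdsPos}, \code{codonIndex}, \code{refAA}, \code{altAA}
#'   (one-letter, "*" = stop), \code{refAA3}, \code{altAA3},
#'   \code{effect} in \{synonymous, missense, nonsense, stop-loss,
#'   noncoding, splice-adjacent\}.
#' @examples
#' g <- geneModel("toy", "chr1", 1, 9, "+", cbind(1, 9))
#' classifyEffect(g, "ATGGGTTAA", 5, "G", "C")  # Gly -> Ala, missense
#' @export
classifyEffect <- function(gene, cdsSeq, pos, ref, alt) {
  cdsSeq <- as.character(cdsSeq)
  if (nchar(cdsSeq) != cdsLength(gene))
    stop("CDS sequence length (", nchar(cdsSeq),
         ") does not match the summed CDS segments (", cdsLength(gene), ")")
  base <- list(geneId = gene@geneId, pos = pos, cdsPos = NA_integer_,
               codonIndex = NA_integer_, refAA = NA_character_,
               altAA = NA_character_, refAA3 = NA_character_,
               altAA3 = NA_character_)
  seg <- gene@cdsSegments
  inCds <- nrow(seg) > 0 && any(pos >= seg[, 1] & pos <= seg[, 2])
  if (!inCds) {
    nearBoundary <- nrow(seg) > 0 &&
      any(abs(pos - c(seg[, 1], seg[, 2])) <= 2)
    base$effect <- if (nearBoundary) "splice-adjacent" else "noncoding"
    return(base)
  }
  cdsPos <- .cdsCoord(gene, pos)
  refC <- if (gene@strand == "+") ref else .complement[[ref]]
  altC <- if (gene@strand == "+") alt else .complement[[alt]]
  haveRef <- substr(cdsSeq, cdsPos, cdsPos)
  if (haveRef != refC)
    warning("reference base mismatch at ", gene@geneId, ":", pos,
            " (CDS has ", haveRef, ", variant says ", refC, ")")
  ci <- (cdsPos - 1L) %/% 3L + 1L
  codon <- substr(cdsSeq, 3L * ci - 2L, 3L * ci)
  off <- cdsPos - (3L * ci - 2L) + 1L
  mutCodon <- codon
  substr(mutCodon, off, off) <- altC
  refAA <- as.character(Biostrings::GENETIC_CODE[[codon]])
  altAA <- as.character(Biostrings::GENETIC_CODE[[mutCodon]])
  effect <-
    if (refAA == altAA) "synonymous"
    else if (altAA == "*") "nonsense"
    else if (refAA == "*") "stop-loss"
    else "missense"
  modifyList(base, list(cdsPos = cdsPos, codonIndex = ci,
                        refAA = refAA, altAA = altAA,
                        refAA3 = unname(.AA3[refAA]),
                        altAA3 = unname(.AA3[altAA]),
                        effect = effect))
}

#' Per-gene and per-class variant-effect summary
#'
#' @param effects data.frame with columns \code{gene_id} and
#'   \code{effect} (classes as from \code{classifyEffect}; the
#'   nonsynonymous classes are missense, nonsense and stop-loss), or a
#'   list of \code{classifyEffect} outputs.
#' @return list with \code{perGene} (gene_id, nSnps, nMissense,
#'   nSynonymous) and \code{totals} (nSnps, nGenes, nMissense,
#'   nMissenseGenes, nSynonymous).
#' @export
summarizeVariants <- function(effects) {
  if (!is.data.frame(effects))
    effects <- do.call(rbind, lapply(effects, function(e)
      data.frame(gene_id = e$geneId, effect = e$effect)))
  if (is.null(effects) || nrow(effects) == 0) {
    return(list(perGene = data.frame(gene_id = character(0),
                                     nSnps = integer(0),
                                     nMissense = integer(0),
                                     nSynonymous = integer(0)),
                totals = c(nSnps = 0L, nGenes = 0L, nMissense = 0L,
                           nMissenseGenes = 0L, nSynonymous = 0L)))
  }
  nonsyn <- c("missense", "nonsense", "stop-loss")
  coding <- effects[effects$effect %in% c(nonsyn, "synonymous"), ,
                    drop = FALSE]
  perGene <- do.call(rbind, lapply(split(coding, coding$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], nSnps = nrow(d),
               nMissense = sum(d$effect %in% nonsyn),
               nSynonymous = sum(d$effect == "synonymous"))))
  rownames(perGene) <- NULL
  totals <- c(nSnps = sum(perGene$nSnps),
              nGenes = nrow(perGene),
              nMissense = sum(perGene$nMissense),
              nMissenseGenes = sum(perGene$nMissense >= 1),
              nSynonymous = sum(perGene$nSynonymous))
  list(perGene = perGene, totals = totals)
}

#' Differential-expression flag
#'
#' A gene is a DEG when \code{p <= pThreshold} AND \code{|log2FC| >=
#' lfcThreshold}; both inequalities are closed, so boundary values count.
#'
#' @param p p-values in [0, 1] (vectorized).
#' @param log2fc log2 fold changes.
#' @param pThreshold,lfcThreshold thresholds (defaults 0.05 and 1).
#' @return logical vector.
#' @export
degFlag <- function(p, log2fc, pThreshold = 0.05, lfcThreshold = 1) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  !is.na(p) & !is.na(log2fc) & p <= pThreshold & abs(log2fc) >= lfcThreshold
}

#' Rank candidate genes by combined evidence
#'
#' Tier 1: at least one nonsynonymous coding variant AND differentially
#' expressed. Tier 2: exactly one of the two. Tier 3: neither. Sorted by
#' (tier, decreasing missense count, gene id) — a deterministic, pure
#' function of the evidence.
#'
#' @param intervalGenes character vector of gene ids inside the mapping
#'   interval (or a \code{GRanges} with \code{gene_id}).
#' @param effects data.frame (gene_id, effect) or list of
#'   \code{classifyEffect} outputs; may be empty.
#' @param degRecords data.frame with \code{gene_id}, \code{log2fc} (or
#'   \code{log2_fold_change}), \code{pvalue} (or \code{p_value}); or a
#'   character vector of DEG gene ids.
#' @param pThreshold,lfcThreshold DEG thresholds.
#' @return data.frame: gene_id, in_interval, missense_count,
#'   total_cds_snps, is_deg, tier.
#' @export
rankCandidates <- function(intervalGenes, effects = NULL, degRecords = NULL,
                           pThreshold = 0.05, lfcThreshold = 1) {
  if (inherits(intervalGenes, "GRanges"))
    intervalGenes <- S4Vectors::mcols(intervalGenes)$gene_id
  vs <- summarizeVariants(if (is.null(effects))
    data.frame(gene_id = character(0), effect = character(0)) else effects)
  pg <- vs$perGene

  degIds <- character(0)
  if (is.character(degRecords)) {
    degIds <- degRecords
  } else if (is.data.frame(degRecords) && nrow(degRecords) > 0) {
    p <- degRecords$pvalue %||% degRecords$p_value
    l <- degRecords$log2fc %||% degRecords$log2_fold_change
    degIds <- degRecords$gene_id[degFlag(p, l, pThreshold, lfcThreshold)]
  }

  extra <- setdiff(pg$gene_id, intervalGenes)
  if (length(extra))
    warning("effects reported for gene(s) outside the interval: ",
            paste(extra, collapse = ", "), " (retained, flagged)")
  ids <- c(intervalGenes, extra)
  mis <- setNames(pg$nMissense, pg$gene_id)
  tot <- setNames(pg$nSnps, pg$gene_id)
  out <- data.frame(
    gene_id = ids,
    in_interval = ids %in% intervalGenes,
    missense_count = as.integer(ifelse(is.na(mis[ids]), 0L, mis[ids])),
    total_cds_snps = as.integer(ifelse(is.na(tot[ids]), 0L, tot[ids])),
    is_deg = ids %in% degIds,
    stringsAsFactors = FALSE)
  hasMis <- out$missense_count >= 1
  out$tier <- ifelse(hasMis & out$is_deg, 1L,
                     ifelse(hasMis | out$is_deg, 2L, 3L))
  out <- out[order(out$tier, -out$missense_count, out$gene_id), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
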