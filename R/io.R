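#' Read observed cross counts
#'
#' Two-column CSV: phenotype class label, count.
#'
#' @param path CSV file.
#' @return named integer vector of counts in file order.
#' @export
readCrossCounts <- function(path) {
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected two columns: class, count")
  counts <- as.integer(df[[2]])
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("total observed count is zero")
  setNames(counts, df[[1]])
}

#' Write segregation-test results
#'
#' @param results data.frame with columns cross, model, chi2, df, p,
#'   decision (e.g. built from \code{classifyInheritance} output).
#' @param tsvPath,jsonPath output paths (either may be NULL).
#' @return invisibly, \code{results}.
#' @export
writeSegTestReport <- function(results, tsvPath = NULL, jsonPath = NULL) {
  if (!is.null(tsvPath))
    write.table(results, tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(results, jsonPath, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Read a marker map CSV (name, chrom, bp[, cM])
#' @param path CSV file.
#' @return data.frame.
#' @export
readMarkerMap <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "bp")
  if (!all(need %in% names(df)))
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read/write genotype-table CSVs
#'
#' The calls CSV holds individuals in rows (first column = id) and markers
#' in columns, codes P1/P2/H with empty or NA for missing.
#'
#' @param callsPath calls CSV.
#' @param mapPath marker map CSV (see \code{readMarkerMap}).
#' @return a \code{MarkerGenotypeTable}.
#' @export
readGenotypeTable <- function(callsPath, mapPath) {
  mk <- readMarkerMap(mapPath)
  df <- read.csv(callsPath, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  calls <- as.matrix(df[, -1, drop = FALSE])
  calls[calls == ""] <- NA_character_
  if (!setequal(colnames(calls), mk$name))
    stop("calls columns do not match the marker map")
  calls <- calls[, mk$name, drop = FALSE]
  markerGenotypeTable(calls, mk, individuals = ids)
}

#' @rdname readGenotypeTable
#' @param table a \code{MarkerGenotypeTable}.
#' @param callsPath,mapPath output paths.
#' @export
writeGenotypeTable <- function(table, callsPath, mapPath) {
  mk <- markerInfo(table)
  write.csv(mk, mapPath, row.names = FALSE, quote = FALSE)
  df <- data.frame(id = table@individuals, genotypeCalls(table),
                   check.names = FALSE)
  write.csv(df, callsPath, row.names = FALSE, quote = FALSE, na = "")
  invisible(table)
}

.vcfInfoKeys <- c("QD", "FS", "MQ", "ReadPosRankSum", "InbreedingCoeff")

#' Write pooled variant sites as a two-sample VCF
#'
#' Minimal VCFv4.2 with INFO fields QD, FS, MQ, ReadPosRankSum,
#' InbreedingCoeff and FORMAT GT:AD:GQ for the WT and MT pool samples.
#'
#' @param sites pooled variant site table (see \code{applyHardFilters}).
#' @param path output file.
#' @param chromLengths named vector for \code{##contig} headers.
#' @param wtSample,mtSample sample column names.
#' @return invisibly, \code{path}.
#' @export
writePooledVcf <- function(sites, path, chromLengths = NULL,
                           wtSample = "WT", mtSample = "MT") {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(chromLengths))
             sprintf("##contig=<ID=%s,length=%d>", names(chromLengths),
                     as.integer(chromLengths)),
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   .vcfInfoKeys, .vcfInfoKeys),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", wtSample, mtSample), collapse = "\t"))
  fmtInfo <- function(i) {
    vals <- vapply(.vcfInfoKeys, function(k) sites[[k]][i], numeric(1))
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(sprintf("%s=%.6g", .vcfInfoKeys[keep], vals[keep]), collapse = ";")
  }
  gtOf <- function(refc, altc) {
    tot <- refc + altc
    ifelse(tot == 0, "./.",
           ifelse(altc / tot >= 0.9, "1/1",
                  ifelse(altc / tot <= 0.1, "0/0", "0/1")))
  }
  n <- nrow(sites)
  body <- paste(
    sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
    vapply(seq_len(n), fmtInfo, character(1)), "GT:AD:GQ",
    sprintf("%s:%d,%d:%d", gtOf(sites$wtRef, sites$wtAlt),
            sites$wtRef, sites$wtAlt, as.integer(sites$gqWT)),
    sprintf("%s:%d,%d:%d", gtOf(sites$mtRef, sites$mtAlt),
            sites$mtRef, sites$mtAlt, as.integer(sites$gqMT)),
    sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read pooled variant sites from a VCF
#'
#' Parses per-sample allele depths (FORMAT AD, required) and genotype
#' qualities (GQ) for the two pool samples, plus the INFO site statistics
#' QD, FS, MQ, ReadPosRankSum, InbreedingCoeff. Multiallelic records are
#' split into biallelic sites and flagged (\code{multiallelic} column);
#' positions stay 1-based throughout.
#'
#' @param path VCF file (plain or bgzipped).
#' @param wtSample,mtSample sample column names (default WT, MT).
#' @return pooled variant site table as consumed by
#'   \code{applyHardFilters}; empty VCF body yields a zero-row table with
#'   a warning.
#' @export
readPooledVcf <- function(path, wtSample = "WT", mtSample = "MT") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      isIndel = logical(0), multiallelic = logical(0))
  if (nrow(v@fix) == 0) {
    warning("VCF has no variant records")
    return(empty)
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  for (s in c(wtSample, mtSample))
    if (!s %in% samples) stop("sample '", s, "' not present in VCF")
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)AD(:|$)", fmt)))
    stop("FORMAT field AD (allele depths) missing for sample records")

  ad <- function(s) vcfR::extract.gt(v, element = "AD")[, s]
  gq <- function(s) suppressWarnings(
    as.numeric(vcfR::extract.gt(v, element = "GQ")[, s]))
  info <- function(k) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = k)))

  adWT <- ad(wtSample); adMT <- ad(mtSample)
  if (any(is.na(adWT))) stop("missing AD values for sample '", wtSample, "'")
  if (any(is.na(adMT))) stop("missing AD values for sample '", mtSample, "'")

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  nAlt <- lengths(alts)
  rows <- rep(seq_len(nrow(fix)), nAlt)
  altIdx <- unlist(lapply(nAlt, seq_len))
  pick <- function(adStr, k) {
    parts <- strsplit(adStr, ",", fixed = TRUE)
    ref <- as.integer(vapply(parts, `[`, character(1), 1))
    alt <- as.integer(mapply(function(p, i) p[i + 1], parts, k))
    cbind(ref, alt)
  }
  wt <- pick(adWT[rows], altIdx)
  mt <- pick(adMT[rows], altIdx)
  altAllele <- unlist(alts)

  out <- data.frame(
    chrom = fix$CHROM[rows], pos = as.numeric(fix$POS[rows]),
    ref = fix$REF[rows], alt = altAllele,
    isIndel = nchar(fix$REF[rows]) != 1 | nchar(altAllele) != 1,
    multiallelic = (nAlt > 1)[rows],
    wtRef = wt[, "ref"], wtAlt = wt[, "alt"],
    mtRef = mt[, "ref"], mtAlt = mt[, "alt"],
    stringsAsFactors = FALSE)
  for (k in .vcfInfoKeys) out[[k]] <- info(k)[rows]
  out$gqWT <- gq(wtSample)[rows]
  out$gqMT <- gq(mtSample)[rows]
  rownames(out) <- NULL
  out
}

#' Contig lengths declared in a VCF header
#' @param path VCF file.
#' @return named numeric vector (empty when no contig lines).
#' @export
vcfContigLengths <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE, nrows = 1)
  meta <- v@meta[grepl("^##contig", v@meta)]
  ids <- sub('.*ID=([^,>]+).*', "\\1", meta)
  lens <- as.numeric(sub(".*length=([0-9]+).*", "\\1", meta))
  setNames(lens, ids)
}

#' Write a delta SNP-index window track as TSV
#' @param track output of \code{scanDeltaIndex}.
#' @param path output file.
#' @export
writeWindowTrack <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write candidate regions as BED (0-based half-open)
#' @param regions \code{GRanges} from \code{callCandidateRegions}.
#' @param path output file.
#' @export
writeRegionsBed <- function(regions, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    name = sprintf("region%d", seq_along(regions)),
    score = S4Vectors::mcols(regions)$peakDelta)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write gene models (with CDS) as GFF3
#'
#' @param genes list of \code{GeneModel}.
#' @param path output file.
#' @export
writeGff3Genes <- function(genes, path) {
  feats <- do.call(rbind, lapply(genes, function(g) {
    seg <- g@cdsSegments
    rbind(
      data.frame(chrom = g@chrom, type = "gene", start = g@start,
                 end = g@stop, strand = g@strand,
                 attr = sprintf("ID=%s;Note=%s", g@geneId,
                                gsub("[;=\t]", " ", g@annotation))),
      data.frame(chrom = g@chrom, type = "CDS", start = seg[, 1],
                 end = seg[, 2], strand = g@strand,
                 attr = sprintf("ID=%s.cds;Parent=%s", g@geneId, g@geneId)))
  }))
  lines <- c("##gff-version 3",
             sprintf("%s\tdigenicBSA\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                     feats$chrom, feats$type, as.integer(feats$start),
                     as.integer(feats$end), feats$strand,
                     ifelse(feats$type == "CDS", "0", "."), feats$attr))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' CDS features are grouped under their parent gene, ordered by genomic
#' coordinate, strand preserved. A CDS without a parent gene or a
#' duplicated gene id is an error.
#'
#' @param path GFF3 file.
#' @return list of \code{GeneModel}, named by gene id.
#' @export
readGff3Genes <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  isGene <- gff$type == "gene"
  genes <- gff[isGene]
  ids <- genes$ID
  if (anyDuplicated(ids)) stop("duplicate gene id in GFF3")
  cds <- gff[gff$type == "CDS"]
  parent <- as.character(S4Vectors::unstrsplit(cds$Parent))
  parent <- sub("\\.cds$", "", parent)
  if (!all(parent %in% ids))
    stop("CDS feature without parent gene: ",
         paste(unique(setdiff(parent, ids)), collapse = ", "))
  out <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    segs <- cds[parent == ids[i]]
    ann <- if (!is.null(g$Note) && length(g$Note[[1]])) g$Note[[1]] else ""
    geneModel(ids[i], as.character(GenomicRanges::seqnames(g)),
              GenomicRanges::start(g), GenomicRanges::end(g),
              as.character(GenomicRanges::strand(g)),
              cbind(GenomicRanges::start(segs), GenomicRanges::end(segs)),
              annotation = ann)
  })
  setNames(out, ids)
}

#' Read CDS sequences from FASTA
#' @param path FASTA file (wrapped lines fine).
#' @return named \code{DNAStringSet}.
#' @export
readCdsFasta <- function(path) Biostrings::readDNAStringSet(path)

#' Read a differential-expression TSV
#'
#' Columns: gene id, log2 fold change, p-value, optional mean expression.
#' Common header spellings are normalized to \code{gene_id},
#' \code{log2fc}, \code{pvalue}, \code{mean_expr}.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readDeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  names(df)[nm %in% c("gene", "gene_id", "geneid")] <- "gene_id"
  names(df)[nm %in% c("log2fc", "log2_fold_change", "log2foldchange")] <-
    "log2fc"
  names(df)[nm %in% c("pvalue", "p_value", "p")] <- "pvalue"
  names(df)[nm %in% c("mean_expr", "fpkm", "mean_expression")] <- "mean_expr"
  if (!all(c("gene_id", "log2fc", "pvalue") %in% names(df)))
    stop("DE table needs gene id, log2 fold change and p-value columns")
  df
}

#' Bundled worked-example tables
#'
#' Convenience accessors for the small plain-text tables shipped under
#' \code{inst/extdata}: annotated genes of the two soybean fine-mapping
#' intervals (chromosomes 14 and 11), the coding variants found between
#' the NIL pools on chromosome 11 (with the amino-acid conversion as
#' printed, plus a normalized spelling), and observed F2 / progeny-test
#' segregation counts.
#'
#' @param name one of \code{"chr14_interval_genes"},
#'   \code{"chr11_interval_genes"}, \code{"chr11_coding_variants"},
#'   \code{"f2_cross_counts"}, \code{"f23_progeny_counts"}.
#' @return data.frame.
#' @export
exampleTable <- function(name = c("chr14_interval_genes",
                                  "chr11_interval_genes",
                                  "chr11_coding_variants",
                                  "f2_cross_counts",
                                  "f23_progeny_counts")) {
  name <- match.arg(name)
  ext <- if (name %in% c("f2_cross_counts", "f23_progeny_counts"))
    ".csv" else ".tsv"
  path <- system.file("extdata", paste0(name, ext), package = "digenicBSA",
                      mustWork = TRUE)
  if (ext == ".csv") read.csv(path, stringsAsFactors = FALSE)
  else read.delim(path, stringsAsFactors = FALSE)
}
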