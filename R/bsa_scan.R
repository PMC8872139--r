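#' Apply hard filters to pooled variant sites
#'
#' Marks each site pass/fail against a \code{\link{filterPolicy}}. SNPs
#' fail on \code{QD < QDmin | FS > FSmax | MQ < MQmin}; indels on the
#' indel expression. A missing site statistic skips that criterion and
#' flags the record (permissive semantics, as in GATK VariantFiltration).
#' A pool whose genotype quality falls below \code{gqMin} is masked —
#' its allele depths are treated as missing downstream — without failing
#' the site. Decisions are per-record and order-invariant.
#'
#' @param sites data.frame of pooled variant sites with columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{isIndel},
#'   \code{wtRef}, \code{wtAlt}, \code{mtRef}, \code{mtAlt}, \code{QD},
#'   \code{FS}, \code{MQ}, \code{ReadPosRankSum}, \code{InbreedingCoeff},
#'   \code{gqWT}, \code{gqMT}.
#' @param policy a \code{FilterPolicy}.
#' @return \code{sites} with added columns \code{filterPass},
#'   \code{filterReasons} (";"-separated, "" when passing),
#'   \code{wtMasked}, \code{mtMasked}, \code{statMissing}.
#' @export
applyHardFilters <- function(sites, policy = filterPolicy()) {
  validObject(policy)
  n <- nrow(sites)
  if (is.null(sites$isIndel)) sites$isIndel <- FALSE
  for (col in c("QD", "FS", "MQ", "ReadPosRankSum", "InbreedingCoeff"))
    if (is.null(sites[[col]])) sites[[col]] <- NA_real_
  for (col in c("gqWT", "gqMT"))
    if (is.null(sites[[col]])) sites[[col]] <- NA_real_

  reasons <- vector("list", n)
  add <- function(idx, tag) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], tag)
  }
  snp <- !sites$isIndel
  fail <- function(x, cmp, thr) !is.na(x) & cmp(x, thr)
  add(snp & fail(sites$QD, `<`, policy@snpQDmin), "QD")
  add(snp & fail(sites$FS, `>`, policy@snpFSmax), "FS")
  add(snp & fail(sites$MQ, `<`, policy@snpMQmin), "MQ")
  add(!snp & fail(sites$QD, `<`, policy@indelQDmin), "QD")
  add(!snp & fail(sites$FS, `>`, policy@indelFSmax), "FS")
  add(!snp & fail(sites$ReadPosRankSum, `<`, policy@indelRPRSmin),
      "ReadPosRankSum")
  add(!snp & fail(sites$InbreedingCoeff, `<`, policy@indelICmin),
      "InbreedingCoeff")

  sites$filterReasons <- vapply(reasons, function(r)
    paste(r, collapse = ";"), character(1))
  sites$filterPass <- sites$filterReasons == ""
  sites$wtMasked <- !is.na(sites$gqWT) & sites$gqWT < policy@gqMin
  sites$mtMasked <- !is.na(sites$gqMT) & sites$gqMT < policy@gqMin
  needed <- ifelse(snp, 3L, 4L)
  present <- (!is.na(sites$QD)) + (!is.na(sites$FS)) +
    ifelse(snp, !is.na(sites$MQ),
           (!is.na(sites$ReadPosRankSum)) + (!is.na(sites$InbreedingCoeff)))
  sites$statMissing <- present < needed
  sites
}

#' Summarize a filtered site table for run logging
#'
#' @param sites output of \code{applyHardFilters}.
#' @return list with \code{recordsIn}, \code{recordsPassed}, and
#'   \code{failedByReason} (named counts; multi-reason records counted once
#'   under their combined reason string).
#' @export
filterSummary <- function(sites) {
  failed <- sites$filterReasons[!sites$filterPass]
  list(recordsIn = nrow(sites),
       recordsPassed = sum(sites$filterPass),
       failedByReason = if (length(failed)) table(failed) else table(character(0)))
}

#' Pooled SNP index from allele depths
#'
#' The SNP index of a pool at a site is the fraction of reads carrying the
#' alternate (mutant-parent) allele, \code{alt / (ref + alt)}. It is
#' missing (\code{NA}) when the pool has no reads, or fewer than
#' \code{minDepth} reads, at the site.
#'
#' @param refCount,altCount non-negative read counts (vectorized).
#' @param minDepth minimum total depth for a defined index.
#' @return numeric vector in [0, 1] with NAs.
#' @examples
#' snpIndex(0, 31)   # 1
#' snpIndex(31, 0)   # 0
#' snpIndex(10, 10)  # 0.5
#' @export
snpIndex <- function(refCount, altCount, minDepth = 0) {
  if (any(refCount < 0, na.rm = TRUE) || any(altCount < 0, na.rm = TRUE))
    stop("negative read counts")
  total <- refCount + altCount
  idx <- altCount / total
  idx[is.na(total) | total == 0 | total < minDepth] <- NA_real_
  idx
}

#' Sliding-window mean of per-site values along one chromosome
#'
#' Windows are anchored at coordinate 1 and advance by \code{step}; a site
#' at position p belongs to window k iff \code{start_k <= p < start_k +
#' windowSize} (half-open). The window mean is the unweighted average of
#' the non-missing site values it contains; windows holding fewer than
#' \code{minSnps} sites report \code{NA}. The final partial window is
#' retained and flagged.
#'
#' @param positions sorted 1-based site positions on one chromosome.
#' @param values per-site values (same length; NAs allowed).
#' @param chromLength chromosome length in bp.
#' @param config a \code{ScanConfig}.
#' @return data.frame with \code{start}, \code{end} (1-based inclusive
#'   span, clipped at the chromosome end), \code{nSnps}, \code{mean},
#'   \code{partial}.
#' @export
windowScan <- function(positions, values, chromLength,
                       config = scanConfig()) {
  validObject(config)
  if (is.unsorted(positions)) stop("positions must be sorted")
  if (length(positions) != length(values))
    stop("positions and values must have equal length")
  W <- config@windowSize
  s <- config@step
  starts <- seq(1, chromLength, by = s)
  endsExcl <- starts + W            # half-open upper bounds
  ends <- pmin(starts + W - 1, chromLength)

  ## window membership via findInterval on the sorted positions; means are
  ## taken with mean() per window so results are exact (no running-sum
  ## rounding across windows)
  upTo <- function(x) findInterval(x, positions)
  nAll <- upTo(endsExcl - 1) - upTo(starts - 1)
  ok <- !is.na(values)
  posOk <- positions[ok]
  valOk <- values[ok]
  upToOk <- function(x) findInterval(x, posOk)
  hi <- upToOk(endsExcl - 1)
  lo <- upToOk(starts - 1)
  means <- vapply(seq_along(starts), function(k) {
    if (hi[k] <= lo[k]) return(NA_real_)
    mean(valOk[(lo[k] + 1):hi[k]])
  }, numeric(1))
  means[nAll < config@minSnps] <- NA_real_
  data.frame(start = starts, end = ends, nSnps = nAll, mean = means,
             partial = (starts + W - 1) > chromLength)
}

#' Delta SNP-index track from paired pool window scans
#'
#' @param wt,mt window scans (from \code{windowScan}) of the wild-type and
#'   mutant pools on the same window grid.
#' @return the grid with columns \code{nSnps}, \code{meanWT},
#'   \code{meanMT}, \code{delta} (\code{meanMT - meanWT}; NA when either
#'   side is missing).
#' @export
deltaTrack <- function(wt, mt) {
  if (!identical(wt$start, mt$start) || !identical(wt$end, mt$end))
    stop("window grids of the two pools do not match")
  data.frame(start = wt$start, end = wt$end,
             nSnps = pmax(wt$nSnps, mt$nSnps),
             meanWT = wt$mean, meanMT = mt$mean,
             delta = mt$mean - wt$mean,
             partial = wt$partial)
}

#' Full delta SNP-index scan over filtered pooled sites
#'
#' Convenience wrapper: applies \code{snpIndex} per pool (masked pools and
#' sub-threshold depths give missing indices), scans each chromosome, and
#' returns the combined delta track. Only sites with
#' \code{filterPass == TRUE} are used; run \code{applyHardFilters} first
#' (sites without a \code{filterPass} column are all used).
#'
#' @param sites pooled variant site table (see \code{applyHardFilters}).
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param config a \code{ScanConfig}.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{nSnps}, \code{meanWT}, \code{meanMT}, \code{delta},
#'   \code{partial}.
#' @export
scanDeltaIndex <- function(sites, chromLengths, config = scanConfig()) {
  if (!is.null(sites$filterPass)) sites <- sites[sites$filterPass, ]
  idxWT <- snpIndex(sites$wtRef, sites$wtAlt, config@minDepth)
  idxMT <- snpIndex(sites$mtRef, sites$mtAlt, config@minDepth)
  if (!is.null(sites$wtMasked)) idxWT[sites$wtMasked] <- NA_real_
  if (!is.null(sites$mtMasked)) idxMT[sites$mtMasked] <- NA_real_
  out <- lapply(names(chromLengths), function(ch) {
    sel <- which(sites$chrom == ch)
    sel <- sel[order(sites$pos[sel])]
    wt <- windowScan(sites$pos[sel], idxWT[sel], chromLengths[[ch]], config)
    mt <- windowScan(sites$pos[sel], idxMT[sel], chromLengths[[ch]], config)
    cbind(chrom = ch, deltaTrack(wt, mt))
  })
  do.call(rbind, out)
}

#' Call candidate regions from a delta track
#'
#' A candidate region is a maximal run of consecutive windows with
#' \code{delta >= threshold} (inclusive); a missing delta breaks a run.
#' The region span is the union of the member windows' spans.
#'
#' @param track delta track from \code{scanDeltaIndex} (or
#'   \code{deltaTrack} plus a \code{chrom} column).
#' @param threshold call threshold (default 1, the noiseless expectation
#'   for a fixed causal block; lower under sequencing error).
#' @return \code{GRanges} of regions with metadata \code{peakDelta},
#'   \code{nWindows}.
#' @export
callCandidateRegions <- function(track, threshold = 1.0) {
  if (is.null(track$chrom)) track$chrom <- "chr"
  regs <- lapply(split(seq_len(nrow(track)), track$chrom), function(ii) {
    d <- track[ii, ]
    if (is.unsorted(d$start)) stop("track must be sorted by window start")
    hit <- !is.na(d$delta) & d$delta >= threshold
    if (!any(hit)) return(NULL)
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(
      chrom = d$chrom[1],
      start = d$start[starts[keep]],
      end = d$end[ends[keep]],
      peakDelta = vapply(keep, function(k)
        max(d$delta[starts[k]:ends[k]]), numeric(1)),
      nWindows = r$lengths[keep])
  })
  regs <- do.call(rbind, regs)
  if (is.null(regs))
    return(GenomicRanges::GRanges(peakDelta = numeric(0),
                                  nWindows = integer(0)))
  gr <- GenomicRanges::GRanges(regs$chrom,
                               IRanges::IRanges(regs$start, regs$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(peakDelta = regs$peakDelta,
                                               nWindows = regs$nWindows)
  sort(gr)
}
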