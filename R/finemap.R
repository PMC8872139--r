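#' Screen pooled marker profiles for linkage to the mutant locus
#'
#' In SSR-based bulked segregant analysis a marker is a linkage candidate
#' when the mutant bulk shows only the mutant-parent allele while the
#' wild-type bulk differs (typically showing both alleles). Profiles give
#' the set of parental alleles visible in each bulk.
#'
#' @param profiles data.frame with columns \code{marker}, \code{MT},
#'   \code{WT}; \code{MT}/\code{WT} are comma-separated subsets of
#'   \code{"P1","P2"} (alleles visible in the mutant / wild-type pool).
#' @return character vector of linked marker names.
#' @examples
#' bsaMarkerScreen(data.frame(marker = c("m1", "m2"),
#'                            MT = c("P2", "P1,P2"),
#'                            WT = c("P1,P2", "P1,P2")))
#' @export
bsaMarkerScreen <- function(profiles) {
  stopifnot(nrow(profiles) > 0,
            all(c("marker", "MT", "WT") %in% names(profiles)))
  parse <- function(x) strsplit(as.character(x), "[,/]")
  mt <- parse(profiles$MT)
  wt <- parse(profiles$WT)
  if (any(lengths(mt) == 0) || any(lengths(wt) == 0))
    stop("each pool must show at least one allele")
  linked <- vapply(seq_len(nrow(profiles)), function(i) {
    setequal(mt[[i]], "P2") && !setequal(wt[[i]], "P2")
  }, logical(1))
  profiles$marker[linked]
}

#' Build bulk allele profiles from a genotype table
#'
#' Forms the allele sets each bulk would display: the union of parental
#' alleles carried by the pooled individuals at each marker (a heterozygote
#' contributes both alleles). Missing calls contribute nothing.
#'
#' @param table a \code{MarkerGenotypeTable}.
#' @param mutantIds,wildIds individual ids forming the two bulks.
#' @return data.frame with columns marker, MT, WT suitable for
#'   \code{bsaMarkerScreen}.
#' @export
poolProfiles <- function(table, mutantIds, wildIds) {
  calls <- genotypeCalls(table)
  alleleSet <- function(v) {
    v <- v[!is.na(v)]
    a <- character(0)
    if (any(v %in% c("P1", "H"))) a <- c(a, "P1")
    if (any(v %in% c("P2", "H"))) a <- c(a, "P2")
    paste(a, collapse = ",")
  }
  mk <- markerInfo(table)$name
  data.frame(
    marker = mk,
    MT = apply(calls[mutantIds, , drop = FALSE], 2, alleleSet),
    WT = apply(calls[wildIds, , drop = FALSE], 2, alleleSet),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Count recombination events at a marker among mutant individuals
#'
#' All individuals in the table are assumed phenotypic mutants, i.e.
#' homozygous for the mutant-parent allele at the causal locus. In
#' \code{"chromosomes"} mode each heterozygous call contributes one
#' recombinant chromosome and each P1 homozygote two; in
#' \code{"individuals"} mode any non-P2 call counts one. Missing calls are
#' excluded from the denominator, never imputed.
#'
#' @param table a \code{MarkerGenotypeTable} of mutant individuals.
#' @param marker marker name (must exist in the table).
#' @param mode counting unit, \code{"chromosomes"} (default) or
#'   \code{"individuals"}.
#' @return list with \code{marker}, \code{events},
#'   \code{individualsCounted}, \code{mode}.
#' @export
countRecombinants <- function(table, marker,
                              mode = c("chromosomes", "individuals")) {
  mode <- match.arg(mode)
  calls <- genotypeCalls(table)
  if (!marker %in% colnames(calls))
    stop("marker '", marker, "' not present in the genotype table")
  v <- calls[, marker]
  v <- v[!is.na(v)]
  events <- if (mode == "chromosomes")
    sum(v == "H") + 2L * sum(v == "P1")
  else
    sum(v != "P2")
  list(marker = marker, events = as.integer(events),
       individualsCounted = length(v), mode = mode)
}

#' Count recombination events at every marker
#'
#' @inheritParams countRecombinants
#' @return data.frame (marker, chrom, bp, events, individualsCounted, mode)
#'   in map order.
#' @export
countRecombinantsAll <- function(table,
                                 mode = c("chromosomes", "individuals")) {
  mode <- match.arg(mode)
  mk <- markerInfo(table)
  res <- lapply(mk$name, countRecombinants, table = table, mode = mode)
  data.frame(
    marker = mk$name, chrom = mk$chrom, bp = mk$bp,
    events = vapply(res, `[[`, integer(1), "events"),
    individualsCounted = vapply(res, `[[`, integer(1), "individualsCounted"),
    mode = mode, stringsAsFactors = FALSE)
}

#' Delimit a mapping interval from ordered recombinant counts
#'
#' Locates the maximal run of zero-recombinant markers and brackets it by
#' the nearest markers with events > 0 on each side. When several zero
#' runs exist the run with the lowest total flanking events is chosen and
#' the ambiguity reported. A run touching a chromosome end yields a
#' one-sided interval flagged open-ended on that side. The physical span
#' is the inclusive bp difference between the flanking markers.
#'
#' @param counts data.frame as from \code{countRecombinantsAll}, for a
#'   single chromosome, ordered by bp.
#' @return a \code{GRanges} of length 1 with metadata columns
#'   \code{leftMarker}, \code{rightMarker}, \code{openLeft},
#'   \code{openRight}, \code{spanBp}, \code{zeroMarkers},
#'   \code{ambiguous}.
#' @examples
#' counts <- data.frame(marker = c("A", "B", "C"), chrom = "Chr14",
#'                      bp = c(1e6, 2e6, 3e6), events = c(2L, 0L, 7L))
#' delimitInterval(counts)
#' @export
delimitInterval <- function(counts) {
  stopifnot(all(c("marker", "chrom", "bp", "events") %in% names(counts)))
  if (length(unique(counts$chrom)) != 1)
    stop("delimitInterval expects counts from a single chromosome")
  if (is.unsorted(counts$bp, strictly = TRUE))
    stop("counts must be ordered by bp")
  if (nrow(counts) < 3)
    stop("need at least three ordered markers")
  zero <- counts$events == 0
  if (!any(zero)) stop("locus not bracketed: no zero-recombinant marker")

  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  flankTotal <- vapply(runs, function(k) {
    lf <- if (starts[k] > 1) counts$events[starts[k] - 1L] else 0L
    rf <- if (ends[k] < nrow(counts)) counts$events[ends[k] + 1L] else 0L
    lf + rf
  }, integer(1))
  ambiguous <- length(runs) > 1 && sum(flankTotal == min(flankTotal)) > 1
  if (ambiguous)
    warning("multiple zero-recombinant runs tie on flanking events; ",
            "reporting the first")
  k <- runs[which.min(flankTotal)]

  openLeft <- starts[k] == 1L
  openRight <- ends[k] == nrow(counts)
  li <- if (openLeft) starts[k] else starts[k] - 1L
  ri <- if (openRight) ends[k] else ends[k] + 1L
  if (openLeft || openRight)
    warning("zero-recombinant run touches the chromosome end; ",
            "interval is open-ended")

  gr <- GenomicRanges::GRanges(
    counts$chrom[1],
    IRanges::IRanges(counts$bp[li], counts$bp[ri]))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    leftMarker = counts$marker[li], rightMarker = counts$marker[ri],
    openLeft = openLeft, openRight = openRight,
    spanBp = counts$bp[ri] - counts$bp[li] + 1,
    zeroMarkers = paste(counts$marker[starts[k]:ends[k]], collapse = ","),
    ambiguous = ambiguous)
  gr
}
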