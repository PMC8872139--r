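#' Built-in epistasis model registry
#'
#' \code{epistasisModel} retrieves a named model:
#' \describe{
#'   \item{duplicate_recessive_mutant}{two loci; mutant phenotype only when
#'     homozygous recessive at both (15:1 wild:mutant in F2).}
#'   \item{monogenic_recessive}{one locus; mutant when homozygous recessive
#'     (3:1).}
#'   \item{monogenic_dominant}{one locus; mutant when carrying at least one
#'     dominant allele (1:3 wild:mutant).}
#' }
#' Custom maps are built with \code{makeEpistasisModel}.
#'
#' @param name registry name.
#' @param fixedBackground optional \code{c(locus = "1"|"2",
#'   genotype = "aa")} pinning one locus, e.g. a cross to a parent already
#'   homozygous recessive at that locus.
#' @return an \code{EpistasisModel}.
#' @examples
#' epistasisModel("duplicate_recessive_mutant")
#' @export
epistasisModel <- function(name, fixedBackground = character(0)) {
  keys2 <- jointClassKeys(2L)
  switch(name,
    duplicate_recessive_mutant = {
      map <- setNames(rep("wild-type", 9L), keys2)
      map["aa:aa"] <- "mutant"
      makeEpistasisModel(name, map, fixedBackground)
    },
    monogenic_recessive = {
      map <- c(AA = "wild-type", Aa = "wild-type", aa = "mutant")
      makeEpistasisModel(name, map)
    },
    monogenic_dominant = {
      map <- c(AA = "mutant", Aa = "mutant", aa = "wild-type")
      makeEpistasisModel(name, map)
    },
    stop("unknown model '", name, "'; use makeEpistasisModel() for custom maps")
  )
}

#' @rdname epistasisModel
#' @param phenoMap named character vector over the 3 (one-locus) or 9
#'   (two-locus) joint genotype classes, values "wild-type"/"mutant".
#' @export
makeEpistasisModel <- function(name, phenoMap, fixedBackground = character(0)) {
  nLoci <- if (length(phenoMap) == 3L) 1L else 2L
  new("EpistasisModel", name = name, nLoci = nLoci, phenoMap = phenoMap,
      fixedBackground = fixedBackground)
}

## Mendelian selfing frequencies of a single heterozygous locus, in
## sixteenths of the per-locus denominator 4.
.selfFreq4 <- c(AA = 1L, Aa = 2L, aa = 1L)

#' Enumerate F2 joint genotype classes
#'
#' Enumerates the joint genotype classes of a selfed (double) heterozygote
#' under Mendelian segregation, in exact rational arithmetic (integer
#' numerators over a common denominator), so class frequencies sum to
#' exactly one. With a fixed background the pinned locus contributes a
#' single genotype with frequency one and only the segregating locus
#' expands, giving three classes over denominator 4.
#'
#' @param model an \code{EpistasisModel}.
#' @return data.frame with columns \code{locus1}, \code{locus2} (NA for
#'   one-locus models), \code{class} (joint key), \code{num}, \code{den}
#'   (exact frequency \code{num/den}), and \code{phenotype}.
#' @examples
#' enumerateF2(epistasisModel("duplicate_recessive_mutant"))
#' @export
enumerateF2 <- function(model) {
  validObject(model)
  if (model@nLoci == 1L) {
    df <- data.frame(locus1 = GENOTYPE_CODES, locus2 = NA_character_,
                     num = unname(.selfFreq4[GENOTYPE_CODES]), den = 4L,
                     stringsAsFactors = FALSE)
  } else if (length(model@fixedBackground)) {
    fb <- model@fixedBackground
    segLocus <- if (fb[["locus"]] == "1") "locus2" else "locus1"
    df <- data.frame(locus1 = NA_character_, locus2 = NA_character_,
                     num = unname(.selfFreq4[GENOTYPE_CODES]), den = 4L,
                     stringsAsFactors = FALSE)
    df[[segLocus]] <- GENOTYPE_CODES
    df[[if (segLocus == "locus1") "locus2" else "locus1"]] <- fb[["genotype"]]
  } else {
    g <- expand.grid(locus1 = GENOTYPE_CODES, locus2 = GENOTYPE_CODES,
                     stringsAsFactors = FALSE)
    df <- data.frame(g, num = .selfFreq4[g$locus1] * .selfFreq4[g$locus2],
                     den = 16L, stringsAsFactors = FALSE)
  }
  df$class <- if (model@nLoci == 1L) df$locus1 else
    paste(df$locus1, df$locus2, sep = ":")
  df$phenotype <- unname(model@phenoMap[df$class])
  rownames(df) <- NULL
  stopifnot(sum(df$num) == df$den[1])  # exact normalization
  df
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

.reduceRatio <- function(a, b, labels) {
  d <- .gcd(max(a, b), min(a, b))
  if (d == 0) d <- 1
  out <- c(a %/% d, b %/% d)
  names(out) <- labels
  attr(out, "degenerate") <- any(out == 0)
  out
}

#' Expected F2 phenotypic ratio under a model
#'
#' Sums exact class frequencies by phenotype and reduces to coprime integer
#' parts. A model with an empty phenotype class yields a degenerate ratio
#' (one part zero) with a warning.
#'
#' @param model an \code{EpistasisModel}.
#' @return named integer vector \code{c(wild, mutant)} with attribute
#'   \code{degenerate}.
#' @examples
#' f2PhenotypeRatio(epistasisModel("duplicate_recessive_mutant"))  # 15:1
#' @export
f2PhenotypeRatio <- function(model) {
  df <- enumerateF2(model)
  wild <- sum(df$num[df$phenotype == "wild-type"])
  mut <- sum(df$num[df$phenotype == "mutant"])
  out <- .reduceRatio(wild, mut, c("wild", "mutant"))
  if (attr(out, "degenerate"))
    warning("degenerate phenotypic ratio: one phenotype class is empty")
  out
}

## Selfed-progeny genotype classes of one locus genotype.
.selfProgeny1 <- function(g) {
  switch(g, AA = "AA", aa = "aa", Aa = GENOTYPE_CODES)
}

## TRUE when selfing an individual of this joint class can yield at least
## one mutant-phenotype progeny genotype under the model.
.selfSegregates <- function(class, model) {
  parts <- strsplit(class, ":", fixed = TRUE)[[1]]
  prog <- if (model@nLoci == 1L) .selfProgeny1(parts[1])
  else as.vector(outer(.selfProgeny1(parts[1]), .selfProgeny1(parts[2]),
                       paste, sep = ":"))
  any(model@phenoMap[prog] == "mutant")
}

#' Expected F2:3 progeny-test ratio under a model
#'
#' Among F2 individuals of wild-type phenotype, a line is expected to
#' segregate in the F2:3 generation iff selfed progeny of its genotype
#' class include at least one mutant-phenotype genotype. Frequencies are
#' summed exactly and reduced to coprime integer parts.
#'
#' @param model an \code{EpistasisModel}.
#' @return named integer vector \code{c(segregating, nonsegregating)} with
#'   attribute \code{degenerate}.
#' @examples
#' f23ProgenyRatio(epistasisModel("duplicate_recessive_mutant"))  # 8:7
#' @export
f23ProgenyRatio <- function(model) {
  df <- enumerateF2(model)
  wt <- df[df$phenotype == "wild-type", , drop = FALSE]
  if (nrow(wt) == 0)
    stop("model has no wild-type F2 class; progeny-test ratio undefined")
  seg <- vapply(wt$class, .selfSegregates, logical(1), model = model)
  out <- .reduceRatio(sum(wt$num[seg]), sum(wt$num[!seg]),
                      c("segregating", "nonsegregating"))
  if (attr(out, "degenerate"))
    warning("degenerate progeny-test ratio: one class is empty")
  out
}

#' Chi-square goodness-of-fit test against an expected ratio
#'
#' Pearson statistic \eqn{\sum (O-E)^2/E} with \eqn{E_i = N p_i} from the
#' integer ratio parts. Two reporting conventions found in segregation
#' tables are exposed: \code{roundExpected} rounds each expected count to
#' the nearest integer before computing the statistic, and \code{yates}
#' applies the continuity correction \eqn{(|O-E|-0.5)^2/E} (floored at 0).
#' Both default off.
#'
#' @param observed non-negative integer counts, one per phenotype class.
#' @param ratio integer ratio parts in the same class order (e.g.
#'   \code{c(15, 1)} or the output of \code{f2PhenotypeRatio}).
#' @param roundExpected,yates convention flags.
#' @return object of class \code{"segTest"}: list with \code{observed},
#'   \code{expected}, \code{chi2}, \code{df}, \code{p.value},
#'   \code{convention}.
#' @examples
#' chiSquareGof(c(420, 120), c(3, 1))   # chi2 2.22, p 0.14
#' chiSquareGof(c(93, 87), c(8, 7))     # chi2 0.20, p 0.65
#' @export
chiSquareGof <- function(observed, ratio, roundExpected = FALSE,
                         yates = FALSE) {
  if (length(observed) < 2) stop("need at least two phenotype classes")
  if (length(ratio) != length(observed))
    stop("ratio must have one part per observed class")
  if (any(observed < 0)) stop("negative observed counts")
  if (any(ratio < 0)) stop("negative ratio parts")
  total <- sum(observed)
  if (total < 1) stop("total observed count must be >= 1")
  expected <- total * ratio / sum(ratio)
  stopifnot(isTRUE(all.equal(sum(expected), total)))
  eUsed <- if (roundExpected) round(expected) else expected
  if (any(eUsed == 0)) stop("expected count of zero; test undefined")
  dev <- abs(observed - eUsed)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / eUsed)
  df <- length(observed) - 1L
  structure(
    list(observed = observed, expected = eUsed, chi2 = chi2, df = df,
         p.value = pchisq(chi2, df, lower.tail = FALSE),
         convention = c(roundExpected = roundExpected, yates = yates)),
    class = "segTest")
}

#' @export
print.segTest <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit: chi2 = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p.value))
  cat("  observed:", paste(x$observed, collapse = ":"),
      " expected:", paste(signif(x$expected, 6), collapse = ":"), "\n")
  if (any(x$convention))
    cat("  convention:", paste(names(x$convention)[x$convention],
                               collapse = ", "), "\n")
  invisible(x)
}

#' Classify the inheritance mode of observed crosses
#'
#' Tests each cross against the expected F2 phenotypic ratio of every
#' candidate model and reports the models whose p-value clears
#' \code{alpha}, plus the best (maximum-p) model. Ties are broken by fewer
#' loci, then lexicographic model name.
#'
#' @param observations named list of count vectors \code{c(wild, mutant)}
#'   (or a data.frame with columns \code{cross}, \code{wild},
#'   \code{mutant}).
#' @param models list of \code{EpistasisModel}s.
#' @param alpha acceptance threshold on the p-value (default 0.05).
#' @return list with \code{tests} (long data.frame: cross, model, chi2, df,
#'   p, accepted) and \code{best} (data.frame: cross, model, p).
#' @export
classifyInheritance <- function(observations, models, alpha = 0.05) {
  if (is.data.frame(observations)) {
    observations <- setNames(
      lapply(seq_len(nrow(observations)),
             function(i) c(observations$wild[i], observations$mutant[i])),
      observations$cross)
  }
  if (length(observations) == 0 || length(models) == 0)
    stop("need at least one observation and one model")
  rows <- list()
  for (cross in names(observations)) {
    counts <- observations[[cross]]
    for (m in models) {
      ratio <- suppressWarnings(f2PhenotypeRatio(m))
      res <- tryCatch(chiSquareGof(counts, unname(ratio)),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cross = cross, model = m@name, nLoci = m@nLoci,
        chi2 = res$chi2, df = res$df, p = res$p.value,
        accepted = res$p.value >= alpha, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(tests, tests$cross), function(d) {
    d <- d[order(-d$p, d$nLoci, d$model), , drop = FALSE]
    d[1, c("cross", "model", "p")]
  }))
  rownames(best) <- NULL
  list(tests = tests, best = best)
}
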