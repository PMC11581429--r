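#' Mutation significance cutoff (MSC) for one gene
#'
#' The MSC is a per-gene CADD threshold below which a variant is unlikely to
#' be disease causing. It is derived from the CADD scores of the gene's
#' known disease-causing mutations as the lower boundary of the two-sided
#' Student-t confidence interval of their mean at the given confidence
#' level. With a single score the score itself is returned; with no scores
#' the supplied fallback is used. Zero-variance inputs return the common
#' value.
#'
#' @param diseaseScores numeric CADD scores of known disease mutations.
#' @param confidence confidence level in (0,1); default 0.99.
#' @param fallback value returned when no disease score is available.
#' @return The MSC (numeric scalar).
#' @examples
#' computeMSC(c(24, 24, 24))         # 24
#' computeMSC(numeric(0), fallback = 15)
#' @export
computeMSC <- function(diseaseScores, confidence = 0.99, fallback = NA_real_) {
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0,1)")
  if (length(diseaseScores) == 0) return(fallback)
  if (any(!is.finite(diseaseScores)))
    stop("non-finite disease score in input")
  n <- length(diseaseScores)
  if (n == 1) return(diseaseScores)
  m <- mean(diseaseScores)
  s <- stats::sd(diseaseScores)
  if (s == 0) return(m)
  m - stats::qt(1 - (1 - confidence) / 2, df = n - 1) * s / sqrt(n)
}

#' Compute MSC values for a per-gene disease-score table
#'
#' @param scoreTable data.frame or TSV path with columns `gene` and `score`
#'   (one row per known disease mutation).
#' @param confidence confidence level, see [computeMSC()].
#' @param fallback MSC for genes with no scores.
#' @return data.frame with columns `gene` and `msc`.
#' @export
computeGeneMSC <- function(scoreTable, confidence = 0.99,
                           fallback = NA_real_) {
  st <- .readTab(scoreTable, "disease-score")
  if (!all(c("gene", "score") %in% names(st)))
    stop("score table needs columns: gene, score")
  msc <- vapply(split(st$score, st$gene), computeMSC, numeric(1),
                confidence = confidence, fallback = fallback)
  data.frame(gene = names(msc), msc = unname(msc))
}

#' Gene damage index (GDI) filter
#'
#' The GDI measures the accumulated mutational damage of a gene in healthy
#' populations; genes with GDI strictly above the cutoff (default 13.84, the
#' 95% CI upper boundary) are unlikely to be disease-causing and are
#' excluded. Genes with no GDI value pass with a warning, so a candidate is
#' never lost to an annotation gap.
#'
#' @param geneScores data.frame with columns `gene` and `gdi`.
#' @param cutoff exclusion is strictly above this value; 13.84 retained.
#' @return Character vector of retained gene symbols.
#' @export
gdiFilter <- function(geneScores, cutoff = 13.84) {
  stopifnot(cutoff > 0)
  miss <- is.na(geneScores$gdi)
  if (any(miss))
    warning("genes with missing GDI retained: ",
            paste(geneScores$gene[miss], collapse = ", "))
  geneScores$gene[miss | geneScores$gdi <= cutoff]
}

#' CADD/MSC deleteriousness ratio filter
#'
#' A variant is kept iff its CADD score divided by its gene's MSC is
#' strictly higher than the threshold (default 1): the variant must exceed
#' the gene's own significance cutoff. Variants with a missing CADD are
#' dropped (flagged unscored by the caller); a non-positive MSC makes the
#' ratio undefined and the variant is kept with a warning.
#'
#' @param cadd numeric vector of CADD scores (NA = unscored).
#' @param msc numeric vector (recycled) of gene MSC values.
#' @param ratioThreshold kept iff cadd/msc strictly above; default 1.
#' @return Logical vector, `TRUE` for kept variants.
#' @examples
#' deleteriousnessFilter(c(25, 20, 3), 20)   # TRUE FALSE FALSE
#' @export
deleteriousnessFilter <- function(cadd, msc, ratioThreshold = 1.0) {
  n <- max(length(cadd), length(msc))
  cadd <- rep_len(cadd, n); msc <- rep_len(msc, n)
  keep <- logical(n)
  undef <- !is.na(msc) & msc <= 0 & !is.na(cadd)
  if (any(undef)) {
    warning(sum(undef), " variant(s) kept with non-positive MSC ",
            "(ratio undefined)")
    keep[undef] <- TRUE
  }
  ok <- !is.na(cadd) & !is.na(msc) & msc > 0
  keep[ok] <- cadd[ok] / msc[ok] > ratioThreshold
  # cadd missing -> drop (unscored); msc missing with cadd present -> keep,
  # same annotation-gap policy as gdiFilter
  mscgap <- is.na(msc) & !is.na(cadd)
  if (any(mscgap)) {
    warning(sum(mscgap), " variant(s) kept with missing MSC")
    keep[mscgap] <- TRUE
  }
  keep
}
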