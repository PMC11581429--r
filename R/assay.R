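#' Construct an antigen-array container
#'
#' @param nfi numeric matrix of net fluorescence intensities (antigens x
#'   samples).
#' @param snr numeric matrix of signal-to-noise ratios, same shape.
#' @param groups character vector of per-sample group labels (e.g. DMSO,
#'   AIM100, Cpd4f).
#' @param isControl logical vector flagging internal IgG control antigens
#'   (used for normalization); default none.
#' @return An \linkS4class{AntigenArray}.
#' @export
antigenArray <- function(nfi, snr, groups,
                         isControl = rep(FALSE, nrow(nfi))) {
  se <- SummarizedExperiment(
    assays = list(nfi = as.matrix(nfi), snr = as.matrix(snr)),
    rowData = S4Vectors::DataFrame(is_control = isControl,
                                   row.names = rownames(nfi)),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(nfi)))
  new("AntigenArray", se)
}

setMethod("show", "AntigenArray", function(object) {
  cat("AntigenArray:", nrow(object), "antigens x", ncol(object),
      "samples; groups:",
      paste(unique(SummarizedExperiment::colData(object)$group),
            collapse = ", "), "\n")
  invisible(NULL)
})

#' Autoantibody Ab Score
#'
#' `log2(NFI * SNR + 1)`: zero signal maps to 0 and the score is strictly
#' increasing in the product of net fluorescence intensity and
#' signal-to-noise ratio. Negative inputs (over-subtracted background) are
#' clamped to 0 with a warning.
#'
#' @param nfi net fluorescence intensity (scalar, vector or matrix).
#' @param snr signal-to-noise ratio, same shape or recyclable.
#' @return Ab Score(s), same shape as the inputs.
#' @examples
#' abScore(0, 5)   # 0
#' abScore(1, 1)   # 1
#' abScore(3, 5)   # 4
#' @export
abScore <- function(nfi, snr) {
  if (any(nfi < 0, na.rm = TRUE) || any(snr < 0, na.rm = TRUE)) {
    warning("negative NFI/SNR clamped to 0")
    nfi <- pmax(nfi, 0)
    snr <- pmax(snr, 0)
  }
  log2(nfi * snr + 1)
}

#' Ab Score matrix of an antigen array
#'
#' Normalizes each sample's NFI column to that sample's internal IgG
#' controls (division by the mean control NFI) when control antigens are
#' flagged, then applies [abScore()]. Control rows are dropped from the
#' result.
#'
#' @param x an \linkS4class{AntigenArray}.
#' @param normalize divide NFI by the per-sample mean IgG-control NFI
#'   (default `TRUE` when control antigens are present).
#' @return Numeric matrix of Ab Scores (non-control antigens x samples).
#' @export
abScores <- function(x, normalize = any(rowData(x)$is_control)) {
  nfi <- assay(x, "nfi")
  snr <- assay(x, "snr")
  ctrl <- rowData(x)$is_control
  if (normalize) {
    if (!any(ctrl)) stop("no IgG control antigens flagged")
    f <- colMeans(nfi[ctrl, , drop = FALSE])
    if (any(f <= 0)) stop("non-positive control mean; cannot normalize")
    nfi <- sweep(nfi, 2, f, "/")
  }
  abScore(nfi[!ctrl, , drop = FALSE], snr[!ctrl, , drop = FALSE])
}

#' One-minus-Pearson distance between matrix rows
#'
#' Distance `1 - r` between all row pairs. A constant row has an undefined
#' correlation; its distance to every other row is defined as 1
#' (uncorrelated) to keep the metric total.
#'
#' @param mat numeric matrix.
#' @return A `dist` object.
#' @export
pearsonDistance <- function(mat) {
  constant <- apply(mat, 1, function(r) stats::sd(r) == 0)
  cc <- suppressWarnings(stats::cor(t(mat)))
  d <- 1 - cc
  d[constant, ] <- 1
  d[, constant] <- 1
  if (sum(constant) > 1) {
    # distance between two constant rows is also 1 by the same policy
    d[constant, constant] <- 1
  }
  diag(d) <- 0
  stats::as.dist(d)
}

#' Cluster an Ab Score matrix for heatmap display
#'
#' Hierarchical clustering uses one minus Pearson correlation with complete
#' linkage and is deterministic given the input order; k-means uses
#' Euclidean distance with `k` clusters (default 2) and up to 10,000
#' iterations under a caller-fixed seed.
#'
#' @param mat numeric matrix (rows are clustered).
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param k number of k-means clusters (default 2).
#' @param iterMax maximum k-means iterations (default 10000).
#' @param seed integer seed for the k-means starts.
#' @return For hierarchical: list with `hclust` and leaf `order`; for
#'   k-means: list with `cluster` labels and `centers`.
#' @export
clusterHeatmap <- function(mat, method = c("hierarchical", "kmeans"),
                           k = 2L, iterMax = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (nrow(mat) < 2) stop("need at least two rows to cluster")
  if (method == "hierarchical") {
    hc <- stats::hclust(pearsonDistance(mat), method = "complete")
    list(hclust = hc, order = hc$order)
  } else {
    set.seed(seed)
    km <- stats::kmeans(mat, centers = k, iter.max = iterMax, nstart = 10)
    list(cluster = km$cluster, centers = km$centers)
  }
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired scores (paired by antigen).
#' Zero differences are dropped (the standard zero-drop convention); the
#' exact distribution is used for up to 25 non-zero pairs without ties and
#' the normal approximation above. Identical vectors give p = 1.
#'
#' @param groupA,groupB numeric vectors of equal length.
#' @return Two-sided p-value.
#' @examples
#' pairedSignedRank(2:7, rep(1, 6))   # 2/2^6 = 0.03125
#' @export
pairedSignedRank <- function(groupA, groupB) {
  stopifnot(length(groupA) == length(groupB))
  d <- groupA - groupB
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  exact <- n <= 25 && !anyDuplicated(abs(d))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = !exact)$p.value)
}

#' Linescan intensity profile
#'
#' A background-corrected intensity profile along a line crossing a cell,
#' with marked edge positions (F1, F2) and three equally spaced central
#' positions (F3, F4, F5). Negative intensities are clamped to 0.
#'
#' @param intensity numeric vector of intensities along the line.
#' @param edges integer positions of F1 and F2 within the profile.
#' @param center integer positions of F3, F4, F5 within the profile.
#' @return A list of class `LinescanProfile`.
#' @export
linescanProfile <- function(intensity, edges, center) {
  stopifnot(length(edges) == 2, length(center) == 3)
  pos <- c(edges, center)
  if (any(pos < 1 | pos > length(intensity)))
    stop("marker positions must lie within the profile")
  if (any(intensity < 0, na.rm = TRUE)) {
    warning("negative intensities clamped to 0")
    intensity <- pmax(intensity, 0)
  }
  structure(list(intensity = intensity, edges = edges, center = center),
            class = "LinescanProfile")
}

#' TIRF actin clearance ratio
#'
#' For each linescan the ratio of the mean central intensity
#' (positions F3, F4, F5) to the mean edge intensity (positions F1, F2):
#' `mean(F3 + F4 + F5) / mean(F1 + F2)`. The ratios from the two
#' perpendicular linescans of a cell are averaged. A ring-shaped actin
#' distribution (cleared centre) gives a ratio below 1; a flat profile
#' gives 1; the ratio is invariant to multiplicative intensity scaling.
#' A zero edge mean makes the ratio undefined: `NA` is returned with a
#' warning.
#'
#' @param scan1,scan2 two perpendicular [linescanProfile()] objects.
#' @return The cell's clearance ratio (numeric scalar, `NA` if undefined).
#' @export
actinClearanceRatio <- function(scan1, scan2) {
  one <- function(p) {
    stopifnot(inherits(p, "LinescanProfile"))
    e <- mean(p$intensity[p$edges])
    if (e == 0) return(NA_real_)
    mean(p$intensity[p$center]) / e
  }
  r <- c(one(scan1), one(scan2))
  if (any(is.na(r))) {
    warning("zero edge intensity: clearance ratio undefined")
    return(NA_real_)
  }
  mean(r)
}

#' Order antigens by significance of the treatment increase
#'
#' Reproduces the heatmap row rule: rows sorted top to bottom starting with
#' the most significantly increased Ab Score in treated versus control
#' samples, using the matched-pairs signed-rank p-value with the sign of
#' the mean difference (increases first, then decreases).
#'
#' @param scores Ab Score matrix (antigens x samples).
#' @param treated,control column indices or names of the two paired groups
#'   (equal lengths; pairing is positional).
#' @return data.frame with `antigen`, `p`, `delta`, sorted most
#'   significantly increased first.
#' @export
rankAntigens <- function(scores, treated, control) {
  res <- t(apply(scores, 1, function(r) {
    a <- r[treated]; b <- r[control]
    c(p = pairedSignedRank(a, b), delta = mean(a) - mean(b))
  }))
  out <- data.frame(antigen = rownames(scores), p = res[, "p"],
                    delta = res[, "delta"], stringsAsFactors = FALSE)
  up <- out$delta > 0
  # exact p-values are discrete and floor at 2/2^n: break ties by the
  # magnitude of the shift
  out <- out[order(!up, ifelse(up, out$p, -out$p),
                   ifelse(up, -out$delta, out$delta)), ]
  rownames(out) <- NULL
  out
}
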