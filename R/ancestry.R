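#' Construct a labelled reference panel
#'
#' @param genotypes numeric matrix of dosages (individuals x variants,
#'   values 0/1/2 or `NA`).
#' @param populations character vector of population labels, one per
#'   individual.
#' @return A \linkS4class{ReferencePanel}.
#' @export
referencePanel <- function(genotypes, populations) {
  new("ReferencePanel", genotypes = as.matrix(genotypes),
      populations = as.character(populations))
}

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel:", nrow(object@genotypes), "individuals x",
      ncol(object@genotypes), "variants;",
      length(unique(object@populations)), "populations\n")
  invisible(NULL)
})

setMethod("show", "ReferencePCA", function(object) {
  cat("ReferencePCA:", ncol(object@scores), "PCs over",
      nrow(object@loadings), "variants (",
      round(100 * sum(object@varExplained), 1), "% variance )\n")
  invisible(NULL)
})

.pattersonStandardize <- function(x, p, s) {
  z <- sweep(x, 2, 2 * p, "-")
  z <- sweep(z, 2, s, "/")
  z[is.na(z)] <- 0                         # mean imputation after centering
  z
}

#' Fit a principal-component decomposition of a reference panel
#'
#' Columns are centred by twice the panel allele frequency and scaled by
#' `sqrt(2p(1-p))` (Patterson scaling, the standard for genotype PCA), with
#' missing dosages mean-imputed. Monomorphic variants are dropped with a
#' warning. The decomposition is panel-only: study samples are projected
#' afterwards with [projectSamples()] so they cannot induce their own axes.
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param nPcs number of components to retain (default 10).
#' @return A \linkS4class{ReferencePCA}.
#' @export
fitReferencePCA <- function(panel, nPcs = 10L) {
  g <- panel@genotypes
  if (nrow(g) < nPcs)
    stop("panel must have at least nPcs individuals")
  p <- colMeans(g, na.rm = TRUE) / 2
  mono <- !is.finite(p) | p <= 0 | p >= 1
  if (any(mono)) {
    warning("dropping ", sum(mono), " monomorphic variant(s)")
    g <- g[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  s <- sqrt(2 * p * (1 - p))
  z <- .pattersonStandardize(g, p, s)
  sv <- svd(z)
  rank <- sum(sv$d > max(dim(z)) * .Machine$double.eps * sv$d[1])
  if (nPcs > rank)
    stop("nPcs (", nPcs, ") exceeds the rank of the panel (", rank, ")")
  scores <- sv$u[, seq_len(nPcs), drop = FALSE] %*%
    diag(sv$d[seq_len(nPcs)], nPcs)
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(nPcs)))
  loadings <- sv$v[, seq_len(nPcs), drop = FALSE]
  dimnames(loadings) <- list(colnames(g), paste0("PC", seq_len(nPcs)))
  new("ReferencePCA", scores = scores, loadings = loadings,
      freqs = p, scale = s,
      varExplained = sv$d[seq_len(nPcs)]^2 / sum(sv$d^2),
      populations = panel@populations)
}

#' Project samples onto reference-panel principal components
#'
#' Standardizes sample dosages with the panel's frequencies and scale and
#' applies the panel loadings. Missing dosages are mean-imputed (an
#' all-missing sample lands at the origin). The variant set and order must
#' match the panel's retained variants.
#'
#' @param genotypes numeric matrix (samples x variants) or vector for a
#'   single sample.
#' @param pca a \linkS4class{ReferencePCA}.
#' @return Numeric matrix of coordinates (samples x PCs).
#' @export
projectSamples <- function(genotypes, pca) {
  if (is.null(dim(genotypes)))
    genotypes <- matrix(genotypes, nrow = 1)
  if (ncol(genotypes) != nrow(pca@loadings)) {
    if (!is.null(colnames(genotypes)) && !is.null(rownames(pca@loadings))) {
      missing <- setdiff(rownames(pca@loadings), colnames(genotypes))
      stop("sample variants do not match the panel; missing: ",
           paste(utils::head(missing, 10), collapse = ", "))
    }
    stop("sample genotypes must cover the panel's ", nrow(pca@loadings),
         " retained variants (got ", ncol(genotypes), ")")
  }
  z <- .pattersonStandardize(genotypes, pca@freqs, pca@scale)
  out <- z %*% pca@loadings
  rownames(out) <- rownames(genotypes)
  out
}

#' Assign ancestry by nearest neighbours in PC space
#'
#' Each sample is labelled by majority vote among its `k` Euclidean nearest
#' reference-panel neighbours computed on the first `nPcs` principal
#' components (the screen uses the 10 first PCs). Ties are broken by the
#' smaller summed neighbour distance, then lexicographically.
#'
#' @param coords sample coordinates from [projectSamples()].
#' @param pca a \linkS4class{ReferencePCA} (provides panel coordinates and
#'   labels).
#' @param k number of neighbours (default 10).
#' @param nPcs number of leading PCs used in the distance (default 10,
#'   capped at the fitted number).
#' @return data.frame with one row per sample: `label`, `votes` (k-vote
#'   share of the winning label) and `meanDistance` to the k neighbours.
#' @export
assignAncestry <- function(coords, pca, k = 10L, nPcs = 10L) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  if (k > nrow(pca@scores)) stop("k exceeds panel size")
  nPcs <- min(nPcs, ncol(pca@scores), ncol(coords))
  ref <- pca@scores[, seq_len(nPcs), drop = FALSE]
  qry <- coords[, seq_len(nPcs), drop = FALSE]
  out <- lapply(seq_len(nrow(qry)), function(i) {
    d <- sqrt(colSums((t(ref) - qry[i, ])^2))
    nn <- order(d)[seq_len(k)]
    labs <- pca@populations[nn]
    tab <- table(labs)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      sums <- vapply(top, function(l) sum(d[nn][labs == l]), numeric(1))
      top <- top[order(sums, top)]
    }
    data.frame(label = top[1],
               votes = max(tab) / k,
               meanDistance = mean(d[nn]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- rownames(qry)
  out
}
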