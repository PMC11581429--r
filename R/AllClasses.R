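#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

GT_CODES <- c("hom_ref", "het", "hom_alt", "hemi_alt", "missing")

CONSEQUENCES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                  "essential_splice", "synonymous", "other")

NONSYN_CONSEQUENCES <- c("missense", "nonsense", "frameshift",
                         "inframe_indel", "essential_splice")

#' Pedigree of one or more families
#'
#' Holds pedigree members for one or several families, with parent links,
#' sex and affection status. This is the segregation substrate for the
#' inheritance screen: genotype patterns are evaluated against the affected
#' and unaffected members recorded here.
#'
#' The `members` slot is a data.frame with columns `family_id`,
#' `individual_id`, `father_id`, `mother_id` (`NA` when the parent is not in
#' the pedigree), `sex` (`"male"`, `"female"`, `"unknown"`) and `affected`
#' (`"affected"`, `"unaffected"`, `"unknown"`).
#'
#' @slot members data.frame of pedigree members, one row per individual.
#' @seealso [readPedigree()], [families()]
#' @export
setClass("Pedigree", representation(members = "data.frame"))

.validPedigree <- function(object) {
  m <- object@members
  msgs <- character()
  need <- c("family_id", "individual_id", "father_id", "mother_id",
            "sex", "affected")
  if (!all(need %in% names(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m[c("family_id", "individual_id")]))
    msgs <- c(msgs, "individual_id must be unique within family")
  if (!all(m$sex %in% c("male", "female", "unknown")))
    msgs <- c(msgs, "sex must be male/female/unknown")
  if (!all(m$affected %in% c("affected", "unaffected", "unknown")))
    msgs <- c(msgs, "affected must be affected/unaffected/unknown")
  for (fam in unique(m$family_id)) {
    fm <- m[m$family_id == fam, ]
    ids <- fm$individual_id
    for (col in c("father_id", "mother_id")) {
      ref <- fm[[col]]
      bad <- !is.na(ref) & !(ref %in% ids)
      if (any(bad))
        msgs <- c(msgs, sprintf("family %s: %s '%s' not in pedigree",
                                fam, col, ref[bad][1]))
    }
    fathers <- stats::na.omit(fm$father_id)
    if (length(fathers) &&
        !all(fm$sex[match(fathers, ids)] %in% c("male")))
      msgs <- c(msgs, sprintf("family %s: a father is not male", fam))
    mothers <- stats::na.omit(fm$mother_id)
    if (length(mothers) &&
        !all(fm$sex[match(mothers, ids)] %in% c("female")))
      msgs <- c(msgs, sprintf("family %s: a mother is not female", fam))
    # acyclicity: walk ancestor links, a path longer than n implies a cycle
    n <- nrow(fm)
    parent <- function(id, col) {
      p <- fm[[col]][match(id, ids)]
      p[!is.na(id)]
    }
    for (id in ids) {
      frontier <- id
      for (step in seq_len(n + 1)) {
        frontier <- unique(stats::na.omit(c(
          fm$father_id[match(frontier, ids)],
          fm$mother_id[match(frontier, ids)])))
        if (!length(frontier)) break
        if (id %in% frontier) {
          msgs <- c(msgs, sprintf("family %s: individual %s is its own ancestor",
                                  fam, id))
          break
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("Pedigree", .validPedigree)

#' Cohort of variant calls with genotypes and annotations
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one row per
#' biallelic variant record (multi-allelic sites are decomposed on import)
#' and one column per genotyped individual. Assays: `gt`, a character matrix
#' of genotype codes (`hom_ref`, `het`, `hom_alt`, `hemi_alt`, `missing`);
#' `dp`, an integer matrix of per-sample read depths. `rowData()` carries
#' `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence` and the site `qual`,
#' plus, after [joinAnnotations()], `cadd`, `maf_global`, `maf_inhouse` and
#' one `maf_<subpopulation>` column per subpopulation. The pedigree and the
#' per-gene score table live in `metadata()`.
#'
#' @seealso [readVariantCalls()], [applyCallQualityFilter()],
#'   [joinAnnotations()], [runScreen()]
#' @export
setClass("VariantCohort", contains = "SummarizedExperiment")

.validVariantCohort <- function(object) {
  msgs <- character()
  if (!all(c("gt", "dp") %in% SummarizedExperiment::assayNames(object)))
    msgs <- c(msgs, "assays 'gt' and 'dp' are required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "qual")
  if (!all(need %in% names(rd)))
    msgs <- c(msgs, paste("rowData must have:", paste(need, collapse = ", ")))
  else {
    if (nrow(object) && any(rd$pos < 1, na.rm = TRUE))
      msgs <- c(msgs, "pos must be >= 1")
    if (nrow(object) && any(rd$ref == rd$alt, na.rm = TRUE))
      msgs <- c(msgs, "ref must differ from alt")
    gt <- SummarizedExperiment::assay(object, "gt")
    if (length(gt) && !all(gt %in% GT_CODES))
      msgs <- c(msgs, "gt codes must be hom_ref/het/hom_alt/hemi_alt/missing")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("VariantCohort", .validVariantCohort)

#' Screen configuration
#'
#' Holds the thresholds of the screen. Defaults are the screen's operating
#' point: GDI cutoff 13.84 (the 95% CI upper boundary of the gene damage
#' index, above which a gene is unlikely to be disease-causing), MSC from the
#' 99% confidence interval of disease-mutation CADD scores, CADD/MSC ratio
#' strictly above 1, common-variant exclusion at MAF > 0.01, model-specific
#' subpopulation MAF ceilings (AD and X-linked 1e-4, AR 1e-2), 10 principal
#' components and 10 nearest neighbours for ancestry.
#'
#' @slot gdiCutoff numeric, genes with GDI strictly above are excluded.
#' @slot mscConfidence numeric in (0,1), confidence level of the MSC interval.
#' @slot ratioThreshold numeric, variants kept iff CADD/MSC strictly above.
#' @slot mafCommonExclusion numeric, global/public MAF above which a variant
#'   is excluded outright.
#' @slot mafAD,mafAR,mafXL numeric, per-model subpopulation MAF ceilings
#'   (strict \code{<}).
#' @slot inhouseThreshold numeric, in-house cohort frequency ceiling.
#' @slot nPcs,knnK integer, PCs and neighbours used for ancestry assignment.
#' @slot penetrance `"complete"` or `"incomplete"`.
#' @seealso [screenConfig()], [runScreen()]
#' @export
setClass("ScreenConfig", representation(
  gdiCutoff = "numeric", mscConfidence = "numeric",
  ratioThreshold = "numeric", mafCommonExclusion = "numeric",
  mafAD = "numeric", mafAR = "numeric", mafXL = "numeric",
  inhouseThreshold = "numeric", nPcs = "integer", knnK = "integer",
  penetrance = "character"))

.validScreenConfig <- function(object) {
  msgs <- character()
  for (s in c("gdiCutoff", "ratioThreshold", "mafCommonExclusion",
              "mafAD", "mafAR", "mafXL", "inhouseThreshold")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msgs <- c(msgs, paste(s, "must be a single positive number"))
  }
  if (object@mscConfidence <= 0 || object@mscConfidence >= 1)
    msgs <- c(msgs, "mscConfidence must be in (0,1)")
  if (!object@penetrance %in% c("complete", "incomplete"))
    msgs <- c(msgs, "penetrance must be complete or incomplete")
  if (object@nPcs < 1 || object@knnK < 1)
    msgs <- c(msgs, "nPcs and knnK must be >= 1")
  if (length(msgs)) msgs else TRUE
}
setValidity("ScreenConfig", .validScreenConfig)

#' Construct a screen configuration
#'
#' @param gdiCutoff gene damage index cutoff (exclusion is strictly above).
#' @param mscConfidence confidence level of the MSC interval.
#' @param ratioThreshold CADD/MSC ratio that a kept variant must strictly
#'   exceed.
#' @param mafCommonExclusion global MAF above which variants are excluded.
#' @param mafAD,mafAR,mafXL subpopulation MAF ceilings per inheritance model.
#' @param inhouseThreshold in-house frequency ceiling.
#' @param nPcs number of principal components for ancestry distances.
#' @param knnK number of nearest neighbours for the ancestry vote.
#' @param penetrance `"complete"` (default) or `"incomplete"`.
#' @return A \linkS4class{ScreenConfig}.
#' @examples
#' cfg <- screenConfig()
#' cfg
#' @export
screenConfig <- function(gdiCutoff = 13.84, mscConfidence = 0.99,
                         ratioThreshold = 1.0, mafCommonExclusion = 0.01,
                         mafAD = 1e-4, mafAR = 1e-2, mafXL = 1e-4,
                         inhouseThreshold = 0.01, nPcs = 10L, knnK = 10L,
                         penetrance = c("complete", "incomplete")) {
  new("ScreenConfig", gdiCutoff = gdiCutoff, mscConfidence = mscConfidence,
      ratioThreshold = ratioThreshold, mafCommonExclusion = mafCommonExclusion,
      mafAD = mafAD, mafAR = mafAR, mafXL = mafXL,
      inhouseThreshold = inhouseThreshold, nPcs = as.integer(nPcs),
      knnK = as.integer(knnK), penetrance = match.arg(penetrance))
}

#' Labelled reference genotype panel
#'
#' Genotype dosages (0/1/2 copies of the alternate allele, `NA` = missing)
#' for a set of reference individuals with known population labels, used to
#' anchor principal-component ancestry assignment.
#'
#' @slot genotypes numeric matrix, individuals x variants.
#' @slot populations character vector of population labels, one per row.
#' @seealso [fitReferencePCA()], [simulateReferencePanel()]
#' @export
setClass("ReferencePanel", representation(
  genotypes = "matrix", populations = "character"))

setValidity("ReferencePanel", function(object) {
  msgs <- character()
  g <- object@genotypes
  if (nrow(g) != length(object@populations))
    msgs <- c(msgs, "one population label per individual is required")
  if (length(g) && !all(g[!is.na(g)] %in% 0:2))
    msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  if (length(msgs)) msgs else TRUE
})

#' Principal components of a reference panel
#'
#' The fitted panel PCA: per-individual coordinates, variant loadings and the
#' allele frequencies and scale used for Patterson standardization, so that
#' new samples can be projected onto panel-only axes.
#'
#' @slot scores numeric matrix, panel individuals x PCs.
#' @slot loadings numeric matrix, variants x PCs.
#' @slot freqs numeric, panel allele frequencies of the retained variants.
#' @slot scale numeric, per-variant standard deviation sqrt(2p(1-p)).
#' @slot varExplained numeric, fraction of variance per PC (non-increasing).
#' @slot populations character, panel population labels.
#' @seealso [projectSamples()], [assignAncestry()]
#' @export
setClass("ReferencePCA", representation(
  scores = "matrix", loadings = "matrix", freqs = "numeric",
  scale = "numeric", varExplained = "numeric", populations = "character"))

setValidity("ReferencePCA", function(object) {
  msgs <- character()
  if (ncol(object@scores) != ncol(object@loadings))
    msgs <- c(msgs, "scores and loadings must have the same number of PCs")
  if (nrow(object@loadings) != length(object@freqs))
    msgs <- c(msgs, "one frequency per retained variant is required")
  ve <- object@varExplained
  if (length(ve) > 1 && any(diff(ve) > 1e-8))
    msgs <- c(msgs, "explained variance must be non-increasing")
  if (length(msgs)) msgs else TRUE
})

#' Antigen-array fluorescence matrices
#'
#' A \linkS4class{SummarizedExperiment} subclass with assays `nfi` (net
#' fluorescence intensity) and `snr` (signal-to-noise ratio), antigens as
#' rows and serum samples as columns. `colData()$group` carries the treatment
#' group; `rowData()$is_control` flags internal IgG control features used for
#' normalization.
#'
#' @seealso [abScores()], [simulateArray()]
#' @export
setClass("AntigenArray", contains = "SummarizedExperiment")

setValidity("AntigenArray", function(object) {
  msgs <- character()
  if (!all(c("nfi", "snr") %in% SummarizedExperiment::assayNames(object)))
    msgs <- c(msgs, "assays 'nfi' and 'snr' are required")
  else {
    for (a in c("nfi", "snr")) {
      m <- SummarizedExperiment::assay(object, a)
      if (length(m) && (any(!is.finite(m)) || any(m < 0)))
        msgs <- c(msgs, paste(a, "must be finite and non-negative"))
    }
  }
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData must have a 'group' column")
  if (length(msgs)) msgs else TRUE
})
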