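CARRIER_CODES <- c("het", "hom_alt", "hemi_alt")

#' Consequence-class filter
#'
#' Keeps non-synonymous coding variants and essential splice-site variants:
#' missense, nonsense, frameshift, in-frame indel and essential splice.
#' Synonymous and other classes are dropped; an unknown/missing class is
#' dropped.
#'
#' @param consequence character vector of consequence classes.
#' @return Logical vector, `TRUE` for kept variants.
#' @export
consequenceFilter <- function(consequence) {
  !is.na(consequence) & consequence %in% NONSYN_CONSEQUENCES
}

.mafColumns <- function(df) {
  setdiff(grep("^maf_", names(df), value = TRUE),
          c("maf_global", "maf_inhouse"))
}

#' Inheritance-model frequency filter
#'
#' Two stages. First the common-variant exclusion: variants with a global
#' (public database) MAF above 0.01 or an in-house frequency above the
#' configured threshold are dropped outright. Then the model-specific rule:
#' the maximum MAF over every ethnic subpopulation column must be strictly
#' below the model threshold (AD and X-linked 1e-4, AR 1e-2). A frequency
#' that is missing counts as 0 (the variant was not observed in that
#' population); a variant absent from the annotation tables therefore
#' passes under every model.
#'
#' @param x a \linkS4class{VariantCohort} (annotated) or a data.frame with
#'   `maf_global`, `maf_inhouse` and `maf_<subpop>` columns.
#' @param model `"AD"`, `"AR"` or `"XL"`.
#' @param cfg a \linkS4class{ScreenConfig}.
#' @return Logical vector, `TRUE` for kept variants.
#' @export
frequencyFilter <- function(x, model = c("AD", "AR", "XL"),
                            cfg = screenConfig()) {
  model <- match.arg(model)
  df <- if (is(x, "VariantCohort")) as.data.frame(rowData(x)) else x
  z <- function(v) { v[is.na(v)] <- 0; v }
  mg <- z(if ("maf_global" %in% names(df)) df$maf_global else
    rep(0, nrow(df)))
  mi <- z(if ("maf_inhouse" %in% names(df)) df$maf_inhouse else
    rep(0, nrow(df)))
  keep <- mg <= cfg@mafCommonExclusion & mi <= cfg@inhouseThreshold
  sub <- .mafColumns(df)
  mx <- if (length(sub))
    do.call(pmax, c(lapply(df[sub], z), list(mg))) else mg
  thr <- switch(model, AD = cfg@mafAD, AR = cfg@mafAR, XL = cfg@mafXL)
  keep & mx < thr
}

#' Hardy-Weinberg genotype-frequency expectations
#'
#' For an allele at frequency q the expected homozygote frequency is q^2;
#' for two alleles of the same gene at frequencies q1 and q2 the expected
#' compound-heterozygote frequency is 2 q1 q2.
#'
#' @param mafA allele frequency in \[0,1\].
#' @param mafB optional second allele frequency for the compound
#'   heterozygote expectation.
#' @return List with `homozygote` (mafA^2) and `comphet` (2*mafA*mafB, or
#'   `NA` when `mafB` is not supplied).
#' @examples
#' hweFrequencies(8e-5)$homozygote        # 6.4e-9
#' hweFrequencies(8e-5, 5e-3)$comphet     # 8e-7
#' @export
hweFrequencies <- function(mafA, mafB = NULL) {
  chk <- function(q, nm) if (any(q < 0 | q > 1 | !is.finite(q)))
    stop(nm, " must be in [0,1]")
  chk(mafA, "mafA")
  if (!is.null(mafB)) chk(mafB, "mafB")
  list(homozygote = mafA^2,
       comphet = if (is.null(mafB)) NA_real_ else 2 * mafA * mafB)
}

# Possible parental origins of a het variant in a child.
# Returns a subset of c("father", "mother"). A homozygous-alternate parent
# must have transmitted the allele, which forces the origin; an ungenotyped
# or missing parent can always be the origin. An empty set (Mendelian
# inconsistency / de novo) is widened to both parents: the origin is
# unknowable.
.originSet <- function(gtF, gtM) {
  poss <- function(g) is.na(g) || g == "missing" || g %in% CARRIER_CODES
  forced <- function(g) !is.na(g) && g %in% c("hom_alt", "hemi_alt")
  if (forced(gtF) && !forced(gtM)) return("father")
  if (forced(gtM) && !forced(gtF)) return("mother")
  out <- c(if (poss(gtF)) "father", if (poss(gtM)) "mother")
  if (!length(out)) out <- c("father", "mother")
  out
}

# Phase classification for one affected child het for both variants.
.phaseForChild <- function(o1, o2) {
  combos <- expand.grid(o1 = o1, o2 = o2, stringsAsFactors = FALSE)
  trans <- any(combos$o1 != combos$o2)
  cis <- any(combos$o1 == combos$o2)
  if (trans && cis) "ambiguous" else if (trans) "trans" else "cis"
}

.familyMembers <- function(family) {
  if (is(family, "Pedigree")) members(family) else family
}

.gtOf <- function(gt, variant, id) {
  if (is.na(id) || !id %in% colnames(gt)) return(NA_character_)
  gt[variant, id]
}

#' Detect compound-heterozygote variant pairs in one gene
#'
#' Enumerates all unordered pairs of variants of one gene for which at least
#' one affected family member is heterozygous for both, and determines the
#' phase from parental genotypes: `trans` when every consistent assignment
#' puts the two alleles on opposite parental haplotypes (e.g. one parent
#' carries exactly one of the two and the other parent the other), `cis`
#' when both alleles can only have come from the same parent, and
#' `ambiguous` when both configurations remain possible, typically because a
#' parent is ungenotyped and no contradiction exists. Ambiguous pairs are
#' retained and flagged rather than discarded.
#'
#' @param x a \linkS4class{VariantCohort} (with `gene` set, requires the
#'   `gene` argument) or a character genotype matrix (variants x
#'   individuals, codes as in [readVariantCalls()]).
#' @param family a single-family \linkS4class{Pedigree} or its members
#'   data.frame.
#' @param gene gene symbol to restrict to when `x` is a cohort.
#' @return data.frame with columns `gene`, `variant_a`, `variant_b`,
#'   `phase` and `carriers` (comma-separated ids heterozygous for both).
#' @export
detectCompHetPairs <- function(x, family, gene = NULL) {
  fm <- .familyMembers(family)
  if (is(x, "VariantCohort")) {
    stopifnot(!is.null(gene))
    idx <- which(rowData(x)$gene %in% gene &
                   !.isSexChrom(rowData(x)$chrom))
    gt <- assay(x, "gt")[idx, intersect(fm$individual_id, colnames(x)),
                         drop = FALSE]
  } else {
    gt <- x
    if (is.null(gene)) gene <- NA_character_
  }
  out <- data.frame(gene = character(), variant_a = character(),
                    variant_b = character(), phase = character(),
                    carriers = character(), stringsAsFactors = FALSE)
  nv <- nrow(gt)
  if (nv < 2) return(out)
  vn <- rownames(gt)
  if (is.null(vn)) vn <- as.character(seq_len(nv))
  affected <- fm$individual_id[fm$affected == "affected"]
  present <- intersect(fm$individual_id, colnames(gt))
  for (i in seq_len(nv - 1)) {
    for (j in (i + 1):nv) {
      hetBoth <- present[gt[i, present] == "het" & gt[j, present] == "het"]
      affCarriers <- intersect(hetBoth, affected)
      if (!length(affCarriers)) next
      phases <- vapply(affCarriers, function(id) {
        row <- fm[fm$individual_id == id, ]
        oF <- .originSet(.gtOf(gt, i, row$father_id),
                         .gtOf(gt, i, row$mother_id))
        oS <- .originSet(.gtOf(gt, j, row$father_id),
                         .gtOf(gt, j, row$mother_id))
        .phaseForChild(oF, oS)
      }, character(1))
      phase <- if (all(phases == "trans")) "trans"
      else if (all(phases == "cis")) "cis"
      else "ambiguous"
      out <- rbind(out, data.frame(
        gene = gene, variant_a = vn[i], variant_b = vn[j], phase = phase,
        carriers = paste(sort(hetBoth), collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  out
}

# Genotype lookup helpers over a variants x individuals code matrix.
.carries <- function(g) !is.na(g) & g %in% CARRIER_CODES
.genotyped <- function(g) !is.na(g) & g != "missing"

#' Check segregation of candidate variants in one family
#'
#' Evaluates whether a gene's qualifying variants segregate with disease in
#' the family under a given inheritance model. Missing genotypes never veto
#' a pattern (only available members were genotyped). Under complete
#' penetrance no unaffected member may carry a full causal genotype; under
#' incomplete penetrance unaffected carriers are tolerated and the report is
#' labelled `incomplete_only`. X-linked female heterozygous carriers are
#' allowed to be unaffected under every penetrance setting.
#'
#' @param gt character genotype matrix (variants x individuals) for one
#'   gene, rownames = variant labels.
#' @param family a single-family \linkS4class{Pedigree} or members
#'   data.frame.
#' @param model `"AD"`, `"AR_hom"`, `"AR_comphet"` or `"XL"`.
#' @param penetrance `"complete"` or `"incomplete"`.
#' @param gene gene symbol for the report.
#' @return A one-row data.frame (family, model, gene, variants, phase,
#'   segregation, notes) or `NULL` when the pattern is inconsistent.
#' @export
segregate <- function(gt, family, model = c("AD", "AR_hom", "AR_comphet", "XL"),
                      penetrance = c("complete", "incomplete"),
                      gene = NA_character_) {
  model <- match.arg(model)
  penetrance <- match.arg(penetrance)
  fm <- .familyMembers(family)
  famId <- fm$family_id[1]
  aff <- fm$individual_id[fm$affected == "affected"]
  una <- fm$individual_id[fm$affected == "unaffected"]
  present <- intersect(fm$individual_id, colnames(gt))
  affP <- intersect(aff, present); unaP <- intersect(una, present)
  vn <- rownames(gt)
  if (is.null(vn)) vn <- as.character(seq_len(nrow(gt)))
  report <- function(variants, phase, seg, notes = "") {
    data.frame(family = famId, model = model, gene = gene,
               variants = paste(variants, collapse = ","),
               phase = phase, segregation = seg, notes = notes,
               stringsAsFactors = FALSE)
  }

  checkSingle <- function(affOk, unaViolates) {
    hits <- NULL
    for (i in seq_len(nrow(gt))) {
      ga <- gt[i, affP]; gu <- gt[i, unaP]
      genA <- ga[.genotyped(ga)]
      if (!length(genA) || !all(affOk(genA))) next
      viol <- any(unaViolates(gu[.genotyped(gu)]))
      if (viol && penetrance == "complete") next
      hits <- rbind(hits, data.frame(
        i = i, seg = if (viol) "incomplete_only"
        else "complete_penetrance_consistent"))
    }
    hits
  }

  if (model == "AD") {
    hits <- checkSingle(affOk = .carries, unaViolates = .carries)
    if (is.null(hits)) return(NULL)
    return(report(vn[hits$i],
                  phase = NA_character_,
                  seg = if (any(hits$seg == "incomplete_only"))
                    "incomplete_only" else "complete_penetrance_consistent"))
  }
  if (model == "AR_hom") {
    hits <- checkSingle(affOk = function(g) g == "hom_alt",
                        unaViolates = function(g) g == "hom_alt")
    if (is.null(hits)) return(NULL)
    return(report(vn[hits$i], NA_character_,
                  if (any(hits$seg == "incomplete_only"))
                    "incomplete_only" else "complete_penetrance_consistent"))
  }
  if (model == "AR_comphet") {
    pairs <- detectCompHetPairs(gt, fm, gene = gene)
    pairs <- pairs[pairs$phase != "cis", , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      ia <- match(pairs$variant_a[k], vn); ib <- match(pairs$variant_b[k], vn)
      # every affected genotyped at both sites must carry both alleles
      ok <- all(vapply(affP, function(id) {
        g1 <- gt[ia, id]; g2 <- gt[ib, id]
        if (!.genotyped(g1) || !.genotyped(g2)) return(TRUE)  # non-vetoing
        .carries(g1) && .carries(g2)
      }, logical(1)))
      if (!ok) next
      viol <- any(vapply(unaP, function(id) {
        g1 <- gt[ia, id]; g2 <- gt[ib, id]
        .genotyped(g1) && .genotyped(g2) && .carries(g1) && .carries(g2)
      }, logical(1)))
      if (viol && penetrance == "complete") next
      note <- if (pairs$phase[k] == "ambiguous")
        "phase unresolved (ungenotyped parent)" else ""
      return(report(vn[c(ia, ib)], pairs$phase[k],
                    if (viol) "incomplete_only"
                    else "complete_penetrance_consistent", note))
    }
    return(NULL)
  }
  # XL
  sex <- fm$sex[match(fm$individual_id, fm$individual_id)]
  sexOf <- function(id) fm$sex[match(id, fm$individual_id)]
  hits <- NULL
  for (i in seq_len(nrow(gt))) {
    ga <- gt[i, affP, drop = TRUE]
    genA <- affP[.genotyped(gt[i, affP])]
    if (!length(genA)) next
    okAff <- all(vapply(genA, function(id) {
      if (sexOf(id) == "male") gt[i, id] == "hemi_alt"
      else gt[i, id] == "hom_alt"
    }, logical(1)))
    if (!okAff) next
    genU <- unaP[.genotyped(gt[i, unaP])]
    viol <- any(vapply(genU, function(id) {
      if (sexOf(id) == "male") gt[i, id] == "hemi_alt"
      else gt[i, id] == "hom_alt"          # het female carriers always allowed
    }, logical(1)))
    if (viol && penetrance == "complete") next
    hits <- rbind(hits, data.frame(
      i = i, seg = if (viol) "incomplete_only"
      else "complete_penetrance_consistent"))
  }
  if (is.null(hits)) return(NULL)
  report(vn[hits$i], NA_character_,
         if (any(hits$seg == "incomplete_only")) "incomplete_only"
         else "complete_penetrance_consistent")
}

#' Run the full inheritance screen on an annotated cohort
#'
#' Deterministic composition of the screen's filters, applied independently
#' to each family: consequence filter (non-synonymous coding and essential
#' splice), common-variant exclusion and model-specific subpopulation MAF
#' ceilings, gene-level GDI cutoff, allele-level CADD/MSC ratio, then
#' genotype pattern matching and segregation under each requested
#' inheritance model (AD; AR as homozygous and compound-heterozygous with
#' trans-phasing; X-linked).
#'
#' @param vc an annotated \linkS4class{VariantCohort} (see
#'   [joinAnnotations()]).
#' @param cfg a \linkS4class{ScreenConfig}.
#' @param models subset of `c("AD", "AR", "XL")`.
#' @return data.frame of candidate reports (family, model, gene, variants,
#'   phase, segregation, notes) sorted by family, model and gene, with a
#'   per-filter attrition table in `attr(, "attrition")`.
#' @export
runScreen <- function(vc, cfg = screenConfig(), models = c("AD", "AR", "XL")) {
  if (!isTRUE(metadata(vc)$annotated))
    stop("cohort must be annotated first (joinAnnotations)")
  models <- match.arg(models, several.ok = TRUE)
  ped <- metadata(vc)$pedigree
  gs <- metadata(vc)$geneScores
  rd <- as.data.frame(rowData(vc))
  attrition <- c(input = nrow(vc))

  keep <- consequenceFilter(rd$consequence)
  attrition["consequence"] <- sum(keep)

  # gene-level: GDI cutoff; genes with no row in the score table pass with
  # a warning (annotation gap must not lose candidates)
  genes <- unique(stats::na.omit(rd$gene))
  unknown <- setdiff(genes, gs$gene)
  scored <- gs[gs$gene %in% genes, , drop = FALSE]
  retained <- withCallingHandlers(
    gdiFilter(scored, cfg@gdiCutoff),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(unknown))
    warning("genes absent from score table pass the GDI filter: ",
            paste(unknown, collapse = ", "))
  keep <- keep & (is.na(rd$gene) | rd$gene %in% c(retained, unknown))
  attrition["gdi"] <- sum(keep)

  msc <- gs$msc[match(rd$gene, gs$gene)]
  keep <- keep & suppressWarnings(
    deleteriousnessFilter(rd$cadd, msc, cfg@ratioThreshold))
  attrition["deleteriousness"] <- sum(keep)

  freqKeep <- list()
  for (m in c("AD", "AR", "XL"))
    freqKeep[[m]] <- keep & frequencyFilter(rd, m, cfg)
  attrition["frequency_AR"] <- sum(freqKeep$AR)

  submodels <- unlist(lapply(models, function(m)
    switch(m, AD = "AD", AR = c("AR_hom", "AR_comphet"), XL = "XL")))
  gtAll <- assay(vc, "gt")
  reports <- list()
  for (fam in families(ped)) {
    fm <- members(fam)
    ids <- intersect(fm$individual_id, colnames(gtAll))
    if (!length(ids)) next
    for (sm in submodels) {
      base <- if (sm == "AD") "AD" else if (sm == "XL") "XL" else "AR"
      idx <- which(freqKeep[[base]])
      if (sm == "XL") idx <- idx[.isX(rd$chrom[idx])]
      else idx <- idx[!.isSexChrom(rd$chrom[idx])]
      if (!length(idx)) next
      for (g in sort(unique(stats::na.omit(rd$gene[idx])))) {
        gi <- idx[rd$gene[idx] %in% g]
        gt <- gtAll[gi, ids, drop = FALSE]
        rownames(gt) <- rownames(vc)[gi]
        rep1 <- segregate(gt, fm, model = sm, penetrance = cfg@penetrance,
                          gene = g)
        if (!is.null(rep1)) reports[[length(reports) + 1L]] <- rep1
      }
    }
  }
  out <- if (length(reports)) do.call(rbind, reports) else
    data.frame(family = character(), model = character(), gene = character(),
               variants = character(), phase = character(),
               segregation = character(), notes = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$family, out$model, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attrition") <- attrition
  out
}
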