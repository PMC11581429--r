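# Shared fixtures: in-code pedigrees, genotype matrices and the brute-force
# phasing oracle. Everything is generated programmatically.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

gtAssay <- function(vc) assay(vc, "gt")

# --- kindred fixtures ------------------------------------------------------

# Two healthy parents, two affected sons compound heterozygous for two
# missense alleles of one gene, one allele from each parent (trans).
family1Members <- function() {
  data.frame(
    family_id = "K1",
    individual_id = c("K1_F", "K1_M", "K1_S1", "K1_S2"),
    father_id = c(NA, NA, "K1_F", "K1_F"),
    mother_id = c(NA, NA, "K1_M", "K1_M"),
    sex = c("male", "female", "male", "male"),
    affected = c("unaffected", "unaffected", "affected", "affected"),
    stringsAsFactors = FALSE)
}

family1Gt <- function() {
  m <- rbind(v1 = c("het", "hom_ref", "het", "het"),
             v2 = c("hom_ref", "het", "het", "het"))
  colnames(m) <- family1Members()$individual_id
  m
}

# Three affected siblings compound heterozygous, an unaffected sibling
# carrying only the second allele, one genotyped parent carrying the first
# allele, the other parent ungenotyped.
family2Members <- function() {
  data.frame(
    family_id = "K2",
    individual_id = c("K2_P1", "K2_P2", "K2_A1", "K2_A2", "K2_A3", "K2_U1"),
    father_id = c(NA, NA, rep("K2_P1", 4)),
    mother_id = c(NA, NA, rep("K2_P2", 4)),
    sex = c("male", "female", "female", "female", "male", "female"),
    affected = c("unaffected", "unaffected", "affected", "affected",
                 "affected", "unaffected"),
    stringsAsFactors = FALSE)
}

family2Gt <- function() {
  # columns omit the ungenotyped parent K2_P2 entirely
  m <- rbind(vA = c("het", "het", "het", "het", "hom_ref"),
             vB = c("hom_ref", "het", "het", "het", "het"))
  colnames(m) <- c("K2_P1", "K2_A1", "K2_A2", "K2_A3", "K2_U1")
  m
}

# Build a small annotated VariantCohort around a genotype matrix for one
# autosomal gene whose annotations pass every screen threshold.
cohortFromGt <- function(gt, members, gene = "GENE1", chrom = "chr3",
                         cadd = 25, msc = 10, gdi = 5,
                         subpopMafs = c(maf_pop1 = 0, maf_pop2 = 0)) {
  ped <- new("Pedigree", members = members)
  nv <- nrow(gt)
  row <- data.frame(
    chrom = chrom, pos = 1000L + seq_len(nv),
    ref = rep("A", nv), alt = rep("G", nv), gene = gene,
    consequence = "missense", qual = 99, stringsAsFactors = FALSE)
  dp <- matrix(30L, nv, ncol(gt), dimnames = dimnames(gt))
  vc <- famscreen:::.newVariantCohort(row, gt, dp, ped)
  vt <- cbind(as.data.frame(rowData(vc))[c("chrom", "pos", "ref", "alt",
                                           "gene", "consequence")],
              cadd = cadd, maf_global = 0, maf_inhouse = 0,
              as.data.frame(as.list(subpopMafs)))
  gt2 <- data.frame(gene = gene, gdi = gdi, msc = msc)
  joinAnnotations(vc, vt, gt2)
}

# --- brute-force phasing oracle -------------------------------------------

# Enumerate parental haplotype contents for a variant pair consistent with
# the parents' genotypes, and all transmissions that leave the child
# heterozygous for both variants; classify the achievable phases.
# Genotypes are codes; NA or "missing" = unconstrained.
oracleChildPhase <- function(fatherGt, motherGt) {
  hapSets <- function(g1, g2) {
    # all (hap1, hap2) content pairs for one parent over the two variants;
    # each hap is c(v1, v2) in {0,1}
    ok1 <- function(h1, h2, g) {
      if (is.na(g) || g == "missing") return(TRUE)
      n <- h1 + h2
      switch(g, hom_ref = n == 0, het = n == 1,
             hom_alt = n == 2, hemi_alt = n >= 1, FALSE)
    }
    out <- list()
    for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1)
      if (ok1(a1, a2, g1) && ok1(b1, b2, g2))
        out[[length(out) + 1L]] <- list(h1 = c(a1, b1), h2 = c(a2, b2))
    out
  }
  fsets <- hapSets(fatherGt[1], fatherGt[2])
  msets <- hapSets(motherGt[1], motherGt[2])
  phases <- character()
  for (f in fsets) for (m in msets)
    for (fi in c("h1", "h2")) for (mi in c("h1", "h2")) {
      hf <- f[[fi]]; hm <- m[[mi]]
      if (hf[1] + hm[1] != 1 || hf[2] + hm[2] != 1) next  # child not het/het
      phases <- c(phases, if (hf[1] == 1 && hf[2] == 1) "cis"
                  else if (hm[1] == 1 && hm[2] == 1) "cis" else "trans")
    }
  phases <- unique(phases)
  if (!length(phases)) return(NA_character_)            # inconsistent trio
  if (all(phases == "trans")) "trans"
  else if (all(phases == "cis")) "cis" else "ambiguous"
}

# Oracle over a whole family genotype matrix: expected comp-het pair table.
oraclePairs <- function(gt, fm) {
  affected <- fm$individual_id[fm$affected == "affected"]
  present <- intersect(fm$individual_id, colnames(gt))
  out <- NULL
  vn <- rownames(gt)
  for (i in seq_len(nrow(gt) - 1)) for (j in (i + 1):nrow(gt)) {
    hetBoth <- present[gt[i, present] == "het" & gt[j, present] == "het"]
    affC <- intersect(hetBoth, affected)
    if (!length(affC)) next
    phases <- vapply(affC, function(id) {
      r <- fm[fm$individual_id == id, ]
      g <- function(pid, v) if (is.na(pid) || !pid %in% colnames(gt))
        NA_character_ else gt[v, pid]
      oracleChildPhase(c(g(r$father_id, i), g(r$father_id, j)),
                       c(g(r$mother_id, i), g(r$mother_id, j)))
    }, character(1))
    phases[is.na(phases)] <- "ambiguous"
    phase <- if (all(phases == "trans")) "trans"
    else if (all(phases == "cis")) "cis" else "ambiguous"
    out <- rbind(out, data.frame(variant_a = vn[i], variant_b = vn[j],
                                 phase = phase, stringsAsFactors = FALSE))
  }
  out
}

# --- random Mendelian-consistent families ---------------------------------

# One nuclear family with 2-4 variants of one autosomal gene, founder
# haplotypes Bernoulli draws, children by whole-haplotype transmission, and
# optional masking of parents (ungenotyped).
randomFamily <- function(nKids = sample(1:4, 1), nVar = sample(2:4, 1),
                         pAllele = 0.4, pMaskParent = 0.3) {
  haps <- function() stats::runif(nVar) < pAllele
  fa <- list(haps(), haps()); mo <- list(haps(), haps())
  kids <- lapply(seq_len(nKids), function(k)
    list(fa[[sample(2, 1)]], mo[[sample(2, 1)]]))
  code <- function(h) c("hom_ref", "het", "hom_alt")[h[[1]] + h[[2]] + 1L]
  ids <- c("F", "M", paste0("C", seq_len(nKids)))
  gt <- cbind(code(fa), code(mo),
              vapply(kids, code, character(nVar)))
  dimnames(gt) <- list(paste0("v", seq_len(nVar)), ids)
  for (p in 1:2) if (stats::runif(1) < pMaskParent)
    gt[, p] <- "missing"
  fm <- data.frame(
    family_id = "R", individual_id = ids,
    father_id = c(NA, NA, rep("F", nKids)),
    mother_id = c(NA, NA, rep("M", nKids)),
    sex = c("male", "female", sample(c("male", "female"), nKids,
                                     replace = TRUE)),
    affected = c("unaffected", "unaffected",
                 sample(c("affected", "unaffected"), nKids,
                        replace = TRUE, prob = c(0.7, 0.3))),
    stringsAsFactors = FALSE)
  list(gt = gt, fm = fm)
}

# Mendelian feasibility of one child genotype given parents (autosomal).
mendelOk <- function(child, father, mother) {
  donat <- function(g) switch(g, hom_ref = 0, het = 0:1, hom_alt = 1,
                              hemi_alt = 1, missing = 0:1)
  cnt <- switch(child, hom_ref = 0, het = 1, hom_alt = 2,
                hemi_alt = NA, missing = NA)
  if (is.na(cnt)) return(TRUE)
  any(outer(donat(father), donat(mother), "+") == cnt)
}
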