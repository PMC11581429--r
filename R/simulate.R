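#' Simulation configuration for synthetic cohorts
#'
#' Bundles the generator's parameters: pedigree structure, planted
#' inheritance model per family, allele-frequency and deleteriousness-score
#' distributions, and subpopulation structure. Planted causal variants are
#' constructed to satisfy every screen threshold (subpopulation MAFs below
#' the model ceiling, CADD/MSC above 1, gene GDI at or below 13.84,
#' missense consequence), so recovery measures the screen, not the
#' annotation.
#'
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param nFamilies number of families.
#' @param plantedModel planted model per family, recycled: `"AR_comphet"`,
#'   `"AR_comphet_cis"`, `"AR_hom"`, `"AD"`, `"XL"` or `"none"`.
#' @param nChildrenRange inclusive range of children per family.
#' @param nGenes number of genes carrying background variation.
#' @param backgroundVariantsPerGene background variants per gene.
#' @param nSubpops number of ethnic subpopulations in the annotation.
#' @param dirichletConcentration concentration of the per-subpopulation MAF
#'   perturbation (larger = more homogeneous).
#' @param causalMafRange range of the causal base MAF (clipped below the
#'   model ceiling in every subpopulation).
#' @param ungenotypedParentProb probability that one parent of a family is
#'   left ungenotyped (deliberately injected missingness).
#' @param lowQualFrac fraction of background sites given failing call
#'   quality.
#' @param lowDepthFrac fraction of background genotype cells given failing
#'   read depth.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, nFamilies = 10L,
                      plantedModel = "AR_comphet",
                      nChildrenRange = c(2L, 4L), nGenes = 30L,
                      backgroundVariantsPerGene = 3L, nSubpops = 5L,
                      dirichletConcentration = 50,
                      causalMafRange = c(1e-5, 5e-3),
                      ungenotypedParentProb = 0,
                      lowQualFrac = 0.02, lowDepthFrac = 0.01) {
  models <- c("AR_comphet", "AR_comphet_cis", "AR_hom", "AD", "XL", "none")
  if (!all(plantedModel %in% models))
    stop("plantedModel must be one of: ", paste(models, collapse = ", "))
  stopifnot(nFamilies >= 1, nGenes >= 2, nSubpops >= 1,
            causalMafRange[1] > 0, causalMafRange[2] <= 0.5)
  structure(list(
    seed = as.integer(seed), nFamilies = as.integer(nFamilies),
    plantedModel = rep_len(plantedModel, nFamilies),
    nChildrenRange = as.integer(nChildrenRange), nGenes = as.integer(nGenes),
    backgroundVariantsPerGene = as.integer(backgroundVariantsPerGene),
    nSubpops = as.integer(nSubpops),
    dirichletConcentration = dirichletConcentration,
    causalMafRange = causalMafRange,
    ungenotypedParentProb = ungenotypedParentProb,
    lowQualFrac = lowQualFrac, lowDepthFrac = lowDepthFrac),
    class = "SimConfig")
}

.randAlleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  cbind(ref, alt)
}

# Subpopulation MAFs around a base frequency: mean-one gamma perturbations
# (a Dirichlet-style spread), clipped below `ceiling`.
.subpopMafs <- function(base, nSub, conc, ceiling = 0.5) {
  f <- stats::rgamma(nSub, shape = conc, rate = conc)
  pmin(base * f, ceiling)
}

#' Simulate a multiplex-family cohort with planted causal genotypes
#'
#' Generates pedigrees (two founders plus children), founder haplotypes
#' drawn under Hardy-Weinberg from subpopulation-specific MAFs, offspring by
#' Mendelian transmission of whole per-gene haplotypes (no intragenic
#' recombination, so compound-heterozygote phase is well defined), affection
#' status assigned from the planted genotype under complete penetrance, and
#' the matching annotation tables. Trans compound-heterozygote plants put
#' the two causal alleles on opposite parental haplotypes; cis plants put
#' both on one haplotype of one parent. Truth labels are returned (and
#' written) as a sidecar table, never embedded in the VCF.
#'
#' @param cfg a [simConfig()].
#' @return List with `pedigree` (\linkS4class{Pedigree}), `cohort`
#'   (\linkS4class{VariantCohort}), `variantTable`, `geneTable` (annotation
#'   data.frames), and `truth` (family, model, gene, variants, phase,
#'   parents_genotyped).
#' @export
simulateCohort <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  nSub <- cfg$nSubpops
  subpops <- paste0("pop", seq_len(nSub))

  # gene table: GDI lognormal (most genes below the 13.84 cutoff), MSC
  # uniform on the CADD scale; planted genes forced to pass the GDI cutoff
  genes <- sprintf("GENE%03d", seq_len(cfg$nGenes))
  gdi <- stats::rlnorm(cfg$nGenes, meanlog = log(4), sdlog = 0.9)
  msc <- stats::runif(cfg$nGenes, 5, 15)
  geneChrom <- paste0("chr", 1 + (seq_len(cfg$nGenes) - 1) %% 22)
  xGene <- cfg$nGenes                       # last gene lives on chrX
  geneChrom[xGene] <- "chrX"
  plantable <- which(gdi <= 13.84 & seq_len(cfg$nGenes) != xGene)
  if (length(plantable) < 2) { gdi[1:2] <- stats::runif(2, 1, 13); plantable <- 1:2 }
  gdi[xGene] <- min(gdi[xGene], stats::runif(1, 1, 13))

  # background variant registry, shared across families
  reg <- NULL
  for (g in seq_len(cfg$nGenes)) {
    n <- cfg$backgroundVariantsPerGene
    if (!n) next
    al <- .randAlleles(n)
    base <- 10^stats::runif(n, -4, -0.7)
    sub <- t(vapply(base, .subpopMafs, numeric(nSub),
                    nSub = nSub, conc = cfg$dirichletConcentration))
    reg1 <- data.frame(
      chrom = geneChrom[g], pos = g * 1000000L + seq_len(n) * 100L,
      ref = al[, "ref"], alt = al[, "alt"], gene = genes[g],
      consequence = sample(CONSEQUENCES[c(1, 6, 7, 5, 2)], n, replace = TRUE,
                           prob = c(0.5, 0.3, 0.1, 0.05, 0.05)),
      cadd = round(stats::runif(n, 0, 30), 2),
      maf_global = base,
      maf_inhouse = base * stats::runif(n, 0.5, 1.5),
      stringsAsFactors = FALSE)
    colnames(sub) <- paste0("maf_", subpops)
    reg <- rbind(reg, cbind(reg1, as.data.frame(sub)))
  }

  members <- NULL; truth <- NULL
  h1 <- list(); h2 <- list(); sexOf <- character(); genotyped <- character()
  causalRows <- list()
  nBack <- if (is.null(reg)) 0L else nrow(reg)

  addCausal <- function(g, fam, k, mafCeil, csq = "missense") {
    al <- .randAlleles(1)
    base <- 10^stats::runif(1, log10(cfg$causalMafRange[1]),
                            log10(min(cfg$causalMafRange[2], mafCeil / 2)))
    sub <- pmin(.subpopMafs(base, nSub, cfg$dirichletConcentration),
                mafCeil * 0.9)
    row <- data.frame(
      chrom = geneChrom[g], pos = g * 1000000L + 500000L + k,
      ref = al[, "ref"], alt = al[, "alt"], gene = genes[g],
      consequence = csq,
      cadd = round(msc[g] * stats::runif(1, 1.5, 2.5), 2),
      maf_global = base, maf_inhouse = base,
      stringsAsFactors = FALSE)
    sub <- matrix(sub, nrow = 1, dimnames = list(NULL, paste0("maf_", subpops)))
    cbind(row, as.data.frame(sub))
  }

  famSubpop <- sample(subpops, cfg$nFamilies, replace = TRUE)
  counter <- 0L
  for (f in seq_len(cfg$nFamilies)) {
    famId <- sprintf("FAM%03d", f)
    model <- cfg$plantedModel[f]
    nKids <- sample(seq(cfg$nChildrenRange[1], cfg$nChildrenRange[2]), 1)
    kidSex <- sample(c("male", "female"), nKids, replace = TRUE)
    if (model == "XL")
      kidSex[1:2] <- "male"    # the forced carriers must be hemizygous
    ids <- c(paste0(famId, "_F"), paste0(famId, "_M"),
             paste0(famId, "_C", seq_len(nKids)))
    sex <- c("male", "female", kidSex)

    # planted causal variants for this family (family-private alleles)
    causal <- integer(0)
    plantGene <- NA_integer_
    if (model %in% c("AR_comphet", "AR_comphet_cis", "AR_hom", "AD")) {
      plantGene <- sample(plantable, 1)
      mafCeil <- if (model %in% c("AR_comphet", "AR_comphet_cis", "AR_hom"))
        1e-2 else 1e-4
      nC <- if (model %in% c("AR_comphet", "AR_comphet_cis")) 2L else 1L
      for (k in seq_len(nC)) {
        counter <- counter + 1L
        causalRows[[length(causalRows) + 1L]] <-
          addCausal(plantGene, f, counter, mafCeil)
        causal <- c(causal, nBack + length(causalRows))
      }
    } else if (model == "XL") {
      plantGene <- xGene
      counter <- counter + 1L
      causalRows[[length(causalRows) + 1L]] <-
        addCausal(xGene, f, counter, 1e-4)
      causal <- nBack + length(causalRows)
    }

    nv <- nBack + length(causalRows)
    maf <- c(if (nBack) reg[[paste0("maf_", famSubpop[f])]] else numeric(0),
             rep(0, length(causalRows)))   # causal alleles: family-private
    vGene <- c(if (nBack) reg$gene else character(0),
               vapply(causalRows, function(r) r$gene, character(1)))
    vChrom <- c(if (nBack) reg$chrom else character(0),
                vapply(causalRows, function(r) r$chrom, character(1)))
    isXv <- .isX(vChrom)

    # founder haplotypes: HWE draws from the family's subpopulation MAF
    drawHap <- function() stats::runif(nv) < maf
    fa1 <- drawHap(); fa2 <- drawHap()
    mo1 <- drawHap(); mo2 <- drawHap()
    fa1[isXv] <- FALSE                      # father's X lives in slot 2
    # plant causal alleles
    if (model == "AR_comphet") {
      fa1[causal] <- c(TRUE, FALSE); fa2[causal] <- FALSE
      mo1[causal] <- c(FALSE, TRUE); mo2[causal] <- FALSE
    } else if (model == "AR_comphet_cis") {
      fa1[causal] <- TRUE; fa2[causal] <- FALSE
      mo1[causal] <- FALSE; mo2[causal] <- FALSE
    } else if (model == "AR_hom") {
      fa1[causal] <- TRUE; fa2[causal] <- FALSE
      mo1[causal] <- TRUE; mo2[causal] <- FALSE
    } else if (model == "AD") {
      fa1[causal] <- TRUE; fa2[causal] <- FALSE
      mo1[causal] <- FALSE; mo2[causal] <- FALSE
    } else if (model == "XL") {
      fa2[causal] <- FALSE
      mo1[causal] <- TRUE; mo2[causal] <- FALSE
    }

    # per-gene whole-haplotype transmission; force the first two children
    # to receive the planted configuration (multiplex family)
    geneOf <- match(vGene, genes)
    kidH1 <- vector("list", nKids); kidH2 <- vector("list", nKids)
    for (k in seq_len(nKids)) {
      c1 <- logical(nv); c2 <- logical(nv)
      for (g in unique(geneOf)) {
        vi <- which(geneOf == g)
        fromF <- if (sample(2, 1) == 1) fa1 else fa2
        fromM <- if (sample(2, 1) == 1) mo1 else mo2
        if (k <= 2 && !is.na(plantGene) && g == plantGene) {
          if (model %in% c("AR_comphet", "AR_comphet_cis", "AD"))
            fromF <- fa1
          if (model %in% c("AR_comphet", "AR_hom")) fromM <- mo1
          if (model == "AR_comphet_cis") fromM <- mo2
          if (model == "AR_hom") fromF <- fa1
          if (model == "XL") fromM <- mo1
        }
        if (geneChrom[g] == "chrX") {
          if (sex[2 + k] == "male") { c2[vi] <- fromM[vi] }
          else { c1[vi] <- fa2[vi]; c2[vi] <- fromM[vi] }
        } else {
          c1[vi] <- fromF[vi]; c2[vi] <- fromM[vi]
        }
      }
      kidH1[[k]] <- c1; kidH2[[k]] <- c2
    }

    h1[ids] <- c(list(fa1, mo1), kidH1)
    h2[ids] <- c(list(fa2, mo2), kidH2)
    sexOf[ids] <- sex

    # affection from the planted genotype (complete penetrance)
    carriesBoth <- function(H1, H2)
      (H1[causal[1]] | H2[causal[1]]) & (H1[causal[2]] | H2[causal[2]])
    affected <- switch(
      model,
      AR_comphet = vapply(ids, function(id)
        carriesBoth(h1[[id]], h2[[id]]), logical(1)),
      # cis plant emulates a phenocopy sibship: the transmitting parent is
      # a healthy carrier, only children carrying the pair are "affected"
      AR_comphet_cis = vapply(ids, function(id)
        carriesBoth(h1[[id]], h2[[id]]), logical(1)) &
        c(FALSE, FALSE, rep(TRUE, nKids)),
      AR_hom = vapply(ids, function(id)
        h1[[id]][causal] & h2[[id]][causal], logical(1)),
      AD = vapply(ids, function(id)
        h1[[id]][causal] | h2[[id]][causal], logical(1)),
      XL = vapply(ids, function(id)
        sexOf[id] == "male" & (h1[[id]][causal] | h2[[id]][causal]),
        logical(1)),
      none = c(FALSE, FALSE, rep(TRUE, 2), rep(FALSE, max(0, nKids - 2)))[
        seq_along(ids)])

    geno <- ids
    parentsGenotyped <- TRUE
    if (stats::runif(1) < cfg$ungenotypedParentProb) {
      geno <- setdiff(geno, sample(ids[1:2], 1))
      parentsGenotyped <- FALSE
    }
    genotyped <- c(genotyped, geno)

    members <- rbind(members, data.frame(
      family_id = famId, individual_id = ids,
      father_id = c(NA, NA, rep(ids[1], nKids)),
      mother_id = c(NA, NA, rep(ids[2], nKids)),
      sex = sex,
      affected = ifelse(affected, "affected", "unaffected"),
      stringsAsFactors = FALSE))
    if (!is.na(plantGene)) {
      cr <- causalRows[causal - nBack]
      truth <- rbind(truth, data.frame(
        family = famId,
        model = sub("_cis$", "", model),
        gene = genes[plantGene],
        variants = paste(vapply(cr, function(r)
          sprintf("%s:%d:%s:%s", r$chrom, r$pos, r$ref, r$alt),
          character(1)), collapse = ","),
        phase = if (model == "AR_comphet") "trans"
        else if (model == "AR_comphet_cis") "cis" else NA_character_,
        parents_genotyped = parentsGenotyped,
        stringsAsFactors = FALSE))
    }
  }

  variantTable <- rbind(reg, do.call(rbind, causalRows))
  variantTable <- variantTable[order(variantTable$chrom, variantTable$pos), ]
  rownames(variantTable) <- NULL

  # genotype codes for genotyped individuals
  nv <- nrow(variantTable)
  key <- sprintf("%s:%d:%s:%s", variantTable$chrom, variantTable$pos,
                 variantTable$ref, variantTable$alt)
  regKey <- c(if (nBack) sprintf("%s:%d:%s:%s", reg$chrom, reg$pos,
                                 reg$ref, reg$alt) else character(0),
              vapply(causalRows, function(r)
                sprintf("%s:%d:%s:%s", r$chrom, r$pos, r$ref, r$alt),
                character(1)))
  ord <- match(key, regKey)
  gt <- matrix("hom_ref", nv, length(genotyped),
               dimnames = list(key, genotyped))
  pad <- function(v, n) { length(v) <- n; v[is.na(v)] <- FALSE; v }
  for (id in genotyped) {
    # haplotypes predate later families' private causal alleles: pad with
    # FALSE (nobody outside the family carries them)
    cnt <- (pad(h1[[id]], length(regKey)) + pad(h2[[id]], length(regKey)))[ord]
    code <- c("hom_ref", "het", "hom_alt")[cnt + 1L]
    xv <- .isX(variantTable$chrom)
    if (sexOf[id] == "male")
      code[xv] <- ifelse(cnt[xv] > 0, "hemi_alt", "hom_ref")
    gt[, id] <- code
  }
  dp <- matrix(3L + stats::rpois(nv * length(genotyped), 35), nv,
               dimnames = list(key, genotyped))
  qual <- round(stats::runif(nv, 40, 200), 1)
  # low-quality noise on background sites only (planted sites stay clean)
  isBack <- ord <= nBack
  if (nBack && cfg$lowQualFrac > 0) {
    bad <- which(isBack & stats::runif(nv) < cfg$lowQualFrac)
    qual[bad] <- stats::runif(length(bad), 0, 20)
  }
  if (nBack && cfg$lowDepthFrac > 0) {
    cells <- which(matrix(stats::runif(nv * length(genotyped)), nv) <
                     cfg$lowDepthFrac & isBack)
    dp[cells] <- sample(0:2, length(cells), replace = TRUE)
  }

  rownames(members) <- NULL
  ped <- new("Pedigree", members = members)
  row <- data.frame(chrom = variantTable$chrom, pos = variantTable$pos,
                    ref = variantTable$ref, alt = variantTable$alt,
                    gene = variantTable$gene,
                    consequence = variantTable$consequence,
                    qual = qual, stringsAsFactors = FALSE)
  cohort <- .newVariantCohort(row, gt, dp, ped)
  geneTable <- data.frame(gene = genes, gdi = round(gdi, 2),
                          msc = round(msc, 2), stringsAsFactors = FALSE)
  list(pedigree = ped, cohort = cohort, variantTable = variantTable,
       geneTable = geneTable, truth = truth)
}

#' Write a simulated cohort to PED/VCF/TSV files
#'
#' Writes `cohort.ped`, `cohort.vcf`, `variants.tsv`, `genes.tsv` and the
#' `truth.tsv` sidecar into a directory.
#'
#' @param sim the list returned by [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(dir, "cohort.ped"),
             vcf = file.path(dir, "cohort.vcf"),
             variants = file.path(dir, "variants.tsv"),
             genes = file.path(dir, "genes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writePedigree(sim$pedigree, paths["ped"])
  writeVariantCalls(sim$cohort, paths["vcf"])
  utils::write.table(sim$variantTable, paths["variants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$geneTable, paths["genes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth))
    utils::write.table(sim$truth, paths["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate a population-structured reference panel
#'
#' Balding-Nichols model: per-population allele frequencies are Beta
#' distributed around shared ancestral frequencies with the configured
#' F_ST, and genotypes are binomial(2, p) draws.
#'
#' @param nPopulations number of populations (>= 2).
#' @param fst between-population F_ST, in (0,1).
#' @param nPerPop individuals per population.
#' @param nVariants number of variants.
#' @param seed integer seed.
#' @return A \linkS4class{ReferencePanel}; per-population frequencies are
#'   kept in `attr(, "popFreqs")`.
#' @export
simulateReferencePanel <- function(nPopulations = 3L, fst = 0.1,
                                   nPerPop = 50L, nVariants = 500L,
                                   seed = 1L) {
  if (nPopulations < 2) stop("need at least 2 populations")
  if (fst <= 0 || fst >= 1) stop("fst must be in (0,1)")
  set.seed(seed)
  anc <- stats::runif(nVariants, 0.1, 0.9)
  a <- anc * (1 - fst) / fst
  b <- (1 - anc) * (1 - fst) / fst
  popFreqs <- vapply(seq_len(nPopulations), function(k)
    stats::rbeta(nVariants, a, b), numeric(nVariants))
  colnames(popFreqs) <- paste0("POP", seq_len(nPopulations))
  g <- do.call(rbind, lapply(seq_len(nPopulations), function(k)
    t(vapply(seq_len(nPerPop), function(i)
      stats::rbinom(nVariants, 2, popFreqs[, k]), numeric(nVariants)))))
  rownames(g) <- paste0(rep(colnames(popFreqs), each = nPerPop), "_",
                        rep(seq_len(nPerPop), nPopulations))
  colnames(g) <- paste0("V", seq_len(nVariants))
  panel <- referencePanel(g, rep(colnames(popFreqs), each = nPerPop))
  attr(panel, "popFreqs") <- popFreqs
  panel
}

#' Simulate an autoantigen-array experiment
#'
#' Log-normal NFI with an additive (log2-scale) group effect on a chosen
#' subset of antigens in the treated groups, positive multiplicative SNR
#' noise, and a few internal IgG control antigens. The perturbed antigens
#' are returned as the truth list.
#'
#' @param nAntigens number of (non-control) antigens.
#' @param nControls number of IgG control antigens.
#' @param groups group labels; the first is the control group.
#' @param nPerGroup samples per group.
#' @param nPerturbed number of antigens raised in the treated groups.
#' @param effectSize log2 fold change of the perturbation.
#' @param noiseSd log2-scale sample noise SD.
#' @param seed integer seed.
#' @return An \linkS4class{AntigenArray} with the perturbed antigen names
#'   in `metadata()$perturbed`.
#' @export
simulateArray <- function(nAntigens = 120L, nControls = 4L,
                          groups = c("DMSO", "AIM100", "Cpd4f"),
                          nPerGroup = 5L, nPerturbed = 10L,
                          effectSize = 2, noiseSd = 0.5, seed = 1L) {
  if (length(groups) < 2) stop("need at least 2 groups")
  set.seed(seed)
  antigens <- c(sprintf("Ag%03d", seq_len(nAntigens)),
                sprintf("IgG_ctrl%d", seq_len(nControls)))
  sampleGroup <- rep(groups, each = nPerGroup)
  samples <- paste0(sampleGroup, "_", rep(seq_len(nPerGroup), length(groups)))
  baseline <- stats::runif(nAntigens + nControls, 6, 12)   # log2 NFI
  baseline[nAntigens + seq_len(nControls)] <- 13           # bright stable controls
  perturbed <- sample(seq_len(nAntigens), nPerturbed)
  eff <- matrix(0, nAntigens + nControls, length(samples))
  eff[perturbed, sampleGroup != groups[1]] <- effectSize
  lognfi <- baseline + eff +
    matrix(stats::rnorm((nAntigens + nControls) * length(samples),
                        sd = noiseSd), ncol = length(samples))
  nfi <- 2^lognfi
  snr <- matrix(stats::rlnorm((nAntigens + nControls) * length(samples),
                              meanlog = 1, sdlog = 0.3),
                ncol = length(samples))
  dimnames(nfi) <- dimnames(snr) <- list(antigens, samples)
  arr <- antigenArray(nfi, snr, sampleGroup,
                      isControl = grepl("^IgG_ctrl", antigens))
  metadata(arr)$perturbed <- antigens[perturbed]
  arr
}

#' Recovery of planted candidate genes by the screen
#'
#' Compares an AR compound-heterozygote screen report against the truth
#' sidecar of [simulateCohort()]: recall over trans-planted families whose
#' parents were both genotyped, precision of all reported comp-het
#' candidates, and the number of reports hitting cis-planted genes (which
#' must be rejected by phasing).
#'
#' @param report the data.frame from [runScreen()].
#' @param truth the truth data.frame from [simulateCohort()].
#' @return List with `recall`, `precision` and `cisHits`.
#' @export
evaluateRecovery <- function(report, truth) {
  rep2 <- report[report$model == "AR_comphet", , drop = FALSE]
  repKey <- paste(rep2$family, rep2$gene)
  transTruth <- truth[truth$model == "AR_comphet" & truth$phase %in% "trans", ]
  evalTruth <- transTruth[transTruth$parents_genotyped, ]
  recall <- if (nrow(evalTruth))
    mean(paste(evalTruth$family, evalTruth$gene) %in% repKey) else NA_real_
  truthKey <- paste(transTruth$family, transTruth$gene)
  precision <- if (nrow(rep2)) mean(repKey %in% truthKey) else NA_real_
  cisTruth <- truth[truth$phase %in% "cis", ]
  cisHits <- sum(repKey %in% paste(cisTruth$family, cisTruth$gene))
  list(recall = recall, precision = precision, cisHits = cisHits)
}
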