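test_that("the cohort generator is deterministic under a fixed seed", {
  s1 <- simulateCohort(simConfig(seed = 17, nFamilies = 4))
  s2 <- simulateCohort(simConfig(seed = 17, nFamilies = 4))
  expect_identical(members(s1$pedigree), members(s2$pedigree))
  expect_identical(gtAssay(s1$cohort), gtAssay(s2$cohort))
  expect_identical(s1$variantTable, s2$variantTable)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateCohort(simConfig(seed = 18, nFamilies = 4))
  expect_false(identical(gtAssay(s1$cohort), gtAssay(s3$cohort)))
})

test_that("every simulated child genotype is Mendelian-consistent", {
  sim <- simulateCohort(simConfig(seed = 23, nFamilies = 8,
    plantedModel = c("AR_comphet", "AR_hom", "AD", "XL")))
  gt <- gtAssay(sim$cohort)
  m <- members(sim$pedigree)
  rd <- as.data.frame(rowData(sim$cohort))
  auto <- !rd$chrom %in% "chrX"
  kids <- m[!is.na(m$father_id), ]
  for (k in seq_len(nrow(kids))) {
    ok <- vapply(which(auto), function(v)
      mendelOk(gt[v, kids$individual_id[k]],
               gt[v, kids$father_id[k]], gt[v, kids$mother_id[k]]),
      logical(1))
    expect_true(all(ok))
  }
})

test_that("planted causal variants pass every screen threshold by construction", {
  sim <- simulateCohort(simConfig(seed = 29, nFamilies = 10))
  vt <- sim$variantTable
  key <- sprintf("%s:%d:%s:%s", vt$chrom, vt$pos, vt$ref, vt$alt)
  causal <- unlist(strsplit(sim$truth$variants, ","))
  cv <- vt[match(causal, key), ]
  expect_false(any(is.na(cv$pos)))
  expect_true(all(cv$consequence == "missense"))
  subcols <- grep("^maf_pop", names(cv), value = TRUE)
  expect_true(all(as.matrix(cv[subcols]) < 1e-2))      # AR ceiling everywhere
  expect_true(all(cv$maf_global <= 0.01))
  msc <- sim$geneTable$msc[match(cv$gene, sim$geneTable$gene)]
  expect_true(all(cv$cadd / msc > 1))
  gdi <- sim$geneTable$gdi[match(cv$gene, sim$geneTable$gene)]
  expect_true(all(gdi <= 13.84))
})

test_that("affection tracks the planted genotype under complete penetrance", {
  sim <- simulateCohort(simConfig(seed = 37, nFamilies = 6,
                                  plantedModel = "AD"))
  gt <- gtAssay(sim$cohort)
  m <- members(sim$pedigree)
  key <- unlist(strsplit(sim$truth$variants, ","))
  for (i in seq_len(nrow(sim$truth))) {
    fam <- m[m$family_id == sim$truth$family[i], ]
    ids <- intersect(fam$individual_id, colnames(gt))
    carrier <- gt[key[i], ids] %in% c("het", "hom_alt", "hemi_alt")
    expect_identical(fam$affected[match(ids, fam$individual_id)] == "affected",
                     unname(carrier))
  }
})

test_that("Balding-Nichols panels are reproducible and respect the F_ST limit", {
  p1 <- simulateReferencePanel(3, 0.1, 20, 100, seed = 2)
  p2 <- simulateReferencePanel(3, 0.1, 20, 100, seed = 2)
  expect_identical(p1@genotypes, p2@genotypes)
  expect_error(simulateReferencePanel(3, 1.5), "fst")
  expect_error(simulateReferencePanel(1), "2 populations")
  # small F_ST: between-population frequency spread shrinks
  lo <- attr(simulateReferencePanel(3, 0.001, 10, 300, seed = 3), "popFreqs")
  hi <- attr(simulateReferencePanel(3, 0.3, 10, 300, seed = 3), "popFreqs")
  expect_lt(mean(apply(lo, 1, var)), mean(apply(hi, 1, var)) / 10)
})

test_that("null arrays give uniform signed-rank p-values, strong effects rank top", {
  nullP <- c()
  for (s in 1:5) {
    arr <- simulateArray(nAntigens = 40, nPerturbed = 0, effectSize = 0,
                         nPerGroup = 12, seed = s)
    sc <- abScores(arr)
    grp <- SummarizedExperiment::colData(arr)$group
    nullP <- c(nullP, apply(sc, 1, function(r)
      pairedSignedRank(r[grp == "AIM100"], r[grp == "DMSO"])))
  }
  # exact p-values are discrete, so ties are expected
  expect_gt(suppressWarnings(ks.test(nullP, "punif"))$p.value, 0.01)
  arr <- simulateArray(nAntigens = 50, nPerturbed = 10, effectSize = 4,
                       noiseSd = 0.3, seed = 12)
  sc <- abScores(arr)
  grp <- SummarizedExperiment::colData(arr)$group
  rk <- rankAntigens(sc, treated = which(grp == "Cpd4f"),
                     control = which(grp == "DMSO"))
  expect_setequal(rk$antigen[1:10], S4Vectors::metadata(arr)$perturbed)
})
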