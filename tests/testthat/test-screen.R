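test_that("consequence filter keeps non-synonymous coding and essential splice", {
  expect_true(all(consequenceFilter(c("missense", "nonsense", "frameshift",
                                      "inframe_indel", "essential_splice"))))
  expect_false(any(consequenceFilter(c("synonymous", "other", NA))))
})

test_that("frequency filter applies global exclusion then per-model subpopulation ceilings", {
  cfg <- screenConfig()
  df <- data.frame(maf_global = c(1e-3, 1e-3, 0.02, 1e-3, 0),
                   maf_inhouse = c(0, 0, 0, 0.02, 0),
                   maf_afr = c(5e-3, 5e-5, 1e-3, 1e-3, 0),
                   maf_sas = c(1e-3, 2e-4, 1e-3, 1e-3, 0))
  # AR: all subpop MAF < 1e-2
  expect_equal(frequencyFilter(df, "AR", cfg),
               c(TRUE, TRUE, FALSE, FALSE, TRUE))
  # AD: one subpopulation at 2e-4 >= 1e-4 is enough to drop
  expect_equal(frequencyFilter(df, "AD", cfg),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # unannotated variant (all frequencies 0) passes every model
  expect_true(frequencyFilter(df[5, ], "XL", cfg))
})

test_that("Hardy-Weinberg expectations match q^2 and 2*q1*q2", {
  hw <- hweFrequencies(8e-5, 5e-3)
  expect_equal(hw$homozygote, 6.4e-9)
  expect_equal(hw$comphet, 8e-7)
  expect_equal(hweFrequencies(0)$homozygote, 0)
  expect_error(hweFrequencies(-0.1), "in \\[0,1\\]")
  expect_error(hweFrequencies(0.5, 1.2), "in \\[0,1\\]")
})

test_that("comp-het phase follows parental origin logic", {
  fm <- family1Members()
  # father carries v1 only, mother v2 only -> trans
  gt <- family1Gt()
  pairs <- detectCompHetPairs(gt, fm, gene = "G")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$phase, "trans")
  expect_true(all(c("K1_S1", "K1_S2") %in%
                    strsplit(pairs$carriers, ",")[[1]]))
  # both alleles in the father, none in the mother -> cis
  gt2 <- rbind(v1 = c("het", "hom_ref", "het", "het"),
               v2 = c("het", "hom_ref", "het", "het"))
  colnames(gt2) <- fm$individual_id
  expect_equal(detectCompHetPairs(gt2, fm, gene = "G")$phase, "cis")
  # ungenotyped father, mother carries one allele -> ambiguous
  gt3 <- rbind(v1 = c("missing", "hom_ref", "het", "het"),
               v2 = c("missing", "het", "het", "het"))
  colnames(gt3) <- fm$individual_id
  expect_equal(detectCompHetPairs(gt3, fm, gene = "G")$phase, "ambiguous")
})

test_that("phasing equals the brute-force haplotype-enumeration oracle", {
  set.seed(20240601)
  nfam <- 1000
  for (i in seq_len(nfam)) {
    rf <- randomFamily()
    got <- detectCompHetPairs(rf$gt, rf$fm, gene = "G")
    want <- oraclePairs(rf$gt, rf$fm)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[c("variant_a", "variant_b", "phase")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("AD segregation respects penetrance settings", {
  fm <- family1Members()
  gt <- rbind(v1 = c("het", "hom_ref", "het", "het"))  # father unaffected carrier
  colnames(gt) <- fm$individual_id
  expect_null(segregate(gt, fm, "AD", "complete", gene = "G"))
  rep <- segregate(gt, fm, "AD", "incomplete", gene = "G")
  expect_equal(rep$segregation, "incomplete_only")
  # clean AD pattern: only affected carry
  gt2 <- rbind(v1 = c("hom_ref", "hom_ref", "het", "het"))
  colnames(gt2) <- fm$individual_id
  rep2 <- segregate(gt2, fm, "AD", "complete", gene = "G")
  expect_equal(rep2$segregation, "complete_penetrance_consistent")
})

test_that("AR homozygous segregation requires hom_alt in every affected", {
  fm <- family1Members()
  gt <- rbind(v1 = c("het", "het", "hom_alt", "het"))  # one affected only het
  colnames(gt) <- fm$individual_id
  expect_null(segregate(gt, fm, "AR_hom", gene = "G"))
  gt2 <- rbind(v1 = c("het", "het", "hom_alt", "hom_alt"))
  colnames(gt2) <- fm$individual_id
  expect_equal(segregate(gt2, fm, "AR_hom", gene = "G")$segregation,
               "complete_penetrance_consistent")
  # missing genotypes never veto
  gt3 <- rbind(v1 = c("het", "het", "hom_alt", "missing"))
  colnames(gt3) <- fm$individual_id
  expect_false(is.null(segregate(gt3, fm, "AR_hom", gene = "G")))
})

test_that("X-linked segregation uses hemizygous males and spares het females", {
  fm <- data.frame(
    family_id = "FX",
    individual_id = c("F", "M", "S1", "S2", "D1"),
    father_id = c(NA, NA, "F", "F", "F"),
    mother_id = c(NA, NA, "M", "M", "M"),
    sex = c("male", "female", "male", "male", "female"),
    affected = c("unaffected", "unaffected", "affected", "affected",
                 "unaffected"))
  gt <- rbind(vx = c("hom_ref", "het", "hemi_alt", "hemi_alt", "het"))
  colnames(gt) <- fm$individual_id
  rep <- segregate(gt, fm, "XL", gene = "GX")
  expect_equal(rep$segregation, "complete_penetrance_consistent")
  # an unaffected hemizygous male vetoes complete penetrance
  gt["vx", "F"] <- "hemi_alt"
  expect_null(segregate(gt, fm, "XL", "complete", gene = "GX"))
  expect_equal(segregate(gt, fm, "XL", "incomplete", gene = "GX")$segregation,
               "incomplete_only")
})

test_that("kindred 1: trans comp-het in both affected sons is an AR candidate", {
  vc <- cohortFromGt(family1Gt(), family1Members())
  rep <- runScreen(vc)
  hit <- rep[rep$model == "AR_comphet", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$phase, "trans")
  expect_equal(hit$segregation, "complete_penetrance_consistent")
})

test_that("kindred 2: ungenotyped parent gives an ambiguous but retained candidate", {
  vc <- cohortFromGt(family2Gt(), family2Members(),
                     subpopMafs = c(maf_afr1 = 8e-5, maf_afr2 = 5e-3))
  rep <- runScreen(vc)
  hit <- rep[rep$model == "AR_comphet", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$phase, "ambiguous")
  # the unaffected sibling carries one allele only: no penetrance violation
  expect_equal(hit$segregation, "complete_penetrance_consistent")
})

test_that("screen filters compose as an order-invariant intersection", {
  sim <- simulateCohort(simConfig(seed = 31, nFamilies = 4))
  rd <- as.data.frame(rowData(joinAnnotations(
    sim$cohort, sim$variantTable, sim$geneTable)))
  cfg <- screenConfig()
  a <- consequenceFilter(rd$consequence) & frequencyFilter(rd, "AR", cfg)
  b <- frequencyFilter(rd, "AR", cfg) & consequenceFilter(rd$consequence)
  expect_identical(a, b)
  expect_identical(a & a, a)                            # idempotent
})

test_that("a planted common variant is excluded and clean cohorts report nothing", {
  vc <- cohortFromGt(family1Gt(), family1Members())
  rd <- as.data.frame(rowData(vc))
  rd$maf_global[1] <- 0.02                              # too common
  rowData(vc) <- rd
  rep <- runScreen(vc)
  expect_false(any(grepl(rownames(vc)[1], rep$variants)))
  # families with no qualifying pattern produce an empty report
  sim <- simulateCohort(simConfig(seed = 8, nFamilies = 3,
                                  plantedModel = "none"))
  vc2 <- suppressWarnings(joinAnnotations(applyCallQualityFilter(sim$cohort),
                                          sim$variantTable, sim$geneTable))
  rep2 <- suppressWarnings(runScreen(vc2))
  expect_equal(nrow(rep2[rep2$model == "AR_comphet", ]), 0)
})

test_that("no unaffected complete-penetrance carrier of a full AR genotype is reported", {
  sim <- simulateCohort(simConfig(seed = 13, nFamilies = 20))
  vc <- suppressWarnings(joinAnnotations(applyCallQualityFilter(sim$cohort),
                                         sim$variantTable, sim$geneTable))
  rep <- suppressWarnings(runScreen(vc))
  gt <- gtAssay(vc)
  m <- members(sim$pedigree)
  for (k in seq_len(nrow(rep))) {
    if (rep$model[k] != "AR_comphet") next
    vs <- strsplit(rep$variants[k], ",")[[1]]
    fam <- m[m$family_id == rep$family[k], ]
    una <- intersect(fam$individual_id[fam$affected == "unaffected"],
                     colnames(gt))
    carriesBoth <- vapply(una, function(id)
      all(gt[vs, id] %in% c("het", "hom_alt")), logical(1))
    expect_false(any(carriesBoth))
  }
})
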