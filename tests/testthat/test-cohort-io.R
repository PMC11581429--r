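test_that("PED parsing maps codes, missing parents and trio structure", {
  p <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1 dad 0 0 1 1",
               "F1 mum 0 0 2 1",
               "F1 kid dad mum 1 2"), p)
  ped <- readPedigree(p)
  fam <- families(ped)
  expect_length(fam, 1)
  m <- members(fam$F1)
  expect_equal(nrow(m), 3)
  expect_equal(m$father_id[m$individual_id == "kid"], "dad")
  expect_true(is.na(m$father_id[m$individual_id == "dad"]))
  expect_equal(m$affected, c("unaffected", "unaffected", "affected"))
  expect_equal(m$sex, c("male", "female", "male"))
})

test_that("PED errors name the offending line and validate parent links", {
  p <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1 a 0 0 1 1", "F1 b 0 0 2"), p)
  expect_error(readPedigree(p), "line 2")
  writeLines(c("F1 kid ghost 0 1 2"), p)
  expect_error(readPedigree(p), "ghost")
})

test_that("pedigree validity rejects parent-sex and cycle violations", {
  m <- family1Members()
  bad <- m; bad$sex[1] <- "female"
  expect_error(new("Pedigree", members = bad), "father is not male")
  cyc <- data.frame(family_id = "F", individual_id = c("a", "b"),
                    father_id = c("b", "a"), mother_id = c(NA, NA),
                    sex = c("male", "male"),
                    affected = c("unknown", "unknown"))
  expect_error(new("Pedigree", members = cyc), "ancestor")
})

writeTestVcf <- function(lines, samples) {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT",
                       samples), collapse = "\t"),
               lines), p)
  p
}

trioPed <- function() {
  new("Pedigree", members = data.frame(
    family_id = "F1", individual_id = c("dad", "mum", "kid"),
    father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mum"),
    sex = c("male", "female", "male"),
    affected = c("unaffected", "unaffected", "affected")))
}

test_that("VCF genotypes map to codes, chrX males become hemizygous", {
  p <- writeTestVcf(c(
    "chr1\t100\t.\tA\tG\t60\tPASS\tGENE=G1;CSQ=missense\tGT:DP\t0/0:30\t0/1:25\t0/1:31",
    "chrX\t500\t.\tC\tT\t60\tPASS\tGENE=G2;CSQ=missense\tGT:DP\t1:20\t0/1:22\t1:28"),
    c("dad", "mum", "kid"))
  vc <- readVariantCalls(p, trioPed())
  gt <- gtAssay(vc)
  expect_equal(unname(gt[1, ]), c("hom_ref", "het", "het"))
  expect_equal(unname(gt[2, ]), c("hemi_alt", "het", "hemi_alt"))
  expect_equal(rowData(vc)$gene, c("G1", "G2"))
  expect_equal(unname(assay(vc, "dp")[1, ]), c(30L, 25L, 31L))
})

test_that("multi-allelic sites decompose and conserve allele counts", {
  p <- writeTestVcf(
    "chr2\t200\t.\tA\tG,T\t80\tPASS\tGENE=G3;CSQ=missense\tGT:DP\t1/2:30\t0/1:30\t2/2:30",
    c("dad", "mum", "kid"))
  vc <- readVariantCalls(p, trioPed())
  expect_equal(nrow(vc), 2)
  expect_equal(rowData(vc)$alt, c("G", "T"))
  gt <- gtAssay(vc)
  expect_equal(unname(gt[1, ]), c("het", "het", "hom_ref"))
  expect_equal(unname(gt[2, ]), c("het", "hom_ref", "hom_alt"))
  # per-sample alt allele counts summed over decomposed records = original
  cnt <- function(g) c(hom_ref = 0, het = 1, hom_alt = 2, hemi_alt = 1)[g]
  expect_equal(unname(cnt(gt[1, ]) + cnt(gt[2, ])), c(2, 1, 2),
               ignore_attr = TRUE)
})

test_that("unknown VCF samples are dropped with a warning", {
  p <- writeTestVcf(
    "chr1\t100\t.\tA\tG\t60\tPASS\tGENE=G1;CSQ=missense\tGT:DP\t0/1:30\t0/1:30\t0/1:30\t0/1:30",
    c("dad", "mum", "kid", "stranger"))
  expect_warning(vc <- readVariantCalls(p, trioPed()), "stranger")
  expect_equal(sort(colnames(vc)), c("dad", "kid", "mum"))
})

test_that("call-quality filter drops sites at the <=20 boundary and masks low depth", {
  ped <- trioPed()
  row <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "G",
                    gene = "G1", consequence = "missense",
                    qual = c(19.9, 20.0, 50))
  gt <- matrix("het", 3, 3, dimnames = list(NULL, c("dad", "mum", "kid")))
  dp <- matrix(c(30L, 30L, 30L, 30L, 30L, 30L, 3L, 2L, 30L), 3,
               byrow = TRUE, dimnames = list(NULL, c("dad", "mum", "kid")))
  vc <- famscreen:::.newVariantCohort(row, gt, dp, ped)
  out <- applyCallQualityFilter(vc)
  expect_equal(nrow(out), 1)                      # 19.9 and 20.0 both removed
  expect_equal(rowData(out)$qual, 50)
  # depth 2 masks only that sample's genotype; depth 3 survives
  expect_equal(unname(gtAssay(out)[1, ]), c("het", "missing", "het"))
  # idempotent
  expect_identical(gtAssay(applyCallQualityFilter(out)), gtAssay(out))
})

test_that("annotation join copies fields, flags unmatched and rejects duplicates", {
  ped <- trioPed()
  row <- data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "G",
                    gene = NA_character_, consequence = NA_character_,
                    qual = 99)
  gt <- matrix("het", 2, 3, dimnames = list(NULL, c("dad", "mum", "kid")))
  dp <- matrix(30L, 2, 3, dimnames = list(NULL, c("dad", "mum", "kid")))
  vc <- famscreen:::.newVariantCohort(row, gt, dp, ped)
  vt <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G",
                   gene = "G1", consequence = "missense", cadd = 25,
                   maf_global = 1e-3, maf_inhouse = 0,
                   maf_afr = 2e-3, maf_sas = NA)
  gtab <- data.frame(gene = "G1", gdi = 3, msc = 10)
  ann <- joinAnnotations(vc, vt, gtab)
  rd <- as.data.frame(rowData(ann))
  expect_equal(rd$cadd, c(25, NA))
  expect_equal(rd$maf_afr, c(2e-3, 0))
  expect_equal(rd$maf_sas, c(0, 0))               # NA frequency -> 0
  expect_equal(rd$gene, c("G1", NA))
  expect_equal(rd$ann_matched, c(TRUE, FALSE))
  expect_error(joinAnnotations(vc, rbind(vt, vt), gtab), "duplicate")
  expect_error(joinAnnotations(vc, vt, rbind(gtab, gtab)), "duplicate")
})

test_that("a synthetic cohort round-trips identically through PED/VCF", {
  for (seed in c(4, 42)) {
    sim <- simulateCohort(simConfig(seed = seed, nFamilies = 3))
    dir <- withr::local_tempdir()
    paths <- writeCohort(sim, dir)
    ped2 <- readPedigree(paths["ped"])
    expect_identical(members(ped2), members(sim$pedigree))
    vc2 <- readVariantCalls(paths["vcf"], ped2)
    gt1 <- gtAssay(sim$cohort)
    expect_true(all(gt1 == gtAssay(vc2)[rownames(gt1), colnames(gt1)]))
    expect_true(all(assay(sim$cohort, "dp") ==
                      assay(vc2, "dp")[rownames(gt1), colnames(gt1)]))
    expect_equal(rowData(vc2)[rownames(gt1), "qual"],
                 rowData(sim$cohort)$qual, tolerance = 1e-6)
  }
})
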