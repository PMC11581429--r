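#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData rowData<-
NULL

.isX <- function(chrom) sub("^chr", "", chrom) %in% c("X", "x")
.isSexChrom <- function(chrom) sub("^chr", "", chrom) %in% c("X", "x", "Y", "y")

# Assemble a VariantCohort from parsed pieces. `row` needs chrom, pos, ref,
# alt, gene, consequence, qual; gt/dp are variants x samples.
.newVariantCohort <- function(row, gt, dp, pedigree) {
  stopifnot(nrow(row) == nrow(gt), all(dim(gt) == dim(dp)))
  rn <- sprintf("%s:%d:%s:%s", row$chrom, row$pos, row$ref, row$alt)
  rownames(row) <- rownames(gt) <- rownames(dp) <- make.unique(rn)
  se <- SummarizedExperiment(
    assays = list(gt = gt, dp = dp),
    rowData = row,
    colData = S4Vectors::DataFrame(row.names = colnames(gt)))
  vc <- new("VariantCohort", se)
  metadata(vc)$pedigree <- pedigree
  metadata(vc)$annotated <- FALSE
  vc
}

# Map one GT string to a genotype code for decomposed alt allele `k`.
.gtCode <- function(gtstr, k, male, xchrom) {
  if (is.na(gtstr) || gtstr %in% c(".", "./.", ".|.")) return("missing")
  gtstr <- sub(":.*$", "", gtstr)
  tok <- strsplit(gtstr, "[/|]")[[1]]
  if (any(tok == ".")) return("missing")
  cnt <- sum(tok == as.character(k))
  if (length(tok) == 1L)
    return(if (cnt > 0) "hemi_alt" else "hom_ref")
  code <- c("hom_ref", "het", "hom_alt")[cnt + 1L]
  if (code == "hom_alt" && male && xchrom) code <- "hemi_alt"
  code
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF (GT, DP and QUAL are used) into a
#' \linkS4class{VariantCohort}. Multi-allelic sites are decomposed into one
#' record per alternate allele, with per-allele genotype codes. On chrX, a
#' haploid alternate call (GT "1") in a male, or a male homozygous alternate
#' call, is coded `hemi_alt`. Gene symbol and consequence class are taken
#' from the INFO fields `GENE` and `CSQ` when present (they can also be
#' supplied later via [joinAnnotations()]).
#'
#' Samples present in the VCF but absent from the pedigree are dropped with
#' a warning; pedigree members without a VCF column are simply ungenotyped.
#'
#' @param path path to a VCF file.
#' @param pedigree a \linkS4class{Pedigree} naming the expected samples.
#' @return A \linkS4class{VariantCohort}.
#' @export
readVariantCalls <- function(path, pedigree) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("no variant records in ", path)
  gtraw <- v@gt
  samples <- colnames(gtraw)[-1]            # first column is FORMAT
  known <- members(pedigree)$individual_id
  drop <- setdiff(samples, known)
  if (length(drop)) {
    warning("dropping VCF samples absent from pedigree: ",
            paste(drop, collapse = ", "))
    samples <- setdiff(samples, drop)
  }
  if (!length(samples)) stop("no VCF sample matches the pedigree")
  sex <- members(pedigree)$sex[match(samples, known)]
  male <- sex == "male"

  gtmat <- vcfR::extract.gt(v, element = "GT")
  dpmat <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dpmat)) dpmat <- matrix(NA_real_, nrow(fix), length(samples))
  gtmat <- gtmat[, samples, drop = FALSE]
  dpmat <- dpmat[, samples, drop = FALSE]

  info1 <- function(info, key) {
    hit <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    ok <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
    out[ok] <- sub(paste0("^;?", key, "="), "", hit)
    out
  }
  gene <- info1(fix$INFO, "GENE")
  csq <- info1(fix$INFO, "CSQ")

  rows <- list(); gts <- list(); dps <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    xc <- .isX(fix$CHROM[i])
    for (k in seq_along(alts)) {
      codes <- vapply(seq_along(samples), function(j)
        .gtCode(gtmat[i, j], k, male[j], xc), character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        gene = gene[i], consequence = csq[i],
        qual = suppressWarnings(as.numeric(fix$QUAL[i])),
        stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- codes
      dps[[length(dps) + 1L]] <- as.integer(round(dpmat[i, ]))
    }
  }
  row <- do.call(rbind, rows)
  gt <- do.call(rbind, gts); colnames(gt) <- samples
  dp <- do.call(rbind, dps); colnames(dp) <- samples
  .newVariantCohort(row, gt, dp, pedigree)
}

#' Filter variant calls on depth and call quality
#'
#' A site survives iff its Phred-scaled call quality is strictly greater
#' than `minQualExclusive` (calls with quality <= 20 are filtered out).
#' Per-sample read depths at or below `minDepthExclusive` (<= 2x) mask that
#' sample's genotype to `missing` rather than dropping the whole site, so
#' other samples' information is preserved; a missing depth for a called
#' genotype is masked the same way. The filter is total and idempotent.
#'
#' @param vc a \linkS4class{VariantCohort}.
#' @param minDepthExclusive depths `<=` this value mask the genotype.
#' @param minQualExclusive site qualities `<=` this value drop the record.
#' @return The filtered \linkS4class{VariantCohort}.
#' @export
applyCallQualityFilter <- function(vc, minDepthExclusive = 2,
                                   minQualExclusive = 20) {
  keep <- !is.na(rowData(vc)$qual) & rowData(vc)$qual > minQualExclusive
  vc <- vc[keep, ]
  gt <- assay(vc, "gt")
  dp <- assay(vc, "dp")
  mask <- (is.na(dp) | dp <= minDepthExclusive) & gt != "missing"
  gt[mask] <- "missing"
  SummarizedExperiment::assay(vc, "gt") <- gt
  vc
}

.readTab <- function(x, what) {
  if (is.data.frame(x)) return(x)
  if (!file.exists(x)) stop(what, " table not found: ", x)
  utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Join variant- and gene-level annotations onto a cohort
#'
#' Attaches per-variant annotations (CADD, global/in-house MAF and one MAF
#' column per gnomAD-style subpopulation) keyed on (chrom, pos, ref, alt),
#' and stores the per-gene score table (GDI, MSC) in the cohort metadata.
#' Variants absent from the annotation table get frequency 0 everywhere
#' (unobserved = rare) and a missing CADD, and are flagged in
#' `rowData()$ann_matched`. Missing `gene`/`consequence` fields from the VCF
#' are filled from the table when available.
#'
#' @param vc a \linkS4class{VariantCohort}.
#' @param variantTable data.frame or TSV path with columns chrom, pos, ref,
#'   alt, optionally gene and consequence, cadd, maf_global, maf_inhouse and
#'   any number of `maf_<subpop>` columns.
#' @param geneTable data.frame or TSV path with columns gene, gdi, msc.
#' @return The annotated \linkS4class{VariantCohort}.
#' @export
joinAnnotations <- function(vc, variantTable, geneTable) {
  vt <- .readTab(variantTable, "variant")
  gt <- .readTab(geneTable, "gene")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(vt)))
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  if (!all(c("gene", "gdi", "msc") %in% names(gt)))
    stop("gene table needs columns: gene, gdi, msc")
  vkey <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  if (anyDuplicated(vkey(vt)))
    stop("duplicate variant keys in annotation table: ",
         paste(unique(vkey(vt)[duplicated(vkey(vt))]), collapse = ", "))
  if (anyDuplicated(gt$gene))
    stop("duplicate gene keys in gene table: ",
         paste(unique(gt$gene[duplicated(gt$gene)]), collapse = ", "))

  rd <- as.data.frame(rowData(vc))
  idx <- match(vkey(rd), vkey(vt))
  mafcols <- grep("^maf_", names(vt), value = TRUE)
  for (col in c("maf_global", "maf_inhouse"))
    if (!col %in% mafcols) { vt[[col]] <- 0; mafcols <- c(mafcols, col) }
  for (col in mafcols) {
    val <- vt[[col]][idx]
    val[is.na(val)] <- 0                 # unobserved = frequency 0
    rd[[col]] <- val
  }
  rd$cadd <- if ("cadd" %in% names(vt)) vt$cadd[idx] else NA_real_
  rd$ann_matched <- !is.na(idx)
  for (col in c("gene", "consequence")) {
    if (col %in% names(vt)) {
      fill <- is.na(rd[[col]]) & !is.na(idx)
      rd[[col]][fill] <- vt[[col]][idx[fill]]
    }
  }
  rowData(vc) <- rd
  metadata(vc)$geneScores <- gt[, c("gene", "gdi", "msc")]
  metadata(vc)$subpopCols <- setdiff(mafcols, c("maf_global", "maf_inhouse"))
  metadata(vc)$annotated <- TRUE
  vc
}

#' Write a cohort's calls back to a (biallelic) VCF
#'
#' Writes one VCF record per (already decomposed) variant, with GENE/CSQ in
#' INFO and GT:DP per sample, so a synthetic cohort round-trips through
#' [readVariantCalls()].
#'
#' @param vc a \linkS4class{VariantCohort}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariantCalls <- function(vc, path) {
  rd <- as.data.frame(rowData(vc))
  gt <- assay(vc, "gt")
  dp <- assay(vc, "dp")
  ped <- metadata(vc)$pedigree
  sex <- members(ped)$sex[match(colnames(gt), members(ped)$individual_id)]
  enc <- function(code, male, xc) {
    switch(code,
           hom_ref = if (male && xc) "0" else "0/0",
           het = "0/1", hom_alt = "1/1",
           hemi_alt = "1", missing = "./.")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
               "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gt)), collapse = "\t")), con)
  for (i in seq_len(nrow(rd))) {
    xc <- .isX(rd$chrom[i])
    cells <- vapply(seq_len(ncol(gt)), function(j) {
      d <- dp[i, j]
      paste0(enc(gt[i, j], sex[j] == "male", xc), ":",
             if (is.na(d)) "." else d)
    }, character(1))
    info <- paste0("GENE=", ifelse(is.na(rd$gene[i]), ".", rd$gene[i]),
                   ";CSQ=", ifelse(is.na(rd$consequence[i]), ".",
                                   rd$consequence[i]))
    writeLines(paste(c(rd$chrom[i], rd$pos[i], ".", rd$ref[i], rd$alt[i],
                       format(rd$qual[i]), "PASS", info, "GT:DP", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

setMethod("show", "VariantCohort", function(object) {
  cat("VariantCohort:", nrow(object), "variant records x",
      ncol(object), "samples;",
      if (isTRUE(metadata(object)$annotated)) "annotated" else "unannotated",
      "\n")
  invisible(NULL)
})
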