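#' Run the end-to-end pipeline
#'
#' Orchestrates the stages in a fixed order — simulate (or read) a cohort,
#' apply the call-quality filter, join annotations, run the inheritance
#' screen, assign ancestry against a reference panel, and quantify an
#' antigen array — writing the candidate report, the stage outputs and a
#' run manifest (seed, per-filter attrition counts, file checksums) to an
#' output directory. All randomness derives from the single seed, so a
#' rerun with the same configuration is byte-identical.
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' optional sections `cohort` (arguments of [simConfig()], or `ped`, `vcf`,
#' `variant_ann`, `gene_ann` paths to real inputs), `screen` (arguments of
#' [screenConfig()]), `panel` (arguments of [simulateReferencePanel()]) and
#' `array` (arguments of [simulateArray()]). Missing sections fall back to
#' the defaults.
#'
#' @param config path to a YAML configuration file, or a nested list.
#' @param outDir output directory (created if needed).
#' @param seed integer master seed; overrides the config seed.
#' @return Invisibly, a list with `report`, `ancestry`, `antigenRanking`
#'   and `manifest`.
#' @export
runAll <- function(config = list(), outDir, seed = 1L) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  scfg <- do.call(screenConfig, cfg$screen %||% list())

  # stage 1: cohort (simulated unless real file paths are given)
  ccfg <- cfg$cohort %||% list()
  if (!is.null(ccfg$vcf)) {
    for (p in c("ped", "vcf", "variant_ann", "gene_ann"))
      if (is.null(ccfg[[p]]) || !file.exists(ccfg[[p]]))
        stop("missing input file for cohort stage: ", p)
    ped <- readPedigree(ccfg$ped)
    vc <- readVariantCalls(ccfg$vcf, ped)
    vc <- applyCallQualityFilter(vc)
    vc <- joinAnnotations(vc, ccfg$variant_ann, ccfg$gene_ann)
    truth <- NULL
  } else {
    ccfg$seed <- seed
    sim <- simulateCohort(do.call(simConfig, ccfg))
    vc <- applyCallQualityFilter(sim$cohort)
    vc <- suppressWarnings(
      joinAnnotations(vc, sim$variantTable, sim$geneTable))
    truth <- sim$truth
    writeCohort(sim, file.path(outDir, "cohort"))
  }

  # stage 2: inheritance screen
  report <- suppressWarnings(runScreen(vc, scfg))
  reportPath <- file.path(outDir, "report.tsv")
  utils::write.table(report, reportPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # stage 3: ancestry
  pcfg <- cfg$panel %||% list()
  pcfg$seed <- seed + 1L
  panel <- do.call(simulateReferencePanel, pcfg)
  pca <- fitReferencePCA(panel, nPcs = min(scfg@nPcs, 10L))
  coords <- projectSamples(panel@genotypes, pca)
  anc <- assignAncestry(coords, pca, k = scfg@knnK, nPcs = scfg@nPcs)
  anc <- cbind(sample = rownames(coords), anc,
               truth = panel@populations)
  utils::write.table(anc, file.path(outDir, "ancestry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # stage 4: antigen array
  acfg <- cfg$array %||% list()
  acfg$seed <- seed + 2L
  arr <- do.call(simulateArray, acfg)
  sc <- abScores(arr)
  grp <- SummarizedExperiment::colData(arr)$group
  ctrlGroup <- unique(grp)[1]
  ranking <- rankAntigens(sc, treated = which(grp != ctrlGroup)[
    seq_len(sum(grp == ctrlGroup))], control = which(grp == ctrlGroup))
  utils::write.table(ranking, file.path(outDir, "antigen_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  attrition <- attr(report, "attrition")
  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    seed = seed,
    config = cfg,
    attrition = as.list(attrition),
    records = list(variants_screened = unname(attrition[["input"]]),
                   candidates = nrow(report),
                   samples_assigned = nrow(anc)),
    checksums = as.list(tools::md5sum(setdiff(
      files, file.path(outDir, "manifest.json")))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = report, ancestry = anc,
                 antigenRanking = ranking, truth = truth,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
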