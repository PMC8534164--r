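## End-to-end orchestration: simulate -> filter -> drivers -> tmb ->
## signatures -> phylo -> annotate, with a reproducibility manifest.
## Stages communicate only through on-disk TSV/JSON/Newick artifacts, so
## each stage can also be run or tested in isolation.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes every stage on a simulated cohort (or on tables under
#' \code{inputDir}) and writes all artifacts plus a manifest under
#' \code{outdir}. Re-running with the same configuration and seed
#' reproduces byte-identical outputs.
#'
#' @param outdir Output directory (created if absent).
#' @param config A \linkS4class{RunConfig}; its \code{rngSeed} drives every
#'   randomized step.
#' @param simulate Generate the cohort with \code{\link{simulateCohort}}.
#' @param inputDir When not simulating: directory containing
#'   \code{variants.tsv}, \code{cnvs.tsv} (optional unless copy-number tree
#'   characters are enabled) and \code{catalog.tsv}.
#' @param lesionCounts Lesions per simulated patient.
#' @param driverList Driver list data frame; defaults to the bundled toy
#'   list.
#' @param pathwayMap Pathway map data frame; defaults to the bundled toy
#'   map.
#' @param actionability Actionability data frame; defaults to the bundled
#'   synthetic table.
#' @return The manifest, invisibly (also written to
#'   \code{outdir/manifest.json}).
#' @export
runAll <- function(outdir, config = runConfig(), simulate = TRUE,
                   inputDir = NULL, lesionCounts = c(5L, 2L, 3L, 6L),
                   driverList = NULL, pathwayMap = NULL,
                   actionability = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config@rngSeed
  if (is.null(driverList))
    driverList <- readDriverList(system.file("extdata", "driver_genes.tsv",
                                             package = "oncophylo"))
  if (is.null(pathwayMap))
    pathwayMap <- readPathwayMap(system.file("extdata", "pathway_map.tsv",
                                             package = "oncophylo"))
  if (is.null(actionability))
    actionability <- readActionabilityTable(
      system.file("extdata", "actionability_synthetic.tsv",
                  package = "oncophylo"))

  counts <- list()

  ## stage: simulate / load -------------------------------------------------
  if (simulate) {
    cohort <- simulateCohort(lesionCounts = lesionCounts, seed = seed,
                             driverGenes = driverList)
    catalog <- cohort$catalog
    variants <- do.call(rbind, lapply(cohort$patients, `[[`, "variants"))
    cnvs <- do.call(rbind, lapply(cohort$patients, `[[`, "cnvs"))
    rownames(variants) <- rownames(cnvs) <- NULL
    inDir <- file.path(outdir, "input")
    dir.create(inDir, showWarnings = FALSE)
    writeVariantTable(variants, file.path(inDir, "variants.tsv"))
    writeCnvTable(cnvs, file.path(inDir, "cnvs.tsv"))
    writeSignatureCatalog(catalog, file.path(inDir, "catalog.tsv"))
    for (pid in names(cohort$patients))
      writeSimTruth(cohort$patients[[pid]]$truth,
                    file.path(inDir, paste0("truth_", pid, ".json")))
  } else {
    if (is.null(inputDir)) stop("inputDir is required when simulate=FALSE")
    variants <- readVariantTable(file.path(inputDir, "variants.tsv"))
    cnvPath <- file.path(inputDir, "cnvs.tsv")
    if (file.exists(cnvPath)) {
      cnvs <- readCnvTable(cnvPath)
    } else if (config@phyloUseCnv) {
      stop("stage phylo: cnvs.tsv is missing but copy-number tree ",
           "characters are enabled; disable phyloUseCnv or supply the ",
           "table")
    } else {
      cnvs <- NULL
    }
    catalog <- readSignatureCatalog(file.path(inputDir, "catalog.tsv"))
  }
  counts$input_variants <- nrow(variants)
  counts$input_cnvs <- if (is.null(cnvs)) 0L else nrow(cnvs)

  ## stage: filter -----------------------------------------------------------
  report <- filterVariants(variants, config)
  kept <- keptVariants(report)
  .writeTsv(kept, file.path(outdir, "filtered_variants.tsv"))
  .writeTsv(removedVariants(report),
            file.path(outdir, "removed_variants.tsv"))
  jsonlite::write_json(as.list(filterTallies(report)),
                       file.path(outdir, "filter_tallies.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  counts$filtered_kept <- nrow(kept)

  cnvKept <- NULL
  if (!is.null(cnvs)) {
    cnvFiltered <- filterCnvs(cnvs)
    cnvKept <- cnvFiltered$kept
    .writeTsv(cnvKept, file.path(outdir, "filtered_cnvs.tsv"))
    counts$cnvs_kept <- nrow(cnvKept)
  }

  ## stage: drivers ----------------------------------------------------------
  drivers <- classifyDriver(kept, driverList)
  .writeTsv(drivers, file.path(outdir, "driver_calls.tsv"))
  counts$pathogenic_drivers <- sum(drivers$pathogenic)

  ## stage: tmb --------------------------------------------------------------
  tmb <- do.call(rbind, lapply(split(kept, kept$sample_id), function(d)
    data.frame(patient_id = d$patient_id[1], sample_id = d$sample_id[1],
               n_mutations = nrow(d),
               tmb = computeTmb(d, config@exomeMb, config@tmbNonsynOnly),
               stringsAsFactors = FALSE)))
  tmb <- tmb[order(tmb$patient_id, tmb$sample_id, method = "radix"), ,
             drop = FALSE]
  .writeTsv(tmb, file.path(outdir, "tmb.tsv"))
  counts$samples <- nrow(tmb)

  ## stage: signatures -------------------------------------------------------
  sampleIds <- sort(unique(kept$sample_id), method = "radix")
  exposures <- lapply(sampleIds, function(s) {
    sp <- countContexts(kept[kept$sample_id == s, , drop = FALSE],
                          sampleId = s)
    refitExposures(sp, catalog, cutoff = config@signatureWeightCutoff)
  })
  W <- exposureMatrix(exposures)
  expOut <- data.frame(sample_id = rownames(W), W, check.names = FALSE)
  .writeTsv(expOut, file.path(outdir, "exposures.tsv"))
  k <- min(config@clusterK, nrow(W))
  cl <- clusterExposures(exposures, linkage = config@clusterLinkage, k = k)
  groups <- sharedSignatureGroups(exposures, cl$labels,
                                  presenceCutoff =
                                    config@signatureWeightCutoff)
  .writeTsv(data.frame(sample_id = names(cl$labels),
                       cluster = unname(cl$labels),
                       shared_group = unname(groups[names(cl$labels)]),
                       stringsAsFactors = FALSE),
            file.path(outdir, "signature_groups.tsv"))
  jsonlite::write_json(dendrogramToList(cl$hclust),
                       file.path(outdir, "dendrogram.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  counts$signatures_detected <- sum(colSums(W) > 0)

  ## stage: phylo ------------------------------------------------------------
  treeDir <- file.path(outdir, "trees")
  dir.create(treeDir, showWarnings = FALSE)
  partRows <- list()
  pids <- sort(unique(kept$patient_id), method = "radix")
  for (i in seq_along(pids)) {
    pid <- pids[i]
    pv <- kept[kept$patient_id == pid, , drop = FALSE]
    pc <- if (!is.null(cnvKept) && config@phyloUseCnv)
      cnvKept[cnvKept$patient_id == pid, , drop = FALSE] else NULL
    presence <- presenceSets(pv, pc)
    if (length(presence) < 2L) next
    part <- classifyClonality(presence)
    partRows[[pid]] <- data.frame(
      patient_id = pid, event = names(part$labels),
      label = unname(part$labels), stringsAsFactors = FALSE)
    mat <- buildBinaryMatrix(presence, patientId = pid)
    .writeTsv(data.frame(taxon = rownames(matrixEvents(mat)),
                         matrixEvents(mat), check.names = FALSE),
              file.path(treeDir, paste0(pid, "_matrix.tsv")))
    boot <- bootstrapSupport(mat, reps = config@bootstrapReps,
                             seed = seed + i)
    writeNewick(boot$tree, file.path(treeDir, paste0(pid, ".nwk")))
  }
  if (length(partRows))
    .writeTsv(do.call(rbind, partRows),
              file.path(outdir, "clonality_partition.tsv"))
  counts$patients_with_tree <- length(partRows)

  ## stage: annotate ---------------------------------------------------------
  drvGenes <- unique(c(drivers$gene[drivers$pathogenic],
                       if (!is.null(cnvKept)) cnvKept$gene))
  if (length(drvGenes)) {
    .writeTsv(pathwayFractions(drvGenes, pathwayMap),
              file.path(outdir, "pathway_fractions.tsv"))
  }
  targets <- matchActionable(drivers, cnvKept, actionability,
                             dedup = "patient")
  .writeTsv(targets, file.path(outdir, "actionable_targets.tsv"))
  counts$actionable_targets <- nrow(targets)

  ## manifest ----------------------------------------------------------------
  files <- sort(method = "radix",
                setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  digests <- as.list(tools::md5sum(file.path(outdir, files)))
  names(digests) <- files
  manifest <- list(
    tool = "oncophylo",
    version = as.character(utils::packageVersion("oncophylo")),
    seed = seed,
    config = {
      s <- slotNames(config)
      stats::setNames(lapply(s, function(x) slot(config, x)), s)
    },
    stage_counts = counts,
    files = digests)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
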