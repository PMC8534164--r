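## Synthetic multi-lesion cohort generator with known clonal ground truth.
##
## The generator emulates the study design the pipeline targets: 4 patients
## carrying 2-6 lesions each, every lesion sampling a single clone of a
## rooted clone tree whose root carries the truncal mutations. SNV contexts
## are drawn from per-clone signature mixtures over a toy catalog, VAFs from
## Beta(20, 20) scaled by 0.5 tumor purity, and read depths from
## Poisson(100) with a binomial strand split. Indels arise at 5% of events
## and carry no context.

.BASES <- c("A", "C", "G", "T")

#' Generate a toy signature catalog
#'
#' Draws random sparse context distributions and redraws until every
#' signature pair has cosine similarity at most \code{maxCosine}, so
#' refitting against the catalog is identifiable.
#'
#' @param nSignatures Number of signatures (2 to 30).
#' @param seed Integer seed.
#' @param support Number of nonzero contexts per signature.
#' @param maxCosine Maximum allowed pairwise cosine similarity.
#' @param retries Redraw attempts before giving up.
#' @return A \linkS4class{SignatureCatalog}.
#' @export
#' @examples
#' makeToyCatalog(5, seed = 1)
makeToyCatalog <- function(nSignatures = 5L, seed = 1L, support = 10L,
                           maxCosine = 0.7, retries = 100L) {
  if (nSignatures < 2L || nSignatures > 30L)
    stop("config error: nSignatures must lie in [2, 30]")
  set.seed(seed)
  labs <- contextLabels96()
  for (try in seq_len(retries)) {
    m <- matrix(0, nSignatures, 96L,
                dimnames = list(sprintf("TS%02d", seq_len(nSignatures)),
                                labs))
    for (i in seq_len(nSignatures)) {
      idx <- sample.int(96L, support)
      w <- stats::rgamma(support, shape = 1)
      m[i, idx] <- w / sum(w)
    }
    cos <- m / sqrt(rowSums(m^2))
    cm <- cos %*% t(cos)
    diag(cm) <- 0
    if (max(cm) <= maxCosine) return(signatureCatalog(m))
  }
  stop("could not draw a catalog with pairwise cosine <= ", maxCosine,
       " in ", retries, " attempts")
}

#' Simulate a multinomial context spectrum from known exposures
#'
#' @param catalog A \linkS4class{SignatureCatalog}.
#' @param weights Named or positional non-negative signature weights; they
#'   are normalized to a mixture.
#' @param n Number of substitutions to draw.
#' @param sampleId Sample identifier.
#' @return A \linkS4class{ContextSpectrum}.
#' @export
simulateContextSpectrum <- function(catalog, weights, n = 500L,
                                    sampleId = "sim") {
  p <- as.numeric(weights %*% signatureProbs(catalog)[seq_along(weights), ,
                                                      drop = FALSE])
  p <- p / sum(p)
  counts <- as.numeric(stats::rmultinom(1L, n, p))
  names(counts) <- contextLabels96()
  new("ContextSpectrum", sampleId = sampleId, counts = counts,
      skipped = 0L)
}

## Draw a batch of clone events: context classes from the clone's mixture,
## each SNV reported on the forward or reverse strand with equal
## probability; `indelFrac` of events become context-free indels.
.drawCloneEvents <- function(n, contextDist, indelFrac) {
  labs <- contextLabels96()
  isIndel <- stats::runif(n) < indelFrac
  chrom <- paste0("chr", sample.int(22L, n, replace = TRUE))
  pos <- sample.int(100000000L, n, replace = TRUE)
  gene <- sprintf("G%05d", sample.int(20000L, n, replace = TRUE))
  bins <- sample(labs, n, replace = TRUE, prob = contextDist)
  five <- substr(bins, 1L, 1L)
  ref <- substr(bins, 3L, 3L)
  alt <- substr(bins, 5L, 5L)
  three <- substr(bins, 7L, 7L)
  ctx <- paste0(five, ref, three)
  flip <- stats::runif(n) < 0.5
  if (any(flip)) {
    newRef <- unname(.COMP[ref[flip]])
    alt[flip] <- unname(.COMP[alt[flip]])
    ctx[flip] <- paste0(unname(.COMP[three[flip]]), newRef,
                        unname(.COMP[five[flip]]))
    ref[flip] <- newRef
  }
  cons <- sample(c("synonymous", "nonsynonymous"), n, replace = TRUE,
                 prob = c(0.3, 0.7))
  ## indels: short deletions without context
  if (any(isIndel)) {
    iref <- paste0(sample(.BASES, sum(isIndel), replace = TRUE),
                   sample(.BASES, sum(isIndel), replace = TRUE))
    ref[isIndel] <- iref
    alt[isIndel] <- substr(iref, 1L, 1L)
    ctx[isIndel] <- NA_character_
    cons[isIndel] <- "indel"
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = cons, context = ctx,
             id = paste(chrom, pos, ref, alt, sep = ":"),
             driver = FALSE, stringsAsFactors = FALSE)
}

#' Simulate one multi-lesion patient
#'
#' Builds a rooted clone tree (a truncal root clone plus one clone per
#' lesion; with \code{lymphNodeEarly} the lymph-node and tumor lineages
#' diverge immediately below the root through two ancestral clones, so
#' lymph-node lesions share a non-truncal branch and share none of the
#' tumor lineage's non-truncal mutations). Each clone carries
#' \code{mutationsPerClone} private events; each lesion's mutation set is
#' the union over its clone lineage. Deterministic under \code{seed}.
#'
#' @param nLesions Number of tumor lesions (>= 2).
#' @param lymphNodeEarly Plant an early-diverging lymph-node lineage.
#' @param nLymphNodes Number of lymph-node lesions when
#'   \code{lymphNodeEarly} (2 to \code{nLesions - 1}).
#' @param mutationsPerClone Private events per clone (>= 1).
#' @param catalog Toy \linkS4class{SignatureCatalog}; a default 5-signature
#'   catalog is drawn from the seed when omitted.
#' @param mixtures Optional clones x signatures mixture matrix; random
#'   sparse mixtures of at most \code{maxActiveSignatures} signatures are
#'   drawn when omitted.
#' @param maxActiveSignatures Maximum active signatures per clone.
#' @param seed Integer seed.
#' @param depth Mean sequencing depth (Poisson).
#' @param purity Tumor purity scaling the Beta(20, 20) VAF draw.
#' @param indelFrac Per-event indel probability.
#' @param driverGenes Optional driver list data frame (gene, role); plants
#'   driver SNVs and directional CNV events on clones.
#' @param cnvsPerClone Directional copy-number events planted per clone.
#' @param nClones Override the clone count (1 to 6) for the non-lymph-node
#'   layout; lesions cycle over clones. \code{nClones = 1} yields a purely
#'   clonal patient (every event truncal). Default: a truncal root plus one
#'   clone per lesion with random attachment.
#' @param patientId Patient identifier.
#' @return List with \code{variants} (data frame), \code{cnvs} (data
#'   frame) and \code{truth} (a \linkS4class{SimTruth}).
#' @export
#' @examples
#' sim <- simulatePatient(nLesions = 3, seed = 42)
#' head(sim$variants)
simulatePatient <- function(nLesions, lymphNodeEarly = FALSE,
                            nLymphNodes = 2L, mutationsPerClone = 10L,
                            catalog = NULL, mixtures = NULL,
                            maxActiveSignatures = 3L, seed = 1L,
                            depth = 100, purity = 0.5, indelFrac = 0.05,
                            driverGenes = NULL, cnvsPerClone = 1L,
                            nClones = NULL, patientId = "P1") {
  if (nLesions < 2L)
    stop("config error: nLesions must be >= 2")
  if (mutationsPerClone < 1L)
    stop("config error: mutationsPerClone must be >= 1")
  if (lymphNodeEarly &&
      (nLymphNodes < 2L || nLymphNodes > nLesions - 1L))
    stop("config error: lymphNodeEarly requires 2 <= nLymphNodes <= ",
         "nLesions - 1")
  if (is.null(catalog)) catalog <- makeToyCatalog(5L, seed = seed)
  set.seed(seed)
  nSig <- nrow(signatureProbs(catalog))

  ## clone tree ------------------------------------------------------------
  if (lymphNodeEarly) {
    nTumor <- nLesions - nLymphNodes
    cloneParent <- c(0L, 1L, 1L,
                     rep(2L, nLymphNodes), rep(3L, nTumor))
    lesionIds <- paste0(patientId, "_",
                        c(sprintf("LN%d", seq_len(nLymphNodes)),
                          sprintf("TU%d", seq_len(nTumor))))
    lesionClone <- stats::setNames(3L + seq_len(nLesions), lesionIds)
  } else if (!is.null(nClones)) {
    if (nClones < 1L || nClones > 6L)
      stop("config error: nClones must lie in [1, 6]")
    cloneParent <- if (nClones == 1L) 0L
      else c(0L, vapply(2:nClones, function(i)
        sample.int(i - 1L, 1L), integer(1)))
    lesionIds <- paste0(patientId, "_TU", seq_len(nLesions))
    lesionClone <- stats::setNames(
      ((seq_len(nLesions) - 1L) %% nClones) + 1L, lesionIds)
  } else {
    cloneParent <- c(0L, vapply(seq_len(nLesions), function(i)
      sample.int(i, 1L), integer(1)))
    lesionIds <- paste0(patientId, "_TU", seq_len(nLesions))
    lesionClone <- stats::setNames(1L + seq_len(nLesions), lesionIds)
  }
  nClones <- length(cloneParent)
  lineage <- function(cl) {
    out <- cl
    while (cloneParent[cl] != 0L) {
      cl <- cloneParent[cl]
      out <- c(out, cl)
    }
    out
  }

  ## clone signature mixtures ----------------------------------------------
  if (is.null(mixtures)) {
    mixtures <- matrix(0, nClones, nSig,
                       dimnames = list(NULL, signatureIds(catalog)))
    for (c in seq_len(nClones)) {
      k <- sample.int(min(maxActiveSignatures, nSig), 1L)
      sigs <- sample.int(nSig, k)
      w <- stats::rgamma(k, shape = 2)
      mixtures[c, sigs] <- w / sum(w)
    }
  }

  ## per-clone events -------------------------------------------------------
  allIds <- character(0)
  usedCnv <- character(0)
  cloneEvents <- vector("list", nClones)
  cloneSnv <- vector("list", nClones)
  cloneCnvRows <- vector("list", nClones)
  cloneSnvCount <- integer(nClones)
  drivers <- if (!is.null(driverGenes)) driverGenes else NULL

  for (c in seq_len(nClones)) {
    ctxDist <- as.numeric(mixtures[c, ] %*% signatureProbs(catalog))
    ev <- .drawCloneEvents(mutationsPerClone, ctxDist, indelFrac)
    repeat {  # redraw the (rare) event-id collisions
      dup <- ev$id %in% allIds | duplicated(ev$id)
      if (!any(dup)) break
      ev[dup, ] <- .drawCloneEvents(sum(dup), ctxDist, indelFrac)
    }
    ## plant an occasional driver SNV (root always; others with prob 0.3)
    if (!is.null(drivers) && (c == 1L || stats::runif(1) < 0.3)) {
      repeat {
        drv <- .drawCloneEvents(1L, ctxDist, indelFrac = 0)
        drv$gene <- sample(drivers$gene, 1L)
        if (!drv$id %in% c(allIds, ev$id)) break
      }
      drv$consequence <- "nonsynonymous"
      drv$driver <- TRUE
      ev <- rbind(ev, drv)
    }
    cloneSnv[[c]] <- ev
    allIds <- c(allIds, ev$id)
    cloneSnvCount[c] <- sum(ev$consequence != "indel")

    ## directional copy-number events
    cnvRows <- list()
    for (j in seq_len(cnvsPerClone)) {
      repeat {
        if (!is.null(drivers) && any(drivers$role != "unknown")) {
          k <- sample(which(drivers$role != "unknown"), 1L)
          gene <- drivers$gene[k]
          role <- drivers$role[k]
        } else {
          gene <- sprintf("CG%03d", sample.int(500L, 1L))
          role <- sample(c("oncogene", "tsg"), 1L)
        }
        dir <- if (role == "oncogene") "amp" else "del"
        key <- paste(gene, dir, sep = ":")
        if (!key %in% usedCnv) break
      }
      usedCnv <- c(usedCnv, key)
      cn <- if (dir == "amp") sample(3:8, 1L) else sample(0:1, 1L)
      cnvRows[[length(cnvRows) + 1L]] <-
        list(gene = gene, role = role, cn = cn, id = key)
    }
    cloneCnvRows[[c]] <- cnvRows
    cloneEvents[[c]] <- c(ev$id,
                          vapply(cnvRows, `[[`, character(1), "id"))
  }

  ## per-lesion tables -------------------------------------------------------
  vtab <- list()
  ctab <- list()
  predPool <- c("tolerated", "missing")
  for (les in lesionIds) {
    lin <- sort(lineage(lesionClone[[les]]))
    evs <- do.call(rbind, cloneSnv[lin])
    n <- nrow(evs)
    vaf <- purity * stats::rbeta(n, 20, 20)
    dp <- stats::rpois(n, depth)
    altTot <- stats::rbinom(n, dp, vaf)
    fwd <- stats::rbinom(n, altTot, 0.5)
    isDrv <- evs$driver
    vtab[[length(vtab) + 1L]] <- data.frame(
      patient_id = patientId, sample_id = les, chrom = evs$chrom,
      pos = evs$pos, ref = evs$ref, alt = evs$alt, gene = evs$gene,
      consequence = evs$consequence, context = evs$context, vaf = vaf,
      alt_reads_fwd = fwd, alt_reads_rev = altTot - fwd,
      pop_af_max = 0, common_snp = FALSE,
      clinvar = ifelse(isDrv, "pathogenic", "unknown"),
      pred_sift = ifelse(isDrv, "deleterious",
                         sample(predPool, n, replace = TRUE)),
      pred_polyphen2 = ifelse(isDrv, "deleterious",
                              sample(predPool, n, replace = TRUE)),
      pred_mutationtaster = sample(predPool, n, replace = TRUE),
      hotspot = isDrv & stats::runif(n) < 0.5,
      stringsAsFactors = FALSE)
    for (c in lin) {
      for (ev in cloneCnvRows[[c]]) {
        ctab[[length(ctab) + 1L]] <- data.frame(
          patient_id = patientId, sample_id = les, gene = ev$gene,
          copy_number = ev$cn, gene_role = ev$role,
          stringsAsFactors = FALSE)
      }
    }
    ## copy-neutral and role-less decoy rows exercising the CNV filter
    for (j in 1:2) {
      ctab[[length(ctab) + 1L]] <- data.frame(
        patient_id = patientId, sample_id = les,
        gene = sprintf("NEUT%03d", sample.int(500L, 1L)),
        copy_number = 2L,
        gene_role = sample(c("oncogene", "tsg"), 1L),
        stringsAsFactors = FALSE)
    }
    ctab[[length(ctab) + 1L]] <- data.frame(
      patient_id = patientId, sample_id = les,
      gene = sprintf("UNKN%03d", sample.int(500L, 1L)),
      copy_number = 4L, gene_role = "unknown", stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, vtab)
  variants$id <- NULL
  variants$driver <- NULL
  cnvs <- do.call(rbind, ctab)

  ## ground truth ------------------------------------------------------------
  lesionsWithClone <- function(c) {
    lesionIds[vapply(lesionIds, function(l)
      c %in% lineage(lesionClone[[l]]), logical(1))]
  }
  clonality <- character(0)
  for (c in seq_len(nClones)) {
    nl <- length(lesionsWithClone(c))
    lab <- if (nl == nLesions) "truncal"
           else if (nl == 1L) "private"
           else if (nl == 0L) NA_character_
           else "shared"
    clonality <- c(clonality,
                   stats::setNames(rep(lab, length(cloneEvents[[c]])),
                                   cloneEvents[[c]]))
  }
  clonality <- clonality[!is.na(clonality)]

  exposures <- matrix(0, nLesions, nSig,
                      dimnames = list(lesionIds, signatureIds(catalog)))
  for (les in lesionIds) {
    lin <- lineage(lesionClone[[les]])
    w <- cloneSnvCount[lin]
    exposures[les, ] <- as.numeric(w %*% mixtures[lin, , drop = FALSE]) /
      sum(w)
  }

  truth <- new("SimTruth", patientId = patientId,
               cloneParent = as.integer(cloneParent),
               cloneEvents = cloneEvents,
               cloneMixtures = mixtures,
               lesionClone = stats::setNames(as.integer(lesionClone),
                                             names(lesionClone)),
               clonality = clonality, exposures = exposures,
               decoys = data.frame())
  list(variants = validateVariantTable(variants), cnvs = cnvs,
       truth = truth)
}

#' Append filter decoys with known failure labels
#'
#' For each filter rule, appends \code{nPerRule} records violating exactly
#' that rule (population allele frequency at or above 0.001; common SNP
#' without a pathogenic ClinVar report; fewer than two alternate reads on
#' one strand; VAF below 0.05), plus \code{nPerRule} ClinVar-override
#' records (common SNP and ClinVar-pathogenic) that must survive.
#'
#' @param variants Variant data frame to append to.
#' @param nPerRule Decoys planted per rule.
#' @param seed Integer seed.
#' @return List with \code{variants} (input plus decoys) and \code{truth}
#'   (data frame keying each decoy by sample/chrom/pos/ref/alt with its
#'   \code{planted_rule} label).
#' @export
plantFilterDecoys <- function(variants, nPerRule = 5L, seed = 1L) {
  set.seed(seed)
  sampleIds <- unique(variants$sample_id)
  patientIds <- unique(variants$patient_id)
  rules <- c("fails_pop_af", "fails_common_snp", "fails_strand",
             "fails_vaf", "override_survivor")
  rows <- list()
  truth <- list()
  counter <- 0L
  for (rule in rules) {
    for (i in seq_len(nPerRule)) {
      counter <- counter + 1L
      ref <- sample(c("C", "T"), 1L)
      alt <- sample(setdiff(.BASES, ref), 1L)
      ctx <- paste0(sample(.BASES, 1L), ref, sample(.BASES, 1L))
      row <- data.frame(
        patient_id = patientIds[1L],
        sample_id = sampleIds[1L + (counter - 1L) %% length(sampleIds)],
        chrom = "chrD", pos = 9000000L + counter, ref = ref, alt = alt,
        gene = sprintf("DECOY%03d", counter),
        consequence = "nonsynonymous", context = ctx, vaf = 0.3,
        alt_reads_fwd = 10L, alt_reads_rev = 10L, pop_af_max = 0,
        common_snp = FALSE, clinvar = "unknown",
        pred_sift = "tolerated", pred_polyphen2 = "tolerated",
        pred_mutationtaster = "missing", hotspot = FALSE,
        stringsAsFactors = FALSE)
      if (rule == "fails_pop_af") {
        row$pop_af_max <- stats::runif(1L, 0.001, 0.05)
      } else if (rule == "fails_common_snp") {
        row$common_snp <- TRUE
        row$clinvar <- sample(c("unknown", "benign"), 1L)
      } else if (rule == "fails_strand") {
        if (i %% 2L == 0L) {
          row$alt_reads_fwd <- 1L; row$alt_reads_rev <- 9L
        } else {
          row$alt_reads_fwd <- 9L; row$alt_reads_rev <- 1L
        }
      } else if (rule == "fails_vaf") {
        row$vaf <- stats::runif(1L, 0.005, 0.049)
      } else {  # override_survivor
        row$common_snp <- TRUE
        row$clinvar <- "pathogenic"
      }
      rows[[counter]] <- row
      truth[[counter]] <- data.frame(
        sample_id = row$sample_id, chrom = row$chrom, pos = row$pos,
        ref = row$ref, alt = row$alt, planted_rule = rule,
        stringsAsFactors = FALSE)
    }
  }
  list(variants = rbind(variants, do.call(rbind, rows)),
       truth = do.call(rbind, truth))
}

#' Simulate a multi-patient cohort
#'
#' Default design mirrors a 4-patient cohort with 5, 2, 3 and 6 lesions
#' (16 lesions in total); patients with at least 4 lesions carry an
#' early-diverging lymph-node lineage.
#'
#' @param lesionCounts Integer vector of lesions per patient.
#' @param seed Integer seed; per-patient seeds are derived from it.
#' @param catalog Shared toy catalog; drawn from the seed when omitted.
#' @param driverGenes Optional driver list data frame.
#' @param ... Further arguments passed to \code{\link{simulatePatient}}.
#' @return Named list of per-patient results (see
#'   \code{\link{simulatePatient}}), plus attribute-free element
#'   \code{catalog}.
#' @export
simulateCohort <- function(lesionCounts = c(5L, 2L, 3L, 6L), seed = 1L,
                           catalog = NULL, driverGenes = NULL, ...) {
  if (is.null(catalog)) catalog <- makeToyCatalog(5L, seed = seed)
  patients <- list()
  for (i in seq_along(lesionCounts)) {
    pid <- sprintf("SIM%02d", i)
    patients[[pid]] <- simulatePatient(
      nLesions = lesionCounts[i],
      lymphNodeEarly = lesionCounts[i] >= 4L,
      catalog = catalog, seed = (seed %% 21000000L) * 100L + i,
      driverGenes = driverGenes, patientId = pid, ...)
  }
  list(patients = patients, catalog = catalog)
}

#' Serialize simulation ground truth to JSON
#'
#' @param truth A \linkS4class{SimTruth}.
#' @param path Output path.
#' @export
writeSimTruth <- function(truth, path) {
  x <- list(patient_id = truth@patientId,
            clone_parent = truth@cloneParent,
            clone_events = truth@cloneEvents,
            lesion_clone = as.list(truth@lesionClone),
            clonality = as.list(truth@clonality),
            exposures = apply(truth@exposures, 1L, as.list,
                              simplify = FALSE))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
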