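#' @import methods
NULL

setOldClass("phylo")
setOldClass("hclust")

## ---------------------------------------------------------------------------
## RunConfig
## ---------------------------------------------------------------------------

#' Run configuration
#'
#' Holds every tunable threshold of the pipeline. Defaults follow the
#' published analysis conventions: population allele-frequency cutoff 0.001,
#' variant allele fraction cutoff 0.05, at least two alternate reads on each
#' strand, a 37 Mb coding exome for mutational-burden normalization, a 0.06
#' signature-weight reporting cutoff, and 100 bootstrap replicates.
#'
#' @slot popAfThreshold Maximum population allele frequency for somatic calls.
#' @slot vafThreshold Minimum variant allele fraction.
#' @slot minStrandReads Minimum alternate reads required on each strand.
#' @slot exomeMb Size in megabases of the assayed coding territory.
#' @slot signatureWeightCutoff Minimum reported signature weight.
#' @slot bootstrapReps Number of bootstrap replicates.
#' @slot rngSeed Integer seed driving all randomized steps.
#' @slot clusterLinkage Agglomeration method for exposure clustering.
#' @slot clusterK Number of exposure clusters to cut.
#' @slot tmbNonsynOnly Count only nonsynonymous events in the burden numerator.
#' @slot phyloUseCnv Include directional copy-number events as tree characters.
#' @export
setClass("RunConfig", representation(
  popAfThreshold = "numeric",
  vafThreshold = "numeric",
  minStrandReads = "integer",
  exomeMb = "numeric",
  signatureWeightCutoff = "numeric",
  bootstrapReps = "integer",
  rngSeed = "integer",
  clusterLinkage = "character",
  clusterK = "integer",
  tmbNonsynOnly = "logical",
  phyloUseCnv = "logical"
))

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (object@popAfThreshold < 0 || object@popAfThreshold > 1)
    msg <- c(msg, "popAfThreshold must lie in [0, 1]")
  if (object@vafThreshold < 0 || object@vafThreshold > 1)
    msg <- c(msg, "vafThreshold must lie in [0, 1]")
  if (object@minStrandReads < 0)
    msg <- c(msg, "minStrandReads must be >= 0")
  if (object@exomeMb <= 0)
    msg <- c(msg, "exomeMb must be positive")
  if (object@signatureWeightCutoff < 0 || object@signatureWeightCutoff > 1)
    msg <- c(msg, "signatureWeightCutoff must lie in [0, 1]")
  if (object@bootstrapReps < 1)
    msg <- c(msg, "bootstrapReps must be >= 1")
  if (!object@clusterLinkage %in%
      c("average", "complete", "single", "ward.D2"))
    msg <- c(msg, "unsupported clusterLinkage")
  if (object@clusterK < 1) msg <- c(msg, "clusterK must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a run configuration
#'
#' @param popAfThreshold,vafThreshold,minStrandReads,exomeMb Filtering and
#'   burden parameters; see \linkS4class{RunConfig}.
#' @param signatureWeightCutoff,clusterLinkage,clusterK Signature parameters.
#' @param bootstrapReps,rngSeed Phylogeny parameters.
#' @param tmbNonsynOnly,phyloUseCnv Behaviour switches.
#' @return A validated \linkS4class{RunConfig}.
#' @export
#' @examples
#' runConfig(rngSeed = 7L)
runConfig <- function(popAfThreshold = 0.001, vafThreshold = 0.05,
                      minStrandReads = 2L, exomeMb = 37,
                      signatureWeightCutoff = 0.06, bootstrapReps = 100L,
                      rngSeed = 1L, clusterLinkage = "average",
                      clusterK = 3L, tmbNonsynOnly = FALSE,
                      phyloUseCnv = TRUE) {
  new("RunConfig",
      popAfThreshold = popAfThreshold, vafThreshold = vafThreshold,
      minStrandReads = as.integer(minStrandReads), exomeMb = exomeMb,
      signatureWeightCutoff = signatureWeightCutoff,
      bootstrapReps = as.integer(bootstrapReps),
      rngSeed = as.integer(rngSeed), clusterLinkage = clusterLinkage,
      clusterK = as.integer(clusterK), tmbNonsynOnly = tmbNonsynOnly,
      phyloUseCnv = phyloUseCnv)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat("  popAf <", object@popAfThreshold,
      " | vaf >=", object@vafThreshold,
      " | strand reads >=", object@minStrandReads, "\n")
  cat("  exome", object@exomeMb, "Mb | signature cutoff",
      object@signatureWeightCutoff, "| bootstrap", object@bootstrapReps,
      "reps | seed", object@rngSeed, "\n")
})

## ---------------------------------------------------------------------------
## SignatureCatalog
## ---------------------------------------------------------------------------

#' Reference catalog of mutational signatures
#'
#' A matrix of signatures by the 96 pyrimidine-centric trinucleotide classes.
#' Each row is a probability distribution over contexts.
#'
#' @slot probs Numeric matrix, signatures x 96; rownames are signature ids,
#'   colnames the canonical context labels.
#' @export
setClass("SignatureCatalog", representation(probs = "matrix"))

setValidity("SignatureCatalog", function(object) {
  p <- object@probs
  msg <- character(0)
  if (ncol(p) != 96L)
    msg <- c(msg, sprintf("catalog must have 96 context columns, found %d",
                          ncol(p)))
  else if (!identical(colnames(p), contextLabels96()))
    msg <- c(msg, "context columns must follow the canonical 96-class order")
  if (is.null(rownames(p)) || anyDuplicated(rownames(p)))
    msg <- c(msg, sprintf("signature ids must be unique; duplicated: %s",
                          paste(unique(rownames(p)[duplicated(rownames(p))]),
                                collapse = ", ")))
  if (any(p < 0)) msg <- c(msg, "signature probabilities must be >= 0")
  bad <- which(abs(rowSums(p) - 1) > 1e-8)
  if (length(bad))
    msg <- c(msg, sprintf("signature rows must sum to 1: %s",
                          paste(rownames(p)[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn SignatureCatalog-class Construct a catalog from a matrix with
#'   signature rownames and canonical context colnames.
#' @param probs Numeric signatures x 96 matrix.
#' @export
signatureCatalog <- function(probs) {
  new("SignatureCatalog", probs = probs)
}

#' @describeIn SignatureCatalog-class Signature identifiers.
#' @param object A \code{SignatureCatalog}.
#' @export
signatureIds <- function(object) rownames(object@probs)

#' @describeIn SignatureCatalog-class The signatures x 96 probability matrix.
#' @export
signatureProbs <- function(object) object@probs

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog:", nrow(object@probs), "signatures x 96 contexts\n")
  cat("  ids:", paste(utils::head(signatureIds(object), 8), collapse = ", "),
      if (nrow(object@probs) > 8) "..." else "", "\n")
})

## ---------------------------------------------------------------------------
## ContextSpectrum
## ---------------------------------------------------------------------------

#' Per-sample 96-context mutation spectrum
#'
#' @slot sampleId Sample identifier.
#' @slot counts Named numeric vector of 96 non-negative counts in canonical
#'   order.
#' @slot skipped Number of input records skipped (indels carry no context).
#' @export
setClass("ContextSpectrum", representation(
  sampleId = "character", counts = "numeric", skipped = "integer"))

setValidity("ContextSpectrum", function(object) {
  msg <- character(0)
  if (length(object@counts) != 96L ||
      !identical(names(object@counts), contextLabels96()))
    msg <- c(msg, "counts must be a named 96-vector in canonical order")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ContextSpectrum-class Total number of binned substitutions.
#' @param object A \code{ContextSpectrum}.
#' @export
spectrumTotal <- function(object) sum(object@counts)

#' @describeIn ContextSpectrum-class The named 96-vector of counts.
#' @export
spectrumCounts <- function(object) object@counts

setMethod("show", "ContextSpectrum", function(object) {
  cat("ContextSpectrum for", object@sampleId, "-", spectrumTotal(object),
      "substitutions binned,", object@skipped, "records skipped\n")
})

## ---------------------------------------------------------------------------
## ExposureVector
## ---------------------------------------------------------------------------

#' Fitted signature exposures for one sample
#'
#' Non-negative weights per catalog signature, summing to at most 1; the
#' shortfall from 1 is reported as the unexplained residual.
#'
#' @slot sampleId Sample identifier.
#' @slot weights Named non-negative weights, one per catalog signature.
#' @slot residual \code{1 - sum(weights)}.
#' @export
setClass("ExposureVector", representation(
  sampleId = "character", weights = "numeric", residual = "numeric"))

setValidity("ExposureVector", function(object) {
  msg <- character(0)
  if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
  if (sum(object@weights) > 1 + 1e-8)
    msg <- c(msg, "weights must sum to <= 1")
  if (abs(object@residual - (1 - sum(object@weights))) > 1e-6)
    msg <- c(msg, "residual must equal 1 - sum(weights)")
  if (length(msg)) msg else TRUE
})

#' @describeIn ExposureVector-class Named weight vector.
#' @param object An \code{ExposureVector}.
#' @export
exposureWeights <- function(object) object@weights

setMethod("show", "ExposureVector", function(object) {
  w <- object@weights[object@weights > 0]
  cat("ExposureVector for", object@sampleId, "-",
      paste(sprintf("%s=%.3f", names(w), w), collapse = ", "),
      sprintf("(residual %.3f)\n", object@residual))
})

## ---------------------------------------------------------------------------
## MutationMatrix
## ---------------------------------------------------------------------------

#' Per-patient binary mutation matrix
#'
#' Taxa (tumor samples plus one all-zero normal) by mutation events,
#' coded 0/1 for absence/presence.
#'
#' @slot patientId Patient identifier.
#' @slot mat Integer 0/1 matrix; rownames are taxa (normal last), colnames
#'   event ids (\code{chrom:pos:ref:alt} for SNV/indel, \code{gene:amp} or
#'   \code{gene:del} for copy-number events).
#' @slot normalTaxon Label of the all-zero normal taxon.
#' @export
setClass("MutationMatrix", representation(
  patientId = "character", mat = "matrix", normalTaxon = "character"))

setValidity("MutationMatrix", function(object) {
  m <- object@mat
  msg <- character(0)
  if (!all(m %in% c(0L, 1L))) msg <- c(msg, "entries must be 0 or 1")
  if (!(object@normalTaxon %in% rownames(m)))
    msg <- c(msg, "normal taxon must be a row of the matrix")
  else if (any(m[object@normalTaxon, ] != 0))
    msg <- c(msg, "normal taxon row must be all zeros")
  if (ncol(m) > 0 && any(colSums(m) == 0))
    msg <- c(msg, "all-zero event columns are not allowed")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "event ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn MutationMatrix-class Taxa labels (normal last).
#' @param object A \code{MutationMatrix}.
#' @export
matrixTaxa <- function(object) rownames(object@mat)

#' @describeIn MutationMatrix-class The binary taxa x events matrix.
#' @export
matrixEvents <- function(object) object@mat

setMethod("show", "MutationMatrix", function(object) {
  cat("MutationMatrix for", object@patientId, "-", nrow(object@mat),
      "taxa x", ncol(object@mat), "events (normal:", object@normalTaxon,
      ")\n")
})

## ---------------------------------------------------------------------------
## ParsimonyTree
## ---------------------------------------------------------------------------

#' Rooted maximum-parsimony tree
#'
#' An \code{ape} phylo rooted on the pendant branch of the normal taxon.
#' Branch lengths are the number of mutation events assigned to each branch,
#' so lengths sum to the parsimony score. Internal node labels, when present,
#' carry integer bootstrap supports in [0, 100].
#'
#' @slot tree An \code{ape::phylo} object.
#' @slot score Integer parsimony score.
#' @export
setClass("ParsimonyTree", representation(tree = "phylo", score = "integer"))

setValidity("ParsimonyTree", function(object) {
  msg <- character(0)
  if (object@score < 0) msg <- c(msg, "parsimony score must be >= 0")
  len <- object@tree$edge.length
  if (!is.null(len)) {
    if (any(len < 0)) msg <- c(msg, "branch lengths must be >= 0")
    if (abs(sum(len) - object@score) > 1e-9)
      msg <- c(msg, "branch lengths must sum to the parsimony score")
  }
  lab <- object@tree$node.label
  if (!is.null(lab)) {
    sup <- suppressWarnings(as.numeric(lab[lab != ""]))
    if (any(!is.na(sup) & (sup < 0 | sup > 100)))
      msg <- c(msg, "supports must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ParsimonyTree-class The underlying \code{ape::phylo}.
#' @param object A \code{ParsimonyTree}.
#' @export
treePhylo <- function(object) object@tree

#' @describeIn ParsimonyTree-class Integer parsimony score.
#' @export
treeScore <- function(object) object@score

setMethod("show", "ParsimonyTree", function(object) {
  cat("ParsimonyTree:", length(object@tree$tip.label), "taxa, score",
      object@score, "\n  ", newickString(object), "\n")
})

## ---------------------------------------------------------------------------
## FilterReport
## ---------------------------------------------------------------------------

#' Result of the somatic variant filter cascade
#'
#' @slot kept Data frame of records passing every rule.
#' @slot removed Data frame of failing records with a \code{reasons} column
#'   (semicolon-separated failed rules).
#' @slot tallies Named integer vector: per-rule removal counts plus
#'   \code{kept} and \code{total}.
#' @export
setClass("FilterReport", representation(
  kept = "data.frame", removed = "data.frame", tallies = "integer"))

setValidity("FilterReport", function(object) {
  msg <- character(0)
  if (nrow(object@kept) + nrow(object@removed) !=
      object@tallies[["total"]])
    msg <- c(msg, "kept + removed must equal the input count")
  if (nrow(object@removed) > 0 &&
      any(!nzchar(object@removed$reasons)))
    msg <- c(msg, "every removed record must list at least one failed rule")
  if (length(msg)) msg else TRUE
})

#' @describeIn FilterReport-class Records passing all rules.
#' @param object A \code{FilterReport}.
#' @export
keptVariants <- function(object) object@kept

#' @describeIn FilterReport-class Failing records with reasons.
#' @export
removedVariants <- function(object) object@removed

#' @describeIn FilterReport-class Per-rule removal tallies.
#' @export
filterTallies <- function(object) object@tallies

setMethod("show", "FilterReport", function(object) {
  t <- object@tallies
  cat("FilterReport:", t[["kept"]], "of", t[["total"]], "records kept\n")
  rules <- setdiff(names(t), c("kept", "total"))
  cat("  removals by rule:",
      paste(sprintf("%s=%d", rules, t[rules]), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## SimTruth
## ---------------------------------------------------------------------------

#' Ground truth of a simulated multi-lesion patient
#'
#' @slot patientId Patient identifier.
#' @slot cloneParent Integer parent pointers (root = 0) of the clone tree.
#' @slot cloneEvents List of event-id character vectors, private to each clone.
#' @slot cloneMixtures Matrix of per-clone signature mixtures (clones x
#'   catalog signatures).
#' @slot lesionClone Named integer vector mapping lesion sample ids to clones.
#' @slot clonality Named character vector: event id ->
#'   truncal/shared/private.
#' @slot exposures Matrix of true per-lesion signature exposures.
#' @slot decoys Data frame of planted filter decoys with truth labels, or an
#'   empty data frame.
#' @export
setClass("SimTruth", representation(
  patientId = "character",
  cloneParent = "integer",
  cloneEvents = "list",
  cloneMixtures = "matrix",
  lesionClone = "integer",
  clonality = "character",
  exposures = "matrix",
  decoys = "data.frame"))

setValidity("SimTruth", function(object) {
  msg <- character(0)
  if (sum(object@cloneParent == 0L) != 1L)
    msg <- c(msg, "clone tree must have exactly one root")
  ev <- unlist(object@cloneEvents, use.names = FALSE)
  if (anyDuplicated(ev))
    msg <- c(msg, "clone mutation sets must be disjoint")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth for", object@patientId, "-", length(object@cloneParent),
      "clones,", length(object@lesionClone), "lesions,",
      length(object@clonality), "events\n")
})
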