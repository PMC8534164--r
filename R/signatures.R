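## 96-context spectra, exposure refitting by forward selection, clustering
## of exposures and shared-signature grouping.

#' Count the 96-context spectrum of a sample
#'
#' Bins each filtered SNV into one of the 96 pyrimidine-centric trinucleotide
#' classes; purine-reference calls are reverse-complemented first. Indels
#' (and other non-SNV records) carry no context and are skipped, with the
#' skipped count retained on the result. SNVs lacking a context are an
#' error: contexts must be present in the table or extracted beforehand.
#'
#' @param records Variant data frame for one sample.
#' @param sampleId Optional sample id; defaults to the records' sample id.
#' @return A \linkS4class{ContextSpectrum}.
#' @export
countContexts <- function(records, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- if (nrow(records)) records$sample_id[1] else "sample"
  labs <- contextLabels96()
  counts <- stats::setNames(numeric(96L), labs)
  snv <- .isSnv(records$ref, records$alt)
  skipped <- sum(!snv)
  snvRec <- records[snv, , drop = FALSE]
  noCtx <- is.na(snvRec$context)
  if (any(noCtx))
    stop("context error: SNV record(s) without trinucleotide context: ",
         paste(utils::head(paste0(snvRec$chrom[noCtx], ":",
                                  snvRec$pos[noCtx]), 10), collapse = ", "))
  if (nrow(snvRec)) {
    bins <- mapply(contextBin96, snvRec$ref, snvRec$alt, snvRec$context)
    tab <- table(factor(bins, levels = labs))
    counts[labs] <- as.numeric(tab)
  }
  new("ContextSpectrum", sampleId = sampleId, counts = counts,
      skipped = as.integer(skipped))
}

## Constrained least squares on a subset of signatures:
## minimize ||v - t(P[idx,]) w||^2 s.t. w >= 0, sum(w) <= 1,
## by projected coordinate descent (deterministic sweep order).
.solveWeights <- function(A, b, idx, tol = 1e-8, maxit = 2000L) {
  k <- length(idx)
  w <- numeric(k)
  Ai <- A[idx, idx, drop = FALSE]
  bi <- b[idx]
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(k)) {
      rest <- sum(Ai[j, ] * w) - Ai[j, j] * w[j]
      cap <- 1 - (sum(w) - w[j])
      wj <- min(max((bi[j] - rest) / Ai[j, j], 0), cap)
      delta <- max(delta, abs(wj - w[j]))
      w[j] <- wj
    }
    if (delta < tol) break
  }
  w
}

.sqErr <- function(A, b, vv, idx, w) {
  if (!length(idx)) return(vv)
  vv - 2 * sum(w * b[idx]) +
    as.numeric(t(w) %*% A[idx, idx, drop = FALSE] %*% w)
}

#' Refit signature exposures by forward selection
#'
#' Normalizes the spectrum to frequencies and greedily adds the catalog
#' signature whose inclusion (re-optimizing all included weights under
#' non-negativity and sum <= 1, minimizing squared reconstruction error)
#' most reduces the error; stops when the improvement falls below
#' \code{tol}. Weights below \code{cutoff} are then zeroed and the remaining
#' weights re-optimized once. Ties are broken by catalog order, so the fit
#' is deterministic.
#'
#' @param spectrum A \linkS4class{ContextSpectrum} with at least one count.
#' @param catalog A \linkS4class{SignatureCatalog}.
#' @param cutoff Minimum reported weight (default 0.06).
#' @param tol Stopping tolerance on error improvement (default 1e-3).
#' @return An \linkS4class{ExposureVector} over all catalog signatures.
#' @export
refitExposures <- function(spectrum, catalog, cutoff = 0.06, tol = 1e-3) {
  v <- spectrumCounts(spectrum)
  if (sum(v) < 1)
    stop("refit error: spectrum for ", spectrum@sampleId,
         " has no binned substitutions")
  v <- v / sum(v)
  P <- signatureProbs(catalog)
  k <- nrow(P)
  A <- P %*% t(P)
  b <- as.numeric(P %*% v)
  vv <- sum(v * v)

  included <- integer(0)
  w <- numeric(0)
  err <- vv
  repeat {
    best <- NULL
    for (cand in setdiff(seq_len(k), included)) {
      idx <- c(included, cand)
      wc <- .solveWeights(A, b, idx)
      e <- .sqErr(A, b, vv, idx, wc)
      if (is.null(best) || e < best$err - 1e-15) {
        best <- list(idx = idx, w = wc, err = e)
      }
    }
    if (is.null(best) || err - best$err < tol) break
    included <- best$idx
    w <- best$w
    err <- best$err
    if (length(included) == k) break
  }

  full <- stats::setNames(numeric(k), rownames(P))
  full[included] <- w
  keep <- which(full >= cutoff)
  full[] <- 0
  if (length(keep)) full[keep] <- .solveWeights(A, b, keep)
  full[full < cutoff] <- 0
  new("ExposureVector", sampleId = spectrum@sampleId, weights = full,
      residual = 1 - sum(full))
}

#' Cluster samples by signature exposures
#'
#' Agglomerative hierarchical clustering on Euclidean distances between
#' exposure weight vectors, with configurable linkage (default average).
#'
#' @param exposures List of \linkS4class{ExposureVector}s over a common
#'   catalog, or a samples x signatures weight matrix.
#' @param linkage Agglomeration method passed to \code{\link[stats]{hclust}}.
#' @param k Number of clusters to cut (default 3); must not exceed the
#'   number of samples.
#' @return List with the weight matrix (\code{weights}), the
#'   \code{\link[stats]{hclust}} object (\code{hclust}) and integer cluster
#'   \code{labels} named by sample.
#' @export
clusterExposures <- function(exposures, linkage = "average", k = 3L) {
  W <- exposureMatrix(exposures)
  if (nrow(W) < 2L)
    stop("clustering requires at least 2 samples")
  if (k > nrow(W))
    stop("config error: k = ", k, " exceeds the number of samples (",
         nrow(W), ")")
  hc <- stats::hclust(stats::dist(W, method = "euclidean"),
                      method = linkage)
  labels <- stats::cutree(hc, k = k)
  list(weights = W, hclust = hc, labels = labels)
}

#' Assemble a weight matrix from exposure vectors
#' @param exposures List of \linkS4class{ExposureVector}s or a matrix.
#' @return Samples x signatures numeric matrix.
#' @export
exposureMatrix <- function(exposures) {
  if (is.matrix(exposures)) return(exposures)
  stopifnot(length(exposures) >= 1L)
  W <- do.call(rbind, lapply(exposures, exposureWeights))
  rownames(W) <- vapply(exposures, function(e) e@sampleId, character(1))
  W
}

#' Group samples by the signatures their cluster shares
#'
#' Within each cluster, the shared set is the set of signatures carried at
#' or above \code{presenceCutoff} by every member; samples are then grouped
#' by the size of that set, bucketed as "1", "2" or ">=3". A singleton
#' cluster uses its own signature count. An empty shared set yields the
#' out-of-scheme label "0" with a warning.
#'
#' @param exposures List of \linkS4class{ExposureVector}s or weight matrix.
#' @param labels Integer cluster labels from \code{\link{clusterExposures}}.
#' @param presenceCutoff Minimum weight for a signature to count as present.
#' @return Character vector of group labels named by sample.
#' @export
sharedSignatureGroups <- function(exposures, labels,
                                  presenceCutoff = 0.06) {
  W <- exposureMatrix(exposures)
  present <- W >= presenceCutoff
  out <- stats::setNames(character(nrow(W)), rownames(W))
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    shared <- which(colSums(present[members, , drop = FALSE]) ==
                      length(members))
    nShared <- length(shared)
    if (nShared == 0L) {
      warning("cluster ", cl, " has an empty shared signature set")
      lab <- "0"
    } else if (nShared >= 3L) lab <- ">=3"
    else lab <- as.character(nShared)
    out[members] <- lab
  }
  out
}

#' Convert an hclust dendrogram to a serializable nested list
#'
#' @param hc An \code{\link[stats]{hclust}} object.
#' @return Nested list of merges with heights, suitable for JSON output.
#' @export
dendrogramToList <- function(hc) {
  build <- function(i) {
    if (i < 0) return(list(leaf = hc$labels[-i]))
    m <- hc$merge[i, ]
    list(height = hc$height[i], children = list(build(m[1]), build(m[2])))
  }
  build(nrow(hc$merge))
}
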