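## Clonality partitioning, binary matrix construction, maximum-parsimony
## search, branch-change assignment and bootstrap support.

#' Event identifiers for variant and copy-number records
#'
#' SNV/indel events are keyed \code{chrom:pos:ref:alt}; directional
#' copy-number events are keyed \code{gene:amp} or \code{gene:del}.
#'
#' @param variants Variant data frame (may be empty or NULL).
#' @param cnvs Kept CNV data frame with a \code{direction} column (may be
#'   NULL).
#' @return Named list mapping each tumor sample id to its character vector
#'   of event ids.
#' @export
presenceSets <- function(variants = NULL, cnvs = NULL) {
  sets <- list()
  addEvents <- function(samples, ids) {
    for (s in unique(samples)) {
      sets[[s]] <<- union(sets[[s]], ids[samples == s])
    }
  }
  if (!is.null(variants) && nrow(variants))
    addEvents(variants$sample_id,
              paste(variants$chrom, variants$pos, variants$ref,
                    variants$alt, sep = ":"))
  if (!is.null(cnvs) && nrow(cnvs)) {
    dir <- ifelse(cnvs$direction == "amplification", "amp", "del")
    addEvents(cnvs$sample_id, paste(cnvs$gene, dir, sep = ":"))
  }
  sets
}

#' Partition mutation events into truncal, shared and private
#'
#' For one patient with at least two tumor samples: an event is truncal if
#' present in every sample, private if present in exactly one, and shared
#' otherwise (more than one but not all).
#'
#' @param presence Named list of per-sample event-id character vectors
#'   (tumor samples only), e.g. from \code{\link{presenceSets}}.
#' @return List with \code{labels} (named character vector event ->
#'   truncal/shared/private), \code{truncal} and \code{shared} counts, and
#'   \code{private} (named integer vector of per-sample private counts).
#' @export
classifyClonality <- function(presence) {
  nSamples <- length(presence)
  if (nSamples < 2L)
    stop("clonality partition undefined for a single-sample patient")
  events <- sort(unique(unlist(presence, use.names = FALSE)),
                 method = "radix")
  inSample <- vapply(presence, function(s) events %in% s,
                     logical(length(events)))
  if (length(events) == 1L) inSample <- matrix(inSample, nrow = 1L,
                                               dimnames = list(NULL,
                                                 names(presence)))
  occ <- rowSums(inSample)
  labels <- ifelse(occ == nSamples, "truncal",
                   ifelse(occ == 1L, "private", "shared"))
  names(labels) <- events
  privatePer <- stats::setNames(integer(nSamples), names(presence))
  for (s in names(presence)) {
    privatePer[s] <- sum(labels == "private" & inSample[, s])
  }
  list(labels = labels,
       truncal = sum(labels == "truncal"),
       shared = sum(labels == "shared"),
       private = privatePer)
}

#' Build the per-patient binary mutation matrix
#'
#' One row per tumor sample plus an all-zero normal taxon (last row), one
#' column per distinct event id (duplicates collapse to one column);
#' all-zero columns are dropped. Entries are 0/1 for absence/presence.
#'
#' @param presence Named list of per-sample event-id vectors.
#' @param patientId Patient identifier.
#' @param normalTaxon Label for the normal taxon (default "normal").
#' @return A \linkS4class{MutationMatrix}.
#' @export
buildBinaryMatrix <- function(presence, patientId = "patient",
                              normalTaxon = "normal") {
  if (normalTaxon %in% names(presence))
    stop("normal taxon label collides with a tumor sample id")
  events <- sort(unique(unlist(presence, use.names = FALSE)),
                 method = "radix")
  m <- vapply(names(presence),
              function(s) as.integer(events %in% presence[[s]]),
              integer(length(events)))
  m <- matrix(m, nrow = length(events),
              dimnames = list(events, names(presence)))
  m <- t(m)
  m <- rbind(m, matrix(0L, 1L, ncol(m),
                       dimnames = list(normalTaxon, NULL)))
  m <- m[, colSums(m) > 0L, drop = FALSE]
  new("MutationMatrix", patientId = patientId, mat = m,
      normalTaxon = normalTaxon)
}

#' Fitch parsimony score of a tree
#'
#' Sums, over matrix columns, the minimum number of state changes of each
#' binary unordered character on the given topology (post-order state-set
#' pass, counting empty intersections).
#'
#' @param tree A \linkS4class{ParsimonyTree} or \code{ape::phylo} whose leaf
#'   set equals the matrix taxa.
#' @param mat A \linkS4class{MutationMatrix}.
#' @return Integer parsimony score.
#' @export
fitchScore <- function(tree, mat) {
  phy <- if (is(tree, "ParsimonyTree")) treePhylo(tree) else tree
  m <- matrixEvents(mat)
  .phyloStates(phy, m)  # validates tree/matrix taxa agreement
  cc <- .collapseColumns(m[phy$tip.label, , drop = FALSE])
  as.integer(.fitchPhylo(phy, cc$states, cc$weights)$score)
}

#' Exact maximum-parsimony tree search
#'
#' Enumerates unrooted binary topologies by stepwise addition (exhaustively
#' for up to 9 taxa, branch-and-bound with the partial-tree Fitch lower
#' bound for 10-12) and returns every topology achieving the minimum score,
#' each rooted on the pendant branch of the normal taxon, with branch
#' changes assigned. Output order is deterministic (lexicographic Newick).
#'
#' @param mat A \linkS4class{MutationMatrix} with 3 to 12 taxa.
#' @return List of \linkS4class{ParsimonyTree}s, all with the same (minimum)
#'   score.
#' @export
searchParsimony <- function(mat) {
  m <- matrixEvents(mat)
  taxa <- rownames(m)
  res <- .mpSearch(m)
  normalIdx <- match(mat@normalTaxon, taxa)
  nwk <- vapply(res$trees, .rootedNewickFromEdges, character(1),
                normalIdx = normalIdx, tipLabels = taxa)
  keep <- !duplicated(nwk)  # distinct additions can yield the same topology
  nwk <- nwk[keep]
  o <- order(nwk, method = "radix")
  lapply(nwk[o], function(s) {
    phy <- ape::read.tree(text = s)
    assignBranchChanges(phy, mat)
  })
}

#' Assign mutation changes to branches
#'
#' Chooses one minimal Fitch state assignment deterministically (state 0 is
#' preferred at the root, consistent with the all-zero normal rooting) and
#' sets each branch length to the number of event columns changing on that
#' branch. Branch lengths therefore sum to the parsimony score.
#'
#' @param tree A \linkS4class{ParsimonyTree} or rooted \code{ape::phylo}.
#' @param mat A \linkS4class{MutationMatrix}.
#' @return A \linkS4class{ParsimonyTree} with branch lengths and score.
#' @export
assignBranchChanges <- function(tree, mat) {
  phy <- if (is(tree, "ParsimonyTree")) treePhylo(tree) else tree
  m <- matrixEvents(mat)
  .phyloStates(phy, m)  # validates tree/matrix taxa agreement
  cc <- .collapseColumns(m[phy$tip.label, , drop = FALSE])
  fit <- .fitchPhylo(phy, cc$states, cc$weights)
  S <- fit$S
  E <- fit$postorderEdge
  nTip <- length(phy$tip.label)
  root <- nTip + 1L
  nm <- ncol(cc$states)
  chosen <- matrix(0L, nrow(S), nm)
  chosen[root, ] <- ifelse(bitwAnd(S[root, ], 1L) > 0L, 1L, 2L)
  for (i in rev(seq_len(nrow(E)))) {  # preorder
    p <- E[i, 1L]; ch <- E[i, 2L]
    keepParent <- bitwAnd(chosen[p, ], S[ch, ]) > 0L
    chosen[ch, ] <- ifelse(keepParent, chosen[p, ],
                           ifelse(bitwAnd(S[ch, ], 1L) > 0L, 1L, 2L))
  }
  lens <- numeric(nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    lens[i] <- sum(cc$weights * (chosen[p, ] != chosen[ch, ]))
  }
  phy$edge.length <- lens
  new("ParsimonyTree", tree = phy, score = as.integer(round(sum(lens))))
}

#' Bootstrap clade supports
#'
#' Resamples event columns with replacement (keeping the column count),
#' recomputes the maximum-parsimony tree set for each replicate, and counts
#' a clade when it appears in the strict consensus of that replicate's
#' minimum-score trees. Supports (100 x count / reps) are annotated onto
#' the first best tree as internal-node labels.
#'
#' @param mat A \linkS4class{MutationMatrix}.
#' @param reps Number of replicates (default 100).
#' @param seed Integer seed; the same seed reproduces identical supports.
#' @return List with \code{tree} (the support-annotated
#'   \linkS4class{ParsimonyTree}), \code{supports} (named vector,
#'   clade key -> percent) and \code{trees} (all minimum-score trees of the
#'   original matrix).
#' @export
bootstrapSupport <- function(mat, reps = 100L, seed = 1L) {
  if (reps < 1L) stop("config error: reps must be >= 1")
  m <- matrixEvents(mat)
  taxa <- rownames(m)
  normalIdx <- match(mat@normalTaxon, taxa)
  M <- ncol(m)

  orig <- searchParsimony(mat)
  best <- orig[[1L]]
  phy <- treePhylo(best)
  nTip <- length(phy$tip.label)
  cladeOfNode <- .phyloCladeKeys(phy)
  cladeKeys <- unique(unlist(cladeOfNode))
  counts <- stats::setNames(numeric(length(cladeKeys)), cladeKeys)

  set.seed(seed)
  for (r in seq_len(reps)) {
    idx <- sample.int(M, M, replace = TRUE)
    res <- .mpSearch(m[, idx, drop = FALSE])
    cladeSets <- lapply(res$trees, .rootedClades,
                        normalIdx = normalIdx, tipLabels = taxa)
    strict <- Reduce(intersect, cladeSets)
    hit <- intersect(names(counts), strict)
    counts[hit] <- counts[hit] + 1
  }
  supports <- round(100 * counts / reps)
  lab <- character(phy$Nnode)
  for (nd in seq_len(phy$Nnode)) {
    key <- cladeOfNode[[as.character(nTip + nd)]]
    lab[nd] <- if (is.null(key) || is.na(key)) "" else
      as.character(supports[[key]])
  }
  phy$node.label <- lab
  annotated <- new("ParsimonyTree", tree = phy, score = best@score)
  list(tree = annotated, supports = supports, trees = orig)
}

## Clade keys (sorted tip labels joined by "|") of the non-trivial internal
## nodes of a rooted phylo: every internal node except the root, plus any
## internal node whose clade is a single tip is excluded by construction.
.phyloCladeKeys <- function(phy) {
  nTip <- length(phy$tip.label)
  keys <- list()
  tipsUnder <- function(node) {
    if (node <= nTip) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, tipsUnder))
  }
  if (phy$Nnode >= 2L) {
    for (nd in (nTip + 2L):(nTip + phy$Nnode)) {
      keys[[as.character(nd)]] <- paste(sort(tipsUnder(nd), method = "radix"), collapse = "|")
    }
  }
  ## the root split "all tumor taxa" is carried by the root's non-normal
  ## child when that child is internal; single-tip children are trivial.
  keys
}
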