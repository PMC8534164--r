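## Internal parsimony machinery.
##
## Unrooted binary topologies over leaves 1..n are represented as 2-column
## edge matrices; internal nodes are numbered n+1 .. 2n-2 in order of
## creation. Character states are bitmasks over columns: 1 = state 0,
## 2 = state 1, 3 = {0,1}. Duplicate matrix columns are collapsed to unique
## patterns with multiplicity weights before scoring.

.collapseColumns <- function(m) {
  key <- apply(m, 2L, paste, collapse = "")
  first <- !duplicated(key)
  weights <- as.numeric(table(key)[key[first]])
  list(states = m[, first, drop = FALSE] + 1L, weights = weights)
}

## Fitch length of an unrooted (or partial) topology given leaf bitmasks.
## Roots at the highest-numbered internal node; pairwise sequential state
## combination at each node, counting empty intersections.
.fitchEdges <- function(edges, leafStates, weights) {
  nLeaf <- nrow(leafStates)
  if (nrow(edges) == 1L) {  # two leaves, single edge
    inter <- bitwAnd(leafStates[edges[1, 1], ], leafStates[edges[1, 2], ])
    return(sum(weights[inter == 0L]))
  }
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root <- nodes  # last-created internal node
  parent <- integer(nodes)
  ord <- integer(nodes)
  stack <- root
  parent[root] <- -1L
  k <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    ord[k] <- v
    for (u in adj[[v]]) if (u != parent[v]) {
      parent[u] <- v
      stack <- c(stack, u)
    }
  }
  m <- ncol(leafStates)
  S <- matrix(0L, nodes, m)
  changes <- numeric(m)
  for (v in rev(ord[seq_len(k)])) {
    if (v <= nLeaf) {
      S[v, ] <- leafStates[v, ]
    } else {
      s <- NULL
      for (u in adj[[v]]) if (parent[u] == v) {
        if (is.null(s)) s <- S[u, ]
        else {
          inter <- bitwAnd(s, S[u, ])
          empty <- inter == 0L
          changes <- changes + empty
          s <- ifelse(empty, bitwOr(s, S[u, ]), inter)
        }
      }
      S[v, ] <- s
    }
  }
  sum(changes * weights)
}

## Exact maximum-parsimony search on a raw binary matrix (taxa x events).
## Exhaustive stepwise-addition enumeration for <= 9 taxa; branch-and-bound
## with the partial-tree Fitch lower bound for 10-12. Returns every
## minimum-score unrooted topology.
.mpSearch <- function(m) {
  n <- nrow(m)
  if (n < 3L) stop("parsimony search requires at least 3 taxa")
  if (n > 12L)
    stop("parsimony search supports at most 12 taxa per patient cohort; ",
         "got ", n)
  cc <- .collapseColumns(m)
  states <- cc$states
  weights <- cc$weights
  useBB <- n >= 10L

  best <- Inf
  bestTrees <- list()
  rec <- function(edges, nextLeaf) {
    if (nextLeaf > n) {
      sc <- .fitchEdges(edges, states, weights)
      if (sc < best) {
        best <<- sc
        bestTrees <<- list(edges)
      } else if (sc == best) {
        bestTrees[[length(bestTrees) + 1L]] <<- edges
      }
      return(invisible())
    }
    if (useBB && nextLeaf > 5L && is.finite(best)) {
      if (.fitchEdges(edges, states, weights) > best) return(invisible())
    }
    v <- n + nextLeaf - 2L
    for (i in seq_len(nrow(edges))) {
      e <- edges[i, ]
      rec(rbind(edges[-i, , drop = FALSE],
                c(e[1L], v), c(v, e[2L]), c(v, nextLeaf)),
          nextLeaf + 1L)
    }
  }
  rec(rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)), 4L)
  list(score = best, trees = bestTrees)
}

## Adjacency list of an edge matrix.
.adjacency <- function(edges) {
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

## Deterministic topology-only Newick of an unrooted topology rooted on the
## pendant branch of the normal leaf; children ordered by smallest leaf
## label.
.rootedNewickFromEdges <- function(edges, normalIdx, tipLabels) {
  adj <- .adjacency(edges)
  nLeaf <- length(tipLabels)
  rec <- function(v, par) {
    if (v <= nLeaf) return(list(str = tipLabels[v], min = tipLabels[v]))
    kids <- setdiff(adj[[v]], par)
    subs <- lapply(kids, rec, par = v)
    o <- order(vapply(subs, `[[`, character(1), "min"),
               method = "radix")
    subs <- subs[o]
    list(str = paste0("(", paste(vapply(subs, `[[`, character(1), "str"),
                                 collapse = ","), ")"),
         min = subs[[1L]]$min)
  }
  u <- adj[[normalIdx]][1L]
  parts <- list(list(str = tipLabels[normalIdx], min = tipLabels[normalIdx]),
                rec(u, normalIdx))
  o <- order(vapply(parts, `[[`, character(1), "min"), method = "radix")
  paste0("(", paste(vapply(parts[o], `[[`, character(1), "str"),
                    collapse = ","), ");")
}

## Non-trivial rooted clades (descendant tip-label sets, sorted and joined
## with "|") of an unrooted topology rooted on the normal leaf's branch.
## The clade of all tumor taxa (the root split) is included; single tips
## and the full taxon set are not.
.rootedClades <- function(edges, normalIdx, tipLabels) {
  adj <- .adjacency(edges)
  nLeaf <- length(tipLabels)
  clades <- character(0)
  rec <- function(v, par) {
    if (v <= nLeaf) return(tipLabels[v])
    tips <- character(0)
    for (u in setdiff(adj[[v]], par)) tips <- c(tips, rec(u, v))
    clades <<- c(clades, paste(sort(tips, method = "radix"),
                               collapse = "|"))
    tips
  }
  u <- adj[[normalIdx]][1L]
  rec(u, normalIdx)
  unique(clades)
}

## Post-order Fitch on a rooted ape phylo; returns per-node state sets and
## the weighted score.
.fitchPhylo <- function(phy, states, weights) {
  nTip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  E <- po$edge
  nNode <- phy$Nnode
  m <- ncol(states)
  S <- matrix(0L, nTip + nNode, m)
  S[seq_len(nTip), ] <- states
  seen <- logical(nTip + nNode)
  seen[seq_len(nTip)] <- TRUE
  changes <- numeric(m)
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    if (!seen[p]) {
      S[p, ] <- S[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(S[p, ], S[ch, ])
      empty <- inter == 0L
      changes <- changes + empty
      S[p, ] <- ifelse(empty, bitwOr(S[p, ], S[ch, ]), inter)
    }
  }
  list(score = sum(changes * weights), S = S, postorderEdge = E)
}

## Leaf bitmask states for a rooted phylo from a binary matrix keyed by taxa.
.phyloStates <- function(phy, m) {
  miss <- setdiff(phy$tip.label, rownames(m))
  if (length(miss))
    stop("tree/matrix taxa mismatch: ", paste(miss, collapse = ", "),
         " absent from the matrix")
  if (length(setdiff(rownames(m), phy$tip.label)))
    stop("tree/matrix taxa mismatch: matrix has taxa absent from the tree")
  m[phy$tip.label, , drop = FALSE] + 1L
}
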