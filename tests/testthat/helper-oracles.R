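## Independent oracles: brute-force small parsimony by exhaustive
## enumeration of internal-node labelings, complete topology lists from
## phangorn, and dense constrained least squares from pracma.

## Minimum change count of one binary character on a fixed topology,
## minimized over all 2^Nnode internal labelings.
bruteColumnScore <- function(phy, tipStates) {
  nTip <- length(phy$tip.label)
  I <- phy$Nnode
  labelings <- as.matrix(expand.grid(rep(list(0:1), I)))
  E <- phy$edge
  stateOf <- function(node) {
    if (node <= nTip) rep(tipStates[[phy$tip.label[node]]],
                          nrow(labelings))
    else labelings[, node - nTip]
  }
  total <- rep(0L, nrow(labelings))
  for (i in seq_len(nrow(E)))
    total <- total + (stateOf(E[i, 1L]) != stateOf(E[i, 2L]))
  min(total)
}

bruteTreeScore <- function(phy, m) {
  sum(vapply(seq_len(ncol(m)), function(j)
    bruteColumnScore(phy, stats::setNames(m[, j], rownames(m))),
    numeric(1)))
}

## Complete-enumeration minimum score over all unrooted topologies.
bruteMinScore <- function(m) {
  trees <- phangorn::allTrees(nrow(m), rooted = FALSE,
                              tip.label = rownames(m))
  min(vapply(trees, bruteTreeScore, numeric(1), m = m))
}

## Dense non-negative least-squares refit over the full catalog
## (sum constraint not binding for normalized mixtures).
denseRefitOracle <- function(freqs, catalog) {
  P <- signatureProbs(catalog)
  fit <- pracma::lsqnonneg(t(P), as.numeric(freqs))
  stats::setNames(fit$x, rownames(P))
}

## Squared reconstruction error of a weight vector against frequencies.
reconstructionError <- function(weights, freqs, catalog) {
  P <- signatureProbs(catalog)
  sum((as.numeric(freqs) - as.numeric(t(P) %*% weights))^2)
}
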