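## In-code fixtures shared across tests.

variantRow <- function(...) {
  base <- data.frame(
    patient_id = "P1", sample_id = "S1", chrom = "chr1", pos = 100L,
    ref = "C", alt = "T", gene = "TP53", consequence = "nonsynonymous",
    context = "ACA", vaf = 0.3, alt_reads_fwd = 10L, alt_reads_rev = 10L,
    pop_af_max = 0, common_snp = FALSE, clinvar = "unknown",
    pred_sift = "tolerated", pred_polyphen2 = "tolerated",
    pred_mutationtaster = "missing", hotspot = FALSE,
    stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

variantTable <- function(...) {
  df <- do.call(rbind, list(...))
  df$pos <- seq(100L, by = 50L, length.out = nrow(df))  # unique events
  df
}

## Binary matrix over nTaxa - 1 tumor samples plus an all-zero normal,
## non-empty columns only.
randomBinaryMatrix <- function(nTaxa, nCols) {
  repeat {
    m <- matrix(stats::rbinom((nTaxa - 1L) * nCols, 1L, 0.5),
                nTaxa - 1L, nCols)
    m <- rbind(m, 0L)
    rownames(m) <- c(paste0("S", seq_len(nTaxa - 1L)), "normal")
    m <- m[, colSums(m) > 0L, drop = FALSE]
    if (ncol(m) >= 1L) return(m)
  }
}

asMutationMatrix <- function(m, patientId = "P1") {
  colnames(m) <- paste0("e", seq_len(ncol(m)))
  new("MutationMatrix", patientId = patientId, mat = m,
      normalTaxon = "normal")
}

toyDriverList <- function() {
  readDriverList(system.file("extdata", "driver_genes.tsv",
                             package = "oncophylo"))
}
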