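## Readers and writers for the on-disk formats: variant TSV, copy-number TSV,
## driver-gene list, signature catalog TSV, Newick trees and JSON run config.

.VARIANT_COLUMNS <- c(
  "patient_id", "sample_id", "chrom", "pos", "ref", "alt", "gene",
  "consequence", "context", "vaf", "alt_reads_fwd", "alt_reads_rev",
  "pop_af_max", "common_snp", "clinvar",
  "pred_sift", "pred_polyphen2", "pred_mutationtaster", "hotspot")

.CONSEQUENCES <- c("synonymous", "nonsynonymous", "indel", "other")
.CLINVAR <- c("pathogenic", "benign", "unknown")
.PREDICTOR <- c("deleterious", "tolerated", "missing")
.CNV_COLUMNS <- c("patient_id", "sample_id", "gene", "copy_number",
                  "gene_role")
.GENE_ROLES <- c("oncogene", "tsg", "unknown")

.isSnv <- function(ref, alt) nchar(ref) == 1L & nchar(alt) == 1L &
  ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

#' Validate a variant table
#'
#' Enforces the record invariants: mandatory columns, enum domains,
#' \code{ref != alt}, positions >= 1, VAF in [0, 1], non-negative strand
#' read counts, and, for SNVs carrying a context, a context middle base equal
#' to the reference base. Empty or NA contexts are normalized to NA
#' (context is optional).
#'
#' @param df Data frame of variant records.
#' @return The validated data frame, row order preserved.
#' @export
validateVariantTable <- function(df) {
  missing <- setdiff(.VARIANT_COLUMNS, names(df))
  if (length(missing))
    stop("variant table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df$vaf <- as.numeric(df$vaf)
  df$alt_reads_fwd <- as.integer(df$alt_reads_fwd)
  df$alt_reads_rev <- as.integer(df$alt_reads_rev)
  df$pop_af_max <- as.numeric(df$pop_af_max)
  df$common_snp <- as.logical(df$common_snp)
  df$hotspot <- as.logical(df$hotspot)
  df$context <- as.character(df$context)
  df$context[is.na(df$context) | df$context == ""] <- NA_character_

  .rowFail <- function(bad, what) {
    if (any(bad))
      stop("variant table validation error at row(s) ",
           paste(which(bad), collapse = ", "), ": ", what)
  }
  .rowFail(df$ref == df$alt, "ref equals alt")
  .rowFail(is.na(df$pos) | df$pos < 1L, "pos must be >= 1")
  .rowFail(is.na(df$vaf) | df$vaf < 0 | df$vaf > 1,
           "vaf must lie in [0, 1]")
  .rowFail(df$alt_reads_fwd < 0L | df$alt_reads_rev < 0L,
           "strand read counts must be >= 0")
  .rowFail(df$pop_af_max < 0 | df$pop_af_max > 1,
           "pop_af_max must lie in [0, 1]")
  .rowFail(!df$consequence %in% .CONSEQUENCES,
           paste("consequence must be one of",
                 paste(.CONSEQUENCES, collapse = "/")))
  .rowFail(!df$clinvar %in% .CLINVAR,
           paste("clinvar must be one of", paste(.CLINVAR, collapse = "/")))
  for (p in c("pred_sift", "pred_polyphen2", "pred_mutationtaster"))
    .rowFail(!df[[p]] %in% .PREDICTOR,
             paste(p, "must be one of", paste(.PREDICTOR, collapse = "/")))
  snv <- .isSnv(df$ref, df$alt)
  hasCtx <- !is.na(df$context)
  .rowFail(hasCtx & nchar(df$context) != 3L, "context must be 3 bases")
  .rowFail(snv & hasCtx & substr(df$context, 2L, 2L) != df$ref,
           "context middle base must equal ref for SNVs")
  df
}

#' Read a per-sample annotated somatic variant table
#'
#' Tab-separated, one row per variant per sample, with the documented header
#' (coordinates, ref/alt, gene, consequence, trinucleotide context, VAF,
#' strand-split alternate read counts, maximum population allele frequency,
#' common-SNP flag, ClinVar class, three predictor calls, hotspot flag).
#'
#' @param path Path to the TSV file.
#' @return A validated data frame of variant records, row order preserved.
#' @export
readVariantTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", comment.char = "")
  validateVariantTable(df)
}

#' Write a variant table
#' @param df Validated variant data frame.
#' @param path Output TSV path.
#' @export
writeVariantTable <- function(df, path) {
  out <- df
  out$context[is.na(out$context)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-level copy-number table
#'
#' Columns: patient_id, sample_id, gene, copy_number (non-negative integer),
#' gene_role (oncogene / tsg / unknown).
#'
#' @param path Path to the TSV file.
#' @return A validated data frame.
#' @export
readCnvTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(.CNV_COLUMNS, names(df))
  if (length(missing))
    stop("CNV table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  df$copy_number <- as.integer(df$copy_number)
  if (any(is.na(df$copy_number) | df$copy_number < 0L))
    stop("CNV table validation error: copy_number must be a non-negative ",
         "integer (rows ",
         paste(which(is.na(df$copy_number) | df$copy_number < 0L),
               collapse = ", "), ")")
  if (any(!df$gene_role %in% .GENE_ROLES))
    stop("CNV table validation error: gene_role must be one of ",
         paste(.GENE_ROLES, collapse = "/"))
  df
}

#' Write a copy-number table
#' @param df CNV data frame.
#' @param path Output TSV path.
#' @export
writeCnvTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a driver-gene list
#'
#' Two tab-separated columns without header: gene and role
#' (oncogene / tsg / unknown).
#'
#' @param path Path to the list.
#' @return Data frame with columns \code{gene} and \code{role}.
#' @export
readDriverList <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("gene", "role"))
  if (any(!df$role %in% .GENE_ROLES))
    stop("driver list validation error: role must be one of ",
         paste(.GENE_ROLES, collapse = "/"))
  if (anyDuplicated(df$gene))
    stop("driver list validation error: duplicated gene(s) ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  df
}

#' Read a signature reference catalog
#'
#' TSV with one row per signature and 96 context columns in the canonical
#' order (a COSMIC-v2-like layout; a transposed 96-row layout is also
#' accepted). Rows must already be normalized: a row sum deviating from 1 by
#' more than 1e-6 is an error, not silently renormalized.
#'
#' @param path Path to the catalog TSV.
#' @return A \linkS4class{SignatureCatalog}.
#' @export
readSignatureCatalog <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           check.names = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("signature catalog validation error: duplicated signature id(s) ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- ids
  labs <- contextLabels96()
  if (nrow(m) == 96L && all(rownames(m) %in% labs) && ncol(m) != 96L) {
    m <- t(m)  # contexts-as-rows layout
  }
  if (ncol(m) != 96L)
    stop("signature catalog format error: expected 96 context columns, ",
         "found ", ncol(m))
  if (!setequal(colnames(m), labs))
    stop("signature catalog format error: context labels do not match the ",
         "canonical 96-class set")
  m <- m[, labs, drop = FALSE]
  if (anyDuplicated(rownames(m)))
    stop("signature catalog validation error: duplicated signature id(s) ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  bad <- which(abs(rowSums(m) - 1) > 1e-6)
  if (length(bad))
    stop("signature catalog validation error: row(s) not summing to 1: ",
         paste(rownames(m)[bad], collapse = ", "))
  signatureCatalog(m)
}

#' Write a signature catalog
#' @param catalog A \linkS4class{SignatureCatalog}.
#' @param path Output TSV path.
#' @export
writeSignatureCatalog <- function(catalog, path) {
  m <- signatureProbs(catalog)
  df <- data.frame(signature = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Newick serialization
## ---------------------------------------------------------------------------

.newickNode <- function(phy, node, nTip) {
  if (node <= nTip) {
    lab <- phy$tip.label[node]
    len <- .edgeLengthTo(phy, node)
    if (is.na(len)) lab else paste0(lab, ":", format(len, scientific = FALSE))
  } else {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    sub <- vapply(kids, function(k) .newickNode(phy, k, nTip), character(1))
    minLab <- vapply(kids, function(k) .minLeafLabel(phy, k, nTip),
                     character(1))
    sub <- sub[order(minLab, method = "radix")]
    lab <- if (!is.null(phy$node.label)) phy$node.label[node - nTip] else ""
    if (is.na(lab)) lab <- ""
    len <- .edgeLengthTo(phy, node)
    paste0("(", paste(sub, collapse = ","), ")", lab,
           if (!is.na(len)) paste0(":", format(len, scientific = FALSE))
           else "")
  }
}

.edgeLengthTo <- function(phy, node) {
  if (is.null(phy$edge.length)) return(NA_real_)
  i <- which(phy$edge[, 2] == node)
  if (length(i)) phy$edge.length[i] else NA_real_
}

.minLeafLabel <- function(phy, node, nTip) {
  if (node <= nTip) return(phy$tip.label[node])
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  min(vapply(kids, function(k) .minLeafLabel(phy, k, nTip), character(1)))
}

#' Deterministic Newick string of a tree
#'
#' Children are ordered by their smallest leaf label, so equal trees always
#' serialize identically. Branch lengths are written when present; internal
#' node labels carry integer bootstrap supports when annotated.
#'
#' @param tree A \linkS4class{ParsimonyTree} or \code{ape::phylo}.
#' @return A Newick string terminated by ";".
#' @export
newickString <- function(tree) {
  phy <- if (is(tree, "ParsimonyTree")) treePhylo(tree) else tree
  nTip <- length(phy$tip.label)
  root <- nTip + 1L
  paste0(.newickNode(phy, root, nTip), ";")
}

#' Write a tree to a Newick file
#'
#' @param tree A \linkS4class{ParsimonyTree}.
#' @param path Output path.
#' @export
writeNewick <- function(tree, path) {
  writeLines(newickString(tree), path)
  invisible(path)
}

#' Read a Newick tree written by \code{writeNewick}
#'
#' @param path Path to a Newick file.
#' @return A \linkS4class{ParsimonyTree}; the score is recovered as the sum
#'   of branch lengths.
#' @export
readNewickTree <- function(path) {
  phy <- ape::read.tree(path)
  score <- if (is.null(phy$edge.length)) 0L
           else as.integer(round(sum(phy$edge.length)))
  new("ParsimonyTree", tree = phy, score = score)
}

## ---------------------------------------------------------------------------
## Run configuration serialization
## ---------------------------------------------------------------------------

#' Write a run configuration to JSON
#' @param config A \linkS4class{RunConfig}.
#' @param path Output path.
#' @export
writeRunConfig <- function(config, path) {
  slots <- slotNames(config)
  x <- lapply(slots, function(s) slot(config, s))
  names(x) <- slots
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path Path to a config JSON.
#' @return A validated \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, x)
}
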