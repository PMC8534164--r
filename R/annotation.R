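## Pathway summarization of driver genes and the actionability join.

#' Read a gene-to-pathway map
#'
#' Two tab-separated columns with header: gene, pathway. Each gene maps to
#' exactly one pathway.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns \code{gene} and \code{pathway}.
#' @export
readPathwayMap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(c("gene", "pathway"), names(df))
  if (length(missing))
    stop("pathway map format error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene))
    stop("pathway map validation error: gene(s) mapped to more than one ",
         "pathway: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  df
}

#' Fraction of driver genes per signaling pathway
#'
#' Percent of the driver-gene set falling in each pathway, rounded to one
#' decimal; genes absent from the map are reported under "unassigned".
#'
#' @param genes Character vector (or set) of driver genes; must be
#'   non-empty.
#' @param map Pathway map data frame from \code{\link{readPathwayMap}}.
#' @return Data frame with columns \code{pathway}, \code{n},
#'   \code{percent}, sorted by decreasing percent.
#' @export
#' @examples
#' map <- data.frame(gene = paste0("G", 1:15),
#'                   pathway = "transcription factors")
#' pathwayFractions(paste0("G", 1:67), map)  # 15 of 67 -> 22.4
pathwayFractions <- function(genes, map) {
  genes <- unique(genes)
  if (!length(genes)) stop("pathwayFractions requires a non-empty gene set")
  pw <- map$pathway[match(genes, map$gene)]
  pw[is.na(pw)] <- "unassigned"
  tab <- table(pw)
  out <- data.frame(pathway = names(tab), n = as.integer(tab),
                    percent = round(100 * as.integer(tab) / length(genes),
                                    1),
                    stringsAsFactors = FALSE)
  out[order(-out$percent, out$pathway), , drop = FALSE]
}

#' Read an actionability table
#'
#' Tab-separated with header: gene, alteration (snv / amplification /
#' deletion), drug, tumor_type, evidence_level. Duplicate
#' (gene, alteration, drug, tumor_type) rows are an error.
#'
#' @param path Path to the TSV.
#' @return Validated data frame.
#' @export
readActionabilityTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  cols <- c("gene", "alteration", "drug", "tumor_type", "evidence_level")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("actionability table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  bad <- which(!df$alteration %in% c("snv", "amplification", "deletion"))
  if (length(bad))
    stop("actionability table validation error at row(s) ",
         paste(bad, collapse = ", "),
         ": alteration must be snv/amplification/deletion")
  key <- paste(df$gene, df$alteration, df$drug, df$tumor_type)
  if (anyDuplicated(key))
    stop("actionability table validation error: duplicated row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  df
}

#' Join driver alterations to an actionability table
#'
#' A match requires gene equality and alteration-class equality: pathogenic
#' SNV/indel drivers match \code{snv} rows, kept amplifications match
#' \code{amplification} rows and kept deletions match \code{deletion} rows.
#'
#' @param driverCalls Data frame from \code{\link{classifyDriver}}; only
#'   rows with \code{pathogenic == TRUE} are joined. NULL to skip.
#' @param keptCnvs Kept CNV data frame (with \code{direction}) from
#'   \code{\link{filterCnvs}}. NULL to skip.
#' @param table Actionability data frame.
#' @param dedup \code{"sample"} keeps one row per sample-level alteration
#'   and drug; \code{"patient"} deduplicates to one row per patient-level
#'   alteration and drug.
#' @return Data frame of (patient_id, sample_id, gene, alteration, drug,
#'   tumor_type, evidence_level); \code{sample_id} is dropped under
#'   patient-level dedup.
#' @export
matchActionable <- function(driverCalls, keptCnvs, table,
                            dedup = c("sample", "patient")) {
  dedup <- match.arg(dedup)
  alts <- list()
  if (!is.null(driverCalls) && nrow(driverCalls)) {
    snv <- driverCalls[driverCalls$pathogenic, , drop = FALSE]
    if (nrow(snv))
      alts[[length(alts) + 1L]] <- data.frame(
        patient_id = snv$patient_id, sample_id = snv$sample_id,
        gene = snv$gene, alteration = "snv", stringsAsFactors = FALSE)
  }
  if (!is.null(keptCnvs) && nrow(keptCnvs)) {
    alts[[length(alts) + 1L]] <- data.frame(
      patient_id = keptCnvs$patient_id, sample_id = keptCnvs$sample_id,
      gene = keptCnvs$gene, alteration = keptCnvs$direction,
      stringsAsFactors = FALSE)
  }
  if (!length(alts)) {
    return(data.frame(patient_id = character(0), sample_id = character(0),
                      gene = character(0), alteration = character(0),
                      drug = character(0), tumor_type = character(0),
                      evidence_level = character(0)))
  }
  alt <- unique(do.call(rbind, alts))
  hits <- merge(alt, table, by = c("gene", "alteration"))
  if (dedup == "patient") {
    hits$sample_id <- NULL
    hits <- unique(hits)
  } else {
    hits <- unique(hits)
  }
  rownames(hits) <- NULL
  ord <- order(hits$patient_id, hits$gene, hits$alteration, hits$drug)
  hits[ord, , drop = FALSE]
}
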