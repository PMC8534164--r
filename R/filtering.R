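## Somatic variant filter cascade, driver classification, directional
## copy-number filter, and tumor mutational burden.

#' Filter somatic variant calls
#'
#' Applies the four-rule cascade conjunctively; a record is kept only if it
#' passes every rule:
#' \enumerate{
#'   \item \code{pop_af}: maximum population allele frequency across panels
#'     below the threshold (default 0.001);
#'   \item \code{common_snp}: common SNPs are excluded unless reported
#'     pathogenic in ClinVar (the rescue applies to this rule only);
#'   \item \code{strand}: at least \code{minStrandReads} alternate reads on
#'     each strand (default 2, both strands);
#'   \item \code{vaf}: variant allele fraction at or above the threshold
#'     (default 0.05, inclusive).
#' }
#' Every failed rule is recorded, so removal tallies count each rule
#' independently.
#'
#' @param records Validated variant data frame.
#' @param config A \linkS4class{RunConfig}.
#' @return A \linkS4class{FilterReport}.
#' @export
#' @examples
#' v <- simulatePatient(nLesions = 2, seed = 1)$variants
#' filterVariants(v, runConfig())
filterVariants <- function(records, config = runConfig()) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  passPop <- records$pop_af_max < config@popAfThreshold
  passSnp <- !records$common_snp | records$clinvar == "pathogenic"
  passStrand <- records$alt_reads_fwd >= config@minStrandReads &
    records$alt_reads_rev >= config@minStrandReads
  passVaf <- records$vaf >= config@vafThreshold

  fails <- cbind(pop_af = !passPop, common_snp = !passSnp,
                 strand = !passStrand, vaf = !passVaf)
  keptIdx <- rowSums(fails) == 0
  reasons <- apply(fails, 1L, function(f)
    paste(colnames(fails)[f], collapse = ";"))

  removed <- records[!keptIdx, , drop = FALSE]
  if (nrow(removed)) removed$reasons <- reasons[!keptIdx]
  else removed$reasons <- character(0)

  tallies <- c(colSums(fails), kept = sum(keptIdx), total = n)
  new("FilterReport",
      kept = records[keptIdx, , drop = FALSE],
      removed = removed,
      tallies = as.integer(tallies) |> stats::setNames(names(tallies)))
}

#' Classify driver pathogenicity of filtered variants
#'
#' A variant is a candidate driver only if its gene is on the supplied
#' driver-gene list. A candidate is called pathogenic if any of three
#' evidence arms holds: reported pathogenic in ClinVar, at least two of the
#' three in-silico predictors call it deleterious, or it is a known hotspot.
#' Every satisfied arm is recorded in the evidence column.
#'
#' @param records Variant data frame (typically \code{keptVariants()} of a
#'   \linkS4class{FilterReport}).
#' @param driverGenes Data frame from \code{\link{readDriverList}} or a
#'   character vector of gene symbols.
#' @return The input with columns \code{in_driver_list}, \code{pathogenic}
#'   and \code{evidence} (comma-separated subset of
#'   clinvar/predictor_consensus/hotspot) appended.
#' @export
classifyDriver <- function(records, driverGenes) {
  genes <- if (is.data.frame(driverGenes)) driverGenes$gene else driverGenes
  inList <- records$gene %in% genes
  armClinvar <- records$clinvar == "pathogenic"
  preds <- cbind(records$pred_sift, records$pred_polyphen2,
                 records$pred_mutationtaster)
  armPred <- rowSums(preds == "deleterious") >= 2L
  armHotspot <- records$hotspot

  ev <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    arms <- c("clinvar", "predictor_consensus", "hotspot")[
      c(armClinvar[i], armPred[i], armHotspot[i])]
    ev[i] <- paste(arms, collapse = ",")
  }
  records$in_driver_list <- inList
  records$pathogenic <- inList & (armClinvar | armPred | armHotspot)
  records$evidence <- ifelse(records$pathogenic, ev, "")
  records
}

#' Filter copy-number calls by gene-role directionality
#'
#' Keeps only biologically coherent events: amplifications (copy number > 2)
#' in oncogenes and deletions (copy number < 2) in tumor suppressors.
#' Copy-neutral calls (CN = 2) are always removed; genes with no assigned
#' role carry no directional rule and are removed.
#'
#' @param records Validated CNV data frame.
#' @return List with \code{kept} (records plus a \code{direction} column,
#'   \code{"amplification"} or \code{"deletion"}) and \code{removed}
#'   (records plus a \code{reason} column).
#' @export
filterCnvs <- function(records) {
  cn <- records$copy_number
  role <- records$gene_role
  keepAmp <- role == "oncogene" & cn > 2L
  keepDel <- role == "tsg" & cn < 2L
  keep <- keepAmp | keepDel

  kept <- records[keep, , drop = FALSE]
  kept$direction <- ifelse(keepAmp[keep], "amplification", "deletion")

  removed <- records[!keep, , drop = FALSE]
  reason <- character(nrow(removed))
  rcn <- removed$copy_number
  rrole <- removed$gene_role
  reason[rcn == 2L] <- "copy-neutral"
  reason[rrole == "unknown" & rcn != 2L] <- "no directional rule"
  reason[rrole == "oncogene" & rcn < 2L] <- "oncogene loss"
  reason[rrole == "tsg" & rcn > 2L] <- "tsg gain"
  removed$reason <- reason
  list(kept = kept, removed = removed)
}

#' Tumor mutational burden
#'
#' The number of filtered somatic mutations divided by the size in megabases
#' of the assayed coding territory (default 37 Mb). By default all filtered
#' coding events (synonymous, nonsynonymous, indels) are counted;
#' \code{nonsynOnly} restricts the numerator to nonsynonymous SNVs and
#' indels.
#'
#' @param records Filtered variant data frame for one sample.
#' @param exomeMb Assayed coding size in megabases; must be positive.
#' @param nonsynOnly Count only nonsynonymous SNVs and indels.
#' @return Mutations per megabase as an exact ratio.
#' @export
#' @examples
#' computeTmb(data.frame(consequence = rep("nonsynonymous", 37)))  # 1.0
computeTmb <- function(records, exomeMb = 37, nonsynOnly = FALSE) {
  if (!is.numeric(exomeMb) || length(exomeMb) != 1L || exomeMb <= 0)
    stop("config error: exomeMb must be a positive number")
  n <- if (nonsynOnly)
    sum(records$consequence %in% c("nonsynonymous", "indel"))
  else nrow(records)
  n / exomeMb
}
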