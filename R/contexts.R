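#' Canonical 96 trinucleotide context labels
#'
#' Single-base substitutions are described in a pyrimidine-centric frame:
#' six substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the
#' sixteen 5'/3' flanking-base combinations, giving 96 classes. The order is
#' substitution-major, then 5' flank, then 3' flank (the COSMIC v2 layout),
#' so published reference catalogs drop in unchanged.
#'
#' @return Character vector of 96 labels such as \code{"A[C>T]G"}.
#' @export
#' @examples
#' head(contextLabels96())
contextLabels96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    for (p5 in bases) {
      for (p3 in bases) {
        out <- c(out, paste0(p5, "[", s, "]", p3))
      }
    }
  }
  out
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp3 <- function(ctx) {
  x <- strsplit(ctx, "")[[1]]
  paste0(.COMP[[x[3]]], .COMP[[x[2]]], .COMP[[x[1]]])
}

#' Map an SNV to its pyrimidine-centric 96-context bin
#'
#' Purine-reference calls (ref A or G on the forward strand) are
#' reverse-complemented into the pyrimidine frame before binning.
#'
#' @param ref,alt Single reference/alternate bases on the forward strand.
#' @param context Three-base forward-strand context; its middle base must
#'   equal \code{ref}.
#' @return The bin label (an element of \code{contextLabels96()}).
#' @export
#' @examples
#' contextBin96("C", "T", "ACA")  # "A[C>T]A"
#' contextBin96("G", "A", "TGT")  # reverse complement -> "A[C>T]A"
contextBin96 <- function(ref, alt, context) {
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("contextBin96() is defined for single-base substitutions")
  if (is.na(context) || nchar(context) != 3L)
    stop("context must be a 3-base string")
  if (substr(context, 2L, 2L) != ref)
    stop("middle base of context ('", context, "') does not equal ref ('",
         ref, "')")
  if (ref %in% c("A", "G")) {
    ref <- .COMP[[ref]]
    alt <- .COMP[[alt]]
    context <- .revcomp3(context)
  }
  paste0(substr(context, 1L, 1L), "[", ref, ">", alt, "]",
         substr(context, 3L, 3L))
}

## Decompose a bin label into (fiveprime, ref, alt, threeprime)
.binParts <- function(label) {
  c(five = substr(label, 1L, 1L),
    ref = substr(label, 3L, 3L),
    alt = substr(label, 5L, 5L),
    three = substr(label, 7L, 7L))
}
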