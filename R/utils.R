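# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats median sd rnorm runif rbinom quantile setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string vector
#'
#' Thin wrapper around \code{Biostrings::reverseComplement} that accepts and
#' returns plain character vectors (ACGTN alphabet).
#'
#' @param x character vector of nucleotide sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# phred qualities from a Sanger-encoded quality string (offset 33)
phred_from_qual <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

# distance between two half-open intervals [s1,e1) and [s2,e2); 0 if they
# overlap or touch is counted as gap 0 only when overlapping (touching = 0 gap)
interval_gap <- function(s1, e1, s2, e2) {
  pmax(pmax(s1, s2) - pmin(e1, e2), 0L)
}

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(pmin(e1, e2) - pmax(s1, s2), 0L)
}

stage_log <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}
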