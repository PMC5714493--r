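#' @keywords internal
"_PACKAGE"

#' @import Biostrings
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges strand
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats qnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

## reverse complement for plain character vectors (DNA, N allowed)
rc_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## 0-based half-open genomic slice of a character sequence
slice0 <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

## genome (DNAStringSet) -> named character vector, computed once per call site
genome_chars <- function(genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  setNames(as.character(genome), names(genome))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom methods is
NULL
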