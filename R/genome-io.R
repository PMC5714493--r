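#' Read a genome from a FASTA file
#'
#' Reads DNA sequences into a [Biostrings::DNAStringSet], enforcing the
#' conventions used throughout the package: sequences are uppercased, RNA
#' `U` is mapped to `T`, the alphabet is restricted to `A,C,G,T,N`, record
#' ids (the first whitespace-delimited token of each header) must be unique
#' and every record must be non-empty.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet` over the alphabet `{A,C,G,T,N}`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[[1L]])
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0L)) {
    stop("empty record: ", ids[nchar(seqs) == 0L][[1L]])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1L], regexpr("[^ACGTN]", seqs[bad][1L]))
    stop("disallowed character '", ch, "' in record ", ids[bad][1L])
  }
  as_genome(setNames(seqs, ids))
}

#' Build a genome object from named character sequences
#'
#' @param x Named character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return A named `DNAStringSet`.
#' @export
as_genome <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  stopifnot(is.character(x), !is.null(names(x)))
  if (anyDuplicated(names(x))) {
    stop("duplicate id ", names(x)[duplicated(names(x))][[1L]])
  }
  if (any(nchar(x) == 0L)) stop("empty record")
  if (any(grepl("[^ACGTN]", x))) stop("disallowed character in sequence")
  Biostrings::DNAStringSet(x)
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output file path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Qualities are ignored; only the read sequences are used (junction
#' evidence is sequence identity of spanning reads). The format is chosen
#' from the first non-empty character of the file (`>` FASTA, `@` FASTQ).
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return A named `DNAStringSet` of reads.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- substr(trimws(readLines(path, n = 1L)), 1L, 1L)
  if (identical(first, "@")) {
    reads <- Biostrings::readDNAStringSet(path, format = "fastq")
    names(reads) <- sub("\\s.*$", "", names(reads))
    reads
  } else {
    read_genome(path)
  }
}
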