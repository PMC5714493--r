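#' Write a junction table
#'
#' Serializes junction calls as a tab-separated table with a header line
#' and BED-like 0-based half-open intron coordinates, sorted
#' deterministically by (seq_id, start, end).
#'
#' @param calls data.frame of junction calls with columns `seq_id, start,
#'   end, strand, donor, acceptor, support, n_ambiguous` (extra columns are
#'   preserved).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(calls, path) {
  need <- c("seq_id", "start", "end", "strand", "donor", "acceptor",
            "support", "n_ambiguous")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("missing junction column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(calls) && any(calls$start >= calls$end)) {
    stop("intron start must be < end")
  }
  calls <- calls[order(calls$seq_id, calls$start, calls$end), , drop = FALSE]
  calls <- calls[, c(need, setdiff(names(calls), need)), drop = FALSE]
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a junction table written by [write_junction_table()]
#'
#' @param path Path to the TSV file.
#' @return data.frame of junction calls.
#' @export
read_junction_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("seq_id", "strand", "donor", "acceptor")) {
    if (col %in% names(tab)) tab[[col]] <- as.character(tab[[col]])
  }
  tab
}
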