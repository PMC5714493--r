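#' Window specification for a splice-site alignment
#'
#' Default window sizes follow the conventional presentation of donor and
#' acceptor logos for this system: donors show 10 exon bases and 13 intron
#' bases; acceptors 16 intron bases and 7 exon bases.
#'
#' @param site `"donor"` or `"acceptor"`.
#' @param exon_side,intron_side Window lengths in nt (>= 1); defaults
#'   depend on `site`.
#' @return List of class `window_spec`.
#' @export
window_spec <- function(site = c("donor", "acceptor"),
                        exon_side = NULL, intron_side = NULL) {
  site <- match.arg(site)
  exon_side <- as.integer(exon_side %||% if (site == "donor") 10L else 7L)
  intron_side <- as.integer(intron_side %||% if (site == "donor") 13L else 16L)
  if (exon_side < 1L || intron_side < 1L) stop("window sides must be >= 1")
  structure(list(site = site, exon_side = exon_side,
                 intron_side = intron_side), class = "window_spec")
}

## transcribed-strand slice with N padding outside [0, len)
padded_slice <- function(seq, start0, end0, strand) {
  L <- nchar(seq)
  s <- max(start0, 0L)
  e <- min(end0, L)
  core <- if (s < e) slice0(seq, s, e) else ""
  out <- paste0(strrep("N", s - start0), core, strrep("N", end0 - e))
  if (strand == "-") rc_chr(out) else out
}

#' Extract aligned splice-site windows
#'
#' For each intron, extracts the transcribed-strand window around the
#' donor (exon end | intron start) or acceptor (intron end | exon start)
#' with the exact configured lengths; positions outside the sequence are
#' padded with `N`. Rows are returned in input order.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param introns data.frame with `seq_id, start, end, strand` (0-based
#'   half-open intron intervals).
#' @param spec A [window_spec()].
#' @return Character matrix, one row per intron, one column per window
#'   position; total width `exon_side + intron_side`.
#' @export
extract_windows <- function(genome, introns, spec) {
  chars <- if (is.character(genome)) genome else genome_chars(genome)
  w <- spec$exon_side + spec$intron_side
  rows <- vapply(seq_len(nrow(introns)), function(i) {
    seq <- chars[[introns$seq_id[i]]]
    s <- introns$start[i]
    e <- introns$end[i]
    strand <- introns$strand[i]
    if (spec$site == "donor") {
      if (strand == "+") {
        padded_slice(seq, s - spec$exon_side, s + spec$intron_side, "+")
      } else {
        padded_slice(seq, e - spec$intron_side, e + spec$exon_side, "-")
      }
    } else {
      if (strand == "+") {
        padded_slice(seq, e - spec$intron_side, e + spec$exon_side, "+")
      } else {
        padded_slice(seq, s - spec$exon_side, s + spec$intron_side, "-")
      }
    }
  }, character(1))
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  if (is.null(mat)) mat <- matrix(character(0), nrow = 0L, ncol = w)
  colnames(mat) <- window_positions(spec)
  mat
}

## position labels: exon side negative, intron side +1.. (donor) or
## intron side -.. and exon +1.. (acceptor)
window_positions <- function(spec) {
  if (spec$site == "donor") {
    c(paste0("E", -rev(seq_len(spec$exon_side))),
      paste0("I", seq_len(spec$intron_side)))
  } else {
    c(paste0("I", -rev(seq_len(spec$intron_side))),
      paste0("E", seq_len(spec$exon_side)))
  }
}

#' Per-position base counts and frequencies
#'
#' Counts `A,C,G,T` per window position; cells holding `N` are excluded
#' from that position's counts, so the effective sample size is tracked
#' per position. Frequencies use an additive pseudocount:
#' `(count + pseudocount) / (effective_n + 4 * pseudocount)`.
#'
#' @param windows Character matrix from [extract_windows()].
#' @param pseudocount Non-negative pseudocount.
#' @return List with `counts` (4 x width), `frequencies` (4 x width),
#'   `effective_n` (per position), `n_sequences`.
#' @export
position_frequencies <- function(windows, pseudocount = 0) {
  if (nrow(windows) == 0L) stop("no windows")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  counts <- apply(windows, 2L, function(col) {
    vapply(DNA_BASES4, function(b) sum(col == b), integer(1))
  })
  rownames(counts) <- DNA_BASES4
  eff_n <- colSums(counts)
  freq <- sweep(counts + pseudocount, 2L, eff_n + 4 * pseudocount, "/")
  list(counts = counts, frequencies = freq, effective_n = eff_n,
       n_sequences = nrow(windows))
}

#' Per-position information content in bits
#'
#' The classical sequence-logo measure `R(pos) = 2 - H(pos) - e(n)`, with
#' `H` the Shannon entropy in bits over `{A,C,G,T}` and the small-sample
#' correction `e(n) = 3 / (2 ln(2) n)` applied when
#' `small_sample_correction` is `TRUE`; corrected values are clamped at 0.
#'
#' @param frequencies 4 x width matrix of per-position base probabilities.
#' @param n_sequences Sequences behind each position (scalar or
#'   per-position vector; >= 1).
#' @param small_sample_correction Apply `e(n)`?
#' @return Numeric vector of per-position bits in `[0, 2]`.
#' @export
information_content <- function(frequencies, n_sequences,
                                small_sample_correction = TRUE) {
  if (any(n_sequences < 1L)) stop("n_sequences must be >= 1")
  H <- apply(frequencies, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  e <- if (small_sample_correction) 3 / (2 * log(2) * n_sequences) else 0
  pmin(2, pmax(0, 2 - H - e))
}

#' Build a motif matrix for a set of introns
#'
#' Convenience wrapper: extracts windows, computes counts, frequencies and
#' information content.
#'
#' @inheritParams extract_windows
#' @param pseudocount Passed to [position_frequencies()].
#' @param small_sample_correction Passed to [information_content()]
#'   (per-position effective n is used).
#' @return List of class `motif_matrix` with `window`, `n_sequences`,
#'   `counts`, `frequencies`, `effective_n`, `information`,
#'   `correction_applied`.
#' @export
motif_matrix <- function(genome, introns, spec = window_spec("donor"),
                         pseudocount = 0, small_sample_correction = TRUE) {
  windows <- extract_windows(genome, introns, spec)
  pf <- position_frequencies(windows, pseudocount)
  info <- information_content(pf$frequencies, pmax(pf$effective_n, 1L),
                              small_sample_correction)
  structure(list(window = spec, n_sequences = pf$n_sequences,
                 counts = pf$counts, frequencies = pf$frequencies,
                 effective_n = pf$effective_n, information = info,
                 correction_applied = isTRUE(small_sample_correction)),
            class = "motif_matrix")
}

#' Write a motif matrix as TSV
#'
#' One row per window position with base counts, frequencies, effective n
#' and information content — the machine-readable form of a sequence logo.
#'
#' @param m A [motif_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_matrix <- function(m, path) {
  tab <- data.frame(position = colnames(m$counts),
                    t(m$counts), t(m$frequencies),
                    effective_n = m$effective_n,
                    information = m$information)
  names(tab) <- c("position", paste0("count_", DNA_BASES4),
                  paste0("freq_", DNA_BASES4), "effective_n",
                  "information_bits")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a sequence logo as stacked information bars
#'
#' A simple rendering of the information-content profile: per position,
#' bases stack to a total height of the position's information (bits),
#' each base's share proportional to its frequency. Requires ggplot2.
#'
#' @param m A [motif_matrix()].
#' @return A ggplot object.
#' @export
plot_logo <- function(m) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  w <- ncol(m$counts)
  df <- do.call(rbind, lapply(seq_len(w), function(j) {
    data.frame(pos = j, label = colnames(m$counts)[j], base = DNA_BASES4,
               height = m$frequencies[, j] * m$information[j])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$height,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_x_continuous(breaks = seq_len(w),
                                labels = colnames(m$counts)) +
    ggplot2::scale_fill_manual(values = c(A = "#1b9e77", C = "#377eb8",
                                          G = "#ff7f00", T = "#e41a1c")) +
    ggplot2::labs(x = "position", y = "bits",
                  title = sprintf("%s site logo (n = %d)", m$window$site,
                                  m$n_sequences)) +
    ggplot2::theme_minimal()
}
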