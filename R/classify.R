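#' Classify one intron by its splice-site dinucleotides
#'
#' Reads the donor and acceptor dinucleotides, intron position 3, and the
#' last two bases of the preceding exon, all on the transcribed strand
#' (minus-strand slices are reverse-complemented), and derives the donor
#' class (GT/GC/GA/GG/other), acceptor class (AG/other) and intron phase.
#' Any `N` in a field makes the corresponding class `"other"`.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param seq_id Sequence id.
#' @param start,end Intron interval, 0-based half-open on the plus axis.
#' @param strand `"+"` or `"-"`.
#' @param cds_before Coding nucleotides upstream of the intron (`NA` for
#'   introns 5' of the coding start; phase is then `NA`).
#' @return One-row data.frame: `donor_class, acceptor_class, donor,
#'   acceptor, pos3, exon_end, phase`.
#' @export
classify_intron <- function(genome, seq_id, start, end, strand,
                            cds_before = NA_integer_) {
  chars <- if (is.character(genome)) genome else genome_chars(genome)
  if (!seq_id %in% names(chars)) stop("unknown sequence ", seq_id)
  seq <- chars[[seq_id]]
  if (start < 0L || end > nchar(seq)) stop("intron out of bounds on ", seq_id)
  if (end - start < 4L) stop("intron shorter than 4 nt")
  if (strand == "+") {
    donor <- slice0(seq, start, start + 2L)
    pos3 <- slice0(seq, start + 2L, start + 3L)
    acceptor <- slice0(seq, end - 2L, end)
    exon_end <- if (start >= 2L) slice0(seq, start - 2L, start) else NA_character_
  } else {
    donor <- rc_chr(slice0(seq, end - 2L, end))
    pos3 <- rc_chr(slice0(seq, end - 3L, end - 2L))
    acceptor <- rc_chr(slice0(seq, start, start + 2L))
    exon_end <- if (end + 2L <= nchar(seq)) rc_chr(slice0(seq, end, end + 2L))
                else NA_character_
  }
  donor_class <- if (donor %in% DONOR_PRIORITY) donor else "other"
  acceptor_class <- if (identical(acceptor, "AG")) "AG" else "other"
  phase <- if (is.na(cds_before)) NA_integer_ else as.integer(cds_before %% 3L)
  data.frame(donor_class = donor_class, acceptor_class = acceptor_class,
             donor = donor, acceptor = acceptor, pos3 = pos3,
             exon_end = exon_end, phase = phase)
}

#' Classify every intron of a set of gene models
#'
#' @param models List of [gene_model()] objects.
#' @param genome `DNAStringSet` or named character vector.
#' @return data.frame: one row per intron (transcript order within gene)
#'   with interval, strand and the [classify_intron()] fields.
#' @export
classify_model_introns <- function(models, genome) {
  chars <- if (is.character(genome)) genome else genome_chars(genome)
  rows <- lapply(models, function(m) {
    intr <- model_introns(m)
    if (!nrow(intr)) return(NULL)
    cls <- do.call(rbind, lapply(seq_len(nrow(intr)), function(i) {
      classify_intron(chars, intr$seq_id[i], intr$start[i], intr$end[i],
                      intr$strand[i], intr$cds_before[i])
    }))
    cbind(intr, cls)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene_id = character(), intron_index = integer(),
                      seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      cds_before = integer(), donor_class = character(),
                      acceptor_class = character(), donor = character(),
                      acceptor = character(), pos3 = character(),
                      exon_end = character(), phase = integer()))
  }
  rownames(out) <- NULL
  out
}

#' Classify discovered junction calls
#'
#' Classifies each junction call's intron from the genome and, when gene
#' models are supplied, assigns each call to the gene whose span contains
#' it (for per-gene tabulation).
#'
#' @param calls data.frame from [discover_junctions()] (flagged calls with
#'   `pass_filter = FALSE` are dropped when the column is present).
#' @param genome `DNAStringSet` or named character vector.
#' @param models Optional list of [gene_model()] objects.
#' @return data.frame of classified introns with a `gene_id` column
#'   (`NA` when unassigned).
#' @export
classify_junctions <- function(calls, genome, models = NULL) {
  if ("pass_filter" %in% names(calls)) {
    calls <- calls[calls$pass_filter, , drop = FALSE]
  }
  chars <- if (is.character(genome)) genome else genome_chars(genome)
  gene_of <- function(seq_id, start, end, strand) {
    if (is.null(models)) return(NA_character_)
    for (m in models) {
      span <- c(m$exons[1L, "start"], m$exons[nrow(m$exons), "end"])
      if (m$seq_id == seq_id && m$strand == strand &&
          start >= span[1L] && end <= span[2L]) {
        return(m$gene_id)
      }
    }
    NA_character_
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    cls <- classify_intron(chars, calls$seq_id[i], calls$start[i],
                           calls$end[i], calls$strand[i])
    cbind(data.frame(gene_id = gene_of(calls$seq_id[i], calls$start[i],
                                       calls$end[i], calls$strand[i]),
                     seq_id = calls$seq_id[i], start = calls$start[i],
                     end = calls$end[i], strand = calls$strand[i],
                     support = calls$support[i]),
          cls)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), seq_id = character(),
               start = integer(), end = integer(), strand = character(),
               support = integer(), donor_class = character(),
               acceptor_class = character(), donor = character(),
               acceptor = character(), pos3 = character(),
               exon_end = character(), phase = integer())
  rownames(out) <- NULL
  out
}

#' Wilson score interval for a binomial proportion
#'
#' Closed-form Wilson interval bounds in `[0, 1]`.
#'
#' @param successes Number of successes (0..trials).
#' @param trials Number of trials (>= 1).
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
wilson_interval <- function(successes, trials, confidence = 0.95) {
  if (trials < 1L) stop("trials must be >= 1")
  if (successes < 0L || successes > trials) {
    stop("successes must be in [0, trials]")
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Tabulate donor classes per gene and genome-wide
#'
#' Builds a per-gene table of intron and donor-class counts plus totals,
#' the exact noncanonical (GA+GG) fraction with a 95\% Wilson interval,
#' and the fraction rounded half-up to the nearest whole percent (the
#' conventional presentation).
#'
#' @param classified data.frame of classified introns (from
#'   [classify_model_introns()] or [classify_junctions()]) with columns
#'   `gene_id` and `donor_class`.
#' @param confidence Confidence level for the Wilson interval.
#' @return List of class `donor_summary`: `per_gene` (data.frame),
#'   `totals` (named counts), `n_introns`, `noncanonical_fraction`,
#'   `noncanonical_percent_rounded`, `wilson` (low/high).
#' @export
tabulate_donors <- function(classified, confidence = 0.95) {
  classes <- c(DONOR_PRIORITY, "other")
  gid <- classified$gene_id
  gid[is.na(gid)] <- "(unassigned)"
  per_gene <- do.call(rbind, lapply(sort(unique(gid)), function(g) {
    dc <- classified$donor_class[gid == g]
    counts <- vapply(classes, function(cl) sum(dc == cl), integer(1))
    data.frame(gene_id = g, intron_count = length(dc),
               GT = counts[["GT"]], GC = counts[["GC"]],
               GA = counts[["GA"]], GG = counts[["GG"]],
               other = counts[["other"]])
  }))
  if (is.null(per_gene)) {
    per_gene <- data.frame(gene_id = character(), intron_count = integer(),
                           GT = integer(), GC = integer(), GA = integer(),
                           GG = integer(), other = integer())
  }
  totals <- vapply(c("intron_count", classes),
                   function(cl) sum(per_gene[[cl]] %||% integer(0)),
                   integer(1))
  names(totals)[1L] <- "introns"
  n <- totals[["introns"]]
  nonc <- totals[["GA"]] + totals[["GG"]]
  frac <- if (n > 0L) nonc / n else NA_real_
  structure(list(
    per_gene = per_gene,
    totals = totals,
    n_introns = n,
    noncanonical_count = nonc,
    noncanonical_fraction = frac,
    noncanonical_percent_rounded = if (is.na(frac)) NA_integer_
                                   else as.integer(floor(frac * 100 + 0.5)),
    wilson = if (n > 0L) wilson_interval(nonc, n, confidence)
             else c(low = NA_real_, high = NA_real_)),
    class = "donor_summary")
}

#' @export
print.donor_summary <- function(x, ...) {
  cat("Donor class summary over", x$n_introns, "introns\n")
  print(x$per_gene, row.names = FALSE)
  cat("totals:", paste(names(x$totals), x$totals, sep = "=",
                       collapse = " "), "\n")
  if (!is.na(x$noncanonical_fraction)) {
    cat(sprintf(
      "noncanonical (GA+GG): %d/%d = %.4f (%d%%), 95%% CI [%.4f, %.4f]\n",
      x$noncanonical_count, x$n_introns, x$noncanonical_fraction,
      x$noncanonical_percent_rounded, x$wilson[["low"]],
      x$wilson[["high"]]))
  } else {
    cat("noncanonical (GA+GG): not available (no introns)\n")
  }
  invisible(x)
}

#' Donor summary from curated per-gene counts
#'
#' Builds a [tabulate_donors()]-style summary directly from published
#' per-gene GA/GG tallies when the underlying sequences are not machine
#' readable; remaining introns are attributed to the canonical GT class.
#'
#' @param gene_id Character vector of gene ids.
#' @param introns Intron count per gene.
#' @param GA,GG Noncanonical donor counts per gene.
#' @param confidence Confidence level for the Wilson interval.
#' @return A `donor_summary`.
#' @export
donor_summary_from_counts <- function(gene_id, introns, GA, GG,
                                      confidence = 0.95) {
  stopifnot(length(gene_id) == length(introns),
            length(GA) == length(introns), length(GG) == length(introns))
  classified <- do.call(rbind, lapply(seq_along(gene_id), function(i) {
    data.frame(gene_id = gene_id[i],
               donor_class = c(rep("GA", GA[i]), rep("GG", GG[i]),
                               rep("GT", introns[i] - GA[i] - GG[i])))
  }))
  tabulate_donors(classified, confidence = confidence)
}
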