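#' Construct a gene model
#'
#' A gene model is a stranded chain of exons on one sequence, with an
#' optional offset of the first coding base into the first exon (in
#' transcript order). All coordinates are 0-based half-open on the plus
#' genomic axis; on the minus strand, transcript order is the reverse of
#' genomic order. The coding sequence is taken to run from
#' `cds_start_offset` to the end of the transcript.
#'
#' @param gene_id Gene identifier.
#' @param seq_id Sequence (scaffold) identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of exon `start`/`end`
#'   (0-based half-open), ascending and non-overlapping on the genomic axis.
#' @param cds_start_offset Non-negative integer: transcript-order offset of
#'   the first coding base (0 = fully coding from the first exon base).
#' @param donor_classes Optional character vector of per-intron donor class
#'   labels, in transcript order.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, exons, cds_start_offset = 0L,
                       donor_classes = NULL) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  n <- nrow(exons)
  if (n < 1L) stop("gene ", gene_id, ": no exons")
  if (any(exons[, "end"] - exons[, "start"] < 1L)) {
    stop("gene ", gene_id, ": exon length < 1")
  }
  if (n > 1L) {
    if (is.unsorted(exons[, "start"], strictly = TRUE)) {
      stop("gene ", gene_id, ": exons unsorted")
    }
    gaps <- exons[-1L, "start"] - exons[-n, "end"]
    if (any(gaps < 0L)) stop("gene ", gene_id, ": overlapping exons")
    if (any(gaps < 4L)) stop("gene ", gene_id, ": intron shorter than 4 nt")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  cds_start_offset <- as.integer(cds_start_offset)
  if (cds_start_offset < 0L) stop("cds_start_offset must be >= 0")
  if (!is.null(donor_classes) && length(donor_classes) != n - 1L) {
    stop("gene ", gene_id, ": need one donor class per intron")
  }
  structure(
    list(gene_id = as.character(gene_id), seq_id = as.character(seq_id),
         strand = strand, exons = exons,
         cds_start_offset = cds_start_offset,
         donor_classes = donor_classes),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model ", x$gene_id, " (", x$seq_id, x$strand, "): ",
      nrow(x$exons), " exons, span ", x$exons[1L, "start"], "-",
      x$exons[nrow(x$exons), "end"], "\n", sep = "")
  invisible(x)
}

n_introns <- function(model) nrow(model$exons) - 1L

## exon genomic intervals in transcript order
exons_tx_order <- function(model) {
  ex <- model$exons
  if (model$strand == "-") ex[rev(seq_len(nrow(ex))), , drop = FALSE] else ex
}

#' Intron table of a gene model
#'
#' One row per intron in transcript order, with genomic interval (0-based
#' half-open), strand, and the number of coding nucleotides upstream of the
#' intron (`NA` while the intron lies 5' of the coding start).
#'
#' @param model A `gene_model`.
#' @return data.frame with columns `gene_id, intron_index, seq_id, start,
#'   end, strand, cds_before`.
#' @export
model_introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(data.frame(gene_id = character(), intron_index = integer(),
                      seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      cds_before = integer()))
  }
  gaps <- cbind(start = ex[-n, "end"], end = ex[-1L, "start"])
  if (model$strand == "-") gaps <- gaps[rev(seq_len(n - 1L)), , drop = FALSE]
  exlen_tx <- {
    e <- exons_tx_order(model)
    e[, "end"] - e[, "start"]
  }
  tx_before <- cumsum(exlen_tx)[seq_len(n - 1L)]
  cds_before <- tx_before - model$cds_start_offset
  cds_before[cds_before < 0L] <- NA_integer_
  data.frame(gene_id = model$gene_id, intron_index = seq_len(n - 1L),
             seq_id = model$seq_id, start = unname(gaps[, "start"]),
             end = unname(gaps[, "end"]), strand = model$strand,
             cds_before = as.integer(cds_before))
}

#' Spliced transcript sequence of a gene model
#'
#' @param model A `gene_model`.
#' @param genome `DNAStringSet` (or named character) holding `seq_id`.
#' @return Single character string: the exon chain on the transcribed strand.
#' @export
transcript_seq <- function(model, genome) {
  chars <- if (is.character(genome)) genome else genome_chars(genome)
  seq <- chars[[model$seq_id]]
  parts <- apply(model$exons, 1L, function(e) slice0(seq, e[[1L]], e[[2L]]))
  joined <- paste(parts, collapse = "")
  if (model$strand == "-") rc_chr(joined) else joined
}

cds_length <- function(model) {
  sum(model$exons[, "end"] - model$exons[, "start"]) - model$cds_start_offset
}

#' Read gene models from GFF3
#'
#' Expects standard gene/mRNA/exon/CDS features with `ID`/`Parent`
#' attributes; one mRNA per gene. GFF3 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention at this
#' boundary, and exon chains are validated against the genome bounds.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional `DNAStringSet` used to validate exon bounds.
#' @return List of `gene_model` objects, ordered by gene id.
#' @export
read_gene_models <- function(path, genome = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gff)
  typ <- as.character(md$type)
  parent_of <- function(i) {
    p <- md$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }
  parents <- vapply(seq_along(gff), parent_of, character(1))
  mrna_idx <- which(typ == "mRNA")
  mrna_gene <- parents[mrna_idx]
  mrna_id <- as.character(md$ID[mrna_idx])
  models <- vector("list", length(mrna_idx))
  for (j in seq_along(mrna_idx)) {
    mid <- mrna_id[[j]]
    gid <- mrna_gene[[j]]
    if (is.na(gid)) gid <- mid
    child <- which(!is.na(parents) & parents == mid)
    ex_i <- child[typ[child] == "exon"]
    cds_i <- child[typ[child] == "CDS"]
    if (length(ex_i) == 0L) stop("mRNA ", mid, " has no exons")
    seq_id <- as.character(GenomicRanges::seqnames(gff))[ex_i[1L]]
    strand <- as.character(GenomicRanges::strand(gff))[ex_i[1L]]
    if (!strand %in% c("+", "-")) strand <- "+"
    st <- GenomicRanges::start(gff)[ex_i] - 1L   # to 0-based
    en <- GenomicRanges::end(gff)[ex_i]          # half-open
    o <- order(st)
    exons <- cbind(start = st[o], end = en[o])
    if (!is.null(genome)) {
      L <- Biostrings::width(genome)[match(seq_id, names(genome))]
      if (is.na(L)) stop("sequence ", seq_id, " absent from genome")
      if (any(exons[, "end"] > L)) {
        stop("mRNA ", mid, ": exon beyond end of ", seq_id)
      }
    }
    cds_off <- 0L
    if (length(cds_i)) {
      cst <- GenomicRanges::start(gff)[cds_i] - 1L
      cen <- GenomicRanges::end(gff)[cds_i]
      cds_first <- if (strand == "+") min(cst) else max(cen)
      ex_tx <- if (strand == "+") exons[order(exons[, "start"]), , drop = FALSE]
               else exons[order(-exons[, "start"]), , drop = FALSE]
      off <- 0L
      for (r in seq_len(nrow(ex_tx))) {
        s <- ex_tx[r, "start"]; e <- ex_tx[r, "end"]
        if (strand == "+") {
          if (cds_first >= s && cds_first < e) { off <- off + (cds_first - s); break }
        } else {
          if (cds_first > s && cds_first <= e) { off <- off + (e - cds_first); break }
        }
        off <- off + (e - s)
      }
      cds_off <- as.integer(off)
    }
    dc <- md$donor_classes[mrna_idx[j]]
    dc <- if (!is.null(dc) && !is.na(dc)) strsplit(dc, ",", fixed = TRUE)[[1L]]
          else NULL
    models[[j]] <- gene_model(gid, seq_id, strand, exons,
                              cds_start_offset = cds_off, donor_classes = dc)
  }
  models[order(vapply(models, `[[`, character(1), "gene_id"))]
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features (CDS from the coding start to
#' the transcript end), converting internal 0-based half-open intervals to
#' GFF3's 1-based inclusive coordinates. Per-intron donor class labels, if
#' present, are stored in a `donor_classes` attribute of the mRNA.
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- list()
  for (m in models) {
    ex <- m$exons
    n <- nrow(ex)
    span <- c(ex[1L, "start"], ex[n, "end"])
    mid <- paste0(m$gene_id, ".t1")
    dc <- if (!is.null(m$donor_classes)) paste(m$donor_classes, collapse = ",")
          else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      seq = m$seq_id, type = "gene", start = span[1L], end = span[2L],
      strand = m$strand, ID = m$gene_id, Parent = NA_character_,
      donor_classes = NA_character_, phase = NA_integer_)
    rows[[length(rows) + 1L]] <- data.frame(
      seq = m$seq_id, type = "mRNA", start = span[1L], end = span[2L],
      strand = m$strand, ID = mid, Parent = m$gene_id, donor_classes = dc,
      phase = NA_integer_)
    ## CDS intervals: transcript positions >= cds_start_offset
    ex_tx <- exons_tx_order(m)
    off <- m$cds_start_offset
    cds <- NULL
    cum <- 0L
    for (r in seq_len(n)) {
      w <- ex_tx[r, "end"] - ex_tx[r, "start"]
      if (off >= w) { off <- off - w; next }
      s <- ex_tx[r, "start"]; e <- ex_tx[r, "end"]
      if (m$strand == "+") s <- s + off else e <- e - off
      off <- 0L
      cds <- rbind(cds, c(s, e, (3L - cum %% 3L) %% 3L))
      cum <- cum + (e - s)
    }
    for (r in seq_len(n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq = m$seq_id, type = "exon", start = ex[r, "start"],
        end = ex[r, "end"], strand = m$strand,
        ID = sprintf("%s.exon%d", m$gene_id, r), Parent = mid,
        donor_classes = NA_character_, phase = NA_integer_)
    }
    if (!is.null(cds)) {
      cds <- cds[order(cds[, 1L]), , drop = FALSE]
      for (r in seq_len(nrow(cds))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq = m$seq_id, type = "CDS", start = cds[r, 1L],
          end = cds[r, 2L], strand = m$strand,
          ID = sprintf("%s.cds%d", m$gene_id, r), Parent = mid,
          donor_classes = NA_character_, phase = cds[r, 3L])
      }
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seq,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$ID <- tab$ID
  S4Vectors::mcols(gr)$Parent <- tab$Parent
  S4Vectors::mcols(gr)$donor_classes <- tab$donor_classes
  S4Vectors::mcols(gr)$phase <- as.integer(tab$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
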