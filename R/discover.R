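DONOR_PRIORITY <- c("GT", "GC", "GA", "GG")

#' Admissible donor dinucleotides for a donor-acceptance mode
#'
#' Modes mirror how spliced aligners constrain the intron's first two
#' bases: `"gt"` admits only GT, `"gy"` GT or GC (the common default, and
#' the constraint that makes GA/GG introns invisible to standard mappers),
#' `"g"` any G-starting dinucleotide (GT, GC, GA, GG), and `"any"` no
#' donor constraint. The acceptor must be AG in every mode.
#'
#' @param mode One of `"gt"`, `"gy"`, `"g"`, `"any"`.
#' @return Character vector of admissible donors, or `NULL` for `"any"`.
#' @export
donor_mode_set <- function(mode) {
  switch(match.arg(mode, c("gt", "gy", "g", "any")),
         gt = "GT",
         gy = c("GT", "GC"),
         g = c("GT", "GC", "GA", "GG"),
         any = NULL)
}

donor_admissible <- function(donor, mode) {
  if (grepl("N", donor, fixed = TRUE)) return(FALSE)
  set <- donor_mode_set(mode)
  is.null(set) || donor %in% set
}

donor_rank <- function(donor) {
  r <- match(donor, DONOR_PRIORITY)
  ifelse(is.na(r), length(DONOR_PRIORITY) + 1L, r)
}

#' Test whether a [call_junction()] result is a no-call
#'
#' @param x Result of [call_junction()].
#' @return `TRUE` for a no-call sentinel (its reason code is in
#'   `x$reason`), `FALSE` for a junction call.
#' @export
is_no_call <- function(x) inherits(x, "junction_no_call")

#' Find exact terminal k-mer anchors of a read
#'
#' Matches the first and last k-mer of the read (and, for the minus
#' strand, of its reverse complement) exactly against the genome. Hits are
#' reported in the aligned-read frame: for a minus-strand hit the aligned
#' read is the reverse complement of the input read, and `read_offset` is
#' the k-mer's offset within that aligned read (0 for the left anchor,
#' `length - k` for the right).
#'
#' @param read Read sequence (character).
#' @param genome `DNAStringSet` or named character vector.
#' @param k Anchor k-mer length (>= 11).
#' @return data.frame with columns `read_offset, seq_id, genome_offset,
#'   strand, side` (`"left"`/`"right"`); 0-based genome offsets.
#' @export
find_anchors <- function(read, genome, k = 16L) {
  if (k < 11L) stop("k must be >= 11")
  L <- nchar(read)
  empty <- data.frame(read_offset = integer(), seq_id = character(),
                      genome_offset = integer(), strand = character(),
                      side = character())
  if (L < 2L * k) return(empty)
  chars <- if (is.character(genome)) genome else genome_chars(genome)
  hits <- list(empty)
  frames <- list(`+` = read, `-` = rc_chr(read))
  for (strand in names(frames)) {
    r <- frames[[strand]]
    for (side in c("left", "right")) {
      off <- if (side == "left") 0L else L - k
      kmer <- substr(r, off + 1L, off + k)
      if (grepl("N", kmer, fixed = TRUE)) next
      for (sid in names(chars)) {
        m <- Biostrings::matchPattern(kmer, chars[[sid]])
        if (length(m)) {
          hits[[length(hits) + 1L]] <- data.frame(
            read_offset = off, seq_id = sid,
            genome_offset = BiocGenerics::start(m) - 1L,
            strand = strand, side = side)
        }
      }
    }
  }
  do.call(rbind, hits)
}

char_vec <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

## donor/acceptor dinucleotides of a genomic intron on the transcribed strand
intron_dinucs <- function(seq, start0, end0, strand) {
  if (strand == "+") {
    c(donor = slice0(seq, start0, start0 + 2L),
      acceptor = slice0(seq, end0 - 2L, end0))
  } else {
    c(donor = rc_chr(slice0(seq, end0 - 2L, end0)),
      acceptor = rc_chr(slice0(seq, start0, start0 + 2L)))
  }
}

#' Call a splice junction from one anchored read
#'
#' Given colinear left/right anchors of an (aligned-frame) read on one
#' strand of one sequence, enumerates every split position at which the
#' read is explained exactly as the concatenation of a left and a right
#' genomic slice, keeps the placements whose intron starts with a donor
#' admissible under `mode` and ends with AG, and reports the placement
#' selected by donor priority (GT > GC > GA > GG), then leftmost genomic
#' interval. All admissible placements are kept in the ambiguity set.
#'
#' @param read Read sequence in the aligned frame (already
#'   reverse-complemented for minus-strand placements).
#' @param genome `DNAStringSet` or named character vector.
#' @param left_anchor,right_anchor Single rows of [find_anchors()] output
#'   (lists or 1-row data.frames with `seq_id, genome_offset, strand`).
#' @param mode Donor-acceptance mode, see [donor_mode_set()].
#' @param k Anchor k-mer length used to produce the anchors.
#' @param min_anchor Minimum matched nt on each side of the junction.
#' @param mismatch_budget Maximum substitutions tolerated outside the
#'   `min_anchor` windows around the junction (0-2).
#' @return A one-row data.frame (`seq_id, start, end, strand, donor,
#'   acceptor, n_ambiguous, ambiguity, chosen_by`) or a no-call sentinel
#'   (see [is_no_call()]) carrying the reason code in `$reason`.
#' @export
call_junction <- function(read, genome, left_anchor, right_anchor,
                          mode = "gy", k = 16L, min_anchor = 8L,
                          mismatch_budget = 0L) {
  no_call <- function(reason) {
    structure(list(reason = reason), class = "junction_no_call")
  }
  if (mismatch_budget > 2L) stop("mismatch_budget must be 0-2")
  la <- as.list(left_anchor)
  ra <- as.list(right_anchor)
  if (!identical(la$seq_id, ra$seq_id)) return(no_call("different_sequences"))
  if (!identical(la$strand, ra$strand)) return(no_call("different_strands"))
  chars <- if (is.character(genome)) genome else genome_chars(genome)
  seq <- chars[[la$seq_id]]
  L <- nchar(read)
  gL <- la$genome_offset
  aR <- ra$genome_offset
  glen <- aR - (L - k) - gL
  if (glen < 4L) return(no_call("gap_too_short"))
  if (gL < 0L || aR + k > nchar(seq)) return(no_call("out_of_bounds"))
  suf_start <- aR + k - L              # 0-based start of the suffix frame
  GL <- slice0(seq, gL, gL + L)
  GR <- slice0(seq, suf_start, suf_start + L)
  rv <- char_vec(read)
  eqL <- rv == char_vec(GL)
  eqR <- rv == char_vec(GR)
  mismL <- cumsum(!eqL)
  mismR_tail <- rev(cumsum(rev(!eqR)))   # mismatches in read[p..L]
  ps <- seq.int(min_anchor, L - min_anchor)
  keep <- logical(length(ps))
  for (i in seq_along(ps)) {
    p <- ps[i]
    mm <- mismL[p] + if (p < L) mismR_tail[p + 1L] else 0L
    if (mm > mismatch_budget) next
    near_l <- seq.int(p - min_anchor + 1L, p)
    near_r <- seq.int(p + 1L, p + min_anchor)
    if (!all(eqL[near_l]) || !all(eqR[near_r])) next
    keep[i] <- TRUE
  }
  ps <- ps[keep]
  if (!length(ps)) return(no_call("no_exact_split"))
  strand <- la$strand
  placements <- lapply(ps, function(p) {
    s <- gL + p
    e <- s + glen
    di <- intron_dinucs(seq, s, e, strand)
    list(start = s, end = e, donor = di[["donor"]],
         acceptor = di[["acceptor"]])
  })
  ok <- vapply(placements, function(pl) {
    pl$acceptor == "AG" && donor_admissible(pl$donor, mode)
  }, logical(1))
  placements <- placements[ok]
  if (!length(placements)) return(no_call("no_admissible_donor"))
  ranks <- vapply(placements, function(pl) donor_rank(pl$donor), numeric(1))
  starts <- vapply(placements, `[[`, numeric(1), "start")
  best <- order(ranks, starts)[1L]
  pl <- placements[[best]]
  data.frame(
    seq_id = la$seq_id, start = pl$start, end = pl$end, strand = strand,
    donor = pl$donor, acceptor = pl$acceptor,
    n_ambiguous = length(placements),
    ambiguity = paste(sprintf("%d-%d", starts,
                              starts + (pl$end - pl$start)), collapse = ";"),
    chosen_by = if (length(placements) == 1L) "unique"
                else "donor_priority_leftmost")
}

#' Discover splice junctions from a read set
#'
#' Anchors every read by its terminal k-mers on both genome strands (via a
#' batched exact k-mer lookup), calls a junction per read with
#' [call_junction()], merges identical calls across reads, and reports
#' per-junction support. Calls with fewer than `min_support` reads are
#' retained but flagged (`pass_filter = FALSE`); downstream summaries
#' count only passing calls.
#'
#' @param reads `DNAStringSet` or named character vector of reads.
#' @param genome `DNAStringSet` or named character vector.
#' @param mode Donor-acceptance mode, see [donor_mode_set()].
#' @param k Anchor k-mer length.
#' @param min_anchor Minimum matched nt each side of the junction.
#' @param min_support Reads required for `pass_filter = TRUE`.
#' @param mismatch_budget Substitutions tolerated per read (see
#'   [call_junction()]).
#' @param max_intron Maximum intron length considered.
#' @return data.frame of junction calls sorted by (seq_id, start, end)
#'   with columns `seq_id, start, end, strand, donor, acceptor, support,
#'   n_ambiguous, pass_filter`.
#' @export
discover_junctions <- function(reads, genome, mode = "gy", k = 16L,
                               min_anchor = 8L, min_support = 2L,
                               mismatch_budget = 0L, max_intron = 100000L) {
  read_chr <- if (is.character(reads)) reads else
    setNames(as.character(reads), names(reads))
  chars <- if (is.character(genome)) genome else genome_chars(genome)
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      donor = character(), acceptor = character(),
                      support = integer(), n_ambiguous = integer(),
                      pass_filter = logical())
  if (!length(read_chr)) return(empty)

  ## batched anchor lookup over all unique terminal k-mers
  Ls <- nchar(read_chr)
  usable <- Ls >= 2L * k
  read_chr <- read_chr[usable]
  Ls <- Ls[usable]
  if (!length(read_chr)) return(empty)
  rc_reads <- rc_chr(read_chr)
  kmers <- unique(c(substr(read_chr, 1L, k),
                    substr(read_chr, Ls - k + 1L, Ls),
                    substr(rc_reads, 1L, k),
                    substr(rc_reads, Ls - k + 1L, Ls)))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  hit_env <- new.env(hash = TRUE, parent = emptyenv())
  if (length(kmers)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
    for (sid in names(chars)) {
      subject <- Biostrings::DNAString(chars[[sid]])
      ml <- Biostrings::matchPDict(pd, subject)
      nh <- S4Vectors::elementNROWS(ml)
      for (i in which(nh > 0L)) {
        st <- BiocGenerics::start(ml[[i]])
        key <- kmers[i]
        cur <- if (exists(key, hit_env)) get(key, hit_env) else NULL
        assign(key, rbind(cur, cbind(seq = match(sid, names(chars)),
                                     pos = st - 1L)), hit_env)
      }
    }
  }
  lookup <- function(kmer) {
    if (grepl("N", kmer, fixed = TRUE) || !exists(kmer, hit_env)) return(NULL)
    get(kmer, hit_env)
  }

  calls <- list()
  for (ri in seq_along(read_chr)) {
    L <- Ls[ri]
    frames <- list(`+` = read_chr[[ri]], `-` = rc_reads[[ri]])
    read_calls <- list()
    for (strand in c("+", "-")) {
      r <- frames[[strand]]
      hl <- lookup(substr(r, 1L, k))
      hr <- lookup(substr(r, L - k + 1L, L))
      if (is.null(hl) || is.null(hr)) next
      for (a in seq_len(nrow(hl))) {
        same <- hr[hr[, "seq"] == hl[a, "seq"], , drop = FALSE]
        if (!nrow(same)) next
        glen <- same[, "pos"] - (L - k) - hl[a, "pos"]
        same <- same[glen >= 4L & glen <= max_intron, , drop = FALSE]
        for (b in seq_len(nrow(same))) {
          sid <- names(chars)[hl[a, "seq"]]
          cl <- call_junction(
            r, chars,
            list(read_offset = 0L, seq_id = sid,
                 genome_offset = unname(hl[a, "pos"]), strand = strand),
            list(read_offset = L - k, seq_id = sid,
                 genome_offset = unname(same[b, "pos"]), strand = strand),
            mode = mode, k = k, min_anchor = min_anchor,
            mismatch_budget = mismatch_budget)
          if (!is_no_call(cl)) read_calls[[length(read_calls) + 1L]] <- cl
        }
      }
    }
    if (!length(read_calls)) next
    rc_tab <- do.call(rbind, read_calls)
    rc_tab <- rc_tab[!duplicated(rc_tab[, c("seq_id", "start", "end",
                                            "strand")]), , drop = FALSE]
    o <- order(donor_rank(rc_tab$donor), rc_tab$seq_id, rc_tab$start,
               rc_tab$strand)
    calls[[length(calls) + 1L]] <- rc_tab[o[1L], , drop = FALSE]
  }
  if (!length(calls)) return(empty)
  tab <- do.call(rbind, calls)
  key <- paste(tab$seq_id, tab$start, tab$end, tab$strand, sep = "\r")
  agg <- lapply(split(seq_len(nrow(tab)), key), function(ix) {
    row <- tab[ix[1L], c("seq_id", "start", "end", "strand", "donor",
                         "acceptor")]
    row$support <- length(ix)
    row$n_ambiguous <- max(tab$n_ambiguous[ix])
    row
  })
  out <- do.call(rbind, agg)
  out$pass_filter <- out$support >= min_support
  out <- out[order(out$seq_id, out$start, out$end, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
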