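## Small in-code fixtures and independent oracles shared across test files.

## a tiny simulation config that runs in well under a second
tiny_config <- function(seed = 101L, ...) {
  defaults <- list(n_genes = 2L, exons_per_gene = c(4L, 6L),
                   exon_length = c(40L, 120L), intron_length = c(60L, 200L),
                   flank_length = c(50L, 120L), seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

## Hand-built single-gene genome: exon1 | intron (donor class of choice) |
## exon2, everything deterministic, on a chosen strand. Returns the pieces
## plus genomic coordinates of the intron.
toy_junction <- function(donor = "GT", exon1 = NULL, exon2 = NULL,
                         intron_mid = "TTTTTTTTTTTTTTTTTTTT",
                         strand = "+") {
  if (is.null(exon1)) exon1 <- "ACCTGATCGATTACCGATTACAGCTAACG"
  if (is.null(exon2)) exon2 <- "CATTCCGATAAGCTTACGGATCCTAGAAC"
  intron <- paste0(donor, "AAGT", intron_mid, "TTTCTTCTCC", "AG")
  sense <- paste0(exon1, intron, exon2)
  s <- nchar(exon1)
  e <- s + nchar(intron)
  L <- nchar(sense)
  if (strand == "+") {
    genome <- c(chr1 = sense)
    start <- s; end <- e
  } else {
    genome <- c(chr1 = gasplice:::rc_chr(sense))
    start <- L - e; end <- L - s
  }
  list(genome = as_genome(genome), chars = genome,
       exon1 = exon1, exon2 = exon2, intron = intron,
       transcript = paste0(exon1, exon2),
       start = start, end = end, strand = strand, seq_len = L)
}

write_fasta_tmp <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

## ---- independent oracles -------------------------------------------------

## naive scan of both strands for exact occurrences of a k-mer
brute_anchor_scan <- function(kmer, chars) {
  hits <- NULL
  for (sid in names(chars)) {
    for (frame in c("+", "-")) {
      seq <- if (frame == "+") chars[[sid]] else gasplice:::rc_chr(chars[[sid]])
      L <- nchar(seq)
      k <- nchar(kmer)
      for (p in seq_len(L - k + 1L)) {
        if (substr(seq, p, p + k - 1L) == kmer) {
          pos <- if (frame == "+") p - 1L else L - (p - 1L) - k
          hits <- rbind(hits, data.frame(seq_id = sid, strand = frame,
                                         pos = pos))
        }
      }
    }
  }
  hits
}

## exhaustive split enumeration for one anchored read: naive per-position
## character loops, no shared code with call_junction
brute_force_call <- function(read, chars, seq_id, gL, aR, mode, k = 16L,
                             min_anchor = 8L, strand = "+") {
  seq <- chars[[seq_id]]
  L <- nchar(read)
  glen <- aR - (L - k) - gL
  if (glen < 4L) return(NULL)
  placements <- list()
  for (p in min_anchor:(L - min_anchor)) {
    ok <- TRUE
    for (i in 1:p) {
      if (substr(read, i, i) != substr(seq, gL + i, gL + i)) { ok <- FALSE; break }
    }
    if (ok && p < L) {
      e0 <- gL + p + glen
      for (i in (p + 1L):L) {
        gpos <- e0 + (i - p - 1L)
        if (substr(read, i, i) != substr(seq, gpos + 1L, gpos + 1L)) {
          ok <- FALSE; break
        }
      }
    }
    if (!ok) next
    s <- gL + p
    e <- s + glen
    if (strand == "+") {
      donor <- substr(seq, s + 1L, s + 2L)
      acceptor <- substr(seq, e - 1L, e)
    } else {
      donor <- gasplice:::rc_chr(substr(seq, e - 1L, e))
      acceptor <- gasplice:::rc_chr(substr(seq, s + 1L, s + 2L))
    }
    set <- switch(mode, gt = "GT", gy = c("GT", "GC"),
                  g = c("GT", "GC", "GA", "GG"), any = NULL)
    adm <- acceptor == "AG" && !grepl("N", donor) &&
      (is.null(set) || donor %in% set)
    if (adm) {
      placements[[length(placements) + 1L]] <-
        data.frame(start = s, end = e, donor = donor, acceptor = acceptor)
    }
  }
  if (!length(placements)) return(NULL)
  tab <- do.call(rbind, placements)
  pri <- match(tab$donor, c("GT", "GC", "GA", "GG"))
  pri[is.na(pri)] <- 5L
  tab[order(pri, tab$start)[1L], , drop = FALSE]
}

## random small spliced-read instance for the oracle suite
random_oracle_instance <- function(mode) {
  k <- 11L
  min_anchor <- 8L
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  donor <- sample(c("GT", "GC", "GA", "GG", "CT"), 1L)
  exon1 <- bg(sample(30:60, 1L))
  exon2 <- bg(sample(30:60, 1L))
  intron <- paste0(donor, bg(sample(20:60, 1L)), "AG")
  flank <- bg(sample(10:40, 1L))
  seq <- paste0(flank, exon1, intron, exon2, bg(sample(10:40, 1L)))
  s <- nchar(flank) + nchar(exon1)
  e <- s + nchar(intron)
  pick <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L
  L <- pick(2L * k, min(60L, nchar(exon1) + nchar(exon2)))
  j <- pick(max(min_anchor, L - nchar(exon2)),
            min(L - min_anchor, nchar(exon1)))
  read <- paste0(substr(seq, s - j + 1L, s),
                 substr(seq, e + 1L, e + (L - j)))
  gL <- s - j
  aR <- e + (L - j) - k
  list(chars = c(chr = seq), read = read, gL = gL, aR = aR, k = k,
       min_anchor = min_anchor, mode = mode, true_start = s, true_end = e,
       donor = donor)
}

## brute-force pairwise clustering of intron positions (igraph components)
brute_shared <- function(positions, alignment, column_slack = 0L) {
  cols <- vapply(seq_len(nrow(positions)), function(i) {
    map_to_alignment(alignment, positions$species[i],
                     positions$residue_index[i])
  }, integer(1))
  n <- nrow(positions)
  edges <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && positions$phase[i] == positions$phase[j] &&
          abs(cols[i] - cols[j]) <= column_slack) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  vapply(seq_len(max(comp)), function(cc) {
    length(unique(positions$species[comp == cc])) >= 2L
  }, logical(1))[comp]
}
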