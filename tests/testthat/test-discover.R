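test_that("anchors place a read at its unique genomic origin", {
  tj <- toy_junction("GT")
  # contiguous genomic slice: both terminal k-mers anchor colinearly
  slice <- substr(tj$chars[["chr1"]], 3, 40)
  an <- find_anchors(slice, tj$genome, k = 16L)
  plus <- an[an$strand == "+", ]
  expect_equal(nrow(plus), 2L)
  expect_equal(plus$genome_offset[plus$side == "left"], 2L)
  expect_equal(plus$genome_offset[plus$side == "right"],
               2L + nchar(slice) - 16L)

  expect_equal(nrow(find_anchors(strrep("N", 40), tj$genome)), 0L)
})

test_that("anchor hits match a brute-force scan of both strands", {
  set.seed(19)
  chars <- c(a = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                       collapse = ""))
  g <- as_genome(chars)
  # a minus-strand read: reverse complement of a genomic slice
  read <- gasplice:::rc_chr(substr(chars[["a"]], 101, 140))
  an <- find_anchors(read, g, k = 16L)
  expect_true(all(an$strand == "-"))
  # the aligned frame of a minus hit is rc(read) = the original slice
  left <- an[an$side == "left", ]
  oracle <- brute_anchor_scan(substr(gasplice:::rc_chr(read), 1, 16), chars)
  expect_equal(sort(left$genome_offset),
               sort(oracle$pos[oracle$strand == "+"]))
})

test_that("donor modes gate junction calls as defined", {
  for (donor in c("GT", "GC", "GA", "GG")) {
    tj <- toy_junction(donor)
    j <- 14L
    L <- 30L
    read <- paste0(substr(tj$transcript, tj$start - j + 1, tj$start),
                   substr(tj$transcript, tj$start + 1, tj$start + L - j))
    gL <- tj$start - j
    aR <- tj$end + (L - j) - 16L
    la <- list(read_offset = 0L, seq_id = "chr1", genome_offset = gL,
               strand = "+")
    ra <- list(read_offset = L - 16L, seq_id = "chr1", genome_offset = aR,
               strand = "+")
    for (mode in c("gt", "gy", "g", "any")) {
      cl <- call_junction(read, tj$chars, la, ra, mode = mode)
      admits <- switch(mode, gt = "GT", gy = c("GT", "GC"),
                       g = c("GT", "GC", "GA", "GG"),
                       any = c("GT", "GC", "GA", "GG"))
      if (donor %in% admits) {
        expect_false(is_no_call(cl))
        expect_equal(cl$start, tj$start)
        expect_equal(cl$end, tj$end)
        expect_equal(cl$donor, donor)
        expect_equal(cl$acceptor, "AG")
      } else {
        expect_true(is_no_call(cl))
        expect_equal(cl$reason, "no_admissible_donor")
      }
    }
  }
})

test_that("anchors on different sequences or strands are no-calls", {
  tj <- toy_junction("GT")
  la <- list(read_offset = 0L, seq_id = "chr1", genome_offset = 0L,
             strand = "+")
  ra_seq <- list(read_offset = 24L, seq_id = "chr2", genome_offset = 60L,
                 strand = "+")
  ra_str <- list(read_offset = 24L, seq_id = "chr1", genome_offset = 60L,
                 strand = "-")
  read <- strrep("A", 40)
  expect_equal(call_junction(read, tj$chars, la, ra_seq)$reason,
               "different_sequences")
  expect_equal(call_junction(read, tj$chars, la, ra_str)$reason,
               "different_strands")
})

test_that("junction slide ambiguity is resolved by donor priority", {
  # exon1 ends GAG, intron ends AGGAG: shifting the junction 3 nt left
  # yields an equivalent placement with a GA donor; GT must win.
  exon1 <- paste0("CCTGATCGATTACCGATTACAGCTA", "GAG")
  intron <- paste0("GT", "AAGT", strrep("T", 20), "TTTCTTCT", "AGGAG")
  exon2 <- "CATTCCGATAAGCTTACGGATCCTAGAAC"
  chars <- c(chr1 = paste0(exon1, intron, exon2))
  s <- nchar(exon1)
  e <- s + nchar(intron)
  j <- 14L; L <- 30L
  tx <- paste0(exon1, exon2)
  read <- paste0(substr(tx, s - j + 1, s), substr(tx, s + 1, s + L - j))
  la <- list(read_offset = 0L, seq_id = "chr1", genome_offset = s - j,
             strand = "+")
  ra <- list(read_offset = L - 16L, seq_id = "chr1",
             genome_offset = e + (L - j) - 16L, strand = "+")
  cl <- call_junction(read, chars, la, ra, mode = "g")
  expect_false(is_no_call(cl))
  expect_gte(cl$n_ambiguous, 2L)
  expect_equal(cl$donor, "GT")
  expect_equal(cl$start, s)
  expect_equal(cl$chosen_by, "donor_priority_leftmost")
  # under gt mode the shifted GA placement is not admissible
  expect_equal(call_junction(read, chars, la, ra, mode = "gt")$n_ambiguous, 1L)
})

test_that("call_junction matches exhaustive enumeration on random instances", {
  set.seed(23)
  n_checked <- 0L
  for (rep in 1:80) {
    inst <- random_oracle_instance(sample(c("gt", "gy", "g", "any"), 1L))
    la <- list(read_offset = 0L, seq_id = "chr",
               genome_offset = inst$gL, strand = "+")
    ra <- list(read_offset = nchar(inst$read) - inst$k,
               seq_id = "chr", genome_offset = inst$aR, strand = "+")
    got <- call_junction(inst$read, inst$chars, la, ra, mode = inst$mode,
                         k = inst$k, min_anchor = inst$min_anchor)
    want <- brute_force_call(inst$read, inst$chars, "chr", inst$gL,
                             inst$aR, inst$mode, k = inst$k,
                             min_anchor = inst$min_anchor)
    if (is.null(want)) {
      expect_true(is_no_call(got))
    } else {
      expect_false(is_no_call(got))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$donor, want$donor)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 20L)
})

test_that("discovery is empty on empty input", {
  tj <- toy_junction("GT")
  expect_equal(nrow(discover_junctions(character(0), tj$genome)), 0L)
})

test_that("discovered calls honour splice fidelity and mode monotonicity", {
  ds <- simulate_dataset(tiny_config(seed = 91L))
  modes <- c("gt", "gy", "g", "any")
  calls <- lapply(modes, function(m) {
    discover_junctions(ds$reads, ds$genome, mode = m)
  })
  names(calls) <- modes
  key <- function(d) paste(d$seq_id, d$start, d$end, d$strand)
  for (i in 1:3) {
    expect_true(all(key(calls[[i]]) %in% key(calls[[i + 1L]])))
  }
  # splice fidelity: donor/acceptor columns equal the genomic slices
  chars <- setNames(as.character(ds$genome), names(ds$genome))
  g <- calls[["g"]]
  for (i in seq_len(nrow(g))) {
    cls <- classify_intron(chars, g$seq_id[i], g$start[i], g$end[i],
                           g$strand[i])
    expect_equal(cls$donor, g$donor[i])
    expect_equal(cls$acceptor, g$acceptor[i])
  }
})

test_that("strand symmetry: mirrored genome yields the mirrored call set", {
  ds <- simulate_dataset(tiny_config(seed = 141L))
  chars <- setNames(as.character(ds$genome), names(ds$genome))
  mirrored <- as_genome(setNames(gasplice:::rc_chr(chars), names(chars)))
  fwd <- discover_junctions(ds$reads, ds$genome, mode = "g")
  rev <- discover_junctions(ds$reads, mirrored, mode = "g")
  L <- setNames(nchar(chars), names(chars))
  expected <- data.frame(seq_id = fwd$seq_id,
                         start = L[fwd$seq_id] - fwd$end,
                         end = L[fwd$seq_id] - fwd$start,
                         strand = ifelse(fwd$strand == "+", "-", "+"),
                         donor = fwd$donor)
  key <- function(d) paste(d$seq_id, d$start, d$end, d$strand, d$donor)
  expect_setequal(key(rev), key(expected))
})

test_that("G-any discovery recovers the full truth set; GY drops GA/GG", {
  ds <- simulate_dataset(tiny_config(seed = 171L,
                                     quota = c(GT = 8L, GC = 0L,
                                               GA = 3L, GG = 1L),
                                     n_genes = 2L,
                                     exons_per_gene = c(6L, 8L)))
  g <- splice_pipeline(dataset = ds, mode = "g")
  expect_equal(g$recovery$n_recovered, nrow(ds$truth))
  expect_equal(g$recovery$n_class_match, nrow(ds$truth))
  expect_equal(g$recovery$n_spurious, 0L)

  gy <- splice_pipeline(dataset = ds, mode = "gy")
  tab <- gy$recovery$table
  expect_true(all(tab$recovered[tab$donor_class %in% c("GT", "GC")]))
  expect_false(any(tab$recovered[tab$donor_class %in% c("GA", "GG")]))
})

test_that("min_support flags weak junctions without deleting them", {
  ds <- simulate_dataset(tiny_config(seed = 201L, coverage = 1L))
  calls <- discover_junctions(ds$reads, ds$genome, mode = "g",
                              min_support = 2L)
  expect_true(nrow(calls) > 0L)
  expect_true(all(!calls$pass_filter))
  cls <- classify_junctions(calls, ds$genome)
  expect_equal(nrow(cls), 0L)
})
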