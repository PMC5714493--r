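test_that("window extraction uses exact lengths, padding and strand", {
  tj <- toy_junction("GT")
  introns <- data.frame(seq_id = "chr1", start = tj$start, end = tj$end,
                        strand = "+")
  w <- extract_windows(tj$genome, introns, window_spec("donor"))
  expect_equal(dim(w), c(1L, 23L))
  expect_equal(paste(w[1, 1:10], collapse = ""),
               substr(tj$exon1, nchar(tj$exon1) - 9, nchar(tj$exon1)))
  expect_equal(paste(w[1, 11:23], collapse = ""),
               substr(tj$intron, 1, 13))

  wa <- extract_windows(tj$genome, introns, window_spec("acceptor"))
  expect_equal(dim(wa), c(1L, 23L))
  expect_equal(paste(wa[1, 1:16], collapse = ""),
               substr(tj$intron, nchar(tj$intron) - 15, nchar(tj$intron)))
  expect_equal(paste(wa[1, 17:23], collapse = ""),
               substr(tj$exon2, 1, 7))

  # intron starting 5 nt into the sequence: exon side padded with N
  small <- as_genome(c(s = paste0("CCCCC", "GTAAGTTTTTTTTTTTAG", "AAAA")))
  wpad <- extract_windows(small,
                          data.frame(seq_id = "s", start = 5L, end = 23L,
                                     strand = "+"),
                          window_spec("donor"))
  expect_equal(paste(wpad[1, 1:5], collapse = ""), "NNNNN")
  expect_equal(paste(wpad[1, 6:10], collapse = ""), "CCCCC")
})

test_that("minus-strand windows equal the reverse-complement oracle", {
  minus <- toy_junction("GA", strand = "-")
  plus <- toy_junction("GA", strand = "+")
  wm <- extract_windows(minus$genome,
                        data.frame(seq_id = "chr1", start = minus$start,
                                   end = minus$end, strand = "-"),
                        window_spec("donor"))
  wp <- extract_windows(plus$genome,
                        data.frame(seq_id = "chr1", start = plus$start,
                                   end = plus$end, strand = "+"),
                        window_spec("donor"))
  expect_identical(wm, wp)
  # direct reverse-complement oracle on the raw slice
  chars <- minus$chars[["chr1"]]
  raw <- substr(chars, minus$end - 13L + 1L, minus$end + 10L)
  expect_equal(paste(wm[1, ], collapse = ""), gasplice:::rc_chr(raw))
})

test_that("position frequencies follow the pseudocount formula", {
  rows <- rbind(strsplit("AAAA", "")[[1]], strsplit("CCCC", "")[[1]],
                strsplit("GGGG", "")[[1]], strsplit("TTTT", "")[[1]])
  pf <- position_frequencies(rows, pseudocount = 0)
  expect_true(all(abs(pf$frequencies - 0.25) < 1e-12))

  single <- matrix(strsplit("GGGG", "")[[1]], nrow = 1)
  pf1 <- position_frequencies(single, pseudocount = 0)
  expect_true(all(pf1$frequencies["G", ] == 1))
  pf2 <- position_frequencies(single, pseudocount = 1)
  expect_true(all(abs(pf2$frequencies["G", ] - 2 / 5) < 1e-12))
  expect_true(all(abs(colSums(pf2$frequencies) - 1) < 1e-9))

  # N cells drop out of that position's effective n
  withN <- rbind(strsplit("GN", "")[[1]], strsplit("GA", "")[[1]])
  pfN <- position_frequencies(withN, pseudocount = 0)
  expect_equal(unname(pfN$effective_n), c(2L, 1L))
  expect_equal(unname(pfN$frequencies["A", 2]), 1)

  expect_error(position_frequencies(rows[0, , drop = FALSE]), "no windows")
})

test_that("information content equals 2 - H - e(n)", {
  uniform <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T")))
  expect_equal(information_content(uniform, 100L, FALSE), c(0, 0, 0))

  certain <- matrix(c(1, 0, 0, 0), 4, 1,
                    dimnames = list(c("A", "C", "G", "T")))
  expect_equal(information_content(certain, 100L, FALSE), 2)

  # small-sample correction, independently evaluated
  expect_equal(information_content(certain, 36L, TRUE),
               2 - 3 / (2 * log(2) * 36), tolerance = 1e-12)

  # general case against a direct evaluation of the formula
  set.seed(5)
  p <- matrix(runif(20), 4, 5)
  p <- sweep(p, 2, colSums(p), "/")
  rownames(p) <- c("A", "C", "G", "T")
  direct <- 2 - apply(p, 2, function(q) -sum(q * log2(q))) -
    3 / (2 * log(2) * 17)
  expect_equal(information_content(p, 17L, TRUE), pmax(0, direct),
               tolerance = 1e-12)

  expect_error(information_content(certain, 0L), "n_sequences")
})

test_that("forced noncanonical constraints shape the donor logo", {
  cfg <- tiny_config(seed = 93L, n_genes = 3L, exons_per_gene = c(5L, 7L),
                     quota = c(GT = 0L, GC = 0L, GA = 9L, GG = 5L),
                     pos3_A_prob = 1)
  ds <- simulate_dataset(cfg)
  introns <- ds$truth[ds$truth$donor_class %in% c("GA", "GG"), ]
  m <- motif_matrix(ds$genome, introns, window_spec("donor"),
                    small_sample_correction = FALSE)
  info <- m$information
  pos <- colnames(m$counts)
  # obligate exon-terminal AG and intron positions 1 and 3
  expect_equal(unname(info[pos == "E-2"]), 2)
  expect_equal(unname(info[pos == "E-1"]), 2)
  expect_equal(unname(info[pos == "I1"]), 2)   # G in both GA and GG
  expect_equal(unname(info[pos == "I3"]), 2)   # forced A
  # intron position 2 splits between A and G
  i2 <- m$frequencies[, pos == "I2"]
  expect_equal(unname(i2[["A"]] + i2[["G"]]), 1)
  expect_lt(info[pos == "I2"], 2)
  expect_true(all(abs(colSums(m$frequencies) - 1) < 1e-9))
})

test_that("information decreases as consensus strength weakens", {
  info_at <- function(strength) {
    cfg <- sim_config(n_genes = 6L, exons_per_gene = c(15L, 20L),
                      exon_length = c(40L, 80L),
                      intron_length = c(60L, 120L),
                      flank_length = c(50L, 80L),
                      donor_consensus_strength = strength, seed = 7L)
    set.seed(7L)
    sk <- simulate_gene_structure(cfg)
    em <- emit_genome(sk, cfg)
    m <- motif_matrix(em$genome, em$truth, window_spec("donor"),
                      small_sample_correction = FALSE)
    m$information[colnames(m$counts) == "I4"]   # consensus A position
  }
  vals <- vapply(c(1, 0.7, 0.3), info_at, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 2, tolerance = 1e-9)
})

test_that("motif matrices serialize as readable TSV", {
  tj <- toy_junction("GT")
  m <- motif_matrix(tj$genome,
                    data.frame(seq_id = "chr1", start = tj$start,
                               end = tj$end, strand = "+"),
                    window_spec("donor"))
  p <- tempfile(fileext = ".tsv")
  write_motif_matrix(m, p)
  tab <- utils::read.delim(p)
  expect_equal(nrow(tab), 23L)
  expect_equal(tab$information_bits, unname(m$information))
})
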