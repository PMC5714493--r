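test_that("intron positions map to protein residues by codon arithmetic", {
  # 3 exons of 150/151/152 nt: cds_before = 150 then 301
  m <- gene_model("g1", "s", "+",
                  rbind(c(0L, 150L), c(250L, 401L), c(500L, 652L)))
  pp <- intron_protein_positions(m, species = "spA")
  expect_equal(pp$residue_index, c(50L, 100L))
  expect_equal(pp$phase, c(0L, 1L))

  single <- gene_model("g2", "s", "+", rbind(c(0L, 300L)))
  expect_equal(nrow(intron_protein_positions(single)), 0L)

  bad <- gene_model("g3", "s", "+", rbind(c(0L, 100L), c(200L, 302L)))
  expect_error(intron_protein_positions(bad), "divisible by 3")
})

test_that("alignment-column mapping skips gaps and inverts cleanly", {
  aln <- c(spA = "MKLV", spB = "M-KL")
  expect_equal(map_to_alignment(aln, "spA", 2L), 2L)   # gapless: identity
  expect_equal(map_to_alignment(aln, "spB", 1L), 2L)   # K behind one gap
  expect_error(map_to_alignment(aln, "spC", 0L), "absent")
  expect_error(map_to_alignment(aln, "spB", 3L), "beyond ungapped length")

  # inverse-mapping property on random gapped rows
  set.seed(13)
  for (rep in 1:25) {
    n_res <- 5L + sample.int(20L, 1L)
    row <- character(0)
    for (r in seq_len(n_res)) {
      row <- c(row, rep("-", sample.int(3L, 1L) - 1L), "X")
    }
    aln1 <- c(sp = paste(row, collapse = ""))
    for (ri in seq_len(n_res) - 1L) {
      col <- map_to_alignment(aln1, "sp", ri)
      chars <- strsplit(aln1[["sp"]], "")[[1]]
      expect_equal(sum(chars[seq_len(col + 1L)] != "-") - 1L, ri)
    }
  }
})

test_that("shared/idiosyncratic classification follows phase and column", {
  aln <- c(spA = "MKLVRT", spB = "MKLVRT")
  pos <- data.frame(species = c("spA", "spB"),
                    gene_id = c("g", "h"), intron_index = 1L,
                    residue_index = 2L, phase = 0L)
  rec <- classify_shared(pos, aln)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$status, "shared")

  # same column, different phases: two idiosyncratic records
  pos$phase <- c(0L, 1L)
  rec <- classify_shared(pos, aln)
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$status == "idiosyncratic"))
})

test_that("three-species fixture matches the exhaustive pairing oracle", {
  skip_if_not_installed("igraph")
  aln <- c(spA = "MAC-DEFGHIKL",
           spB = "MACQDEFGH-KL",
           spC = "M-CQDEFGHIKL")
  # five introns, two conserved across species (residues 3 and 7 of spA)
  pos <- data.frame(
    species = c("spA", "spB", "spA", "spC", "spA"),
    gene_id = "ir", intron_index = c(1L, 1L, 2L, 1L, 3L),
    residue_index = c(3L, 4L, 7L, 7L, 9L),
    phase = c(1L, 1L, 0L, 0L, 2L))
  rec <- classify_shared(pos, aln)
  expect_equal(sum(rec$status == "shared"), 2L)
  expect_equal(sum(rec$status == "idiosyncratic"), 1L)
  expect_equal(sum(rec$n_members), nrow(pos))   # partition property

  oracle_shared <- brute_shared(pos, aln)
  got <- rep(NA, nrow(pos))
  for (i in seq_len(nrow(rec))) {
    mem <- strsplit(rec$members[i], ";")[[1]]
    for (m in mem) {
      parts <- strsplit(m, ":")[[1]]
      idx <- which(pos$species == parts[1] & pos$gene_id == parts[2] &
                   pos$intron_index == as.integer(parts[3]))
      got[idx] <- rec$status[i] == "shared"
    }
  }
  expect_equal(got, oracle_shared)
})

test_that("random fixtures agree with the pairing oracle under slack", {
  skip_if_not_installed("igraph")
  set.seed(29)
  for (rep in 1:20) {
    width <- 40L
    species <- paste0("sp", 1:3)
    aln <- setNames(vapply(species, function(s) {
      chars <- sample(c(LETTERS[1:10], "-"), width, TRUE,
                      prob = c(rep(0.085, 10), 0.15))
      # ensure at least 12 residues
      chars[1:12] <- "M"
      paste(chars, collapse = "")
    }, character(1)), species)
    n <- 8L
    pos <- data.frame(
      species = sample(species, n, TRUE),
      gene_id = "g", intron_index = seq_len(n),
      residue_index = sample(0:11, n, TRUE),
      phase = sample(0:2, n, TRUE))
    for (slack in c(0L, 1L, 2L)) {
      rec <- classify_shared(pos, aln, column_slack = slack)
      expect_equal(sum(rec$n_members), n)
      oracle <- brute_shared(pos, aln, column_slack = slack)
      expect_equal(sum(rec$n_members[rec$status == "shared"]),
                   sum(oracle))
    }
  }
})

test_that("shared count is monotone in slack and order-invariant", {
  aln <- c(spA = "MKLVRTWQ", spB = "MKLVRTWQ")
  pos <- data.frame(species = c("spA", "spB", "spA", "spB"),
                    gene_id = "g", intron_index = 1:4,
                    residue_index = c(2L, 3L, 6L, 6L),
                    phase = 0L)
  n_shared <- vapply(0:3, function(s) {
    rec <- classify_shared(pos, aln, column_slack = s)
    sum(rec$n_members[rec$status == "shared"])
  }, numeric(1))
  expect_true(all(diff(n_shared) >= 0))

  perm <- pos[c(3, 1, 4, 2), ]
  rec1 <- classify_shared(pos, aln)
  rec2 <- classify_shared(perm, aln)
  expect_equal(rec1$alignment_column, rec2$alignment_column)
  expect_equal(rec1$status, rec2$status)
})

test_that("per-species shared counts partition the intron complement", {
  # a 33-intron complement with 9 positions shared with other species
  aln <- c(focal = strrep("A", 120), other1 = strrep("A", 120),
           other2 = strrep("A", 120))
  focal_pos <- data.frame(species = "focal", gene_id = "ir25a",
                          intron_index = 1:33,
                          residue_index = seq(0L, 96L, by = 3L),
                          phase = rep(0:2, 11L))
  shared_idx <- c(1L, 5L, 8L, 12L, 15L, 19L, 23L, 27L, 31L)
  other_pos <- data.frame(species = rep(c("other1", "other2"), length.out = 9),
                          gene_id = "ir25a_h",
                          intron_index = seq_len(9L),
                          residue_index = focal_pos$residue_index[shared_idx],
                          phase = focal_pos$phase[shared_idx])
  rec <- classify_shared(rbind(focal_pos, other_pos), aln)
  counts <- shared_counts(rec, "focal")
  expect_equal(unname(counts[["shared"]]), 9L)
  expect_equal(unname(counts[["idiosyncratic"]]), 24L)
  expect_equal(unname(counts[["total"]]), 33L)
})
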