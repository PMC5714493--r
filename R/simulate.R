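#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic genome: multi-exon
#' genes with mostly short exons, canonical `AG|GTAAGT`-consensus donors,
#' noncanonical GA/GG donors planted at a configurable frequency (with an
#' obligate AG at the end of the preceding exon and a strong A preference
#' at intron position 3), AG acceptors preceded by a pyrimidine-rich
#' tract, and error-free junction-spanning reads.
#'
#' Donor classes are planted either probabilistically (`donor_probs`) or
#' deterministically by exact counts (`quota`), e.g.
#' `quota = c(GT = 261, GC = 0, GA = 31, GG = 5)` reproduces a curated set
#' of 297 introns of which 36 (12\%) have noncanonical donors.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range (lo, hi) of coding exons per gene.
#' @param exon_length Integer range of exon lengths (nt).
#' @param intron_length Integer range of intron lengths (nt).
#' @param donor_probs Named probabilities for donor classes GT, GC, GA, GG;
#'   must sum to 1.
#' @param quota Optional named integer counts for GT/GC/GA/GG. When given,
#'   the total intron count equals `sum(quota)` and classes are planted as
#'   an exact multiset (quota mode); `donor_probs` is ignored.
#' @param noncanonical_exon_end_AG Force the last two bases of the exon
#'   preceding every GA/GG intron to `AG`.
#' @param exon_end_AG_prob Probability that the exon preceding a canonical
#'   intron ends in `AG` (the canonical consensus preference, not obligate).
#' @param pos3_A_prob Probability that position 3 of a noncanonical intron
#'   is `A`.
#' @param donor_consensus_strength Per-position probability that intron
#'   positions 3-6 of a canonical donor follow the `GTAAGT` consensus.
#' @param tract_length Length of the pyrimidine-rich tract before the
#'   acceptor `AG`.
#' @param tract_pyrimidine_prob Per-base pyrimidine probability in the tract.
#' @param flank_length Integer range of intergenic flank lengths per
#'   scaffold (one gene per scaffold).
#' @param read_length Read length (nt); reads shorter than this are emitted
#'   when the two flanking exons cannot hold a full-length read.
#' @param coverage Junction-spanning reads per intron.
#' @param error_rate Per-base substitution probability in reads.
#' @param min_anchor Minimum exonic bases required on each side of the
#'   junction within a read; must satisfy `read_length >= 2 * min_anchor`.
#' @param seed Optional integer seed applied by [simulate_dataset()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10L,
                       exons_per_gene = c(19L, 47L),
                       exon_length = c(40L, 250L),
                       intron_length = c(60L, 2000L),
                       donor_probs = c(GT = 0.85, GC = 0.03,
                                       GA = 0.105, GG = 0.015),
                       quota = NULL,
                       noncanonical_exon_end_AG = TRUE,
                       exon_end_AG_prob = 0.55,
                       pos3_A_prob = 0.9,
                       donor_consensus_strength = 0.9,
                       tract_length = 10L,
                       tract_pyrimidine_prob = 0.8,
                       flank_length = c(200L, 500L),
                       read_length = 100L,
                       coverage = 10L,
                       error_rate = 0,
                       min_anchor = 8L,
                       seed = NULL) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              donor_probs = donor_probs, quota = quota,
              noncanonical_exon_end_AG = isTRUE(noncanonical_exon_end_AG),
              exon_end_AG_prob = exon_end_AG_prob,
              pos3_A_prob = pos3_A_prob,
              donor_consensus_strength = donor_consensus_strength,
              tract_length = as.integer(tract_length),
              tract_pyrimidine_prob = tract_pyrimidine_prob,
              flank_length = as.integer(flank_length),
              read_length = as.integer(read_length),
              coverage = as.integer(coverage),
              error_rate = error_rate,
              min_anchor = as.integer(min_anchor),
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  classes <- c("GT", "GC", "GA", "GG")
  for (rng in c("exons_per_gene", "exon_length", "intron_length",
                "flank_length")) {
    r <- cfg[[rng]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L) {
      stop("invalid range for ", rng)
    }
  }
  if (is.null(cfg$quota)) {
    p <- cfg$donor_probs
    if (!setequal(names(p), classes)) stop("donor_probs needs GT, GC, GA, GG")
    if (abs(sum(p) - 1) > 1e-9) stop("donor_probs must sum to 1")
    if (any(p < 0)) stop("donor_probs must be non-negative")
  } else {
    q <- cfg$quota
    if (!all(names(q) %in% classes)) stop("quota names must be donor classes")
    if (any(q < 0) || sum(q) < 1L) stop("quota must be non-negative counts")
    lo <- cfg$n_genes * (cfg$exons_per_gene[1L] - 1L)
    hi <- cfg$n_genes * (cfg$exons_per_gene[2L] - 1L)
    if (sum(q) < lo || sum(q) > hi) {
      stop("quota total ", sum(q), " introns cannot be distributed over ",
           cfg$n_genes, " genes with ", cfg$exons_per_gene[1L], "-",
           cfg$exons_per_gene[2L], " exons")
    }
  }
  if (cfg$read_length < 2L * cfg$min_anchor) {
    stop("read_length must be >= 2 * min_anchor")
  }
  if (cfg$intron_length[1L] < cfg$tract_length + 8L) {
    stop("intron_length too short for donor consensus + tract + acceptor")
  }
  if (cfg$exon_length[1L] < cfg$min_anchor) {
    stop("exon_length must be >= min_anchor")
  }
  invisible(cfg)
}

r_int <- function(n, range) {
  range[1L] + sample.int(range[2L] - range[1L] + 1L, n, replace = TRUE) - 1L
}

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

## distribute `total` introns over n genes, each within [lo, hi]
distribute_introns <- function(total, n, lo, hi) {
  counts <- r_int(n, c(lo, hi))
  delta <- total - sum(counts)
  while (delta != 0L) {
    step <- sign(delta)
    movable <- if (step > 0L) which(counts < hi) else which(counts > lo)
    i <- movable[sample.int(length(movable), 1L)]
    counts[i] <- counts[i] + step
    delta <- delta - step
  }
  counts
}

#' Simulate gene structures and planted donor classes
#'
#' Draws exon counts and exon/intron lengths from the configured ranges and
#' assigns each intron a donor class, either by sampling `donor_probs` or,
#' in quota mode, by dealing an exact multiset of classes across all
#' introns. Total coding length per gene is padded to a multiple of 3.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param config A [sim_config()].
#' @return List of gene skeletons, each with `gene_id, strand, n_exons,
#'   exon_lengths, intron_lengths, donor_classes` (transcript order).
#' @export
simulate_gene_structure <- function(config) {
  validate_sim_config(config)
  lo <- config$exons_per_gene[1L] - 1L
  hi <- config$exons_per_gene[2L] - 1L
  if (!is.null(config$quota)) {
    introns_per_gene <- distribute_introns(sum(config$quota),
                                           config$n_genes, lo, hi)
    pool <- rep(names(config$quota), times = config$quota)
    pool <- pool[sample.int(length(pool))]
  } else {
    introns_per_gene <- r_int(config$n_genes, c(lo, hi))
    pool <- NULL
  }
  skeletons <- vector("list", config$n_genes)
  taken <- 0L
  for (g in seq_len(config$n_genes)) {
    ni <- introns_per_gene[g]
    ne <- ni + 1L
    exon_len <- r_int(ne, config$exon_length)
    pad <- (3L - sum(exon_len) %% 3L) %% 3L
    exon_len[ne] <- exon_len[ne] + pad
    if (is.null(pool)) {
      classes <- sample(names(config$donor_probs), ni, replace = TRUE,
                        prob = config$donor_probs)
    } else {
      classes <- pool[taken + seq_len(ni)]
      taken <- taken + ni
    }
    skeletons[[g]] <- list(
      gene_id = sprintf("gene%02d", g),
      strand = sample(c("+", "-"), 1L),
      n_exons = ne,
      exon_lengths = exon_len,
      intron_lengths = r_int(ni, config$intron_length),
      donor_classes = classes)
  }
  skeletons
}

sample_tract <- function(n, pyr_prob) {
  pyr <- runif(n) < pyr_prob
  bases <- character(n)
  bases[pyr] <- sample(c("C", "T"), sum(pyr), replace = TRUE)
  bases[!pyr] <- sample(c("A", "G"), sum(!pyr), replace = TRUE)
  paste(bases, collapse = "")
}

## intron sequence on the transcribed strand for a planted donor class
build_intron <- function(len, class, config) {
  consensus <- c("A", "A", "G", "T")          # intron positions 3-6 of GTAAGT
  head <- character(6L)
  head[1L] <- substr(class, 1L, 1L)
  head[2L] <- substr(class, 2L, 2L)
  noncanonical <- class %in% c("GA", "GG")
  for (i in 3:6) {
    p <- if (i == 3L && noncanonical) config$pos3_A_prob
         else config$donor_consensus_strength
    head[i] <- if (runif(1L) < p) consensus[i - 2L]
               else sample(DNA_BASES4, 1L)
  }
  tail_len <- config$tract_length + 2L
  body <- rand_dna(len - 6L - tail_len)
  paste0(paste(head, collapse = ""), body,
         sample_tract(config$tract_length, config$tract_pyrimidine_prob),
         "AG")
}

## exon sequence; `end_mode` one of "AG" (forced), "maybe" (consensus
## preference), "free" (terminal exon)
build_exon <- function(len, end_mode, config) {
  s <- rand_dna(len)
  force_ag <- switch(end_mode,
                     AG = TRUE,
                     maybe = runif(1L) < config$exon_end_AG_prob,
                     free = FALSE)
  if (force_ag && len >= 2L) {
    substr(s, len - 1L, len) <- "AG"
  }
  s
}

#' Emit a synthetic genome, gene models and ground truth
#'
#' Realizes gene skeletons as DNA: one scaffold per gene with intergenic
#' flanks, uniform i.i.d. background, planted donor dinucleotides,
#' consensus-biased donor positions 3-6, pyrimidine tract plus `AG`
#' acceptors, and (for noncanonical introns) an obligate `AG` at the end of
#' the preceding exon. Minus-strand genes are reverse-complemented into
#' genomic orientation. A uniqueness guard verifies that the spliced
#' junction core (`min_anchor` bases each side) of every intron occurs
#' nowhere in the genome as a contiguous sequence, so junction-spanning
#' read windows cannot be explained by an unspliced placement; offending
#' genes are resampled a bounded number of times.
#'
#' @param skeletons Output of [simulate_gene_structure()].
#' @param config A [sim_config()].
#' @param max_retries Resampling attempts per uniqueness violation.
#' @return List with `genome` (DNAStringSet), `models` (list of
#'   [gene_model()]), and `truth` (data.frame: gene_id, intron_index,
#'   seq_id, start, end, strand, donor_class, acceptor, phase).
#' @export
emit_genome <- function(skeletons, config, max_retries = 5L) {
  validate_sim_config(config)
  realize <- function(sk) {
    seq_id <- paste0("scaffold_", sub("gene", "", sk$gene_id))
    left <- r_int(1L, config$flank_length)
    right <- r_int(1L, config$flank_length)
    ni <- sk$n_exons - 1L
    parts <- character(2L * sk$n_exons - 1L)
    for (e in seq_len(sk$n_exons)) {
      end_mode <- if (e == sk$n_exons) "free"
                  else if (sk$donor_classes[e] %in% c("GA", "GG") &&
                           config$noncanonical_exon_end_AG) "AG"
                  else "maybe"
      parts[2L * e - 1L] <- build_exon(sk$exon_lengths[e], end_mode, config)
      if (e <= ni) {
        parts[2L * e] <- build_intron(sk$intron_lengths[e],
                                      sk$donor_classes[e], config)
      }
    }
    sense <- paste0(rand_dna(left), paste(parts, collapse = ""),
                    rand_dna(right))
    ## exon intervals in sense coordinates
    lens <- c(rbind(sk$exon_lengths,
                    c(sk$intron_lengths, 0L)))[seq_len(2L * sk$n_exons - 1L)]
    starts <- left + c(0L, cumsum(lens))[seq_len(2L * sk$n_exons - 1L)]
    ex_sense <- cbind(start = starts[seq(1L, by = 2L,
                                         length.out = sk$n_exons)],
                      end = starts[seq(1L, by = 2L,
                                       length.out = sk$n_exons)] +
                            sk$exon_lengths)
    L <- nchar(sense)
    if (sk$strand == "+") {
      scaffold <- sense
      exons <- ex_sense
    } else {
      scaffold <- rc_chr(sense)
      exons <- cbind(start = L - ex_sense[, "end"],
                     end = L - ex_sense[, "start"])
      exons <- exons[rev(seq_len(sk$n_exons)), , drop = FALSE]
    }
    model <- gene_model(sk$gene_id, seq_id, sk$strand, exons,
                        cds_start_offset = 0L,
                        donor_classes = sk$donor_classes)
    list(seq_id = seq_id, scaffold = scaffold, model = model)
  }
  realized <- lapply(skeletons, realize)

  junction_cores <- function(realized_list, chars) {
    cores <- character(0)
    for (r in realized_list) {
      m <- r$model
      intr <- model_introns(m)
      if (!nrow(intr)) next
      tx <- transcript_seq(m, chars)
      exlen <- {
        e <- exons_tx_order(m)
        e[, "end"] - e[, "start"]
      }
      pos <- cumsum(exlen)[seq_len(nrow(intr))]
      a <- config$min_anchor
      cores <- c(cores, substr(rep(tx, length(pos)), pos - a + 1L, pos + a))
    }
    cores
  }

  for (attempt in seq_len(max_retries + 1L)) {
    chars <- setNames(vapply(realized, `[[`, character(1), "scaffold"),
                      vapply(realized, `[[`, character(1), "seq_id"))
    cores <- junction_cores(realized, chars)
    genome <- Biostrings::DNAStringSet(chars)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(cores))
    hits <- rowSums(vapply(seq_along(genome), function(i) {
      Biostrings::countPDict(pd, genome[[i]]) +
        Biostrings::countPDict(pd, Biostrings::reverseComplement(genome[[i]]))
    }, integer(length(cores))))
    if (all(hits == 0L)) break
    if (attempt > max_retries) {
      stop("uniqueness guard failed after ", max_retries,
           " retries; consider longer reads")
    }
    gene_of_core <- rep(seq_along(realized),
                        vapply(realized, function(r) n_introns(r$model),
                               integer(1)))
    for (g in unique(gene_of_core[hits > 0L])) {
      realized[[g]] <- realize(skeletons[[g]])
    }
  }

  models <- lapply(realized, `[[`, "model")
  truth <- do.call(rbind, lapply(seq_along(models), function(g) {
    m <- models[[g]]
    intr <- model_introns(m)
    if (!nrow(intr)) return(NULL)
    data.frame(gene_id = m$gene_id, intron_index = intr$intron_index,
               seq_id = m$seq_id, start = intr$start, end = intr$end,
               strand = m$strand,
               donor_class = skeletons[[g]]$donor_classes,
               acceptor = "AG",
               phase = intr$cds_before %% 3L)
  }))
  rownames(truth) <- NULL
  list(genome = genome, models = models, truth = truth)
}

#' Simulate junction-spanning reads
#'
#' For every intron, draws `coverage` reads from the spliced transcript
#' such that each read is the concatenation of two exon-side slices
#' (confined to the two flanking exons) and covers the junction with at
#' least `min_anchor` nt on both sides; the junction offset within the
#' read is uniform over admissible positions. Reads are clamped to the
#' available flanking-exon sequence when the configured read length does
#' not fit. Error-free unless `error_rate > 0`.
#'
#' @param genome `DNAStringSet` from [emit_genome()].
#' @param models Gene models from [emit_genome()].
#' @param truth Truth table from [emit_genome()].
#' @param config A [sim_config()].
#' @return List with `reads` (DNAStringSet) and `provenance` (data.frame:
#'   read_id, gene_id, intron_index, read_length, junction_offset).
#' @export
simulate_reads <- function(genome, models, truth, config) {
  validate_sim_config(config)
  chars <- genome_chars(genome)
  model_by_id <- setNames(models, vapply(models, `[[`, character(1),
                                         "gene_id"))
  n_total <- nrow(truth) * config$coverage
  seqs <- character(n_total)
  prov <- vector("list", nrow(truth))
  k <- 0L
  a <- config$min_anchor
  for (i in if (config$coverage > 0L) seq_len(nrow(truth)) else integer(0)) {
    m <- model_by_id[[truth$gene_id[i]]]
    tx <- transcript_seq(m, chars)
    exlen <- {
      e <- exons_tx_order(m)
      e[, "end"] - e[, "start"]
    }
    idx <- truth$intron_index[i]
    pos <- cumsum(exlen)[idx]               # junction position in transcript
    left_avail <- exlen[idx]
    right_avail <- exlen[idx + 1L]
    if (left_avail < a || right_avail < a) {
      stop("read length too short to span intron ", idx, " of ",
           truth$gene_id[i], " with required anchors")
    }
    L <- min(config$read_length, left_avail + right_avail)
    jlo <- max(a, L - right_avail)
    jhi <- min(L - a, left_avail)
    offs <- r_int(config$coverage, c(jlo, jhi))
    rs <- substr(rep(tx, config$coverage), pos - offs + 1L, pos - offs + L)
    if (config$error_rate > 0) {
      rs <- vapply(rs, function(s) {
        b <- strsplit(s, "", fixed = TRUE)[[1L]]
        hit <- which(runif(length(b)) < config$error_rate)
        for (h in hit) b[h] <- sample(setdiff(DNA_BASES4, b[h]), 1L)
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    ids <- sprintf("read%06d", k + seq_len(config$coverage))
    seqs[k + seq_len(config$coverage)] <- rs
    prov[[i]] <- data.frame(read_id = ids, gene_id = truth$gene_id[i],
                            intron_index = idx, read_length = L,
                            junction_offset = offs)
    k <- k + config$coverage
  }
  provenance <- do.call(rbind, prov)
  if (is.null(provenance)) {
    provenance <- data.frame(read_id = character(),
                             gene_id = character(),
                             intron_index = integer(),
                             read_length = integer(),
                             junction_offset = integer())
  }
  reads <- Biostrings::DNAStringSet(setNames(seqs[seq_len(k)],
                                             provenance$read_id))
  list(reads = reads, provenance = provenance)
}

#' Run the whole simulator
#'
#' Seeds the RNG (if `config$seed` is set), simulates gene structures,
#' emits the genome and samples junction-spanning reads.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `models`, `truth`, `reads`, `provenance`,
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  skeletons <- simulate_gene_structure(config)
  emitted <- emit_genome(skeletons, config)
  rd <- simulate_reads(emitted$genome, emitted$models, emitted$truth, config)
  list(genome = emitted$genome, models = emitted$models,
       truth = emitted$truth, reads = rd$reads,
       provenance = rd$provenance, config = config)
}
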