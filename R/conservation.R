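#' Protein-relative positions of a gene model's introns
#'
#' For each intron (transcript order), computes the 0-based index of the
#' protein residue the intron falls after (phase 0) or within whose codon
#' it falls (phases 1 and 2): `residue_index = floor(cds_before / 3)`,
#' `phase = cds_before %% 3`. Introns 5' of the coding start are skipped.
#'
#' @param model A [gene_model()]; its CDS length must be divisible by 3.
#' @param species Optional species label carried through.
#' @return data.frame: `species, gene_id, intron_index, residue_index,
#'   phase`.
#' @export
intron_protein_positions <- function(model, species = NA_character_) {
  if (cds_length(model) %% 3L != 0L) {
    stop("CDS length of ", model$gene_id, " not divisible by 3")
  }
  intr <- model_introns(model)
  intr <- intr[!is.na(intr$cds_before), , drop = FALSE]
  data.frame(species = rep(species, nrow(intr)),
             gene_id = rep(model$gene_id, nrow(intr)),
             intron_index = intr$intron_index,
             residue_index = intr$cds_before %/% 3L,
             phase = intr$cds_before %% 3L)
}

#' Read an aligned protein FASTA
#'
#' @param path Path to an aligned FASTA (gaps as `-`).
#' @return Named character vector of aligned rows (uppercased), all of
#'   equal length.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  rows <- toupper(setNames(as.character(aln), sub("\\s.*$", "", names(aln))))
  if (length(unique(nchar(rows))) > 1L) {
    stop("alignment rows differ in length")
  }
  rows
}

#' Map a residue index to its alignment column
#'
#' @param alignment Named character vector of aligned rows (or a path or
#'   `AAStringSet`); gaps are `-` or `.`.
#' @param species Row name to use.
#' @param residue_index 0-based index into the ungapped sequence.
#' @return 0-based alignment column holding that residue.
#' @export
map_to_alignment <- function(alignment, species, residue_index) {
  if (length(alignment) == 1L && is.character(alignment) &&
      is.null(names(alignment)) && file.exists(alignment)) {
    alignment <- read_alignment(alignment)
  }
  if (!is.character(alignment)) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (!species %in% names(alignment)) {
    stop("species ", species, " absent from alignment")
  }
  row <- strsplit(alignment[[species]], "", fixed = TRUE)[[1L]]
  resident <- which(!row %in% c("-", "."))
  if (residue_index + 1L > length(resident)) {
    stop("residue index ", residue_index, " beyond ungapped length of ",
         species)
  }
  resident[[residue_index + 1L]] - 1L
}

#' Cluster intron positions across species into homology records
#'
#' Maps every intron to its alignment column and groups introns whose
#' phases are equal and whose columns differ by at most `column_slack`
#' (single-linkage along the column axis). A record whose members span at
#' least two species is `shared`; all others are `idiosyncratic`. Every
#' input intron belongs to exactly one record.
#'
#' @param positions data.frame from [intron_protein_positions()] (rows for
#'   all species, with a `species` column matching alignment row names).
#' @param alignment Named character vector of aligned protein rows.
#' @param column_slack Maximum column distance merged into one record.
#' @return data.frame: one row per record with `alignment_column` (of the
#'   first member), `phase`, `n_members`, `n_species`, `status`,
#'   `members` (semicolon-joined `species:gene:intron`).
#' @export
classify_shared <- function(positions, alignment, column_slack = 0L) {
  if (!nrow(positions)) {
    return(data.frame(alignment_column = integer(), phase = integer(),
                      n_members = integer(), n_species = integer(),
                      status = character(), members = character()))
  }
  cols <- vapply(seq_len(nrow(positions)), function(i) {
    map_to_alignment(alignment, positions$species[i],
                     positions$residue_index[i])
  }, integer(1))
  positions$alignment_column <- cols
  out <- list()
  for (ph in sort(unique(positions$phase))) {
    sub <- positions[positions$phase == ph, , drop = FALSE]
    sub <- sub[order(sub$alignment_column, sub$species, sub$gene_id,
                     sub$intron_index), , drop = FALSE]
    grp <- cumsum(c(1L, diff(sub$alignment_column) > column_slack))
    for (g in unique(grp)) {
      mem <- sub[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        alignment_column = mem$alignment_column[1L],
        phase = ph,
        n_members = nrow(mem),
        n_species = length(unique(mem$species)),
        status = if (length(unique(mem$species)) >= 2L) "shared"
                 else "idiosyncratic",
        members = paste(sprintf("%s:%s:%d", mem$species, mem$gene_id,
                                mem$intron_index), collapse = ";"))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$alignment_column, res$phase), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count shared vs idiosyncratic introns for one species
#'
#' Summarizes a [classify_shared()] record table from the point of view of
#' one species: how many of its introns sit in records shared with at
#' least one other species, and how many are idiosyncratic to it.
#'
#' @param records data.frame from [classify_shared()].
#' @param species Species label.
#' @return Named integer vector `c(shared, idiosyncratic, total)`.
#' @export
shared_counts <- function(records, species) {
  shared <- 0L
  idio <- 0L
  for (i in seq_len(nrow(records))) {
    mem <- strsplit(records$members[i], ";", fixed = TRUE)[[1L]]
    sp <- sub(":.*$", "", mem)
    mine <- sum(sp == species)
    if (mine == 0L) next
    if (records$status[i] == "shared" && any(sp != species)) {
      shared <- shared + mine
    } else {
      idio <- idio + mine
    }
  }
  c(shared = shared, idiosyncratic = idio, total = shared + idio)
}
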