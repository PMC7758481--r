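#' Strand rule for editable substitutions
#'
#' A-to-I editing acts on the transcribed strand, so a genomic A>G call is
#' only a plausible editing event in a gene encoded on the plus strand, and
#' a genomic T>C call only in a minus-strand gene (where it is A>G in
#' transcript space).
#'
#' @param ref,alt Reference and alternate base on the genomic plus strand.
#' @param strand Gene strand, `"+"` or `"-"`.
#' @return Logical (vectorized).
#' @export
strand_rule <- function(ref, alt, strand) {
  (strand == "+" & ref == "A" & alt == "G") |
    (strand == "-" & ref == "T" & alt == "C")
}

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  unname(GENETIC_CODE_TABLE[codon])
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# spliced coding sequence of a transcript model (rows of one transcript_id),
# 5'->3' in transcript orientation, phase-trimmed
transcript_cds_seq <- function(model, genome) {
  model <- model[order(model$start), ]
  pieces <- vapply(seq_len(nrow(model)), function(i)
    as.character(Biostrings::subseq(genome[[model$contig[1]]],
                                    model$start[i], model$end[i])),
    character(1))
  cds <- paste(pieces, collapse = "")
  if (model$strand[1] == "-") cds <- revcomp(cds)
  phase <- model$phase[1]
  if (phase > 0L) cds <- substr(cds, phase + 1L, nchar(cds))
  cds
}

# 0-based offset of a genomic position within the spliced CDS (transcript
# orientation), before phase trimming; NA if not in any interval
genomic_to_cds_offset <- function(model, pos) {
  model <- model[order(model$start), ]
  widths <- model$end - model$start + 1L
  hit <- which(model$start <= pos & model$end >= pos)
  if (length(hit) == 0L) return(NA_integer_)
  if (model$strand[1] == "+") {
    sum(widths[seq_len(hit - 1L)]) + (pos - model$start[hit])
  } else {
    k <- nrow(model)
    before <- if (hit < k) sum(widths[(hit + 1L):k]) else 0L
    before + (model$end[hit] - pos)
  }
}

#' Annotate the coding effect of editing sites
#'
#' For every transcript whose coding sequence covers a site that passed the
#' strand rule, maps the genomic position to a CDS offset (reverse
#' complementing on minus-strand transcripts), mutates the codon, and
#' translates reference and alternate codons under the standard genetic
#' code. Sites covered by no CDS yield no rows (non-coding, dropped).
#' Codons containing N are dropped with a warning.
#'
#' @param sites Site tibble (`contig`, `pos`, `ref`, `alt`, other columns
#'   carried through).
#' @param models Transcript-model tibble from [read_gtf_cds()].
#' @param genome Genome from [read_fasta()].
#' @return Tibble with one row per (site, covering transcript) where the
#'   strand rule holds: site columns plus `transcript_id`, `gene_id`,
#'   `strand`, `cds_offset` (0-based), `codon_index` (1-based),
#'   `codon_pos` (1-3), `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `consequence` (synonymous / missense / stop_gained / stop_lost).
#' @export
annotate_coding <- function(sites, models, genome) {
  empty <- tibble(
    contig = character(), pos = integer(), ref = character(), alt = character(),
    editing_level = numeric(), transcript_id = character(), gene_id = character(),
    strand = character(), cds_offset = integer(), codon_index = integer(),
    codon_pos = integer(), ref_codon = character(), alt_codon = character(),
    ref_aa = character(), alt_aa = character(), consequence = character())
  if (nrow(sites) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    mods_here <- models[models$contig == sites$contig[i] &
                          models$start <= sites$pos[i] &
                          models$end >= sites$pos[i], ]
    for (tx in unique(mods_here$transcript_id)) {
      model <- models[models$transcript_id == tx, ]
      if (!strand_rule(sites$ref[i], sites$alt[i], model$strand[1])) next
      raw_off <- genomic_to_cds_offset(model, sites$pos[i])
      off <- raw_off - model$phase[1]
      if (is.na(off) || off < 0L) next      # in the phase-trimmed partial codon
      cds <- transcript_cds_seq(model, genome)
      codon_index <- off %/% 3L
      codon_pos <- off %% 3L + 1L
      ref_codon <- substr(cds, codon_index * 3L + 1L, codon_index * 3L + 3L)
      if (nchar(ref_codon) < 3L) next
      # transcript-space alternate base: as-is on '+', complemented on '-'
      tx_alt <- if (model$strand[1] == "+") sites$alt[i]
                else chartr("ACGT", "TGCA", sites$alt[i])
      alt_codon <- ref_codon
      substr(alt_codon, codon_pos, codon_pos) <- tx_alt
      ref_aa <- translate_codon(ref_codon)
      alt_aa <- translate_codon(alt_codon)
      if (is.na(ref_aa) || is.na(alt_aa)) {
        warning("ambiguous codon (contains N) at ", sites$contig[i], ":",
                sites$pos[i], " in ", tx, "; effect dropped")
        next
      }
      consequence <-
        if (ref_aa == alt_aa) "synonymous"
        else if (alt_aa == "*") "stop_gained"
        else if (ref_aa == "*") "stop_lost"
        else "missense"
      rows[[length(rows) + 1L]] <- tibble(
        contig = sites$contig[i], pos = sites$pos[i],
        ref = sites$ref[i], alt = sites$alt[i],
        editing_level = if ("editing_level" %in% names(sites))
          sites$editing_level[i] else NA_real_,
        transcript_id = tx, gene_id = model$gene_id[1],
        strand = model$strand[1],
        cds_offset = off, codon_index = codon_index + 1L,
        codon_pos = codon_pos, ref_codon = ref_codon, alt_codon = alt_codon,
        ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence)
    }
  }
  if (length(rows) == 0L) return(empty)
  bind_rows(rows)
}

#' Translate a transcript model to its protein sequence
#'
#' @param model Rows of one transcript from [read_gtf_cds()].
#' @param genome Genome from [read_fasta()].
#' @return Amino-acid string; a terminal stop is removed.
#' @export
transcript_protein <- function(model, genome) {
  cds <- transcript_cds_seq(model, genome)
  n_codon <- nchar(cds) %/% 3L
  aas <- vapply(seq_len(n_codon), function(j)
    translate_codon(substr(cds, 3L * j - 2L, 3L * j)), character(1))
  stop_at <- which(aas == "*")
  if (length(stop_at) > 0L) aas <- aas[seq_len(stop_at[1] - 1L)]
  paste(aas, collapse = "")
}

#' Build the variant-centered long peptide pair
#'
#' Extracts a window of up to `flank` residues on each side of the edited
#' residue from the mutant protein (21 residues total at the default flank
#' of 10), truncated at the protein termini when the edit sits close to an
#' end. The normal sequence is the same window of the unedited protein.
#' Only missense effects yield a pair; stop gains/losses are rejected.
#'
#' @param effects Coding-effect tibble from [annotate_coding()] (missense
#'   rows are used; others are dropped with a message).
#' @param models Transcript-model tibble.
#' @param genome Genome.
#' @param flank Residues flanking the edit on each side (default 10).
#' @return Tibble of long peptide pairs: effect columns plus
#'   `mutant_peptide`, `normal_peptide`, `edit_residue_index` (1-based
#'   within the peptide), `length`.
#' @export
long_peptides <- function(effects, models, genome, flank = 10L) {
  empty <- tibble(
    gene_id = character(), transcript_id = character(), contig = character(),
    pos = integer(), editing_level = numeric(), mutant_peptide = character(),
    normal_peptide = character(), edit_residue_index = integer(),
    length = integer())
  if (nrow(effects) == 0L) return(empty)
  dropped <- effects |> filter(.data$consequence %in% c("stop_gained", "stop_lost"))
  if (nrow(dropped) > 0L)
    message(nrow(dropped), " stop-gain/stop-loss effect(s) dropped (no peptide contract)")
  eff <- effects |> filter(.data$consequence == "missense")
  if (nrow(eff) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(eff)), function(i) {
    model <- models[models$transcript_id == eff$transcript_id[i], ]
    protein <- transcript_protein(model, genome)
    res <- eff$codon_index[i]
    if (res > nchar(protein)) return(NULL)   # edit beyond the stop codon
    lo <- max(1L, res - flank)
    hi <- min(nchar(protein), res + flank)
    normal <- substr(protein, lo, hi)
    mutant <- normal
    substr(mutant, res - lo + 1L, res - lo + 1L) <- eff$alt_aa[i]
    tibble(
      gene_id = eff$gene_id[i], transcript_id = eff$transcript_id[i],
      contig = eff$contig[i], pos = eff$pos[i],
      editing_level = eff$editing_level[i],
      mutant_peptide = mutant, normal_peptide = normal,
      edit_residue_index = res - lo + 1L, length = nchar(mutant))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) empty else out
}

#' Chop long peptide pairs into 9-11-mer short pairs
#'
#' Enumerates every window of length 9 to 11 of each long peptide that
#' contains the edited residue; mutant and normal windows are taken at
#' identical offsets, so each short pair differs at exactly the edited
#' position. Duplicate (mutant sequence, length) pairs are removed.
#'
#' @param long Long-peptide tibble from [long_peptides()].
#' @param kmin,kmax Window length range (defaults 9 and 11).
#' @return Tibble of short pairs with the same columns as `long`.
#' @export
chop_peptides <- function(long, kmin = 9L, kmax = 11L) {
  empty <- long[0, ]
  if (nrow(long) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(long)), function(i) {
    L <- long$length[i]
    e <- long$edit_residue_index[i]
    if (L < kmin) return(NULL)
    out <- list()
    for (k in seq.int(kmin, min(kmax, L))) {
      starts <- seq.int(max(1L, e - k + 1L), min(e, L - k + 1L))
      for (s in starts) {
        out[[length(out) + 1L]] <- tibble(
          gene_id = long$gene_id[i], transcript_id = long$transcript_id[i],
          contig = long$contig[i], pos = long$pos[i],
          editing_level = long$editing_level[i],
          mutant_peptide = substr(long$mutant_peptide[i], s, s + k - 1L),
          normal_peptide = substr(long$normal_peptide[i], s, s + k - 1L),
          edit_residue_index = e - s + 1L, length = k)
      }
    }
    bind_rows(out)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  distinct(out, .data$mutant_peptide, .data$length, .keep_all = TRUE)
}
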