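#' Specify a synthetic fixture
#'
#' Describes a deterministic toy dataset: one gene (90 bp CDS exon, 60 bp
#' intron, 90 bp CDS exon — a 60-codon protein) per planted edit, with the
#' edit's genomic context chosen by its class:
#' \describe{
#'   \item{clean}{missense edit inside the CDS, far from every filter bait}
#'   \item{synonymous}{third-position CDS edit that does not change the
#'     residue}
#'   \item{known_snp}{clean CDS edit whose position is also written to the
#'     known-variant VCF}
#'   \item{edge}{clean CDS edit whose supporting reads all carry it within
#'     the first 3 bp of the read}
#'   \item{splice}{intronic edit 2 bp from a splice junction, outside Alu}
#'   \item{alu}{intronic edit 2 bp from a junction but inside an Alu
#'     interval (exempt from the splice filter)}
#'   \item{homopolymer}{intronic edit immediately 3' of a planted AAAAA run}
#'   \item{panel}{clean CDS edit also written into two normal-sample site
#'     lists}
#'   \item{low_baseq}{clean CDS edit whose reads carry base quality exactly
#'     25 (fails the strict > 25 call threshold)}
#'   \item{low_mapq}{clean CDS edit whose reads carry mapping quality
#'     exactly 20 (fails the strict > 20 threshold)}
#'   \item{tpm_low}{clean CDS edit in a gene expressed below (or at) the
#'     TPM cut}
#' }
#'
#' @param edits Tibble with one row per planted edit: `class` (above),
#'   `codon_pos` (1-3, CDS classes only), `strand` ("+"/"-"), `level`
#'   (target editing level in (0, 1\]), `coverage` (reads over the site),
#'   `tpm` (expression assigned to the gene).
#' @param seed Integer seed; identical (spec, seed) reproduce byte-identical
#'   files.
#' @param read_length Read length (default 50).
#' @param base_q,map_q Default base and mapping quality (35 and 60; the
#'   low-quality classes override them with the boundary values 25 and 20).
#' @param n_normals Number of normal-sample site lists (default 3).
#' @param contig Contig name (default "chr1").
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(edits = default_fixture_edits(), seed = 1L,
                         read_length = 50L, base_q = 35L, map_q = 60L,
                         n_normals = 3L, contig = "chr1") {
  edits <- as_tibble(edits)
  needed <- c("class", "codon_pos", "strand", "level", "coverage", "tpm")
  for (nm in setdiff(needed, names(edits))) {
    edits[[nm]] <- switch(nm, class = "clean", codon_pos = 2L, strand = "+",
                          level = 1.0, coverage = 30L, tpm = 10)
  }
  known <- c("clean", "synonymous", "known_snp", "edge", "splice", "alu",
             "homopolymer", "panel", "low_baseq", "low_mapq", "tpm_low")
  if (any(!edits$class %in% known))
    stop("unknown edit class(es): ",
         paste(setdiff(edits$class, known), collapse = ", "))
  if (any(edits$level <= 0 | edits$level > 1))
    stop("editing levels must lie in (0, 1]")
  if (any(edits$coverage < 1L)) stop("coverage must be >= 1")
  if (any(!edits$codon_pos %in% 1:3)) stop("codon_pos must be 1, 2 or 3")
  if (any(!edits$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (read_length < 20L) stop("read_length must be >= 20")
  structure(list(edits = edits, seed = as.integer(seed),
                 read_length = as.integer(read_length),
                 base_q = as.integer(base_q), map_q = as.integer(map_q),
                 n_normals = as.integer(n_normals), contig = contig),
            class = "fixture_spec")
}

#' Default planted-edit table: one edit of every class
#'
#' @return Tibble usable as the `edits` argument of [fixture_spec()].
#' @export
default_fixture_edits <- function() {
  tibble(
    class = c("clean", "clean", "synonymous", "known_snp", "edge", "splice",
              "alu", "homopolymer", "panel", "low_baseq", "low_mapq",
              "tpm_low"),
    codon_pos = c(2L, 1L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
    strand = c("+", "-", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+"),
    level = 1.0,
    coverage = 30L,
    tpm = c(10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 0.5))
}

# gene cassette geometry (all lengths in bp)
FIX_EXON <- 90L       # per CDS exon
FIX_INTRON <- 60L
FIX_GAP <- 150L       # background between cassettes
FIX_MARGIN <- 100L
FIX_CODON_IDX <- 30L  # planted codon (1-based) for CDS classes

# planted codons: edited base A at codon_pos, chosen consequence
fix_codon <- function(codon_pos, synonymous = FALSE) {
  if (synonymous) return("GCA")                 # GCA -> GCG, Ala -> Ala
  switch(codon_pos, "ATG",                      # ATG -> GTG, Met -> Val
                    "TAT",                      # TAT -> TGT, Tyr -> Cys
                    stop("third-position plants are the synonymous class"))
}

# random DNA with no run longer than 3, as a character vector of bases
random_bases <- function(n) {
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      b <- sample(c("A", "C", "G", "T"), 1L)
      if (i < 3L || !(b == out[i - 1L] && b == out[i - 2L])) break
    }
    out[i] <- b
  }
  out
}

# 60-codon CDS (no stop codons, no run > 3) with the planted codon inserted
random_cds <- function(n_codon, plant_idx, plant_codon) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codon)
  prev_tail <- ""
  for (j in seq_len(n_codon)) {
    if (j == plant_idx) {
      codons[j] <- plant_codon
    } else {
      repeat {
        cd <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                    collapse = "")
        if (cd %in% stops) next
        if (!grepl("(.)\\1\\1", paste0(prev_tail, cd))) break
      }
      codons[j] <- cd
    }
    prev_tail <- substr(codons[j], 2L, 3L)
  }
  paste(codons, collapse = "")
}

#' Generate synthetic pipeline inputs with planted edits
#'
#' Writes a complete, mutually consistent input set — reference FASTA,
#' coordinate-sorted SAM, CDS GTF, Alu BED, known-variant VCF, normal-sample
#' site lists, expression TSV and a mock-predictor affinity TSV — plus a
#' `truth.tsv`, and returns the truth table: one row per planted edit with
#' its coordinates, the binomially drawn edited-read count, and the expected
#' behavior of every filter stage. Outputs are byte-identical for identical
#' (spec, seed).
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return The truth tibble, invisibly carrying `outdir` as an attribute.
#' @export
generate_fixtures <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "normals"), showWarnings = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  edits <- spec$edits
  n <- nrow(edits)
  rl <- spec$read_length
  stride <- 2L * FIX_EXON + FIX_INTRON + FIX_GAP
  glen <- FIX_MARGIN + n * stride + FIX_MARGIN
  genome_chars <- random_bases(glen)

  truth_rows <- list()
  gtf_rows <- list()
  sam_reads <- list()
  alu_rows <- list()
  known_rows <- list()
  panel_rows <- list()
  expr_rows <- list(tibble(
    gene_id = c("GZMA", "GZMB", "PRF1", "KLRD1", "CD8A", "CD8B"),
    tpm = c(8, 4, 2, 1, 5, 3)))

  for (i in seq_len(n)) {
    cls <- edits$class[i]
    strand <- edits$strand[i]
    gene_id <- sprintf("gene_%02d", i)
    tx_id <- sprintf("tx_%02d", i)
    s <- FIX_MARGIN + (i - 1L) * stride + 1L
    e1 <- c(s, s + FIX_EXON - 1L)
    e2 <- c(s + FIX_EXON + FIX_INTRON, s + 2L * FIX_EXON + FIX_INTRON - 1L)
    cds_in_gene <- cls %in% c("clean", "synonymous", "known_snp", "edge",
                              "panel", "low_baseq", "low_mapq", "tpm_low")

    # coding sequence with the planted codon (intron-class genes get a
    # benign codon so the gene still translates cleanly)
    plant_codon <- if (cds_in_gene)
      fix_codon(edits$codon_pos[i], synonymous = cls == "synonymous")
    else "TAC"
    cds <- random_cds((2L * FIX_EXON) %/% 3L, FIX_CODON_IDX, plant_codon)
    genomic_cds <- if (strand == "+") cds else revcomp(cds)
    gchars <- strsplit(genomic_cds, "")[[1]]
    genome_chars[e1[1]:e1[2]] <- gchars[1:FIX_EXON]
    genome_chars[e2[1]:e2[2]] <- gchars[(FIX_EXON + 1L):(2L * FIX_EXON)]

    # genomic position of the edited base
    if (cds_in_gene) {
      o <- (FIX_CODON_IDX - 1L) * 3L + (edits$codon_pos[i] - 1L)  # 0-based CDS offset
      j <- if (strand == "+") o else (2L * FIX_EXON - 1L) - o     # offset in genomic concat
      pos <- if (j < FIX_EXON) s + j else e2[1] + (j - FIX_EXON)
      ref <- if (strand == "+") "A" else "T"
      alt <- if (strand == "+") "G" else "C"
    } else {
      intron_start <- e1[2] + 1L
      pos <- switch(cls,
        splice = intron_start + 1L,                 # 2 bp from the donor junction
        alu = intron_start + 1L,
        homopolymer = intron_start + FIX_INTRON %/% 2L)
      ref <- "A"; alt <- "G"
      genome_chars[pos] <- "A"
      genome_chars[pos - 1L] <- "C"
      genome_chars[pos + 1L] <- "T"
      if (cls == "homopolymer") {
        genome_chars[(pos - 5L):(pos - 1L)] <- "A"
        genome_chars[pos - 6L] <- "C"
      }
      if (cls == "alu")
        alu_rows[[length(alu_rows) + 1L]] <-
          tibble(contig = spec$contig, start = intron_start,
                 end = e2[1] - 1L)
    }

    gtf_rows[[length(gtf_rows) + 1L]] <- tibble(
      start = c(e1[1], e2[1]), end = c(e1[2], e2[2]), strand = strand,
      gene_id = gene_id, transcript_id = tx_id)

    # reads: coverage c over the site, edited count drawn binomially
    cvg <- edits$coverage[i]
    k <- rbinom(1L, cvg, edits$level[i])
    edited_idx <- if (k > 0L) sort(sample.int(cvg, k)) else integer(0)
    bq <- if (cls == "low_baseq") 25L else spec$base_q
    mq <- if (cls == "low_mapq") 20L else spec$map_q
    interior <- seq.int(4L, rl - 4L)   # 0-based site offsets clear of both edges
    for (r in seq_len(cvg)) {
      off <- if (cls == "edge") 1L else interior[(r - 1L) %% length(interior) + 1L]
      rstart <- pos - off
      rseq <- genome_chars[rstart:(rstart + rl - 1L)]
      if (r %in% edited_idx) rseq[off + 1L] <- alt
      sam_reads[[length(sam_reads) + 1L]] <- tibble(
        qname = sprintf("rd_%02d_%03d", i, r), flag = 0L, rname = spec$contig,
        pos = rstart, mapq = mq, cigar = paste0(rl, "M"),
        seq = paste(rseq, collapse = ""),
        qual = strrep(intToUtf8(33L + bq), rl))
    }

    if (cls == "known_snp")
      known_rows[[length(known_rows) + 1L]] <-
        tibble(contig = spec$contig, pos = pos, ref = ref, alt = alt)
    if (cls == "panel")
      panel_rows[[length(panel_rows) + 1L]] <-
        tibble(contig = spec$contig, pos = pos, ref = ref, alt = alt)
    expr_rows[[length(expr_rows) + 1L]] <- tibble(gene_id = gene_id,
                                                  tpm = edits$tpm[i])

    # expected behavior and peptide truth
    consequence <- if (!cds_in_gene) "non_coding"
      else if (cls == "synonymous") "synonymous" else "missense"
    long_mut <- long_nrm <- NA_character_
    edit_idx <- NA_integer_
    if (consequence == "missense") {
      protein <- vapply(seq_len(nchar(cds) %/% 3L), function(jj)
        unname(GENETIC_CODE_TABLE[substr(cds, 3L * jj - 2L, 3L * jj)]),
        character(1))
      alt_codon <- plant_codon
      substr(alt_codon, edits$codon_pos[i], edits$codon_pos[i]) <- "G"
      mut_protein <- protein
      mut_protein[FIX_CODON_IDX] <- unname(GENETIC_CODE_TABLE[alt_codon])
      lo <- FIX_CODON_IDX - 10L; hi <- FIX_CODON_IDX + 10L
      long_mut <- paste(mut_protein[lo:hi], collapse = "")
      long_nrm <- paste(protein[lo:hi], collapse = "")
      edit_idx <- 11L
    }
    truth_rows[[length(truth_rows) + 1L]] <- tibble(
      class = cls, gene_id = gene_id, transcript_id = tx_id, strand = strand,
      contig = spec$contig, pos = pos, ref = ref, alt = alt,
      level = edits$level[i], coverage = cvg, n_edited = k,
      tpm = edits$tpm[i],
      detectable = k > 0L && !cls %in% c("low_baseq", "low_mapq"),
      survives_known = cls != "known_snp",
      survives_edge = cls != "edge",
      survives_splice = cls != "splice",
      survives_homopolymer = cls != "homopolymer",
      survives_panel = cls != "panel",
      consequence = consequence,
      long_mutant = long_mut, long_normal = long_nrm,
      edit_residue_index = edit_idx)
  }

  truth <- bind_rows(truth_rows)
  genome_seq <- paste(genome_chars, collapse = "")

  # reference FASTA
  writeLines(c(paste0(">", spec$contig),
               substring(genome_seq, seq(1L, glen, 70L),
                         pmin(seq(1L, glen, 70L) + 69L, glen))),
             file.path(outdir, "ref.fa"))

  # coordinate-sorted SAM
  reads <- bind_rows(sam_reads) |> arrange(.data$pos, .data$qname)
  sam_lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", spec$contig, glen),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
            reads$cigar, reads$seq, reads$qual))
  writeLines(sam_lines, file.path(outdir, "reads.sam"))

  # CDS GTF
  gtf <- bind_rows(gtf_rows)
  writeLines(sprintf(
    '%s\teditscan\tCDS\t%d\t%d\t.\t%s\t0\tgene_id "%s"; transcript_id "%s";',
    spec$contig, gtf$start, gtf$end, gtf$strand, gtf$gene_id,
    gtf$transcript_id), file.path(outdir, "models.gtf"))

  # Alu BED (1-based inclusive -> BED half-open)
  alu <- bind_rows(alu_rows)
  writeLines(if (nrow(alu) > 0L)
    sprintf("%s\t%d\t%d", alu$contig, alu$start - 1L, alu$end)
    else character(0), file.path(outdir, "alu.bed"))

  # known-variant VCF
  known <- bind_rows(known_rows)
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", spec$contig, glen),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    if (nrow(known) > 0L)
      sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", known$contig, known$pos,
              known$ref, known$alt) else character(0)),
    file.path(outdir, "known.vcf"))

  # normal-sample site lists: panel-class sites occur in normals 1 and 2
  panel <- bind_rows(panel_rows)
  for (nn in seq_len(spec$n_normals)) {
    lines <- if (nn <= 2L && nrow(panel) > 0L)
      sprintf("%s\t%d\t%s\t%s", panel$contig, panel$pos, panel$ref, panel$alt)
    else character(0)
    writeLines(lines, file.path(outdir, "normals",
                                sprintf("normal_%d.tsv", nn)))
  }

  # expression TSV
  expr <- bind_rows(expr_rows)
  writeLines(c("gene_id\ttpm",
               sprintf("%s\t%s", expr$gene_id, sprintf("%.6g", expr$tpm))),
             file.path(outdir, "expression.tsv"))

  # affinity TSV via the mock predictor over the truth peptides
  pred <- mock_predictor(spec$seed)
  alleles <- c("HLA-A*02:01", "HLA-B*07:02")
  aff_rows <- list()
  for (i in which(!is.na(truth$long_mutant))) {
    lp <- tibble(gene_id = truth$gene_id[i],
                 transcript_id = truth$transcript_id[i],
                 contig = truth$contig[i], pos = truth$pos[i],
                 editing_level = truth$level[i],
                 mutant_peptide = truth$long_mutant[i],
                 normal_peptide = truth$long_normal[i],
                 edit_residue_index = truth$edit_residue_index[i],
                 length = nchar(truth$long_mutant[i]))
    sp <- chop_peptides(lp)
    for (pep in unique(c(sp$mutant_peptide, sp$normal_peptide)))
      for (al in alleles)
        aff_rows[[length(aff_rows) + 1L]] <-
          tibble(peptide = pep, allele = al, rank = pred(pep, al))
  }
  aff <- bind_rows(aff_rows)
  writeLines(c("peptide\tallele\trank",
               if (nrow(aff) > 0L)
                 sprintf("%s\t%s\t%.10g", aff$peptide, aff$allele, aff$rank)
               else character(0)),
             file.path(outdir, "affinity.tsv"))

  readr::write_tsv(truth, file.path(outdir, "truth.tsv"))
  attr(truth, "outdir") <- outdir
  invisible(truth)
}

#' Compare pipeline outputs against fixture truth
#'
#' Reconciles the filtered site table and final candidate table of a
#' pipeline run with the truth table of the fixture it ran on, and reports
#' confusion counts per planted-edit class. Candidate expectations assume a
#' permissive binding-rank cut (the mock predictor's ranks are uniform on
#' (0, 100\], so with the default cut of 2 most peptides are rejected by
#' design); the expression cut stays at its default.
#'
#' @param truth Truth tibble from [generate_fixtures()].
#' @param sites Filtered site tibble produced by the pipeline.
#' @param candidates Final candidate tibble (may be `NULL` to check sites
#'   only).
#' @return Tibble with one row per class: `class`, `n_planted`,
#'   `expected_in_sites`, `found_in_sites`, `expected_in_candidates`,
#'   `found_in_candidates`; plus attributes `false_positive_sites` (site
#'   rows matching no planted position) and `false_negatives` (truth rows
#'   expected but absent).
#' @export
end_to_end_check <- function(truth, sites, candidates = NULL) {
  truth <- truth |>
    mutate(expect_site = .data$detectable & .data$survives_known &
             .data$survives_edge & .data$survives_splice &
             .data$survives_homopolymer & .data$survives_panel,
           expect_candidate = .data$expect_site &
             .data$consequence == "missense" & .data$tpm > 1,
           in_sites = paste(.data$contig, .data$pos) %in%
             paste(sites$contig, sites$pos),
           in_candidates = if (is.null(candidates)) NA else
             .data$gene_id %in% candidates$gene_id)
  report <- truth |>
    group_by(.data$class) |>
    summarise(
      n_planted = dplyr::n(),
      expected_in_sites = sum(.data$expect_site),
      found_in_sites = sum(.data$in_sites),
      expected_in_candidates = sum(.data$expect_candidate),
      found_in_candidates = if (is.null(candidates)) NA_integer_
        else sum(.data$in_candidates & .data$expect_candidate),
      .groups = "drop")
  fp <- sites[!paste(sites$contig, sites$pos) %in%
                paste(truth$contig, truth$pos), ]
  fn <- truth[truth$expect_site & !truth$in_sites, ]
  attr(report, "false_positive_sites") <- fp
  attr(report, "false_negatives") <- fn
  report
}
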