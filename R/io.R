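#' Read a reference genome from FASTA
#'
#' Loads every contig, uppercases the sequence, and checks the alphabet is
#' restricted to A/C/G/T/N. The result is a named [Biostrings::DNAStringSet]
#' with one entry per contig; use [genome_base()] for single-base lookup at a
#' 1-based position.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], names are contig names (first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  gen <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ", conditionMessage(e))
  )
  if (length(gen) == 0L) stop("no records in FASTA file: ", path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  gen <- Biostrings::DNAStringSet(toupper(as.character(gen)))
  bad <- setdiff(unique(strsplit(paste(as.character(gen), collapse = ""), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L)
    stop("FASTA alphabet outside {A,C,G,T,N}: ", paste(bad, collapse = ","))
  gen
}

#' Look up reference bases at 1-based positions
#'
#' @param genome A genome as returned by [read_fasta()].
#' @param contig Contig name (length 1 or recycled against `pos`).
#' @param pos 1-based position(s).
#' @return Character vector of single bases.
#' @export
genome_base <- function(genome, contig, pos) {
  n <- max(length(contig), length(pos))
  contig <- rep_len(contig, n)
  pos <- rep_len(as.integer(pos), n)
  vapply(seq_len(n), function(i) {
    cl <- genome_contig_length(genome, contig[i])
    if (is.na(pos[i]) || pos[i] < 1L || pos[i] > cl)
      stop("position ", contig[i], ":", pos[i], " out of range (contig length ", cl, ")")
    as.character(Biostrings::subseq(genome[[contig[i]]], pos[i], pos[i]))
  }, character(1))
}

genome_contig_length <- function(genome, contig) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  Biostrings::width(genome[names(genome) == contig])[1]
}

#' Read CDS transcript models from GTF/GFF
#'
#' Keeps `CDS` features only and assembles one model per transcript: ordered
#' (genomic order) CDS intervals, strand, and the phase of the first coding
#' base. Transcripts whose total CDS length is not a multiple of three after
#' phase adjustment are dropped with a warning.
#'
#' @param path Path to a GTF or GFF file with CDS features carrying
#'   `transcript_id` and `gene_id` attributes.
#' @return A tibble with one row per CDS interval:
#'   `transcript_id`, `gene_id`, `contig`, `strand`, `start`, `end`, `phase`
#'   (phase of the transcript's first coding base, repeated on every row).
#'   Rows are sorted by transcript then genomic start.
#' @export
read_gtf_cds <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in: ", path)
  strand_chr <- as.character(GenomicRanges::strand(gr))
  if (any(!strand_chr %in% c("+", "-")))
    stop("strand required ('+' or '-') for every CDS feature")
  ph <- gr$phase %||% rep(0L, length(gr))
  ph[is.na(ph)] <- 0L
  tab <- tibble(
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = strand_chr,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    row_phase = as.integer(ph)
  ) |>
    arrange(.data$transcript_id, .data$start)

  out <- tab |>
    group_by(.data$transcript_id) |>
    mutate(
      # phase of the 5'-most coding base: first interval in genomic order on
      # '+', last interval on '-'
      phase = ifelse(.data$strand[1] == "+",
                     .data$row_phase[1],
                     .data$row_phase[dplyr::n()])
    ) |>
    ungroup() |>
    select(-"row_phase")

  keep <- out |>
    group_by(.data$transcript_id) |>
    summarise(
      len = sum(.data$end - .data$start + 1L),
      phase = .data$phase[1],
      overlapping = any(.data$start[-1] <= cummax(.data$end)[-dplyr::n()]),
      .groups = "drop"
    ) |>
    mutate(ok = !.data$overlapping & ((.data$len - .data$phase) %% 3L == 0L))
  bad <- keep$transcript_id[!keep$ok]
  if (length(bad) > 0L)
    warning("dropping transcript(s) with invalid CDS structure: ",
            paste(bad, collapse = ", "))
  out |> filter(!.data$transcript_id %in% bad)
}

#' Read a site list (VCF or 3-column TSV)
#'
#' Accepts either a sites-only VCF (extension `.vcf`) or a headerless
#' tab-separated file with columns contig, position, alt (optionally with a
#' ref column: contig, position, ref, alt).
#'
#' @param path Path to the site list.
#' @return A site tibble with columns `contig`, `pos` (1-based), `ref`,
#'   `alt` (ref may be `NA` for 3-column TSV input).
#' @export
read_site_list <- function(path) {
  if (!file.exists(path)) stop("site list not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                  function(a) as.character(a)[1], character(1))
    out <- tibble(
      contig = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(VariantAnnotation::ref(vcf)),
      alt = alt
    )
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    if (nrow(raw) == 0L)
      return(tibble(contig = character(), pos = integer(),
                    ref = character(), alt = character()))
    if (ncol(raw) < 3L) stop("site TSV needs >= 3 columns (contig, pos, alt): ", path)
    if (ncol(raw) >= 4L) {
      out <- tibble(contig = raw[[1]], pos = as.integer(raw[[2]]),
                    ref = raw[[3]], alt = raw[[4]])
    } else {
      out <- tibble(contig = raw[[1]], pos = as.integer(raw[[2]]),
                    ref = NA_character_, alt = raw[[3]])
    }
  }
  validate_site_table(out)
}

validate_site_table <- function(tab) {
  stopifnot(all(c("contig", "pos", "alt") %in% names(tab)))
  if (any(tab$pos < 1L, na.rm = TRUE)) stop("site position < 1")
  badref <- !is.na(tab$ref) & nchar(tab$ref) != 1L
  if (any(badref | nchar(tab$alt) != 1L))
    stop("ref/alt must be single bases")
  if (anyDuplicated(tab[, c("contig", "pos", "alt")]) > 0L)
    stop("duplicate (contig, pos, alt) rows in site table")
  as_tibble(tab)
}

#' Write a site table as 4-column TSV
#'
#' Columns contig, pos, ref, alt, readable back by [read_site_list()]
#' (round-trip preserves the row set).
#'
#' @param tab A site tibble (`contig`, `pos`, `ref`, `alt`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(tab, path) {
  out <- tab
  out$ref[is.na(out$ref)] <- "N"
  readr::write_tsv(out[, c("contig", "pos", "ref", "alt")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a gene expression table (gene, TPM)
#'
#' @param path Two-column TSV, gene id then TPM; a header line is detected
#'   and skipped when the second field is non-numeric.
#' @return Tibble with columns `gene_id`, `tpm`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) > 0L && is.na(suppressWarnings(as.numeric(raw[[2]][1]))))
    raw <- raw[-1, ]
  out <- tibble(gene_id = raw[[1]], tpm = as.numeric(raw[[2]]))
  if (any(is.na(out$tpm)) || any(out$tpm < 0))
    stop("TPM values must be non-negative numbers")
  out
}

#' Read a BED file into 1-based inclusive intervals
#'
#' BED is 0-based half-open; intervals are converted at this boundary so a
#' BED line `chr1 99 100` becomes the single base chr1:100.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `contig`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),  # rtracklayer converts to 1-based
    end = GenomicRanges::end(gr)
  )
  if (nrow(out) > 0L && any(out$start < 1L)) stop("interval start < 1 after conversion")
  out
}

#' Write 1-based inclusive intervals as BED
#'
#' Inverse of [read_bed()]: internal 1-based inclusive intervals are written
#' 0-based half-open.
#'
#' @param intervals Tibble with `contig`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(
    tibble(intervals$contig, intervals$start - 1L, intervals$end),
    path, col_names = FALSE)
  invisible(path)
}

# membership of positions in a 1-based inclusive interval set
in_intervals <- function(contig, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(intervals$contig == contig[i] &
          intervals$start <= pos[i] & intervals$end >= pos[i])
  }, logical(1))
}
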