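#' Read aligned reads from a coordinate-sorted SAM file
#'
#' Parses the plain-text SAM format directly (the fixtures and unit tests in
#' this package are all text SAM). Records that are unmapped, secondary,
#' supplementary, or flagged as PCR/optical duplicates are skipped —
#' duplicate marking is expected upstream and only the FLAG bit is honored.
#' A header is required and coordinate order is verified.
#'
#' @param path Path to a SAM file with an `@HD`/`@SQ` header.
#' @return A tibble with one row per usable alignment: `read_id`, `flag`,
#'   `contig`, `pos` (1-based leftmost reference position), `mapq`, `cigar`,
#'   `seq`, `qual` (ASCII Phred+33 string).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  hdr <- startsWith(lines, "@")
  if (!any(hdr) || !hdr[1]) stop("SAM header missing in: ", path)
  body <- lines[!hdr & nzchar(lines)]
  if (length(body) == 0L) {
    return(tibble(read_id = character(), flag = integer(), contig = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  seq = character(), qual = character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L))
    stop("malformed SAM record (fewer than 11 fields) at body line ",
         which(nf < 11L)[1])
  get <- function(i) vapply(f, `[[`, character(1), i)
  out <- tibble(
    read_id = get(1), flag = as.integer(get(2)), contig = get(3),
    pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
    seq = toupper(get(10)), qual = get(11)
  )
  # coordinate-sorted: positions non-decreasing within a contig block, and no
  # contig block repeated
  rle_contig <- rle(out$contig)
  if (anyDuplicated(rle_contig$values) > 0L ||
      any(unlist(tapply(out$pos, factor(out$contig, levels = unique(out$contig)),
                        function(p) diff(p) < 0L))))
    stop("SAM input is not coordinate-sorted: ", path)
  drop <- bitwAnd(out$flag, 0x4L) > 0L |   # unmapped
    bitwAnd(out$flag, 0x100L) > 0L |       # secondary
    bitwAnd(out$flag, 0x800L) > 0L |       # supplementary
    bitwAnd(out$flag, 0x400L) > 0L         # duplicate
  out <- out[!drop, ]
  bad <- nchar(out$seq) != nchar(out$qual)
  if (any(bad)) stop("sequence/quality length mismatch for read ", out$read_id[bad][1])
  qlen <- vapply(out$cigar, cigar_query_length, integer(1), USE.NAMES = FALSE)
  if (any(qlen != nchar(out$seq)))
    stop("CIGAR does not consume the read sequence for read ",
         out$read_id[qlen != nchar(out$seq)][1])
  out
}

parse_cigar <- function(cigar) {
  if (cigar == "*") stop("missing CIGAR")
  toks <- regmatches(cigar, gregexpr("\\d+[MIDSN=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("unsupported CIGAR: ", cigar)
  list(len = as.integer(sub("[MIDSN=X]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

cigar_query_length <- function(cigar) {
  p <- parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
}

#' Expand alignments into per-base pileup observations
#'
#' Walks each read's CIGAR and emits one row per aligned (match-state) base:
#' its reference position, the read base and quality, the read mapping
#' quality, and the base's offset from each end of the aligned query
#' (soft-clipped bases excluded from the offset count). This long
#' observation table is the substrate for candidate detection, editing-level
#' computation, and the read-edge filter.
#'
#' @param reads Alignment tibble from [read_sam()].
#' @return Tibble with columns `read_id`, `contig`, `pos` (reference,
#'   1-based), `base`, `base_q` (integer Phred), `map_q`, `off_start`,
#'   `off_end` (0-based offsets from the aligned-query ends).
#' @export
pileup_observations <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble(read_id = character(), contig = character(), pos = integer(),
                  base = character(), base_q = integer(), map_q = integer(),
                  off_start = integer(), off_end = integer()))
  }
  per_read <- lapply(seq_len(nrow(reads)), function(i) {
    p <- parse_cigar(reads$cigar[i])
    op <- ifelse(p$op %in% c("=", "X"), "M", p$op)
    qseq <- strsplit(reads$seq[i], "")[[1]]
    quals <- utf8ToInt(reads$qual[i]) - 33L
    aligned_len <- sum(p$len[op %in% c("M", "I")])
    rpos <- reads$pos[i]
    qpos <- 1L          # 1-based index into the query sequence
    apos <- 0L          # 0-based offset within the aligned (non-clipped) query
    ref <- integer(0); qidx <- integer(0); aoff <- integer(0)
    for (k in seq_along(op)) {
      l <- p$len[k]
      switch(op[k],
        M = {
          ref <- c(ref, seq.int(rpos, length.out = l))
          qidx <- c(qidx, seq.int(qpos, length.out = l))
          aoff <- c(aoff, seq.int(apos, length.out = l))
          rpos <- rpos + l; qpos <- qpos + l; apos <- apos + l
        },
        I = { qpos <- qpos + l; apos <- apos + l },
        D = ,
        N = { rpos <- rpos + l },
        S = { qpos <- qpos + l }
      )
    }
    tibble(
      read_id = reads$read_id[i], contig = reads$contig[i], pos = ref,
      base = qseq[qidx], base_q = quals[qidx], map_q = reads$mapq[i],
      off_start = aoff, off_end = aligned_len - 1L - aoff
    )
  })
  bind_rows(per_read)
}
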