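# in-code builders for tiny hand-crafted inputs

write_mini_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm), seqs[[nm]])))
  writeLines(lines, path)
  path
}

# reads: list of c(qname, flag, rname, pos, mapq, cigar, seq, qual)
write_mini_sam <- function(reads, path = tempfile(fileext = ".sam"),
                           contigs = c(chr1 = 10000L), header = TRUE) {
  lines <- character(0)
  if (header) {
    lines <- c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  }
  for (r in reads) {
    lines <- c(lines, paste(r[1], r[2], r[3], r[4], r[5], r[6],
                            "*", "0", "0", r[7], r[8], sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# n identical-length reads stacked over one locus; `bases` gives the read
# base at reference position `site` for each read
stack_reads <- function(refseq, site, bases, start = NULL, rl = 50L,
                        baseq = 35L, mapq = 60L, contig = "chr1") {
  n <- length(bases)
  starts <- if (is.null(start)) site - (3L + (seq_len(n) - 1L) %% (rl - 8L))
            else rep_len(start, n)
  lapply(seq_len(n), function(i) {
    s <- starts[i]
    sq <- substring(refseq, s, s + rl - 1L)
    substr(sq, site - s + 1L, site - s + 1L) <- bases[i]
    c(sprintf("r%03d", i), "0", contig, s, mapq, paste0(rl, "M"), sq,
      strrep(intToUtf8(33L + baseq), rl))
  })[order(starts)]
}

# independent codon table (standard genetic code), frozen from an external
# reference implementation
FROZEN_CODE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",TCT="S",TCC="S",TCA="S",TCG="S",
  TAT="Y",TAC="Y",TAA="*",TAG="*",TGT="C",TGC="C",TGA="*",TGG="W",
  CTT="L",CTC="L",CTA="L",CTG="L",CCT="P",CCC="P",CCA="P",CCG="P",
  CAT="H",CAC="H",CAA="Q",CAG="Q",CGT="R",CGC="R",CGA="R",CGG="R",
  ATT="I",ATC="I",ATA="I",ATG="M",ACT="T",ACC="T",ACA="T",ACG="T",
  AAT="N",AAC="N",AAA="K",AAG="K",AGT="S",AGC="S",AGA="R",AGG="R",
  GTT="V",GTC="V",GTA="V",GTG="V",GCT="A",GCC="A",GCA="A",GCG="A",
  GAT="D",GAC="D",GAA="E",GAG="E",GGT="G",GGC="G",GGA="G",GGG="G")

# brute-force per-read mismatch scanner: counts qualifying observations at
# every reference position by walking each read base-by-base, independent of
# the pileup implementation
brute_force_counts <- function(reads, refseq, min_base_q = 25L,
                               min_map_q = 20L) {
  counts <- list()
  for (r in reads) {
    pos <- as.integer(r[4]); mapq <- as.integer(r[5])
    if (mapq <= min_map_q) next
    stopifnot(grepl("^\\d+M$", r[6]))  # scanner handles ungapped reads
    sq <- strsplit(r[7], "")[[1]]
    qs <- utf8ToInt(r[8]) - 33L
    for (k in seq_along(sq)) {
      if (qs[k] <= min_base_q) next
      rp <- pos + k - 1L
      key <- as.character(rp)
      cur <- counts[[key]]
      if (is.null(cur)) cur <- c(total = 0L, G = 0L, C = 0L)
      cur["total"] <- cur["total"] + 1L
      if (sq[k] == "G") cur["G"] <- cur["G"] + 1L
      if (sq[k] == "C") cur["C"] <- cur["C"] + 1L
      counts[[key]] <- cur
    }
  }
  counts
}

# all length-k substrings of `long` whose window covers position `e`
# (enumeration oracle for the chopper)
all_variant_windows <- function(long, e, kmin = 9L, kmax = 11L) {
  out <- character(0)
  L <- nchar(long)
  for (k in kmin:kmax) {
    if (k > L) next
    for (s in 1:(L - k + 1L)) {
      if (s <= e && e <= s + k - 1L) out <- c(out, substr(long, s, s + k - 1L))
    }
  }
  unique(out)
}

# one hand-built two-exon gene for peptide tests: 12-codon CDS split 18|18
# across a 10-bp intron
mini_gene <- function(strand = "+", cds = NULL) {
  if (is.null(cds))
    cds <- "ATGGATTGTCCAGTACGCTTAGACATTGTCAACTAG"  # M D C P V R L D I V N *
  stopifnot(nchar(cds) == 36L)
  genomic <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  pad5 <- "CCTTCCTTCC"; intron <- "GTCCTTCCAG"; pad3 <- "TTCCTTCCTT"
  seqs <- paste0(pad5, substr(genomic, 1, 18), intron,
                 substr(genomic, 19, 36), pad3)
  models <- tibble::tibble(
    transcript_id = "tx1", gene_id = "g1", contig = "chrM",
    strand = strand, start = c(11L, 39L), end = c(28L, 56L), phase = 0L)
  list(genome = Biostrings::DNAStringSet(c(chrM = seqs)), models = models,
       cds = cds)
}
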