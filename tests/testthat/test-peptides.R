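test_that("strand rule keeps transcript-space A>G only", {
  expect_true(strand_rule("A", "G", "+"))
  expect_false(strand_rule("T", "C", "+"))
  expect_true(strand_rule("T", "C", "-"))
  expect_false(strand_rule("A", "G", "-"))
  expect_false(strand_rule("C", "T", "+"))
})

test_that("codon translation agrees with an independent code table", {
  for (cd in names(FROZEN_CODE)) {
    expect_equal(unname(editscan:::translate_codon(cd)),
                 unname(FROZEN_CODE[cd]))
  }
  expect_true(is.na(editscan:::translate_codon("ANA")))
})

test_that("plus-strand annotation mutates the codon and classifies effects", {
  g <- mini_gene("+")
  # CDS codon 2 is GAT at genomic 14..16; the A at pos 15 (codon pos 2)
  site <- tibble::tibble(contig = "chrM", pos = 15L, ref = "A", alt = "G",
                         editing_level = 1.0)
  eff <- annotate_coding(site, g$models, g$genome)
  expect_equal(nrow(eff), 1L)
  expect_equal(eff$ref_codon, "GAT")
  expect_equal(eff$alt_codon, "GGT")
  expect_equal(eff$ref_aa, "D")
  expect_equal(eff$alt_aa, "G")
  expect_equal(eff$consequence, "missense")
  expect_equal(eff$codon_index, 2L)
  expect_equal(eff$codon_pos, 2L)

  # third-position CCA -> CCG is synonymous (codon 4, genomic 22)
  syn <- tibble::tibble(contig = "chrM", pos = 22L, ref = "A", alt = "G")
  effs <- annotate_coding(syn, g$models, g$genome)
  expect_equal(effs$consequence, "synonymous")

  # a site outside every CDS yields no rows
  nc <- tibble::tibble(contig = "chrM", pos = 3L, ref = "A", alt = "G")
  expect_equal(nrow(annotate_coding(nc, g$models, g$genome)), 0L)
})

test_that("minus-strand annotation works in reverse-complement space", {
  g <- mini_gene("-")
  # CDS offset 4 (A of codon-2 GAT) lands at genomic 39 + (31-18) = 52,
  # base T on the plus strand, editable as T>C
  expect_equal(genome_base(g$genome, "chrM", 52L), "T")
  site <- tibble::tibble(contig = "chrM", pos = 52L, ref = "T", alt = "C",
                         editing_level = 1.0)
  eff <- annotate_coding(site, g$models, g$genome)
  expect_equal(nrow(eff), 1L)
  expect_equal(eff$strand, "-")
  expect_equal(eff$ref_codon, "GAT")
  expect_equal(eff$alt_codon, "GGT")   # transcript-space A>G
  expect_equal(eff$consequence, "missense")
  # an A>G call at the same position violates the strand rule -> no rows
  wrong <- tibble::tibble(contig = "chrM", pos = 52L, ref = "A", alt = "G")
  expect_equal(nrow(annotate_coding(wrong, g$models, g$genome)), 0L)
})

test_that("annotation round-trips against exhaustive per-base mapping", {
  for (strand in c("+", "-")) {
    g <- mini_gene(strand)
    model <- g$models
    # every genomic CDS base maps to the CDS offset whose base matches
    cds_chars <- strsplit(g$cds, "")[[1]]
    for (iv in 1:2) {
      for (pos in model$start[iv]:model$end[iv]) {
        o <- editscan:::genomic_to_cds_offset(model, pos)
        gb <- genome_base(g$genome, "chrM", pos)
        expected <- if (strand == "+") gb else chartr("ACGT", "TGCA", gb)
        expect_equal(cds_chars[o + 1L], expected)
      }
    }
  }
})

test_that("long peptides are 21-mers inside and truncate at the termini", {
  # synthetic 200-aa protein via direct construction of the effect
  set.seed(5)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  protein <- paste(sample(aa, 200, replace = TRUE), collapse = "")
  mk_effect <- function(res) tibble::tibble(
    contig = "chr1", pos = 1L, ref = "A", alt = "G", editing_level = 1,
    transcript_id = "t", gene_id = "g", strand = "+",
    cds_offset = (res - 1L) * 3L, codon_index = res, codon_pos = 1L,
    ref_codon = "AAA", alt_codon = "GAA", ref_aa = substr(protein, res, res),
    alt_aa = "W", consequence = "missense")
  with_mocked_protein <- function(res, prot = protein) {
    # drive long_peptides through a fabricated single-exon model
    n <- nchar(prot)
    cds <- paste(vapply(strsplit(prot, "")[[1]], function(a)
      names(FROZEN_CODE)[FROZEN_CODE == a][1], character(1)), collapse = "")
    genome <- Biostrings::DNAStringSet(c(chr1 = cds))
    models <- tibble::tibble(transcript_id = "t", gene_id = "g",
                             contig = "chr1", strand = "+", start = 1L,
                             end = nchar(cds), phase = 0L)
    long_peptides(mk_effect(res), models, genome)
  }
  lp <- with_mocked_protein(50)
  expect_equal(lp$length, 21L)
  expect_equal(lp$edit_residue_index, 11L)
  expect_equal(nchar(lp$mutant_peptide), 21L)
  expect_equal(substr(lp$mutant_peptide, 11, 11), "W")
  expect_equal(substr(lp$normal_peptide, 11, 11), substr(protein, 50, 50))

  # residue 5: truncated to 4 left + 1 + 10 right = 15
  lp5 <- with_mocked_protein(5)
  expect_equal(lp5$length, 15L)
  expect_equal(lp5$edit_residue_index, 5L)

  # residue 1 of an 8-aa protein: the whole protein
  lp8 <- with_mocked_protein(1, substr(protein, 1, 8))
  expect_equal(lp8$length, 8L)
  expect_equal(lp8$edit_residue_index, 1L)
})

test_that("stop gains are dropped and synonymous effects yield no peptides", {
  g <- mini_gene("+")
  syn <- annotate_coding(
    tibble::tibble(contig = "chrM", pos = 22L, ref = "A", alt = "G"),
    g$models, g$genome)
  expect_equal(nrow(suppressMessages(long_peptides(syn, g$models, g$genome))), 0L)
  fake_stop <- dplyr::mutate(syn, consequence = "stop_gained")
  expect_message(out <- long_peptides(fake_stop, g$models, g$genome),
                 "stop-gain")
  expect_equal(nrow(out), 0L)
})

test_that("chopping enumerates exactly the variant-containing windows", {
  long <- tibble::tibble(
    gene_id = "g", transcript_id = "t", contig = "chr1", pos = 1L,
    editing_level = 1, mutant_peptide = "ABCDEFGHIJKLMNOPQRSTU",
    normal_peptide = "ABCDEFGHIJZLMNOPQRSTU", edit_residue_index = 11L,
    length = 21L)
  shorts <- chop_peptides(long)
  # 9 + 10 + 11 windows cover the central residue of a 21-mer
  expect_equal(nrow(shorts), 30L)
  expect_equal(sort(unique(shorts$length)), c(9L, 10L, 11L))
  # every window contains the edit and differs from its twin at exactly one
  # position
  for (i in seq_len(nrow(shorts))) {
    a <- strsplit(shorts$mutant_peptide[i], "")[[1]]
    b <- strsplit(shorts$normal_peptide[i], "")[[1]]
    expect_equal(sum(a != b), 1L)
    expect_equal(a[shorts$edit_residue_index[i]], "K")
  }
  # a 9-residue long peptide yields exactly one window
  l9 <- dplyr::mutate(long, mutant_peptide = substr(mutant_peptide, 7, 15),
                      normal_peptide = substr(normal_peptide, 7, 15),
                      edit_residue_index = 5L, length = 9L)
  expect_equal(nrow(chop_peptides(l9)), 1L)
  # shorter than 9 yields none
  l8 <- dplyr::mutate(l9, mutant_peptide = substr(mutant_peptide, 1, 8),
                      normal_peptide = substr(normal_peptide, 1, 8),
                      length = 8L)
  expect_equal(nrow(chop_peptides(l8)), 0L)
})

test_that("chop output equals the all-substrings oracle on random cases", {
  set.seed(99)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  for (case in 1:50) {
    L <- sample(9:25, 1)
    e <- sample(seq_len(L), 1)
    normal <- paste(sample(aa, L, replace = TRUE), collapse = "")
    mutant <- normal
    substr(mutant, e, e) <- setdiff(aa, substr(normal, e, e))[1]
    long <- tibble::tibble(
      gene_id = "g", transcript_id = "t", contig = "chr1", pos = 1L,
      editing_level = 1, mutant_peptide = mutant, normal_peptide = normal,
      edit_residue_index = e, length = L)
    shorts <- chop_peptides(long)
    oracle <- all_variant_windows(mutant, e)
    expect_setequal(shorts$mutant_peptide, oracle)
    expect_true(all(vapply(shorts$mutant_peptide, grepl, logical(1),
                           x = mutant, fixed = TRUE)))
  }
})
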