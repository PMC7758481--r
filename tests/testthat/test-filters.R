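mk_sites <- function(pos, alt = "G", contig = "chr1", edited = 3L,
                     total = 10L) {
  tibble::tibble(contig = contig, pos = as.integer(pos),
                 ref = ifelse(alt == "G", "A", "T"), alt = alt,
                 edited = as.integer(edited), total = as.integer(total),
                 editing_level = edited / total)
}

test_that("known-variant filter matches by position, not allele", {
  sites <- mk_sites(c(100, 200))
  dbsnp <- tibble::tibble(contig = "chr1", pos = 100L, ref = "A", alt = "T")
  out <- filter_known_variants(sites, dbsnp)
  expect_equal(out$pos, 200L)          # different alt still removed
  # empty known set is the identity
  expect_equal(filter_known_variants(sites), sites)
  # several lists combine
  l2 <- tibble::tibble(contig = "chr1", pos = 200L, ref = "A", alt = "G")
  expect_equal(nrow(filter_known_variants(sites, dbsnp, l2)), 0L)
})

test_that("read-edge filter trims 3 bp windows and recomputes support", {
  ref <- paste(rep("ACGTTGCAAT", 10), collapse = "")
  genome <- read_fasta(write_mini_fasta(list(chr1 = ref)))

  # single supporting read with the edit at read position 2 (offset 1) -> gone
  reads <- stack_reads(ref, 48, "G", start = 47, rl = 50)
  obs <- pileup_observations(read_sam(write_mini_sam(reads)))
  sites <- detect_candidates(obs, genome)
  expect_equal(nrow(sites), 1L)
  expect_equal(nrow(filter_read_edges(sites, obs)), 0L)

  # edit at read position 4 (offset 3) is just outside the trimmed window
  reads4 <- stack_reads(ref, 48, "G", start = 45, rl = 50)
  obs4 <- pileup_observations(read_sam(write_mini_sam(reads4)))
  sites4 <- detect_candidates(obs4, genome)
  expect_equal(nrow(filter_read_edges(sites4, obs4)), 1L)

  # offsets 1 and 25: edited support drops 2 -> 1 and E is recomputed
  reads2 <- stack_reads(ref, 48, c("G", "G", "A", "A"),
                        start = c(47, 23, 20, 21), rl = 50)
  obs2 <- pileup_observations(read_sam(write_mini_sam(reads2)))
  sites2 <- detect_candidates(obs2, genome)
  expect_equal(sites2$edited, 2L)
  out2 <- filter_read_edges(sites2, obs2)
  expect_equal(out2$edited, 1L)
  expect_equal(out2$total, 3L)
  expect_equal(out2$editing_level, 1 / 3)
})

test_that("splice-proximal filter removes near-junction intronic non-Alu sites", {
  models <- tibble::tibble(
    transcript_id = "t1", gene_id = "g1", contig = "chr1", strand = "+",
    start = c(101L, 301L), end = c(200L, 400L), phase = 0L)
  # intron is 201..300; 202 is 2 bp from the donor junction
  near <- mk_sites(202)
  far <- mk_sites(250)
  exonic <- mk_sites(150)
  outside <- mk_sites(500)
  expect_equal(nrow(filter_splice_proximal(near, models)), 0L)
  expect_equal(nrow(filter_splice_proximal(far, models)), 1L)
  expect_equal(nrow(filter_splice_proximal(exonic, models)), 1L)
  expect_equal(nrow(filter_splice_proximal(outside, models)), 1L)
  # acceptor side, distance 4 removed / distance 5 retained (window 4)
  expect_equal(nrow(filter_splice_proximal(mk_sites(297), models)), 0L)
  expect_equal(nrow(filter_splice_proximal(mk_sites(296), models)), 1L)
  # the same coordinates inside an Alu interval are exempt
  alu <- tibble::tibble(contig = "chr1", start = 201L, end = 300L)
  expect_equal(nrow(filter_splice_proximal(near, models, alu)), 1L)
})

test_that("homopolymer filter drops sites at the end of runs of five or more", {
  #          123456789012345678901234567
  ref <- "GTCAAAAAGCCTTTTGACGGGGGGGTC"
  genome <- read_fasta(write_mini_fasta(list(chr1 = ref)))
  # pos 9 follows the 5-A run (4..8) -> removed
  expect_equal(nrow(filter_homopolymer(mk_sites(9), genome)), 0L)
  # pos 16 follows a 4-T run only -> retained
  expect_equal(nrow(filter_homopolymer(mk_sites(16), genome)), 1L)
  # run of 7 on the right flank: pos 18 precedes GGGGGGG (19..25) -> removed
  expect_equal(nrow(filter_homopolymer(mk_sites(18), genome)), 0L)
})

test_that("panel of normals keeps recurrent sites and subtracts them", {
  s1 <- mk_sites(c(10, 20, 30))
  s2 <- mk_sites(c(10, 30))
  s3 <- mk_sites(40)
  panel <- build_normal_panel(list(s1, s2, s3))
  expect_setequal(panel$pos, c(10L, 30L))     # in 2 of 3 normals
  expect_false(20L %in% panel$pos)            # in 1 of 3
  # three identical tables -> panel equals the table
  panel3 <- build_normal_panel(list(s1, s1, s1))
  expect_setequal(panel3$pos, s1$pos)

  tumor <- mk_sites(c(10, 20, 50))
  out <- subtract_panel(tumor, panel)
  expect_setequal(out$pos, c(20L, 50L))
  # disjoint panel is the identity; covering panel empties the table
  expect_equal(subtract_panel(tumor, mk_sites(99)), tumor)
  expect_equal(nrow(subtract_panel(tumor, tumor)), 0L)
})

test_that("panel subtraction agrees with brute-force set difference", {
  set.seed(42)
  for (rep in 1:20) {
    tumor <- mk_sites(sample(1:50, 15), alt = sample(c("G", "C"), 15, TRUE))
    panel <- mk_sites(sample(1:50, 10), alt = sample(c("G", "C"), 10, TRUE))
    out <- subtract_panel(tumor, panel)
    key <- function(x) paste(x$contig, x$pos, x$alt)
    expect_setequal(key(out), setdiff(key(tumor), key(panel)))
  }
})

test_that("somatic filter requires edited tumor and zero-level matched normal", {
  tumor <- mk_sites(c(10, 20, 30), edited = c(3L, 3L, 0L), total = 10L)
  normal <- mk_sites(c(20, 30), edited = c(1L, 0L), total = 20L)
  out <- somatic_re_filter(tumor, normal)
  expect_equal(out$pos, 10L)   # 20 edited in normal; 30 not edited in tumor
  # site absent from the normal table counts as level zero
  expect_equal(somatic_re_filter(mk_sites(5), mk_sites(99, edited = 0L))$pos, 5L)
})

test_that("cohort recurrence needs >=3 edited reads in >=3 samples", {
  at <- function(edited) mk_sites(100, edited = edited, total = 50L)
  expect_equal(nrow(cohort_recurrence_filter(list(at(3L), at(3L), at(3L)))), 1L)
  expect_equal(nrow(cohort_recurrence_filter(list(at(2L), at(2L), at(2L)))), 0L)
  expect_equal(nrow(cohort_recurrence_filter(list(at(10L), at(10L)))), 0L)
  expect_equal(nrow(cohort_recurrence_filter(list(at(10L), at(10L), at(2L)))), 0L)
})

test_that("pure set-operation filters commute and sites stay consistent", {
  spec <- fixture_spec(seed = 11)
  dir <- withr::local_tempdir()
  generate_fixtures(spec, dir)
  genome <- read_fasta(file.path(dir, "ref.fa"))
  obs <- pileup_observations(read_sam(file.path(dir, "reads.sam")))
  sites <- detect_candidates(obs, genome)
  known <- read_site_list(file.path(dir, "known.vcf"))
  normals <- lapply(list.files(file.path(dir, "normals"), full.names = TRUE),
                    read_site_list)
  panel <- build_normal_panel(normals)

  a <- subtract_panel(filter_homopolymer(filter_known_variants(sites, known),
                                         genome), panel)
  b <- filter_known_variants(filter_homopolymer(subtract_panel(sites, panel),
                                                genome), known)
  expect_equal(dplyr::arrange(a, pos), dplyr::arrange(b, pos))
  expect_true(all(a$edited <= a$total))
  expect_true(all(a$editing_level > 0 & a$editing_level <= 1))
})
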