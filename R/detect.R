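#' Detect candidate A-to-G editing sites from a pileup
#'
#' Scans per-base observations for positions where at least one
#' quality-passing base mismatches the reference with an A>G (or T>C)
#' substitution. Base quality and mapping quality thresholds are strict
#' (`>`), and an observation failing either threshold contributes to neither
#' the edited nor the total count. Only A>G and T>C rows are emitted; other
#' mismatch classes are never materialized because the downstream strand
#' rule cannot use them.
#'
#' @param reads Alignment tibble from [read_sam()], or a pre-built
#'   observation table from [pileup_observations()].
#' @param genome Genome from [read_fasta()].
#' @param min_base_q Minimum base quality, exclusive (default 25: a base
#'   qualifies only if its quality is `> 25`).
#' @param min_map_q Minimum mapping quality, exclusive (default 20).
#' @return A site tibble: `contig`, `pos`, `ref`, `alt`, `edited`
#'   (qualifying reads carrying the alternate base), `total` (all qualifying
#'   reads at the position), `editing_level` = edited/total.
#' @export
detect_candidates <- function(reads, genome, min_base_q = 25L, min_map_q = 20L) {
  obs <- if (all(c("off_start", "base_q") %in% names(reads))) reads
         else pileup_observations(reads)
  unknown <- setdiff(unique(obs$contig), names(genome))
  if (length(unknown) > 0L)
    stop("reads reference unknown contig(s): ", paste(unknown, collapse = ", "))
  qual <- obs |> filter(.data$base_q > min_base_q, .data$map_q > min_map_q)
  if (nrow(qual) == 0L) return(empty_site_counts())
  counts <- qual |>
    group_by(.data$contig, .data$pos) |>
    summarise(
      total = dplyr::n(),
      n_G = sum(.data$base == "G"),
      n_C = sum(.data$base == "C"),
      .groups = "drop"
    )
  counts$ref <- genome_base(genome, counts$contig, counts$pos)
  out <- counts |>
    mutate(
      alt = dplyr::case_when(.data$ref == "A" ~ "G",
                             .data$ref == "T" ~ "C",
                             TRUE ~ NA_character_),
      edited = dplyr::case_when(.data$ref == "A" ~ .data$n_G,
                                .data$ref == "T" ~ .data$n_C,
                                TRUE ~ 0L)
    ) |>
    filter(!is.na(.data$alt), .data$edited > 0L) |>
    mutate(editing_level = .data$edited / .data$total) |>
    select("contig", "pos", "ref", "alt", "edited", "total", "editing_level") |>
    arrange(.data$contig, .data$pos)
  out
}

empty_site_counts <- function() {
  tibble(contig = character(), pos = integer(), ref = character(),
         alt = character(), edited = integer(), total = integer(),
         editing_level = numeric())
}

#' Editing level of one pileup column
#'
#' The editing level E is the number of edited reads divided by the total
#' number of reads at the position, counting only bases with quality at or
#' above `min_base_q` (inclusive `>=`, the convention used for level
#' estimation, as opposed to the stricter exclusive threshold used for site
#' calling).
#'
#' @param obs Observation tibble (one pileup column: rows of
#'   [pileup_observations()] restricted to one contig/position).
#' @param alt The edited base to count ("G" for A>G context, "C" for T>C).
#' @param min_base_q Inclusive base-quality threshold (default 20).
#' @return E in \[0, 1\]. Errors if no observation qualifies.
#' @export
editing_level <- function(obs, alt, min_base_q = 20L) {
  qual <- obs[obs$base_q >= min_base_q, ]
  if (nrow(qual) == 0L) stop("no qualifying coverage")
  sum(qual$base == alt) / nrow(qual)
}

#' Remove sites that match known genomic variants
#'
#' Drops every candidate whose (contig, position) appears in any of the
#' supplied known-variant tables (dbSNP / 1000 Genomes / HapMap style
#' lists). Matching is positional, not allele-aware: any known variant at
#' the position disqualifies the site.
#'
#' @param sites Candidate site tibble.
#' @param ... One or more known-variant site tibbles (from
#'   [read_site_list()]).
#' @return `sites` with matching rows removed.
#' @export
filter_known_variants <- function(sites, ...) {
  known <- bind_rows(lapply(list(...), function(k) k[, c("contig", "pos")]))
  if (nrow(known) == 0L) return(sites)
  anti_join(sites, distinct(known), by = c("contig", "pos"))
}

#' Remove read-edge artifacts and recompute editing support
#'
#' Base calls near read ends are error-prone, so observations whose offset
#' from either end of the aligned query is below `edge_bp` (offsets 0, 1, 2
#' for the default 3 bp) are discarded — from both the edited and the total
#' count — and each site's counts and editing level are recomputed. A site
#' left without edited support is removed.
#'
#' @param sites Candidate site tibble (with `ref`, `alt`).
#' @param obs Observation table from [pileup_observations()] covering the
#'   sites.
#' @param edge_bp Width of the trimmed edge window (default 3).
#' @param min_base_q,min_map_q Quality thresholds re-applied during the
#'   recount (same strict `>` convention as [detect_candidates()]).
#' @return Filtered site tibble with recomputed `edited`, `total`,
#'   `editing_level`.
#' @export
filter_read_edges <- function(sites, obs, edge_bp = 3L,
                              min_base_q = 25L, min_map_q = 20L) {
  if (nrow(sites) == 0L) return(sites)
  keep_obs <- obs |>
    filter(.data$off_start >= edge_bp, .data$off_end >= edge_bp,
           .data$base_q > min_base_q, .data$map_q > min_map_q)
  recount <- keep_obs |>
    semi_join(sites, by = c("contig", "pos")) |>
    inner_join(sites[, c("contig", "pos", "ref", "alt")],
               by = c("contig", "pos")) |>
    group_by(.data$contig, .data$pos) |>
    summarise(
      edited = sum(.data$base == .data$alt[1]),
      total = dplyr::n(),
      .groups = "drop"
    )
  sites |>
    select(-"edited", -"total", -"editing_level") |>
    inner_join(recount, by = c("contig", "pos")) |>
    filter(.data$edited > 0L) |>
    mutate(editing_level = .data$edited / .data$total) |>
    arrange(.data$contig, .data$pos)
}

#' Remove splice-proximal intronic sites outside Alu regions
#'
#' Reads overhanging exon boundaries can be misaligned into the adjacent
#' intron, so a non-Alu site that falls in an intron (inside a transcript
#' span, outside all its coding intervals) within `window_bp` of a splice
#' junction is removed. Sites inside a supplied Alu interval set are exempt;
#' with no Alu set every site is treated as non-Alu (the stricter choice).
#'
#' @param sites Candidate site tibble.
#' @param models Transcript-model tibble from [read_gtf_cds()].
#' @param alu Optional Alu interval tibble from [read_bed()] (`NULL` = none).
#' @param window_bp Distance window: an intronic base whose distance to the
#'   nearest junction is `<= window_bp` is removed (the base adjacent to the
#'   exon has distance 1). Default 4.
#' @return Filtered site tibble.
#' @export
filter_splice_proximal <- function(sites, models, alu = NULL, window_bp = 4L) {
  if (nrow(sites) == 0L || nrow(models) == 0L) return(sites)
  is_alu <- in_intervals(sites$contig, sites$pos, alu)
  drop <- vapply(seq_len(nrow(sites)), function(i) {
    if (is_alu[i]) return(FALSE)
    site_splice_proximal(sites$contig[i], sites$pos[i], models, window_bp)
  }, logical(1))
  sites[!drop, ]
}

site_splice_proximal <- function(contig, pos, models, window_bp) {
  mods <- models[models$contig == contig, ]
  for (tx in unique(mods$transcript_id)) {
    iv <- mods[mods$transcript_id == tx, ]
    if (pos < min(iv$start) || pos > max(iv$end)) next       # outside span
    if (any(iv$start <= pos & iv$end >= pos)) next           # exonic here
    # intronic in this transcript: distance to the nearest junction
    d_left <- pos - max(iv$end[iv$end < pos])                # from upstream exon end
    d_right <- min(iv$start[iv$start > pos]) - pos           # to downstream exon start
    if (min(d_left, d_right) <= window_bp) return(TRUE)
  }
  FALSE
}

#' Remove sites at the end of homopolymer runs
#'
#' Sequencing errors concentrate at homopolymer ends, so a site whose
#' position immediately follows a run of at least `min_run` identical
#' reference bases — on either flank — is discarded. The run base need not
#' match the site's ref or alt allele.
#'
#' @param sites Candidate site tibble.
#' @param genome Genome from [read_fasta()].
#' @param min_run Minimum homopolymer length (default 5).
#' @return Filtered site tibble.
#' @export
filter_homopolymer <- function(sites, genome, min_run = 5L) {
  if (nrow(sites) == 0L) return(sites)
  drop <- vapply(seq_len(nrow(sites)), function(i) {
    adjacent_homopolymer(genome, sites$contig[i], sites$pos[i], min_run)
  }, logical(1))
  sites[!drop, ]
}

adjacent_homopolymer <- function(genome, contig, pos, min_run) {
  clen <- genome_contig_length(genome, contig)
  run_from <- function(positions) {
    if (length(positions) == 0L) return(0L)
    bases <- genome_base(genome, contig, positions)
    r <- 0L
    for (b in bases) {
      if (b != bases[1]) break
      r <- r + 1L
    }
    r
  }
  left <- run_from(rev(seq.int(max(1L, pos - min_run - 2L), pos - 1L)))
  right <- if (pos >= clen) 0L else run_from(seq.int(pos + 1L, min(clen, pos + min_run + 2L)))
  left >= min_run || right >= min_run
}

#' Build a panel of normals from per-sample site tables
#'
#' Editing sites recurrently observed in normal samples are treated as
#' tolerated, non-immunogenic events. A site enters the panel when it occurs
#' (by contig, position and alt allele) in at least `min_samples` of the
#' supplied normal-sample tables.
#'
#' @param per_sample_sites List of site tibbles, one per normal sample.
#' @param min_samples Minimum number of samples (default 2).
#' @return Site tibble (`contig`, `pos`, `alt`, `n_samples`).
#' @export
build_normal_panel <- function(per_sample_sites, min_samples = 2L) {
  stopifnot(length(per_sample_sites) >= 1L)
  all_sites <- bind_rows(lapply(seq_along(per_sample_sites), function(i) {
    s <- per_sample_sites[[i]]
    distinct(s[, c("contig", "pos", "alt")]) |> mutate(sample = i)
  }))
  all_sites |>
    group_by(.data$contig, .data$pos, .data$alt) |>
    summarise(n_samples = dplyr::n(), .groups = "drop") |>
    filter(.data$n_samples >= min_samples)
}

#' Subtract a panel of normals from tumor sites
#'
#' Set difference by (contig, position, alt allele).
#'
#' @param sites Tumor site tibble.
#' @param panel Panel tibble from [build_normal_panel()] (or any site table).
#' @return `sites` without panel rows.
#' @export
subtract_panel <- function(sites, panel) {
  if (nrow(panel) == 0L) return(sites)
  anti_join(sites, panel[, c("contig", "pos", "alt")],
            by = c("contig", "pos", "alt"))
}

#' Keep somatic editing sites (edited in tumor, absent in matched normal)
#'
#' A site qualifies as somatic when its tumor editing level is non-zero and
#' its editing level in the matched normal sample is exactly zero (a site
#' absent from the normal table counts as zero).
#'
#' @param tumor Tumor site tibble with `editing_level`.
#' @param matched_normal Matched-normal site tibble with `editing_level`.
#' @return Filtered tumor tibble.
#' @export
somatic_re_filter <- function(tumor, matched_normal) {
  tumor <- tumor |> filter(.data$editing_level > 0)
  if (nrow(matched_normal) == 0L) return(tumor)
  edited_normal <- matched_normal |>
    filter(.data$editing_level > 0) |>
    select("contig", "pos", "alt")
  anti_join(tumor, edited_normal, by = c("contig", "pos", "alt"))
}

#' Cohort recurrence filter
#'
#' Keeps sites supported by at least `min_edited_reads` edited reads in at
#' least `min_samples` samples of a cohort.
#'
#' @param per_sample List of site tibbles (with `edited` counts), one per
#'   sample.
#' @param min_edited_reads Minimum edited reads per sample (default 3).
#' @param min_samples Minimum number of qualifying samples (default 3).
#' @return Tibble of recurrent sites (`contig`, `pos`, `alt`,
#'   `n_supporting_samples`).
#' @export
cohort_recurrence_filter <- function(per_sample, min_edited_reads = 3L,
                                     min_samples = 3L) {
  stopifnot(length(per_sample) >= 1L)
  support <- bind_rows(lapply(per_sample, function(s)
    s[s$edited >= min_edited_reads, c("contig", "pos", "alt")]))
  if (nrow(support) == 0L)
    return(tibble(contig = character(), pos = integer(), alt = character(),
                  n_supporting_samples = integer()))
  support |>
    group_by(.data$contig, .data$pos, .data$alt) |>
    summarise(n_supporting_samples = dplyr::n(), .groups = "drop") |>
    filter(.data$n_supporting_samples >= min_samples)
}
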