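#' Assemble a run configuration
#'
#' Collects every stage parameter (at its conventional default) together
#' with input paths. Parameters: quality thresholds for site calling
#' (`min_base_q` 25, `min_map_q` 20, both strict), read-edge trim
#' (`edge_bp` 3), homopolymer run length (`homopolymer_run` 5), splice
#' window (`splice_window_bp` 4), panel recurrence (`panel_min_samples` 2),
#' peptide window (`flank` 10 -> 21-mer; `kmin` 9, `kmax` 11), candidate
#' cuts (`rank_cut` 2, `tpm_cut` 1), and the logistic parameters of the
#' immunogenicity score (`l_slope` 5, `l_midpoint` 2).
#'
#' @param sam,ref,gtf,expr Input paths (SAM, FASTA, GTF, expression TSV).
#' @param known Character vector of known-variant site-list paths (VCF or
#'   TSV); may be empty.
#' @param alu Optional Alu BED path.
#' @param normals Character vector of normal-sample site-list paths (the
#'   panel of normals); may be empty.
#' @param alleles Character vector of HLA alleles.
#' @param predictor `"mock"`, `"tsv"`, or a predictor function.
#' @param affinity_tsv Rank table path when `predictor = "tsv"`.
#' @param sample_id Sample label.
#' @param seed Seed for the mock predictor.
#' @param markers Marker sets (see [default_markers()]).
#' @param min_base_q,min_map_q,edge_bp,homopolymer_run,splice_window_bp,panel_min_samples,flank,kmin,kmax,rank_cut,tpm_cut,l_slope,l_midpoint
#'   Stage parameters as described above.
#' @return A `run_config` list.
#' @export
run_config <- function(sam, ref, gtf, expr, known = character(0), alu = NULL,
                       normals = character(0), alleles = "HLA-A*02:01",
                       predictor = "mock", affinity_tsv = NULL,
                       sample_id = "sample", seed = 1L,
                       markers = default_markers(),
                       min_base_q = 25L, min_map_q = 20L, edge_bp = 3L,
                       homopolymer_run = 5L, splice_window_bp = 4L,
                       panel_min_samples = 2L, flank = 10L, kmin = 9L,
                       kmax = 11L, rank_cut = 2.0, tpm_cut = 1.0,
                       l_slope = 5, l_midpoint = 2) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Run the full pipeline
#'
#' Executes detection and the filter cascade (known variants, read edges,
#' splice-proximal, homopolymer, panel of normals, in that order), the
#' strand-aware coding annotation, long-peptide construction and chopping,
#' binding-rank acquisition, the expression/affinity candidate filter, and
#' per-sample scoring. Every intermediate is written to `outdir` as TSV and
#' the run manifest (per-stage row counts and the configuration echo) as
#' JSON-compatible list.
#'
#' @param config A [run_config()].
#' @param outdir Optional directory for intermediate TSVs (`NULL` = don't
#'   write).
#' @return An `editscan_run` object: list with `sites` (filtered site
#'   table), `effects`, `long_peptides`, `short_peptides`, `records`,
#'   `candidates` (with S, H, p), `sample` (one-row score tibble),
#'   `manifest` (named list of stage counts), `config`.
#' @export
run_all <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  genome <- stage("read_ref", function() read_fasta(config$ref))
  reads <- stage("read_sam", function() read_sam(config$sam))
  models <- stage("read_gtf", function() read_gtf_cds(config$gtf))
  expr <- stage("read_expression", function() read_expression(config$expr))
  known <- lapply(config$known, function(p)
    stage("read_known", function() read_site_list(p)))
  alu <- if (!is.null(config$alu))
    stage("read_alu", function() read_bed(config$alu)) else NULL
  normals <- lapply(config$normals, function(p)
    stage("read_normals", function() read_site_list(p)))

  obs <- stage("pileup", function() pileup_observations(reads))
  detected <- stage("detect", function()
    detect_candidates(obs, genome, config$min_base_q, config$min_map_q))
  s1 <- stage("filter_known", function()
    do.call(filter_known_variants, c(list(detected), known)))
  s2 <- stage("filter_edges", function()
    filter_read_edges(s1, obs, config$edge_bp, config$min_base_q,
                      config$min_map_q))
  s3 <- stage("filter_splice", function()
    filter_splice_proximal(s2, models, alu, config$splice_window_bp))
  s4 <- stage("filter_homopolymer", function()
    filter_homopolymer(s3, genome, config$homopolymer_run))
  s5 <- if (length(normals) > 0L) {
    panel <- stage("build_panel", function()
      build_normal_panel(normals, config$panel_min_samples))
    stage("subtract_panel", function() subtract_panel(s4, panel))
  } else s4

  effects <- stage("annotate", function()
    annotate_coding(s5, models, genome))
  longs <- stage("long_peptides", function()
    suppressMessages(long_peptides(effects, models, genome, config$flank)))
  shorts <- stage("chop", function()
    chop_peptides(longs, config$kmin, config$kmax))

  pred <- if (is.function(config$predictor)) config$predictor
    else switch(config$predictor,
                mock = mock_predictor(config$seed),
                tsv = tsv_predictor(config$affinity_tsv),
                stop("unknown predictor: ", config$predictor))
  records <- stage("bind", function() score_pairs(shorts, config$alleles, pred))
  candidates <- stage("candidate_filter", function()
    suppressMessages(candidate_filter(records, expr, config$rank_cut,
                                      config$tpm_cut)))
  scored <- stage("score", function()
    score_sample(candidates, expr, config$markers,
                 sample_id = config$sample_id,
                 slope = config$l_slope, midpoint = config$l_midpoint))

  manifest <- list(
    sample_id = config$sample_id,
    tool_version = as.character(utils::packageVersion("editscan")),
    stage_counts = list(
      reads = nrow(reads), detected = nrow(detected),
      after_known_variant_filter = nrow(s1),
      after_read_edge_filter = nrow(s2),
      after_splice_filter = nrow(s3),
      after_homopolymer_filter = nrow(s4),
      after_panel_filter = nrow(s5),
      coding_effects = nrow(effects),
      long_peptides = nrow(longs), short_peptides = nrow(shorts),
      binding_records = nrow(records), candidates = nrow(scored$candidates)),
    config = config[!vapply(config, is.function, logical(1))])

  out <- structure(list(
    sites = s5, effects = effects, long_peptides = longs,
    short_peptides = shorts, records = records,
    candidates = scored$candidates, sample = scored$sample,
    manifest = manifest, config = config), class = "editscan_run")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(s5, file.path(outdir, "sites.tsv"))
    readr::write_tsv(longs, file.path(outdir, "long_peptides.tsv"))
    readr::write_tsv(shorts, file.path(outdir, "short_peptides.tsv"))
    readr::write_tsv(scored$candidates, file.path(outdir, "candidates.tsv"))
    readr::write_tsv(scored$sample, file.path(outdir, "sample_scores.tsv"))
  }
  out
}

#' @export
print.editscan_run <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("<editscan_run> sample:", x$manifest$sample_id, "\n")
  cat("  sites after filters:", sc$after_panel_filter,
      "(detected:", sc$detected, ")\n")
  cat("  short peptide pairs:", sc$short_peptides,
      " candidates:", sc$candidates, "\n")
  cat(sprintf("  RENIS %.4g | REscore %.4g | CYT %.4g\n",
              x$sample$RENIS, x$sample$REscore, x$sample$CYT))
  invisible(x)
}

#' Tidy the per-candidate table of a pipeline run
#'
#' @param x An `editscan_run`.
#' @param ... Unused.
#' @return The candidate tibble (one row per kept peptide-allele record,
#'   with S, H and p).
#' @export
tidy.editscan_run <- function(x, ...) as_tibble(x$candidates)

#' One-row summary of a pipeline run
#'
#' @param x An `editscan_run`.
#' @param ... Unused.
#' @return One-row tibble: sample id, candidate burden, RENIS, CD8, CTL,
#'   REscore, CYT.
#' @export
glance.editscan_run <- function(x, ...) as_tibble(x$sample)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Attrition plot of a pipeline run
#'
#' Bar chart of record counts through the detection, filtering, peptide and
#' candidate stages.
#'
#' @param object An `editscan_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.editscan_run <- function(object, ...) {
  sc <- object$manifest$stage_counts
  keep <- c("detected", "after_known_variant_filter", "after_read_edge_filter",
            "after_splice_filter", "after_homopolymer_filter",
            "after_panel_filter", "short_peptides", "candidates")
  df <- tibble(stage = factor(keep, levels = keep),
               count = unlist(sc[keep]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "records",
                  title = "Attrition through the pipeline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Editing-level plot of a site table
#'
#' @param sites Site tibble with `editing_level` (and `pos`).
#' @return A ggplot object: editing level by genomic position.
#' @export
plot_editing_levels <- function(sites) {
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$pos, y = .data$editing_level)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0),
                          color = "grey60") +
    ggplot2::geom_point(color = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "genomic position", y = "editing level E") +
    ggplot2::theme_minimal()
}
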