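#' Validate HLA allele names
#'
#' Accepts 4-digit class-I nomenclature such as `HLA-A*02:01`.
#'
#' @param alleles Character vector of allele names.
#' @return The input, invisibly; errors on a malformed name.
#' @export
check_hla_alleles <- function(alleles) {
  ok <- grepl("^HLA-[A-Z]+[0-9]*\\*[0-9]{2,}:[0-9]{2,}$", alleles)
  if (any(!ok))
    stop("malformed HLA allele name(s): ", paste(alleles[!ok], collapse = ", "))
  invisible(alleles)
}

# stable polynomial hash over a string; all arithmetic stays below 2^53 so
# the result is exact in double precision on every platform
stable_hash <- function(x) {
  h <- 17
  for (b in utf8ToInt(x)) {
    h <- (h * 131 + b) %% 2147483647
  }
  h
}

#' Deterministic mock %rank predictor
#'
#' Returns a predictor function `(peptide, allele) -> %rank` whose output is
#' a deterministic, platform-independent function of a stable hash of
#' (peptide, allele, seed), uniform over (0, 100]. Used as the test surface
#' in place of an external binding predictor.
#'
#' @param seed Integer seed folded into the hash.
#' @return A function of `(peptide, allele)` returning a %rank in (0, 100].
#' @export
mock_predictor <- function(seed = 0L) {
  force(seed)
  function(peptide, allele) {
    h <- stable_hash(paste(peptide, allele, seed, sep = "|"))
    (h %% 1000000 + 1) / 1000000 * 100
  }
}

#' Predictor backed by a precomputed %rank table
#'
#' @param affinities Tibble (or TSV path) with columns `peptide`, `allele`,
#'   `rank`.
#' @return A function of `(peptide, allele)` returning the tabulated %rank;
#'   errors on a missing combination.
#' @export
tsv_predictor <- function(affinities) {
  if (is.character(affinities))
    affinities <- readr::read_tsv(affinities, show_col_types = FALSE)
  stopifnot(all(c("peptide", "allele", "rank") %in% names(affinities)))
  key <- paste(affinities$peptide, affinities$allele, sep = "|")
  lut <- setNames(affinities$rank, key)
  function(peptide, allele) {
    r <- lut[paste(peptide, allele, sep = "|")]
    if (is.na(r)) stop("no tabulated %rank for ", peptide, " / ", allele)
    unname(r)
  }
}

#' Score peptide pairs against HLA alleles
#'
#' Obtains mutant (`Rm`) and normal (`Rn`) percentile ranks for every
#' (pair, allele) combination through the supplied predictor. A predictor
#' failure on any peptide excludes that record (with a warning) and the run
#' continues.
#'
#' @param pairs Short-peptide tibble from [chop_peptides()].
#' @param alleles Character vector of HLA allele names.
#' @param predictor A `(peptide, allele) -> %rank` function, e.g.
#'   [mock_predictor()] or [tsv_predictor()].
#' @return Binding-record tibble: pair columns plus `allele`, `Rm`, `Rn`.
#' @export
score_pairs <- function(pairs, alleles, predictor) {
  check_hla_alleles(alleles)
  grid <- tidyr::crossing(pairs, allele = alleles)
  if (nrow(grid) == 0L) return(mutate(grid, Rm = numeric(0), Rn = numeric(0)))
  ranks <- purrr::map(seq_len(nrow(grid)), function(i) {
    tryCatch(
      list(Rm = predictor(grid$mutant_peptide[i], grid$allele[i]),
           Rn = predictor(grid$normal_peptide[i], grid$allele[i]),
           ok = TRUE),
      error = function(e) {
        warning("predictor failed for ", grid$mutant_peptide[i], " / ",
                grid$allele[i], ": ", conditionMessage(e))
        list(Rm = NA_real_, Rn = NA_real_, ok = FALSE)
      })
  })
  grid$Rm <- purrr::map_dbl(ranks, "Rm")
  grid$Rn <- purrr::map_dbl(ranks, "Rn")
  grid[purrr::map_lgl(ranks, "ok"), ]
}

#' Expression/affinity candidate filter
#'
#' Keeps binding records whose mutant %rank is below `rank_cut` and whose
#' source gene is expressed above `tpm_cut` TPM (both strict). The normal
#' peptide's rank is never filtered on; it enters only the immunogenicity
#' score. A gene absent from the expression table is treated as TPM 0 and
#' dropped (with a message).
#'
#' @param records Binding-record tibble from [score_pairs()].
#' @param expr Expression tibble from [read_expression()].
#' @param rank_cut Keep `Rm < rank_cut` (default 2.0).
#' @param tpm_cut Keep `TPM > tpm_cut` (default 1.0).
#' @return Filtered records with a `tpm` column added.
#' @export
candidate_filter <- function(records, expr, rank_cut = 2.0, tpm_cut = 1.0) {
  out <- left_join(records, rename(expr, tpm_lookup = "tpm"),
                   by = "gene_id")
  missing <- unique(out$gene_id[is.na(out$tpm_lookup)])
  if (length(missing) > 0L)
    message("gene(s) absent from expression table treated as TPM 0: ",
            paste(missing, collapse = ", "))
  out$tpm <- ifelse(is.na(out$tpm_lookup), 0, out$tpm_lookup)
  out$tpm_lookup <- NULL
  out |> filter(.data$Rm < rank_cut, .data$tpm > tpm_cut)
}

#' Neoantigen burden of a candidate table
#'
#' The burden is the number of distinct mutant short-peptide sequences
#' passing the candidate filter (allele multiplicity does not inflate it).
#'
#' @param candidates Filtered binding-record tibble.
#' @return Integer count.
#' @export
neoantigen_burden <- function(candidates) {
  length(unique(candidates$mutant_peptide))
}
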