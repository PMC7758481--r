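#' Logistic weighting of a binding percentile rank
#'
#' `L(x) = 1 / (1 + exp(slope * (x - midpoint)))`, a decreasing sigmoid that
#' is 0.5 at the midpoint (default: %rank 2, the conventional strong-binder
#' cutoff) and saturates quickly on either side with the default slope 5.
#'
#' @param x Percentile rank(s).
#' @param slope Steepness (default 5).
#' @param midpoint Rank at which L = 0.5 (default 2).
#' @return Value(s) in (0, 1).
#' @export
logistic_L <- function(x, slope = 5, midpoint = 2) {
  1 / (1 + exp(slope * (x - midpoint)))
}

#' Per-candidate immunogenicity p
#'
#' The immunogenicity of one editing-derived neoantigen candidate is the
#' product of three terms:
#' `p = [tanh(F) * E] * [L(Rm) * (1 - L(Rn)/2) * S] * [H]`
#' where `F` is the gene's expression (TPM; tanh saturates it toward 1),
#' `E` the editing level, `Rm`/`Rn` the mutant/normal peptide percentile
#' ranks weighted by the logistic [logistic_L()], `S` the mutant-normal
#' sequence dissimilarity, and `H` the T-cell recognition probability.
#' Since every factor lies in \[0, 1\] and `tanh(F) < 1`, p is always in
#' \[0, 1).
#'
#' @param F Gene expression in TPM (>= 0).
#' @param E Editing level in \[0, 1\].
#' @param Rm,Rn Mutant and normal %ranks (> 0).
#' @param S Sequence dissimilarity in \[0, 1\].
#' @param H Recognition probability in \[0, 1\].
#' @param slope,midpoint Parameters of [logistic_L()].
#' @return p in \[0, 1). Out-of-range inputs raise an error; nothing is
#'   clamped silently.
#' @export
immunogenicity_p <- function(F, E, Rm, Rn, S, H, slope = 5, midpoint = 2) {
  if (any(F < 0)) stop("F (TPM) must be >= 0")
  for (nm in c("E", "S", "H")) {
    v <- get(nm)
    if (any(v < 0 | v > 1)) stop(nm, " must lie in [0, 1]")
  }
  if (any(Rm <= 0) || any(Rn <= 0)) stop("Rm and Rn must be positive %ranks")
  (tanh(F) * E) *
    (logistic_L(Rm, slope, midpoint) * (1 - logistic_L(Rn, slope, midpoint) / 2) * S) *
    H
}

#' Sequence dissimilarity between equal-length peptides
#'
#' `S = 1 - (identical aligned positions / length)`; a mutant/normal pair
#' differing at one residue of a 9-mer has S = 1/9.
#'
#' @param mutant,normal Equal-length peptide strings (vectorized).
#' @return Dissimilarity in \[0, 1\].
#' @export
dissimilarity_S <- function(mutant, normal) {
  if (any(nchar(mutant) != nchar(normal)))
    stop("peptides must have equal length")
  vapply(seq_along(mutant), function(i) {
    a <- strsplit(mutant[i], "")[[1]]
    b <- strsplit(normal[i], "")[[1]]
    1 - sum(a == b) / length(a)
  }, numeric(1))
}

# Kyte-Doolittle hydropathy index
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' T-cell recognition probability from peptide hydrophobicity
#'
#' Default recognition model: hydrophobic TCR-contact residues favor
#' recognition, so H is a logistic of the mean Kyte-Doolittle hydropathy of
#' the contact span — positions 4-8 of a 9-mer, and the analogous interior
#' span (position 4 through the penultimate-1) for other lengths:
#' `H = 1 / (1 + exp(-mean_hydropathy / 2))`, which maps the hydropathy
#' range \[-4.5, 4.5\] into (0, 1) monotonically. Any function
#' `(peptide) -> [0, 1]` may be substituted wherever an `h_model` argument
#' is accepted.
#'
#' @param peptide Peptide string(s), standard one-letter amino acids.
#' @return H in (0, 1), vectorized.
#' @export
recognition_H <- function(peptide) {
  vapply(peptide, function(p) {
    aa <- strsplit(p, "")[[1]]
    if (any(!aa %in% names(KYTE_DOOLITTLE)))
      stop("non-standard residue in peptide: ", p)
    L <- length(aa)
    span <- if (L >= 5L) seq.int(min(4L, L), max(min(4L, L), L - 1L)) else seq_len(L)
    m <- mean(KYTE_DOOLITTLE[aa[span]])
    1 / (1 + exp(-m / 2))
  }, numeric(1), USE.NAMES = FALSE)
}

#' RENIS: summed neoantigen immunogenicity of a sample
#'
#' The RNA-editing neoantigen immunogenicity score of a sample is the plain
#' sum of its candidates' per-candidate immunogenicities p.
#'
#' @param p Numeric vector of per-candidate immunogenicities (or a candidate
#'   tibble with a `p` column).
#' @return Non-negative scalar; 0 for an empty candidate set.
#' @export
renis <- function(p) {
  if (is.data.frame(p)) p <- p$p
  if (length(p) == 0L) return(0)
  sum(p)
}

#' Marker-mean immune-cell abundance
#'
#' A simple marker-based abundance: the mean of `log2(TPM + 1)` over a
#' marker gene set. A marker absent from the expression table contributes 0
#' with a warning.
#'
#' @param expr Expression tibble from [read_expression()].
#' @param markers Character vector of marker gene ids.
#' @return Non-negative scalar abundance.
#' @export
marker_abundance <- function(expr, markers) {
  stopifnot(length(markers) >= 1L)
  tpm <- setNames(expr$tpm, expr$gene_id)[markers]
  if (any(is.na(tpm))) {
    warning("marker gene(s) missing from expression table: ",
            paste(markers[is.na(tpm)], collapse = ", "))
    tpm[is.na(tpm)] <- 0
  }
  mean(log2(tpm + 1))
}

#' Default immune marker sets
#'
#' Editable defaults for the two abundance terms: CD8+ T cells (CD8A, CD8B)
#' and cytotoxic lymphocytes (GZMA, GZMB, PRF1, KLRD1). A YAML file with
#' top-level keys `CD8` and `CTL` overrides them.
#'
#' @param path Optional YAML file path.
#' @return Named list with character vectors `CD8` and `CTL`.
#' @export
default_markers <- function(path = NULL) {
  if (!is.null(path)) {
    m <- yaml::read_yaml(path)
    stopifnot(all(c("CD8", "CTL") %in% names(m)))
    return(lapply(m[c("CD8", "CTL")], as.character))
  }
  list(CD8 = c("CD8A", "CD8B"), CTL = c("GZMA", "GZMB", "PRF1", "KLRD1"))
}

#' REscore: immune-weighted RENIS
#'
#' `REscore = (abundance(CD8) + abundance(CTL)) * RENIS`, combining the
#' sample's summed neoantigen immunogenicity with its infiltrating
#' cytotoxic compartment.
#'
#' @param renis_value Sample RENIS.
#' @param cd8,ctl Immune abundances from [marker_abundance()].
#' @return Scalar REscore.
#' @export
rescore <- function(renis_value, cd8, ctl) {
  (cd8 + ctl) * renis_value
}

#' Cytolytic activity (CYT)
#'
#' Geometric mean of GZMA and PRF1 expression in TPM; zero in either gene
#' propagates to zero (no pseudocount).
#'
#' @param expr Expression tibble from [read_expression()].
#' @return `sqrt(TPM_GZMA * TPM_PRF1)`; missing genes count as 0.
#' @export
cyt <- function(expr) {
  tpm <- setNames(expr$tpm, expr$gene_id)
  g <- unname(tpm["GZMA"]); p <- unname(tpm["PRF1"])
  if (is.na(g)) g <- 0
  if (is.na(p)) p <- 0
  sqrt(g * p)
}

#' Score a filtered candidate table for one sample
#'
#' Computes S, H and p for every candidate record and summarises the sample:
#' RENIS, CD8 and CTL abundances, REscore, and CYT.
#'
#' @param candidates Filtered binding-record tibble from
#'   [candidate_filter()] (needs `mutant_peptide`, `normal_peptide`, `Rm`,
#'   `Rn`, `tpm`, `editing_level`).
#' @param expr Expression tibble.
#' @param markers Marker sets from [default_markers()].
#' @param h_model Recognition model, a `(peptide) -> [0,1]` function
#'   (default [recognition_H()]).
#' @param sample_id Sample label carried into the summary.
#' @param slope,midpoint Logistic parameters of [logistic_L()].
#' @return List with `candidates` (input plus `S`, `H`, `p` columns) and
#'   `sample` (one-row tibble: `sample_id`, `n_candidates`, `burden`,
#'   `RENIS`, `CD8`, `CTL`, `REscore`, `CYT`).
#' @export
score_sample <- function(candidates, expr, markers = default_markers(),
                         h_model = recognition_H, sample_id = "sample",
                         slope = 5, midpoint = 2) {
  cand <- candidates
  if (nrow(cand) > 0L) {
    cand$S <- dissimilarity_S(cand$mutant_peptide, cand$normal_peptide)
    cand$H <- vapply(cand$mutant_peptide, h_model, numeric(1), USE.NAMES = FALSE)
    cand$p <- immunogenicity_p(cand$tpm, cand$editing_level, cand$Rm, cand$Rn,
                               cand$S, cand$H, slope = slope, midpoint = midpoint)
  } else {
    cand$S <- numeric(0); cand$H <- numeric(0); cand$p <- numeric(0)
  }
  cd8 <- suppressWarnings(marker_abundance(expr, markers$CD8))
  ctl <- suppressWarnings(marker_abundance(expr, markers$CTL))
  rn <- renis(cand$p)
  list(
    candidates = cand,
    sample = tibble(
      sample_id = sample_id,
      n_candidates = nrow(cand),
      burden = neoantigen_burden(cand),
      RENIS = rn, CD8 = cd8, CTL = ctl,
      REscore = rescore(rn, cd8, ctl),
      CYT = cyt(expr)))
}
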