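---
title: "Detecting and scoring neoantigen candidates from A-to-I RNA editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and scoring neoantigen candidates from A-to-I RNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

## The biological problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA.
Sequencers and ribosomes both read inosine as guanosine, so an edited
adenosine shows up in RNA-seq as an A>G mismatch against the genome (T>C on
the plus strand when the edited gene lies on the minus strand), and an
edited codon can encode an amino acid absent from the germline proteome.
When such a recoded peptide binds an HLA class-I molecule it becomes a
candidate neoantigen — a tumor antigen that does not require a somatic DNA
mutation. `editscan` implements the full desk-scale path from aligned reads
to per-sample immunogenicity scores.

## Pipeline model and assumptions

The pipeline is a fixed sequence of table transformations:

1. **Pileup detection.** Every aligned base is expanded into an observation
   (base, base quality, mapping quality, offset from each read end).
   A candidate site is a position where a quality-passing base mismatches
   the reference as A>G or T>C. Both thresholds are *strict*: a base
   qualifies only with base quality `> 25` and mapping quality `> 20`, so a
   base at exactly 25 (or a read at mapping quality exactly 20) is
   excluded. Editing level `E` is edited/total over qualifying
   observations. For level *estimation* (as opposed to site calling) the
   conventional inclusive `>= 20` base-quality rule is exposed separately
   in `editing_level()`, because the two conventions come from different
   analysis traditions and the package keeps both explicit as parameters.
2. **False-positive filters**, in the order: known genomic variants
   (positional match against dbSNP-style lists — matching by position, not
   allele, is deliberately conservative), read-edge artifacts (observations
   with offset 0–2 from either end of the aligned query are discarded and
   counts recomputed; soft-clipped bases do not count toward the offset),
   splice-proximal intronic sites outside Alu repeats, homopolymer-adjacent
   sites (a run of ≥ 5 identical reference bases ending immediately at the
   site, scanned on *both* flanks since the artifact is not directional),
   and a panel of normals (sites seen in ≥ 2 normal samples). The purely
   set-valued filters (known variants, homopolymer, panel) commute; the
   edge filter must run before the final editing level is taken because it
   changes the counts.
3. **Strand-aware coding annotation.** Only A>G calls in plus-strand genes
   and T>C calls in minus-strand genes are editable in transcript space.
   The genomic position is mapped into the spliced CDS (reverse-complement
   on minus-strand transcripts), the codon is mutated, and both codons are
   translated under the standard genetic code. Synonymous effects and
   stop gains/losses yield no peptides.
4. **Peptides.** A window of 10 residues on each side of the edited residue
   gives the 21-mer long peptide (truncated at the protein termini — the
   truncation rule is this package's documented choice; an edit at residue
   5 gives a 15-mer). The long peptide is chopped into every 9-, 10- and
   11-mer window that *contains* the edited residue; windows without it
   would be wild-type self peptides and are never emitted. Mutant and
   normal windows are cut at identical offsets, so each short pair differs
   at exactly one residue.
5. **Binding and expression filter.** Percentile ranks for mutant (`Rm`)
   and normal (`Rn`) peptides come from a pluggable predictor contract —
   a deterministic mock, a precomputed rank table, or any user function.
   Candidates are kept when `Rm < 2` **and** gene TPM `> 1`, both strict;
   the normal peptide's rank is never filtered on, it only enters the
   score.
6. **Scoring.** Per candidate,
   `p = [tanh(F) · E] · [L(Rm) · (1 − L(Rn)/2) · S] · [H]` with
   `L(x) = 1 / (1 + e^{5(x−2)})`. `F` is TPM (tanh saturates expression
   toward 1, and is applied to TPM directly, with no log transform);
   `E` the per-site editing level (the score needs a gene-level editing
   level, and each candidate descends from exactly one site, so that
   site's `E` is used); `S = 1 − fraction of identical positions` between
   the equal-length mutant and normal peptides (alignment-based similarity
   would be overkill for pairs that differ at one known residue);
   `H` a T-cell recognition probability. Per sample,
   `RENIS = Σ p`, `REscore = (abundance(CD8) + abundance(CTL)) · RENIS`,
   and cytolytic activity `CYT = √(TPM_GZMA · TPM_PRF1)` with no
   pseudocount, so zero expression propagates to zero.

### The recognition model H

The trained hydrophobicity model that motivated the `H` term is not
reproducible here, so the default is a transparent stand-in with the same
shape constraints: `H = 1/(1 + exp(−m̄/2))` where `m̄` is the mean
Kyte–Doolittle hydropathy of the TCR-contact span (positions 4–8 of a
9-mer; position 4 through the penultimate-minus-one residue for 10/11-mers).
It is bounded in (0, 1), monotone in contact-residue hydrophobicity, and
pluggable: any `(peptide) -> [0, 1]` function can replace it in
`score_sample()`, and `H ≡ 1` reduces `p` to the other two brackets.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_base_q` / `min_map_q` | 25 / 20 | strict (exclusive) call thresholds |
| `edge_bp` | 3 | trimmed window at each aligned-read end |
| `splice_window_bp` | 4 | intronic distance to a junction that is removed ("next to" a junction is not a number; 4 bp covers the misalignment overhang this filter targets and is configurable) |
| `homopolymer_run` | 5 | minimum adjacent run length |
| `panel_min_samples` | 2 | recurrence for the panel of normals |
| `flank` | 10 | long peptide = 2·flank+1 = 21 residues |
| `kmin`/`kmax` | 9 / 11 | short-peptide lengths |
| `rank_cut` / `tpm_cut` | 2 / 1 | strict candidate cuts |
| `l_slope` / `l_midpoint` | 5 / 2 | logistic rank weighting |

Open choices resolved here, beyond those already noted: edge-trimmed
observations are removed from both the numerator and the denominator of
`E` (removing them from the edited count alone would bias levels downward
with no physical justification); with no Alu annotation supplied, all
sites are treated as non-Alu, which only ever removes more.

## The synthetic fixture generator

`generate_fixtures()` builds a fully consistent toy dataset: one two-exon
gene (60-codon CDS split 90/90 bp across a 60 bp intron) per planted edit,
a background genome free of runs ≥ 4 so the only homopolymers are planted
ones, ungapped 50 bp reads placed so the edit falls well inside the read
(except for the deliberate edge-bait class), and matching GTF/BED/VCF/TSV
side files. Each planted edit carries a class that determines which filter
(if any) should remove it, and the returned truth table records the
expected fate, consequence and 21-mer peptide of every plant. Edited read
counts are drawn `Binomial(coverage, level)`, so recovered editing levels
are compared against binomial intervals, not point equality. Defaults are
deliberate: coverage 30, read length 50, base quality 35 and mapping
quality 60 for ordinary plants — comfortably inside the thresholds — with
the boundary classes pinned at exactly 25 and exactly 20 to exercise the
strict inequalities.

What the generator does *not* emulate: sequencing error models, splice-
aware (gapped) read placement, fragment-length or strand biases, multi-
mapping, and real Alu editing structure. Passing tests on these fixtures
therefore demonstrate the correctness of the detection arithmetic, the
filter contracts, the coordinate/strand handling and the score algebra —
not calling performance on real tumor RNA-seq.

## Numerical and degenerate-input behavior

Score inputs are validated, never clamped: `E`, `S`, `H` outside [0, 1],
negative TPM or non-positive ranks raise errors. `p` is always in [0, 1)
because `tanh(F) < 1` and every other factor is in [0, 1]. An empty
candidate set gives RENIS = REscore = 0 and an intact one-row sample
summary. Duplicate short peptides (same mutant sequence and length, e.g.
from overlapping transcripts) are collapsed; candidate burden counts
distinct mutant sequences, so allele multiplicity does not inflate it.
The mock binding predictor is a pure integer hash of (peptide, allele,
seed) mapped to (0, 100], exactly reproducible across platforms.

Problem sizes used throughout the test-suite and the worked examples — a
dozen genes of 60 codons, coverage 30–50, a few thousand bases of genome —
were chosen so that every property can be checked against brute-force
oracles (a per-read scanner for the pileup, exhaustive substring
enumeration for the chopper, a one-line scalar evaluation for `p`).

## Worked example

```{r example, eval = FALSE}
dir <- tempfile()
truth <- generate_fixtures(fixture_spec(seed = 7), dir)

cfg <- run_config(
  sam = file.path(dir, "reads.sam"), ref = file.path(dir, "ref.fa"),
  gtf = file.path(dir, "models.gtf"), expr = file.path(dir, "expression.tsv"),
  known = file.path(dir, "known.vcf"), alu = file.path(dir, "alu.bed"),
  normals = list.files(file.path(dir, "normals"), full.names = TRUE),
  alleles = c("HLA-A*02:01", "HLA-B*07:02"),
  predictor = "mock", rank_cut = 100, seed = 7)
run <- run_all(cfg)
run
glance(run)
end_to_end_check(truth, run$sites, run$candidates)
autoplot(run)
```

## Known limitations

* SAM text only (plain-text fixtures by design); BAM support would slot in
  behind the same reader contract.
* The coding annotator handles substitution effects in supplied CDS models;
  it is not a general-purpose effect predictor (no UTR/splice-site
  consequences, no selenocysteine recoding — codons containing N are
  dropped with a warning).
* The default `H` and the marker-mean immune abundances are documented
  simplifications behind pluggable contracts, not reimplementations of the
  externally trained models they stand in for.
* Cohort-scale statistics (survival, correlation analyses) are out of
  scope; the package ends at per-sample scores.
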