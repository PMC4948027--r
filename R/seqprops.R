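#' Charged residue counts and fractions
#'
#' Counts negatively charged residues (Asp + Glu) and positively charged
#' residues (Arg + Lys) in a protein sequence and expresses each as a
#' percentage of length.
#'
#' @param seq Single amino-acid string over the canonical 20-letter alphabet.
#' @return A one-row tibble with columns `ncr`, `pcr` (counts), `ncr_pct`,
#'   `pcr_pct` (exact percentages of sequence length).
#' @examples
#' charged_residue_fractions("DEKR")
#' @export
charged_residue_fractions <- function(seq) {
  seq <- assert_protein_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  ncr <- sum(chars %in% c("D", "E"))
  pcr <- sum(chars %in% c("R", "K"))
  tibble::tibble(
    ncr = ncr, pcr = pcr,
    ncr_pct = 100 * ncr / length(chars),
    pcr_pct = 100 * pcr / length(chars)
  )
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy per residue. Increasingly positive scores
#' indicate greater hydrophobicity.
#'
#' @inheritParams charged_residue_fractions
#' @return Numeric scalar in \[-4.5, 4.5\].
#' @export
gravy <- function(seq) {
  seq <- assert_protein_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  mean(.kd_hydropathy[chars])
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains (Ala, Val, Ile, Leu):
#' `AI = X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with X in mole percent
#' (Ikai coefficients).
#'
#' @inheritParams charged_residue_fractions
#' @return Numeric scalar (0 for a sequence without A/V/I/L).
#' @export
aliphatic_index <- function(seq) {
  seq <- assert_protein_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  x <- function(aa) 100 * sum(chars == aa) / n
  x("A") + .aliphatic_coef_val * x("V") +
    .aliphatic_coef_ile_leu * (x("I") + x("L"))
}

#' Instability index and stability call
#'
#' Guruprasad dipeptide-weight statistic:
#' `II = (10 / L) * sum DIWV(aa_i, aa_(i+1))` over the L - 1 overlapping
#' dipeptides. Proteins with II below 40 are called stable; II of 40 or
#' above is called unstable.
#'
#' @inheritParams charged_residue_fractions
#' @return A one-row tibble with `instability_index` and `stability_call`
#'   (`"stable"` or `"unstable"`).
#' @export
instability_index <- function(seq) {
  seq <- assert_protein_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 2L) stop("instability index requires length >= 2", call. = FALSE)
  ii <- (10 / n) * sum(.diwv[cbind(chars[-n], chars[-1])])
  tibble::tibble(
    instability_index = ii,
    stability_call = if (ii < 40) "stable" else "unstable"
  )
}

# Henderson-Hasselbalch net charge of a protein at a given pH
protein_net_charge <- function(seq, ph) {
  seq <- assert_protein_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  counts <- table(factor(chars, levels = .aa_alphabet))
  pos <- c(Nterm = 1, counts[c("K", "R", "H")])
  names(pos) <- names(.pka_positive)
  neg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  names(neg) <- names(.pka_negative)
  vapply(ph, function(p) {
    sum(pos / (1 + 10^(p - .pka_positive))) -
      sum(neg / (1 + 10^(.pka_negative - p)))
  }, numeric(1))
}

#' Isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge of the protein is
#' zero, found by bisection on \[0, 14\] using a Bjellqvist-style pKa set for
#' D, E, C, Y, H, K, R and the termini.
#'
#' @inheritParams charged_residue_fractions
#' @param tol Bisection tolerance on pH (default 1e-3).
#' @return Numeric pI in (0, 14).
#' @export
isoelectric_point <- function(seq, tol = 1e-3) {
  seq <- assert_protein_seq(seq)
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(seq, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Molecular weight (kDa)
#'
#' Sum of average-isotopic residue masses plus one water, in kDa.
#'
#' @inheritParams charged_residue_fractions
#' @return Numeric scalar, kDa.
#' @export
molecular_weight <- function(seq) {
  seq <- assert_protein_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  (sum(.residue_mass[chars]) + .water_mass) / 1000
}

#' Physicochemical profile of a protein set
#'
#' Computes, for each protein, the standard report columns of a gene-family
#' survey table: length, molecular weight (kDa), pI, counts and percentages of
#' negatively (Asp+Glu) and positively (Arg+Lys) charged residues, instability
#' index with stability call, aliphatic index, and GRAVY.
#'
#' @param data Data frame with one row per protein.
#' @param id,sequence Column names (character) holding the identifier and the
#'   amino-acid sequence.
#' @return A tibble with one row per protein and columns `id`, `length_aa`,
#'   `mw_kda`, `pi`, `ncr`, `ncr_pct`, `pcr`, `pcr_pct`, `instability_index`,
#'   `stability_call`, `aliphatic_index`, `gravy`. Percentages are exact;
#'   round for report output.
#' @examples
#' tibble::tibble(id = "p1", sequence = "MKDEEDLFGVKRK") |> protein_profile()
#' @export
protein_profile <- function(data, id = "id", sequence = "sequence") {
  assert_cols(data, c(id, sequence), "protein table")
  purrr::map2_dfr(data[[id]], data[[sequence]], function(gid, seq) {
    seq <- assert_protein_seq(seq, paste0("sequence of ", gid))
    cr <- charged_residue_fractions(seq)
    ii <- instability_index(seq)
    tibble::tibble(
      id = gid,
      length_aa = nchar(seq),
      mw_kda = molecular_weight(seq),
      pi = isoelectric_point(seq),
      ncr = cr$ncr, ncr_pct = cr$ncr_pct,
      pcr = cr$pcr, pcr_pct = cr$pcr_pct,
      instability_index = ii$instability_index,
      stability_call = ii$stability_call,
      aliphatic_index = aliphatic_index(seq),
      gravy = gravy(seq)
    )
  })
}
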