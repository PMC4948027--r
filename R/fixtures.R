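# Packaged reference tables for the desert-poplar Hsf family, transcribed
# from the published family survey (per-gene lengths, charged-residue counts
# and class labels) and the paralog-pair divergence table (Ka, Ks,
# duplication type, date). The original genome sequences are not
# redistributable; these per-gene summaries are the desk-reproducible part.

#' Hsf family survey table
#'
#' Per-gene class label, protein length, and charged-residue counts
#' (Asp+Glu and Arg+Lys) for the 32-member desert-poplar Hsf family.
#'
#' @return Tibble with columns `gene`, `hsf_class`, `subclass`, `length_aa`,
#'   `ncr`, `pcr`.
#' @export
hsf_family_table <- function() {
  readr::read_tsv(
    system.file("extdata", "hsf_family_table.tsv", package = "famevol",
                mustWork = TRUE),
    col_types = readr::cols(
      gene = "c", hsf_class = "c", subclass = "c",
      length_aa = "i", ncr = "i", pcr = "i"
    ), progress = FALSE)
}

#' Hsf paralog-pair divergence table
#'
#' The ten paralogous pairs of the desert-poplar Hsf family with their
#' duplication type, Ka, Ks, Ka/Ks, and published divergence date (MYA).
#'
#' @return Tibble with columns `subfamily`, `gene_a`, `gene_b`, `dup_type`,
#'   `ka`, `ks`, `ka_ks`, `date_mya`.
#' @export
hsf_paralog_pairs <- function() {
  readr::read_tsv(
    system.file("extdata", "hsf_paralog_pairs.tsv", package = "famevol",
                mustWork = TRUE),
    col_types = readr::cols(
      subfamily = "c", gene_a = "c", gene_b = "c", dup_type = "c",
      ka = "d", ks = "d", ka_ks = "d", date_mya = "d"
    ), progress = FALSE)
}
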