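# Gene models on scaffolds: intron phases, microsynteny duplicated blocks,
# and tandem/WGD/dispersed duplication typing. Coordinates follow GFF3
# conventions (1-based, inclusive).

#' Intron phases of a gene model
#'
#' The phase of an intron is the cumulative coding-sequence length 5' of the
#' intron, modulo 3 (0, 1, or 2). Introns lying entirely within untranslated
#' regions are flagged `"UTR"` instead of phased.
#'
#' @param cds_len_by_exon Integer vector of per-exon CDS lengths in transcript
#'   order (0 for fully untranslated exons). Total must be divisible by 3.
#' @return Tibble with one row per intron: `intron` (index), `phase`
#'   (`"0"`, `"1"`, `"2"`, or `"UTR"`).
#' @examples
#' intron_phases(c(300, 150))       # one phase-0 intron
#' intron_phases(c(0, 100, 200, 0)) # 5' UTR intron, phase-1 intron, 3' UTR intron
#' @export
intron_phases <- function(cds_len_by_exon) {
  if (length(cds_len_by_exon) < 1L || any(cds_len_by_exon < 0)) {
    stop("cds_len_by_exon must be non-negative with >= 1 exon", call. = FALSE)
  }
  total <- sum(cds_len_by_exon)
  if (total %% 3 != 0) {
    stop("total CDS length (", total, ") is not divisible by 3", call. = FALSE)
  }
  n_introns <- length(cds_len_by_exon) - 1L
  if (n_introns == 0L) {
    return(tibble::tibble(intron = integer(), phase = character()))
  }
  upstream <- cumsum(cds_len_by_exon)[seq_len(n_introns)]
  coding_exons <- which(cds_len_by_exon > 0)
  first_cds <- if (length(coding_exons)) min(coding_exons) else Inf
  last_cds <- if (length(coding_exons)) max(coding_exons) else -Inf
  phase <- vapply(seq_len(n_introns), function(i) {
    # intron i sits between exon i and exon i+1
    if (i < first_cds || i >= last_cds) "UTR" else as.character(upstream[i] %% 3)
  }, character(1))
  tibble::tibble(intron = seq_len(n_introns), phase = phase)
}

#' Rank genes along their scaffolds
#'
#' Assigns each gene its 0-based ordinal position among the genes of its
#' scaffold, ordered by start coordinate (strand-agnostic; ties broken by id).
#'
#' @param loci Data frame with columns `id`, `scaffold`, `start`.
#' @return `loci` with an appended integer `rank` column.
#' @export
gene_ranks <- function(loci) {
  assert_cols(loci, c("id", "scaffold", "start"), "locus table")
  loci |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::arrange(.data$start, .data$id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$scaffold, .data$rank)
}

#' Detect duplicated (microsynteny) blocks
#'
#' A duplicated block is a region pair where at least `min_anchors` conserved
#' homologs lie within `window` genes of one another on both scaffolds.
#' Anchors for each scaffold pair are sorted by rank on the first scaffold
#' and chained while consecutive anchors are at most `window` ranks apart on
#' both scaffolds; maximal chains with `min_anchors` or more anchors are
#' reported. Each anchor belongs to at most one block.
#'
#' @param loci Locus table (`id`, `scaffold`, `start`; `rank` is computed if
#'   absent).
#' @param homologs Data frame of homolog pairs with columns `gene_a`,
#'   `gene_b`.
#' @param window Maximum rank gap between consecutive anchors (default 15).
#' @param min_anchors Minimum anchors per block (default 3).
#' @return Tibble with one row per anchor: `block_id`, `scaffold_a`,
#'   `scaffold_b`, `gene_a`, `gene_b`, `rank_a`, `rank_b`, ordered by
#'   scaffold pair then first-anchor rank.
#' @export
find_duplicated_blocks <- function(loci, homologs, window = 15L,
                                   min_anchors = 3L) {
  assert_cols(homologs, c("gene_a", "gene_b"), "homolog table")
  if (!"rank" %in% names(loci)) loci <- gene_ranks(loci)
  idx <- stats::setNames(seq_len(nrow(loci)), loci$id)
  unknown <- setdiff(c(homologs$gene_a, homologs$gene_b), loci$id)
  if (length(unknown) > 0L) {
    stop("homolog list references unknown gene id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  anchors <- tibble::tibble(
    gene_a = homologs$gene_a, gene_b = homologs$gene_b,
    scaffold_a = loci$scaffold[idx[homologs$gene_a]],
    scaffold_b = loci$scaffold[idx[homologs$gene_b]],
    rank_a = loci$rank[idx[homologs$gene_a]],
    rank_b = loci$rank[idx[homologs$gene_b]]
  )
  # orient each pair so scaffold_a <= scaffold_b (rank ties keep gene order)
  flip <- anchors$scaffold_a > anchors$scaffold_b
  anchors[flip, c("gene_a", "gene_b", "scaffold_a", "scaffold_b",
                  "rank_a", "rank_b")] <-
    anchors[flip, c("gene_b", "gene_a", "scaffold_b", "scaffold_a",
                    "rank_b", "rank_a")]
  anchors <- dplyr::distinct(anchors) |>
    dplyr::arrange(.data$scaffold_a, .data$scaffold_b,
                   .data$rank_a, .data$rank_b)
  out <- anchors |>
    dplyr::group_by(.data$scaffold_a, .data$scaffold_b) |>
    dplyr::group_modify(function(df, key) {
      gap_a <- diff(df$rank_a)
      gap_b <- abs(diff(df$rank_b))
      new_chain <- c(TRUE, gap_a > window | gap_b > window)
      df$chain <- cumsum(new_chain)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$scaffold_a, .data$scaffold_b, .data$chain) |>
    dplyr::filter(dplyr::n() >= min_anchors) |>
    dplyr::ungroup()
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      block_id = integer(), scaffold_a = character(), scaffold_b = character(),
      gene_a = character(), gene_b = character(),
      rank_a = integer(), rank_b = integer()
    ))
  }
  out |>
    dplyr::mutate(block_id = dplyr::dense_rank(
      paste(.data$scaffold_a, .data$scaffold_b, .data$chain, sep = "\r"))) |>
    dplyr::select("block_id", "scaffold_a", "scaffold_b",
                  "gene_a", "gene_b", "rank_a", "rank_b") |>
    dplyr::arrange(.data$block_id, .data$rank_a)
}

#' Classify duplication type of paralog pairs
#'
#' A pair is `tandem` when both genes lie on the same scaffold with at most
#' `tandem_max_intervening` genes between them; otherwise `WGD` when the pair
#' anchors (or both genes lie within `window` ranks of the anchors of) an
#' inter-scaffold duplicated block joining their scaffolds; otherwise
#' `dispersed`.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @param loci Locus table (rank computed if absent).
#' @param blocks Output of [find_duplicated_blocks()].
#' @param tandem_max_intervening Maximum intervening genes for a tandem call
#'   (default 5).
#' @param window Rank window for block-flank support (default 15).
#' @return Tibble with `gene_a`, `gene_b`, `dup_type`, `evidence`.
#' @export
classify_duplication <- function(pairs, loci, blocks,
                                 tandem_max_intervening = 5L, window = 15L) {
  assert_cols(pairs, c("gene_a", "gene_b"), "pair table")
  if (!"rank" %in% names(loci)) loci <- gene_ranks(loci)
  idx <- stats::setNames(seq_len(nrow(loci)), loci$id)
  unknown <- setdiff(c(pairs$gene_a, pairs$gene_b), loci$id)
  if (length(unknown) > 0L) {
    stop("pair list references unlocated gene id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  purrr::map2_dfr(pairs$gene_a, pairs$gene_b, function(ga, gb) {
    sa <- loci$scaffold[idx[ga]]; sb <- loci$scaffold[idx[gb]]
    ra <- loci$rank[idx[ga]]; rb <- loci$rank[idx[gb]]
    if (sa == sb && abs(ra - rb) - 1L <= tandem_max_intervening) {
      return(tibble::tibble(
        gene_a = ga, gene_b = gb, dup_type = "tandem",
        evidence = sprintf("%d intervening gene(s) on %s",
                           abs(ra - rb) - 1L, sa)
      ))
    }
    # orient to match block orientation
    if (sa > sb) {
      tmp <- ga; ga2 <- gb; gb2 <- tmp
      sa2 <- sb; sb2 <- sa; ra2 <- rb; rb2 <- ra
    } else {
      ga2 <- ga; gb2 <- gb; sa2 <- sa; sb2 <- sb; ra2 <- ra; rb2 <- rb
    }
    cand <- blocks[blocks$scaffold_a == sa2 & blocks$scaffold_b == sb2 &
                     blocks$scaffold_a != blocks$scaffold_b, , drop = FALSE]
    wgd_block <- NA_integer_
    for (bid in unique(cand$block_id)) {
      b <- cand[cand$block_id == bid, ]
      direct <- any(b$gene_a == ga2 & b$gene_b == gb2)
      flanked <- min(abs(b$rank_a - ra2)) <= window &&
        min(abs(b$rank_b - rb2)) <= window
      if (direct || flanked) { wgd_block <- bid; break }
    }
    if (!is.na(wgd_block)) {
      return(tibble::tibble(gene_a = ga, gene_b = gb, dup_type = "WGD",
                            evidence = sprintf("block %d", wgd_block)))
    }
    tibble::tibble(gene_a = ga, gene_b = gb, dup_type = "dispersed",
                   evidence = "no tandem adjacency or block support")
  })
}
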