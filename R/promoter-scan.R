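# Promoter extraction, IUPAC cis-element scanning, and the enrichment-level
# statistic (total occurrences / genes carrying at least one occurrence).

#' Read or build a cis-element catalog
#'
#' The packaged default catalog carries the element names of the standard
#' plant cis-regulatory survey (HSE, ARE, MBS, TC-rich repeats, hormone and
#' development elements) with published consensus IUPAC strings. It is a
#' stand-in for database-specific matrices and is fully user-replaceable.
#'
#' @param path TSV with columns `name`, `iupac_pattern`, `functional_class`;
#'   when `NULL` the packaged default is returned.
#' @return Tibble catalog.
#' @export
read_element_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_element_catalog.tsv",
                        package = "famevol", mustWork = TRUE)
  }
  cat <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  assert_cols(cat, c("name", "iupac_pattern", "functional_class"), "catalog")
  if (anyDuplicated(cat$name)) stop("catalog names must be unique", call. = FALSE)
  ok <- vapply(cat$iupac_pattern, function(p) {
    all(strsplit(toupper(p), "")[[1]] %in% names(.iupac_bases))
  }, logical(1))
  if (!all(ok)) {
    stop("malformed IUPAC pattern(s): ",
         paste(cat$iupac_pattern[!ok], collapse = ", "), call. = FALSE)
  }
  cat
}

# IUPAC pattern -> regex character classes. An N in the *sequence* never
# matches a constrained code: only the pattern's own N (any base) admits N.
iupac_to_regex <- function(pattern) {
  codes <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(unique(codes), names(.iupac_bases))
  if (length(bad) > 0L) {
    stop("malformed IUPAC code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  paste(vapply(codes, function(cd) {
    bases <- .iupac_bases[[cd]]
    if (length(bases) == 4L) bases <- c(bases, "N")
    if (length(bases) == 1L) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, character(1)), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a promoter sequence
#'
#' Returns the region immediately 5' of the translation start: for a +
#' strand gene, genomic positions `[tss - length, tss - 1]` as-is; for a -
#' strand gene, the reverse complement of `(tss, tss + length]`. The
#' promoter is truncated (and flagged) at scaffold edges. Position 1 of the
#' returned sequence is most distal; the last position abuts the start codon.
#'
#' @param scaffold_seq Scaffold nucleotide string.
#' @param tss 1-based genomic coordinate of the first base of the start
#'   codon.
#' @param strand `"+"` or `"-"`.
#' @param length Promoter length (default 2000).
#' @return A list with `sequence` and `truncated` (logical).
#' @export
extract_promoter <- function(scaffold_seq, tss, strand, length = 2000L) {
  scaffold_seq <- toupper(scaffold_seq)
  n <- nchar(scaffold_seq)
  if (tss < 1L || tss > n) stop("translation start off scaffold", call. = FALSE)
  if (strand == "+") {
    from <- max(1L, tss - length)
    to <- tss - 1L
    if (to < from) return(list(sequence = "", truncated = TRUE))
    list(sequence = substring(scaffold_seq, from, to),
         truncated = from > tss - length)
  } else if (strand == "-") {
    from <- tss + 1L
    to <- min(n, tss + length)
    if (to < from) return(list(sequence = "", truncated = TRUE))
    list(sequence = revcomp(substring(scaffold_seq, from, to)),
         truncated = to < tss + length)
  } else {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
}

#' Extract promoters for a locus table
#'
#' @param loci Data frame with columns `id`, `scaffold`, `tss`, `strand`.
#' @param genome Named character vector (or `Biostrings::DNAStringSet`) of
#'   scaffold sequences.
#' @inheritParams extract_promoter
#' @return Tibble with `gene_id`, `sequence`, `truncated`.
#' @export
extract_promoters <- function(loci, genome, length = 2000L) {
  assert_cols(loci, c("id", "scaffold", "tss", "strand"), "locus table")
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  missing <- setdiff(loci$scaffold, names(genome))
  if (length(missing) > 0L) {
    stop("scaffold(s) absent from genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  purrr::pmap_dfr(loci[, c("id", "scaffold", "tss", "strand")],
    function(id, scaffold, tss, strand) {
      p <- extract_promoter(genome[[scaffold]], tss, strand, length)
      tibble::tibble(gene_id = id, sequence = p$sequence,
                     truncated = p$truncated)
    })
}

#' Scan promoters for cis-element occurrences
#'
#' Matches every catalog IUPAC pattern at every position of each promoter,
#' on the forward strand and (by default) the reverse strand. Overlapping
#' matches of one pattern are all reported; each (position, strand) pair is
#' reported once. An N in the promoter matches only an unconstrained (N)
#' pattern position.
#'
#' For a pattern whose consensus is its own reverse complement (e.g. the
#' palindromic heat stress element AGAAnnTTCT), a forward match is by
#' construction also a reverse-strand match; such patterns are scanned on one
#' strand only so that each site counts as a single occurrence.
#'
#' @param promoters Data frame with `gene_id` and `sequence` columns
#'   (e.g. from [extract_promoters()]).
#' @param catalog Catalog tibble ([read_element_catalog()] by default).
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return Tibble of hits: `gene_id`, `element_name`, `functional_class`,
#'   `start` (1-based on the given promoter), `strand`, `matched_text`,
#'   ordered by gene, element, position, strand.
#' @export
scan_elements <- function(promoters, catalog = read_element_catalog(),
                          both_strands = TRUE) {
  assert_cols(promoters, c("gene_id", "sequence"), "promoter table")
  assert_cols(catalog, c("name", "iupac_pattern", "functional_class"),
              "catalog")
  regexes <- vapply(catalog$iupac_pattern, iupac_to_regex, character(1))
  hits <- purrr::map2_dfr(promoters$gene_id, promoters$sequence,
    function(gid, seq) {
      seq <- toupper(seq)
      purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
        k <- nchar(catalog$iupac_pattern[i])
        fwd <- overlap_matches(seq, regexes[i])
        out <- list()
        if (length(fwd) > 0L) {
          out$f <- tibble::tibble(
            gene_id = gid, element_name = catalog$name[i],
            functional_class = catalog$functional_class[i],
            start = fwd, strand = "+",
            matched_text = substring(seq, fwd, fwd + k - 1L)
          )
        }
        if (both_strands && !iupac_palindromic(catalog$iupac_pattern[i])) {
          rc <- revcomp_iupac_regex(catalog$iupac_pattern[i])
          rev_hits <- overlap_matches(seq, rc)
          if (length(rev_hits) > 0L) {
            out$r <- tibble::tibble(
              gene_id = gid, element_name = catalog$name[i],
              functional_class = catalog$functional_class[i],
              start = rev_hits, strand = "-",
              matched_text = substring(seq, rev_hits, rev_hits + k - 1L)
            )
          }
        }
        dplyr::bind_rows(out)
      })
    })
  if (nrow(hits) == 0L) {
    return(tibble::tibble(gene_id = character(), element_name = character(),
                          functional_class = character(), start = integer(),
                          strand = character(), matched_text = character()))
  }
  dplyr::arrange(hits, .data$gene_id, .data$element_name, .data$start,
                 .data$strand)
}

# all (overlapping) match start positions of regex `rx` in `seq`
overlap_matches <- function(seq, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

.iupac_comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

revcomp_iupac <- function(pattern) {
  codes <- rev(strsplit(toupper(pattern), "")[[1]])
  paste(.iupac_comp[codes], collapse = "")
}

iupac_palindromic <- function(pattern) {
  toupper(pattern) == revcomp_iupac(pattern)
}

# regex matching the reverse complement of an IUPAC pattern on the forward
# sequence (i.e. occurrences on the - strand)
revcomp_iupac_regex <- function(pattern) {
  iupac_to_regex(revcomp_iupac(pattern))
}

#' Enrichment level of cis-elements
#'
#' For each element, the number of genes carrying at least one occurrence,
#' the total occurrence count, and the enrichment level
#' `n_total_hits / n_genes_with_hit`. Elements with no hits are absent from
#' the summary.
#'
#' @param hits Hit table from [scan_elements()] (columns `gene_id`,
#'   `element_name`; `functional_class` carried through when present).
#' @return Tibble with `element_name`, `n_genes_with_hit`, `n_total_hits`,
#'   `enrichment_level` (exact; round to one decimal for reports), sorted by
#'   decreasing enrichment.
#' @examples
#' # 73 occurrences across 27 genes -> enrichment level 2.7
#' @export
enrichment_level <- function(hits) {
  assert_cols(hits, c("gene_id", "element_name"), "hit table")
  grp <- c("element_name",
           intersect("functional_class", names(hits)))
  hits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_genes_with_hit = dplyr::n_distinct(.data$gene_id),
      n_total_hits = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(enrichment_level = .data$n_total_hits / .data$n_genes_with_hit) |>
    dplyr::arrange(dplyr::desc(.data$enrichment_level), .data$element_name)
}

#' Plot per-element gene and occurrence counts
#'
#' Summary figure in the style of a cis-element survey: total occurrences
#' (bars) and genes carrying the element (points), grouped by functional
#' class.
#'
#' @param summary Output of [enrichment_level()] including
#'   `functional_class`.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(summary) {
  assert_cols(summary, c("element_name", "n_genes_with_hit", "n_total_hits"),
              "enrichment summary")
  df <- dplyr::mutate(summary,
                      element_name = stats::reorder(.data$element_name,
                                                    -.data$n_total_hits))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$element_name)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_total_hits), fill = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_genes_with_hit),
                        colour = "red", size = 2) +
    ggplot2::labs(x = NULL, y = "count",
                  title = "cis-element occurrences (bars) and genes with element (dots)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("functional_class" %in% names(summary)) {
    p <- p + ggplot2::facet_grid(~functional_class, scales = "free_x",
                                 space = "free_x")
  }
  p
}
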