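# Hsf functional-motif scanning and class assignment.
#
# DBD and HR-A/B coordinates come from upstream domain annotation and are
# treated as inputs; this module scans the remaining short motifs (RD
# tetrapeptide, basic NLS clusters, acidic-aromatic AHA windows) with simple
# configurable rules and derives the A/B/C class from domain geometry.
# All coordinates are 1-based inclusive.

span_tibble <- function(kind, start, end, seq) {
  tibble::tibble(
    kind = kind,
    start = as.integer(start),
    end = as.integer(end),
    matched_text = substring(seq, start, end)
  )
}

#' Find repressor-domain (RD) tetrapeptide motifs
#'
#' Locates the class-B repressor tetrapeptide (LFGV, with the IFGV variant
#' enabled by default), reporting non-overlapping occurrences leftmost-first.
#'
#' @param seq Amino-acid string.
#' @param patterns Character vector of exact tetrapeptide patterns.
#' @return Tibble of spans (`kind`, `start`, `end`, `matched_text`).
#' @export
find_rd_motif <- function(seq, patterns = c("LFGV", "IFGV")) {
  seq <- assert_protein_seq(seq)
  hits <- purrr::map_dfr(patterns, function(p) {
    m <- gregexpr(p, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(tibble::tibble())
    span_tibble("RD", as.integer(m), as.integer(m) + nchar(p) - 1L, seq)
  })
  if (nrow(hits) == 0L) return(empty_span())
  hits <- dplyr::arrange(hits, .data$start)
  # drop overlaps, keep leftmost
  keep <- rep(TRUE, nrow(hits))
  last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] <= last_end) keep[i] <- FALSE else last_end <- hits$end[i]
  }
  hits[keep, ]
}

empty_span <- function() {
  tibble::tibble(kind = character(), start = integer(), end = integer(),
                 matched_text = character())
}

#' Find candidate nuclear localization signals
#'
#' Flags windows of length `window` containing at least `min_basic` basic
#' residues (K/R); overlapping qualifying windows are merged into maximal
#' spans. This is a deliberately simple composition rule, exposed as
#' configuration; it is validated on planted synthetic signals, not on
#' profile models.
#'
#' @param seq Amino-acid string.
#' @param min_basic Minimum K+R count per window (default 4).
#' @param window Window length (default 8); must be >= `min_basic`.
#' @return Tibble of merged spans.
#' @export
find_nls <- function(seq, min_basic = 4L, window = 8L) {
  seq <- assert_protein_seq(seq)
  if (window < min_basic || min_basic < 2L) {
    stop("window must be >= min_basic >= 2", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < window) return(empty_span())
  basic <- as.integer(chars %in% c("K", "R"))
  counts <- stats::filter(basic, rep(1, window), sides = 1)[window:n]
  starts <- which(counts >= min_basic)
  if (length(starts) == 0L) return(empty_span())
  merge_windows(starts, window, "NLS", seq)
}

# merge overlapping fixed-length windows starting at `starts`
merge_windows <- function(starts, window, kind, seq) {
  starts <- sort(starts)
  ends <- starts + window - 1L
  grp <- cumsum(c(1L, as.integer(starts[-1] > ends[-length(ends)] + 0L)))
  purrr::map_dfr(split(seq_along(starts), grp), function(idx) {
    span_tibble(kind, min(starts[idx]), max(ends[idx]), seq)
  })
}

#' Find candidate AHA activator motifs
#'
#' Scores windows of length 10 centred on an aromatic residue (W or F) that
#' contain at least `min_acidic` acidic residues (D/E); overlapping raw hits
#' are merged. Like the NLS rule this is configurable plumbing around the
#' published exemplar motifs, not a trained model.
#'
#' @param seq Amino-acid string.
#' @param window Window length (default 10).
#' @param min_acidic Minimum D+E count per window (default 2).
#' @return Tibble of merged spans.
#' @export
find_aha_motifs <- function(seq, window = 10L, min_acidic = 2L) {
  seq <- assert_protein_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < window) return(empty_span())
  half_before <- as.integer(floor((window - 1) / 2))  # 4 for window 10
  centre_idx <- which(chars %in% c("W", "F"))
  starts <- centre_idx - half_before
  starts <- starts[starts >= 1L & starts + window - 1L <= n]
  if (length(starts) == 0L) return(empty_span())
  acidic <- as.integer(chars %in% c("D", "E"))
  cum <- c(0L, cumsum(acidic))
  ok <- (cum[starts + window] - cum[starts]) >= min_acidic
  starts <- unique(starts[ok])
  if (length(starts) == 0L) return(empty_span())
  merge_windows(starts, window, "AHA", seq)
}

#' Scan a protein set for Hsf short motifs
#'
#' Runs the RD, NLS and AHA scanners over a table of proteins.
#'
#' @param data Data frame with `id` and `sequence` columns.
#' @return Tibble of spans with an `id` column; every span satisfies
#'   `matched_text == substring(sequence, start, end)`.
#' @export
scan_hsf_motifs <- function(data) {
  assert_cols(data, c("id", "sequence"), "protein table")
  purrr::map2_dfr(data$id, data$sequence, function(gid, seq) {
    dplyr::bind_rows(find_rd_motif(seq), find_nls(seq), find_aha_motifs(seq)) |>
      dplyr::mutate(id = gid, .before = 1)
  })
}

#' Classify Hsf proteins into classes A, B, C from domain geometry
#'
#' Plant Hsfs fall into three classes according to the length of the linker
#' between the DNA-binding domain (DBD) and the HR-A/B oligomerization
#' region, and the length of the insertion within HR-A/B: class A carries a
#' 21-aa insertion (long HR-A/B span), class B a compact HR-A/B with a long
#' linker, class C a compact HR-A/B with a short linker. Thresholds are
#' configuration; the derived quantities and the rule applied are echoed in
#' the output.
#'
#' @param data Data frame with columns `id`, `dbd_start`, `dbd_end`,
#'   `hr_start`, `hr_end` (1-based inclusive residue coordinates).
#' @param a_insert_min Minimum HR-A/B span for class A (default 40).
#' @param b_linker_min Linker length strictly above which a non-A protein is
#'   class B (default 44).
#' @return Tibble with `id`, `linker_len`, `hr_span_len`, `hsf_class`,
#'   `rationale`.
#' @export
classify_hsf <- function(data, a_insert_min = 40L, b_linker_min = 44L) {
  assert_cols(data, c("id", "dbd_start", "dbd_end", "hr_start", "hr_end"),
              "domain table")
  bad <- data$dbd_end >= data$hr_start | data$dbd_start > data$dbd_end |
    data$hr_start > data$hr_end
  if (any(bad)) {
    stop("out-of-order or overlapping DBD/HR-A/B spans for: ",
         paste(data$id[bad], collapse = ", "), call. = FALSE)
  }
  linker <- data$hr_start - data$dbd_end - 1L
  hr_span <- data$hr_end - data$hr_start + 1L
  cls <- ifelse(hr_span >= a_insert_min, "A",
                ifelse(linker > b_linker_min, "B", "C"))
  tibble::tibble(
    id = data$id,
    linker_len = as.integer(linker),
    hr_span_len = as.integer(hr_span),
    hsf_class = cls,
    rationale = dplyr::case_when(
      cls == "A" ~ sprintf("HR-A/B span %d >= %d", hr_span, a_insert_min),
      cls == "B" ~ sprintf("linker %d > %d", linker, b_linker_min),
      TRUE ~ sprintf("HR-A/B span %d < %d and linker %d <= %d",
                     hr_span, a_insert_min, linker, b_linker_min)
    )
  )
}
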