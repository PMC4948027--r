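#' Nei-Gojobori Ka/Ks for one codon-aligned pair
#'
#' Estimates synonymous (Ks) and nonsynonymous (Ka) substitution rates for a
#' gapless codon-aligned sequence pair by approximate-method counting:
#' synonymous/nonsynonymous site totals `S` and `N` averaged over the two
#' sequences, difference counts `Sd` and `Nd` averaged equally over all
#' minimal substitution paths per codon (paths through stop codons excluded),
#' and Jukes-Cantor correction `Ks = -(3/4) log(1 - (4/3) pS)` (Ka analogous).
#'
#' Codon columns containing a gap character (`-`) in either sequence are
#' dropped before counting.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings; length divisible by 3;
#'   no internal stop codons.
#' @param id_a,id_b Optional identifiers carried into the result.
#' @return An object of class `kaks` (a list with `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `ks`, `ka`, `ka_ks`, `n_codons`). `ka_ks` is `NA` when `Ks = 0`.
#'   Use [tidy()] to get a one-row tibble.
#' @examples
#' kaks_pair("TTTGGGGGG", "TTCGGGGGG")
#' @export
kaks_pair <- function(seq_a, seq_b, id_a = "seq_a", id_b = "seq_b") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  if (nchar(seq_a) %% 3 != 0) {
    stop("alignment length must be divisible by 3", call. = FALSE)
  }
  cod_a <- split_codons(seq_a)
  cod_b <- split_codons(seq_b)
  gapped <- grepl("-", cod_a, fixed = TRUE) | grepl("-", cod_b, fixed = TRUE)
  cod_a <- cod_a[!gapped]; cod_b <- cod_b[!gapped]
  if (length(cod_a) == 0L) stop("no ungapped codons in alignment", call. = FALSE)
  tabs <- codon_tables()
  for (cods in list(cod_a, cod_b)) {
    bad <- !cods %in% tabs$codons
    if (any(bad)) {
      stop("invalid codon(s): ", paste(unique(cods[bad]), collapse = ", "),
           call. = FALSE)
    }
    if (any(tabs$is_stop[cods])) {
      stop("internal stop codon in alignment", call. = FALSE)
    }
  }
  s_a <- sum(tabs$syn_sites[cod_a]); s_b <- sum(tabs$syn_sites[cod_b])
  S <- (s_a + s_b) / 2
  N <- 3 * length(cod_a) - S
  diffs <- which(cod_a != cod_b)
  sd_tot <- 0; nd_tot <- 0
  for (i in diffs) {
    d <- codon_path_diffs(cod_a[i], cod_b[i])
    sd_tot <- sd_tot + d[["sd"]]
    nd_tot <- nd_tot + d[["nd"]]
  }
  pS <- if (S > 0) sd_tot / S else NA_real_
  pN <- if (N > 0) nd_tot / N else NA_real_
  if (!is.na(pS) && pS >= 3 / 4) {
    stop("synonymous sites saturated (pS >= 3/4); Jukes-Cantor correction undefined",
         call. = FALSE)
  }
  if (!is.na(pN) && pN >= 3 / 4) {
    stop("nonsynonymous sites saturated (pN >= 3/4); Jukes-Cantor correction undefined",
         call. = FALSE)
  }
  ks <- jc_correct(pS)
  ka <- jc_correct(pN)
  out <- list(
    id_a = id_a, id_b = id_b, n_codons = length(cod_a),
    S = S, N = N, Sd = sd_tot, Nd = nd_tot, pS = pS, pN = pN,
    ks = ks, ka = ka,
    ka_ks = if (is.na(ks) || ks == 0) NA_real_ else ka / ks
  )
  class(out) <- "kaks"
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' @export
print.kaks <- function(x, ...) {
  cat(sprintf("Ka/Ks (Nei-Gojobori, Jukes-Cantor corrected): %s vs %s\n",
              x$id_a, x$id_b))
  cat(sprintf("  codons %d  S %.2f  N %.2f  Sd %.2f  Nd %.2f\n",
              x$n_codons, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ka %.4f  Ks %.4f  Ka/Ks %s\n", x$ka, x$ks,
              ifelse(is.na(x$ka_ks), "NA (Ks = 0)", sprintf("%.4f", x$ka_ks))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname kaks_pair
#' @param x A `kaks` object.
#' @param ... Unused.
#' @method tidy kaks
#' @export
tidy.kaks <- function(x, ...) {
  tibble::tibble(
    id_a = x$id_a, id_b = x$id_b, n_codons = x$n_codons,
    S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd, pS = x$pS, pN = x$pN,
    ka = x$ka, ks = x$ks, ka_ks = x$ka_ks
  )
}

#' @rdname kaks_pair
#' @method glance kaks
#' @export
glance.kaks <- function(x, ...) {
  tibble::tibble(
    n_codons = x$n_codons, ka = x$ka, ks = x$ks, ka_ks = x$ka_ks,
    selection = dplyr::case_when(
      is.na(x$ka_ks) ~ NA_character_,
      x$ka_ks < 1 ~ "purifying",
      x$ka_ks > 1 ~ "positive",
      TRUE ~ "neutral"
    )
  )
}

#' Ka/Ks for a table of codon-aligned pairs
#'
#' @param data Data frame with columns `id_a`, `id_b`, `seq_a`, `seq_b`
#'   (one codon-aligned pair per row).
#' @return Tibble with one row per pair: site and difference counts, `pS`,
#'   `pN`, `ka`, `ks`, `ka_ks` (`NA` when `Ks = 0`).
#' @export
kaks <- function(data) {
  assert_cols(data, c("id_a", "id_b", "seq_a", "seq_b"), "pair table")
  purrr::pmap_dfr(
    data[, c("id_a", "id_b", "seq_a", "seq_b")],
    function(id_a, id_b, seq_a, seq_b) {
      tidy(kaks_pair(seq_a, seq_b, id_a = id_a, id_b = id_b))
    }
  )
}

#' Sliding-window Ka/Ks profile along a codon alignment
#'
#' Recomputes the Nei-Gojobori estimate within codon-aligned windows sliding
#' along the alignment (default window 90 bp, step 9 bp). Windows where the
#' estimate is undefined (saturation or zero-site denominators) are flagged
#' rather than dropped.
#'
#' @inheritParams kaks_pair
#' @param window_bp Window size in bp; multiple of 3 (90 and 60 are the
#'   conventional choices).
#' @param step_bp Step size in bp; multiple of 3 (default 9).
#' @return A tibble of class `kaks_profile` with columns `start_bp`,
#'   `end_bp`, `ka`, `ks`, `ka_ks`, `status` (`"ok"`, `"undefined"`, or
#'   `"saturated"`); window and step sizes are stored as attributes.
#' @export
sliding_window_kaks <- function(seq_a, seq_b, window_bp = 90L, step_bp = 9L,
                                id_a = "seq_a", id_b = "seq_b") {
  if (window_bp %% 3 != 0 || step_bp %% 3 != 0) {
    stop("window_bp and step_bp must be multiples of 3", call. = FALSE)
  }
  len <- nchar(seq_a)
  if (window_bp > len) stop("window_bp exceeds alignment length", call. = FALSE)
  starts <- seq(1L, len - window_bp + 1L, by = step_bp)
  rows <- purrr::map_dfr(starts, function(st) {
    en <- st + window_bp - 1L
    wa <- substring(seq_a, st, en); wb <- substring(seq_b, st, en)
    res <- tryCatch(kaks_pair(wa, wb, id_a, id_b), error = function(e) e)
    if (inherits(res, "error")) {
      status <- if (grepl("saturat", conditionMessage(res))) "saturated" else "undefined"
      return(tibble::tibble(start_bp = st, end_bp = en, ka = NA_real_,
                            ks = NA_real_, ka_ks = NA_real_, status = status))
    }
    tibble::tibble(
      start_bp = st, end_bp = en, ka = res$ka, ks = res$ks, ka_ks = res$ka_ks,
      status = if (is.na(res$ka_ks)) "undefined" else "ok"
    )
  })
  structure(rows, class = c("kaks_profile", class(rows)),
            window_bp = window_bp, step_bp = step_bp,
            id_a = id_a, id_b = id_b)
}

#' @rdname sliding_window_kaks
#' @param object A `kaks_profile`.
#' @param ... Unused.
#' @method autoplot kaks_profile
#' @export
autoplot.kaks_profile <- function(object, ...) {
  mid <- (object$start_bp + object$end_bp) / 2
  df <- tibble::tibble(mid_bp = mid, ka_ks = object$ka_ks)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_bp, y = .data$ka_ks)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = "alignment position (bp, window midpoint)", y = "Ka/Ks",
      title = sprintf("Sliding-window Ka/Ks (%d bp window, %d bp step)",
                      attr(object, "window_bp"), attr(object, "step_bp"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Date a duplication event from its synonymous distance
#'
#' Applies the synonymous molecular clock `T = Ks / (2 lambda)`, with the
#' *Populus* synonymous rate `lambda = 9.1e-9` substitutions/site/year by
#' default, and reports million years ago (MYA).
#'
#' @param ks Numeric vector of synonymous distances (Ks >= 0).
#' @param lambda_rate Clock rate in substitutions/site/year (default 9.1e-9).
#' @return Numeric vector of ages in MYA (same length as `ks`).
#' @examples
#' divergence_time(0.343)  # 18.85 MYA
#' @export
divergence_time <- function(ks, lambda_rate = 9.1e-9) {
  if (any(ks < 0, na.rm = TRUE)) stop("ks must be >= 0", call. = FALSE)
  if (lambda_rate <= 0) stop("lambda_rate must be > 0", call. = FALSE)
  ks / (2 * lambda_rate) / 1e6
}

#' Add divergence dates to a Ka/Ks table
#'
#' @param data Data frame with a `ks` column (e.g. output of [kaks()]).
#' @inheritParams divergence_time
#' @return `data` with an appended `t_mya` column.
#' @export
date_duplications <- function(data, lambda_rate = 9.1e-9) {
  assert_cols(data, "ks", "Ka/Ks table")
  dplyr::mutate(data, t_mya = divergence_time(.data$ks, lambda_rate))
}
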