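# Codon-level lookup tables for the Nei-Gojobori machinery, built once per
# session from the standard genetic code (Biostrings::GENETIC_CODE).

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tables)) return(.codon_env$tables)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  nt <- c("A", "C", "G", "T")
  # 9 one-step neighbours of each codon
  neighbours <- lapply(codons, function(cod) {
    chars <- strsplit(cod, "")[[1]]
    unlist(lapply(1:3, function(p) {
      vapply(setdiff(nt, chars[p]), function(b) {
        x <- chars; x[p] <- b; paste(x, collapse = "")
      }, character(1))
    }), use.names = FALSE)
  })
  names(neighbours) <- codons
  is_stop <- aa == "*"
  names(is_stop) <- codons
  # per-codon synonymous site count: per position, fraction of the 3
  # alternative bases preserving the amino acid (changes to stop count as
  # nonsynonymous); n = 3 - s
  syn_sites <- vapply(codons, function(cod) {
    if (is_stop[cod]) return(NA_real_)
    nb <- neighbours[[cod]]
    sum(gc_tab[nb] == gc_tab[cod] & !is_stop[nb]) / 3
  }, numeric(1))
  .codon_env$tables <- list(
    codons = codons, aa = stats::setNames(aa, codons),
    neighbours = neighbours, is_stop = is_stop, syn_sites = syn_sites,
    sense_codons = codons[!is_stop]
  )
  .codon_env$pair_cache <- new.env(parent = emptyenv())
  .codon_env$tables
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Nei-Gojobori site counting: `s` is the sum over the three codon positions
#' of the fraction of one-step changes at that position that are synonymous
#' (changes to stop codons count as nonsynonymous); `n = 3 - s`.
#'
#' @param codon Character vector of sense codons (A/C/G/T triplets).
#' @return Tibble with columns `codon`, `s`, `n`.
#' @examples
#' ng86_sites(c("TTT", "ATG", "GGG"))
#' @export
ng86_sites <- function(codon) {
  tabs <- codon_tables()
  codon <- toupper(codon)
  bad <- !codon %in% tabs$sense_codons
  if (any(bad)) {
    stop("not a sense codon: ", paste(unique(codon[bad]), collapse = ", "),
         call. = FALSE)
  }
  s <- unname(tabs$syn_sites[codon])
  tibble::tibble(codon = codon, s = s, n = 3 - s)
}

# Synonymous/nonsynonymous difference counts between two codons, averaging
# equally over all minimal substitution paths; paths through stop codons are
# excluded (if every path hits a stop, all paths are used as a fallback).
# Results memoised per codon pair.
codon_path_diffs <- function(cod_a, cod_b) {
  if (cod_a == cod_b) return(c(sd = 0, nd = 0))
  key <- paste0(cod_a, cod_b)
  tabs <- codon_tables()
  cache <- .codon_env$pair_cache
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  ca <- strsplit(cod_a, "")[[1]]
  cb <- strsplit(cod_b, "")[[1]]
  pos <- which(ca != cb)
  perms <- permutations_of(pos)
  path_counts <- lapply(perms, function(order) {
    cur <- ca
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- cb[p]
      cod_from <- paste(cur, collapse = "")
      cod_to <- paste(nxt, collapse = "")
      if (tabs$is_stop[cod_to] && cod_to != cod_b) return(NULL)  # path blocked
      if (tabs$is_stop[cod_from] || tabs$is_stop[cod_to]) {
        nd <- nd + 1  # fallback paths only; stop transitions are nonsyn
      } else if (tabs$aa[cod_from] == tabs$aa[cod_to]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  })
  ok <- !vapply(path_counts, is.null, logical(1))
  if (!any(ok)) {
    # all paths pass through a stop codon: fall back to equal weighting of
    # every minimal path
    path_counts <- lapply(perms, function(order) {
      cur <- ca
      sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- cb[p]
        same <- !tabs$is_stop[paste(cur, collapse = "")] &&
          !tabs$is_stop[paste(nxt, collapse = "")] &&
          tabs$aa[paste(cur, collapse = "")] == tabs$aa[paste(nxt, collapse = "")]
        if (same) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
    ok <- rep(TRUE, length(path_counts))
  }
  mat <- do.call(rbind, path_counts[ok])
  res <- c(sd = mean(mat[, "sd"]), nd = mean(mat[, "nd"]))
  cache[[key]] <- res
  res
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}
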