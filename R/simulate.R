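# Seed-deterministic synthetic-data generators. Every generator returns its
# outputs together with a machine-readable truth record so downstream
# estimators can be tested against known ground truth without external data.

local_seed <- function(seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    fn <- function() {
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }
    return(fn)
  }
  function() invisible(NULL)
}

#' Simulate a codon-aligned paralog pair with known substitution history
#'
#' Draws a random sense-codon ancestor and applies a Poisson number of
#' synonymous one-step substitutions (expectation `ks_target * S` of the
#' ancestor) and nonsynonymous one-step substitutions (expectation
#' `omega * ks_target * N`) to a copy, in random interleaved order, always
#' rejecting changes that create stop codons. The substitution process is
#' count-targeted rather than continuous-time, so the realized event counts
#' are known exactly.
#'
#' @param n_codons Number of codons.
#' @param omega Target Ka/Ks ratio (> 0).
#' @param ks_target Expected synonymous substitutions per synonymous site
#'   (>= 0).
#' @param seed Integer seed.
#' @return List with `seq_a`, `seq_b`, and `truth` (a list with
#'   `n_syn_events`, `n_nonsyn_events`, `omega`, `ks_target`).
#' @export
simulate_codon_pair <- function(n_codons, omega, ks_target, seed = NULL) {
  if (omega <= 0 || ks_target < 0) {
    stop("omega must be > 0 and ks_target >= 0", call. = FALSE)
  }
  restore <- local_seed(seed); on.exit(restore())
  tabs <- codon_tables()
  anc <- sample(tabs$sense_codons, n_codons, replace = TRUE)
  S <- sum(tabs$syn_sites[anc]); N <- 3 * n_codons - S
  n_syn <- stats::rpois(1, ks_target * S)
  n_nonsyn <- stats::rpois(1, omega * ks_target * N)
  events <- sample(c(rep("syn", n_syn), rep("nonsyn", n_nonsyn)))
  der <- anc
  for (ev in events) {
    repeat {
      i <- sample.int(n_codons, 1)
      nb <- tabs$neighbours[[der[i]]]
      cand <- nb[sample.int(9L, 1)]
      if (tabs$is_stop[cand]) next
      syn <- tabs$aa[cand] == tabs$aa[der[i]]
      if ((ev == "syn") == unname(syn)) { der[i] <- cand; break }
    }
  }
  list(
    seq_a = paste(anc, collapse = ""),
    seq_b = paste(der, collapse = ""),
    truth = list(n_syn_events = n_syn, n_nonsyn_events = n_nonsyn,
                 omega = omega, ks_target = ks_target,
                 S_ancestor = S, N_ancestor = N)
  )
}

#' Simulate scaffold layouts with planted duplicated blocks and tandem pairs
#'
#' Plants `n_blocks` inter-scaffold synteny blocks (each with
#' `anchors_per_block` anchor pairs whose rank gaps respect the detection
#' window), `n_tandem` adjacent tandem pairs, and optional decoy homolog
#' pairs that cannot chain into blocks (each decoy pair gets a scaffold pair
#' of its own).
#'
#' @param n_scaffolds Number of scaffolds (>= 2).
#' @param genes_per_scaffold Genes per scaffold.
#' @param n_blocks Number of planted blocks.
#' @param anchors_per_block Anchors per planted block (>= 3).
#' @param max_gap Maximum rank gap between consecutive planted anchors
#'   (default 15, i.e. the detection window).
#' @param n_tandem Number of planted adjacent tandem pairs.
#' @param n_decoys Number of isolated decoy homolog pairs.
#' @param seed Integer seed.
#' @return List with `loci` (id, scaffold, start, end, strand, rank),
#'   `homologs` (gene_a, gene_b), and `truth` (`block_anchors`,
#'   `tandem_pairs`, `decoy_pairs` tibbles).
#' @export
simulate_genome_layout <- function(n_scaffolds = 8L, genes_per_scaffold = 40L,
                                   n_blocks = 2L, anchors_per_block = 3L,
                                   max_gap = 15L, n_tandem = 1L,
                                   n_decoys = 0L, seed = NULL) {
  if (n_scaffolds < 2L) stop("need >= 2 scaffolds", call. = FALSE)
  restore <- local_seed(seed); on.exit(restore())
  scafs <- sprintf("scaffold%02d", seq_len(n_scaffolds))
  loci <- purrr::map_dfr(scafs, function(sc) {
    starts <- sort(sample.int(genes_per_scaffold * 5000L, genes_per_scaffold))
    tibble::tibble(
      id = sprintf("%s_g%03d", sc, seq_len(genes_per_scaffold)),
      scaffold = sc, start = starts, end = starts + 999L,
      strand = sample(c("+", "-"), genes_per_scaffold, replace = TRUE)
    )
  }) |> gene_ranks()
  scaffold_pairs_needed <- n_blocks + n_decoys
  all_pairs <- utils::combn(scafs, 2, simplify = FALSE)
  if (scaffold_pairs_needed > length(all_pairs)) {
    stop("not enough scaffold pairs for the requested blocks and decoys",
         call. = FALSE)
  }
  pair_pick <- sample(all_pairs, scaffold_pairs_needed)
  gene_at <- function(sc, rank) {
    loci$id[loci$scaffold == sc & loci$rank == rank]
  }
  block_anchors <- purrr::map_dfr(seq_len(n_blocks), function(b) {
    sp <- pair_pick[[b]]
    gaps_a <- sample.int(max_gap, anchors_per_block - 1L, replace = TRUE)
    gaps_b <- sample.int(max_gap, anchors_per_block - 1L, replace = TRUE)
    ranks_a <- cumsum(c(sample.int(3L, 1) - 1L, gaps_a))
    ranks_b <- cumsum(c(sample.int(3L, 1) - 1L, gaps_b))
    if (max(ranks_a) >= genes_per_scaffold || max(ranks_b) >= genes_per_scaffold) {
      stop("planted block exceeds scaffold length; increase genes_per_scaffold",
           call. = FALSE)
    }
    tibble::tibble(
      block = b,
      gene_a = vapply(ranks_a, gene_at, character(1), sc = sp[1]),
      gene_b = vapply(ranks_b, gene_at, character(1), sc = sp[2])
    )
  })
  tandem_pairs <- purrr::map_dfr(seq_len(n_tandem), function(t) {
    sc <- sample(scafs, 1)
    r <- sample.int(genes_per_scaffold - 1L, 1) - 1L
    tibble::tibble(gene_a = gene_at(sc, r), gene_b = gene_at(sc, r + 1L))
  })
  # decoys are 2-anchor chains (one per scaffold pair): within the window but
  # below min_anchors, so they must never yield a block
  decoy_pairs <- purrr::map_dfr(seq_len(n_decoys), function(d) {
    sp <- pair_pick[[n_blocks + d]]
    ra <- sample.int(genes_per_scaffold - max_gap, 1) - 1L
    rb <- sample.int(genes_per_scaffold - max_gap, 1) - 1L
    tibble::tibble(
      gene_a = c(gene_at(sp[1], ra),
                 gene_at(sp[1], ra + sample.int(max_gap, 1))),
      gene_b = c(gene_at(sp[2], rb),
                 gene_at(sp[2], rb + sample.int(max_gap, 1)))
    )
  })
  homologs <- dplyr::bind_rows(
    block_anchors[, c("gene_a", "gene_b")], tandem_pairs, decoy_pairs
  )
  homologs <- homologs[sample.int(nrow(homologs)), ]
  list(loci = loci, homologs = homologs,
       truth = list(block_anchors = block_anchors,
                    tandem_pairs = tandem_pairs,
                    decoy_pairs = decoy_pairs))
}

sample_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

instantiate_iupac <- function(pattern) {
  codes <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(codes, function(cd) {
    bases <- .iupac_bases[[cd]]
    bases[sample.int(length(bases), 1)]
  }, character(1)), collapse = "")
}

#' Simulate promoters with planted cis-elements
#'
#' Generates background promoter sequences by rejection sampling until they
#' contain zero chance matches to any catalog pattern (on either strand),
#' then inserts concrete instances of the requested elements at random
#' non-overlapping positions, re-checking after insertion that the scan
#' recovers exactly the planted occurrences. Planted counts are therefore
#' exact by construction.
#'
#' @param n_promoters Number of promoters.
#' @param planted Tibble with columns `gene_index`, `element_name`, `count`
#'   (occurrences of that element to plant in that promoter), or `NULL` for
#'   none.
#' @param catalog Element catalog (restrict it to long/rare patterns; short
#'   patterns make a match-free background infeasible).
#' @param length Promoter length (default 2000).
#' @param gc Background GC content (default 0.40).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap per promoter.
#' @return List with `promoters` (gene_id, sequence, truncated) and `truth`
#'   (gene_id, element_name, start, strand).
#' @export
simulate_promoters <- function(n_promoters, planted = NULL,
                               catalog = read_element_catalog(),
                               length = 2000L, gc = 0.40, seed = NULL,
                               max_tries = 200L) {
  restore <- local_seed(seed); on.exit(restore())
  gene_ids <- sprintf("gene%03d", seq_len(n_promoters))
  truth <- list()
  seqs <- character(n_promoters)
  for (i in seq_len(n_promoters)) {
    want <- if (is.null(planted)) NULL else planted[planted$gene_index == i, ]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      bg <- sample_dna(length, gc)
      prom <- tibble::tibble(gene_id = gene_ids[i], sequence = bg)
      if (nrow(scan_elements(prom, catalog)) > 0L) next
      if (is.null(want) || nrow(want) == 0L || sum(want$count) == 0L) {
        seqs[i] <- bg; ok <- TRUE; break
      }
      elements <- rep(want$element_name, want$count)
      widths <- nchar(catalog$iupac_pattern[match(elements, catalog$name)])
      # non-overlapping insertion positions
      pos <- plant_positions(length, widths)
      if (is.null(pos)) next
      seq_chars <- strsplit(bg, "")[[1]]
      rec <- tibble::tibble(gene_id = character(), element_name = character(),
                            start = integer(), strand = character())
      for (j in seq_along(elements)) {
        pat <- catalog$iupac_pattern[match(elements[j], catalog$name)]
        # a palindromic-consensus site is strand-symmetric; label it "+"
        strand <- if (iupac_palindromic(pat)) "+" else sample(c("+", "-"), 1)
        inst <- instantiate_iupac(pat)
        if (strand == "-") inst <- revcomp(inst)
        seq_chars[pos[j]:(pos[j] + widths[j] - 1L)] <- strsplit(inst, "")[[1]]
        rec <- dplyr::add_row(rec, gene_id = gene_ids[i],
                              element_name = elements[j],
                              start = pos[j], strand = strand)
      }
      cand <- paste(seq_chars, collapse = "")
      hits <- scan_elements(tibble::tibble(gene_id = gene_ids[i],
                                           sequence = cand), catalog)
      # exact recovery required: insertion must not create extra matches
      if (nrow(hits) == sum(want$count) &&
          all(sort(hits$start) == sort(rec$start))) {
        seqs[i] <- cand
        truth[[length(truth) + 1L]] <- rec
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not build a chance-match-free promoter within max_tries; ",
           "use a catalog of longer patterns or raise max_tries", call. = FALSE)
    }
  }
  list(
    promoters = tibble::tibble(gene_id = gene_ids, sequence = seqs,
                               truncated = FALSE),
    truth = if (length(truth)) dplyr::bind_rows(truth) else
      tibble::tibble(gene_id = character(), element_name = character(),
                     start = integer(), strand = character())
  )
}

# sample non-overlapping start positions for motifs of the given widths
plant_positions <- function(seq_len, widths, max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    pos <- vapply(widths, function(w) sample.int(seq_len - w + 1L, 1),
                  integer(1))
    ends <- pos + widths - 1L
    o <- order(pos)
    if (all(pos[o][-1] > ends[o][-length(o)] + 1L)) return(pos)
  }
  NULL
}

#' Simulate a replicate qRT-PCR Ct table with planted induction effects
#'
#' Target Ct values follow `baseline - log2(fold) + Normal(0, sd_ct)` per
#' replicate; the reference-gene Ct is constant. Genes listed in `effects`
#' are induced with the stated log2 fold change at every post-control
#' timepoint of the stated condition; all other gene x condition cells are
#' null (fold 1).
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param conditions Character vector of treatments (default the five
#'   standard stress/hormone treatments).
#' @param timepoints_h Numeric timepoints; the first is the control
#'   (default `c(0, 1, 6, 12)`).
#' @param n_replicates Replicates per cell (default 3).
#' @param effects Tibble with columns `gene_id`, `condition`, `log2fc`
#'   (planted effects), or `NULL` for an all-null table.
#' @param sd_ct Ct noise standard deviation (default 0.3).
#' @param baseline_ct,reference_ct Baseline target Ct and constant reference
#'   Ct.
#' @param seed Integer seed.
#' @return List with `ct_data` (a Ct table for [induction_calls()]) and
#'   `truth` (gene_id, condition, log2fc, induced).
#' @export
simulate_qpcr <- function(gene_ids,
                          conditions = c("drought", "salt", "heat", "cold", "ABA"),
                          timepoints_h = c(0, 1, 6, 12), n_replicates = 3L,
                          effects = NULL, sd_ct = 0.3,
                          baseline_ct = 26, reference_ct = 18, seed = NULL) {
  restore <- local_seed(seed); on.exit(restore())
  grid <- tidyr::expand_grid(
    gene_id = gene_ids, condition = conditions, timepoint_h = timepoints_h,
    replicate = seq_len(n_replicates)
  )
  key <- function(g, cond) paste(g, cond, sep = "\r")
  eff <- stats::setNames(numeric(0), character(0))
  if (!is.null(effects)) {
    assert_cols(effects, c("gene_id", "condition", "log2fc"), "effects")
    eff <- stats::setNames(effects$log2fc, key(effects$gene_id, effects$condition))
  }
  fc <- ifelse(grid$timepoint_h == timepoints_h[1], 0,
               dplyr::coalesce(eff[key(grid$gene_id, grid$condition)], 0))
  ct_data <- dplyr::mutate(grid,
    ct_target = baseline_ct - fc + stats::rnorm(nrow(grid), 0, sd_ct),
    ct_reference = reference_ct
  )
  truth <- tidyr::expand_grid(gene_id = gene_ids, condition = conditions) |>
    dplyr::mutate(
      log2fc = dplyr::coalesce(eff[key(.data$gene_id, .data$condition)], 0),
      induced = .data$log2fc >= 1
    )
  list(ct_data = ct_data, truth = truth)
}

#' Simulate proteins with planted Hsf domain geometry
#'
#' Builds synthetic proteins whose DBD/HR-A/B geometry encodes a chosen Hsf
#' class (A: long HR-A/B insertion; B: compact HR-A/B, long linker; C:
#' compact HR-A/B, short linker), with optional planted NLS, AHA, and RD
#' motifs. The background alphabet excludes the residues scored by the motif
#' scanners (K/R/W/F/D/E) so planted motifs are recovered exactly.
#'
#' @param classes Character vector over `c("A", "B", "C")`, one protein per
#'   entry.
#' @param seed Integer seed.
#' @return List with `proteins` (id, sequence, class_label), `domains`
#'   (id, dbd_start, dbd_end, hr_start, hr_end), and `truth` (planted motif
#'   spans).
#' @export
simulate_proteins <- function(classes, seed = NULL) {
  stopifnot(all(classes %in% c("A", "B", "C")))
  restore <- local_seed(seed); on.exit(restore())
  background <- c("G", "S", "T", "A", "P", "Q", "N", "H", "M", "V", "L", "I")
  bg <- function(n) paste(sample(background, n, replace = TRUE), collapse = "")
  out <- purrr::imap(classes, function(cl, i) {
    geom <- switch(cl,
      A = list(linker = 32L, hr_len = 48L),
      B = list(linker = 51L, hr_len = 29L),
      C = list(linker = 28L, hr_len = 27L))
    dbd_start <- 20L; dbd_len <- 94L
    dbd_end <- dbd_start + dbd_len - 1L
    hr_start <- dbd_end + geom$linker + 1L
    hr_end <- hr_start + geom$hr_len - 1L
    nls <- "NKKRRLKQ"
    tail_len <- 120L
    seq <- paste0(bg(dbd_start - 1L), bg(dbd_len), bg(geom$linker),
                  bg(geom$hr_len), bg(20L), nls, bg(tail_len))
    nls_start <- hr_end + 21L
    motifs <- tibble::tibble(kind = "NLS", start = nls_start,
                             end = nls_start + nchar(nls) - 1L)
    if (cl == "A") {
      aha <- "DVFWEQFLTE"
      aha_start <- nchar(seq) + 11L
      seq <- paste0(seq, bg(10L), aha, bg(20L))
      motifs <- dplyr::add_row(motifs, kind = "AHA", start = aha_start,
                               end = aha_start + nchar(aha) - 1L)
    }
    if (cl == "B") {
      rd_start <- nchar(seq) + 9L
      seq <- paste0(seq, bg(8L), "LFGV", bg(15L))
      motifs <- dplyr::add_row(motifs, kind = "RD", start = rd_start,
                               end = rd_start + 3L)
    }
    id <- sprintf("synthHsf%02d_%s", i, cl)
    list(
      protein = tibble::tibble(id = id, sequence = seq, class_label = cl),
      domains = tibble::tibble(id = id, dbd_start = dbd_start,
                               dbd_end = dbd_end, hr_start = hr_start,
                               hr_end = hr_end),
      truth = dplyr::mutate(motifs, id = id, .before = 1)
    )
  })
  list(
    proteins = purrr::map_dfr(out, "protein"),
    domains = purrr::map_dfr(out, "domains"),
    truth = purrr::map_dfr(out, "truth")
  )
}
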