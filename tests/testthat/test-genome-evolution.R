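# Intron phases, duplicated-block detection, duplication typing.

test_that("intron phases follow cumulative CDS length mod 3", {
  expect_equal(intron_phases(c(300, 150))$phase, "0")
  expect_equal(intron_phases(c(100, 200))$phase, "1")
  expect_equal(intron_phases(c(200, 100))$phase, "2")
  # UTR-only introns flagged, internal phases unaffected
  ph <- intron_phases(c(0, 100, 200, 0))
  expect_equal(ph$phase, c("UTR", "1", "UTR"))
  expect_equal(nrow(intron_phases(600)), 0L)
  expect_error(intron_phases(c(100, 150)), "divisible by 3")
  # two-exon genes whose first coding exon length is a multiple of 3 are all
  # phase 0 (the family-wide pattern for two-exon members)
  set.seed(41)
  for (i in 1:20) {
    e1 <- 3 * sample.int(300, 1)
    e2 <- 3 * sample.int(300, 1)
    expect_equal(intron_phases(c(e1, e2))$phase, "0")
  }
})

test_that("gene ranks are a per-scaffold permutation ordered by start", {
  loci <- tibble::tibble(
    id = c("g3", "g1", "g2", "h1", "h2"),
    scaffold = c("s1", "s1", "s1", "s2", "s2"),
    start = c(900, 100, 500, 50, 40)
  )
  r <- gene_ranks(loci)
  expect_equal(r$rank[match(c("g1", "g2", "g3"), r$id)], c(0L, 1L, 2L))
  expect_equal(r$rank[match(c("h2", "h1"), r$id)], c(0L, 1L))
})

make_layout <- function(ranks_a, ranks_b, n = 30) {
  loci <- tibble::tibble(
    id = c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n)),
    scaffold = rep(c("sA", "sB"), each = n),
    start = rep(seq(1, by = 2000, length.out = n), 2)
  )
  homologs <- tibble::tibble(
    gene_a = sprintf("a%02d", ranks_a + 1),
    gene_b = sprintf("b%02d", ranks_b + 1)
  )
  list(loci = gene_ranks(loci), homologs = homologs)
}

test_that("the 3-in-15 rule finds and rejects blocks as stated", {
  # three homolog pairs within the window on both scaffolds -> one block
  lay <- make_layout(c(2, 5, 9), c(3, 7, 11))
  blocks <- find_duplicated_blocks(lay$loci, lay$homologs)
  expect_equal(dplyr::n_distinct(blocks$block_id), 1L)
  expect_equal(nrow(blocks), 3L)
  # only two shared homologs -> no block
  lay2 <- make_layout(c(2, 5), c(3, 7))
  expect_equal(nrow(find_duplicated_blocks(lay2$loci, lay2$homologs)), 0L)
  # a 16-rank gap breaks the chain
  lay3 <- make_layout(c(0, 16, 20), c(0, 5, 9))
  expect_equal(nrow(find_duplicated_blocks(lay3$loci, lay3$homologs)), 0L)
  expect_error(find_duplicated_blocks(lay$loci,
                                      tibble::tibble(gene_a = "zz", gene_b = "a01")),
               "unknown gene")
})

test_that("block detection is order-invariant and matches the chain oracle", {
  set.seed(42)
  for (i in 1:15) {
    n_scaf <- sample(3:5, 1)
    genes_per <- sample(60:200, 1)
    loci <- purrr::map_dfr(seq_len(n_scaf), function(s) {
      tibble::tibble(
        id = sprintf("s%d_g%03d", s, seq_len(genes_per)),
        scaffold = sprintf("s%d", s),
        start = sort(sample.int(genes_per * 3000, genes_per))
      )
    }) |> gene_ranks()
    n_hom <- sample(10:40, 1)
    homologs <- tibble::tibble(
      gene_a = sample(loci$id, n_hom, replace = TRUE),
      gene_b = sample(loci$id, n_hom, replace = TRUE)
    ) |> dplyr::filter(gene_a != gene_b)
    got <- find_duplicated_blocks(loci, homologs)
    want <- oracle_blocks(loci, homologs)
    expect_equal(dplyr::n_distinct(got$block_id), length(want))
    expect_equal(nrow(got), sum(vapply(want, nrow, integer(1))))
    if (length(want) > 0) {
      got_sets <- lapply(split(got, got$block_id), function(b) {
        sort(paste(b$gene_a, b$gene_b))
      })
      want_sets <- lapply(want, function(b) sort(paste(b$gene_a, b$gene_b)))
      expect_setequal(got_sets, want_sets)
    }
    # input-order invariance
    shuffled <- homologs[sample.int(nrow(homologs)), ]
    expect_equal(find_duplicated_blocks(loci, shuffled), got)
    # reported blocks satisfy their own invariants
    if (nrow(got) > 0) {
      for (b in split(got, got$block_id)) {
        expect_gte(nrow(b), 3L)
        if (nrow(b) > 1) {
          expect_true(all(diff(b$rank_a) <= 15))
          expect_true(all(abs(diff(b$rank_b)) <= 15))
        }
      }
    }
  }
})

test_that("duplication typing partitions pairs into tandem/WGD/dispersed", {
  lay <- make_layout(c(2, 5, 9), c(3, 7, 11))
  blocks <- find_duplicated_blocks(lay$loci, lay$homologs)
  # adjacent same-scaffold pair -> tandem
  pairs <- tibble::tibble(
    gene_a = c("a01", "a03", "a01"),
    gene_b = c("a02", "b04", "b30")
  )
  calls <- classify_duplication(pairs, lay$loci, blocks)
  expect_equal(calls$dup_type, c("tandem", "WGD", "dispersed"))
  # same-scaffold pair far apart with no block support -> dispersed
  far <- classify_duplication(tibble::tibble(gene_a = "a01", gene_b = "a30"),
                              lay$loci, blocks)
  expect_equal(far$dup_type, "dispersed")
  expect_error(classify_duplication(tibble::tibble(gene_a = "a01", gene_b = "zz"),
                                    lay$loci, blocks), "unlocated")
})

test_that("planted layouts are recovered with full sensitivity and no false blocks", {
  for (seed in 1:5) {
    sim <- simulate_genome_layout(n_scaffolds = 8, genes_per_scaffold = 60,
                                  n_blocks = 2, anchors_per_block = 4,
                                  n_tandem = 2, n_decoys = 3, seed = seed)
    blocks <- find_duplicated_blocks(sim$loci, sim$homologs)
    expect_equal(dplyr::n_distinct(blocks$block_id), 2L)
    # every planted anchor is recovered inside a block
    planted <- paste(sim$truth$block_anchors$gene_a,
                     sim$truth$block_anchors$gene_b)
    expect_true(all(planted %in% paste(blocks$gene_a, blocks$gene_b) |
                      planted %in% paste(blocks$gene_b, blocks$gene_a)))
    # decoy 2-anchor chains yield no blocks (already covered by the count),
    # and typing matches the planted truth
    calls <- classify_duplication(
      dplyr::bind_rows(sim$truth$tandem_pairs,
                       sim$truth$block_anchors[, c("gene_a", "gene_b")]),
      sim$loci, blocks)
    expect_true(all(calls$dup_type[seq_len(nrow(sim$truth$tandem_pairs))] ==
                      "tandem"))
    expect_true(all(calls$dup_type[-seq_len(nrow(sim$truth$tandem_pairs))] ==
                      "WGD"))
  }
})
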