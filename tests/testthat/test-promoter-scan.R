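# Promoter extraction, IUPAC scanning, enrichment statistic.

test_that("promoter extraction respects strand and scaffold edges", {
  scaf <- paste(rep(c("A", "C", "G", "T"), length.out = 6000), collapse = "")
  p <- extract_promoter(scaf, tss = 5001, strand = "+")
  expect_equal(nchar(p$sequence), 2000L)
  expect_false(p$truncated)
  expect_equal(p$sequence, substring(scaf, 3001, 5000))
  # minus strand: reverse complement of the downstream 2 kb; extracting from
  # the reverse-complemented scaffold at the mirrored position must agree
  m <- extract_promoter(scaf, tss = 1000, strand = "-")
  rc_scaf <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(scaf)))
  m2 <- extract_promoter(rc_scaf, tss = 6000 - 1000 + 1, strand = "+")
  expect_equal(m$sequence, m2$sequence)
  # truncation at the scaffold edge
  t <- extract_promoter(scaf, tss = 900, strand = "+")
  expect_equal(nchar(t$sequence), 899L)
  expect_true(t$truncated)
  expect_error(extract_promoter(scaf, tss = 9000, strand = "+"), "off scaffold")
})

test_that("IUPAC scanning handles consensus, N, and both strands", {
  catalog <- tibble::tibble(name = "HSE", iupac_pattern = "AGAANNTTCT",
                            functional_class = "stress")
  prom <- tibble::tibble(gene_id = "g1",
                         sequence = paste0(strrep("C", 20), "AGAACCTTCT",
                                           strrep("C", 20)))
  hits <- scan_elements(prom, catalog, both_strands = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 21L)
  expect_equal(hits$matched_text, "AGAACCTTCT")
  # an all-N promoter never matches a constrained code
  n_prom <- tibble::tibble(gene_id = "g2", sequence = strrep("N", 100))
  expect_equal(nrow(scan_elements(n_prom, catalog)), 0L)
  # the HSE consensus is palindromic: a site is one occurrence, not two
  hits_pal <- scan_elements(prom, catalog, both_strands = TRUE)
  expect_equal(nrow(hits_pal), 1L)
  # reverse-strand occurrence of a non-palindromic element
  abre <- tibble::tibble(name = "ABRE", iupac_pattern = "ACGTG",
                         functional_class = "hormone")
  prom_rc <- tibble::tibble(gene_id = "g3",
                            sequence = paste0(strrep("C", 10), "CACGT",
                                              strrep("C", 10)))
  hits_rc <- scan_elements(prom_rc, abre, both_strands = TRUE)
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 11L)
  expect_error(scan_elements(prom, tibble::tibble(
    name = "bad", iupac_pattern = "AGXA", functional_class = "stress")),
    "IUPAC")
})

test_that("hit sets equal the brute-force sliding oracle on random promoters", {
  catalog <- read_element_catalog()
  set.seed(51)
  for (i in 1:40) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    got <- scan_elements(tibble::tibble(gene_id = "g", sequence = seq), catalog)
    for (j in seq_len(nrow(catalog))) {
      want <- oracle_scan_both(seq, catalog$iupac_pattern[j])
      sub <- got[got$element_name == catalog$name[j], ]
      expect_equal(sort(sub$start[sub$strand == "+"]), sort(want$fwd),
                   ignore_attr = TRUE)
      expect_equal(sort(sub$start[sub$strand == "-"]), sort(want$rev),
                   ignore_attr = TRUE)
    }
  }
})

test_that("scanning is mirror-equivalent under reverse complementation", {
  catalog <- read_element_catalog()
  set.seed(52)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h1 <- scan_elements(tibble::tibble(gene_id = "g", sequence = seq), catalog)
  h2 <- scan_elements(tibble::tibble(gene_id = "g", sequence = rc), catalog)
  # mirrored positions; strands swap except for palindromic-consensus
  # elements, whose sites are strand-symmetric
  pat <- catalog$iupac_pattern[match(h1$element_name, catalog$name)]
  k <- nchar(pat)
  pal <- vapply(pat, function(p) oracle_revcomp(p) == p, logical(1))
  mirrored <- sort(paste(h1$element_name, 1000 - (h1$start + k - 1) + 1,
                         ifelse(pal, h1$strand,
                                ifelse(h1$strand == "+", "-", "+"))))
  expect_equal(sort(paste(h2$element_name, h2$start, h2$strand)), mirrored)
})

test_that("overlapping matches of one pattern are all reported", {
  catalog <- tibble::tibble(name = "AA", iupac_pattern = "AA",
                            functional_class = "stress")
  hits <- scan_elements(tibble::tibble(gene_id = "g", sequence = "AAAA"),
                        catalog, both_strands = FALSE)
  expect_equal(hits$start, c(1L, 2L, 3L))
})

test_that("enrichment level is hits over genes with a hit", {
  # printed worked examples: 73/27 -> 2.7 and 37/12 -> 3.1
  hits73 <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:27), length.out = 73),
    element_name = "HSE"
  )
  s <- enrichment_level(hits73)
  expect_equal(s$n_genes_with_hit, 27L)
  expect_equal(s$n_total_hits, 73L)
  expect_equal(round(s$enrichment_level, 1), 2.7)
  hits37 <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:12), length.out = 37),
    element_name = "HSE"
  )
  expect_equal(round(enrichment_level(hits37)$enrichment_level, 1), 3.1)
  # one hit per gene -> exactly 1
  one <- enrichment_level(tibble::tibble(
    gene_id = sprintf("g%d", 1:5), element_name = "MBS"))
  expect_equal(one$enrichment_level, 1)
  # empty input -> empty summary (absent, not 0/0)
  expect_equal(nrow(enrichment_level(
    tibble::tibble(gene_id = character(), element_name = character()))), 0L)
})

test_that("planted promoter elements are recovered exactly", {
  catalog <- read_element_catalog()
  hse_only <- catalog[catalog$name == "HSE", ]
  planted <- tibble::tibble(gene_index = 1:6,
                            element_name = "HSE",
                            count = c(3L, 1L, 0L, 2L, 1L, 4L))
  sim <- simulate_promoters(6, planted = planted, catalog = hse_only,
                            length = 1500, seed = 8)
  hits <- scan_elements(sim$promoters, hse_only)
  expect_equal(nrow(hits), sum(planted$count))
  expect_equal(sort(paste(hits$gene_id, hits$start, hits$strand)),
               sort(paste(sim$truth$gene_id, sim$truth$start,
                          sim$truth$strand)))
  # planting zero yields zero
  sim0 <- simulate_promoters(3, planted = NULL, catalog = hse_only,
                             length = 1000, seed = 9)
  expect_equal(nrow(scan_elements(sim0$promoters, hse_only)), 0L)
})
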