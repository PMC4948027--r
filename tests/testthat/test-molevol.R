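# Nei-Gojobori engine, sliding windows, divergence dating.

test_that("per-codon site counts match neighbour enumeration", {
  expect_equal(ng86_sites("TTT")$s, 1 / 3)
  expect_equal(ng86_sites("ATG")$s, 0)
  expect_equal(ng86_sites("GGG")$s, 1)
  expect_error(ng86_sites("TAA"), "sense codon")
  tabs <- famevol:::codon_tables()
  for (cod in tabs$sense_codons) {
    expect_equal(ng86_sites(cod)$s, oracle_codon_sites(cod)[["s"]],
                 tolerance = 1e-12)
  }
})

test_that("worked single-difference example and basic invariants hold", {
  r <- kaks_pair("TTTGGGGGG", "TTCGGGGGG")
  expect_equal(r$Sd, 1); expect_equal(r$Nd, 0)
  expect_equal(r$S, 7 / 3, tolerance = 1e-12)
  expect_equal(r$pS, 3 / 7, tolerance = 1e-12)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, -0.75 * log(1 - 4 / 7), tolerance = 1e-12)
  # identical sequences: zero rates, undefined ratio
  same <- kaks_pair("ATGAAACCC", "ATGAAACCC")
  expect_equal(same$ka, 0); expect_equal(same$ks, 0)
  expect_true(is.na(same$ka_ks))
  # site conservation
  expect_equal(same$S + same$N, 9, tolerance = 1e-9)
})

test_that("estimator is symmetric and agrees with path-enumeration oracle", {
  set.seed(31)
  n_checked <- 0
  for (i in 1:60) {
    sim <- simulate_codon_pair(50, omega = runif(1, 0.1, 2),
                               ks_target = runif(1, 0.05, 0.5))
    r <- tryCatch(kaks_pair(sim$seq_a, sim$seq_b), error = function(e) NULL)
    if (is.null(r)) next
    n_checked <- n_checked + 1
    # symmetry
    r2 <- kaks_pair(sim$seq_b, sim$seq_a)
    expect_equal(r$S, r2$S, tolerance = 1e-12)
    expect_equal(r$Sd, r2$Sd, tolerance = 1e-12)
    expect_equal(r$Nd, r2$Nd, tolerance = 1e-12)
    # oracle agreement
    o <- oracle_kaks(sim$seq_a, sim$seq_b)
    expect_equal(r$S, o$S, tolerance = 1e-9)
    expect_equal(r$N, o$N, tolerance = 1e-9)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-9)
    expect_equal(r$ks, o$ks, tolerance = 1e-9)
    expect_equal(r$ka, o$ka, tolerance = 1e-9)
    # site conservation
    expect_equal(r$S + r$N, 150, tolerance = 1e-9)
  }
  expect_gt(n_checked, 40)
})

test_that("adding synonymous differences never decreases Ks", {
  # GGA -> GGG is synonymous at every codon
  base <- strrep("GGA", 30)
  prev_ks <- 0
  for (k in 1:10) {
    mutated <- paste0(strrep("GGG", k), strrep("GGA", 30 - k))
    ks_k <- kaks_pair(base, mutated)$ks
    expect_gte(ks_k, prev_ks)
    prev_ks <- ks_k
  }
})

test_that("gapped codon columns are dropped before counting", {
  r <- kaks_pair("TTTG--GGGAAAAAA", "TTCG--GGGAAAAAA")
  expect_equal(r$n_codons, 4L)
  expect_equal(r$Sd, 1)
  full <- kaks_pair("TTTGGGAAAAAA", "TTCGGGAAAAAA")
  expect_equal(r$S, full$S, tolerance = 1e-12)
})

test_that("saturated and invalid alignments are rejected", {
  expect_error(kaks_pair("ATGTAAAAA", "ATGTAAAAA"), "stop codon")
  expect_error(kaks_pair("ATGAA", "ATGAA"), "divisible by 3")
  expect_error(kaks_pair("ATGAAA", "ATG"), "equal length")
})

test_that("sliding windows tile the alignment and preserve counts", {
  set.seed(32)
  sim <- simulate_codon_pair(120, omega = 0.5, ks_target = 0.2)
  prof <- sliding_window_kaks(sim$seq_a, sim$seq_b, window_bp = 90, step_bp = 9)
  expect_s3_class(prof, "kaks_profile")
  expect_true(all(prof$start_bp %% 3 == 1))
  expect_equal(prof$end_bp - prof$start_bp + 1, rep(90L, nrow(prof)))
  # identical pair: all-zero windows
  prof0 <- sliding_window_kaks(sim$seq_a, sim$seq_a, window_bp = 90, step_bp = 9)
  expect_true(all(prof0$ka == 0 & prof0$ks == 0))
  expect_true(all(prof0$status == "undefined"))  # Ks = 0 ratio undefined
  # partition additivity: step = window recovers whole-alignment counts
  whole <- kaks_pair(sim$seq_a, sim$seq_b)
  parts <- lapply(seq(1, 360, by = 90), function(st) {
    kaks_pair(substring(sim$seq_a, st, st + 89), substring(sim$seq_b, st, st + 89))
  })
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "Sd")), whole$Sd,
               tolerance = 1e-9)
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "Nd")), whole$Nd,
               tolerance = 1e-9)
})

test_that("a planted positively selected segment lifts its windows above 1", {
  set.seed(33)
  backg <- simulate_codon_pair(90, omega = 0.1, ks_target = 0.45)
  hot <- simulate_codon_pair(40, omega = 3, ks_target = 0.45)
  tail <- simulate_codon_pair(90, omega = 0.1, ks_target = 0.45)
  seq_a <- paste0(backg$seq_a, hot$seq_a, tail$seq_a)
  seq_b <- paste0(backg$seq_b, hot$seq_b, tail$seq_b)
  prof <- sliding_window_kaks(seq_a, seq_b, window_bp = 90, step_bp = 9)
  ok <- prof[prof$status == "ok", ]
  best <- ok[which.max(ok$ka_ks), ]
  expect_gt(best$ka_ks, 1)
  # the max window overlaps the planted segment (bp 271..390)
  expect_true(best$start_bp <= 390 && best$end_bp >= 271)
})

test_that("divergence dating applies the synonymous clock", {
  expect_equal(round(divergence_time(0.343), 2), 18.85)
  expect_equal(round(divergence_time(0.253), 2), 13.90)
  expect_equal(divergence_time(0), 0)
  expect_error(divergence_time(-0.1), ">= 0")
  # default clock is the Populus rate
  expect_equal(divergence_time(0.2), 0.2 / (2 * 9.1e-9) / 1e6)
})

test_that("tidy and glance summarise a fit", {
  r <- kaks_pair("TTTGGGGGG", "TTCGGGGGG", id_a = "g1", id_b = "g2")
  td <- tidy(r)
  expect_equal(td$id_a, "g1")
  expect_equal(td$Sd, 1)
  gl <- glance(r)
  expect_equal(gl$selection, "purifying")
  tab <- kaks(tibble::tibble(id_a = "g1", id_b = "g2",
                             seq_a = "TTTGGGGGG", seq_b = "TTCGGGGGG"))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$ks, r$ks)
})
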