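# Independent brute-force oracles. These deliberately share no code with the
# package internals: straightforward loops and enumeration only.

oracle_genetic_code <- Biostrings::GENETIC_CODE

oracle_codon_sites <- function(codon) {
  nt <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(nt, chars[p])) {
      alt <- chars; alt[p] <- b
      alt <- paste(alt, collapse = "")
      if (oracle_genetic_code[[alt]] != "*" &&
          oracle_genetic_code[[alt]] == oracle_genetic_code[[codon]]) {
        s <- s + 1 / 3
      }
    }
  }
  c(s = s, n = 3 - s)
}

oracle_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  res <- list()
  for (i in seq_along(x)) {
    for (p in oracle_perms(x[-i])) res[[length(res) + 1]] <- c(x[i], p)
  }
  res
}

# per-codon-pair (sd, nd) by full path enumeration
oracle_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  walk <- function(order, skip_stops) {
    cur <- a; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (skip_stops && oracle_genetic_code[[to]] == "*") return(NULL)
      if (oracle_genetic_code[[from]] != "*" &&
          oracle_genetic_code[[to]] != "*" &&
          oracle_genetic_code[[from]] == oracle_genetic_code[[to]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- Filter(Negate(is.null), lapply(oracle_perms(pos), walk,
                                          skip_stops = TRUE))
  if (length(paths) == 0) {
    paths <- lapply(oracle_perms(pos), walk, skip_stops = FALSE)
  }
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

oracle_kaks <- function(seq_a, seq_b) {
  cods_a <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cods_b <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  S <- 0
  for (cod in cods_a) S <- S + oracle_codon_sites(cod)[["s"]] / 2
  for (cod in cods_b) S <- S + oracle_codon_sites(cod)[["s"]] / 2
  N <- 3 * length(cods_a) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(cods_a)) {
    d <- oracle_pair_diffs(cods_a[i], cods_b[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- Sd / S; pN <- Nd / N
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       ks = -(3 / 4) * log(1 - (4 / 3) * pS),
       ka = -(3 / 4) * log(1 - (4 / 3) * pN))
}

# position-by-position IUPAC matcher (N in sequence matches only pattern N)
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

oracle_scan_one_strand <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  k <- length(pc); n <- length(sc)
  hits <- integer()
  if (n < k) return(hits)
  for (st in 1:(n - k + 1)) {
    ok <- TRUE
    for (j in 1:k) {
      if (!(sc[st + j - 1] %in% oracle_iupac_sets[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, st)
  }
  hits
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# hits of `pattern` on both strands; minus-strand hits reported by their
# start on the forward sequence. Patterns identical to their own reverse
# complement describe one strand-symmetric site, so only forward hits count.
oracle_scan_both <- function(seq, pattern) {
  k <- nchar(pattern)
  fwd <- oracle_scan_one_strand(seq, pattern)
  if (oracle_revcomp(pattern) == pattern) {
    return(list(fwd = fwd, rev = integer()))
  }
  rev_on_rc <- oracle_scan_one_strand(oracle_revcomp(seq), pattern)
  rev_fwd_start <- sort(nchar(seq) - (rev_on_rc + k - 1) + 1)
  list(fwd = fwd, rev = rev_fwd_start)
}

# brute-force window scans for NLS/AHA rules
oracle_nls_windows <- function(seq, min_basic = 4, window = 8) {
  sc <- strsplit(seq, "")[[1]]
  n <- length(sc)
  starts <- integer()
  if (n < window) return(starts)
  for (st in 1:(n - window + 1)) {
    if (sum(sc[st:(st + window - 1)] %in% c("K", "R")) >= min_basic) {
      starts <- c(starts, st)
    }
  }
  starts
}

oracle_aha_windows <- function(seq, window = 10, min_acidic = 2) {
  sc <- strsplit(seq, "")[[1]]
  n <- length(sc)
  starts <- integer()
  if (n < window) return(starts)
  for (st in 1:(n - window + 1)) {
    win <- sc[st:(st + window - 1)]
    centre <- win[5]  # aromatic must sit at the centre slot (offset 4)
    if (centre %in% c("W", "F") &&
        sum(win %in% c("D", "E")) >= min_acidic) {
      starts <- c(starts, st)
    }
  }
  starts
}

merge_starts <- function(starts, window) {
  if (length(starts) == 0) return(data.frame(start = integer(), end = integer()))
  starts <- sort(unique(starts))
  ends <- starts + window - 1
  out <- data.frame(start = starts[1], end = ends[1])
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out$end[nrow(out)] + 1 - 1) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], ends[i])
    } else {
      out <- rbind(out, data.frame(start = starts[i], end = ends[i]))
    }
  }
  out
}

# independent chain scan for duplicated blocks
oracle_blocks <- function(loci, homologs, window = 15, min_anchors = 3) {
  rank_of <- setNames(loci$rank, loci$id)
  scaf_of <- setNames(loci$scaffold, loci$id)
  df <- data.frame(gene_a = homologs$gene_a, gene_b = homologs$gene_b,
                   stringsAsFactors = FALSE)
  flip <- scaf_of[df$gene_a] > scaf_of[df$gene_b]
  tmp <- df$gene_a[flip]; df$gene_a[flip] <- df$gene_b[flip]; df$gene_b[flip] <- tmp
  df$sa <- scaf_of[df$gene_a]; df$sb <- scaf_of[df$gene_b]
  df$ra <- rank_of[df$gene_a]; df$rb <- rank_of[df$gene_b]
  df <- unique(df)
  blocks <- list()
  for (key in unique(paste(df$sa, df$sb))) {
    sub <- df[paste(df$sa, df$sb) == key, ]
    sub <- sub[order(sub$ra, sub$rb), ]
    chain <- list(sub[1, ])
    flush <- function(chain) {
      if (length(chain) >= min_anchors) {
        blocks[[length(blocks) + 1]] <<- do.call(rbind, chain)
      }
    }
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        prev <- chain[[length(chain)]]
        if (sub$ra[i] - prev$ra <= window && abs(sub$rb[i] - prev$rb) <= window) {
          chain[[length(chain) + 1]] <- sub[i, ]
        } else {
          flush(chain)
          chain <- list(sub[i, ])
        }
      }
    }
    flush(chain)
  }
  blocks
}
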