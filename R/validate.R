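# Input validation helpers shared across modules.

assert_protein_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop(what, " must be a single non-empty amino-acid string", call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), .aa_alphabet)
  if (length(bad) > 0L) {
    stop(what, " contains non-canonical residues: ",
         paste(bad, collapse = ", "),
         " (only the 20 one-letter amino-acid codes are accepted)",
         call. = FALSE)
  }
  paste(chars, collapse = "")
}

assert_dna_seq <- function(seq, what = "sequence", allow_n = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop(what, " must be a single non-empty nucleotide string", call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  ok <- c("A", "C", "G", "T", if (allow_n) "N")
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0L) {
    stop(what, " contains invalid nucleotides: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste(chars, collapse = "")
}

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}
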