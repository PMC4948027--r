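# End-to-end orchestration: profile -> domains -> kaks/date -> dupscan ->
# promscan -> express, driven by one plain-text (YAML) config. Every stage
# is optional and runs only when its inputs are configured; a failing stage
# halts with a stage-named error and earlier outputs are preserved.

.pipeline_keys <- c(
  "out_dir", "seed", "lambda_rate", "window_bp", "step_bp",
  "synteny_window", "min_anchors", "tandem_max_intervening",
  "promoter_length", "catalog_tsv",
  "proteins_fasta", "domains_tsv", "pairs_tsv", "loci_tsv", "homologs_tsv",
  "promoters_fasta", "qpcr_tsv"
)

read_fasta_tibble <- function(path, col = "sequence") {
  x <- Biostrings::readBStringSet(path)
  out <- tibble::tibble(id = names(x))
  out[[col]] <- as.character(x)
  out
}

#' Run the full gene-family analysis pipeline
#'
#' Executes whichever stages have inputs configured and writes one TSV per
#' stage plus a JSON manifest (resolved parameters, input checksums, stage
#' outputs) into the output directory.
#'
#' Config keys: `out_dir`; inputs `proteins_fasta` (protein FASTA),
#' `domains_tsv` (id, dbd_start, dbd_end, hr_start, hr_end), `pairs_tsv`
#' (id_a, id_b, seq_a, seq_b codon alignments), `loci_tsv` (id, scaffold,
#' start, ...), `homologs_tsv` (gene_a, gene_b), `promoters_fasta`,
#' `qpcr_tsv` (gene_id, condition, timepoint_h, replicate, ct_target,
#' ct_reference); parameters `lambda_rate`, `window_bp`, `step_bp`,
#' `synteny_window`, `min_anchors`, `tandem_max_intervening`,
#' `promoter_length`, `catalog_tsv`, `seed`. Unknown keys are rejected.
#'
#' @param config Path to a YAML file or a named list.
#' @return (Invisibly) the manifest as a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$out_dir)) stop("config must set out_dir", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(
    lambda_rate = config$lambda_rate %||% 9.1e-9,
    window_bp = config$window_bp %||% 90L,
    step_bp = config$step_bp %||% 9L,
    synteny_window = config$synteny_window %||% 15L,
    min_anchors = config$min_anchors %||% 3L,
    tandem_max_intervening = config$tandem_max_intervening %||% 5L,
    promoter_length = config$promoter_length %||% 2000L,
    seed = config$seed %||% 1L
  )
  inputs <- config[intersect(names(config), c(
    "proteins_fasta", "domains_tsv", "pairs_tsv", "loci_tsv", "homologs_tsv",
    "promoters_fasta", "qpcr_tsv", "catalog_tsv"))]
  missing <- unlist(inputs)[!file.exists(unlist(inputs))]
  if (length(missing) > 0L) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  manifest <- list(
    package = "famevol",
    version = as.character(utils::packageVersion("famevol")),
    parameters = params,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    stages = list()
  )
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- res
  }
  write_stage_tsv <- function(df, file) {
    path <- file.path(out_dir, file)
    readr::write_tsv(df, path)
    path
  }
  read_tsv_ <- function(path) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }

  if (!is.null(config$proteins_fasta)) {
    run_stage("protein_profile", function() {
      prof <- protein_profile(read_fasta_tibble(config$proteins_fasta))
      list(output = write_stage_tsv(prof, "01_protein_profile.tsv"),
           n = nrow(prof))
    })
  }
  if (!is.null(config$domains_tsv)) {
    run_stage("hsf_classes", function() {
      cls <- classify_hsf(read_tsv_(config$domains_tsv))
      list(output = write_stage_tsv(cls, "02_hsf_classes.tsv"),
           n = nrow(cls))
    })
  }
  if (!is.null(config$proteins_fasta)) {
    run_stage("hsf_motifs", function() {
      motifs <- scan_hsf_motifs(read_fasta_tibble(config$proteins_fasta))
      list(output = write_stage_tsv(motifs, "03_hsf_motifs.tsv"),
           n = nrow(motifs))
    })
  }
  if (!is.null(config$pairs_tsv)) {
    run_stage("kaks", function() {
      res <- kaks(read_tsv_(config$pairs_tsv)) |>
        date_duplications(lambda_rate = params$lambda_rate)
      list(output = write_stage_tsv(res, "04_kaks.tsv"), n = nrow(res))
    })
  }
  if (!is.null(config$loci_tsv) && !is.null(config$homologs_tsv)) {
    run_stage("duplication_scan", function() {
      loci <- gene_ranks(read_tsv_(config$loci_tsv))
      homologs <- read_tsv_(config$homologs_tsv)
      blocks <- find_duplicated_blocks(loci, homologs,
                                       window = params$synteny_window,
                                       min_anchors = params$min_anchors)
      calls <- classify_duplication(
        homologs, loci, blocks,
        tandem_max_intervening = params$tandem_max_intervening,
        window = params$synteny_window)
      list(
        blocks = write_stage_tsv(blocks, "05_synteny_blocks.tsv"),
        calls = write_stage_tsv(calls, "06_duplication_calls.tsv"),
        n_blocks = dplyr::n_distinct(blocks$block_id), n_calls = nrow(calls))
    })
  }
  if (!is.null(config$promoters_fasta)) {
    run_stage("promoter_scan", function() {
      catalog <- read_element_catalog(config$catalog_tsv)
      proms <- read_fasta_tibble(config$promoters_fasta)
      names(proms)[1] <- "gene_id"
      hits <- scan_elements(proms, catalog)
      summ <- enrichment_level(hits)
      list(hits = write_stage_tsv(hits, "07_element_hits.tsv"),
           summary = write_stage_tsv(summ, "08_element_enrichment.tsv"),
           n_hits = nrow(hits))
    })
  }
  if (!is.null(config$qpcr_tsv)) {
    run_stage("expression", function() {
      calls <- induction_calls(read_tsv_(config$qpcr_tsv))
      counts <- count_induced(calls)
      list(calls = write_stage_tsv(calls, "09_induction_calls.tsv"),
           counts = write_stage_tsv(counts, "10_induced_counts.tsv"),
           n_calls = nrow(calls))
    })
  }
  manifest$config <- config
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
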