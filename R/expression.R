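# qRT-PCR analysis: 2^-ddCt relative expression, log2 fold changes vs the
# 0-h control, Student's t test, the induction criterion
# (P < 0.05 and log2FC >= 1), median-centred tissue profiles, and induced
# counts per treatment.

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target,ct_reference Numeric Ct values (target and internal
#'   reference gene), recycled to a common length.
#' @param calibrator_delta Delta-Ct (`ct_target - ct_reference`) of the
#'   calibrator sample (e.g. the 0-h control mean); default 0.
#' @return Numeric fold values `2^-((ct_target - ct_reference) - calibrator_delta)`.
#' @export
relative_expression <- function(ct_target, ct_reference, calibrator_delta = 0) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)) ||
      any(!is.finite(calibrator_delta))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  2^-((ct_target - ct_reference) - calibrator_delta)
}

# pooled-variance (or Welch) two-sample t test on log2 expression values,
# with a zero-variance shortcut
induction_t_test <- function(log2_treated, log2_control, var_equal = TRUE) {
  if (length(log2_treated) < 2L || length(log2_control) < 2L) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  log2fc <- mean(log2_treated) - mean(log2_control)
  if (stats::sd(log2_treated) == 0 && stats::sd(log2_control) == 0) {
    p <- if (log2fc == 0) 1 else 0
  } else {
    p <- stats::t.test(log2_treated, log2_control,
                       var.equal = var_equal)$p.value
  }
  list(log2fc = log2fc, p_value = p)
}

#' Call stress induction from replicate Ct tables
#'
#' For each gene x condition x post-control timepoint, compares replicate
#' log2 expression (`-(ct_target - ct_reference)`) against the 0-h control
#' of the same gene and condition with a Student's t test (pooled variance
#' by default) and calls the gene induced when `p_value < 0.05` and
#' `log2fc >= 1` (the fold-change boundary is inclusive, the significance
#' boundary is not).
#'
#' @param ct_data Data frame with columns `gene_id`, `condition`,
#'   `timepoint_h`, `replicate`, `ct_target`, `ct_reference`; the control is
#'   `timepoint_h == control_timepoint`.
#' @param control_timepoint Timepoint used as calibrator (default 0).
#' @param p_threshold,log2fc_threshold Induction criterion (defaults 0.05
#'   and 1).
#' @param var_equal Pooled-variance t test when `TRUE` (default); Welch
#'   otherwise.
#' @param adjust_p Multiple-testing correction passed to [stats::p.adjust()]
#'   applied across all calls; `"none"` (default) reports raw p values.
#' @return Tibble with `gene_id`, `condition`, `timepoint_h`, `log2fc`,
#'   `p_value`, `induced`.
#' @export
induction_calls <- function(ct_data, control_timepoint = 0,
                            p_threshold = 0.05, log2fc_threshold = 1,
                            var_equal = TRUE, adjust_p = "none") {
  assert_cols(ct_data, c("gene_id", "condition", "timepoint_h", "replicate",
                         "ct_target", "ct_reference"), "Ct table")
  if (any(!is.finite(ct_data$ct_target)) ||
      any(!is.finite(ct_data$ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  dat <- dplyr::mutate(ct_data,
                       log2_expr = -(.data$ct_target - .data$ct_reference))
  calls <- dat |>
    dplyr::group_by(.data$gene_id, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      ctrl <- df$log2_expr[df$timepoint_h == control_timepoint]
      if (length(ctrl) < 2L) {
        stop("need >= 2 control replicates for ", key$gene_id, " / ",
             key$condition, call. = FALSE)
      }
      tps <- sort(unique(df$timepoint_h[df$timepoint_h != control_timepoint]))
      purrr::map_dfr(tps, function(tp) {
        res <- induction_t_test(df$log2_expr[df$timepoint_h == tp], ctrl,
                                var_equal)
        tibble::tibble(timepoint_h = tp, log2fc = res$log2fc,
                       p_value = res$p_value)
      })
    }) |>
    dplyr::ungroup()
  calls$p_value <- stats::p.adjust(calls$p_value, method = adjust_p)
  dplyr::mutate(calls,
                induced = .data$p_value < p_threshold &
                  .data$log2fc >= log2fc_threshold)
}

#' Count induced genes per condition
#'
#' A gene counts as induced under a condition when it is induced at any
#' timepoint of that condition (set semantics: once per gene).
#'
#' @param calls Output of [induction_calls()].
#' @return Tibble with `condition`, `n_induced`.
#' @export
count_induced <- function(calls) {
  assert_cols(calls, c("gene_id", "condition", "induced"), "call table")
  calls |>
    dplyr::filter(.data$induced) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_induced = dplyr::n_distinct(.data$gene_id),
                     .groups = "drop")
}

#' Median-centred tissue expression profile
#'
#' Expresses per-tissue expression of a gene as log2 of the ratio to the
#' gene's median across tissues (an even tissue count uses the mean of the
#' two central values). The profile is invariant to multiplicative
#' rescaling.
#'
#' @param values Positive numeric vector of per-tissue expression
#'   (optionally named by tissue).
#' @return Tibble with `tissue` (names or index) and `log2_ratio`.
#' @export
tissue_profile <- function(values) {
  if (length(values) < 2L) stop("need >= 2 tissues", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("expression values must be positive and finite", call. = FALSE)
  }
  tissues <- if (is.null(names(values))) as.character(seq_along(values)) else names(values)
  tibble::tibble(tissue = tissues,
                 log2_ratio = log2(values / stats::median(values)))
}

#' Tissue profiles for an expression matrix
#'
#' @param data Data frame with columns `gene_id`, `tissue`, `expression`.
#' @return Tibble with `gene_id`, `tissue`, `log2_ratio`.
#' @export
tissue_profiles <- function(data) {
  assert_cols(data, c("gene_id", "tissue", "expression"), "expression table")
  data |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      tissue_profile(stats::setNames(df$expression, df$tissue))
    }) |>
    dplyr::ungroup()
}

#' Heatmap-style plot of induction log2 fold changes
#'
#' @param calls Output of [induction_calls()].
#' @return A ggplot object (genes x condition/timepoint tiles, log2FC fill).
#' @export
plot_induction <- function(calls) {
  assert_cols(calls, c("gene_id", "condition", "timepoint_h", "log2fc"),
              "call table")
  df <- dplyr::mutate(calls,
                      cell = paste0(.data$condition, " ", .data$timepoint_h, "h"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$gene_id,
                                   fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "black",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
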