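#' Per-gene fold changes and t-tests
#'
#' Computes, for every feature of a log2-scale expression table, the
#' group means, the log2 fold change on the control-over-case convention
#' (`log2_fc = mean_log2_control - mean_log2_case`, so a positive value
#' means lower expression in cases), the fold change `2^log2_fc` (a
#' ratio of geometric means of the intensities), a two-sided two-sample
#' t-test p-value, the direction (`"down"` = lower in cases), and an
#' informational Benjamini-Hochberg adjusted p-value.
#'
#' @param expr A log2-scale expression table.
#' @param design A case/control design covering the table's samples.
#' @param var_equal Use the pooled-variance Student t-test instead of
#'   the default Welch test.
#' @return A tibble with one row per feature: `gene_id`,
#'   `mean_log2_case`, `mean_log2_control`, `log2_fc`, `fold_change`,
#'   `t_pvalue`, `direction`, `padj_bh`.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 20), seed = 1)
#' de_table(floor_log2(sim$expr), sim$design)
#' @export
de_table <- function(expr, design, var_equal = FALSE) {
  if (!expr_is_log2(expr)) {
    abort("differential expression is computed on the log2 scale; call floor_log2() first")
  }
  design <- validate_design(design, expr)
  vals <- expr_matrix(expr)
  case_cols <- design$sample_id[design$group == "case"]
  ctrl_cols <- design$sample_id[design$group == "control"]
  case_m <- vals[, case_cols, drop = FALSE]
  ctrl_m <- vals[, ctrl_cols, drop = FALSE]
  mean_case <- rowMeans(case_m)
  mean_ctrl <- rowMeans(ctrl_m)
  pvals <- vapply(seq_len(nrow(vals)), function(i) {
    two_sample_t_pvalue(case_m[i, ], ctrl_m[i, ], var_equal = var_equal)
  }, numeric(1))
  log2_fc <- mean_ctrl - mean_case
  tibble::tibble(
    gene_id = rownames(vals),
    mean_log2_case = unname(mean_case),
    mean_log2_control = unname(mean_ctrl),
    log2_fc = unname(log2_fc),
    fold_change = 2^unname(log2_fc),
    t_pvalue = pvals,
    direction = ifelse(log2_fc > 0, "down", "up"),
    padj_bh = p.adjust(pvals, method = "BH")
  )
}

# two-sided two-sample t p-value with degenerate-variance handling:
# equal constants carry no evidence (p = 1); distinct constants are
# infinitely separated (p -> 0)
two_sample_t_pvalue <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    abort("t-test needs at least two values per group")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  t.test(x, y, var.equal = var_equal)$p.value
}

#' Screen a differential-expression table
#'
#' Applies the study's screening rule - at least `fc_min`-fold change in
#' either direction with a raw t-test p-value below `p_max` - to a
#' per-gene table as produced by [de_table()] (or a reference table with
#' compatible `fold_change`, `t_pvalue` and `direction` columns).  No
#' multiple-testing correction is applied in the screen; the fold-change
#' floor plays that role, and `padj_bh` from [de_table()] is carried
#' through for information only.
#'
#' Fold changes follow the control-over-case convention, so down-in-case
#' genes pass at `fold_change >= fc_min` and up-in-case genes at
#' `fold_change <= 1/fc_min`.
#'
#' @param de A per-gene tibble with columns `fold_change`, `t_pvalue`
#'   and `direction`.
#' @param fc_min Minimum fold change (default 2).
#' @param p_max Maximum raw t-test p-value (default 0.05).
#' @return The input with a logical `passes_screen` column, sorted by
#'   `t_pvalue` (ascending).
#' @examples
#' screened <- de_screen(pcd_de_table())
#' sum(screened$passes_screen & screened$direction == "down")  # 10
#' @export
de_screen <- function(de, fc_min = 2, p_max = 0.05) {
  stopifnot(all(c("fold_change", "t_pvalue", "direction") %in% names(de)))
  de |>
    dplyr::mutate(
      direction = tolower(.data$direction),
      passes_screen = (.data$fold_change >= fc_min |
                         .data$fold_change <= 1 / fc_min) &
        .data$t_pvalue < p_max
    ) |>
    dplyr::arrange(.data$t_pvalue)
}

#' Volcano plot of a differential-expression table
#'
#' @param de A tibble from [de_table()] or [de_screen()].
#' @param fc_min,p_max Screening thresholds drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_de_volcano <- function(de, fc_min = 2, p_max = 0.05) {
  stopifnot(all(c("log2_fc", "t_pvalue") %in% names(de)))
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$t_pvalue))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_max),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "log2 fold change (control / case)",
      y = expression(-log[10] ~ "t-test p-value")
    ) +
    ggplot2::theme_minimal()
}
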