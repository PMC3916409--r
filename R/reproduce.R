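#' Recompute every derivable quantity of the reference tables
#'
#' One-shot consistency report against the packaged reference results:
#' (a) every printed fold change must equal `2^(mean_log2_control -
#' mean_log2_case)` of its own row; (b) feeding the 37 printed per-gene
#' one-tailed Wilcoxon p-values into the unweighted Z-method must return
#' the four printed per-module combined p-values; (c) screening the
#' 24-gene PCD table at fold change >= 2 and p < 0.05 must flag exactly
#' 10 down-regulated genes.
#'
#' @param fc_tol Relative tolerance for the fold-change checks
#'   (default 1e-5).
#' @param comb_tol Relative tolerance for the combined-p checks
#'   (default 1e-4).
#' @return A tibble with one row per check: `check`, `observed`,
#'   `expected`, `rel_err`, `pass`.
#' @examples
#' rep <- reproduce_reference_analysis()
#' all(rep$pass)
#' @export
reproduce_reference_analysis <- function(fc_tol = 1e-5, comb_tol = 1e-4) {
  ciliary <- ciliary_de_table()
  pcd <- pcd_de_table()
  printed <- ciliary_combined_p()

  rel_err <- function(obs, exp) abs(obs - exp) / abs(exp)

  fc_checks <- dplyr::bind_rows(
    dplyr::transmute(ciliary, table = "ciliary", gene = .data$gene,
                     printed_fc = .data$fold_change,
                     recomputed = 2^(.data$mean_log2_control -
                                       .data$mean_log2_case)),
    dplyr::transmute(pcd, table = "pcd", gene = .data$gene,
                     printed_fc = .data$fold_change,
                     recomputed = 2^(.data$mean_log2_control -
                                       .data$mean_log2_case))
  ) |>
    dplyr::mutate(err = rel_err(.data$recomputed, .data$printed_fc))

  fc_rows <- fc_checks |>
    dplyr::group_by(.data$table) |>
    dplyr::summarise(observed = max(.data$err), .groups = "drop") |>
    dplyr::transmute(
      check = paste0("fold_change_max_rel_err_", .data$table),
      observed = .data$observed, expected = fc_tol,
      rel_err = NA_real_, pass = .data$observed < fc_tol
    )

  comb_rows <- ciliary |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(combine_pvalues_z(.data$wilcoxon_p), .groups = "drop") |>
    dplyr::left_join(printed, by = "category") |>
    dplyr::transmute(
      check = paste0("combined_p_", .data$category),
      observed = .data$p_combined.x, expected = .data$p_combined.y,
      rel_err = rel_err(.data$p_combined.x, .data$p_combined.y),
      pass = .data$rel_err < comb_tol
    )

  screened <- de_screen(pcd)
  n_down <- sum(screened$passes_screen & screened$direction == "down")
  screen_row <- tibble::tibble(
    check = "pcd_screen_n_down", observed = n_down, expected = 10,
    rel_err = NA_real_, pass = n_down == 10
  )

  dplyr::bind_rows(fc_rows, comb_rows, screen_row)
}
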