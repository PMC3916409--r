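#' Reference differential-expression tables
#'
#' Published per-gene results from a bronchial-biopsy expression study of
#' six PCD patients versus nine non-PCD controls, transcribed at full
#' printed precision.  They serve as ground truth for the arithmetic this
#' package implements and as ready-made inputs for the combination and
#' screening steps.
#'
#' `ciliary_de_table()` covers the 37 genes assigned to four axonemal
#' modules (ODA, IDA, radial spokes, IFT).  Columns: gene symbol (as
#' printed, with `alias` holding the current symbol where the printed one
#' is a legacy name), module `category`, group means of log2 expression
#' (`mean_log2_case` for PCD, `mean_log2_control`), `direction`
#' (all `"down"`: lower in cases), `log2_fc` and `fold_change` on the
#' control-over-case convention, the one-tailed Wilcoxon-Mann-Whitney
#' `wilcoxon_p` per gene, and a `multi_probe` flag for genes whose values
#' average several probes.
#'
#' `ciliary_combined_p()` returns the four published unweighted-Z
#' combined p-values, one per module.
#'
#' `pcd_de_table()` covers 24 PCD disease genes (22 stably expressed PCD
#' genes plus the syndromic genes RPGR and ODF1) with the probe shown,
#' group means, fold change and two-sided t-test p-value; `best_probe`
#' flags genes for which the most significant of several probes is shown.
#'
#' @return A tibble; see Details for columns.
#' @examples
#' tab <- ciliary_de_table()
#' dplyr::count(tab, category)
#' ciliary_combined_p()
#' @export
ciliary_de_table <- function() {
  path <- system.file("extdata", "ciliary_de_table.tsv", package = "ciliashift",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "cccddcdddl", progress = FALSE,
                  show_col_types = FALSE, na = "NA")
}

#' @rdname ciliary_de_table
#' @export
ciliary_combined_p <- function() {
  path <- system.file("extdata", "ciliary_combined_p.tsv", package = "ciliashift",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "cd", progress = FALSE,
                  show_col_types = FALSE)
}

#' @rdname ciliary_de_table
#' @export
pcd_de_table <- function() {
  path <- system.file("extdata", "pcd_de_table.tsv", package = "ciliashift",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "cccddcdddl", progress = FALSE,
                  show_col_types = FALSE, na = "NA")
}
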