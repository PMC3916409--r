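#' Floor low intensities and scale to log2
#'
#' Replicates the study's preprocessing of the analysed matrix: every
#' linear intensity below `threshold` is raised to `threshold`, then the
#' whole matrix is scaled by a base-2 logarithm.  The floor (default 5
#' intensity units) tames the noisy low-intensity tail of bead-array
#' data before ratios are formed.
#'
#' The operation is monotone in each value and idempotent on the linear
#' scale (re-flooring a floored matrix changes nothing); applying it to
#' an already log2-scaled table is an error.
#'
#' @param expr A linear-scale expression table ([as_expression_table()]).
#' @param threshold Positive intensity floor; values below it are raised
#'   to it before logging.  Default 5.
#' @return A log2-scale expression table.
#' @examples
#' m <- as_expression_table(
#'   data.frame(feature_id = "g1", s1 = 2, s2 = 5, s3 = 1024)
#' )
#' floor_log2(m)  # 2.321928, 2.321928, 10
#' @export
floor_log2 <- function(expr, threshold = 5) {
  if (expr_is_log2(expr)) {
    abort("expression table is already log2-scaled; refusing to log again")
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("'threshold' must be a single positive intensity")
  }
  vals <- expr_matrix(expr)
  vals <- log2(pmax(vals, threshold))
  expr_from_matrix(vals, log2 = TRUE)
}

#' Quantile-normalize an expression table
#'
#' Forces every sample onto a common distribution: each sample's sorted
#' values are replaced by the across-sample mean of sorted values, with
#' ties receiving the average of the reference values they span.  In the
#' study's own pipeline this step ran upstream (in the array vendor's
#' software, on the linear scale, before flooring); it is offered here as
#' optional plumbing for raw matrices that arrive unnormalized.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param expr An expression table with at least two samples.
#' @return The normalized expression table, same scale flag as the input.
#' @export
quantile_normalize <- function(expr) {
  vals <- expr_matrix(expr)
  if (ncol(vals) < 2) {
    warn("quantile normalization needs >= 2 samples; returning input unchanged")
    return(expr)
  }
  norm <- limma::normalizeQuantiles(vals, ties = TRUE)
  dimnames(norm) <- dimnames(vals)
  expr_from_matrix(norm, log2 = expr_is_log2(expr))
}

#' Aggregate probe rows to gene rows
#'
#' Genes represented by multiple probes are summarized by the per-sample
#' arithmetic mean of their probes' log2 values, matching how the
#' reference tables report multi-probe genes.  Probes absent from the
#' map are dropped (with a message giving the count); aggregation on the
#' linear scale is refused because all downstream statistics are defined
#' on log2 values.
#'
#' @param expr A log2-scale expression table whose rows are probes.
#' @param probe_map A tibble with columns `probe_id` and `gene_id`
#'   ([read_probe_map()]).
#' @return An expression table with one row per gene.
#' @export
aggregate_probes <- function(expr, probe_map) {
  if (!expr_is_log2(expr)) {
    abort("aggregate probes on the log2 scale; call floor_log2() first")
  }
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  keep <- expr$feature_id %in% probe_map$probe_id
  n_dropped <- sum(!keep)
  if (all(!keep)) {
    abort("no probe in the expression table is present in the probe map")
  }
  if (n_dropped > 0) {
    inform(paste0("dropping ", n_dropped, " unmapped probe(s)"))
  }
  long <- expr[keep, , drop = FALSE] |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "value") |>
    dplyr::left_join(probe_map, by = c(feature_id = "probe_id")) |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  wide <- tidyr::pivot_wider(long, names_from = "sample_id",
                             values_from = "value")
  names(wide)[1] <- "feature_id"
  # restore the sample order of the input
  wide <- wide[, c("feature_id", names(expr)[-1])]
  as_expression_table(wide, log2 = TRUE)
}
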