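#' Leave-one-out robustness over case samples
#'
#' Re-runs the gene-set shift tests (and a differential-expression
#' screen summary) once per dropped case sample, mirroring the study's
#' check that no single patient drives the coordinated down-regulation
#' signal.  Controls can optionally be dropped too.
#'
#' @param expr A log2-scale, gene-level expression table.
#' @param design A case/control design with at least two cases.
#' @param sets A tidy gene-set tibble.
#' @param drop Which group's samples to leave out: `"case"` (default,
#'   the study's check) or `"control"`.
#' @param fc_min,p_max Screening thresholds for the per-drop screen
#'   summary.
#' @param ... Passed to [set_shift_test()].
#' @return An object of class `loo_result`: list with `per_set`
#'   (dropped_sample x set combined results) and `screen` (per-drop
#'   down/up screen counts) tibbles.
#' @examples
#' sim <- simulate_expression(
#'   sim_config(n_genes = 30, affected_sets = list(list(name = "hit",
#'     size = 10, delta = 2))), seed = 7)
#' loo <- leave_one_out(floor_log2(sim$expr), sim$design, sim$sets)
#' stability_summary(loo)
#' @export
leave_one_out <- function(expr, design, sets, drop = c("case", "control"),
                          fc_min = 2, p_max = 0.05, ...) {
  drop <- match.arg(drop)
  design <- validate_design(design, expr)
  dropped_ids <- design$sample_id[design$group == drop]
  if (length(dropped_ids) < 2) {
    abort(paste0("need at least two ", drop,
                 " samples to leave one out"))
  }
  runs <- purrr::map(dropped_ids, function(s) {
    d <- design[design$sample_id != s, , drop = FALSE]
    fit <- set_shift_test(expr, d, sets, ...)
    screened <- de_screen(de_table(expr, d), fc_min = fc_min, p_max = p_max)
    list(
      per_set = dplyr::mutate(fit$per_set, dropped_sample = s,
                              .before = 1),
      screen = tibble::tibble(
        dropped_sample = s,
        n_down = sum(screened$passes_screen & screened$direction == "down"),
        n_up = sum(screened$passes_screen & screened$direction == "up")
      )
    )
  })
  structure(
    list(
      per_set = dplyr::bind_rows(purrr::map(runs, "per_set")),
      screen = dplyr::bind_rows(purrr::map(runs, "screen")),
      dropped_group = drop
    ),
    class = "loo_result"
  )
}

#' @export
print.loo_result <- function(x, ...) {
  cat("Leave-one-out re-analysis (dropped group:", x$dropped_group, ")\n\n")
  print(x$per_set)
  invisible(x)
}

#' @rdname tidy.set_shift_test
#' @method tidy loo_result
#' @export
tidy.loo_result <- function(x, ...) x$per_set

#' Summarize leave-one-out stability
#'
#' Per-set order statistics of the combined p-value across drops, with a
#' flag recording whether the set stayed significant at `alpha` in every
#' re-analysis - the operational meaning of "the result does not depend
#' on any single patient".
#'
#' @param loo A `loo_result` from [leave_one_out()], or its `per_set`
#'   tibble.
#' @param alpha Significance level for the all-drops flag (default
#'   0.01).
#' @return A tibble with one row per set: `n_drops`, `min_p`,
#'   `median_p`, `max_p`, `all_significant`.
#' @export
stability_summary <- function(loo, alpha = 0.01) {
  per_set <- if (inherits(loo, "loo_result")) loo$per_set else loo
  if (is.null(per_set) || nrow(per_set) == 0) {
    return(tibble::tibble(set_name = character(), n_drops = integer(),
                          min_p = double(), median_p = double(),
                          max_p = double(), all_significant = logical()))
  }
  per_set |>
    dplyr::group_by(.data$set_name) |>
    dplyr::summarise(
      n_drops = dplyr::n(),
      min_p = min(.data$p_combined),
      median_p = median(.data$p_combined),
      max_p = max(.data$p_combined),
      all_significant = all(.data$p_combined < alpha),
      .groups = "drop"
    )
}

#' @rdname autoplot.set_shift_test
#' @method autoplot loo_result
#' @export
autoplot.loo_result <- function(object, ...) {
  ggplot2::ggplot(object$per_set,
                  ggplot2::aes(x = .data$dropped_sample,
                               y = -log10(.data$p_combined),
                               group = .data$set_name,
                               colour = .data$set_name)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "dropped sample",
                  y = expression(-log[10] ~ "combined p"),
                  colour = "gene set") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
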