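#' One-tailed Wilcoxon-Mann-Whitney test
#'
#' Directional rank-sum test of a location shift between two independent
#' samples.  For small problems (total n at or below `exact_threshold`)
#' the p-value is exact: the null distribution of the case rank sum is
#' built over all choose(n1+n2, n1) equally likely group assignments by
#' dynamic programming over (doubled) midranks, which handles ties
#' without approximation.  Larger problems fall back to the normal
#' approximation with the usual tie correction and a 0.5 continuity
#' correction.
#'
#' `alternative = "case_less"` asks whether case values are
#' stochastically smaller than control values (the down-regulation
#' direction); the p-value is the null probability that the case rank
#' sum is at or below the observed one.  With every value identical the
#' test carries no evidence and returns 1 for either alternative.
#'
#' Because the rank-sum statistic is discrete (a 6-vs-9 comparison has
#' only 55 attainable values), the standard convention - include the
#' observed point in the tail - yields p-values that are stochastically
#' larger than uniform, which in turn makes the downstream Z-method
#' combination conservative.  `mid_p = TRUE` switches to the mid-p
#' convention (half the probability of the observed point), whose
#' inverse-normal deviate has exactly zero null mean and which restores
#' the combined test's nominal size; see [run_simulation_study()].
#'
#' @param case,control Numeric vectors of the two groups' values.
#' @param alternative `"case_less"` (default) or `"case_greater"`.
#' @param exact_threshold Largest total sample size for which the exact
#'   null distribution is enumerated (default 25; the 6-vs-9 study
#'   design is always exact).
#' @param mid_p Use the mid-p convention (default `FALSE`, the standard
#'   exact tail).  With every value tied, mid-p returns 0.5 rather
#'   than 1.
#' @return A single one-tailed p-value.
#' @examples
#' # all six case values below all nine controls: p = 1/choose(15, 6)
#' wilcoxon_one_tailed(1:6, 7:15, "case_less")
#' @export
wilcoxon_one_tailed <- function(case, control,
                                alternative = c("case_less", "case_greater"),
                                exact_threshold = 25, mid_p = FALSE) {
  alternative <- match.arg(alternative)
  case <- as.numeric(case)
  control <- as.numeric(control)
  if (length(case) == 0 || length(control) == 0) {
    abort("both groups must be non-empty")
  }
  if (anyNA(case) || anyNA(control)) abort("missing values are not allowed")
  n1 <- length(case)
  n <- n1 + length(control)
  r <- rank(c(case, control))
  w <- sum(r[seq_len(n1)])
  if (n <= exact_threshold) {
    # doubled midranks are integers, so the rank-sum support is a lattice
    dr <- as.integer(round(2 * r))
    dist <- ranksum_null_distribution(dr, n1)
    obs <- as.integer(round(2 * w))
    at_obs <- sum(dist$prob[dist$sum == obs])
    tail <- if (alternative == "case_less") {
      sum(dist$prob[dist$sum <= obs])
    } else {
      sum(dist$prob[dist$sum >= obs])
    }
    if (mid_p) tail - 0.5 * at_obs else tail
  } else {
    ranksum_normal_pvalue(w, r, n1, alternative, mid_p = mid_p)
  }
}

# cache of exact rank-sum null distributions keyed by the midrank
# multiset and group size; continuous data repeatedly hit the same key
.ranksum_cache <- new.env(parent = emptyenv())

# exact null distribution of the case rank sum (doubled midranks):
# dynamic programming over features, counting subsets of size n1 by
# their doubled-rank total
ranksum_null_distribution <- function(doubled_ranks, n1) {
  key <- paste(n1, paste(sort(doubled_ranks), collapse = ","), sep = "|")
  hit <- .ranksum_cache[[key]]
  if (!is.null(hit)) return(hit)
  total <- sum(doubled_ranks)
  # counts[k + 1, s + 1] = number of size-k subsets with doubled sum s
  counts <- matrix(0, nrow = n1 + 1, ncol = total + 1)
  counts[1, 1] <- 1
  for (dr in doubled_ranks) {
    for (k in seq(n1, 1)) {
      nz <- which(counts[k, ] > 0)
      if (length(nz) == 0) next
      counts[k + 1, nz + dr] <- counts[k + 1, nz + dr] + counts[k, nz]
    }
  }
  sums <- which(counts[n1 + 1, ] > 0) - 1L
  cnt <- counts[n1 + 1, sums + 1]
  dist <- list(sum = sums, prob = cnt / sum(cnt))
  .ranksum_cache[[key]] <- dist
  dist
}

# normal approximation with tie correction; the 0.5 continuity
# correction emulates the inclusive exact tail and is dropped for mid-p
ranksum_normal_pvalue <- function(w, r, n1, alternative, mid_p = FALSE) {
  n <- length(r)
  n2 <- n - n1
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  sd <- sqrt(sigma2)
  cc <- if (mid_p) 0 else 0.5
  if (alternative == "case_less") {
    pnorm((w - mu + cc) / sd)
  } else {
    pnorm((w - mu - cc) / sd, lower.tail = FALSE)
  }
}

#' Combine one-tailed p-values by the unweighted Z-method
#'
#' Stouffer's Z-transform: each one-tailed p-value p_i is converted to a
#' standard normal deviate Z_i = qnorm(1 - p_i); under the joint null of
#' k independent tests the statistic Z = sum(Z_i) / sqrt(k) is standard
#' normal, and the combined p-value is its upper-tail probability.
#' Values are clipped into `[clip, 1 - clip]` before the inverse-normal
#' transform to keep the deviates finite.
#'
#' The method assumes the combined tests are independent; correlated
#' tests (for example co-regulated genes in one set) inflate Z and make
#' the combined p anti-conservative.  [run_simulation_study()]
#' quantifies that sensitivity.
#'
#' @param p Numeric vector of one-tailed p-values (length k >= 1).
#' @param clip Clipping bound applied to each p before qnorm
#'   (default 1e-16).
#' @return A one-row tibble with `k`, `z_combined`, `p_combined`.
#' @examples
#' combine_pvalues_z(c(0.01, 0.02, 0.5))
#' @export
combine_pvalues_z <- function(p, clip = 1e-16) {
  if (length(p) < 1) abort("need at least one p-value to combine")
  if (anyNA(p) || !is.numeric(p)) abort("p-values must be numeric and non-missing")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p <- pmin(pmax(p, clip), 1 - clip)
  z <- qnorm(p, lower.tail = FALSE)
  z_combined <- sum(z) / sqrt(length(p))
  tibble::tibble(
    k = length(p),
    z_combined = z_combined,
    p_combined = pnorm(z_combined, lower.tail = FALSE)
  )
}

#' Test gene sets for coordinated down-regulation
#'
#' The package's central procedure: for every member of each gene set
#' present in the (gene-level, log2-scale) expression table, a one-tailed
#' Wilcoxon-Mann-Whitney test of the directional shift in cases is run
#' ([wilcoxon_one_tailed()]), and the per-gene p-values are combined
#' across the set with the unweighted Z-method ([combine_pvalues_z()]).
#' Set members absent from the table are dropped with a warning; a set
#' with no members present is an error.
#'
#' @param expr A log2-scale, gene-level expression table.
#' @param design A case/control design.
#' @param sets A tidy gene-set tibble (`set_name`, optional `category`,
#'   `gene_id`), e.g. from [read_gmt()] or [ciliary_gene_sets()].
#' @param alternative Direction of the per-gene tests; `"case_less"`
#'   (default) tests down-regulation in cases.
#' @param exact_threshold,mid_p,clip Passed to the per-gene test and
#'   the combiner; see [wilcoxon_one_tailed()] for the mid-p
#'   convention, which keeps the combined test calibrated under the
#'   discrete null.
#' @return An object of class `set_shift_test`: a list with `per_gene`
#'   (gene-level p-values and deviates) and `per_set` (k, z_combined,
#'   p_combined per set) tibbles.  Use [tidy.set_shift_test()] /
#'   [glance.set_shift_test()] or [autoplot.set_shift_test()].
#' @examples
#' sim <- simulate_expression(
#'   sim_config(n_genes = 40, affected_sets = list(list(name = "hit",
#'     size = 10, delta = 1.5))), seed = 42)
#' fit <- set_shift_test(floor_log2(sim$expr), sim$design, sim$sets)
#' glance(fit)
#' @export
set_shift_test <- function(expr, design, sets,
                           alternative = c("case_less", "case_greater"),
                           exact_threshold = 25, mid_p = FALSE,
                           clip = 1e-16) {
  alternative <- match.arg(alternative)
  if (!expr_is_log2(expr)) {
    abort("set tests run on the log2 scale; call floor_log2() first")
  }
  stopifnot(all(c("set_name", "gene_id") %in% names(sets)))
  design <- validate_design(design, expr)
  vals <- expr_matrix(expr)
  case_cols <- design$sample_id[design$group == "case"]
  ctrl_cols <- design$sample_id[design$group == "control"]

  if (!"category" %in% names(sets)) sets$category <- "other"
  missing <- dplyr::anti_join(sets, tibble::tibble(gene_id = rownames(vals)),
                              by = "gene_id")
  if (nrow(missing) > 0) {
    warn(paste0(nrow(missing), " set member(s) absent from the expression table: ",
                paste(head(missing$gene_id, 8), collapse = ", ")))
  }
  present <- dplyr::semi_join(sets, tibble::tibble(gene_id = rownames(vals)),
                              by = "gene_id")
  empty <- setdiff(unique(sets$set_name), unique(present$set_name))
  if (length(empty) > 0) {
    abort(paste0("no members present for set(s): ", paste(empty, collapse = ", ")))
  }

  per_gene <- present |>
    dplyr::mutate(
      p = vapply(.data$gene_id, function(g) {
        wilcoxon_one_tailed(vals[g, case_cols], vals[g, ctrl_cols],
                            alternative = alternative,
                            exact_threshold = exact_threshold,
                            mid_p = mid_p)
      }, numeric(1))
    ) |>
    dplyr::mutate(z = qnorm(pmin(pmax(.data$p, clip), 1 - clip),
                            lower.tail = FALSE))

  per_set <- per_gene |>
    dplyr::group_by(.data$set_name, .data$category) |>
    dplyr::summarise(combine_pvalues_z(.data$p, clip = clip),
                     .groups = "drop")

  structure(
    list(per_gene = per_gene, per_set = per_set, alternative = alternative),
    class = "set_shift_test"
  )
}

#' @export
print.set_shift_test <- function(x, ...) {
  cat("Gene-set directional shift test (one-tailed Wilcoxon + unweighted Z)\n")
  cat("alternative:", x$alternative, "\n\n")
  print(x$per_set)
  invisible(x)
}

#' Tidiers for set-shift tests
#'
#' `tidy()` returns the per-gene table (one row per tested gene with its
#' one-tailed p-value and normal deviate); `glance()` returns the
#' per-set summary (k, combined Z, combined p).
#'
#' @param x A `set_shift_test` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy set_shift_test
#' @export
tidy.set_shift_test <- function(x, ...) x$per_gene

#' @rdname tidy.set_shift_test
#' @method glance set_shift_test
#' @export
glance.set_shift_test <- function(x, ...) x$per_set

#' Plot a set-shift test
#'
#' Per-gene standard normal deviates by set, with each set's combined Z
#' marked; larger deviates mean stronger evidence for the tested
#' direction.
#'
#' @param object A `set_shift_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot set_shift_test
#' @export
autoplot.set_shift_test <- function(object, ...) {
  ggplot2::ggplot(object$per_gene,
                  ggplot2::aes(x = .data$set_name, y = .data$z)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    ggplot2::geom_point(data = object$per_set,
                        ggplot2::aes(y = .data$z_combined),
                        colour = "red", shape = 18, size = 3) +
    ggplot2::labs(x = NULL, y = "standard normal deviate",
                  caption = "red diamond: combined Z / sqrt(k)") +
    ggplot2::theme_minimal()
}

#' Exact binomial set-membership enrichment
#'
#' Upper-tail exact binomial test of whether a selected gene list
#' contains more members of a category (for example, ciliome genes among
#' down-regulated genes) than expected under a background proportion
#' `p0`: P(X >= n_in_set) with X ~ Binomial(n_selected, p0).
#'
#' @param n_selected Number of selected genes.
#' @param n_in_set How many of them belong to the category.
#' @param p0 Background proportion of category members among all genes
#'   (in (0, 1); e.g. 0.10 for an assumed 10% ciliary genome).
#' @return One-sided p-value.
#' @examples
#' binomial_set_enrichment(10, 10, 0.5)  # 2^-10
#' @export
binomial_set_enrichment <- function(n_selected, n_in_set, p0) {
  if (!is.numeric(p0) || length(p0) != 1 || p0 <= 0 || p0 >= 1) {
    abort("'p0' must lie strictly between 0 and 1")
  }
  if (n_in_set < 0 || n_in_set > n_selected) {
    abort("'n_in_set' must lie between 0 and 'n_selected'")
  }
  pbinom(n_in_set - 1, size = n_selected, prob = p0, lower.tail = FALSE)
}
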