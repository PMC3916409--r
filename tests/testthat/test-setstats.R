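test_that("exact one-tailed rank-sum p-values match closed-form cases", {
  # complete separation in a 3v3: one assignment in choose(6,3) = 20
  expect_equal(wilcoxon_one_tailed(1:3, 4:6, "case_less"), 1 / 20)
  # complete separation in the 6v9 study design: 1/choose(15,6) = 1/5005
  expect_equal(wilcoxon_one_tailed(1:6, 7:15, "case_less"), 1 / 5005)
  expect_equal(wilcoxon_one_tailed(7:15, 1:6, "case_greater"), 1 / 5005)
  # identical multisets carry no evidence of a shift
  expect_gte(wilcoxon_one_tailed(c(1, 2, 3), c(3, 1, 2), "case_less"), 0.5)
  # all values tied: p = 1 for either direction
  expect_equal(wilcoxon_one_tailed(rep(2, 4), rep(2, 5), "case_less"), 1)
  expect_equal(wilcoxon_one_tailed(rep(2, 4), rep(2, 5), "case_greater"), 1)
  expect_error(wilcoxon_one_tailed(numeric(0), 1:3), "non-empty")
})

test_that("exact rank-sum p-values agree with untied wilcox.test", {
  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1))
    y <- rnorm(sample(2:9, 1))
    expect_equal(
      wilcoxon_one_tailed(x, y, "case_less"),
      stats::wilcox.test(x, y, alternative = "less", exact = TRUE)$p.value
    )
  }
})

test_that("exact rank-sum p-values equal complete enumeration, ties included", {
  set.seed(52)
  cases <- list(
    list(x = c(1, 1, 2), y = c(2, 2, 3)),
    list(x = c(5, 5, 5, 5), y = c(5, 5, 6)),
    list(x = c(1, 2, 2, 3), y = c(2, 2, 2, 4, 4))
  )
  # add random tied configurations drawn from small value pools
  for (i in 1:25) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:(12 - n1), 1)
    pool <- sample(1:5, n1 + n2, replace = TRUE)
    cases[[length(cases) + 1]] <- list(x = pool[1:n1], y = pool[-(1:n1)])
  }
  for (cs in cases) {
    for (alt in c("case_less", "case_greater")) {
      expect_equal(wilcoxon_one_tailed(cs$x, cs$y, alt),
                   oracle_wilcoxon(cs$x, cs$y, alt),
                   info = paste(alt, paste(cs$x, collapse = ","), "|",
                                paste(cs$y, collapse = ",")))
    }
  }
})

test_that("mid-p values match the enumeration oracle's mid-p and average the two tails to one-half", {
  set.seed(59)
  for (i in 1:10) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:6, 1)
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    lt <- oracle_wilcoxon(x, y, "case_less")
    gt <- oracle_wilcoxon(x, y, "case_greater")
    # oracle mid-p: halve the mass of the observed configuration
    at_obs <- lt + gt - 1
    expect_equal(wilcoxon_one_tailed(x, y, "case_less", mid_p = TRUE),
                 lt - at_obs / 2)
    # mid-p tails are complementary: p_less + p_greater = 1 exactly
    expect_equal(wilcoxon_one_tailed(x, y, "case_less", mid_p = TRUE) +
                   wilcoxon_one_tailed(x, y, "case_greater", mid_p = TRUE), 1)
  }
  # all values tied: mid-p is the no-evidence midpoint
  expect_equal(wilcoxon_one_tailed(rep(1, 3), rep(1, 4), mid_p = TRUE), 0.5)
})

test_that("the two one-tailed p-values of a discrete test sum to at least 1", {
  set.seed(53)
  for (i in 1:15) {
    x <- sample(1:6, sample(2:5, 1), replace = TRUE)
    y <- sample(1:6, sample(2:6, 1), replace = TRUE)
    expect_gte(wilcoxon_one_tailed(x, y, "case_less") +
                 wilcoxon_one_tailed(x, y, "case_greater"), 1)
  }
})

test_that("the normal approximation tracks the exact test at moderate n", {
  set.seed(54)
  for (i in 1:10) {
    x <- rnorm(10)
    y <- rnorm(16, 0.3)
    exact <- wilcoxon_one_tailed(x, y, "case_less", exact_threshold = 26)
    approx <- wilcoxon_one_tailed(x, y, "case_less", exact_threshold = 10)
    expect_equal(approx, exact, tolerance = 0.02)
  }
})

test_that("unweighted Z-combination follows the Stouffer formula", {
  # a single p of 0.5 maps to z = 0 and combines to 0.5
  res <- combine_pvalues_z(0.5)
  expect_equal(res$z_combined, 0)
  expect_equal(res$p_combined, 0.5)

  # closed form for k copies of one p, and monotonicity in k for p < 0.5
  p0 <- 0.03
  prev <- 1
  for (k in 1:5) {
    res <- combine_pvalues_z(rep(p0, k))
    expect_equal(res$p_combined,
                 pnorm(sqrt(k) * qnorm(1 - p0), lower.tail = FALSE))
    expect_lt(res$p_combined, prev)
    prev <- res$p_combined
  }

  # permutation invariance
  p <- c(0.01, 0.2, 0.77, 0.004)
  expect_equal(combine_pvalues_z(p)$p_combined,
               combine_pvalues_z(rev(p))$p_combined)

  # extreme inputs survive clipping
  expect_true(is.finite(combine_pvalues_z(c(0, 1, 1e-300))$z_combined))
  expect_error(combine_pvalues_z(numeric(0)), "at least one")
  expect_error(combine_pvalues_z(c(0.1, 1.2)), "0, 1")
})

test_that("combining the printed per-gene p-values returns the printed module p-values", {
  ciliary <- ciliary_de_table()
  printed <- ciliary_combined_p()
  for (cat in printed$category) {
    obs <- combine_pvalues_z(ciliary$wilcoxon_p[ciliary$category == cat])
    expect_equal(obs$p_combined,
                 printed$p_combined[printed$category == cat],
                 tolerance = 1e-4)
  }
})

test_that("set tests combine per-gene Wilcoxon p-values over present members", {
  set.seed(55)
  m <- make_expr(matrix(rnorm(5 * 15, 8), nrow = 5))
  d <- design_6v9(names(m)[-1])
  sets <- tibble::tibble(set_name = "s1", gene_id = paste0("g", 1:5))
  fit <- set_shift_test(m, d, sets)
  expect_s3_class(fit, "set_shift_test")
  expect_equal(nrow(tidy(fit)), 5)
  manual <- combine_pvalues_z(tidy(fit)$p)
  expect_equal(glance(fit)$p_combined, manual$p_combined)

  # a single-gene set's combined p is that gene's Wilcoxon p
  single <- set_shift_test(m, d, tibble::tibble(set_name = "solo",
                                                gene_id = "g2"))
  gene_p <- wilcoxon_one_tailed(unlist(m[2, 2:7]), unlist(m[2, 8:16]))
  expect_equal(glance(single)$p_combined, gene_p)

  # absent members are dropped with a warning; fully absent sets error
  with_missing <- tibble::tibble(set_name = "s1",
                                 gene_id = c("g1", "g2", "ghost"))
  expect_warning(fit2 <- set_shift_test(m, d, with_missing), "ghost")
  expect_equal(glance(fit2)$k, 2)
  expect_error(
    suppressWarnings(
      set_shift_test(m, d, tibble::tibble(set_name = "none", gene_id = "nope"))
    ),
    "no members"
  )
})

test_that("set test on linear-scale input is refused", {
  m <- make_expr(matrix(1:30 + 10, nrow = 2), log2 = FALSE)
  d <- design_6v9(names(m)[-1])
  sets <- tibble::tibble(set_name = "s", gene_id = c("g1", "g2"))
  expect_error(set_shift_test(m, d, sets), "log2")
})

test_that("binomial set enrichment is an exact upper-tail binomial", {
  expect_equal(binomial_set_enrichment(10, 10, 0.5), 2^-10)
  expect_equal(binomial_set_enrichment(20, 0, 0.1), 1)
  # independent route: base binom.test on a moderate configuration
  expect_equal(binomial_set_enrichment(602, 61, 0.10),
               stats::binom.test(61, 602, 0.10, alternative = "greater")$p.value)
  expect_equal(binomial_set_enrichment(602, 61, 0.10), 0.4765315,
               tolerance = 1e-6)
  expect_error(binomial_set_enrichment(10, 11, 0.5), "between 0")
  expect_error(binomial_set_enrichment(10, 5, 0), "strictly between")
})
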