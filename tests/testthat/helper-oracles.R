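# Brute-force oracle for the one-tailed rank-sum test: enumerate all
# choose(n1+n2, n1) group assignments over the midranks and count how
# many give a case rank sum at least as extreme as the observed one.
# Integer arithmetic on doubled midranks avoids floating-point compares.
oracle_wilcoxon <- function(case, control, alternative = "case_less") {
  vals <- c(case, control)
  n1 <- length(case)
  dr <- as.integer(round(2 * rank(vals)))
  obs <- sum(dr[seq_len(n1)])
  sums <- utils::combn(length(vals), n1, FUN = function(idx) sum(dr[idx]))
  if (alternative == "case_less") mean(sums <= obs) else mean(sums >= obs)
}

# small expression table builder
make_expr <- function(values, log2 = TRUE, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  genes <- genes %||% paste0("g", seq_len(nrow(m)))
  samples <- samples %||% paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  df <- data.frame(feature_id = genes, m, check.names = FALSE)
  as_expression_table(df, log2 = log2)
}

# 6-case / 9-control design matching given sample names
design_6v9 <- function(samples) {
  group_design(samples, rep(c("case", "control"), c(6, 9)))
}

`%||%` <- rlang::`%||%`
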