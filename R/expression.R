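#' Expression tables
#'
#' An expression table is an ordinary tibble whose first column,
#' `feature_id`, holds unique probe or gene identifiers and whose remaining
#' columns hold one numeric vector of expression values per sample.  A
#' logical attribute `log2` records whether the values are on the log2
#' scale (`TRUE`) or are linear intensities (`FALSE`); the preprocessing
#' verbs maintain the flag and refuse to re-log already-logged data.
#'
#' `as_expression_table()` validates a data frame and stamps the scale
#' flag; `expr_is_log2()` reads it back.
#'
#' Invariants enforced here: unique feature identifiers, unique sample
#' names, an all-numeric body with no missing values, and non-negative
#' values whenever the table claims to be on the linear scale.
#'
#' @param x A data frame with identifier first column and numeric sample
#'   columns.
#' @param log2 Logical; are the values log2-scaled?
#' @return `as_expression_table()` returns a tibble with the `log2`
#'   attribute set; `expr_is_log2()` returns a logical scalar.
#' @examples
#' m <- as_expression_table(
#'   data.frame(feature_id = c("a", "b"), s1 = c(10, 5), s2 = c(20, 5))
#' )
#' expr_is_log2(m)
#' @export
as_expression_table <- function(x, log2 = FALSE) {
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("an expression table needs an identifier column and at least one sample column")
  }
  x <- tibble::as_tibble(x)
  names(x)[1] <- "feature_id"
  ids <- as.character(x$feature_id)
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(paste0("duplicated feature identifiers: ", paste(head(dups, 5), collapse = ", ")))
  }
  if (anyDuplicated(names(x))) {
    abort("duplicated sample names in the header")
  }
  body <- x[-1]
  bad <- names(body)[!vapply(body, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric sample column(s): ", paste(bad, collapse = ", ")))
  }
  vals <- as.matrix(body)
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(paste0("missing value at feature '", ids[idx[1]], "', sample '",
                 colnames(vals)[idx[2]], "'"))
  }
  if (!isTRUE(log2) && any(vals < 0)) {
    abort("linear-scale expression values must be non-negative")
  }
  x$feature_id <- ids
  attr(x, "log2") <- isTRUE(log2)
  x
}

#' @rdname as_expression_table
#' @export
expr_is_log2 <- function(x) {
  isTRUE(attr(x, "log2"))
}

# numeric matrix view (features x samples) of an expression table
expr_matrix <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$feature_id
  m
}

# rebuild an expression table from a matrix, keeping the scale flag
expr_from_matrix <- function(m, log2) {
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)), out)
  attr(out, "log2") <- isTRUE(log2)
  out
}

#' Read and write expression tables
#'
#' Expression values travel as TSV in GEO series-matrix style: feature
#' identifiers in the first column, one header field per sample, numeric
#' body.  The scale of the stored values is not recorded in the file, so
#' the reader takes an explicit `log2` flag.
#'
#' @param path Path to a tab-separated expression table.
#' @param log2 Logical; `TRUE` if the stored values are log2-scaled.
#' @param x An expression table (see [as_expression_table()]).
#' @return `read_expression_table()` returns a validated expression
#'   tibble; `write_expression_table()` returns `path` invisibly.
#' @export
read_expression_table <- function(path, log2 = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  bad <- names(raw)[-1][!vapply(raw[-1], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric cell(s) in column(s): ", paste(bad, collapse = ", ")))
  }
  as_expression_table(raw, log2 = log2)
}

#' @rdname read_expression_table
#' @export
write_expression_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Two-group sample designs
#'
#' A design is a tibble with columns `sample_id` and `group`, where
#' `group` is `"case"` or `"control"`.  The study design this package is
#' modelled on contrasts 6 PCD patients (cases) against 9 non-PCD
#' controls.
#'
#' @param sample_id Character vector of sample names.
#' @param group Character vector of `"case"`/`"control"` labels, one per
#'   sample.
#' @param path Path to a two-column TSV (`sample_id`, `group`).
#' @param design A design tibble.
#' @param expr Optionally, an expression table the design must cover.
#' @return A validated design tibble.
#' @export
group_design <- function(sample_id, group) {
  design <- tibble::tibble(sample_id = as.character(sample_id),
                           group = as.character(group))
  validate_design(design)
}

#' @rdname group_design
#' @export
read_group_design <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  design <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                            show_col_types = FALSE)
  names(design)[1:2] <- c("sample_id", "group")
  validate_design(design)
}

#' @rdname group_design
#' @export
validate_design <- function(design, expr = NULL) {
  if (!all(c("sample_id", "group") %in% names(design))) {
    abort("a design needs 'sample_id' and 'group' columns")
  }
  design$group <- tolower(design$group)
  bad <- setdiff(unique(design$group), c("case", "control"))
  if (length(bad) > 0) {
    abort(paste0("group labels must be 'case' or 'control', got: ",
                 paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) abort("duplicated sample_id in design")
  if (sum(design$group == "case") < 1 || sum(design$group == "control") < 1) {
    abort("need at least one case and one control sample")
  }
  if (!is.null(expr)) {
    missing <- setdiff(design$sample_id, names(expr)[-1])
    if (length(missing) > 0) {
      abort(paste0("design samples absent from the expression table: ",
                   paste(missing, collapse = ", ")))
    }
  }
  tibble::as_tibble(design)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV mapping each probe to exactly one gene; genes may own
#' several probes (the reference tables mark such genes explicitly).
#'
#' @param path Path to a two-column TSV (`probe_id`, `gene_id`).
#' @return A tibble with columns `probe_id` and `gene_id`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  map <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                         show_col_types = FALSE)
  names(map)[1:2] <- c("probe_id", "gene_id")
  if (anyDuplicated(map$probe_id)) {
    abort("a probe may map to exactly one gene; duplicated probe_id found")
  }
  tibble::as_tibble(map)
}
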