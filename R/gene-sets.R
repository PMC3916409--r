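#' Read and write GMT gene-set files
#'
#' Gene sets are kept tidy: one row per (set, gene) pair, with columns
#' `set_name`, `category` and `gene_id`.  The category is parsed from the
#' GMT description field when it matches one of the ultrastructural
#' labels used for axonemal modules (`ODA`, `IDA`, `radial_spoke`,
#' `IFT`); any other description yields `"other"`.
#'
#' @param path Path to a GMT file (set name, description, then
#'   tab-separated member genes).
#' @param sets A tidy gene-set tibble as returned by `read_gmt()`.
#' @param descriptions Optional named character vector of description
#'   fields to write, keyed by set name; defaults to the category.
#' @return `read_gmt()` returns a tibble with one row per set member;
#'   `write_gmt()` returns `path` invisibly.
#' @examples
#' gmt <- system.file("extdata", "ciliary_sets.gmt", package = "ciliashift")
#' sets <- read_gmt(gmt)
#' dplyr::count(sets, set_name)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(set_name = character(), category = character(),
                          gene_id = character()))
  }
  parsed <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(paste0("GMT line ", i, " has fewer than 3 fields"))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      abort(paste0("GMT line ", i, " ('", fields[1], "') has no members"))
    }
    tibble::tibble(set_name = fields[1],
                   category = parse_set_category(fields[2]),
                   gene_id = members)
  })
  dplyr::bind_rows(parsed)
}

set_category_levels <- c("ODA", "IDA", "radial_spoke", "IFT", "other")

parse_set_category <- function(description) {
  hit <- set_category_levels[match(tolower(trimws(description)),
                                   tolower(set_category_levels))]
  if (is.na(hit)) "other" else hit
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(all(c("set_name", "gene_id") %in% names(sets)))
  split_sets <- split(sets, factor(sets$set_name, levels = unique(sets$set_name)))
  lines <- vapply(split_sets, function(s) {
    desc <- if (!is.null(descriptions) && s$set_name[1] %in% names(descriptions)) {
      descriptions[[s$set_name[1]]]
    } else if ("category" %in% names(s)) {
      s$category[1]
    } else {
      s$set_name[1]
    }
    paste(c(s$set_name[1], desc, s$gene_id), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Packaged axonemal gene sets
#'
#' The four predefined ciliary modules tested for coordinated
#' down-regulation: 8 outer-dynein-arm (ODA) genes, 10 inner-dynein-arm
#' (IDA) genes, 8 radial-spoke genes and 11 intraflagellar-transport
#' (IFT) genes, 37 genes in all.  Symbols are kept as printed in the
#' reference tables (legacy aliases such as RSHL3 for RSPH4A are
#' recorded in the reference DE table, see [ciliary_de_table()]).
#'
#' @return A tidy gene-set tibble (`set_name`, `category`, `gene_id`).
#' @export
ciliary_gene_sets <- function() {
  read_gmt(system.file("extdata", "ciliary_sets.gmt", package = "ciliashift",
                       mustWork = TRUE))
}
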