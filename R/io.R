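#' Read a gene-by-cell APA score matrix
#'
#' Reads a tab-separated matrix of per-cell 3'UTR-length-change scores.
#' The first column holds gene ids, the header row holds cell ids, and an
#' empty field encodes a missing estimate (genes for which the APA caller
#' produced no value in that cell). Two dialects are supported:
#' `"dapars"` stores delta-PDUI values in \[-1, 1\] (negative = 3'UTR
#' shortening), `"roar"` stores strictly positive ratio-of-ratio values
#' (> 1 = shortening).
#'
#' @param path Path to a TSV file.
#' @param dialect `"dapars"` or `"roar"`; controls range validation and how
#'   [orient_shortening()] later converts values to a shortening score.
#' @return A tibble with column `gene` followed by one numeric column per
#'   cell, with attribute `dialect`.
#' @seealso [read_expression_matrix()], [write_matrix_tsv()]
#' @export
read_apa_matrix <- function(path, dialect = c("dapars", "roar")) {
  dialect <- match.arg(dialect)
  tbl <- read_wide_tsv(path, id_col = "gene")
  m <- as_score_matrix(tbl, what = "APA matrix")
  validate_apa_values(m, dialect, where = path)
  attr(tbl, "dialect") <- dialect
  tbl
}

#' Read a gene-by-cell TPM expression matrix
#'
#' Same layout as [read_apa_matrix()] but values are transcripts per million:
#' non-negative with no missing entries allowed.
#'
#' @inheritParams read_apa_matrix
#' @return A tibble with column `gene` followed by one numeric column per cell.
#' @export
read_expression_matrix <- function(path) {
  tbl <- read_wide_tsv(path, id_col = "gene")
  m <- as_score_matrix(tbl, what = "expression matrix")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("expression matrix %s: missing value at gene '%s', cell '%s'",
                  path, rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("expression matrix %s: negative TPM at gene '%s', cell '%s'",
                  path, rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  tbl
}

validate_apa_values <- function(m, dialect, where = "input") {
  bad <- if (dialect == "dapars") {
    which(!is.na(m) & (m < -1 | m > 1), arr.ind = TRUE)
  } else {
    which(!is.na(m) & m <= 0, arr.ind = TRUE)
  }
  if (nrow(bad) > 0) {
    abort(sprintf(
      "%s: %s value out of range at gene '%s', cell '%s' (%s)",
      where, dialect, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
      if (dialect == "dapars") "delta-PDUI must lie in [-1, 1]"
      else "roar ratios must be > 0"))
  }
  invisible(m)
}

read_wide_tsv <- function(path, id_col) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    !!rlang::sym(id_col) := readr::col_character()
  ), progress = FALSE, name_repair = "minimal")
  if (ncol(tbl) < 2 || names(tbl)[1] != id_col) {
    abort(sprintf("%s: malformed header; expected first column '%s' then cell ids",
                  path, id_col))
  }
  tbl
}

#' Write a gene-by-cell matrix as TSV
#'
#' Inverse of the matrix readers: UTF-8, Unix newlines, no quoting, missing
#' values written as empty fields so a write/read cycle is lossless.
#'
#' @param tbl Wide tibble (id column first) as returned by the readers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path, na = "", quote = "none", eol = "\n",
                   progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' MSigDB interchange format: one set per line, tab-separated fields
#' `set id`, `description`, then member gene ids. Duplicate members within
#' a set are dropped with a warning. An empty file yields an empty
#' collection.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set`, `description` and list-column
#'   `genes`, preserving file order.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(set = character(), description = character(),
                  genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("%s: line %d has fewer than 3 tab-separated fields",
                  path, short[1]))
  }
  sets <- purrr::map_chr(fields, 1)
  if (anyDuplicated(sets)) {
    abort(sprintf("%s: duplicate set id '%s'", path, sets[duplicated(sets)][1]))
  }
  genes <- purrr::map(fields, ~ .x[-(1:2)])
  dup <- purrr::map_lgl(genes, ~ anyDuplicated(.x) > 0)
  if (any(dup)) {
    warn(sprintf("deduplicated member genes in %d set(s): %s",
                 sum(dup), paste(utils::head(sets[dup], 5), collapse = ", ")))
    genes <- purrr::map(genes, unique)
  }
  tibble(set = sets, description = purrr::map_chr(fields, 2), genes = genes)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Gene-set tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  sets <- gene_set_list(gene_sets)
  desc <- if (is.data.frame(gene_sets) && "description" %in% names(gene_sets)) {
    gene_sets$description
  } else {
    rep("na", length(sets))
  }
  lines <- purrr::map_chr(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a GO term-to-parent table
#'
#' Two-column TSV (`term`, `parent`), several rows per term. Duplicated
#' rows are collapsed; a term absent from the table is treated downstream
#' as having no parents (its Jaccard similarity with anything is 0).
#'
#' @param path Path to a TSV file with header `term`, `parent`.
#' @return A tibble with character columns `term` and `parent`, one row per
#'   distinct (term, parent) pair.
#' @export
read_parent_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("term", "parent") %in% names(tbl))) {
    abort(sprintf("%s: expected columns 'term' and 'parent'", path))
  }
  dplyr::distinct(tbl, .data$term, .data$parent)
}

#' Read a per-cell annotation table
#'
#' @param path TSV with columns `cell`, `patient`, `cell_type` and
#'   optionally `tumor_type`.
#' @return A tibble with one row per cell.
#' @export
read_cell_annotation <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_annotation(tbl)
}

validate_annotation <- function(tbl) {
  need <- c("cell", "patient", "cell_type")
  if (!all(need %in% names(tbl))) {
    abort(paste0("cell annotation needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tbl$cell)) abort("cell annotation has duplicated cell ids")
  as_tibble(tbl)
}

#' Read a patient survival table
#'
#' @param path TSV with columns `patient`, `time` (years since diagnosis),
#'   `event` (1 = death, 0 = censored) and any number of covariate columns.
#' @return A tibble, one row per patient.
#' @export
read_survival_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    patient = "c", time = "d", event = "i", .default = "?"
  ), progress = FALSE)
  if (!all(c("patient", "time", "event") %in% names(tbl))) {
    abort(sprintf("%s: expected columns 'patient', 'time', 'event'", path))
  }
  if (any(tbl$time < 0, na.rm = TRUE)) abort("survival times must be >= 0")
  if (!all(tbl$event %in% c(0L, 1L))) abort("event must be 0/1")
  tbl
}
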