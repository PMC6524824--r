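#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Wide score table (first column = feature ids, remaining columns = cells)
# -> numeric matrix with feature rownames. All downstream statistics run on
# the matrix; user-facing functions take and return tibbles.
as_score_matrix <- function(tbl, what = "matrix") {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    abort(paste0(what, " must be a data frame with an id column plus >= 1 cell column"))
  }
  ids <- as.character(tbl[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate ids in ", what, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(paste0(what, " has non-numeric value columns"))
  if (anyDuplicated(colnames(m))) {
    abort(paste0("duplicate cell ids in ", what))
  }
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

score_tbl <- function(m, id_col = "gene") {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(!!id_col := rownames(m)), out)
}

id_col_name <- function(tbl) names(tbl)[1]

# Gene-set collection: tibble(set, description, genes = list of character)
# or a named list of character vectors. Returns the named-list form.
gene_set_list <- function(gene_sets) {
  if (is.data.frame(gene_sets)) {
    if (!all(c("set", "genes") %in% names(gene_sets))) {
      abort("gene set table must have columns 'set' and 'genes'")
    }
    sets <- gene_sets$genes
    names(sets) <- gene_sets$set
  } else if (is.list(gene_sets)) {
    sets <- gene_sets
  } else {
    abort("gene_sets must be a gene-set tibble or a named list")
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("gene set ids must be unique and non-missing")
  }
  if (any(lengths(sets) == 0)) abort("gene sets must be non-empty")
  lapply(sets, as.character)
}

check_fraction <- function(x, name, allow_zero = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || !lo_ok || x > 1) {
    abort(sprintf("%s must be a single value in %s0, 1]", name,
                  if (allow_zero) "[" else "("))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("%s must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
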