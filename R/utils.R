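# shared internal helpers

# embedding tables are tibbles: column `id` then v1..vD numeric columns
embedding_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), "id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "id")])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$id
  m
}

as_embedding_tbl <- function(ids, values, source) {
  values <- as.matrix(values)
  colnames(values) <- paste0("v", seq_len(ncol(values)))
  out <- dplyr::bind_cols(tibble(id = as.character(ids)), as_tibble(values))
  attr(out, "embedding_source") <- source
  out
}

#' Provenance tag of an embedding table
#'
#' Embedding tables produced by this package carry a tag recording how their
#' features were derived: `"contact_map"`, `"spike2vec"`, `"external"` or
#' `"fused"`.
#'
#' @param x An embedding table (tibble with `id` and `v1..vD` columns).
#' @return A character scalar, or `NA` for tables built elsewhere.
#' @export
embedding_source <- function(x) {
  attr(x, "embedding_source") %||% NA_character_
}

check_embedding_tbl <- function(tbl, arg = "embeddings") {
  if (!is.data.frame(tbl) || !"id" %in% names(tbl) || ncol(tbl) < 2) {
    abort(sprintf("`%s` must be a data frame with an `id` column and at least one feature column", arg))
  }
  if (anyDuplicated(tbl$id)) {
    abort(sprintf("duplicate ids in `%s`: %s", arg,
                  paste(unique(tbl$id[duplicated(tbl$id)]), collapse = ", ")))
  }
  m <- embedding_matrix(tbl)
  if (!all(is.finite(m))) abort(sprintf("non-finite values in `%s`", arg))
  invisible(tbl)
}

# deterministic local RNG: runs code under a seed without disturbing the
# caller's RNG stream; seed = NULL leaves the stream alone
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
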