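#' Fuse embeddings by concatenation
#'
#' Concatenates per-protein feature vectors from several embedding tables,
#' in the order given, into a single fused vector per protein. All tables
#' must cover exactly the same identifiers; the fused length is the sum of
#' the part lengths.
#'
#' @param ... Embedding tables (`id, v1..vD` tibbles), or a single list of
#'   them.
#' @return A tibble `id, v1..vD` tagged with source `"fused"`, in the id
#'   order of the first table. A single input table is returned unchanged
#'   apart from the tag.
#' @examples
#' a <- tibble::tibble(id = c("p1", "p2"), v1 = c(1, 2), v2 = c(3, 4))
#' b <- tibble::tibble(id = c("p2", "p1"), v1 = c(9, 8))
#' fuse_embeddings(a, b)  # length 3, aligned on id
#' @export
fuse_embeddings <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  if (length(parts) == 0L) abort("no embedding tables to fuse")
  for (i in seq_along(parts)) check_embedding_tbl(parts[[i]], sprintf("part %d", i))
  ids <- parts[[1]]$id
  for (i in seq_along(parts)[-1]) {
    extra <- setdiff(parts[[i]]$id, ids)
    missing_ids <- setdiff(ids, parts[[i]]$id)
    if (length(extra) || length(missing_ids)) {
      abort(sprintf(
        "id mismatch between part 1 and part %d: missing {%s}, unexpected {%s}",
        i, paste(missing_ids, collapse = ", "), paste(extra, collapse = ", ")))
    }
  }
  mats <- lapply(parts, function(p) embedding_matrix(p)[ids, , drop = FALSE])
  as_embedding_tbl(ids, do.call(cbind, mats), "fused")
}
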