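# 20 standard amino acids plus 'X' for unknown/non-standard residues
PROTEIN_ALPHABET <- "ACDEFGHIKLMNPQRSTVWXY"

#' k-mer vocabulary over an amino-acid alphabet
#'
#' Enumerates all `|alphabet|^k` k-mers in lexicographic order (the order of
#' the alphabet string), defining the column order of k-mer count vectors.
#' With the default 21-letter alphabet and `k = 3` the vocabulary has
#' `21^3 = 9261` entries.
#'
#' @param alphabet String of distinct characters (default the 20 standard
#'   amino acids plus `X`).
#' @param k k-mer length (default 3).
#' @return An object of class `kmer_vocab`: list with `alphabet`, `k`, and
#'   `kmers` (character vector; the index of a k-mer is its position).
#' @examples
#' kmer_vocabulary("AC", k = 2)$kmers  # "AA" "AC" "CA" "CC"
#' @export
kmer_vocabulary <- function(alphabet = PROTEIN_ALPHABET, k = 3) {
  stopifnot(is.character(alphabet), length(alphabet) == 1L, nzchar(alphabet),
            k >= 1, k == as.integer(k))
  chars <- strsplit(alphabet, "")[[1]]
  if (anyDuplicated(chars)) abort("duplicate characters in `alphabet`")
  kmers <- chars
  if (k > 1) {
    for (i in 2:k) kmers <- as.vector(t(outer(kmers, chars, paste0)))
  }
  structure(list(alphabet = alphabet, k = as.integer(k), kmers = kmers),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab> |alphabet| = %d, k = %d, size = %d\n",
              nchar(x$alphabet), x$k, length(x$kmers)))
  invisible(x)
}

#' k-mer count vector of one sequence (Spike2Vec)
#'
#' Slides a window of length `k` over the sequence and counts occurrences of
#' every vocabulary k-mer, yielding a vector of length `|alphabet|^k`.
#' Windows containing a character outside the alphabet are skipped;
#' sequences shorter than `k` yield the zero vector. For a sequence of
#' length `L` fully over the alphabet the counts sum to `L - k + 1`.
#'
#' @param sequence A single protein sequence string.
#' @param vocab A [kmer_vocabulary()]; built from `k`/`alphabet` if omitted.
#' @param k,alphabet Used only when `vocab` is missing.
#' @param normalize Divide counts by the number of valid windows
#'   (default `FALSE`: raw counts).
#' @return Numeric vector of length `length(vocab$kmers)`.
#' @examples
#' v <- spike2vec("ACDE", kmer_vocabulary(k = 3))
#' sum(v)  # 2 windows: ACD, CDE
#' @export
spike2vec <- function(sequence, vocab = NULL, k = 3, alphabet = PROTEIN_ALPHABET,
                      normalize = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  vocab <- vocab %||% kmer_vocabulary(alphabet, k)
  stopifnot(inherits(vocab, "kmer_vocab"))
  k <- vocab$k
  chars <- strsplit(vocab$alphabet, "")[[1]]
  S <- length(chars)
  size <- S^k
  codes <- match(strsplit(sequence, "")[[1]], chars)  # NA = out-of-alphabet
  L <- length(codes)
  if (L < k) return(numeric(size))
  # embed() row i is codes[i+k-1], ..., codes[i]; weight accordingly
  windows <- stats::embed(codes, k)
  idx <- as.vector(windows %*% S^(0:(k - 1))) - sum(S^(0:(k - 1))) + 1
  idx <- idx[!is.na(idx)]
  v <- tabulate(idx, nbins = size)
  v <- as.numeric(v)
  if (normalize && length(idx) > 0) v <- v / length(idx)
  v
}

#' Spike2Vec embeddings for a corpus of sequences
#'
#' @param sequences A tibble with columns `id` and `sequence`
#'   (as from [trace_sequences()]).
#' @inheritParams spike2vec
#' @return A tibble `id, v1..vD` tagged with source `"spike2vec"`, where
#'   `D = |alphabet|^k`.
#' @export
embed_spike2vec <- function(sequences, k = 3, alphabet = PROTEIN_ALPHABET,
                            normalize = FALSE) {
  stopifnot(is.data.frame(sequences), all(c("id", "sequence") %in% names(sequences)))
  vocab <- kmer_vocabulary(alphabet, k)
  mat <- t(vapply(sequences$sequence, spike2vec, numeric(length(vocab$kmers)),
                  vocab = vocab, normalize = normalize, USE.NAMES = FALSE))
  as_embedding_tbl(sequences$id, mat, "spike2vec")
}

#' Load precomputed per-protein embeddings from a delimited table
#'
#' Reads externally computed fixed-length vectors (for example
#' language-model sequence embeddings) from a delimited file with header
#' `id, v1..vD`. Vectors are validated to be finite and equal-length and,
#' when `expected_ids` is given, every expected identifier must be present.
#'
#' @param file Path to a delimited table (comma by default).
#' @param expected_ids Optional character vector; an error lists any
#'   identifier absent from the table.
#' @param delim Field delimiter (default `","`).
#' @return A tibble `id, v1..vD` tagged with source `"external"`.
#' @export
read_embedding_table <- function(file, expected_ids = NULL, delim = ",") {
  tbl <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf("ragged or malformed table '%s': first problem at row %d",
                  file, probs$row[1]))
  }
  if (!"id" %in% names(tbl)) abort("embedding table must have an `id` column")
  tbl$id <- as.character(tbl$id)
  check_embedding_tbl(tbl, "embedding table")
  if (!is.null(expected_ids)) {
    missing_ids <- setdiff(expected_ids, tbl$id)
    if (length(missing_ids)) {
      abort(paste0("embedding table is missing ids: ",
                   paste(missing_ids, collapse = ", ")))
    }
  }
  attr(tbl, "embedding_source") <- "external"
  tbl
}

#' Write an embedding table to a delimited file
#'
#' Inverse of [read_embedding_table()]; same dialect as the tables written
#' by the command-line interface (`id, v1..vD` header).
#'
#' @param embeddings A tibble `id, v1..vD`.
#' @param file Output path.
#' @param delim Field delimiter (default `","`).
#' @return `file`, invisibly.
#' @export
write_embedding_table <- function(embeddings, file, delim = ",") {
  check_embedding_tbl(embeddings)
  readr::write_delim(embeddings, file, delim = delim)
  invisible(file)
}
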