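#' Pairwise C-alpha distance matrix
#'
#' Euclidean distances in Angstrom between every pair of C-alpha atoms of
#' one protein.
#'
#' @param trace A single-protein trace tibble from [ca_trace()].
#' @return A symmetric `n x n` numeric matrix with zero diagonal.
#' @examples
#' tr <- tibble::tibble(id = "p", chain = "A", resno = 1:2,
#'                      resname = "ALA", aa = "A",
#'                      x = c(0, 3), y = c(0, 4), z = c(0, 0))
#' pairwise_distances(tr)  # 3-4-5 triangle: off-diagonal 5
#' @export
pairwise_distances <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("x", "y", "z") %in% names(trace)))
  if ("id" %in% names(trace) && length(unique(trace$id)) > 1L) {
    abort("`trace` contains several proteins; pass one id at a time")
  }
  coords <- as.matrix(trace[c("x", "y", "z")])
  bad <- which(!apply(is.finite(coords), 1L, all))
  if (length(bad)) {
    abort(sprintf("non-finite coordinates at residue index %s",
                  paste(bad, collapse = ", ")))
  }
  d <- as.matrix(dist(coords, method = "euclidean"))
  dimnames(d) <- NULL
  d
}

#' Binary contact map from a distance matrix
#'
#' Entry (i, j) is 1 when the distance is less than or equal to the
#' threshold (inclusive), else 0. The diagonal is therefore all 1.
#'
#' @param distances A symmetric distance matrix from [pairwise_distances()].
#' @param threshold Contact threshold in Angstrom (default 8.0).
#' @return An `n x n` 0/1 matrix with attribute `"threshold"`.
#' @export
contact_map <- function(distances, threshold = 8) {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances), threshold > 0)
  cm <- (distances <= threshold) * 1L
  storage.mode(cm) <- "double"
  attr(cm, "threshold") <- threshold
  cm
}

#' Variance-preserving projection and flattening of a contact map
#'
#' Rows of the map are treated as observations and projected onto the
#' smallest number of principal components whose cumulative explained
#' variance reaches `variance_fraction`; the projected `n x m` score matrix
#' is flattened row-major into a length `n * m` vector. When the rows carry
#' no variance at all (all rows identical), a single component is kept and
#' the projected values are all zero. Component signs are fixed by forcing
#' the largest-magnitude loading of each component to be positive, so the
#' result is deterministic.
#'
#' @param map A contact map (or any numeric matrix of row-observations).
#' @param variance_fraction Cumulative explained-variance target in (0, 1]
#'   (default 0.99).
#' @return A numeric vector of length `n * m`.
#' @export
reduce_contact_map <- function(map, variance_fraction = 0.99) {
  stopifnot(is.matrix(map), nrow(map) >= 1L,
            variance_fraction > 0, variance_fraction <= 1)
  as.vector(t(reduce_rows(map, variance_fraction)))  # row-major
}

#' Contact-map embedding of one protein
#'
#' Full composition: pairwise distances, thresholding at `threshold`,
#' variance-preserving projection, row-major flattening, then length
#' normalization to `target_dim` (right-padding with `pad_value` or
#' truncating).
#'
#' @inheritParams pairwise_distances
#' @inheritParams contact_map
#' @inheritParams reduce_contact_map
#' @param target_dim Fixed output length. The per-protein flattened length
#'   varies with protein size, so a corpus-level dimension must be supplied;
#'   `"auto"` is only meaningful inside [embed_contact_maps()] (see
#'   [fit_corpus_dim()]).
#' @param pad_value Value used for right-padding (default 0).
#' @return A numeric vector of length `target_dim`.
#' @export
contact_embedding <- function(trace, threshold = 8, variance_fraction = 0.99,
                              target_dim, pad_value = 0) {
  if (missing(target_dim) || identical(target_dim, "auto")) {
    abort("`target_dim` = \"auto\" requires corpus context: use embed_contact_maps() or fit_corpus_dim()")
  }
  stopifnot(is.numeric(target_dim), length(target_dim) == 1L, target_dim >= 1)
  v <- reduce_contact_map(contact_map(pairwise_distances(trace), threshold),
                          variance_fraction)
  if (length(v) < target_dim) {
    c(v, rep(pad_value, target_dim - length(v)))
  } else {
    v[seq_len(target_dim)]
  }
}

#' Corpus-level embedding dimension
#'
#' The flattened projection length varies per protein; classifiers need
#' equal-length vectors. This returns the maximum flattened length over a
#' corpus of contact maps, intended to be learned on training data and
#' reused for held-out proteins.
#'
#' @param maps A list of contact maps ([contact_map()]).
#' @inheritParams reduce_contact_map
#' @return A positive integer.
#' @export
fit_corpus_dim <- function(maps, variance_fraction = 0.99) {
  if (!is.list(maps) || length(maps) == 0L) abort("`maps` must be a non-empty list of contact maps")
  max(vapply(maps, function(m) length(reduce_contact_map(m, variance_fraction)), 1L))
}

#' Contact-map embeddings for a corpus of proteins
#'
#' Computes a fixed-length structural embedding for every protein in a
#' trace tibble. Two ways of turning the variable-size per-protein
#' projections into equal-length vectors are offered:
#'
#' * `projection = "corpus"` (default): every contact map is zero-padded
#'   (or cropped) to the corpus maximum size `N x N`, flattened row-major,
#'   and a single variance-preserving principal-component projection is
#'   fitted across the corpus, retaining the smallest number of components
#'   whose cumulative explained variance reaches `variance_fraction`. All
#'   proteins then share one component basis, so embedding coordinates are
#'   comparable across proteins.
#' * `projection = "per_protein"`: the literal per-map reading — each map
#'   is projected and flattened on its own ([reduce_contact_map()]) and the
#'   flat vectors are right-padded with `pad_value` / truncated to
#'   `target_dim` (`"auto"` = corpus maximum flattened length,
#'   [fit_corpus_dim()]). Per-protein component bases are not comparable
#'   across proteins, which limits what downstream classifiers can recover;
#'   see the methods vignette.
#'
#' @param traces A trace tibble covering one or more proteins (`id` column).
#' @inheritParams contact_embedding
#' @param projection `"corpus"` or `"per_protein"` (see Details).
#' @return A tibble `id, v1..vD` tagged with source `"contact_map"`.
#' @examples
#' corp <- synthetic_corpus(
#'   components = tibble::tibble(label = c("a", "b"),
#'                               geometry = c("helix", "extended"), n = 3),
#'   length_range = c(20, 30), noise_sd = 0, seed = 1)
#' tr <- read_ca_traces(corp$file)
#' dim(embed_contact_maps(tr))
#' @export
embed_contact_maps <- function(traces, threshold = 8, variance_fraction = 0.99,
                               target_dim = "auto", pad_value = 0,
                               projection = c("corpus", "per_protein")) {
  stopifnot(is.data.frame(traces), "id" %in% names(traces))
  projection <- match.arg(projection)
  ids <- unique(traces$id)
  maps <- lapply(ids, function(i) {
    contact_map(pairwise_distances(traces[traces$id == i, , drop = FALSE]), threshold)
  })

  if (projection == "corpus") {
    N <- max(vapply(maps, nrow, 1L))
    flat <- t(vapply(maps, function(m) {
      p <- matrix(pad_value, N, N)
      keep <- min(nrow(m), N)
      p[seq_len(keep), seq_len(keep)] <- m[seq_len(keep), seq_len(keep)]
      as.vector(t(p))  # row-major
    }, numeric(N * N)))
    mat <- reduce_rows(flat, variance_fraction)
  } else {
    flat <- lapply(maps, reduce_contact_map, variance_fraction = variance_fraction)
    if (identical(target_dim, "auto")) {
      target_dim <- max(lengths(flat))
    }
    stopifnot(is.numeric(target_dim), target_dim >= 1)
    padded <- lapply(flat, function(v) {
      if (length(v) < target_dim) c(v, rep(pad_value, target_dim - length(v)))
      else v[seq_len(target_dim)]
    })
    mat <- matrix(unlist(padded), nrow = length(ids), ncol = target_dim, byrow = TRUE)
  }
  as_embedding_tbl(ids, mat, "contact_map")
}

# variance-preserving projection of a samples x features matrix: scores of
# the smallest component set whose cumulative explained variance reaches
# `variance_fraction`, with the same deterministic sign convention as
# reduce_contact_map; zero total variance degenerates to a single zero
# component
reduce_rows <- function(x, variance_fraction) {
  n <- nrow(x)
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  total <- sum(ev)
  if (n == 1L || total < 1e-12) {
    return(matrix(0, n, 1L))
  }
  k <- which(cumsum(ev) / total >= variance_fraction - 1e-12)[1L]
  scores <- pca$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  scores
}
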