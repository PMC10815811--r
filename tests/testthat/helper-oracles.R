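# independent oracles and fixture builders shared across tests

# brute-force O(n^2) Euclidean distances, double loop
bf_distances <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  d
}

# brute-force sliding-window k-mer dictionary count
bf_kmer_counts <- function(sequence, vocab) {
  counts <- setNames(numeric(length(vocab$kmers)), vocab$kmers)
  L <- nchar(sequence)
  k <- vocab$k
  if (L >= k) {
    for (i in seq_len(L - k + 1)) {
      w <- substr(sequence, i, i + k - 1)
      if (w %in% vocab$kmers) counts[w] <- counts[w] + 1
    }
  }
  unname(counts)
}

# brute-force ROC curve + trapezoidal AUC for a binary 0/1 response
bf_auc <- function(truth01, score) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  fpr <- tpr <- numeric(length(thr))
  np <- sum(truth01 == 1)
  nn <- sum(truth01 == 0)
  for (t in seq_along(thr)) {
    pred <- score >= thr[t]
    tpr[t] <- sum(pred & truth01 == 1) / np
    fpr[t] <- sum(pred & truth01 == 0) / nn
  }
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# explained-variance spectrum of the rows of a matrix via full
# eigendecomposition of the row covariance
bf_row_eigenvalues <- function(m) {
  ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
  pmax(ev, 0)
}

# random C-alpha trace tibble (no file round trip)
random_trace <- function(n, seed, id = "rt") {
  withr::with_seed(seed, {
    tibble::tibble(
      id = id, chain = "A", resno = seq_len(n), resname = "ALA", aa = "A",
      x = stats::runif(n, -20, 20), y = stats::runif(n, -20, 20),
      z = stats::runif(n, -20, 20)
    )
  })
}

# random symmetric binary contact-map-like matrix with unit diagonal
random_binary_map <- function(n, seed, p = 0.3) {
  withr::with_seed(seed, {
    m <- matrix(stats::rbinom(n * n, 1, p), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    storage.mode(m) <- "double"
    m
  })
}

# two Gaussian blobs: feature table + labels, classes `sep` sds apart
make_blobs <- function(n_per_class = 20, dim = 5, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- matrix(stats::rnorm(n * dim), n, dim)
    x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] + sep
    ids <- sprintf("s%03d", seq_len(n))
    feats <- tibble::as_tibble(as.data.frame(x))
    names(feats) <- paste0("v", seq_len(dim))
    feats <- dplyr::bind_cols(tibble::tibble(id = ids), feats)
    labels <- tibble::tibble(id = ids,
                             label = rep(c("pos", "neg"), each = n_per_class))
    list(features = feats, labels = labels)
  })
}

# fixed-column ATOM line for hand-built test structures
atom_line <- function(serial, atom, resname, chain, resno, x, y, z) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, paste0(" ", atom), resname, chain, resno, x, y, z)
}
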