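test_that("pairwise distances match hand values and the brute-force oracle", {
  one <- random_trace(1, seed = 1)
  expect_equal(pairwise_distances(one), matrix(0, 1, 1))

  tri <- tibble::tibble(id = "t", chain = "A", resno = 1:2, resname = "ALA",
                        aa = "A", x = c(0, 3), y = c(0, 4), z = c(0, 0))
  expect_equal(pairwise_distances(tri), rbind(c(0, 5), c(5, 0)))

  tr <- random_trace(25, seed = 42)
  expect_equal(pairwise_distances(tr),
               bf_distances(as.matrix(tr[c("x", "y", "z")])),
               tolerance = 1e-12)
})

test_that("non-finite coordinates are reported with the residue index", {
  tr <- random_trace(5, seed = 1)
  tr$x[3] <- NA
  expect_error(pairwise_distances(tr), "residue index 3")
})

test_that("contact thresholding is inclusive and preserves symmetry", {
  d <- rbind(c(0, 5), c(5, 0))
  expect_equal(unname(contact_map(d, 8)[1, 2]), 1)
  expect_equal(contact_map(rbind(c(0, 9), c(9, 0)), 8), diag(2),
               ignore_attr = TRUE)
  # exactly-at-threshold distances count as contacts
  d8 <- rbind(c(0, 8), c(8, 0))
  expect_equal(contact_map(d8, 8), matrix(1, 2, 2), ignore_attr = TRUE)
})

test_that("contact maps are binary, symmetric, unit-diagonal and monotone in threshold", {
  for (seed in 1:20) {
    tr <- random_trace(sample(5:40, 1), seed = seed)
    d <- pairwise_distances(tr)
    cm <- contact_map(d, 8)
    expect_true(all(cm %in% c(0, 1)))
    expect_identical(unname(cm), unname(t(cm)))
    expect_true(all(diag(cm) == 1))
    cm_lo <- contact_map(d, 4)
    cm_hi <- contact_map(d, 12)
    expect_true(all(cm >= cm_lo))       # raising the threshold never removes a 1
    expect_true(all(cm_hi >= cm))
    expect_true(sum(cm_lo) <= sum(cm) && sum(cm) <= sum(cm_hi))
  }
})

test_that("rigid transforms leave distances, maps and embeddings unchanged", {
  tr <- random_trace(20, seed = 9)
  d <- pairwise_distances(tr)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- as.matrix(tr[c("x", "y", "z")]) %*% t(rot)
  tr2 <- tr
  tr2$x <- moved[, 1] + 5; tr2$y <- moved[, 2] - 3; tr2$z <- moved[, 3] + 11
  expect_equal(pairwise_distances(tr2), d, tolerance = 1e-9)
  expect_equal(contact_map(pairwise_distances(tr2)), contact_map(d),
               tolerance = 1e-9)
  expect_equal(contact_embedding(tr2, target_dim = 50),
               contact_embedding(tr, target_dim = 50), tolerance = 1e-9)
})

test_that("projection matches the closed-form 2x2 eigendecomposition", {
  v <- reduce_contact_map(rbind(c(1, 0), c(0, 1)))
  # one component captures all variance; scores are +/- sqrt(2)/2 with the
  # max-|loading| sign convention making the first score positive
  expect_equal(v, c(sqrt(2) / 2, -sqrt(2) / 2))
})

test_that("zero-variance maps keep one component with all-zero projection", {
  expect_equal(reduce_contact_map(matrix(1, 3, 3)), c(0, 0, 0))
  expect_equal(reduce_contact_map(matrix(0, 4, 4)), rep(0, 4))
  expect_equal(reduce_contact_map(matrix(1, 1, 1)), 0)
})

test_that("retained components reach the variance target against the eigen oracle", {
  for (seed in 1:25) {
    m <- random_binary_map(20, seed = seed)
    v <- reduce_contact_map(m, variance_fraction = 0.99)
    k <- length(v) / nrow(m)
    expect_equal(k, round(k))  # n x m flattening
    ev <- bf_row_eigenvalues(m)
    expect_gte(sum(ev[seq_len(k)]) / sum(ev), 0.99 - 1e-9)
    if (k > 1) expect_lt(sum(ev[seq_len(k - 1)]) / sum(ev), 0.99)  # minimal set
  }
})

test_that("flattening is row-major over the projected score matrix", {
  m <- random_binary_map(8, seed = 3)
  v <- reduce_contact_map(m, variance_fraction = 1)
  pca <- prcomp(m)
  k <- length(v) / nrow(m)
  scores <- pca$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  expect_equal(v, as.vector(t(scores)))
})

test_that("contact_embedding honors the length contract and determinism", {
  p <- synthetic_pdb(length = 30, geometry = "helix", seed = 5)
  tr <- ca_trace(read_pdb(text = p$text, id = "h"))
  v <- contact_embedding(tr, target_dim = 64)
  expect_length(v, 64)
  expect_true(all(is.finite(v)))
  tr_again <- ca_trace(read_pdb(text = p$text, id = "h"))
  expect_identical(contact_embedding(tr_again, target_dim = 64), v)
  expect_error(contact_embedding(tr), "auto")

  # truncation: a target below the flattened length cuts, padding extends
  flat <- reduce_contact_map(contact_map(pairwise_distances(tr)))
  short <- contact_embedding(tr, target_dim = 10)
  expect_equal(short, flat[1:10])
  long <- contact_embedding(tr, target_dim = length(flat) + 5)
  expect_equal(long, c(flat, rep(0, 5)))
})

test_that("fit_corpus_dim returns the maximum flattened length", {
  maps <- lapply(c(5, 12, 8), function(n) {
    contact_map(pairwise_distances(random_trace(n, seed = n)))
  })
  lens <- vapply(maps, function(m) length(reduce_contact_map(m)), 1L)
  expect_equal(fit_corpus_dim(maps), max(lens))
  expect_equal(fit_corpus_dim(maps[2]), lens[2])
  expect_error(fit_corpus_dim(list()), "non-empty")
})

test_that("per-protein corpus embeddings share the corpus-max flattened length", {
  corp <- synthetic_corpus(
    tibble::tibble(label = c("a", "b"), geometry = c("helix", "extended"), n = 6),
    length_range = c(15, 35), noise_sd = 0.1, seed = 13
  )
  traces <- read_ca_traces(attr(corp, "dir"))
  emb <- embed_contact_maps(traces, target_dim = "auto", projection = "per_protein")
  ids <- unique(traces$id)
  lens <- vapply(ids, function(i) {
    length(reduce_contact_map(contact_map(pairwise_distances(
      traces[traces$id == i, , drop = FALSE]))))
  }, 1L)
  expect_equal(ncol(emb) - 1L, max(lens))
  expect_equal(emb$id, ids)
  expect_equal(embedding_source(emb), "contact_map")
})

test_that("corpus-fitted embeddings are equal-length, finite and deterministic", {
  corp <- synthetic_corpus(
    tibble::tibble(label = c("a", "b"), geometry = c("helix", "extended"), n = 6),
    length_range = c(15, 35), noise_sd = 0.1, seed = 14
  )
  traces <- read_ca_traces(attr(corp, "dir"))
  e1 <- embed_contact_maps(traces)
  e2 <- embed_contact_maps(traces)
  expect_identical(e1, e2)
  m <- as.matrix(e1[-1])
  expect_true(all(is.finite(m)))
  # retained corpus components reach the variance target
  flatmaps <- local({
    ids <- unique(traces$id)
    N <- max(table(traces$id))
    t(vapply(ids, function(i) {
      tr <- traces[traces$id == i, , drop = FALSE]
      cm <- contact_map(pairwise_distances(tr))
      p <- matrix(0, N, N)
      p[seq_len(nrow(cm)), seq_len(nrow(cm))] <- cm
      as.vector(t(p))
    }, numeric(N * N)))
  })
  ev <- bf_row_eigenvalues(flatmaps)
  k <- ncol(m)
  expect_gte(sum(ev[seq_len(k)]) / sum(ev), 0.99 - 1e-9)
})
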