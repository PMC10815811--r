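test_that("fusion concatenates parts in order and aligns on id", {
  a <- tibble::tibble(id = c("p1", "p2"), v1 = c(1, 4), v2 = c(2, 5), v3 = c(3, 6))
  b <- tibble::tibble(id = c("p2", "p1"), v1 = c(40, 10), v2 = c(50, 20),
                      v3 = c(60, 30), v4 = c(70, 40))
  fu <- fuse_embeddings(a, b)
  expect_equal(ncol(fu) - 1L, 7L)
  expect_equal(fu$id, c("p1", "p2"))
  expect_equal(unlist(fu[1, -1], use.names = FALSE), c(1, 2, 3, 10, 20, 30, 40))
  expect_equal(embedding_source(fu), "fused")
})

test_that("fusing a single table is the identity on its values", {
  a <- tibble::tibble(id = c("p1", "p2"), v1 = c(1, 2))
  fu <- fuse_embeddings(a)
  expect_equal(as.matrix(fu[-1]), as.matrix(a[-1]), ignore_attr = TRUE)
})

test_that("id mismatches are reported as a symmetric difference", {
  a <- tibble::tibble(id = c("p1", "p2"), v1 = c(1, 2))
  b <- tibble::tibble(id = c("p1", "p3"), v1 = c(1, 2))
  expect_error(fuse_embeddings(a, b), "p2")
  expect_error(fuse_embeddings(a, b), "p3")
})

test_that("fused length is the sum of part lengths on a mixed corpus", {
  n <- 20
  ids <- sprintf("p%02d", 1:n)
  withr::with_seed(2, {
    mk <- function(d) {
      m <- matrix(rnorm(n * d), n)
      colnames(m) <- paste0("v", seq_len(d))
      dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(m))
    }
    fu <- fuse_embeddings(mk(64), mk(9261), mk(1024))
    expect_equal(ncol(fu) - 1L, 64L + 9261L + 1024L)
    expect_equal(ncol(fu) - 1L, 10349L)
  })
})

test_that("splits realize 63/7/30 on a balanced 100-sample corpus", {
  labels <- tibble::tibble(id = sprintf("s%03d", 1:100),
                           label = rep(c("x", "y"), each = 50))
  plan <- split_dataset(labels, seed = 4)
  expect_equal(sum(plan$fold == "train"), 63L)
  expect_equal(sum(plan$fold == "val"), 7L)
  expect_equal(sum(plan$fold == "test"), 30L)
  # stratified: 15 test per class
  expect_equal(unname(table(plan$label[plan$fold == "test"])), c(15L, 15L),
               ignore_attr = TRUE)
  expect_setequal(plan$id, labels$id)
})

test_that("splits are deterministic and partition the corpus exactly", {
  labels <- tibble::tibble(id = sprintf("s%03d", 1:47),
                           label = rep(c("x", "y", "z"), length.out = 47))
  p1 <- split_dataset(labels, seed = 99)
  p2 <- split_dataset(labels, seed = 99)
  expect_identical(p1, p2)
  p3 <- split_dataset(labels, seed = 100)
  expect_false(identical(p1$fold, p3$fold))
  expect_equal(sort(p1$id), sort(labels$id))
  expect_equal(nrow(p1), 47L)
  expect_false(anyDuplicated(p1$id) > 0)
})

test_that("small two-class corpora stratify the test fold", {
  labels <- tibble::tibble(id = sprintf("s%02d", 1:10),
                           label = rep(c("x", "y"), each = 5))
  for (seed in 1:10) {
    plan <- split_dataset(labels, seed = seed)
    per_class <- table(plan$label[plan$fold == "test"])
    expect_true(all(per_class >= 1 & per_class <= 2))
  }
  too_small <- tibble::tibble(id = c("a", "b", "c"), label = c("x", "x", "y"))
  expect_error(split_dataset(too_small, seed = 1), "fewer than 2")
})

test_that("metrics are exact on the printed toy confusion", {
  truth <- c("H", "H", "M", "M")
  pred <- c("H", "M", "M", "M")
  scores <- cbind(H = c(.9, .4, .3, .2), M = c(.1, .6, .7, .8))
  m <- compute_metrics(truth, pred, scores)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 5 / 6)   # (1.0*2 + (2/3)*2) / 4
  expect_equal(m$recall, 0.75)
  # per-class F1: H: 2*(1*0.5)/1.5 = 2/3; M: 2*((2/3)*1)/(5/3) = 0.8
  expect_equal(m$f1_weighted, (2 / 3 + 0.8) / 2)
  expect_equal(m$f1_macro, (2 / 3 + 0.8) / 2)
})

test_that("perfect predictions give all-1 metrics", {
  truth <- c("a", "b", "c", "a", "b", "c")
  scores <- diag(3)[match(truth, c("a", "b", "c")), ]
  colnames(scores) <- c("a", "b", "c")
  m <- compute_metrics(truth, truth, scores)
  expect_equal(unlist(m), rep(1, 6), ignore_attr = TRUE)
})

test_that("one-vs-rest AUC matches brute-force trapezoidal integration", {
  withr::with_seed(21, {
    truth <- sample(c("a", "b", "c"), 30, replace = TRUE, prob = c(.5, .3, .2))
    raw <- matrix(runif(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
    # correlate scores with truth so AUCs are informative
    raw[cbind(seq_len(30), match(truth, c("a", "b", "c")))] <-
      raw[cbind(seq_len(30), match(truth, c("a", "b", "c")))] + 0.5
    scores <- raw / rowSums(raw)
  })
  pred <- colnames(scores)[max.col(scores, ties.method = "first")]
  m <- compute_metrics(truth, pred, scores)
  w <- table(factor(truth, levels = colnames(scores))) / length(truth)
  auc_oracle <- sum(vapply(colnames(scores), function(cl) {
    w[[cl]] * bf_auc(as.integer(truth == cl), scores[, cl])
  }, 0))
  expect_equal(m$roc_auc, auc_oracle, tolerance = 1e-12)
})

test_that("classes missing from the score columns are an error", {
  scores <- cbind(a = c(.6, .4), b = c(.4, .6))
  expect_error(compute_metrics(c("a", "c"), c("a", "b"), scores), "c")
})

test_that("identical reports compare with p = 1 and strong contrasts with p < 0.001", {
  mk_report <- function(acc) {
    runs <- tibble::tibble(
      run = seq_along(acc), seed = seq_along(acc), classifier = "LR",
      accuracy = acc, precision = acc, recall = acc, f1_weighted = acc,
      f1_macro = acc, roc_auc = acc, train_time = 0.01
    )
    structure(list(runs = runs, summary = NULL, n_runs = length(acc),
                   base_seed = 0, classifiers = "LR"), class = "eval_report")
  }
  same <- mk_report(c(0.9, 0.91, 0.92, 0.9, 0.91))
  expect_equal(compare_methods(same, same)$p_value, 1)

  a <- mk_report(c(0.9, 0.91, 0.92, 0.9, 0.91))
  b <- mk_report(c(0.5, 0.52, 0.51, 0.5, 0.53))
  cmp <- compare_methods(a, b)
  expect_lt(cmp$p_value, 0.001)
  # oracle: Welch statistic by hand
  va <- c(0.9, 0.91, 0.92, 0.9, 0.91); vb <- c(0.5, 0.52, 0.51, 0.5, 0.53)
  tstat <- (mean(va) - mean(vb)) / sqrt(var(va) / 5 + var(vb) / 5)
  expect_equal(cmp$statistic, tstat, tolerance = 1e-12)
  # two-sided symmetry
  cmp_rev <- compare_methods(b, a)
  expect_equal(cmp_rev$p_value, cmp$p_value, tolerance = 1e-12)
  expect_equal(cmp_rev$statistic, -cmp$statistic, tolerance = 1e-12)

  one_run <- mk_report(0.9)
  expect_error(compare_methods(one_run, one_run), "2 runs")
  # constant but different samples: the difference is as extreme as possible
  expect_equal(compare_methods(mk_report(rep(0.9, 3)),
                               mk_report(rep(0.5, 3)))$p_value, 0)
})
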