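#' Stratified train/validation/test split
#'
#' Random 70/30 train-test split stratified by class, with 10% of the
#' training portion (again stratified) set aside for hyperparameter tuning.
#' Per-class counts use largest-remainder rounding so the global fractions
#' are met exactly (e.g. 100 samples give 63 train / 7 validation / 30
#' test). Deterministic given `seed`.
#'
#' @param labels A tibble with columns `id` and `label`; every class needs
#'   at least 2 members.
#' @param seed Integer seed controlling the split.
#' @param test_frac,val_frac Test fraction of the corpus and validation
#'   fraction of the training portion (defaults 0.3 and 0.1).
#' @return A tibble `id, label, fold` with `fold` in
#'   `{"train", "val", "test"}`, partitioning the corpus exactly.
#' @export
split_dataset <- function(labels, seed, test_frac = 0.3, val_frac = 0.1) {
  stopifnot(is.data.frame(labels), all(c("id", "label") %in% names(labels)))
  if (anyDuplicated(labels$id)) abort("duplicate ids in `labels`")
  tab <- table(labels$label)
  if (length(tab) < 2L) abort("need at least 2 classes")
  small <- names(tab)[tab < 2]
  if (length(small)) abort(paste0("class(es) with fewer than 2 members: ",
                                  paste(small, collapse = ", ")))
  classes <- sort(names(tab))
  n <- nrow(labels)

  # largest-remainder allocation of `total` across classes, proportional to
  # pool sizes and capped by them
  alloc <- function(pool_sizes, total) {
    ideal <- pool_sizes * total / sum(pool_sizes)
    base <- pmin(floor(ideal), pool_sizes)
    rem <- total - sum(base)
    ord <- order(ideal - base, decreasing = TRUE)
    for (i in ord) {
      if (rem <= 0) break
      if (base[i] < pool_sizes[i]) { base[i] <- base[i] + 1; rem <- rem - 1 }
    }
    base
  }

  with_seed_if(as.integer(seed), {
    by_class <- lapply(classes, function(cl) sort(labels$id[labels$label == cl]))
    pool <- lengths(by_class)
    n_test <- alloc(pool, round(test_frac * n))
    test_ids <- unlist(lapply(seq_along(classes), function(i) {
      sample(by_class[[i]], n_test[i])
    }))
    train_pool <- lapply(seq_along(classes), function(i) setdiff(by_class[[i]], test_ids))
    n_train_total <- sum(lengths(train_pool))
    n_val <- alloc(lengths(train_pool), round(val_frac * n_train_total))
    val_ids <- unlist(lapply(seq_along(classes), function(i) {
      sample(train_pool[[i]], n_val[i])
    }))
    out <- labels[c("id", "label")]
    out$fold <- ifelse(out$id %in% test_ids, "test",
                       ifelse(out$id %in% val_ids, "val", "train"))
    as_tibble(out)
  })
}

CLASSIFIERS <- c("SVM", "NB", "MLP", "KNN", "RF", "LR", "DT")

# small fixed hyperparameter grids, selected on the validation split
classifier_grid <- function(name) {
  switch(name,
    SVM = lapply(c(0.1, 1, 10), function(c) list(cost = c)),
    NB  = list(list()),
    MLP = lapply(c(32L, 64L), function(s) list(size = s)),
    KNN = lapply(c(3L, 5L, 7L), function(k) list(k = k)),
    RF  = list(list(ntree = 100L)),
    LR  = lapply(c(0.1, 1, 10), function(c) list(C = c)),
    DT  = lapply(c(30L, 10L), function(d) list(maxdepth = d)),
    abort(sprintf("unknown classifier '%s'; valid names: %s",
                  name, paste(CLASSIFIERS, collapse = ", ")))
  )
}

# fit one classifier and return a function(Xnew) -> probability matrix with
# columns in levels(y) order
fit_classifier <- function(name, X, y, params, seed) {
  lv <- levels(y)
  reorder_prob <- function(p) {
    p <- as.matrix(p)
    missing_cols <- setdiff(lv, colnames(p))
    if (length(missing_cols)) {
      p <- cbind(p, matrix(0, nrow(p), length(missing_cols),
                           dimnames = list(NULL, missing_cols)))
    }
    p[, lv, drop = FALSE]
  }
  with_seed_if(seed, switch(name,
    SVM = {
      m <- e1071::svm(x = X, y = y, kernel = "radial", cost = params$cost,
                      probability = TRUE, scale = FALSE)
      function(Xn) {
        pr <- attr(predict(m, Xn, probability = TRUE), "probabilities")
        reorder_prob(pr)
      }
    },
    NB = {
      m <- e1071::naiveBayes(x = as.data.frame(X), y = y)
      # guard against zero class-conditional variances on sparse features
      m$tables <- lapply(m$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-6)
        tb
      })
      function(Xn) reorder_prob(predict(m, as.data.frame(Xn), type = "raw"))
    },
    MLP = {
      ymat <- nnet::class.ind(y)
      m <- nnet::nnet(X, ymat, size = params$size, softmax = TRUE,
                      decay = 0.01, maxit = 200, MaxNWts = 5e6, trace = FALSE)
      function(Xn) reorder_prob(predict(m, Xn))
    },
    KNN = {
      m <- caret::knn3(X, y, k = params$k)
      function(Xn) reorder_prob(predict(m, Xn, type = "prob"))
    },
    RF = {
      m <- randomForest::randomForest(x = X, y = y, ntree = params$ntree)
      function(Xn) reorder_prob(predict(m, Xn, type = "prob"))
    },
    LR = {
      fam <- if (length(lv) == 2L) "binomial" else "multinomial"
      lam <- 1 / (params$C * nrow(X))
      # fit along a descending path ending at the target lambda: glmnet
      # warm starts are unreliable when handed a single small lambda
      path <- exp(seq(log(max(1, lam * 1000)), log(lam), length.out = 30))
      m <- suppressWarnings(
        glmnet::glmnet(X, y, family = fam, alpha = 0, lambda = path,
                       standardize = FALSE)
      )
      function(Xn) {
        pr <- predict(m, Xn, type = "response", s = lam)
        if (length(lv) == 2L) {
          p2 <- as.vector(pr[, 1])  # probability of the second level
          reorder_prob(cbind(matrix(1 - p2, ncol = 1, dimnames = list(NULL, lv[1])),
                             matrix(p2, ncol = 1, dimnames = list(NULL, lv[2]))))
        } else {
          reorder_prob(pr[, , 1])
        }
      }
    },
    DT = {
      df <- as.data.frame(X)
      df$.label <- y
      m <- rpart::rpart(.label ~ ., data = df, method = "class",
                        control = rpart::rpart.control(maxdepth = params$maxdepth,
                                                       cp = 0.001))
      function(Xn) reorder_prob(predict(m, as.data.frame(Xn), type = "prob"))
    },
    abort(sprintf("unknown classifier '%s'; valid names: %s",
                  name, paste(CLASSIFIERS, collapse = ", ")))
  ))
}

prob_to_class <- function(prob) {
  colnames(prob)[max.col(prob, ties.method = "first")]
}

#' Classification metrics with one-vs-rest multiclass adaptation
#'
#' Accuracy; precision, recall and F1 with support-weighted averaging;
#' macro-averaged F1; and one-vs-rest ROC-AUC with support-weighted
#' averaging across classes. Classes receiving no predictions contribute
#' precision 0 (and F1 0), so all metrics stay in \[0, 1\].
#'
#' @param truth True class labels.
#' @param pred Predicted class labels.
#' @param scores Numeric matrix of class scores, one column per class,
#'   column names naming the classes. Every class present in `truth` must
#'   have a score column.
#' @return A one-row tibble: `accuracy`, `precision`, `recall`,
#'   `f1_weighted`, `f1_macro`, `roc_auc`.
#' @examples
#' sc <- cbind(H = c(.9, .4, .2, .1), M = c(.1, .6, .8, .9))
#' compute_metrics(c("H", "H", "M", "M"), c("H", "M", "M", "M"), sc)
#' @export
compute_metrics <- function(truth, pred, scores) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) abort("`scores` must have class column names")
  lv <- colnames(scores)
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) == nrow(scores))
  absent <- setdiff(unique(truth), lv)
  if (length(absent)) {
    abort(paste0("class(es) in `truth` without a score column: ",
                 paste(absent, collapse = ", ")))
  }
  tf <- factor(truth, levels = lv)
  pf <- factor(pred, levels = lv)
  if (anyNA(pf)) abort("predicted class outside score columns")
  cm <- table(tf, pf)
  n <- length(truth)
  support <- rowSums(cm)
  w <- support / n
  tp <- diag(cm)
  prec_c <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)

  present <- which(support > 0)
  auc_c <- rep(NA_real_, length(lv))
  for (i in present) {
    if (support[i] == n) next  # single-class truth: OvR AUC undefined
    r <- pROC::roc(response = as.integer(tf == lv[i]), predictor = scores[, i],
                   levels = c(0L, 1L), direction = "<", quiet = TRUE)
    auc_c[i] <- as.numeric(pROC::auc(r))
  }
  ok <- !is.na(auc_c)
  roc_auc <- if (any(ok)) sum(w[ok] * auc_c[ok]) / sum(w[ok]) else NA_real_

  tibble(
    accuracy = sum(tp) / n,
    precision = sum(w * prec_c),
    recall = sum(w * rec_c),
    f1_weighted = sum(w * f1_c),
    f1_macro = mean(f1_c[present]),
    roc_auc = roc_auc
  )
}

#' Tune, train and evaluate one classifier on a split
#'
#' Hyperparameters are chosen on the validation fold from a small fixed
#' grid (by accuracy), the final model is refit on train + validation, and
#' metrics are computed on the test fold. Features are standardized using
#' training-fold statistics; zero-variance training features are dropped.
#' The recorded `train_time` is the elapsed seconds of the final fit.
#'
#' @param features An embedding table (`id, v1..vD`), e.g. from
#'   [embed_contact_maps()], [embed_spike2vec()] or [fuse_embeddings()].
#' @param labels A tibble `id, label`.
#' @param plan A split from [split_dataset()].
#' @param classifier One of `"SVM"`, `"NB"`, `"MLP"`, `"KNN"`, `"RF"`,
#'   `"LR"`, `"DT"`.
#' @param seed Seed threaded to any stochastic learner.
#' @return A one-row tibble: `classifier`, the six metrics of
#'   [compute_metrics()], and `train_time` (seconds).
#' @export
train_and_evaluate <- function(features, labels, plan, classifier, seed = 0L) {
  check_embedding_tbl(features, "features")
  stopifnot(is.data.frame(plan), all(c("id", "fold") %in% names(plan)))
  if (!classifier %in% CLASSIFIERS) {
    abort(sprintf("unknown classifier '%s'; valid names: %s",
                  classifier, paste(CLASSIFIERS, collapse = ", ")))
  }
  missing_feat <- setdiff(plan$id, features$id)
  if (length(missing_feat)) {
    abort(paste0("features missing for ids: ", paste(missing_feat, collapse = ", ")))
  }
  X <- embedding_matrix(features)[plan$id, , drop = FALSE]
  lab <- plan$label %||% labels$label[match(plan$id, labels$id)]
  y <- factor(lab)
  tr <- plan$fold == "train"
  va <- plan$fold == "val"
  te <- plan$fold == "test"

  # drop features constant on the training portion (train + val); features
  # are otherwise used on their native scale, as in the evaluation protocol
  keep <- which(apply(X[tr | va, , drop = FALSE], 2L, sd) > 0)
  if (length(keep) == 0L) {
    # fully degenerate design: no classifier can beat the class prior
    t0 <- proc.time()[["elapsed"]]
    prop <- table(y[tr | va]) / sum(tr | va)
    prob <- matrix(as.numeric(prop), sum(te), length(levels(y)), byrow = TRUE,
                   dimnames = list(NULL, levels(y)))
    res <- compute_metrics(as.character(y[te]), prob_to_class(prob), prob)
    return(dplyr::bind_cols(tibble(classifier = classifier), res,
                            tibble(train_time = proc.time()[["elapsed"]] - t0)))
  }
  if (length(keep) == 1L && ncol(X) > 1L) keep <- c(keep, setdiff(seq_len(ncol(X)), keep)[1L])
  X <- X[, keep, drop = FALSE]

  grid <- classifier_grid(classifier)
  best <- grid[[1L]]
  if (length(grid) > 1L && any(va)) {
    val_acc <- vapply(grid, function(params) {
      pp <- fit_classifier(classifier, X[tr, , drop = FALSE], droplevels(y[tr]),
                           params, seed)
      mean(prob_to_class(pp(X[va, , drop = FALSE])) == as.character(y[va]))
    }, 0)
    best <- grid[[which.max(val_acc)]]
  }

  t0 <- proc.time()[["elapsed"]]
  pp <- fit_classifier(classifier, X[tr | va, , drop = FALSE], y[tr | va], best, seed)
  train_time <- proc.time()[["elapsed"]] - t0

  prob <- pp(X[te, , drop = FALSE])
  pred <- prob_to_class(prob)
  res <- compute_metrics(as.character(y[te]), pred, prob)
  dplyr::bind_cols(tibble(classifier = classifier), res,
                   tibble(train_time = train_time))
}

#' Repeat the evaluation over random splits
#'
#' Runs the full split/tune/train/test protocol `n_runs` times; runs differ
#' only by the split seed (`base_seed + run`). Returns an `eval_report`
#' carrying per-run metric values and their mean and standard deviation.
#'
#' @inheritParams train_and_evaluate
#' @param classifiers Character vector of classifier names (default all 7).
#' @param n_runs Number of repeats (default 5).
#' @param base_seed Base seed; run `r` uses seed `base_seed + r`.
#' @return An `eval_report` object; see [tidy.eval_report()],
#'   [glance.eval_report()] and [autoplot.eval_report()].
#' @export
repeat_experiment <- function(features, labels, classifiers = CLASSIFIERS,
                              n_runs = 5, base_seed = 0L) {
  stopifnot(n_runs >= 1)
  runs <- purrr::map_dfr(seq_len(n_runs), function(r) {
    seed_r <- as.integer(base_seed) + r
    plan <- split_dataset(labels, seed = seed_r)
    purrr::map_dfr(classifiers, function(cl) {
      dplyr::bind_cols(tibble(run = r, seed = seed_r),
                       train_and_evaluate(features, labels, plan, cl, seed = seed_r))
    })
  })
  metric_cols <- c("accuracy", "precision", "recall", "f1_weighted",
                   "f1_macro", "roc_auc", "train_time")
  summ <- runs |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$classifier, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  if (n_runs == 1L) summ$sd <- 0
  structure(list(runs = runs, summary = summ, n_runs = n_runs,
                 base_seed = base_seed, classifiers = classifiers),
            class = "eval_report")
}

#' Compare two methods with a Welch t-test over runs
#'
#' Two-sample, two-sided Welch (unequal-variance) t-test on the per-run
#' values of one metric, for each classifier the two reports share. When
#' both per-run samples are constant the statistic is undefined; identical
#' means return p = 1 and different means p = 0.
#'
#' @param report_a,report_b `eval_report` objects from [repeat_experiment()]
#'   with the same number of runs.
#' @param metric Metric name (default `"accuracy"`).
#' @return A tibble with one row per shared classifier: `classifier`,
#'   `metric`, `mean_a`, `mean_b`, `statistic`, `p_value`.
#' @export
compare_methods <- function(report_a, report_b, metric = "accuracy") {
  stopifnot(inherits(report_a, "eval_report"), inherits(report_b, "eval_report"))
  if (report_a$n_runs != report_b$n_runs) abort("reports have different numbers of runs")
  if (report_a$n_runs < 2L) abort("need at least 2 runs to compare methods")
  shared <- intersect(report_a$classifiers, report_b$classifiers)
  if (length(shared) == 0L) abort("reports share no classifier")
  purrr::map_dfr(shared, function(cl) {
    a <- report_a$runs[[metric]][report_a$runs$classifier == cl]
    b <- report_b$runs[[metric]][report_b$runs$classifier == cl]
    if (sd(a) == 0 && sd(b) == 0) {
      stat <- NA_real_
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      tt <- t.test(a, b, var.equal = FALSE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    tibble(classifier = cl, metric = metric, mean_a = mean(a), mean_b = mean(b),
           statistic = stat, p_value = p)
  })
}
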