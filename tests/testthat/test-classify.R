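separable_table <- function(n_per = 25, seed = 1) {
  withr::with_seed(seed, {
    centers <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
    rows <- lapply(1:4, function(k) {
      tibble::tibble(f1 = rnorm(n_per, centers[k, 1], 0.3),
                     f2 = rnorm(n_per, centers[k, 2], 0.3),
                     label = k)
    })
    tab <- dplyr::bind_rows(rows)
    attr(tab, "feature_cols") <- c("f1", "f2")
    tab
  })
}

test_that("a perfectly separable table cross-validates at accuracy 1", {
  tab <- separable_table()
  m <- train_fine_tree(tab, seed = 4)
  expect_equal(m$cv_acc, 1)
  expect_equal(unname(predict(m, tab)$pred_class), tab$label)
})

test_that("shuffled labels cross-validate at chance level", {
  accs <- vapply(1:10, function(s) {
    tab <- separable_table(n_per = 30, seed = 100 + s)
    withr::with_seed(s, tab$label <- sample(tab$label))
    train_fine_tree(tab, seed = s)$cv_acc
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.05)
})

test_that("training is deterministic given the seed", {
  tab <- separable_table(seed = 9)
  m1 <- train_fine_tree(tab, seed = 7)
  m2 <- train_fine_tree(tab, seed = 7)
  expect_identical(m1$cv_acc, m2$cv_acc)
  expect_identical(m1$training_fingerprint, m2$training_fingerprint)
  expect_identical(tidy(m1), tidy(m2))
})

test_that("training contracts: folds need members, multiple classes required", {
  tab <- separable_table(n_per = 3)
  expect_error(train_fine_tree(tab, cv_folds = 5), ">= 5")
  one <- separable_table()
  one$label <- 1L
  expect_error(train_fine_tree(one), "single class")
})

test_that("leaf probabilities are normalized and pure training points return their label", {
  tab <- separable_table()
  m <- train_fine_tree(tab, seed = 2)
  pr <- predict(m, tab)
  psum <- rowSums(as.matrix(pr[, paste0("prob_", 1:4)]))
  expect_equal(psum, rep(1, nrow(tab)), tolerance = 1e-12)
  # well-separated clusters give pure leaves: own label with probability 1
  own <- vapply(seq_len(nrow(tab)),
                function(i) pr[[paste0("prob_", tab$label[i])]][i], numeric(1))
  expect_equal(own, rep(1, nrow(tab)))
  expect_error(predict(m, tab[, "label"]), "lacks feature")
})

test_that("a single-split tree routes rows by the threshold", {
  # two clearly separated groups on one feature force one split at ~10
  tab <- tibble::tibble(vol = c(rep(5, 20) + rnorm(20, 0, 0.1),
                                rep(15, 20) + rnorm(20, 0, 0.1)),
                        label = rep(c(1L, 2L), each = 20))
  attr(tab, "feature_cols") <- "vol"
  m <- train_fine_tree(tab, seed = 1)
  expect_identical(cytofuse:::n_internal_splits(m$fit), 1L)
  pred <- predict(m, tibble::tibble(vol = c(5, 15)))
  expect_identical(pred$pred_class, c(1L, 2L))
})

test_that("the split cap is honoured on hard-to-separate data", {
  withr::with_seed(31, {
    tab <- tibble::tibble(f1 = runif(600), f2 = runif(600),
                          label = sample(1:4, 600, TRUE))
    attr(tab, "feature_cols") <- c("f1", "f2")
    m <- train_fine_tree(tab, max_splits = 10L, cv_folds = 2L, seed = 3)
    expect_lte(cytofuse:::n_internal_splits(m$fit), 10L)
    m2 <- train_fine_tree(tab, max_splits = 100L, cv_folds = 2L, seed = 3)
    expect_lte(cytofuse:::n_internal_splits(m2$fit), 100L)
  })
})

test_that("metric suite follows the one-vs-rest closed forms", {
  # binary confusion with TP=8, FN=2, TN=9, FP=1 for class 1
  truth <- c(rep(1, 10), rep(2, 10))
  pred <- c(rep(1, 8), 2, 2, rep(2, 9), 1)
  ev <- evaluate_predictions(truth, pred, classes = 1:2)
  m1 <- ev$metrics[ev$metrics$class_id == 1, ]
  expect_equal(m1$tpr, 0.8)
  expect_equal(m1$tnr, 0.9)
  expect_equal(m1$fpr, 0.1)
  expect_equal(m1$fnr, 0.2)
  expect_equal(m1$acc, 0.85)
  expect_equal(ev$accuracy, 0.85)

  # perfect prediction
  evp <- evaluate_predictions(1:4, 1:4, classes = 1:4)
  expect_equal(evp$accuracy, 1)
  expect_equal(evp$confusion, diag(1L, 4),
               ignore_attr = TRUE)
  expect_true(all(evp$metrics$tpr == 1))

  expect_error(evaluate_predictions(1:3, 1:4), "mismatch")
  expect_error(evaluate_predictions(integer(), integer()), "empty")
})

test_that("metrics equal an independent counting oracle on random predictions", {
  withr::with_seed(55, {
    truth <- sample(1:4, 200, TRUE)
    pred <- sample(1:4, 200, TRUE)
    ev <- evaluate_predictions(truth, pred, classes = 1:4)
    for (k in 1:4) {
      tp <- sum(truth == k & pred == k)
      fn <- sum(truth == k & pred != k)
      fp <- sum(truth != k & pred == k)
      tn <- sum(truth != k & pred != k)
      mk <- ev$metrics[ev$metrics$class_id == k, ]
      expect_identical(c(mk$tp, mk$tn, mk$fp, mk$fn), c(tp, tn, fp, fn))
      expect_equal(mk$acc, (tp + tn) / 200)
      expect_equal(mk$tpr, tp / (tp + fn))
      expect_equal(mk$tnr, tn / (tn + fp))
    }
    expect_equal(ev$accuracy, mean(truth == pred))
    expect_identical(sum(ev$confusion), 200L)
  })
})

test_that("metric identities hold exactly on arbitrary confusion matrices", {
  withr::with_seed(19, {
    for (trial in 1:50) {
      truth <- sample(1:4, 60, TRUE)
      pred <- sample(1:4, 60, TRUE)
      m <- evaluate_predictions(truth, pred, classes = 1:4)$metrics
      expect_equal(m$tpr + m$fnr, rep(1, 4), tolerance = 1e-12)
      expect_equal(m$tnr + m$fpr, rep(1, 4), tolerance = 1e-12)
    }
  })
})

test_that("experiment rejects overlapping run ids", {
  run <- generate_run(params = tiny_params())
  expect_error(run_comparison_experiment(list(run), list(run)), "share")
})
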