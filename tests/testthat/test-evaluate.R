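random_fm <- function(n, p, seed = 1, y = NULL) {
  set.seed(seed)
  structure(list(values = matrix(rnorm(n * p), n),
                 column_labels = paste0("CH", seq_len(p), "_Band"),
                 y = if (is.null(y)) runif(n, 0.3, 1) else y,
                 trial_ids = seq_len(n)),
            class = "feature_matrix")
}

test_that("splits are disjoint, covering and sized by round-half-up", {
  scheme <- split_scheme(n_repetitions = 11, base_seed = 7)
  splits <- make_splits(48, scheme)
  expect_length(splits, 11)
  for (sp in splits) {
    expect_length(sp$train, 36) # round(0.75 * 48)
    expect_length(sp$test, 12)
    expect_identical(sort(c(sp$train, sp$test)), 1:48)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  # round-half-away-from-zero: 0.75 * 10 = 7.5 -> 8
  expect_length(make_splits(10, split_scheme())[[1]]$train, 8)
  expect_identical(make_splits(48, scheme), make_splits(48, scheme))
  expect_false(identical(splits[[1]]$train, splits[[2]]$train))
  expect_error(make_splits(7, scheme), "at least 8")
})

test_that("the aggregate MAE is the mean of per-repetition means", {
  expect_equal(mae_repeated(list(c(0.1, 0.1), c(0.2, 0.2))), 0.15)
  # unequal repetition sizes: mean-of-means differs from the pooled mean
  ae <- list(c(0.1, 0.1, 0.1, 0.1), 0.3)
  expect_equal(mae_repeated(ae), 0.2)
  expect_false(isTRUE(all.equal(mae_repeated(ae), mean(unlist(ae)))))
})

test_that("evaluation aggregates satisfy their definitions", {
  fm <- random_fm(24, 6, seed = 61)
  scheme <- split_scheme(n_repetitions = 3, base_seed = 5)
  res <- evaluate_subject(fm, model_spec("lasso"), scheme)
  reps <- res$algorithms$lasso$repetitions
  expect_length(reps, 3)
  ae <- lapply(reps, `[[`, "ae")
  expect_true(all(unlist(ae) >= 0))
  expect_equal(res$algorithms$lasso$mae_s, mae_repeated(ae))
  expect_equal(res$aggregates$mae_s, mae_repeated(ae))
  expect_equal(res$aggregates$max_ae_s, max(unlist(ae)))
  expect_equal(res$aggregates$sd_ae_s, sd(unlist(ae)))
})

test_that("evaluation is deterministic given the scheme seed", {
  fm <- random_fm(24, 6, seed = 62)
  scheme <- split_scheme(n_repetitions = 2, base_seed = 9)
  r1 <- evaluate_subject(fm, small_svr_spec(), scheme)
  r2 <- evaluate_subject(fm, small_svr_spec(), scheme)
  expect_identical(r1$aggregates, r2$aggregates)
})

test_that("a nearly noiseless linear target yields near-zero MAE", {
  set.seed(63)
  X <- matrix(rnorm(40 * 4), 40)
  y <- 0.6 + 0.3 * X[, 1]
  fm <- random_fm(40, 4)
  fm$values <- X
  fm$y <- y
  res <- evaluate_subject(fm, model_spec("lasso"),
                          split_scheme(n_repetitions = 3, base_seed = 1))
  expect_lt(res$aggregates$mae_s, 5e-3)
})

test_that("the shuffled baseline scores like a predict-the-average control", {
  set.seed(64)
  # features carry no information: constant-ish predictions are optimal
  fm <- random_fm(32, 5, seed = 64, y = 0.6 + rnorm(32, sd = 0.05))
  scheme <- split_scheme(n_repetitions = 4, base_seed = 2)
  shuf <- shuffled_baseline(fm, scheme, small_svr_spec("shuffled_svr_rbf"))
  expect_s3_class(shuf, "eval_result")
  # close to the theoretical mean absolute deviation of N(0, 0.05)
  expect_lt(abs(shuf$aggregates$mae_s - 0.05 * sqrt(2 / pi)), 0.03)
  # reproducible
  shuf2 <- shuffled_baseline(fm, scheme, small_svr_spec("shuffled_svr_rbf"))
  expect_identical(shuf$aggregates, shuf2$aggregates)
  expect_error(shuffled_baseline(fm, scheme, small_svr_spec("svr_rbf")),
               "shuffled_svr_rbf")
})

test_that("training on shuffled labels beats nothing when signal exists", {
  set.seed(65)
  X <- matrix(rnorm(48 * 6), 48)
  y <- 0.6 + 0.25 * X[, 2] + rnorm(48, sd = 0.02)
  fm <- random_fm(48, 6)
  fm$values <- X
  fm$y <- y
  scheme <- split_scheme(n_repetitions = 5, base_seed = 3)
  true_res <- evaluate_subject(fm, small_svr_spec(), scheme)
  shuf_res <- shuffled_baseline(fm, scheme, small_svr_spec("shuffled_svr_rbf"))
  expect_lt(true_res$aggregates$mae_s, 0.5 * shuf_res$aggregates$mae_s)
})

test_that("selected-feature summaries count across repetitions", {
  set.seed(66)
  X <- matrix(rnorm(30 * 4), 30)
  y <- 0.5 + 0.3 * X[, 3] + rnorm(30, sd = 0.02)
  fm <- random_fm(30, 4)
  fm$values <- X
  fm$y <- y
  scheme <- split_scheme(n_repetitions = 4, base_seed = 8)
  spec <- model_spec("svr_rbf",
                     grid = list(C = 10, gamma = 0.1, epsilon = 0.01),
                     k_grid = 1)
  res <- evaluate_subject(fm, spec, scheme)
  sel <- summarize_selected_features(res)
  # the informative feature is picked in every repetition
  expect_identical(sel$pooled$feature[1], "CH3_Band")
  expect_equal(sel$pooled$count[1], 4L)

  # no SVR in the results: empty table, not an error
  res2 <- evaluate_subject(fm, model_spec("lasso"), scheme)
  sel2 <- summarize_selected_features(res2)
  expect_equal(nrow(sel2$pooled), 0)

  # pooling across subjects sums the counts
  sel3 <- summarize_selected_features(list(a = res, b = res))
  expect_equal(sel3$pooled$count[1], 8L)
  expect_equal(nrow(sel3$per_subject), 2)
})

test_that("test-set targets never influence the fitted model", {
  fm <- random_fm(24, 5, seed = 67)
  scheme <- split_scheme(n_repetitions = 2, base_seed = 4)
  sp <- make_splits(24, scheme)[[1]]
  fm2 <- fm
  fm2$y[sp$test] <- fm2$y[sp$test] + 10 # corrupt only held-out targets
  std <- fit_standardizer(fm, sp$train)
  Z <- apply_standardizer(std, fm)$values
  f1 <- tune_and_fit(model_spec("lasso"), Z[sp$train, ], fm$y[sp$train],
                     seed = sp$seed)
  f2 <- tune_and_fit(model_spec("lasso"), Z[sp$train, ], fm2$y[sp$train],
                     seed = sp$seed)
  expect_identical(predict(f1$model, Z[sp$test, ]),
                   predict(f2$model, Z[sp$test, ]))
})
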