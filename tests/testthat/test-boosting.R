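test_that("hyperparameter sampling is sized, bounded and reproducible", {
  hp <- sample_hyperparameter_sets(seed = 2)
  expect_identical(nrow(hp), 500L)
  expect_identical(hp, sample_hyperparameter_sets(seed = 2))
  r <- default_hp_ranges()
  expect_true(all(hp$max_depth >= r$max_depth[1] & hp$max_depth <= r$max_depth[2]))
  expect_true(all(hp$n_trees >= r$n_trees[1] & hp$n_trees <= r$n_trees[2]))
  expect_true(all(hp$learning_rate >= r$learning_rate[1] &
                    hp$learning_rate <= r$learning_rate[2]))
  expect_true(all(hp$subsample >= 0.5 & hp$subsample <= 1))
  expect_error(sample_hyperparameter_sets(10, ranges = list(max_depth = 3)),
               "range")
})

test_that("a strongly prognostic gene yields transferable risk predictions", {
  truth <- synthetic_truth(30, n_informative = 1, seed = 14,
                           beta_range = c(3, 3))
  ds <- generate_cohort(300, truth, seed = 14)
  split <- stratified_split(ds, 0.3, seed = 14)
  tr <- match(split$train, ds$clinical$patient_id)
  te <- match(split$test, ds$clinical$patient_id)
  fit <- train_cox_boosting(ds$expression[tr, ], ds$clinical$time[tr],
                            ds$clinical$event[tr],
                            hp = list(n_trees = 60, max_depth = 2,
                                      learning_rate = 0.1), seed = 14)
  risks <- predict_risk(fit, ds$expression[te, ])
  expect_gt(concordance_index(risks, ds$clinical$time[te],
                              ds$clinical$event[te]), 0.7)
})

test_that("training refuses degenerate inputs", {
  m <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], c("g1", "g2")))
  expect_error(train_cox_boosting(m, rep(1:10), rep(1, 10),
                                  hp = list(n_trees = 0)), "n_trees")
  expect_error(train_cox_boosting(m, rep(1:10), rep(0, 10)), "empty event sum")
})

test_that("prediction is deterministic, row-wise, and rank-stable", {
  truth <- synthetic_truth(25, n_informative = 3, seed = 15)
  ds <- generate_cohort(80, truth, seed = 15)
  fit <- train_cox_boosting(ds$expression, ds$clinical$time, ds$clinical$event,
                            hp = list(n_trees = 20, max_depth = 2), seed = 15)
  r1 <- predict_risk(fit, ds$expression)
  r2 <- predict_risk(fit, ds$expression)
  expect_identical(r1, r2)
  # duplicated patient row scores identically
  dup <- ds$expression[c(1, 1), , drop = FALSE]
  rownames(dup) <- c("orig", "copy")
  rd <- predict_risk(fit, dup)
  expect_equal(unname(rd["orig"]), unname(rd["copy"]))
  # C-index only sees ranks: exp() leaves it unchanged
  ci1 <- concordance_index(r1, ds$clinical$time, ds$clinical$event)
  ci2 <- concordance_index(exp(r1), ds$clinical$time, ds$clinical$event)
  expect_identical(ci1, ci2)
  # missing feature genes are named in the error
  expect_error(predict_risk(fit, ds$expression[, -3, drop = FALSE]),
               colnames(ds$expression)[3])
})

test_that("training loss is non-increasing over boosting rounds", {
  truth <- synthetic_truth(40, n_informative = 5, seed = 16)
  ds <- generate_cohort(120, truth, seed = 16)
  fit <- train_cox_boosting(ds$expression, ds$clinical$time, ds$clinical$event,
                            hp = list(n_trees = 40, max_depth = 2,
                                      learning_rate = 0.1), seed = 16)
  losses <- vapply(seq_len(40), function(k) {
    cox_nll(predict_risk(fit, ds$expression, n_trees = k),
            ds$clinical$time, ds$clinical$event)
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-8))
})

test_that("permuted survival labels give chance-level prediction", {
  truth <- synthetic_truth(40, n_informative = 5, seed = 17,
                           beta_range = c(0.8, 1.2))
  cis <- vapply(1:3, function(k) {
    ds <- generate_cohort(550, truth, seed = 17 + k)
    set.seed(k)
    perm <- sample(nrow(ds$expression))
    time <- ds$clinical$time[perm]; event <- ds$clinical$event[perm]
    tr <- 1:150; te <- 151:550
    fit <- train_cox_boosting(ds$expression[tr, ], time[tr], event[tr],
                              hp = list(n_trees = 30, max_depth = 2), seed = k)
    risks <- predict_risk(fit, ds$expression[te, ])
    concordance_index(risks, time[te], event[te])
  }, numeric(1))
  expect_lt(abs(mean(cis) - 0.5), 0.05)
})

test_that("feature gain is the mean split gain and omits unused genes", {
  # two genes, one constant: every split must use the informative one
  set.seed(18)
  n <- 120
  x <- rlnorm(n)
  X <- cbind(gA = x, gB = rep(1, n))
  rownames(X) <- sprintf("p%03d", 1:n)
  time <- rexp(n, 0.01 * exp(1.2 * scale(x)[, 1])) + 1e-3
  event <- rep(1L, n)
  fit1 <- train_cox_boosting(X, time, event,
                             hp = list(n_trees = 1, max_depth = 1), seed = 18)
  g1 <- feature_gain(fit1)
  expect_identical(names(g1), "gA")
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = fit1$booster))
  expect_equal(unname(g1), dump$Gain[dump$Feature != "Leaf"])

  fit2 <- train_cox_boosting(X, time, event,
                             hp = list(n_trees = 2, max_depth = 1), seed = 18)
  g2 <- feature_gain(fit2)
  dump2 <- as.data.frame(xgboost::xgb.model.dt.tree(model = fit2$booster))
  expect_identical(names(g2), "gA")
  expect_equal(unname(g2), mean(dump2$Gain[dump2$Feature != "Leaf"]))
})
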