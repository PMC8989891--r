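oracle_cfg <- function(n_trees, depth, lr = 0.1, min_obs = 1, seed = 1) {
  brt_config(learning_rate = lr, tree_complexity = depth, bag_fraction = 1,
             max_trees = n_trees, min_obs_in_node = min_obs, seed = seed)
}

test_that("boosting matches the independent recursion oracle on the hand dataset", {
  d <- hand_dataset()
  X <- as.matrix(d[, c("x1", "x2")])
  cfg <- oracle_cfg(n_trees = 2, depth = 1, lr = 0.1, min_obs = 1)
  model <- fit_brt(d, cfg, n_trees = 2)
  want <- oracle_boost(X, d$label, n_trees = 2, depth = 1,
                       learning_rate = 0.1, min_obs = 1)
  expect_equal(unname(predict(model, d)), unname(want$prob),
               tolerance = 1e-10)
  # and after only the first tree
  expect_equal(unname(predict(model, d, n_trees = 1)),
               unname(want$prob_path[[1]]), tolerance = 1e-10)
  ri <- relative_influence(model, sort = FALSE)
  expect_equal(unname(ri), unname(want$ri), tolerance = 1e-10)
})

test_that("boosting matches the oracle on random small instances", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(12:20, 1)
    d <- data.frame(a = rnorm(n), b = runif(n), c = rnorm(n, sd = 2))
    d$label <- as.numeric(rank(d$a + rnorm(n)) > n / 2)
    if (length(unique(d$label)) < 2) next
    cfg <- oracle_cfg(n_trees = 3, depth = 2, lr = 0.2, min_obs = 2,
                      seed = seed)
    model <- fit_brt(d, cfg, n_trees = 3)
    want <- oracle_boost(as.matrix(d[, c("a", "b", "c")]), d$label,
                         n_trees = 3, depth = 2, learning_rate = 0.2,
                         min_obs = 2)
    expect_equal(unname(predict(model, d)), unname(want$prob),
                 tolerance = 1e-10)
    expect_equal(unname(relative_influence(model, sort = FALSE)),
                 unname(want$ri), tolerance = 1e-10)
  }
})

test_that("a perfectly separating binary covariate saturates predictions", {
  d <- data.frame(x = rep(c(0, 1), each = 20),
                  label = rep(c(0, 1), each = 20))
  model <- fit_brt(d, oracle_cfg(n_trees = 400, depth = 1, lr = 0.05,
                                 min_obs = 5), n_trees = 400)
  p <- predict(model, d)
  expect_true(all(p[d$label == 1] > 0.95))
  expect_true(all(p[d$label == 0] < 0.05))
})

test_that("training deviance is non-increasing without subsampling", {
  fix <- small_table(seed = 29, n_presence = 150)
  cfg <- brt_config(learning_rate = 0.1, tree_complexity = 3,
                    bag_fraction = 1, max_trees = 60, seed = 2)
  model <- fit_brt(fix$table, cfg, n_trees = 60)
  expect_true(all(diff(model$train_dev) <= 1e-12))
})

test_that("an intercept-only model predicts the base rate", {
  d <- data.frame(x = rnorm(40), label = rep(c(0, 1), 20))
  model <- fit_brt(d, oracle_cfg(1, 1), n_trees = 0)
  expect_equal(unname(predict(model, d)), rep(0.5, 40))
  expect_error(relative_influence(model), "no splits")
})

test_that("degenerate training inputs are rejected", {
  d <- data.frame(x = rnorm(30), label = rep(1, 30))
  expect_error(fit_brt(d, brt_config()), "single-class")
  d2 <- data.frame(x = c(NA, rnorm(29)), label = rep(c(0, 1), 15))
  expect_error(fit_brt(d2, brt_config()), "non-finite")
})

test_that("relative influence normalizes and ignores predictor order", {
  fix <- small_table(seed = 31, n_presence = 200)
  cfg <- brt_config(learning_rate = 0.05, tree_complexity = 3,
                    max_trees = 80, seed = 5)
  m1 <- fit_brt(fix$table, cfg, n_trees = 80)
  ri1 <- relative_influence(m1, sort = FALSE)
  expect_equal(sum(ri1), 100, tolerance = 1e-9)
  expect_true(all(ri1 >= 0))
  preds <- rev(default_predictors(fix$table))
  m2 <- fit_brt(fix$table, cfg, n_trees = 80, predictors = preds)
  ri2 <- relative_influence(m2, sort = FALSE)
  expect_equal(ri2[names(ri1)], ri1, tolerance = 1e-8)
})

test_that("predictions stay strictly inside (0,1) and respect link monotonicity", {
  fix <- small_table(seed = 37, n_presence = 150)
  cfg <- brt_config(learning_rate = 0.1, tree_complexity = 3,
                    max_trees = 50, seed = 3)
  model <- fit_brt(fix$table, cfg, n_trees = 50)
  p <- predict(model, fix$table)
  eta <- predict(model, fix$table, type = "link")
  expect_true(all(p > 0 & p < 1))
  expect_equal(order(p), order(eta))
})

test_that("partial dependence follows tree geometry and its definition", {
  # a constant covariate is never split on -> flat curve
  d <- data.frame(x = rnorm(60), z = rep(1, 60),
                  label = as.numeric(rnorm(60) + 2 * scale(rnorm(60))[, 1] > 0))
  set.seed(8)
  d$label <- as.numeric(d$x + rnorm(60, sd = 0.3) > 0)
  cfg <- oracle_cfg(n_trees = 20, depth = 1, lr = 0.1, min_obs = 5)
  model <- fit_brt(d, cfg, n_trees = 20)
  pd_flat <- partial_dependence(model, "z", grid = c(0, 1, 2))
  expect_equal(diff(pd_flat$response), c(0, 0))
  # a single depth-1 tree is a step function with the step at its threshold
  one <- fit_brt(d, oracle_cfg(1, 1, lr = 1, min_obs = 5), n_trees = 1)
  thr <- one$trees[[1]]$split[1]
  pd <- partial_dependence(one, "x",
                           grid = c(thr - 0.1, thr - 1e-9, thr + 1e-9, thr + 0.1))
  expect_equal(pd$response[1], pd$response[2])
  expect_equal(pd$response[3], pd$response[4])
  expect_true(pd$response[3] != pd$response[2])
  # fixed-at-mean mode equals direct evaluation on the constructed rows
  grid <- seq(min(d$x), max(d$x), length.out = 11)
  pd_fix <- partial_dependence(model, "x", grid = grid)
  rows <- data.frame(x = grid, z = mean(d$z))
  expect_equal(pd_fix$response, unname(predict(model, rows)))
  expect_error(partial_dependence(model, "x", grid = numeric()), "empty")
  expect_error(partial_dependence(model, "nope"), "not in model")
})

test_that("AUC is the Mann-Whitney statistic", {
  expect_equal(compute_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(compute_auc(c(1, 1, 0), c(5, 4, 1)), 1)
  expect_equal(compute_auc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
  expect_error(compute_auc(c(1, 1), c(0.2, 0.4)), "both classes")
  # agrees with pairwise enumeration, and is invariant to monotone
  # transforms of the scores
  set.seed(12)
  labels <- rep(c(0, 1), each = 15)
  scores <- rnorm(30) + labels
  expect_equal(compute_auc(labels, scores), oracle_auc(labels, scores))
  expect_equal(compute_auc(labels, plogis(scores)),
               compute_auc(labels, scores))
})

test_that("cross-validation selects few trees on noise and more on signal", {
  set.seed(44)
  n <- 200
  noise <- data.frame(a = rnorm(n), b = rnorm(n),
                      label = rep(c(0, 1), n / 2))
  cfg <- brt_config(learning_rate = 0.01, tree_complexity = 2,
                    step_size = 25, max_trees = 200, patience = 3, seed = 6)
  sel <- select_n_trees_cv(noise, cfg)
  expect_equal(sel$n_trees, 25) # the minimum checkpoint
  # held-out deviance stays near the analytic null deviance 2*entropy(pbar)
  expect_lt(abs(min(sel$profile$cv_deviance) - sel$null_deviance), 0.1)
  # informative covariate: held-out deviance beats the null
  signal <- data.frame(a = rnorm(n))
  signal$label <- as.numeric(signal$a + rnorm(n, sd = 0.5) > 0)
  cfg2 <- brt_config(learning_rate = 0.05, tree_complexity = 2,
                     step_size = 50, max_trees = 400, patience = 3, seed = 6)
  sel2 <- select_n_trees_cv(signal, cfg2)
  expect_lt(min(sel2$profile$cv_deviance), sel2$null_deviance - 0.3)
  # determinism: identical seed gives identical folds and selection
  sel3 <- select_n_trees_cv(signal, cfg2)
  expect_identical(sel2$fold, sel3$fold)
  expect_identical(sel2$n_trees, sel3$n_trees)
  expect_error(select_n_trees_cv(noise[1:5, ], cfg), "fewer rows")
})

test_that("models serialize to JSON and round-trip predictions exactly", {
  fix <- small_table(seed = 41, n_presence = 120)
  cfg <- brt_config(learning_rate = 0.1, tree_complexity = 3,
                    max_trees = 40, seed = 4)
  model <- fit_brt(fix$table, cfg, n_trees = 40)
  path <- withr::local_tempfile(fileext = ".json")
  brt_to_json(model, path)
  back <- brt_from_json(path)
  expect_equal(predict(back, fix$table), predict(model, fix$table),
               tolerance = 1e-12)
  expect_equal(relative_influence(back), relative_influence(model))
})

test_that("discrimination is comparable to an independent gradient booster", {
  library(xgboost)
  fix <- small_table(seed = 43, n_presence = 300)
  tab <- fix$table
  set.seed(9)
  tr <- sample(nrow(tab), nrow(tab) / 2)
  te <- setdiff(seq_len(nrow(tab)), tr)
  preds <- setdiff(default_predictors(tab), "soil_class")
  model <- fit_brt(tab[tr, ], brt_config(learning_rate = 0.05,
                                         tree_complexity = 3,
                                         max_trees = 200, seed = 7),
                   n_trees = 200, predictors = preds)
  auc_ours <- compute_auc(tab$label[te], predict(model, tab[te, ]))
  dtrain <- xgb.DMatrix(as.matrix(tab[tr, preds]), label = tab$label[tr])
  xgb <- xgb.train(params = list(objective = "binary:logistic", eta = 0.05,
                                 max_depth = 3),
                   data = dtrain, nrounds = 200, verbose = 0)
  auc_xgb <- compute_auc(tab$label[te],
                         predict(xgb, as.matrix(tab[te, preds])))
  expect_gt(auc_ours, 0.85)
  expect_lt(abs(auc_ours - auc_xgb), 0.05)
})
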