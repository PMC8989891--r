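# Boosted regression trees for binary presence/absence, implemented as
# stagewise Bernoulli-deviance gradient boosting: trees are fitted to the
# pointwise gradient (y - p) by exhaustive variance-reduction split search
# (in C++), terminal values are one Newton step sum(y-p)/sum(p(1-p)) within
# the node, shrunken by the learning rate and added to the additive
# log-odds model. Ten-fold cross-validation selects the tree count.

#' Boosting configuration
#'
#' @param learning_rate Shrinkage in (0, 1]; conventional default 0.01.
#' @param tree_complexity Maximum interaction depth per tree (a depth-d tree
#'   has at most 2^d - 1 splits); default 5.
#' @param bag_fraction Fraction of rows subsampled (without replacement) per
#'   boosting stage; default 0.75.
#' @param n_folds Cross-validation folds for tree-count selection (10).
#' @param step_size Trees added per cross-validation checkpoint (50).
#' @param max_trees Cap on the number of trees (1000).
#' @param min_obs_in_node Minimum rows per terminal node (10).
#' @param patience Checkpoints without improvement of the held-out deviance
#'   before cross-validation growth stops early (5).
#' @param seed Integer seed; all fold assignment and bagging randomness
#'   derives from it.
#' @return A `brt_config`.
#' @export
brt_config <- function(learning_rate = 0.01, tree_complexity = 5,
                       bag_fraction = 0.75, n_folds = 10, step_size = 50,
                       max_trees = 1000, min_obs_in_node = 10,
                       patience = 5, seed = 1L) {
  stopifnot(learning_rate > 0, learning_rate <= 1,
            tree_complexity >= 1, bag_fraction > 0, bag_fraction <= 1,
            n_folds >= 2, step_size >= 1, max_trees >= 1,
            min_obs_in_node >= 1, patience >= 1)
  structure(list(learning_rate = learning_rate,
                 tree_complexity = as.integer(tree_complexity),
                 bag_fraction = bag_fraction, n_folds = as.integer(n_folds),
                 step_size = as.integer(step_size),
                 max_trees = as.integer(max_trees),
                 min_obs_in_node = as.integer(min_obs_in_node),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "brt_config")
}

#' Default predictor columns of a design table
#'
#' Everything except the bookkeeping columns `cell_id`, `row`, `col`,
#' `label`.
#'
#' @param data A design table.
#' @return Character vector of predictor names.
#' @export
default_predictors <- function(data) {
  setdiff(names(data), c("cell_id", "row", "col", "label"))
}

# Encode a design data.frame as a numeric matrix; factors/characters become
# integer level codes 1..K (K <= 31) flagged categorical.
encode_design <- function(data, predictors, cat_levels = NULL) {
  X <- matrix(NA_real_, nrow(data), length(predictors),
              dimnames = list(NULL, predictors))
  is_cat <- logical(length(predictors))
  levels_out <- list()
  for (k in seq_along(predictors)) {
    v <- data[[predictors[k]]]
    if (is.null(v)) stop("predictor '", predictors[k], "' not in data")
    if (is.factor(v) || is.character(v)) {
      lv <- if (!is.null(cat_levels) && predictors[k] %in% names(cat_levels))
        cat_levels[[predictors[k]]] else levels(factor(v))
      if (length(lv) > 31)
        stop("categorical predictor '", predictors[k],
             "' has more than 31 levels")
      code <- match(as.character(v), lv)
      X[, k] <- as.numeric(code) # NA -> unseen level, routed by weight
      is_cat[k] <- TRUE
      levels_out[[predictors[k]]] <- lv
    } else {
      X[, k] <- as.numeric(v)
    }
  }
  list(X = X, is_cat = is_cat, cat_levels = levels_out)
}

bernoulli_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# One or more boosting stages over an existing state. The RNG state of the
# caller is used and advanced (bagging draws happen here); callers that need
# reproducibility seed before the first call.
boost_stages <- function(state, X, y, is_cat, config, n_stages,
                         keep_trees = TRUE, Xv = NULL, yv = NULL) {
  n <- nrow(X)
  # alphabetical-name rank as split tie-break priority: deterministic and
  # independent of the column order the caller happened to use
  pref <- match(colnames(X), sort(colnames(X)))
  m <- if (config$bag_fraction < 1) max(1L, round(config$bag_fraction * n)) else n
  for (s in seq_len(n_stages)) {
    p <- plogis(state$F)
    z <- y - p
    bag <- if (config$bag_fraction < 1) sample.int(n, m) else seq_len(n)
    tree <- .grow_tree_cpp(X, is_cat, z, bag - 1L,
                           config$tree_complexity, config$min_obs_in_node,
                           pref)
    leaf_bag <- tree$leaf_of_bag + 1L
    w <- p * (1 - p)
    num <- rowsum(z[bag], leaf_bag)
    den <- rowsum(w[bag], leaf_bag)
    gamma <- as.vector(num / den)
    ids <- as.integer(rownames(num))
    tree$value[ids] <- gamma
    tree$leaf_of_bag <- NULL
    leaf_all <- .tree_leaf_cpp(tree, X, is_cat) + 1L
    state$F <- state$F + config$learning_rate * tree$value[leaf_all]
    state$train_dev <- c(state$train_dev, bernoulli_deviance(y, plogis(state$F)))
    if (!is.null(Xv)) {
      leaf_v <- .tree_leaf_cpp(tree, Xv, is_cat) + 1L
      state$Fv <- state$Fv + config$learning_rate * tree$value[leaf_v]
      state$valid_dev <- c(state$valid_dev,
                           bernoulli_deviance(yv, plogis(state$Fv)))
    }
    if (keep_trees) state$trees[[length(state$trees) + 1L]] <- tree
    state$n_trees <- state$n_trees + 1L
  }
  state
}

new_boost_state <- function(y, yv = NULL) {
  pbar <- mean(y)
  if (pbar <= 0 || pbar >= 1) stop("training labels are single-class")
  f0 <- log(pbar / (1 - pbar))
  list(F = rep(f0, length(y)), Fv = if (!is.null(yv)) rep(f0, length(yv)),
       intercept = f0, trees = list(), n_trees = 0L,
       train_dev = numeric(), valid_dev = numeric())
}

#' Fit a boosted regression tree model
#'
#' @param data Design table with a 0/1 `label` column and predictor columns
#'   (factors are treated as categorical); typically from
#'   [extract_covariates()].
#' @param config A [brt_config()].
#' @param n_trees Number of boosting stages (default `config$max_trees`);
#'   normally chosen beforehand with [select_n_trees_cv()].
#' @param predictors Predictor column names (default: everything except
#'   `cell_id`, `row`, `col`, `label`).
#' @return A `brt_model`: intercept, tree list (each tree records split
#'   variables, thresholds or level subsets, squared-error improvements and
#'   terminal log-odds values), encoding metadata, training summaries.
#' @export
fit_brt <- function(data, config = brt_config(), n_trees = config$max_trees,
                    predictors = NULL) {
  if (is.null(predictors)) predictors <- default_predictors(data)
  y <- data$label
  if (is.null(y)) stop("data must contain a 'label' column")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2) stop("training labels are single-class")
  enc <- encode_design(data, predictors)
  cont <- enc$X[, !enc$is_cat, drop = FALSE]
  if (length(cont) && any(!is.finite(cont))) stop("non-finite covariates")
  if (nrow(enc$X) < 2 * config$min_obs_in_node)
    stop("too few rows: need at least 2 * min_obs_in_node")
  set.seed(config$seed)
  state <- new_boost_state(y)
  state <- boost_stages(state, enc$X, y, enc$is_cat, config, n_trees)
  train_means <- colMeans(enc$X[, !enc$is_cat, drop = FALSE])
  modes <- lapply(which(enc$is_cat), function(k) {
    tb <- table(enc$X[, k])
    as.numeric(names(tb)[which.max(tb)])
  })
  names(modes) <- colnames(enc$X)[enc$is_cat]
  structure(list(intercept = state$intercept, trees = state$trees,
                 n_trees = state$n_trees,
                 feature_names = predictors, is_cat = enc$is_cat,
                 cat_levels = enc$cat_levels, config = config,
                 train_dev = state$train_dev,
                 train_means = train_means, train_modes = modes,
                 train_ranges = apply(enc$X, 2, range, na.rm = TRUE),
                 X = enc$X, y = y),
            class = "brt_model")
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf("brt_model: %d trees (lr %g, depth %d), %d predictors, %d rows\n",
              x$n_trees, x$config$learning_rate, x$config$tree_complexity,
              length(x$feature_names), length(x$y)))
  invisible(x)
}

#' Predict suitability probabilities from a fitted model
#'
#' Inverse logit of intercept + learning_rate * sum of tree outputs.
#' Unseen categorical levels are routed to the heavier child at each split.
#'
#' @param object A `brt_model`.
#' @param newdata data.frame with the model's predictor columns, or an
#'   already-encoded numeric matrix.
#' @param n_trees Use only the first `n_trees` trees (default all).
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... Unused.
#' @return Numeric vector; strictly inside (0, 1) for `"response"`.
#' @export
predict.brt_model <- function(object, newdata, n_trees = object$n_trees,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) {
    X <- newdata
  } else {
    X <- encode_design(newdata, object$feature_names,
                       cat_levels = object$cat_levels)$X
  }
  eta <- .predict_trees_cpp(object$trees, X, object$is_cat, object$intercept,
                            object$config$learning_rate, as.integer(n_trees))
  if (type == "link") eta else plogis(eta)
}

#' Relative influence of each predictor
#'
#' Per variable, the squared-error improvements of every split using it are
#' summed across the first `n_trees` trees and normalized to percentages
#' summing to 100 (the "relative contribution" of suitability modelling).
#'
#' @param model A `brt_model`.
#' @param n_trees Trees to include (default all).
#' @param sort Return in decreasing order (default TRUE).
#' @return Named numeric vector of percentages.
#' @export
relative_influence <- function(model, n_trees = model$n_trees, sort = TRUE) {
  stopifnot(inherits(model, "brt_model"))
  ri <- setNames(numeric(length(model$feature_names)), model$feature_names)
  for (tree in model$trees[seq_len(min(n_trees, model$n_trees))]) {
    internal <- tree$var >= 0
    if (!any(internal)) next
    sums <- rowsum(tree$improve[internal], tree$var[internal] + 1L)
    ri[as.integer(rownames(sums))] <- ri[as.integer(rownames(sums))] + sums
  }
  if (sum(ri) <= 0) stop("model contains no splits")
  ri <- 100 * ri / sum(ri)
  if (sort) ri <- ri[order(-ri)]
  ri
}

#' Partial dependence of the response on one predictor
#'
#' Default mode holds every other continuous predictor at its training mean
#' (categoricals at their mode) and sweeps the target variable over a grid;
#' `mode = "average"` instead averages predictions over the training rows
#' with the target variable substituted.
#'
#' @param model A `brt_model`.
#' @param variable Predictor name.
#' @param grid Values to sweep (default: 50 equal steps over the training
#'   range; all levels for a categorical).
#' @param mode `"fixed"` or `"average"`.
#' @return data.frame with columns `value` (ascending) and `response`
#'   (probability scale).
#' @export
partial_dependence <- function(model, variable, grid = NULL,
                               mode = c("fixed", "average")) {
  mode <- match.arg(mode)
  k <- match(variable, model$feature_names)
  if (is.na(k)) stop("variable '", variable, "' not in model")
  if (is.null(grid)) {
    if (model$is_cat[k]) {
      grid <- seq_along(model$cat_levels[[variable]])
    } else {
      rng <- model$train_ranges[, k]
      grid <- seq(rng[1], rng[2], length.out = 50)
    }
  }
  if (length(grid) == 0) stop("empty partial-dependence grid")
  grid <- sort(as.numeric(grid))
  if (mode == "fixed") {
    base <- numeric(length(model$feature_names))
    names(base) <- model$feature_names
    base[!model$is_cat] <- model$train_means[model$feature_names[!model$is_cat]]
    for (nm in names(model$train_modes)) base[nm] <- model$train_modes[[nm]]
    X <- matrix(rep(base, each = length(grid)), nrow = length(grid),
                dimnames = list(NULL, model$feature_names))
    X[, k] <- grid
    resp <- predict(model, X)
  } else {
    resp <- vapply(grid, function(v) {
      X <- model$X
      X[, k] <- v
      mean(predict(model, X))
    }, numeric(1))
  }
  data.frame(value = grid, response = resp)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' P(score of a random presence > score of a random absence) + half the tie
#' probability, computed exactly from midranks.
#'
#' @param labels 0/1 vector (both classes required).
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select the number of trees by stratified cross-validation
#'
#' Fold assignment is stratified by label. Every fold's model grows in
#' increments of `step_size` trees; the mean held-out Bernoulli deviance is
#' recorded at each checkpoint and growth stops once the profile has not
#' improved for `patience` checkpoints. The selected count minimizes the
#' mean held-out deviance over the visited checkpoints.
#'
#' @param data Design table as for [fit_brt()].
#' @param config A [brt_config()].
#' @param predictors Predictor columns (default as in [fit_brt()]).
#' @return list: `n_trees` (selected), `profile` (data.frame `trees`,
#'   `cv_deviance`), `fold` (per-row fold id), `null_deviance`.
#' @export
select_n_trees_cv <- function(data, config = brt_config(), predictors = NULL) {
  if (is.null(predictors)) predictors <- default_predictors(data)
  y <- as.numeric(data$label)
  n <- length(y)
  if (n < config$n_folds) stop("fewer rows than folds")
  enc <- encode_design(data, predictors)
  set.seed(config$seed)
  fold <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(config$n_folds), length(idx))
  }
  states <- vector("list", config$n_folds)
  folds_data <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f
    folds_data[[f]] <- list(X = enc$X[tr, , drop = FALSE], y = y[tr],
                            Xv = enc$X[!tr, , drop = FALSE], yv = y[!tr])
    set.seed(config$seed + 1009L * f)
    states[[f]] <- new_boost_state(y[tr], folds_data[[f]]$yv)
    states[[f]]$rng <- .Random.seed
  }
  checkpoints <- integer(); cv_dev <- numeric()
  best <- Inf; best_ck <- 0L; since_best <- 0L
  total <- 0L
  while (total < config$max_trees) {
    step <- min(config$step_size, config$max_trees - total)
    total <- total + step
    for (f in seq_len(config$n_folds)) {
      assign(".Random.seed", states[[f]]$rng, envir = globalenv())
      fd <- folds_data[[f]]
      states[[f]] <- boost_stages(states[[f]], fd$X, fd$y, enc$is_cat, config,
                                  step, keep_trees = FALSE,
                                  Xv = fd$Xv, yv = fd$yv)
      states[[f]]$rng <- .Random.seed
    }
    # weight folds by held-out size for an overall mean deviance
    nv <- vapply(folds_data, function(fd) length(fd$yv), numeric(1))
    dev <- sum(vapply(states, function(s) s$valid_dev[total], numeric(1)) * nv) /
      sum(nv)
    checkpoints <- c(checkpoints, total)
    cv_dev <- c(cv_dev, dev)
    if (dev < best - 1e-12) {
      best <- dev; best_ck <- total; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  pbar <- mean(y)
  list(n_trees = best_ck,
       profile = data.frame(trees = checkpoints, cv_deviance = cv_dev),
       fold = fold,
       null_deviance = -2 * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar)))
}

#' Fit with cross-validated tree-count selection
#'
#' The `gbm.step`-style workflow: select the tree count by
#' [select_n_trees_cv()], then fit a final model with that many trees on all
#' rows.
#'
#' @inheritParams select_n_trees_cv
#' @return A `brt_model` with the selection result attached as `$cv`.
#' @export
fit_brt_cv <- function(data, config = brt_config(), predictors = NULL) {
  sel <- select_n_trees_cv(data, config, predictors)
  model <- fit_brt(data, config, n_trees = sel$n_trees, predictors = predictors)
  model$cv <- sel
  model
}

#' Serialize a fitted model to JSON
#'
#' Stores trees (split variables, thresholds, categorical level masks,
#' children, improvements, terminal values), encoding metadata and the
#' configuration, sufficient for exact prediction round-trips.
#'
#' @param model A `brt_model`.
#' @param path Optional file path; if NULL the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
brt_to_json <- function(model, path = NULL) {
  payload <- list(
    intercept = model$intercept, n_trees = model$n_trees,
    feature_names = model$feature_names, is_cat = model$is_cat,
    cat_levels = model$cat_levels,
    config = unclass(model$config),
    train_means = as.list(model$train_means),
    train_modes = model$train_modes,
    trees = lapply(model$trees, function(t)
      t[c("var", "split", "lmask", "smask", "left", "right",
          "improve", "n", "n_left", "n_right", "value")]))
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Restore a model serialized with [brt_to_json()]
#'
#' @param path File path or JSON string.
#' @return A `brt_model` usable with [predict.brt_model()],
#'   [relative_influence()] and fixed-mode [partial_dependence()] (training
#'   rows are not serialized, so `mode = "average"` is unavailable).
#' @export
brt_from_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  trees <- lapply(p$trees, function(t) {
    t$var <- as.integer(t$var); t$left <- as.integer(t$left)
    t$right <- as.integer(t$right); t$n <- as.integer(t$n)
    t$n_left <- as.integer(t$n_left); t$n_right <- as.integer(t$n_right)
    t$split <- as.numeric(t$split); t$lmask <- as.numeric(t$lmask)
    t$smask <- as.numeric(t$smask); t$improve <- as.numeric(t$improve)
    t$value <- as.numeric(t$value)
    t
  })
  cfg <- do.call(brt_config, p$config)
  structure(list(intercept = p$intercept, trees = trees,
                 n_trees = as.integer(p$n_trees),
                 feature_names = p$feature_names,
                 is_cat = as.logical(p$is_cat),
                 cat_levels = p$cat_levels, config = cfg,
                 train_means = unlist(p$train_means),
                 train_modes = p$train_modes,
                 train_ranges = NULL, X = NULL, y = NULL),
            class = "brt_model")
}
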