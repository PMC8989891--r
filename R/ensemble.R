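# Bootstrapped BRT ensemble: repeated stratified 50/50 train/test splits,
# per-member CV tree selection, suitability prediction over the raster
# stack, pixel-wise mean and population-SD aggregation.

#' Predict a fitted model over a raster stack
#'
#' Valid cells (no NoData in any layer) are encoded with the model's
#' training scheme and predicted in row chunks; the chunking only bounds
#' memory and does not affect the result.
#'
#' @param model A `brt_model`.
#' @param stack An `env_stack` whose layer names cover the model's
#'   predictors.
#' @param chunk_rows Grid rows per prediction chunk (default 128).
#' @return A `geo_layer` of probabilities; NoData propagated.
#' @export
predict_stack <- function(model, stack, chunk_rows = 128) {
  stopifnot(inherits(model, "brt_model"), inherits(stack, "env_stack"))
  missing <- setdiff(model$feature_names, names(stack$layers))
  if (length(missing))
    stop("stack lacks predictor layer(s): ", paste(missing, collapse = ", "))
  g <- stack$grid
  ok <- valid_mask(stack)
  out <- matrix(NA_real_, g$nrow, g$ncol)
  starts <- seq(1, g$nrow, by = chunk_rows)
  for (s in starts) {
    rows <- s:min(s + chunk_rows - 1, g$nrow)
    okc <- ok[rows, , drop = FALSE]
    if (!any(okc)) next
    idx <- which(okc, arr.ind = TRUE)
    X <- matrix(NA_real_, nrow(idx), length(model$feature_names),
                dimnames = list(NULL, model$feature_names))
    for (k in seq_along(model$feature_names)) {
      nm <- model$feature_names[k]
      vals <- stack$layers[[nm]][rows, , drop = FALSE][idx]
      if (model$is_cat[k]) {
        code <- match(as.character(vals), model$cat_levels[[nm]])
        X[, k] <- as.numeric(code)
      } else {
        X[, k] <- vals
      }
    }
    pr <- predict(model, X)
    sub <- out[rows, , drop = FALSE]
    sub[idx] <- pr
    out[rows, ] <- sub
  }
  geo_layer(out, g)
}

#' Run the bootstrapped suitability ensemble
#'
#' For each of `n_models` members: draw a label-stratified 50% training
#' split (or, with `with_replacement = TRUE`, a bootstrap resample of rows
#' with the out-of-bag rows as the test set), select the tree count by
#' ten-fold cross-validation on the training half, fit, record training and
#' testing AUC, and predict suitability over the stack. Member predictions
#' are aggregated pixel-wise into a mean map and a population-SD (ddof 0)
#' uncertainty map.
#'
#' @param table Design table from [extract_covariates()].
#' @param stack An `env_stack` to predict over.
#' @param config A [brt_config()] (its seed is overridden per member).
#' @param n_models Ensemble size (default 30; must be >= 2 for the SD).
#' @param train_fraction Training share of each split (default 0.5).
#' @param seed Master seed; member m uses derived seed `seed + 7919 * m`.
#' @param with_replacement Bootstrap rows instead of re-splitting.
#' @param cv_select Select tree count per member by CV (default TRUE);
#'   FALSE fits `config$max_trees` trees directly.
#' @param chunk_rows Passed to [predict_stack()].
#' @return An `ensemble_result`: `mean` and `sd` geo_layers, `train_auc`,
#'   `test_auc`, `n_trees` vectors, `auc_summary`, `member_predictions`
#'   (cells x members matrix over valid cells), `seed`.
#' @export
run_ensemble <- function(table, stack, config = brt_config(), n_models = 30,
                         train_fraction = 0.5, seed = 1L,
                         with_replacement = FALSE, cv_select = TRUE,
                         chunk_rows = 128) {
  if (n_models < 2) stop("n_models must be >= 2 (ensemble SD undefined)")
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- table$label
  if (length(unique(y)) < 2) stop("both labels required")
  g <- stack$grid
  ok <- valid_mask(stack)
  n_valid <- sum(ok)
  preds <- matrix(NA_real_, n_valid, n_models)
  train_auc <- numeric(n_models); test_auc <- numeric(n_models)
  n_trees <- integer(n_models)
  for (m in seq_len(n_models)) {
    member_seed <- as.integer(seed + 7919 * m)
    set.seed(member_seed)
    repeat {
      if (with_replacement) {
        tr_idx <- sample.int(nrow(table), nrow(table), replace = TRUE)
        te_idx <- setdiff(seq_len(nrow(table)), unique(tr_idx))
      } else {
        tr_idx <- unlist(lapply(unique(y), function(cls) {
          idx <- which(y == cls)
          sample(idx, round(train_fraction * length(idx)))
        }))
        te_idx <- setdiff(seq_len(nrow(table)), tr_idx)
      }
      if (length(unique(y[tr_idx])) == 2 && length(unique(y[te_idx])) == 2)
        break
      message("member ", m, ": single-class split, resampling")
    }
    cfg <- config
    cfg$seed <- member_seed + 1L
    train <- table[tr_idx, , drop = FALSE]
    model <- if (cv_select) fit_brt_cv(train, cfg) else
      fit_brt(train, cfg, n_trees = cfg$max_trees)
    n_trees[m] <- model$n_trees
    train_auc[m] <- compute_auc(y[tr_idx], predict(model, train))
    test_auc[m] <- compute_auc(y[te_idx],
                               predict(model, table[te_idx, , drop = FALSE]))
    preds[, m] <- predict_stack(model, stack, chunk_rows)$values[ok]
  }
  mean_map <- matrix(NA_real_, g$nrow, g$ncol)
  sd_map <- matrix(NA_real_, g$nrow, g$ncol)
  mean_map[ok] <- rowMeans(preds)
  sd_map[ok] <- sqrt(rowMeans((preds - rowMeans(preds))^2)) # population SD
  structure(list(mean = geo_layer(mean_map, g), sd = geo_layer(sd_map, g),
                 train_auc = train_auc, test_auc = test_auc,
                 n_trees = n_trees,
                 auc_summary = list(train_auc_mean = mean(train_auc),
                                    train_auc_sd = sd(train_auc),
                                    test_auc_mean = mean(test_auc),
                                    test_auc_sd = sd(test_auc)),
                 member_predictions = preds, seed = seed),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  s <- x$auc_summary
  cat(sprintf(paste0("ensemble_result: %d members; train AUC %.3f +/- %.3f, ",
                     "test AUC %.3f +/- %.3f\n"),
              length(x$train_auc), s$train_auc_mean, s$train_auc_sd,
              s$test_auc_mean, s$test_auc_sd))
  invisible(x)
}

#' Write the ensemble AUC summary as JSON
#' @param result An `ensemble_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_auc_summary <- function(result, path) {
  jsonlite::write_json(result$auc_summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
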