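# Independent literal transcription of the boosting recursion, written as
# straight-line loops with no shared code with the package internals. Used
# to freeze expected predictions/influences for small instances
# (continuous predictors, bag fraction 1).

oracle_grow <- function(X, z, idx, depth, min_obs) {
  n <- length(idx)
  best <- list(gain = 0, var = NA, thr = NA)
  if (depth >= 1 && n >= 2 * min_obs) {
    S <- 0
    for (i in idx) S <- S + z[i]
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[idx, j]))
      if (length(xs) < 2) next
      for (k in seq_len(length(xs) - 1)) {
        thr <- (xs[k] + xs[k + 1]) / 2
        SL <- 0; nL <- 0
        for (i in idx) if (X[i, j] < thr) { SL <- SL + z[i]; nL <- nL + 1 }
        nR <- n - nL
        if (nL < min_obs || nR < min_obs) next
        SR <- S - SL
        gain <- SL^2 / nL + SR^2 / nR - S^2 / n
        if (gain > best$gain) best <- list(gain = gain, var = j, thr = thr)
      }
    }
  }
  if (is.na(best$var))
    return(list(leaf = TRUE, idx = idx))
  lidx <- idx[X[idx, best$var] < best$thr]
  ridx <- idx[X[idx, best$var] >= best$thr]
  list(leaf = FALSE, var = best$var, thr = best$thr, gain = best$gain,
       left = oracle_grow(X, z, lidx, depth - 1, min_obs),
       right = oracle_grow(X, z, ridx, depth - 1, min_obs))
}

oracle_leaf_value <- function(tree, z, w) {
  if (tree$leaf) {
    num <- 0; den <- 0
    for (i in tree$idx) { num <- num + z[i]; den <- den + w[i] }
    tree$value <- num / den
  } else {
    tree$left <- oracle_leaf_value(tree$left, z, w)
    tree$right <- oracle_leaf_value(tree$right, z, w)
  }
  tree
}

oracle_tree_predict <- function(tree, X, i) {
  while (!tree$leaf) {
    tree <- if (X[i, tree$var] < tree$thr) tree$left else tree$right
  }
  tree$value
}

oracle_tree_gains <- function(tree, gains) {
  if (tree$leaf) return(gains)
  gains[tree$var] <- gains[tree$var] + tree$gain
  gains <- oracle_tree_gains(tree$left, gains)
  oracle_tree_gains(tree$right, gains)
}

# Full boosting recursion: returns per-row probabilities after each tree
# and the per-variable summed split improvements.
oracle_boost <- function(X, y, n_trees, depth, learning_rate, min_obs) {
  n <- nrow(X)
  pbar <- mean(y)
  f <- rep(log(pbar / (1 - pbar)), n)
  gains <- numeric(ncol(X))
  prob_path <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    p <- 1 / (1 + exp(-f))
    z <- y - p
    w <- p * (1 - p)
    tree <- oracle_grow(X, z, seq_len(n), depth, min_obs)
    tree <- oracle_leaf_value(tree, z, w)
    gains <- oracle_tree_gains(tree, gains)
    for (i in seq_len(n))
      f[i] <- f[i] + learning_rate * oracle_tree_predict(tree, X, i)
    prob_path[[t]] <- 1 / (1 + exp(-f))
  }
  ri <- if (sum(gains) > 0) 100 * gains / sum(gains) else gains
  list(prob = 1 / (1 + exp(-f)), prob_path = prob_path, ri = ri)
}

# Exact pairwise AUC by enumeration (independent of the rank formulation).
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}
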