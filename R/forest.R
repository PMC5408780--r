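# A compact bagged-tree classifier (gini-split CART on bootstrap samples
# with random feature subsets).  Used only as a transfer-learning baseline
# on extracted deep features; no random-forest package is assumed in the
# runtime environment.

tree_build <- function(X, y, idx, depth, max_depth, min_node, mtry,
                       classes) {
  counts <- tabulate(match(y[idx], classes), length(classes))
  leaf <- list(leaf = TRUE, class = classes[which.max(counts)])
  if (depth >= max_depth || length(idx) < 2 * min_node ||
      max(counts) == length(idx))
    return(leaf)
  p <- ncol(X)
  feats <- sample.int(p, min(mtry, p))
  best <- NULL; best_gain <- 0
  n <- length(idx)
  gini <- function(cnt) 1 - sum((cnt / max(sum(cnt), 1))^2)
  parent_g <- gini(counts)
  for (f in feats) {
    v <- X[idx, f]
    qs <- unique(quantile(v, c(0.25, 0.5, 0.75), names = FALSE))
    for (thr in qs) {
      left <- v <= thr
      nl <- sum(left)
      if (nl < min_node || n - nl < min_node) next
      cl <- tabulate(match(y[idx[left]], classes), length(classes))
      cr <- counts - cl
      gain <- parent_g - (nl / n) * gini(cl) - ((n - nl) / n) * gini(cr)
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(f = f, thr = thr, left = idx[left], right = idx[!left])
      }
    }
  }
  if (is.null(best)) return(leaf)
  list(leaf = FALSE, f = best$f, thr = best$thr,
       l = tree_build(X, y, best$left, depth + 1L, max_depth, min_node,
                      mtry, classes),
       r = tree_build(X, y, best$right, depth + 1L, max_depth, min_node,
                      mtry, classes))
}

tree_predict_one <- function(node, x) {
  while (!node$leaf) node <- if (x[node$f] <= node$thr) node$l else node$r
  node$class
}

rf_fit <- function(X, y, ntree = 60L, mtry = NULL, max_depth = 8L,
                   min_node = 1L, seed = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- with_seed(seed, {
    lapply(seq_len(ntree), function(t) {
      boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
      tree_build(X, y, boot, 0L, max_depth, min_node, mtry, classes)
    })
  })
  structure(list(trees = trees, classes = classes), class = "locnet_rf")
}

rf_predict <- function(rf, X) {
  X <- as.matrix(X)
  votes <- matrix(0L, nrow(X), length(rf$classes))
  for (tr in rf$trees) {
    for (i in seq_len(nrow(X))) {
      k <- match(tree_predict_one(tr, X[i, ]), rf$classes)
      votes[i, k] <- votes[i, k] + 1L
    }
  }
  rf$classes[max.col(votes, ties.method = "first")]
}
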