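#' Per-cell prediction with five-crop averaging
#'
#' For each 64x64 normalized crop, predictions are the arithmetic mean of
#' the network outputs over the five deterministic evaluation patches
#' (center and four corners, see [eval_crops()]).  Cells are processed in
#' chunks to bound memory.
#'
#' @param network a trained `locnet_network` with a `class_vocab`.
#' @param crops `(S, S, C, N)` normalized array, or list of `cell_crop`s.
#' @param cells optional data.frame with one row per cell (`cell_id`,
#'   optionally `protein_id`, `condition`, ...); carried into the output.
#' @param chunk cells per forward chunk.
#' @return a `prediction_table`: data.frame with the metadata columns and
#'   one `p_<class>` probability column per class (rows sum to 1).
#' @export
predict_cells <- function(network, crops, cells = NULL, chunk = 200L) {
  if (is.list(crops) && !is.array(crops)) crops <- stack_crops(crops)$x
  d <- dim(crops)
  if (length(d) == 3L) { dim(crops) <- c(d, 1L); d <- dim(crops) }
  vocab <- network$class_vocab
  if (is.null(vocab))
    vocab <- paste0("class", seq_len(network$config$n_classes))
  patch <- network$config$input_size
  if (d[1] < patch)
    stop_locnet("shape", "crops (%d px) smaller than network input (%d px)",
                d[1], patch)
  offs <- eval_offsets(d[1], patch)
  n <- d[4]
  probs <- matrix(0, n, length(vocab))
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    nb <- j - i + 1L
    batch <- array(0, c(patch, patch, d[3], nb * 5L))
    for (k in seq_along(offs)) {
      o <- offs[[k]]
      batch[, , , ((k - 1L) * nb + 1L):(k * nb)] <-
        crops[(o[1] + 1):(o[1] + patch), (o[2] + 1):(o[2] + patch), ,
              i:j, drop = FALSE]
    }
    p <- forward(network, batch, mode = "eval")
    acc <- matrix(0, nb, length(vocab))
    for (k in seq_along(offs))
      acc <- acc + p[((k - 1L) * nb + 1L):(k * nb), , drop = FALSE]
    probs[i:j, ] <- acc / 5
    i <- j + 1L
  }
  colnames(probs) <- paste0("p_", vocab)
  if (is.null(cells)) cells <- data.frame(cell_id = as.character(seq_len(n)))
  stopifnot(nrow(cells) == n)
  out <- cbind(as.data.frame(cells, stringsAsFactors = FALSE),
               as.data.frame(probs))
  attr(out, "classes") <- vocab
  class(out) <- c("prediction_table", "data.frame")
  out
}

prediction_classes <- function(table) {
  cls <- attr(table, "classes")
  if (is.null(cls))
    cls <- sub("^p_", "", grep("^p_", names(table), value = TRUE))
  cls
}

#' Aggregate per-cell predictions into protein/well profiles
#'
#' The localization profile of a protein (or well) is the unweighted mean
#' of its cells' probability vectors, one mean per localization category.
#' If the table carries a per-cell `green_mean` column, its mean is
#' reported as the protein's mean abundance `I_g`.
#'
#' @param table a `prediction_table`.
#' @param by grouping column name (default `"protein_id"`).
#' @return data.frame with one row per group: `protein_id`, `n_cells`,
#'   the mean `p_<class>` columns, and `I_g` when available.
#' @export
aggregate_protein <- function(table, by = "protein_id") {
  if (!(by %in% names(table)))
    stop_locnet("data", "grouping column '%s' not present", by)
  cls <- prediction_classes(table)
  pcols <- paste0("p_", cls)
  groups <- table[[by]]
  if (anyNA(groups))
    stop_locnet("data", "every cell must be mapped to a group")
  groups <- factor(groups)
  valcols <- c(pcols, intersect("green_mean", names(table)))
  vm <- as.matrix(table[, valcols, drop = FALSE])
  n <- as.vector(base::table(groups))
  means <- rowsum(vm, groups, reorder = TRUE) / n
  out <- data.frame(levels(groups), n_cells = n,
                    as.data.frame(means), stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[1] <- by
  if ("green_mean" %in% names(out))
    names(out)[names(out) == "green_mean"] <- "I_g"
  attr(out, "classes") <- cls
  out
}

#' Average precision (area under the precision-recall curve)
#'
#' Items are ranked by descending score (ties broken by original position,
#' a stable deterministic order) and AP is accumulated step-wise:
#' `AP = sum over positives of precision-at-that-rank / n_positives`,
#' the area under the PR curve traced rank by rank.  AP is invariant to
#' strictly monotone transformations of the scores.
#'
#' @param scores numeric scores, higher = more confident positive.
#' @param labels binary labels (logical or 0/1).
#' @return AP in `[0, 1]`; `NA` with a warning when there are no
#'   positives.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels)
  if (npos == 0) {
    warning("no positive labels; AP undefined", call. = FALSE)
    return(NA_real_)
  }
  ord <- order(-scores)                 # stable: ties keep original order
  hits <- labels[ord]
  prec <- cumsum(hits) / seq_along(hits)
  sum(prec[hits]) / npos
}

#' Mean average precision across classes
#'
#' @param scores `n x K` matrix of per-class scores (e.g. mean class
#'   probabilities per protein).
#' @param labels `n x K` binary matrix of per-class ground truth.
#' @return list with `per_class` (named APs, `NA` where undefined) and
#'   `mean_ap` (unweighted mean over defined classes).
#' @export
mean_average_precision <- function(scores, labels) {
  stopifnot(all(dim(scores) == dim(labels)))
  K <- ncol(scores)
  ap <- numeric(K)
  for (k in seq_len(K)) {
    ap[k] <- if (sum(labels[, k]) == 0) {
      warning(sprintf("class %d has no positives; skipped", k),
              call. = FALSE)
      NA_real_
    } else average_precision(scores[, k], labels[, k])
  }
  names(ap) <- colnames(scores)
  list(per_class = ap, mean_ap = mean(ap, na.rm = TRUE))
}

#' Confusion matrix and per-class accuracies
#'
#' Rows are true classes, columns predicted classes; each row is
#' normalized to the fraction of that class's cells predicted in each
#' column.  Per-class accuracy is the diagonal; the overall figure is the
#' unweighted mean of per-class accuracies (robust to class imbalance).
#'
#' @param table a `prediction_table`.
#' @param truth character vector of true labels, one per row of `table`.
#' @return list with `matrix` (row-normalized), `counts`,
#'   `per_class_accuracy`, and `average_accuracy`.
#' @export
confusion_matrix <- function(table, truth) {
  cls <- prediction_classes(table)
  stopifnot(length(truth) == nrow(table))
  bad <- setdiff(unique(truth), cls)
  if (length(bad))
    stop_locnet("data", "truth label(s) outside vocabulary: %s",
                paste(bad, collapse = ", "))
  probs <- as.matrix(table[, paste0("p_", cls)])
  pred <- cls[max.col(probs, ties.method = "first")]
  counts <- table(factor(truth, levels = cls), factor(pred, levels = cls))
  counts <- matrix(as.integer(counts), length(cls), length(cls),
                   dimnames = list(true = cls, predicted = cls))
  rs <- rowSums(counts)
  norm <- counts / ifelse(rs == 0, 1, rs)
  per_class <- diag(norm)
  per_class[rs == 0] <- NA_real_
  list(matrix = norm, counts = counts, per_class_accuracy = per_class,
       average_accuracy = mean(per_class, na.rm = TRUE))
}
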