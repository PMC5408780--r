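# Two-condition change detection: Welch's t localization-change scores per
# (protein, class), Gaussian + uniform outlier-mixture calibration with a
# fixed 1% outlier prior, log2 abundance fold changes, and flux-network
# construction.

#' Welch's t statistic for a per-class localization change
#'
#' `t = (mean(b) - mean(a)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with unbiased
#' (n-1) sample variances.  Positive values mean an increase in condition
#' B.  Returns `NA` when either sample has fewer than `min_cells`
#' observations or both variances are zero (the caller flags and skips
#' such pairs).
#'
#' @param a per-cell class probabilities in condition A.
#' @param b per-cell class probabilities in condition B.
#' @param min_cells minimum observations per sample (screen pipelines use
#'   5; the statistic itself needs 2).
#' @return the t statistic, or `NA_real_`.
#' @export
welch_t <- function(a, b, min_cells = 2L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < min_cells || length(b) < min_cells) return(NA_real_)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) return(NA_real_)
  (mean(b) - mean(a)) / sqrt(va / length(a) + vb / length(b))
}

#' Fit a Gaussian + uniform outlier mixture to change scores
#'
#' Background scores are modeled by a Gaussian with free mean and
#' variance; outliers by a uniform over the observed score range (padded
#' by a fraction `pad` of the range, so the density is proper).  The
#' outlier weight is fixed at `pi_out` (1% by default) and not
#' re-estimated; EM updates only the Gaussian parameters.  A score is
#' called an outlier when it is more likely under the weighted outlier
#' component, i.e. `pi_out * U(x) > (1 - pi_out) * N(x | mu, sigma^2)`,
#' equivalently responsibility > 0.5.
#'
#' @param scores finite numeric scores (>= 10 required).
#' @param pi_out fixed prior weight of the uniform outlier component.
#' @param max_em_iters EM iteration cap.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param pad uniform-support padding as a fraction of the score range.
#' @return an object of class `mixture_fit`: `mu`, `sigma2`, `support`,
#'   `pi_out`, `responsibilities`, `outlier` (logical calls), `loglik`
#'   (per-iteration trace, non-decreasing), `converged`.
#' @export
fit_outlier_mixture <- function(scores, pi_out = 0.01, max_em_iters = 200L,
                                tol = 1e-8, pad = 0.01) {
  x <- scores[is.finite(scores)]
  if (length(x) < 10)
    stop_locnet("data", "need >= 10 finite scores, got %d", length(x))
  rng <- range(x)
  if (diff(rng) <= 0)
    stop_locnet("data", "scores have zero spread")
  eps <- pad * diff(rng)
  support <- c(rng[1] - eps, rng[2] + eps)
  u <- 1 / diff(support)
  # robust init so planted outliers do not inflate the background fit
  mu <- stats::median(x)
  sigma <- max(stats::mad(x), 1e-6)
  loglik <- numeric(0)
  converged <- FALSE
  r_out <- rep(0, length(x))
  for (it in seq_len(max_em_iters)) {
    dn <- dnorm(x, mu, sigma)
    num <- pi_out * u
    den <- num + (1 - pi_out) * dn
    r_out <- num / den
    ll <- sum(log(den))
    loglik <- c(loglik, ll)
    if (it > 1 && abs(ll - loglik[it - 1]) < tol) { converged <- TRUE; break }
    w <- 1 - r_out
    sw <- sum(w)
    mu <- sum(w * x) / sw
    sigma <- sqrt(max(sum(w * (x - mu)^2) / sw, 1e-12))
  }
  if (!converged)
    warning("EM did not converge within max_em_iters; returning best fit",
            call. = FALSE)
  structure(list(mu = mu, sigma2 = sigma^2, support = support,
                 pi_out = pi_out, responsibilities = r_out,
                 outlier = r_out > 0.5, loglik = loglik,
                 converged = converged, scores = x),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<mixture_fit> N(%.3f, %.3f^2) + U(%.2f, %.2f), ",
                     "pi_out = %.3f\n  %d scores, %d outlier call(s), ",
                     "%d EM iterations%s\n"),
              x$mu, sqrt(x$sigma2), x$support[1], x$support[2], x$pi_out,
              length(x$scores), sum(x$outlier), length(x$loglik),
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Log2 abundance fold change
#'
#' `dPL = log2(I_g_B / I_g_A)`; a protein is flagged as an abundance
#' change when `|dPL| > 1` (strictly more than two-fold).  Antisymmetric
#' under condition swap.  Non-positive intensities are undefined and
#' yield `NA` (the pipeline skips such proteins).
#'
#' @param I_g_B mean green intensity in condition B (treatment).
#' @param I_g_A mean green intensity in condition A (reference).
#' @return list with `dpl` and `abundance_flag` (vectorized).
#' @export
abundance_fold_change <- function(I_g_B, I_g_A) {
  dpl <- ifelse(I_g_B > 0 & I_g_A > 0, log2(I_g_B / I_g_A), NA_real_)
  list(dpl = dpl, abundance_flag = !is.na(dpl) & abs(dpl) > 1)
}

#' Mean abundance over a cell population
#'
#' The per-protein abundance `I_g` is the unweighted mean over cells of
#' the per-cell mean green intensity by area (green intensity sum divided
#' by the cell-region pixel count; the synthetic generator records this
#' within its own body mask, standing in for a segmentation area).
#'
#' @param cells numeric vector of per-cell mean green intensities.
#' @return `I_g`.
#' @export
mean_abundance <- function(cells) {
  cells <- cells[is.finite(cells)]
  if (!length(cells)) stop_locnet("data", "empty cell population")
  mean(cells)
}

#' Score localization and abundance changes between two conditions
#'
#' For every (protein, class) pair, computes the Welch's t statistic
#' between the per-cell class probabilities of the two conditions, then
#' calibrates the scores of each class across proteins with the
#' Gaussian + uniform outlier mixture ([fit_outlier_mixture()]).  When
#' the prediction table carries per-cell `green_mean` intensities,
#' per-protein abundances and `dPL` fold changes are reported as well.
#' Because a distribution can change while the dominant compartment does
#' not, both the outlier call and whether the dominant (argmax) class
#' changed are reported.
#'
#' @param predictions a `prediction_table` with `protein_id` and
#'   `condition` columns; condition labels are taken in sorted order as
#'   (A, B) unless given explicitly.
#' @param conditions length-2 character vector naming (A, B).
#' @param min_cells minimum cells per condition for a valid t score.
#' @param pi_out fixed outlier prior for the mixture.
#' @return an object of class `change_score_table`: data.frame with one
#'   row per (protein, class): `protein_id`, `class`, `t_score`,
#'   `outlier_posterior`, `outlier`, `skipped`, plus per-protein columns
#'   `dpl`, `abundance_flag`, `dominant_a`, `dominant_b`,
#'   `dominant_changed`.  Attribute `"fits"` holds the per-class
#'   `mixture_fit`s; attributes `"profiles_a"`/`"profiles_b"` the
#'   per-condition protein profiles.
#' @export
score_screen <- function(predictions, conditions = NULL, min_cells = 5L,
                         pi_out = 0.01) {
  if (!all(c("protein_id", "condition") %in% names(predictions)))
    stop_locnet("data", "predictions need protein_id and condition columns")
  conds <- sort(unique(predictions$condition))
  if (is.null(conditions)) conditions <- conds
  if (length(conditions) != 2L || !all(conditions %in% conds))
    stop_locnet("data", "exactly two conditions required")
  cls <- prediction_classes(predictions)
  pa <- predictions[predictions$condition == conditions[1], , drop = FALSE]
  pb <- predictions[predictions$condition == conditions[2], , drop = FALSE]
  proteins <- sort(unique(predictions$protein_id))
  res <- expand.grid(protein_id = proteins, class = cls,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- res[order(res$protein_id, res$class), ]
  res$t_score <- NA_real_
  ia <- split(seq_len(nrow(pa)), pa$protein_id)
  ib <- split(seq_len(nrow(pb)), pb$protein_id)
  for (k in seq_along(cls)) {
    col <- paste0("p_", cls[k])
    for (p in proteins) {
      t <- welch_t(pa[[col]][ia[[p]]], pb[[col]][ib[[p]]],
                   min_cells = min_cells)
      res$t_score[res$protein_id == p & res$class == cls[k]] <- t
    }
  }
  res$skipped <- !is.finite(res$t_score)
  res$outlier_posterior <- NA_real_
  res$outlier <- FALSE
  fits <- list()
  for (k in cls) {
    sel <- res$class == k & !res$skipped
    if (sum(sel) >= 10) {
      fit <- fit_outlier_mixture(res$t_score[sel], pi_out = pi_out)
      res$outlier_posterior[sel] <- fit$responsibilities
      res$outlier[sel] <- fit$outlier
      fits[[k]] <- fit
    }
  }
  prof_a <- aggregate_protein(pa)
  prof_b <- aggregate_protein(pb)
  pmat_a <- as.matrix(prof_a[, paste0("p_", cls)])
  pmat_b <- as.matrix(prof_b[, paste0("p_", cls)])
  dom_a <- setNames(cls[max.col(pmat_a, ties.method = "first")],
                    prof_a$protein_id)
  dom_b <- setNames(cls[max.col(pmat_b, ties.method = "first")],
                    prof_b$protein_id)
  res$dominant_a <- dom_a[res$protein_id]
  res$dominant_b <- dom_b[res$protein_id]
  res$dominant_changed <- res$dominant_a != res$dominant_b
  if ("I_g" %in% names(prof_a)) {
    iga <- setNames(prof_a$I_g, prof_a$protein_id)
    igb <- setNames(prof_b$I_g, prof_b$protein_id)
    fc <- abundance_fold_change(igb[res$protein_id], iga[res$protein_id])
    res$dpl <- unname(fc$dpl)
    res$abundance_flag <- unname(fc$abundance_flag)
  }
  rownames(res) <- NULL
  attr(res, "fits") <- fits
  attr(res, "profiles_a") <- prof_a
  attr(res, "profiles_b") <- prof_b
  attr(res, "classes") <- cls
  class(res) <- c("change_score_table", "data.frame")
  res
}

#' Build a localization flux network from change scores
#'
#' Proteins are retained when any class score reaches `|t| >= threshold`
#' (scores of magnitude below the threshold are filtered out).  Each
#' retained protein contributes one edge per gaining class
#' (`t >= threshold`), drawn from the protein's dominant condition-A
#' compartment to that class and weighted by the score magnitude
#' (edge thickness in a graph rendering).  Proteins are annotated with
#' their abundance fold change when available.
#'
#' @param scores a `change_score_table` from [score_screen()].
#' @param threshold score-magnitude filter (default 10).
#' @return an object of class `flux_network`: list with `edges`
#'   (data.frame `from`, `to`, `protein_id`, `weight`, `t_score`),
#'   `proteins` (annotations of retained proteins), and `graph`
#'   (an igraph object whose nodes are compartments).
#' @export
build_flux_network <- function(scores, threshold = 10) {
  stopifnot(inherits(scores, "change_score_table"))
  keep <- stats::aggregate(abs(scores$t_score),
                           by = list(protein_id = scores$protein_id),
                           FUN = function(v) suppressWarnings(
                             max(v, na.rm = TRUE)))
  retained <- keep$protein_id[is.finite(keep$x) & keep$x >= threshold]
  edges <- scores[scores$protein_id %in% retained &
                  !is.na(scores$t_score) &
                  scores$t_score >= threshold, , drop = FALSE]
  edf <- data.frame(from = edges$dominant_a, to = edges$class,
                    protein_id = edges$protein_id,
                    weight = abs(edges$t_score),
                    t_score = edges$t_score,
                    stringsAsFactors = FALSE)
  rownames(edf) <- NULL
  pann <- unique(scores[scores$protein_id %in% retained,
                        intersect(c("protein_id", "dominant_a",
                                    "dominant_b", "dpl", "abundance_flag"),
                                  names(scores))])
  rownames(pann) <- NULL
  g <- if (nrow(edf)) {
    igraph::graph_from_data_frame(edf, directed = TRUE)
  } else {
    igraph::make_empty_graph(directed = TRUE)
  }
  structure(list(edges = edf, proteins = pann, graph = g,
                 threshold = threshold),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("<flux_network> %d edge(s) over %d retained protein(s), |t| >= %g\n",
              nrow(x$edges), nrow(x$proteins), x$threshold))
  invisible(x)
}
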