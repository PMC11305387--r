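#' ROC curve for one model's docking scores
#'
#' Ranks compounds by score (lower = better, docking-energy convention)
#' and returns the receiver-operator characteristic as (FPR, TPR) points
#' from (0, 0) to (1, 1). Compounds with a missing score are excluded from
#' the ranking — they mirror compounds that failed to dock. Tied scores
#' are treated as a single threshold group, producing one ROC vertex per
#' distinct score (the segment across a tie group is diagonal).
#'
#' @param scores numeric vector of docking scores for one model (NA =
#'   failed docking).
#' @param labels `"active"` / `"decoy"` per compound.
#' @return data.frame with columns `fpr`, `tpr`, both monotone
#'   non-decreasing, first row (0, 0), last row (1, 1).
#' @export
compute_roc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- labels[keep]
  n_act <- sum(labels == "active")
  n_dec <- sum(labels == "decoy")
  if (n_act == 0) stop("no active with a non-missing score")
  if (n_dec == 0) stop("no decoy with a non-missing score")
  ord <- order(scores)
  s <- scores[ord]
  act <- labels[ord] == "active"
  tp <- cumsum(act)
  fp <- cumsum(!act)
  # one vertex per distinct score: keep the last index of each tie group
  last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  data.frame(fpr = c(0, fp[last] / n_dec),
             tpr = c(0, tp[last] / n_act))
}

#' Adjusted semilogarithmic LogAUC of a ROC curve
#'
#' Area under TPR as a function of log10(FPR) on \[`lambda_low`, 1\],
#' normalised by log10(1/lambda) and expressed in percent, minus the same
#' quantity for the random classifier (the diagonal), so that random
#' ranking scores 0 and a perfect ROC scores 100 - 14.462 = 85.538 at the
#' default lambda = 0.001. Early enrichment — recovery of actives at very
#' low false-positive rates, the regime that matters when only the top of
#' a ranked library is inspected — dominates this metric by construction.
#'
#' The ROC polyline is evaluated at FPR = lambda by linear interpolation
#' (in FPR), vertices below lambda are then dropped, and the semilog
#' integral is computed exactly: TPR is piecewise linear in FPR between
#' vertices, and for a linear segment the integral against d(log10 FPR)
#' has a closed form, so no quadrature grid is involved. The random term
#' is the closed form 100 (1 - lambda) / (ln 10 log10(1/lambda)), which
#' makes the two-point diagonal ROC score exactly 0.
#'
#' @param roc data.frame from [compute_roc()] (columns `fpr`, `tpr`).
#' @param lambda_low lower FPR bound of the semilog integration window,
#'   0 < lambda_low < 1.
#' @return adjusted LogAUC in percent, in
#'   \[-14.462, 85.538\] at lambda = 0.001.
#' @examples
#' adjusted_logauc(data.frame(fpr = c(0, 1), tpr = c(0, 1)))  # 0
#' adjusted_logauc(data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)))  # 85.54
#' @export
adjusted_logauc <- function(roc, lambda_low = 0.001) {
  if (!is.numeric(lambda_low) || lambda_low <= 0 || lambda_low >= 1)
    stop("`lambda_low` must be in (0, 1)")
  stopifnot(is.data.frame(roc), all(c("fpr", "tpr") %in% names(roc)))
  fpr <- roc$fpr
  tpr <- roc$tpr
  # TPR at the lambda crossing, linear in FPR; ties: take the upper value
  tpr_lambda <- max(stats::approx(fpr, tpr, xout = lambda_low,
                                  ties = max)$y, tpr[fpr <= lambda_low])
  keep <- fpr > lambda_low
  x <- c(lambda_low, fpr[keep])
  y <- c(tpr_lambda, tpr[keep])
  if (x[length(x)] < 1) { x <- c(x, 1); y <- c(y, y[length(y)]) }
  # exact integral of the piecewise-linear (in FPR) polyline against
  # d(log10 FPR): for y = a + b x on [x1, x2] the segment contributes
  # (a ln(x2/x1) + b (x2 - x1)) / ln 10; vertical segments contribute 0
  x1 <- x[-length(x)]; x2 <- x[-1]
  y1 <- y[-length(y)]; y2 <- y[-1]
  run <- x2 - x1
  b <- ifelse(run > 0, (y2 - y1) / run, 0)
  a <- y1 - b * x1
  area <- sum(ifelse(run > 0, (a * log(x2 / x1) + b * run) / log(10), 0))
  width <- log10(1 / lambda_low)
  random_area <- (1 - lambda_low) / log(10)   # integral of x dlog10(x)
  100 * (area - random_area) / width
}

#' Enrichment factor at a top fraction of the ranked database
#'
#' EF at fraction f = (actives found in the top ceil(f N) compounds /
#' total actives) / f, with N the number of compounds that docked
#' (non-missing score). EF = 1 is the random expectation; the maximum is
#' 1/f. The ranking is by (score, compound id), so boundary behaviour at
#' tied scores is deterministic.
#'
#' @inheritParams compute_roc
#' @param fraction top fraction of the ranked database, in (0, 1\].
#' @param ids optional compound ids used as the tie-break key; defaults
#'   to input order.
#' @return the enrichment factor (>= 0).
#' @export
enrichment_factor <- function(scores, labels, fraction = 0.01,
                              ids = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  labels <- as.character(labels)
  if (is.null(ids)) ids <- sprintf("%09d", seq_along(scores))
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]; ids <- ids[keep]
  n_act <- sum(labels == "active")
  if (n_act == 0) stop("no active with a non-missing score")
  if (sum(labels == "decoy") == 0)
    stop("no decoy with a non-missing score")
  n <- length(scores)
  n_top <- ceiling(fraction * n)
  ord <- order(scores, ids)
  hits <- sum(labels[ord][seq_len(n_top)] == "active")
  (hits / n_act) / fraction
}

#' Evaluate every model of a score matrix
#'
#' Computes, per model, the adjusted LogAUC and enrichment factors at the
#' requested fractions; the result carries the whole distribution so
#' medians, arbitrary percentiles and distribution plots can be derived
#' from it.
#'
#' @param x a [score_matrix()].
#' @param lambda_low semilog ROC lower bound (see [adjusted_logauc()]).
#' @param fractions numeric vector of EF fractions (default 0.01, i.e.
#'   EF1%).
#' @return an object of class `enrichment_ensemble`: data.frame with one
#'   row per model (`model_id`, `logauc`, `ef_<fraction>` columns,
#'   `n_active_scored`, `n_decoy_scored`) plus attributes `lambda_low`
#'   and `fractions`.
#' @export
evaluate_ensemble <- function(x, lambda_low = 0.001, fractions = 0.01) {
  stopifnot(inherits(x, "score_matrix"))
  k <- ncol(x$scores)
  if (k < 1) stop("score matrix has no models")
  res <- lapply(seq_len(k), function(m) {
    sc <- x$scores[, m]
    r <- tryCatch({
      roc <- compute_roc(sc, x$labels)
      efs <- vapply(fractions, function(f)
        enrichment_factor(sc, x$labels, f, ids = x$compound_ids), 0)
      c(adjusted_logauc(roc, lambda_low), efs,
        sum(!is.na(sc) & x$labels == "active"),
        sum(!is.na(sc) & x$labels == "decoy"))
    }, error = function(e)
      stop("model '", x$model_ids[m], "': ", conditionMessage(e),
           call. = FALSE))
    r
  })
  res <- do.call(rbind, res)
  out <- data.frame(model_id = x$model_ids,
                    logauc = res[, 1],
                    stringsAsFactors = FALSE)
  ef_cols <- paste0("ef_", fractions)
  for (j in seq_along(fractions))
    out[[ef_cols[j]]] <- res[, 1 + j]
  out$n_active_scored <- res[, 2 + length(fractions)]
  out$n_decoy_scored <- res[, 3 + length(fractions)]
  structure(out, lambda_low = lambda_low, fractions = fractions,
            class = c("enrichment_ensemble", "data.frame"))
}

#' @export
print.enrichment_ensemble <- function(x, ...) {
  cat("enrichment_ensemble:", nrow(x), "models (lambda =",
      attr(x, "lambda_low"), ")\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more models\n")
  invisible(x)
}

#' @export
summary.enrichment_ensemble <- function(object, percentile = 98, ...) {
  ef_cols <- grep("^ef_", names(object), value = TRUE)
  top <- percentile_subset(object, percentile)
  out <- list(
    n_models = nrow(object),
    median = c(logauc = stats::median(object$logauc),
               vapply(ef_cols, function(cl)
                 stats::median(object[[cl]]), 0)),
    percentile = percentile,
    percentile_median = c(logauc = stats::median(top$logauc),
                          vapply(ef_cols, function(cl)
                            stats::median(top[[cl]]), 0)),
    n_percentile = nrow(top))
  class(out) <- "summary.enrichment_ensemble"
  out
}

#' @export
print.summary.enrichment_ensemble <- function(x, ...) {
  cat("Ensemble of", x$n_models, "models\n")
  cat("  median over all models:\n")
  print(round(x$median, 2))
  cat("  median over the ", x$percentile, "th-percentile subset (n = ",
      x$n_percentile, "):\n", sep = "")
  print(round(x$percentile_median, 2))
  invisible(x)
}

#' Distribution plot of per-model enrichment metrics
#'
#' Kernel-density "violin"-style outlines of the LogAUC and EF
#' distributions over models, with the median as a dashed line.
#'
#' @param x an `enrichment_ensemble`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.enrichment_ensemble <- function(x, ...) {
  metrics <- c("logauc", grep("^ef_", names(x), value = TRUE))
  op <- graphics::par(mfrow = c(1, length(metrics)))
  on.exit(graphics::par(op))
  for (m in metrics) {
    v <- x[[m]]
    if (length(unique(v)) > 1) {
      d <- stats::density(v)
      sc <- 0.4 / max(d$y)
      graphics::plot(NA, xlim = c(-0.5, 0.5), ylim = range(d$x),
                     xlab = "", ylab = m, xaxt = "n", main = m, ...)
      graphics::polygon(c(d$y, -rev(d$y)) * sc, c(d$x, rev(d$x)),
                        col = "grey85")
    } else {
      graphics::plot(NA, xlim = c(-0.5, 0.5), ylim = v[1] + c(-1, 1),
                     xlab = "", ylab = m, xaxt = "n", main = m, ...)
    }
    graphics::abline(h = stats::median(v), lty = 2)
  }
  invisible(x)
}

#' Top-percentile subset of an ensemble
#'
#' Nearest-rank convention: the p-th-percentile subset of n models is the
#' top `ceiling((1 - p/100) * n)` models by LogAUC, which makes the 98th
#' percentile of 1000 models exactly 20 models. Ties at the boundary are
#' broken by model id (stable).
#'
#' @param ensemble an `enrichment_ensemble`.
#' @param percentile percentile in \[0, 100).
#' @return the subset rows, best LogAUC first.
#' @export
percentile_subset <- function(ensemble, percentile = 98) {
  if (percentile < 0 || percentile >= 100)
    stop("`percentile` must be in [0, 100)")
  # round before ceiling: 1 - 98/100 is not exactly 0.02 in floating
  # point, and 20.000000000000018 must not become 21 models
  n_top <- ceiling(round((1 - percentile / 100) * nrow(ensemble), 9))
  ord <- order(-ensemble$logauc, ensemble$model_id)
  ensemble[ord[seq_len(n_top)], , drop = FALSE]
}

#' Select k models for a prospective-screen ensemble
#'
#' From the models at or above the given LogAUC percentile, returns `k`
#' model ids. Without a diversity matrix the top `k` by LogAUC are taken.
#' With one (any pairwise model distance, e.g. binding-site RMSD), a
#' greedy max-min selection is run: seeded with the best-LogAUC model,
#' each step adds the eligible model whose minimum distance to the
#' already-selected set is largest. Ties are broken by (higher LogAUC,
#' model id), so selection is deterministic.
#'
#' @param ensemble an `enrichment_ensemble`.
#' @param percentile LogAUC percentile cut (see [percentile_subset()]).
#' @param k number of models to select.
#' @param diversity optional symmetric distance matrix with dimnames
#'   covering the model ids.
#' @return character vector of `k` model ids.
#' @export
select_models <- function(ensemble, percentile = 98, k = 5,
                          diversity = NULL) {
  eligible <- percentile_subset(ensemble, percentile)
  if (nrow(eligible) < k)
    stop("only ", nrow(eligible), " models at or above the ",
         percentile, "th percentile; ", k, " requested")
  if (is.null(diversity))
    return(eligible$model_id[seq_len(k)])
  ids <- eligible$model_id
  if (!all(ids %in% rownames(diversity)) ||
      !all(ids %in% colnames(diversity)))
    stop("`diversity` must have dimnames covering the eligible model ids")
  logauc <- stats::setNames(eligible$logauc, ids)
  chosen <- ids[1]   # eligible is ordered best-LogAUC first
  remaining <- setdiff(ids, chosen)
  while (length(chosen) < k) {
    d_min <- apply(diversity[remaining, chosen, drop = FALSE], 1, min)
    best <- remaining[order(-d_min, -logauc[remaining], remaining)][1]
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  chosen
}
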