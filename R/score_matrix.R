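#' Docking score matrix with activity labels
#'
#' The central container for retrospective screen evaluation: a numeric
#' matrix of docking scores (compounds in rows, receptor models in columns)
#' together with per-compound activity labels. Lower scores are better
#' throughout the package (docking energies). A compound that failed to dock
#' in a given model carries `NA` in that cell; `is.na(x$scores)` is the
#' missingness mask.
#'
#' @param scores numeric matrix, compounds x models. Row and column names,
#'   if present, seed `compound_ids` / `model_ids`.
#' @param labels character or factor with levels `"active"` / `"decoy"`,
#'   one per compound.
#' @param compound_ids unique compound identifiers; defaults to rownames or
#'   `cpd_1 ... cpd_n`.
#' @param model_ids model identifiers; defaults to colnames or
#'   `model_1 ... model_k`.
#' @return an object of class `score_matrix`: a list with elements `scores`,
#'   `labels` (factor), `compound_ids`, `model_ids`.
#' @examples
#' m <- score_matrix(matrix(rnorm(20), 10, 2),
#'                   labels = rep(c("active", "decoy"), 5))
#' print(m)
#' @export
score_matrix <- function(scores, labels, compound_ids = NULL,
                         model_ids = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("`scores` must be a numeric matrix (compounds x models)")
  n <- nrow(scores)
  k <- ncol(scores)
  if (k < 1L) stop("`scores` must have at least one model column")
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("`labels` must have one entry per compound (", n, "), got ",
         length(labels))
  if (!all(labels %in% c("active", "decoy")))
    stop("`labels` must be 'active' or 'decoy'")
  if (is.null(compound_ids))
    compound_ids <- rownames(scores) %||% sprintf("cpd_%d", seq_len(n))
  if (is.null(model_ids))
    model_ids <- colnames(scores) %||% sprintf("model_%d", seq_len(k))
  compound_ids <- as.character(compound_ids)
  model_ids <- as.character(model_ids)
  if (length(compound_ids) != n) stop("`compound_ids` length mismatch")
  if (anyDuplicated(compound_ids))
    stop("compound ids must be unique")
  if (length(model_ids) != k) stop("`model_ids` length mismatch")
  dimnames(scores) <- list(compound_ids, model_ids)
  structure(
    list(scores = scores,
         labels = factor(labels, levels = c("active", "decoy")),
         compound_ids = compound_ids,
         model_ids = model_ids),
    class = "score_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", nrow(x$scores), "compounds x", ncol(x$scores),
      "models\n")
  cat("  actives:", sum(x$labels == "active"),
      " decoys:", sum(x$labels == "decoy"), "\n")
  miss <- mean(is.na(x$scores))
  cat(sprintf("  missing (failed docking): %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.score_matrix <- function(x) dim(x$scores)

#' Read / write the score-matrix CSV dialect
#'
#' Columns: `compound_id`, `label` (active/decoy), then one column per
#' model. An empty cell means the compound failed to dock in that model.
#'
#' @param path file path.
#' @rdname score_matrix_io
#' @return `read_score_matrix` returns a [score_matrix()];
#'   `write_score_matrix` returns `path` invisibly.
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, na.strings = "")
  need <- c("compound_id", "label")
  if (!all(need %in% names(df)))
    stop("score CSV must contain columns: ", paste(need, collapse = ", "))
  model_cols <- setdiff(names(df), need)
  if (length(model_cols) == 0L) stop("score CSV has no model columns")
  scores <- as.matrix(df[model_cols])
  storage.mode(scores) <- "double"
  score_matrix(scores, df$label, compound_ids = df$compound_id,
               model_ids = model_cols)
}

#' @param x a `score_matrix`.
#' @rdname score_matrix_io
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(inherits(x, "score_matrix"))
  df <- data.frame(compound_id = x$compound_ids,
                   label = as.character(x$labels),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$scores, row.names = NULL))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
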