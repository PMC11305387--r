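#' Property-matched decoy selection
#'
#' For each active, picks the `ratio` candidate-pool members closest in
#' normalised physicochemical property space, subject to a topological
#' dissimilarity constraint: a candidate is globally excluded if its
#' fingerprint Tanimoto similarity to *any* active exceeds `tc_exclude`,
#' so no decoy is a lookalike of a known ligand. Actives are processed in
#' input order and chosen decoys are removed from the pool (no decoy
#' serves two actives), which makes the procedure deterministic and
#' linear in |pool| x |actives|.
#'
#' Property distances are Euclidean after per-property scaling; by
#' default each property is divided by its interquartile range over the
#' pool (robust to outliers; IQR of 0 falls back to 1).
#'
#' @param actives,pool `compound_library`-like lists carrying `ids`,
#'   `fingerprints` (0/1 matrix) and `properties` (data.frame with the
#'   same columns in both).
#' @param ratio decoys per active. The default 65 reflects the usual
#'   benchmark composition of roughly 65 property-matched decoys per
#'   ligand (e.g. 11,392 decoys for 173 ligands).
#' @param tc_exclude maximum allowed Tanimoto similarity of a decoy to
#'   any active (candidates above it are excluded).
#' @param property_scales optional named numeric vector of per-property
#'   divisors overriding the pool-IQR normalisation.
#' @return an object of class `decoy_set`: list with `decoys`
#'   (data.frame `active_id`, `decoy_id`, `distance`), `exclusion_log`
#'   (data.frame `candidate_id`, `reason`), and `property_scales`.
#' @export
match_decoys <- function(actives, pool, ratio = 65, tc_exclude = 0.35,
                         property_scales = NULL) {
  if (ratio < 1) stop("`ratio` must be >= 1")
  n_act <- length(actives$ids)
  if (n_act == 0) stop("no actives supplied")
  prop_cols <- names(actives$properties)
  if (!identical(sort(prop_cols), sort(names(pool$properties))))
    stop("actives and pool carry different property columns")
  # per-property scale: pool IQR (robust); 0 -> 1
  if (is.null(property_scales)) {
    property_scales <- vapply(prop_cols, function(p)
      stats::IQR(pool$properties[[p]]), 0)
    property_scales[property_scales == 0] <- 1
  } else {
    if (!all(prop_cols %in% names(property_scales)))
      stop("`property_scales` must name every property column")
    property_scales <- property_scales[prop_cols]
  }
  # global topological exclusion against ALL actives
  tc <- tanimoto_matrix(pool$fingerprints, actives$fingerprints)
  max_tc <- apply(tc, 1, max)
  excluded <- max_tc > tc_exclude
  exclusion_log <- data.frame(
    candidate_id = pool$ids[excluded],
    reason = sprintf("Tc %.3f to active '%s' exceeds %.3f",
                     max_tc[excluded],
                     actives$ids[apply(tc[excluded, , drop = FALSE],
                                       1, which.max)],
                     tc_exclude),
    stringsAsFactors = FALSE)
  avail_ids <- pool$ids[!excluded]
  if (length(avail_ids) < ratio * n_act)
    stop("pool exhausted: ", length(avail_ids),
         " candidates remain after the Tc exclusion but ",
         ratio * n_act, " decoys (", ratio, " x ", n_act,
         " actives) are required")
  scale_mat <- function(props)
    sweep(as.matrix(props[prop_cols]), 2, property_scales, `/`)
  pool_std <- scale_mat(pool$properties)[!excluded, , drop = FALSE]
  rownames(pool_std) <- avail_ids
  act_std <- scale_mat(actives$properties)
  available <- rep(TRUE, length(avail_ids))
  picks <- vector("list", n_act)
  for (i in seq_len(n_act)) {
    d <- sqrt(colSums((t(pool_std) - act_std[i, ])^2))
    d[!available] <- Inf
    ord <- order(d, avail_ids)   # deterministic at tied distances
    take <- ord[seq_len(ratio)]
    if (any(!is.finite(d[take])))
      stop("pool exhausted for active '", actives$ids[i],
           "': only ", sum(available), " candidates remain, ",
           ratio, " needed")
    picks[[i]] <- data.frame(active_id = actives$ids[i],
                             decoy_id = avail_ids[take],
                             distance = d[take],
                             stringsAsFactors = FALSE)
    available[take] <- FALSE
  }
  structure(list(decoys = do.call(rbind, picks),
                 exclusion_log = exclusion_log,
                 property_scales = property_scales),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat("decoy_set:", nrow(x$decoys), "decoys for",
      length(unique(x$decoys$active_id)), "actives;",
      nrow(x$exclusion_log), "candidates excluded by Tc\n")
  invisible(x)
}

#' Write a decoy set as CSV plus an exclusion-log TSV
#'
#' @param x a `decoy_set`.
#' @param stem output path stem (writes `<stem>.csv` and
#'   `<stem>_exclusions.tsv`).
#' @return the two paths, invisibly.
#' @export
write_decoy_set <- function(x, stem) {
  stopifnot(inherits(x, "decoy_set"))
  csv <- paste0(stem, ".csv")
  utils::write.csv(x$decoys, csv, row.names = FALSE)
  tsv <- paste0(stem, "_exclusions.tsv")
  utils::write.table(x$exclusion_log, tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(csv, tsv))
}
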