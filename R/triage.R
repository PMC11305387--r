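#' Rank compounds by their best score over an ensemble of models
#'
#' Each compound is assigned the minimum (best) docking score over its
#' non-missing entries in the selected model columns, then the library is
#' ranked on that score. Compounds missing in every model cannot be
#' ranked; they are dropped and recorded. Ties are broken by compound id,
#' so ranks are strict and contiguous from 1.
#'
#' @param x a [score_matrix()] (labels may be all-decoy for a prospective
#'   library; they are ignored here).
#' @param models optional model ids/indices restricting the ensemble.
#' @return an object of class `ranked_list`: data.frame with `rank`,
#'   `compound_id`, `best_score`, `best_model`; attribute `dropped` holds
#'   the ids that failed to dock in every model.
#' @export
ensemble_best_score <- function(x, models = NULL) {
  stopifnot(inherits(x, "score_matrix"))
  sc <- x$scores
  if (!is.null(models)) sc <- sc[, models, drop = FALSE]
  if (ncol(sc) < 1 || nrow(sc) < 1) stop("empty score matrix")
  has_any <- rowSums(!is.na(sc)) > 0
  dropped <- x$compound_ids[!has_any]
  sc <- sc[has_any, , drop = FALSE]
  ids <- x$compound_ids[has_any]
  best <- apply(sc, 1, min, na.rm = TRUE)
  best_model <- colnames(sc)[apply(sc, 1, which.min)]
  ord <- order(best, ids)
  out <- data.frame(rank = seq_along(ord),
                    compound_id = ids[ord],
                    best_score = best[ord],
                    best_model = best_model[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, dropped = dropped,
            class = c("ranked_list", "data.frame"))
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("ranked_list:", nrow(x), "compounds")
  nd <- length(attr(x, "dropped"))
  if (nd > 0) cat(" (", nd, " dropped: failed in all models)", sep = "")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  invisible(x)
}

#' The SMARTS catalog shipped with the package
#'
#' Reads `inst/extdata/pains_catalog.smarts`: a compact, versioned
#' catalog of well-known assay-interference chemotypes (quinones,
#' catechols, rhodanines, azo compounds, aryl hydrazones,
#' aminothiophenes, alkylidene barbiturates, isothiazolones). It is a
#' starter catalog: any full PAINS dialect can be supplied as a file in
#' the same format (`name<TAB>SMARTS`, `#` comments).
#'
#' @return named character vector of SMARTS patterns.
#' @export
default_pains_catalog <- function() {
  read_pains_catalog(system.file("extdata", "pains_catalog.smarts",
                                 package = "dockscreen"))
}

#' @param path catalog file, one `name<TAB>SMARTS` per line.
#' @rdname default_pains_catalog
#' @export
read_pains_catalog <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty SMARTS catalog: ", path)
  parts <- strsplit(lines, "\t")
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed catalog line(s): ",
                     paste(lines[bad], collapse = "; "))
  stats::setNames(vapply(parts, `[`, "", 2),
                  vapply(parts, `[`, "", 1))
}

#' Flag compounds matching interference substructures
#'
#' A compound is flagged if at least one catalog pattern matches its
#' structure. Unparseable SMILES are quarantined into a rejects list with
#' the reason, never silently dropped and never fatal. Both output lists
#' preserve input order.
#'
#' @param smiles character vector; names (or `ids`) identify compounds.
#' @param catalog named character vector of SMARTS patterns (default:
#'   the shipped catalog).
#' @param ids optional compound ids (default: names of `smiles`, else
#'   the SMILES themselves).
#' @return list with `kept` (data.frame `id`, `smiles`), `flagged`
#'   (`id`, `smiles`, `pattern` — first matching pattern name), and
#'   `rejects` (`id`, `smiles`, `reason`).
#' @export
filter_pains <- function(smiles, catalog = default_pains_catalog(),
                         ids = NULL) {
  if (length(catalog) == 0) stop("empty SMARTS catalog")
  if (is.null(ids)) ids <- names(smiles) %||% as.character(smiles)
  empty <- data.frame(id = character(0), smiles = character(0),
                      stringsAsFactors = FALSE)
  if (length(smiles) == 0)
    return(list(kept = empty,
                flagged = cbind(empty, pattern = character(0)),
                rejects = cbind(empty, reason = character(0))))
  ok <- smiles_valid(smiles)
  rejects <- data.frame(id = ids[!ok],
                        smiles = unname(smiles[!ok]),
                        reason = rep("unparseable SMILES", sum(!ok)),
                        stringsAsFactors = FALSE)
  hit_mat <- if (any(ok))
    smarts_match_matrix(smiles[ok], catalog)
  else matrix(FALSE, 0, length(catalog))
  any_hit <- rowSums(hit_mat) > 0
  first_pat <- apply(hit_mat, 1, function(r)
    if (any(r)) names(catalog)[which(r)[1]] else NA_character_)
  okids <- ids[ok]; oksmi <- smiles[ok]
  list(kept = data.frame(id = okids[!any_hit], smiles = oksmi[!any_hit],
                         stringsAsFactors = FALSE),
       flagged = data.frame(id = okids[any_hit],
                            smiles = oksmi[any_hit],
                            pattern = first_pat[any_hit],
                            stringsAsFactors = FALSE),
       rejects = rejects)
}

#' Exclude compounds similar to known ligands
#'
#' A compound is excluded when its maximum fingerprint Tanimoto
#' similarity over the known-ligand set is strictly greater than
#' `tc_max` (a compound at exactly `tc_max` is kept). Works directly on
#' 0/1 fingerprint matrices so it applies equally to real (ECFP4) and
#' synthetic fingerprints; use [morgan_fp()] to fingerprint SMILES.
#'
#' @param fps compound fingerprints: 0/1 matrix, rownames = ids.
#' @param known_fps known-ligand fingerprints (same bit length). An
#'   empty set keeps everything, with a warning.
#' @param tc_max exclusion threshold (strict inequality), default 0.5.
#' @return list with `kept` (character ids) and `excluded` (data.frame
#'   `id`, `nearest_known`, `tc`).
#' @export
filter_known_similarity <- function(fps, known_fps, tc_max = 0.5) {
  ids <- rownames(fps) %||% paste0("cpd_", seq_len(nrow(fps)))
  if (is.null(known_fps) || nrow(known_fps) == 0) {
    warning("no known ligands supplied; keeping all compounds")
    return(list(kept = ids,
                excluded = data.frame(id = character(0),
                                      nearest_known = character(0),
                                      tc = numeric(0))))
  }
  known_ids <- rownames(known_fps) %||%
    paste0("known_", seq_len(nrow(known_fps)))
  tc <- tanimoto_matrix(fps, known_fps)
  max_tc <- apply(tc, 1, max)
  nearest <- known_ids[apply(tc, 1, which.max)]
  out <- max_tc > tc_max
  list(kept = ids[!out],
       excluded = data.frame(id = ids[out],
                             nearest_known = nearest[out],
                             tc = max_tc[out],
                             stringsAsFactors = FALSE))
}

#' Leader (sphere-exclusion) clustering of a ranked library
#'
#' Single-pass clustering in rank order: walking down the ranked list, a
#' compound founds a new cluster if its Tanimoto similarity to every
#' existing leader is below `tc_threshold`, otherwise it joins the first
#' leader with similarity at or above the threshold. Because the pass is
#' in rank order, each cluster's leader is its best-scoring member — one
#' candidate per chemotype, which is the point of clustering a screen.
#' Clusters are ranked by their leader's rank, and the leaders of the
#' `top_n_clusters` best clusters form the candidate list.
#'
#' @param ranked a `ranked_list` (from [ensemble_best_score()]) or a
#'   data.frame with `rank` and `compound_id`.
#' @param fps 0/1 fingerprint matrix with rownames covering the ranked
#'   compound ids.
#' @param tc_threshold cluster similarity threshold (default 0.5).
#' @param top_n_input how many top-ranked compounds enter clustering
#'   (default 40000); if larger than the list, the full list is used.
#' @param top_n_clusters how many top clusters form the candidate list
#'   (default 2000).
#' @return an object of class `cluster_set`: list with `clusters`
#'   (data.frame `cluster_rank`, `leader_id`, `member_id`,
#'   `member_rank`), `candidates` (leader ids of the top clusters, in
#'   cluster-rank order), `tc_threshold`, `n_input`.
#' @export
cluster_select <- function(ranked, fps, tc_threshold = 0.5,
                           top_n_input = 40000, top_n_clusters = 2000) {
  if (nrow(ranked) == 0) stop("empty ranked list")
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  n_in <- min(top_n_input, nrow(ranked))
  ranked <- ranked[seq_len(n_in), , drop = FALSE]
  ids <- ranked$compound_id
  if (!all(ids %in% rownames(fps)))
    stop("fingerprints missing for ",
         sum(!ids %in% rownames(fps)), " ranked compounds")
  fps <- matrix(as.numeric(fps[ids, , drop = FALSE] != 0),
                nrow = n_in, dimnames = list(ids, NULL))
  pop <- rowSums(fps)
  leader_rows <- integer(0)
  assignment <- integer(n_in)   # index into leader_rows
  for (i in seq_len(n_in)) {
    if (length(leader_rows) > 0) {
      inter <- as.vector(fps[leader_rows, , drop = FALSE] %*% fps[i, ])
      uni <- pop[leader_rows] + pop[i] - inter
      tc <- ifelse(uni == 0, 0, inter / uni)
      j <- which(tc >= tc_threshold)
      if (length(j) > 0) { assignment[i] <- j[1]; next }
    }
    leader_rows <- c(leader_rows, i)
    assignment[i] <- length(leader_rows)
  }
  clusters <- data.frame(
    cluster_rank = assignment,    # leaders are founded in rank order
    leader_id = ids[leader_rows][assignment],
    member_id = ids,
    member_rank = ranked$rank,
    stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$cluster_rank,
                             clusters$member_rank), ]
  rownames(clusters) <- NULL
  candidates <- ids[leader_rows][
    seq_len(min(top_n_clusters, length(leader_rows)))]
  structure(list(clusters = clusters, candidates = candidates,
                 tc_threshold = tc_threshold, n_input = n_in),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", max(x$clusters$cluster_rank), "clusters over",
      x$n_input, "compounds (Tc threshold", x$tc_threshold, ")\n")
  cat("  candidates (top-cluster leaders):", length(x$candidates), "\n")
  invisible(x)
}

#' Write clustering results as CSV
#'
#' @param x a `cluster_set`.
#' @param path output CSV (columns `cluster_rank`, `leader_id`,
#'   `member_id`, `member_rank`).
#' @return `path`, invisibly.
#' @export
write_cluster_set <- function(x, path) {
  stopifnot(inherits(x, "cluster_set"))
  utils::write.csv(x$clusters, path, row.names = FALSE)
  invisible(path)
}
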