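#' Pipeline configuration
#'
#' Assembles and validates the configuration for the two workflow
#' drivers ([run_retrospective()] and [run_prospective()]). All
#' thresholds default to the package's documented values; any can be
#' overridden here or loaded from a YAML file with [read_config()]
#' (explicit arguments win over file values, mirroring CLI-flag
#' behaviour).
#'
#' @param scores path to a score-matrix CSV (see
#'   [read_score_matrix()]).
#' @param library_smi path to a library `.smi` file (SMILES TAB id).
#' @param knowns_smi path to a known-ligand `.smi` file.
#' @param pains path to a SMARTS catalog (default: shipped catalog).
#' @param diversity optional CSV of a pairwise model distance matrix.
#' @param out_dir output directory (created if missing).
#' @param lambda_low,fractions enrichment parameters
#'   (see [evaluate_ensemble()]).
#' @param percentile,k_models model-selection parameters
#'   (see [select_models()]).
#' @param tc_cluster,tc_known,top_n_input,top_n_clusters triage
#'   parameters (see [cluster_select()], [filter_known_similarity()]).
#' @param tc_exclude,ratio decoy-generation parameters
#'   (see [match_decoys()]).
#' @param seed integer seed recorded in the manifest and used for any
#'   stochastic stage.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(scores = NULL, library_smi = NULL,
                            knowns_smi = NULL, pains = NULL,
                            diversity = NULL, out_dir = "dockscreen_out",
                            lambda_low = 0.001, fractions = 0.01,
                            percentile = 98, k_models = 5,
                            tc_cluster = 0.5, tc_known = 0.5,
                            tc_exclude = 0.35, ratio = 65,
                            top_n_input = 40000, top_n_clusters = 2000,
                            seed = 1L) {
  cfg <- list(scores = scores, library_smi = library_smi,
              knowns_smi = knowns_smi, pains = pains,
              diversity = diversity, out_dir = out_dir,
              lambda_low = lambda_low, fractions = fractions,
              percentile = percentile, k_models = k_models,
              tc_cluster = tc_cluster, tc_known = tc_known,
              tc_exclude = tc_exclude, ratio = ratio,
              top_n_input = top_n_input,
              top_n_clusters = top_n_clusters,
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk01 <- function(v, nm, lo = 0, hi = 1) {
    if (!is.numeric(cfg[[v]]) || cfg[[v]] < lo || cfg[[v]] > hi)
      stop("config `", v, "` out of range [", lo, ", ", hi, "]")
  }
  if (cfg$lambda_low <= 0 || cfg$lambda_low >= 1)
    stop("config `lambda_low` out of range (0, 1)")
  chk01("tc_cluster", hi = 1)
  chk01("tc_known", hi = 1)
  chk01("tc_exclude", hi = 1)
  if (cfg$percentile < 0 || cfg$percentile >= 100)
    stop("config `percentile` out of range [0, 100)")
  for (v in c("k_models", "ratio", "top_n_input", "top_n_clusters"))
    if (cfg[[v]] < 1) stop("config `", v, "` must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' @param path YAML config file.
#' @param ... overrides applied on top of the file (flags win).
#' @rdname pipeline_config
#' @export
read_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(pipeline_config, cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (nm in names(x))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-15s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

# manifest: inputs, config hash, seed, package version
.write_manifest <- function(cfg, out_dir, stage, outputs) {
  cfg_yaml <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_yaml)
  manifest <- list(
    stage = stage,
    config_hash = unname(tools::md5sum(cfg_yaml)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("dockscreen")),
    inputs = Filter(Negate(is.null),
                    cfg[c("scores", "library_smi", "knowns_smi",
                          "pains", "diversity")]),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Retrospective model-evaluation workflow
#'
#' Reads a score matrix of actives and decoys docked to an ensemble of
#' receptor models, computes per-model adjusted LogAUC and enrichment
#' factors, summarises the ensemble, and selects the prospective-screen
#' models from the top LogAUC percentile. Writes per-model metrics CSV,
#' a JSON ensemble summary, the selected model ids, and a manifest
#' (config hash + seed); reruns with an identical config produce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @return list with `ensemble` (the [evaluate_ensemble()] result),
#'   `selected` (model ids), `summary`, and `manifest`, invisibly
#'   returned after writing artifacts to `config$out_dir`.
#' @export
run_retrospective <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$scores))
    stop("stage retrospective: config `scores` is required")
  x <- read_score_matrix(config$scores)
  ens <- evaluate_ensemble(x, lambda_low = config$lambda_low,
                           fractions = config$fractions)
  diversity <- NULL
  if (!is.null(config$diversity)) {
    dm <- utils::read.csv(config$diversity, row.names = 1,
                          check.names = FALSE)
    diversity <- as.matrix(dm)
  }
  selected <- select_models(ens, percentile = config$percentile,
                            k = config$k_models, diversity = diversity)
  summ <- summary(ens, percentile = config$percentile)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics_csv <- file.path(config$out_dir, "model_metrics.csv")
  utils::write.csv(as.data.frame(ens), metrics_csv, row.names = FALSE)
  summary_json <- file.path(config$out_dir, "ensemble_summary.json")
  jsonlite::write_json(
    list(n_models = summ$n_models,
         median = as.list(summ$median),
         percentile = summ$percentile,
         percentile_median = as.list(summ$percentile_median),
         selected_models = selected),
    summary_json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  selected_txt <- file.path(config$out_dir, "selected_models.txt")
  writeLines(selected, selected_txt)
  manifest <- .write_manifest(config, config$out_dir, "retrospective",
                              c(metrics_csv, summary_json,
                                selected_txt))
  invisible(list(ensemble = ens, selected = selected, summary = summ,
                 manifest = manifest))
}

#' Prospective-screen triage workflow
#'
#' Runs the post-docking filtering cascade on a prospective library:
#' ensemble best-score ranking, PAINS substructure exclusion,
#' known-ligand similarity exclusion, leader clustering of the
#' top-ranked survivors, and candidate selection (leaders of the top
#' clusters). Writes the candidate `.smi`, the cluster CSV, a filter
#' log TSV, per-stage survivor counts, and a manifest.
#'
#' @param config a [pipeline_config()] (or YAML path); `scores`,
#'   `library_smi` and `knowns_smi` are required.
#' @return list with `ranked`, `stage_counts`, `clusters`
#'   (a `cluster_set`), `candidates`, and `manifest`, invisibly
#'   returned after writing artifacts.
#' @export
run_prospective <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("scores", "library_smi", "knowns_smi"))
    if (is.null(config[[f]]))
      stop("stage prospective: config `", f, "` is required")
  x <- read_score_matrix(config$scores)
  lib <- read_smi(config$library_smi)
  knowns <- read_smi(config$knowns_smi)
  catalog <- if (is.null(config$pains)) default_pains_catalog()
             else read_pains_catalog(config$pains)

  ranked <- ensemble_best_score(x)
  ranked_lib <- ranked[ranked$compound_id %in% lib$id, , drop = FALSE]
  smiles <- stats::setNames(lib$smiles, lib$id)[ranked_lib$compound_id]

  pains <- filter_pains(smiles, catalog = catalog,
                        ids = ranked_lib$compound_id)
  n_after_pains <- nrow(pains$kept)

  kept_fps <- morgan_fp(stats::setNames(pains$kept$smiles,
                                        pains$kept$id))
  known_fps <- morgan_fp(stats::setNames(knowns$smiles, knowns$id))
  sim <- filter_known_similarity(kept_fps, known_fps,
                                 tc_max = config$tc_known)
  surviving <- ranked_lib[ranked_lib$compound_id %in% sim$kept, ,
                          drop = FALSE]

  if (nrow(surviving) > 0) {
    cl <- cluster_select(surviving,
                         kept_fps[sim$kept, , drop = FALSE],
                         tc_threshold = config$tc_cluster,
                         top_n_input = config$top_n_input,
                         top_n_clusters = config$top_n_clusters)
    n_clusters <- max(cl$clusters$cluster_rank)
  } else {
    cl <- structure(list(clusters = data.frame(
                           cluster_rank = integer(0),
                           leader_id = character(0),
                           member_id = character(0),
                           member_rank = integer(0)),
                         candidates = character(0),
                         tc_threshold = config$tc_cluster,
                         n_input = 0L),
                    class = "cluster_set")
    n_clusters <- 0L
  }
  stage_counts <- c(ranked = nrow(ranked_lib),
                    after_pains = n_after_pains,
                    after_known_similarity = nrow(surviving),
                    clustered = cl$n_input,
                    clusters = n_clusters,
                    candidates = length(cl$candidates))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cand_smi <- file.path(config$out_dir, "candidates.smi")
  smi_map <- stats::setNames(lib$smiles, lib$id)
  writeLines(paste(smi_map[cl$candidates], cl$candidates, sep = "\t"),
             cand_smi)
  clusters_csv <- file.path(config$out_dir, "clusters.csv")
  write_cluster_set(cl, clusters_csv)
  filter_tsv <- file.path(config$out_dir, "filter_log.tsv")
  log_rows <- function(id, stage, reason)
    data.frame(id = id, stage = rep(stage, length(id)),
               reason = reason, stringsAsFactors = FALSE)
  flog <- rbind(
    log_rows(pains$flagged$id, "pains", pains$flagged$pattern),
    log_rows(pains$rejects$id, "parse", pains$rejects$reason),
    log_rows(sim$excluded$id, "known_similarity",
             sprintf("Tc %.3f to %s", sim$excluded$tc,
                     sim$excluded$nearest_known)))
  utils::write.table(flog, filter_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  counts_csv <- file.path(config$out_dir, "stage_counts.csv")
  utils::write.csv(data.frame(stage = names(stage_counts),
                              n = as.integer(stage_counts)),
                   counts_csv, row.names = FALSE)
  manifest <- .write_manifest(config, config$out_dir, "prospective",
                              c(cand_smi, clusters_csv, filter_tsv,
                                counts_csv))
  invisible(list(ranked = ranked, stage_counts = stage_counts,
                 clusters = cl, candidates = cl$candidates,
                 manifest = manifest))
}

#' Read a `.smi` file (SMILES TAB id per line)
#'
#' @param path file path.
#' @return data.frame with `smiles` and `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  data.frame(smiles = vapply(parts, `[`, "", 1),
             id = vapply(parts, function(p)
               if (length(p) > 1) p[2] else p[1], ""),
             stringsAsFactors = FALSE)
}
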