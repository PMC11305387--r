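#' Hit rate of a tested compound set
#'
#' A "hit" is a tested compound whose agonist efficacy exceeded 50% of
#' the reference agonist's maximal effect at the screening concentration
#' (the `is_hit` column encodes that call). Reported percentages are
#' rounded half-up to the integer, the convention that turns 7/32
#' (21.875%) into 22%.
#'
#' @param tested data.frame with a logical `is_hit` column (see
#'   [taar1_tested_compounds()] for the canonical layout).
#' @return list with `percent` (integer-rounded), `fraction` (raw),
#'   `n_hits`, `n_tested`.
#' @examples
#' hit_rate(data.frame(is_hit = rep(c(TRUE, FALSE), c(18, 12))))
#' @export
hit_rate <- function(tested) {
  if (NROW(tested) == 0) stop("empty tested-compound list")
  stopifnot(is.logical(tested$is_hit))
  n <- nrow(tested)
  h <- sum(tested$is_hit)
  frac <- h / n
  list(percent = round_half_up(100 * frac), fraction = frac,
       n_hits = h, n_tested = n)
}

# round half away from zero ("half-up" on positives): 21.875 -> 22
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Hit rate adjusted for compounds shared between screens
#'
#' When the same compound surfaces in two screens, a per-screen hit rate
#' can double-count its evidence. The adjustment removes the shared
#' compounds from both numerator and denominator of the screen being
#' adjusted and recomputes the rate on the remainder. Ids in
#' `shared_ids` not present among the tested compounds are ignored with
#' a warning.
#'
#' @inheritParams hit_rate
#' @param shared_ids ids of compounds found by both screens.
#' @return as [hit_rate()].
#' @export
adjusted_hit_rate <- function(tested, shared_ids) {
  if (NROW(tested) == 0) stop("empty tested-compound list")
  unknown <- setdiff(shared_ids, tested$id)
  if (length(unknown) > 0)
    warning("ignoring shared ids not among tested compounds: ",
            paste(unknown, collapse = ", "))
  keep <- !(tested$id %in% shared_ids)
  if (!any(keep))
    stop("removing the shared compounds empties the tested list")
  hit_rate(tested[keep, , drop = FALSE])
}

#' Overlap between the tops of two ranked lists
#'
#' 100 x |top-k(A) intersect top-k(B)| / k. If either list is shorter
#' than `k`, it is truncated to its full length with a warning and `k`
#' becomes the shorter length.
#'
#' @param list_a,list_b character vectors of compound ids, best first.
#' @param k depth of the comparison (default 10000).
#' @return percent overlap in \[0, 100\].
#' @export
overlap_fraction <- function(list_a, list_b, k = 10000) {
  if (k <= 0) stop("`k` must be positive")
  if (length(list_a) < k || length(list_b) < k) {
    k2 <- min(length(list_a), length(list_b))
    warning("lists shorter than k = ", k, "; comparing top ", k2)
    k <- k2
  }
  100 * length(intersect(list_a[seq_len(k)], list_b[seq_len(k)])) / k
}

#' Potency summaries over tested compounds
#'
#' `potency_summary()` reports the pEC50 range over compounds with a
#' measured value (rows without one are excluded and counted);
#' `fold_potency(a, b)` is the potency ratio 10^(pEC50_a - pEC50_b)
#' (direction-sensitive: > 1 means `a` more potent); and
#' `ec50_micromolar(p)` converts a pEC50 (-log10 molar) to an EC50 in
#' micromolar, `10^(6 - p)`, rounded to 2 decimal places by default.
#'
#' @param tested data.frame with a numeric `pec50` column.
#' @return `potency_summary()`: list with `min_pec50`, `max_pec50`,
#'   `n_with_pec50`, `n_missing`.
#' @export
potency_summary <- function(tested) {
  p <- tested$pec50
  if (all(is.na(p))) stop("no pEC50 values present")
  list(min_pec50 = min(p, na.rm = TRUE),
       max_pec50 = max(p, na.rm = TRUE),
       n_with_pec50 = sum(!is.na(p)),
       n_missing = sum(is.na(p)))
}

#' @param a,b pEC50 values (-log10 molar).
#' @rdname potency_summary
#' @export
fold_potency <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  10^(a - b)
}

#' @param p pEC50 value.
#' @param digits decimal places for the reported EC50 (default 2).
#' @rdname potency_summary
#' @export
ec50_micromolar <- function(p, digits = 2) {
  round_half_up(10^(6 - p), digits)
}

#' Normalise a raw response to a reference maximum
#'
#' Assay responses are expressed as a percentage of the response at a
#' saturating concentration of the reference agonist; 50% is the hit
#' threshold.
#'
#' @param raw raw signal.
#' @param reference_max reference agonist's maximal signal (> 0).
#' @return percent of the reference maximum.
#' @export
normalize_response <- function(raw, reference_max) {
  if (any(reference_max <= 0)) stop("`reference_max` must be > 0")
  100 * raw / reference_max
}

#' Pre-pulse inhibition of the acoustic startle response
#'
#' PPI% = \[1 - (mean pre-pulse response / mean startle-only response)\]
#' x 100; `mean_ppi()` averages the PPI% values across the pre-pulse
#' intensities tested (conventionally three).
#'
#' @param startle_mean mean startle-only response (> 0).
#' @param prepulse_mean mean response in pre-pulse trials.
#' @return percent inhibition (100 when the pre-pulse abolishes the
#'   startle, 0 when it has no effect, negative when it potentiates).
#' @export
ppi_percent <- function(startle_mean, prepulse_mean) {
  if (any(startle_mean <= 0)) stop("`startle_mean` must be > 0")
  (1 - prepulse_mean / startle_mean) * 100
}

#' @param ppi_values PPI% at each pre-pulse intensity.
#' @rdname ppi_percent
#' @export
mean_ppi <- function(ppi_values) {
  mean(ppi_values)
}

#' Concentration-time series for one matrix
#'
#' @param time sampling times (strictly increasing, same unit across
#'   series).
#' @param conc measured concentrations (>= 0) as assayed, before any
#'   dilution correction.
#' @param matrix label, e.g. `"plasma"` or `"brain"`.
#' @param dilution dilution factor applied during sample preparation;
#'   concentrations are multiplied by it before AUC calculation (brain
#'   homogenates prepared 1:3 w/v carry a factor of 4).
#' @return an object of class `assay_series`.
#' @export
assay_series <- function(time, conc, matrix = "plasma", dilution = 1) {
  stopifnot(length(time) == length(conc))
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing")
  if (any(conc < 0)) stop("`conc` must be >= 0")
  if (dilution <= 0) stop("`dilution` must be > 0")
  structure(list(time = as.numeric(time), conc = as.numeric(conc),
                 matrix = matrix, dilution = dilution),
            class = "assay_series")
}

#' @export
print.assay_series <- function(x, ...) {
  cat("assay_series (", x$matrix, "): ", length(x$time),
      " time points, dilution x", x$dilution, "\n", sep = "")
  invisible(x)
}

#' Linear-trapezoid AUC of a concentration-time series
#'
#' @param series an [assay_series()].
#' @return the AUC after applying the series' dilution factor.
#' @export
auc_trapezoid <- function(series) {
  stopifnot(inherits(series, "assay_series"))
  pracma::trapz(series$time, series$conc * series$dilution)
}

#' Brain-to-plasma partition coefficient
#'
#' K_p,brain = AUC_brain / AUC_plasma, both AUCs by the linear trapezoid
#' after each series' dilution correction (brain homogenate
#' concentrations are conventionally multiplied by 4).
#'
#' @param plasma,brain [assay_series()] objects.
#' @return list with `auc_plasma`, `auc_brain`, `kp_brain`.
#' @export
brain_penetrance <- function(plasma, brain) {
  auc_p <- auc_trapezoid(plasma)
  auc_b <- auc_trapezoid(brain)
  if (auc_p <= 0) stop("plasma AUC must be positive")
  list(auc_plasma = auc_p, auc_brain = auc_b,
       kp_brain = auc_b / auc_p)
}
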