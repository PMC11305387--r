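#' The TAAR1 prospective-screen test set
#'
#' The 62 docking-prioritised compounds that were experimentally
#' evaluated for TAAR1 agonism at 20 uM: 30 from the AlphaFold-model
#' screen (`origin = "AF"`, ids 1-30) and 32 from the homology-model
#' screen (`origin = "HM"`, ids 31-62). A compound is a hit
#' (`is_hit = TRUE`) if it showed agonist activity with efficacy above
#' 50% of the beta-phenethylamine (beta-PEA) maximum; the 25 confirmed
#' agonists carry their published pEC50 (-log10 molar) and Emax (% of
#' the beta-PEA maximum), and the two ranks printed for each agonist
#' (see Details). Non-hits carry NA in those columns.
#'
#' @details `rank_primary` and `rank_secondary` transcribe the two
#' numbers printed per agonist (e.g. 2938 and 35310); the source tables
#' do not define which is the cluster rank and which the overall
#' library rank, so no claim is made here either. `reference = TRUE`
#' rows are the assay reference agonist beta-PEA and the clinical
#' comparator Ulotaront; they are not screen candidates and are
#' excluded from hit-rate arithmetic.
#'
#' @return data.frame with columns `id`, `compound`, `origin`
#'   (`"AF"`/`"HM"`/`"ref"`), `reference`, `is_hit`, `rank_primary`,
#'   `rank_secondary`, `pec50`, `emax_percent`.
#' @examples
#' tab <- taar1_tested_compounds()
#' af <- tab[tab$origin == "AF" & !tab$reference, ]
#' hit_rate(af)   # 18 of 30 -> 60%
#' @export
taar1_tested_compounds <- function() {
  # confirmed agonists from the AlphaFold screen (compounds 13-30)
  af_hits <- data.frame(
    compound = 13:30,
    rank_primary = c(2938, 1098, 311, 4001, 1017, 84, 573, 151, 555,
                     3272, 1528, 668, 717, 3040, 3060, 187, 381, 963),
    rank_secondary = c(35310, 109532, 56230, 44811, 865757, 437792,
                       382074, 25997, 195139, 195139, 37423, 18592,
                       85960, 212223, 65537, 22718, 7957, 22595),
    pec50 = c(5.5, 5.1, 5.2, 5.8, 5.2, 6.2, 5.4, 5.4, 5.5, 5.5, 5.4,
              5.8, 6.0, 6.0, 6.6, 6.4, 6.8, 7.5),
    emax_percent = c(51.8, 54.3, 57.5, 61.9, 67.8, 68.7, 74.5, 74.5,
                     75.2, 78.5, 79.2, 81.4, 95.3, 95.5, 98.7, 102.6,
                     105.7, 112.5))
  # confirmed agonists from the homology-model screen (compounds 56-62)
  hm_hits <- data.frame(
    compound = 56:62,
    rank_primary = c(2811, 290, 3350, 550, 1877, 1359, 3728),
    rank_secondary = c(467247, 118716, NA, 12903, 165473, 39818, 469),
    pec50 = c(4.9, 5.3, 5.1, 5.2, 5.5, 5.3, 6.5),
    emax_percent = c(63.0, 73.2, 78.4, 78.8, 79.9, 80.3, 107.4))
  blank <- function(compound, origin) data.frame(
    compound = compound, rank_primary = NA_real_,
    rank_secondary = NA_real_, pec50 = NA_real_,
    emax_percent = NA_real_)
  tab <- rbind(
    cbind(blank(1:12, "AF"), origin = "AF", is_hit = FALSE),
    cbind(af_hits, origin = "AF", is_hit = TRUE),
    cbind(blank(31:55, "HM"), origin = "HM", is_hit = FALSE),
    cbind(hm_hits, origin = "HM", is_hit = TRUE))
  tab <- tab[order(tab$compound), ]
  tab$reference <- FALSE
  refs <- data.frame(
    compound = NA_integer_, rank_primary = NA_real_,
    rank_secondary = NA_real_, pec50 = c(6.6, 6.1),
    emax_percent = c(100, 96.4), origin = "ref", is_hit = NA,
    reference = TRUE)
  tab <- rbind(tab, refs)
  tab$id <- c(sprintf("cpd_%02d", tab$compound[!tab$reference]),
              "beta-PEA", "Ulotaront")
  rownames(tab) <- NULL
  tab[, c("id", "compound", "origin", "reference", "is_hit",
          "rank_primary", "rank_secondary", "pec50", "emax_percent")]
}
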