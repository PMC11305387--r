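#' Simulate a docking score matrix with known active/decoy separation
#'
#' Generates the kind of table a large retrospective docking screen
#' produces: per-model scores for a set of known ligands (actives) and
#' presumed non-binders (decoys), with a tunable fraction of failed
#' dockings. Decoy scores are drawn from Normal(0, `noise_sd`); active
#' scores from Normal(-delta_m, `noise_sd`) where `delta_m` is the model's
#' entry in `separation` — lower scores are better, so positive separation
#' shifts actives toward better scores. Docking failure is real (screens
#' routinely fail to dock a large minority of a library) and is modelled by
#' masking each cell independently with probability `fail_rate`.
#'
#' @param n_models number of receptor models (columns).
#' @param n_actives,n_decoys compound counts (each >= 1).
#' @param separation numeric score-shift per model (recycled to
#'   `n_models`); the ground-truth quality gradient.
#' @param noise_sd score noise standard deviation (> 0).
#' @param fail_rate probability a compound fails to dock in a model
#'   (0 <= fail_rate < 1).
#' @param seed integer seed; the same spec and seed give bit-identical
#'   output.
#' @return a [score_matrix()] with attribute `separation` recording the
#'   per-model ground truth.
#' @examples
#' m <- sim_score_matrix(n_models = 3, n_actives = 20, n_decoys = 100,
#'                       separation = c(0, 1, 2), seed = 1)
#' @export
sim_score_matrix <- function(n_models, n_actives, n_decoys,
                             separation = rep(1, n_models),
                             noise_sd = 1, fail_rate = 0, seed = NULL) {
  if (n_models < 1L) stop("invalid `n_models`: must be >= 1")
  if (n_actives < 1L) stop("invalid `n_actives`: must be >= 1")
  if (n_decoys < 1L) stop("invalid `n_decoys`: must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("invalid `noise_sd`: must be > 0")
  if (!is.numeric(fail_rate) || fail_rate < 0 || fail_rate >= 1)
    stop("invalid `fail_rate`: must be in [0, 1)")
  separation <- rep_len(as.numeric(separation), n_models)
  if (!is.null(seed)) set.seed(seed)
  n <- n_actives + n_decoys
  labels <- rep(c("active", "decoy"), c(n_actives, n_decoys))
  scores <- matrix(NA_real_, n, n_models)
  for (m in seq_len(n_models)) {
    mu <- ifelse(labels == "active", -separation[m], 0)
    scores[, m] <- stats::rnorm(n, mean = mu, sd = noise_sd)
  }
  if (fail_rate > 0) {
    scores[matrix(stats::runif(n * n_models) < fail_rate,
                  n, n_models)] <- NA_real_
  }
  out <- score_matrix(scores, labels,
                      compound_ids = sprintf("cpd_%05d", seq_len(n)))
  attr(out, "separation") <- separation
  out
}

#' SMILES fixtures matching the shipped PAINS catalog
#'
#' A small, documented set of molecules each matching at least one pattern
#' in the catalog shipped with the package (see [default_pains_catalog()]).
#' They are test fixtures for the triage filter, not claims about the
#' assay behaviour of these specific chemicals.
#'
#' @return data.frame with columns `smiles`, `id`, `expected_pattern`.
#' @export
pains_fixtures <- function() {
  data.frame(
    smiles = c("O=C1C=CC(=O)C=C1",            # para-quinone
               "Oc1ccccc1O",                   # catechol
               "O=C1CSC(=S)N1",                # rhodanine
               "c1ccc(cc1)N=Nc1ccccc1",        # azobenzene
               "C(=NNc1ccccc1)c1ccccc1",       # aryl hydrazone
               "Nc1cccs1"),                    # 2-aminothiophene
    id = c("fix_quinone", "fix_catechol", "fix_rhodanine",
           "fix_azo", "fix_hydrazone", "fix_aminothiophene"),
    expected_pattern = c("quinone_a", "catechol_a", "rhodanine_a",
                         "azo_a", "aryl_hydrazone_a",
                         "aminothiophene_a"),
    stringsAsFactors = FALSE)
}

#' Simulate a fragment-like compound library
#'
#' Emulates, at desk scale, a screening library: each member carries a
#' binary topological fingerprint (random bits at the requested density)
#' and a physicochemical property vector drawn uniformly within
#' fragment-like bounds (by default molecular weight < 250 Da and
#' cLogP < 3.5, the usual fragment screening criteria). Optionally appends
#' the shipped PAINS fixtures, flagged in ground truth, so the triage
#' filters can be exercised end to end.
#'
#' @param n_compounds library size (0 gives an empty library).
#' @param fingerprint_bits fingerprint length (default 1024, the usual
#'   folded ECFP4 length).
#' @param bit_density expected fraction of set bits per fingerprint.
#' @param property_ranges named list of `c(low, high)` bounds per property;
#'   defaults to fragment-like bounds.
#' @param include_pains_fixtures append the [pains_fixtures()] molecules
#'   (with real fingerprints and properties computed from their SMILES).
#' @param seed integer seed.
#' @return an object of class `compound_library`: list with `ids`, `smiles`
#'   (NA for randomly generated members), `fingerprints` (0/1 matrix),
#'   `properties` (data.frame), `is_pains_fixture` (logical).
#' @export
sim_compound_library <- function(n_compounds,
                                 fingerprint_bits = 1024,
                                 bit_density = 0.1,
                                 property_ranges = NULL,
                                 include_pains_fixtures = FALSE,
                                 seed = NULL) {
  if (n_compounds < 0L) stop("invalid `n_compounds`")
  if (fingerprint_bits < 1L) stop("invalid `fingerprint_bits`")
  if (bit_density < 0 || bit_density > 1) stop("invalid `bit_density`")
  default_ranges <- list(
    molecular_weight = c(100, 250),   # Da, fragment-like
    clogp            = c(-2, 3.5),
    hbd              = c(0, 3),
    hba              = c(0, 6),
    net_charge       = c(-1, 1),
    rotatable_bonds  = c(0, 5))
  if (is.null(property_ranges)) property_ranges <- default_ranges
  else {
    bad <- !vapply(property_ranges, function(r)
      is.numeric(r) && length(r) == 2 && r[1] <= r[2], TRUE)
    if (any(bad))
      stop("invalid `property_ranges` for: ",
           paste(names(property_ranges)[bad], collapse = ", "))
    property_ranges <- utils::modifyList(default_ranges, property_ranges)
  }
  if (!is.null(seed)) set.seed(seed)
  integer_props <- c("hbd", "hba", "net_charge", "rotatable_bonds")
  ids <- if (n_compounds > 0) sprintf("lib_%06d", seq_len(n_compounds))
         else character(0)
  fps <- matrix(as.integer(
    stats::runif(n_compounds * fingerprint_bits) < bit_density),
    nrow = n_compounds, ncol = fingerprint_bits)
  props <- as.data.frame(lapply(names(property_ranges), function(p) {
    r <- property_ranges[[p]]
    v <- stats::runif(n_compounds, r[1], r[2])
    if (p %in% integer_props) round(v) else v
  }), col.names = names(property_ranges))
  smiles <- rep(NA_character_, n_compounds)
  is_fix <- rep(FALSE, n_compounds)
  if (include_pains_fixtures) {
    fix <- pains_fixtures()
    fix_fp <- morgan_fp(fix$smiles, bits = fingerprint_bits)
    fix_prop <- compute_properties(fix$smiles)
    ids <- c(ids, fix$id)
    fps <- rbind(fps, fix_fp)
    props <- rbind(props, fix_prop[names(props)])
    smiles <- c(smiles, fix$smiles)
    is_fix <- c(is_fix, rep(TRUE, nrow(fix)))
  }
  rownames(fps) <- ids
  rownames(props) <- NULL
  structure(list(ids = ids, smiles = smiles, fingerprints = fps,
                 properties = props, is_pains_fixture = is_fix),
            class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  cat("compound_library:", length(x$ids), "compounds,",
      ncol(x$fingerprints), "fingerprint bits\n")
  if (any(x$is_pains_fixture))
    cat("  includes", sum(x$is_pains_fixture), "PAINS fixtures\n")
  invisible(x)
}

#' Write a compound library as SMILES + properties CSV
#'
#' Writes `<stem>.smi` (SMILES TAB id; members without SMILES are skipped)
#' and `<stem>_properties.csv`.
#'
#' @param x a `compound_library`.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
write_compound_library <- function(x, stem) {
  stopifnot(inherits(x, "compound_library"))
  smi_path <- paste0(stem, ".smi")
  keep <- !is.na(x$smiles)
  writeLines(paste(x$smiles[keep], x$ids[keep], sep = "\t"), smi_path)
  prop_path <- paste0(stem, "_properties.csv")
  utils::write.csv(cbind(data.frame(compound_id = x$ids), x$properties),
                   prop_path, row.names = FALSE)
  invisible(c(smi_path, prop_path))
}

# -- toy structures ---------------------------------------------------------

# idealised internal geometry used for the toy peptide trace
.toy_residue_atoms <- function(resid) {
  # offsets relative to CA, roughly physical (Angstrom)
  base <- rbind(N  = c(-1.46, 0.00, 0.00),
                CA = c( 0.00, 0.00, 0.00),
                C  = c( 0.90, 1.20, 0.00),
                O  = c( 2.13, 1.10, 0.05),
                CB = c(-0.55, -0.77, 1.20))
  if (resid == "PHE") {
    # hexagonal ring hanging off CB
    ring <- rbind(CG  = c(0.00, 0.00, 0.00),
                  CD1 = c( 1.21, 0.70, 0.00),
                  CD2 = c(-1.21, 0.70, 0.00),
                  CE1 = c( 1.21, 2.10, 0.00),
                  CE2 = c(-1.21, 2.10, 0.00),
                  CZ  = c( 0.00, 2.80, 0.00))
    ring <- sweep(ring, 2, c(-0.55, -1.60, 2.10), `+`)
    base <- rbind(base, ring)
  } else if (resid == "ASP") {
    side <- rbind(CG  = c(-0.60, -1.80, 2.00),
                  OD1 = c( 0.40, -2.50, 2.30),
                  OD2 = c(-1.80, -2.10, 2.30))
    base <- rbind(base, side)
  }
  base
}

euler_rotation <- function(angles) {
  # intrinsic z-y-x rotations, angles in radians
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Simulate a related pair of toy protein structures
#'
#' Builds a small helical peptide trace (N, CA, C, O, CB per residue, with
#' every third residue a phenylalanine carrying a full aromatic ring and
#' every fifth an aspartate) and a second copy related to the first by a
#' rigid rotation + translation plus isotropic Gaussian coordinate noise.
#' In the second copy the symmetric side-chain atoms of each Phe
#' (CD1/CD2 and CE1/CE2) and Asp (OD1/OD2) are label-swapped, and the
#' ground-truth permutation is recorded, so symmetry-corrected RMSD can be
#' validated exactly.
#'
#' @param n_residues number of residues (>= 1).
#' @param rotation three Euler angles (radians, intrinsic z-y-x).
#' @param translation length-3 offset (Angstrom).
#' @param noise_sd isotropic coordinate noise sd (Angstrom).
#' @param seed integer seed.
#' @return list with `reference` and `model` (data.frames: `resno`,
#'   `resid`, `elety`, `x`, `y`, `z`), `swapped_resno` (residues whose
#'   symmetric labels were swapped), and the true `rotation` /
#'   `translation` / `noise_sd`.
#' @export
sim_toy_structures <- function(n_residues,
                               rotation = c(0.4, -0.3, 0.2),
                               translation = c(5, -3, 8),
                               noise_sd = 0, seed = NULL) {
  if (n_residues < 1L) stop("`n_residues` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  # CA positions along an idealised alpha-helix
  t <- seq_len(n_residues)
  ca <- cbind(2.3 * cos(t * 100 * pi / 180),
              2.3 * sin(t * 100 * pi / 180),
              1.5 * t)
  resid <- rep("ALA", n_residues)
  resid[t %% 3 == 0] <- "PHE"
  resid[t %% 5 == 0 & resid != "PHE"] <- "ASP"
  rows <- lapply(seq_len(n_residues), function(i) {
    at <- .toy_residue_atoms(resid[i])
    data.frame(resno = i, resid = resid[i], elety = rownames(at),
               x = at[, 1] + ca[i, 1], y = at[, 2] + ca[i, 2],
               z = at[, 3] + ca[i, 3], stringsAsFactors = FALSE)
  })
  ref <- do.call(rbind, rows)
  rownames(ref) <- NULL
  R <- euler_rotation(rotation)
  xyz <- as.matrix(ref[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, translation, `+`)
  if (noise_sd > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd),
                        ncol = 3)
  mod <- ref
  mod[, c("x", "y", "z")] <- xyz
  # swap symmetric labels in the model copy
  cat_swaps <- symmetric_atom_catalog()
  swapped <- integer(0)
  for (i in unique(mod$resno)) {
    rs <- mod$resid[mod$resno == i][1]
    if (!rs %in% names(cat_swaps)) next
    for (pair in cat_swaps[[rs]]) {
      a <- which(mod$resno == i & mod$elety == pair[1])
      b <- which(mod$resno == i & mod$elety == pair[2])
      if (length(a) == 1 && length(b) == 1) {
        mod$elety[c(a, b)] <- mod$elety[c(b, a)]
      }
    }
    swapped <- c(swapped, i)
  }
  # restore canonical atom order within residues after the label swap
  mod <- mod[order(mod$resno, match(mod$elety, unique(ref$elety))), ]
  rownames(mod) <- NULL
  list(reference = ref, model = mod, swapped_resno = swapped,
       rotation = R, translation = translation, noise_sd = noise_sd)
}

#' Write a coordinate table as a minimal PDB file
#'
#' Fixed-width ATOM records (one chain, no altlocs, occupancy 1, B 0);
#' enough for any standard PDB reader.
#'
#' @param coords data.frame with `resno`, `resid`, `elety`, `x`, `y`, `z`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_minimal_pdb <- function(coords, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(coords)),
    ifelse(nchar(coords$elety) < 4, paste0(" ", coords$elety),
           coords$elety),
    coords$resid, coords$resno, coords$x, coords$y, coords$z,
    substr(coords$elety, 1, 1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# -- assay fixtures ---------------------------------------------------------

#' Generate assay-table fixtures with known ground truth
#'
#' Emits small tables of the kinds consumed by the hit-statistics module:
#' a tested-compound table (activity calls, pEC50, Emax), startle /
#' pre-pulse readings with known inhibition, and plasma/brain
#' concentration-time curves constructed so the brain-to-plasma AUC ratio
#' is exactly `kp_true` after the homogenate dilution correction.
#'
#' @param seed integer seed.
#' @param kp_true target brain-to-plasma partition coefficient.
#' @return list with `tested` (data.frame id, origin, is_hit, pec50,
#'   emax_percent), `startle` (data.frame intensity_db, startle_mean,
#'   prepulse_mean, ppi_true), `pk` (list `plasma`, `brain` of
#'   [assay_series()]), and `kp_true`.
#' @export
sim_assay_fixtures <- function(seed = NULL, kp_true = 5) {
  if (!is.null(seed)) set.seed(seed)
  n <- 24
  is_hit <- rep(c(TRUE, FALSE), c(10, 14))
  pec50 <- ifelse(is_hit, round(stats::runif(n, 5, 7.5), 1), NA_real_)
  emax <- ifelse(is_hit, round(stats::runif(n, 55, 110), 1),
                 round(stats::runif(n, 0, 45), 1))
  tested <- data.frame(
    id = sprintf("t%02d", seq_len(n)),
    origin = rep(c("AF", "HM"), length.out = n),
    is_hit = is_hit, pec50 = pec50, emax_percent = emax,
    stringsAsFactors = FALSE)
  startle <- data.frame(
    intensity_db = c(3, 6, 12),
    startle_mean = c(100, 100, 100),
    prepulse_mean = c(70, 40, 10))
  startle$ppi_true <- (1 - startle$prepulse_mean /
                         startle$startle_mean) * 100
  times <- c(0, 15, 30, 60, 120, 240)
  plasma_conc <- 1000 * (exp(-times / 90) - exp(-times / 10))
  plasma <- assay_series(times, plasma_conc, matrix = "plasma")
  # brain measured pre-dilution-correction: after x4 it is kp_true x plasma
  brain <- assay_series(times, kp_true * plasma_conc / 4,
                        matrix = "brain", dilution = 4)
  list(tested = tested, startle = startle,
       pk = list(plasma = plasma, brain = brain), kp_true = kp_true)
}
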