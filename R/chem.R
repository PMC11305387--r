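#' Tanimoto similarity between binary fingerprints
#'
#' `tanimoto()` compares two 0/1 vectors; `tanimoto_matrix()` compares
#' every row of `A` against every row of `B` (cross-product based, so it
#' scales to tens of thousands of fingerprints). The degenerate case of
#' two all-zero fingerprints (0/0) is defined as 0: molecules with no
#' features in common share nothing, including with themselves.
#'
#' @param a,b binary vectors of equal length.
#' @return `tanimoto()`: a single similarity in \[0, 1\];
#'   `tanimoto_matrix()`: an `nrow(A)` x `nrow(B)` matrix.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

#' @param A,B 0/1 matrices with fingerprints in rows (same bit length).
#' @rdname tanimoto
#' @export
tanimoto_matrix <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  A <- matrix(as.numeric(A != 0), nrow(A), ncol(A))
  B <- matrix(as.numeric(B != 0), nrow(B), ncol(B))
  inter <- A %*% t(B)
  uni <- outer(rowSums(A), rowSums(B), `+`) - inter
  out <- inter / uni
  out[uni == 0] <- 0
  out
}

# parse one batch of SMILES; on failure, fall back to per-molecule parsing
# so a single bad structure does not take down the batch
.parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  txt <- paste0(paste(smiles, ids, sep = "\t"), "\n", collapse = "")
  mols <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", txt, identity)),
    error = function(e) NULL)
  if (!is.null(mols) && length(mols) == length(smiles))
    return(list(mols = mols, ok = rep(TRUE, length(smiles))))
  ok <- vapply(smiles, function(s) {
    m <- tryCatch(
      suppressWarnings(ChemmineOB::forEachMol(
        "SMILES", paste0(s, "\tx\n"), identity)),
      error = function(e) NULL)
    !is.null(m) && length(m) == 1
  }, TRUE, USE.NAMES = FALSE)
  if (!any(ok)) return(list(mols = NULL, ok = ok))
  txt <- paste0(paste(smiles[ok], ids[ok], sep = "\t"), "\n",
                collapse = "")
  list(mols = suppressWarnings(
         ChemmineOB::forEachMol("SMILES", txt, identity)),
       ok = ok)
}

#' Morgan (ECFP4-type) fingerprints folded to a fixed length
#'
#' Circular fingerprints of radius 2 computed with OpenBabel's ECFP4
#' implementation and folded by bitwise OR to `bits` positions (1024 by
#' default, the length conventionally used for ECFP4 similarity work).
#'
#' @param smiles character vector of SMILES.
#' @param bits folded fingerprint length.
#' @return 0/1 integer matrix, one row per input, rownames = input SMILES
#'   names if present.
#' @export
morgan_fp <- function(smiles, bits = 1024) {
  if (length(smiles) == 0)
    return(matrix(integer(0), 0, bits))
  p <- .parse_smiles(smiles)
  if (!all(p$ok))
    stop("unparseable SMILES: ",
         paste(smiles[!p$ok], collapse = ", "))
  raw <- ChemmineOB::fingerprint_OB(p$mols, "ECFP4")
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  if (ncol(raw) == bits) fp <- raw
  else if (ncol(raw) %% bits == 0) {
    k <- ncol(raw) / bits
    fp <- raw[, seq_len(bits), drop = FALSE]
    for (j in seq_len(k - 1))
      fp <- fp | raw[, j * bits + seq_len(bits), drop = FALSE]
  } else stop("cannot fold ", ncol(raw), " bits to ", bits)
  fp <- matrix(as.integer(fp != 0), nrow = length(smiles), ncol = bits)
  rownames(fp) <- names(smiles)
  fp
}

# net formal charge as written in the SMILES: sum of bracket-atom charges
.smiles_formal_charge <- function(smiles) {
  vapply(smiles, function(s) {
    brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    if (length(brackets) == 0) return(0L)
    sum(vapply(brackets, function(b) {
      ch <- regmatches(b, regexpr("[+-]+[0-9]*", b))
      if (length(ch) == 0) return(0L)
      sign <- if (substr(ch, 1, 1) == "+") 1L else -1L
      digits <- gsub("[+-]", "", ch)
      if (nzchar(digits)) sign * as.integer(digits)
      else sign * nchar(ch)
    }, 0L))
  }, 0L, USE.NAMES = FALSE)
}

# count of N-H / O-H hydrogens via explicit-H-count SMARTS
.count_donor_h <- function(mols) {
  counts <- numeric(length(mols))
  for (h in 1:4) {
    pat <- sprintf("[#7H%d,#8H%d]", h, h)
    counts <- counts + h * as.numeric(
      ChemmineOB::smartsSearch_OB(mols, pat, uniqueMatches = TRUE))
  }
  counts
}

#' Physicochemical property vector for decoy matching
#'
#' Computes, per molecule: molecular weight (Da), calculated logP
#' (OpenBabel's XLogP-type model), hydrogen-bond donors (count of N-H and
#' O-H hydrogens), acceptors (count of N and O atoms), net formal charge
#' (summed from the SMILES as written), and rotatable bonds (standard
#' non-ring single bonds between non-terminal heavy atoms, amide-agnostic
#' SMARTS definition). These are the axes on which decoys are matched to
#' actives.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with columns `molecular_weight`, `clogp`, `hbd`,
#'   `hba`, `net_charge`, `rotatable_bonds`; one row per input.
#' @export
compute_properties <- function(smiles) {
  if (length(smiles) == 0)
    return(data.frame(molecular_weight = numeric(0), clogp = numeric(0),
                      hbd = numeric(0), hba = numeric(0),
                      net_charge = integer(0),
                      rotatable_bonds = numeric(0)))
  p <- .parse_smiles(smiles)
  if (!all(p$ok))
    stop("unparseable SMILES: ", paste(smiles[!p$ok], collapse = ", "))
  mols <- p$mols
  props <- ChemmineOB::prop_OB(mols)
  hba <- as.numeric(ChemmineOB::smartsSearch_OB(
    mols, "[#7,#8]", uniqueMatches = TRUE))
  rot <- as.numeric(ChemmineOB::smartsSearch_OB(
    mols, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE))
  data.frame(molecular_weight = props$MW,
             clogp = props$logP,
             hbd = .count_donor_h(mols),
             hba = hba,
             net_charge = .smiles_formal_charge(smiles),
             rotatable_bonds = rot)
}

#' Match SMILES against a SMARTS catalog
#'
#' Thin wrapper used by the PAINS filter: returns a logical matrix of
#' (molecule, pattern) matches.
#'
#' @param smiles character vector (must all be parseable).
#' @param patterns named character vector of SMARTS.
#' @return logical matrix, molecules x patterns.
#' @keywords internal
smarts_match_matrix <- function(smiles, patterns) {
  p <- .parse_smiles(smiles)
  if (!all(p$ok))
    stop("unparseable SMILES: ", paste(smiles[!p$ok], collapse = ", "))
  out <- vapply(patterns, function(pat)
    as.numeric(ChemmineOB::smartsSearch_OB(p$mols, pat,
                                           uniqueMatches = TRUE)) > 0,
    logical(length(smiles)))
  out <- matrix(out, nrow = length(smiles),
                dimnames = list(NULL, names(patterns)))
  out
}

#' Which SMILES are parseable?
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
smiles_valid <- function(smiles) {
  if (length(smiles) == 0) return(logical(0))
  .parse_smiles(smiles)$ok
}
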