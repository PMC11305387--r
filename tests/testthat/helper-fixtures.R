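# shared fixture builders for the test suite

# random binary fingerprint matrix with rownames
rand_fps <- function(n, bits = 64, density = 0.3, seed = NULL,
                     ids = sprintf("c%03d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(as.integer(runif(n * bits) < density), n, bits)
  rownames(m) <- ids
  m
}

# minimal compound-library-like list for decoy tests
mini_library <- function(n, seed, bits = 64, props = NULL) {
  set.seed(seed)
  fps <- rand_fps(n, bits, ids = sprintf("m%03d_%d", seq_len(n), seed))
  if (is.null(props))
    props <- data.frame(molecular_weight = runif(n, 100, 250),
                        clogp = runif(n, -1, 3.5),
                        hbd = sample(0:3, n, TRUE),
                        hba = sample(0:6, n, TRUE),
                        net_charge = sample(-1:1, n, TRUE),
                        rotatable_bonds = sample(0:5, n, TRUE))
  list(ids = rownames(fps), fingerprints = fps, properties = props)
}

# independent brute-force leader clustering (first-leader assignment)
oracle_leader_clusters <- function(fps, threshold) {
  n <- nrow(fps)
  leaders <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    joined <- FALSE
    for (li in seq_along(leaders)) {
      if (tanimoto(fps[leaders[li], ], fps[i, ]) >= threshold) {
        assign[i] <- li
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      leaders <- c(leaders, i)
      assign[i] <- length(leaders)
    }
  }
  list(leaders = leaders, assign = assign)
}
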