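random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  # quaternion to rotation matrix (always proper)
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]),
           2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
         3, 3, byrow = TRUE)
}

test_that("Kabsch superposition nails identity and rigid motion", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(a, a)
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  R <- random_rotation(2)
  b <- a %*% t(R) + matrix(rep(c(4, -2, 9), each = 10), 10, 3)
  expect_lt(kabsch_superpose(a, b)$rmsd, 1e-10)
  # rotation is proper (no reflection)
  expect_equal(det(kabsch_superpose(a, b)$rotation), 1,
               tolerance = 1e-10)
})

test_that("Kabsch errors on degenerate input", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line + 0), "degenerate")
})

test_that("Kabsch RMSD matches a coarse rotation-grid oracle", {
  set.seed(3)
  a <- matrix(rnorm(30), 10, 3)
  b <- a %*% t(random_rotation(4)) + 0.3 * matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(a, b)
  # oracle: search Euler angles on a grid, refine locally with optim
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  obj <- function(ang) {
    R <- dockscreen:::euler_rotation(ang)
    sqrt(mean(rowSums((bc %*% t(R) - ac)^2)))
  }
  grid <- as.matrix(expand.grid(th1 = seq(-pi, pi, length.out = 13),
                                th2 = seq(-pi / 2, pi / 2,
                                          length.out = 7),
                                th3 = seq(-pi, pi, length.out = 13)))
  vals <- apply(grid, 1, obj)
  best <- stats::optim(grid[which.min(vals), ], obj,
                       control = list(reltol = 1e-14))
  expect_equal(fit$rmsd, best$value, tolerance = 1e-3)
  expect_lte(fit$rmsd, best$value + 1e-6)   # Kabsch is the optimum
})

test_that("Kabsch agrees with an independent superposition routine", {
  set.seed(5)
  a <- matrix(rnorm(45), 15, 3)
  b <- a %*% t(random_rotation(6)) + 0.2 * matrix(rnorm(45), 15, 3)
  fit <- kabsch_superpose(a, b)
  xyz_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(a)), mobile = as.vector(t(b))))
  ref_rmsd <- bio3d::rmsd(as.vector(t(a)), xyz_fit)
  # bio3d::rmsd reports 3 decimals
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 5e-3)
})

test_that("pure ring flip: plain RMSD > 0, corrected exactly 0", {
  ts <- sim_toy_structures(6, noise_sd = 0, seed = 7)
  # undo the rigid motion first (correction never re-fits); fit on the
  # C-alpha trace, which the label swap does not touch
  key <- paste(ts$model$resno, ts$model$elety)
  ref_key <- paste(ts$reference$resno, ts$reference$elety)
  m <- ts$model[match(ref_key, key), ]
  ca <- ts$reference$elety == "CA"
  fit <- kabsch_superpose(
    as.matrix(ts$reference[ca, c("x", "y", "z")]),
    as.matrix(m[ca, c("x", "y", "z")]))
  xyz <- as.matrix(m[, c("x", "y", "z")])
  m[, c("x", "y", "z")] <- sweep(xyz %*% t(fit$rotation), 2,
                                 fit$translation, `+`)
  res <- rmsd_symmetric(ts$reference, m)
  expect_gt(res$plain, 0.5)
  expect_lt(res$corrected, 1e-8)
  expect_setequal(res$flipped_resno, ts$swapped_resno)
})

test_that("residues without symmetric atoms are untouched", {
  set.seed(8)
  a <- data.frame(resno = rep(1:3, each = 4),
                  resid = "ALA",
                  elety = rep(c("N", "CA", "C", "O"), 3),
                  x = rnorm(12), y = rnorm(12), z = rnorm(12))
  b <- a
  b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] +
    0.1 * matrix(rnorm(36), 12, 3)
  res <- rmsd_symmetric(a, b)
  expect_equal(res$corrected, res$plain)
  expect_length(res$flipped_resno, 0)
})

test_that("per-residue correction equals the exhaustive-permutation min", {
  set.seed(9)
  ts <- sim_toy_structures(8, noise_sd = 0.6, seed = 9)
  key <- paste(ts$model$resno, ts$model$elety)
  ref_key <- paste(ts$reference$resno, ts$reference$elety)
  m <- ts$model[match(ref_key, key), ]
  res <- rmsd_symmetric(ts$reference, m)
  # brute force over all 2^k flip combinations (k symmetric residues)
  cat_swaps <- symmetric_atom_catalog()
  sym_res <- unique(ts$reference$resno[
    ts$reference$resid %in% names(cat_swaps)])
  expect_lte(length(sym_res), 8)
  xa <- as.matrix(ts$reference[, c("x", "y", "z")])
  best <- Inf
  for (mask in 0:(2^length(sym_res) - 1)) {
    mm <- m
    for (j in seq_along(sym_res)) {
      if (!bitwAnd(mask, bitwShiftL(1L, j - 1L))) next
      rn <- sym_res[j]
      rtype <- ts$reference$resid[ts$reference$resno == rn][1]
      for (pair in cat_swaps[[rtype]]) {
        i1 <- which(mm$resno == rn & ts$reference$elety == pair[1])
        i2 <- which(mm$resno == rn & ts$reference$elety == pair[2])
        tmp <- mm[i1, c("x", "y", "z")]
        mm[i1, c("x", "y", "z")] <- mm[i2, c("x", "y", "z")]
        mm[i2, c("x", "y", "z")] <- tmp
      }
    }
    xb <- as.matrix(mm[, c("x", "y", "z")])
    best <- min(best, sqrt(mean(rowSums((xa - xb)^2))))
  }
  expect_equal(res$corrected, best, tolerance = 1e-12)
  # hard invariant
  expect_lte(res$corrected, res$plain)
})

test_that("symmetry correction never exceeds plain RMSD", {
  for (seed in 1:5) {
    ts <- sim_toy_structures(7, noise_sd = runif(1, 0, 1), seed = seed)
    key <- paste(ts$model$resno, ts$model$elety)
    ref_key <- paste(ts$reference$resno, ts$reference$elety)
    m <- ts$model[match(ref_key, key), ]
    res <- rmsd_symmetric(ts$reference, m)
    expect_lte(res$corrected, res$plain + 1e-12)
  }
})

test_that("region report: identical structures give zero everywhere", {
  ts <- sim_toy_structures(10, rotation = c(0, 0, 0),
                           translation = c(0, 0, 0), noise_sd = 0,
                           seed = 10)
  rep <- region_report(ts$reference, ts$reference,
                       regions = list(binding_site = c(3, 6, 9),
                                      helix = 1:10))
  expect_true(all(rep$computable))
  expect_lt(max(rep$ca_rmsd), 1e-10)
  expect_lt(rep$sidechain_rmsd[rep$region == "binding_site"], 1e-10)
})

test_that("region report recovers generator ground truth under noise", {
  sigma <- 0.15
  ts <- sim_toy_structures(30, noise_sd = sigma, seed = 11)
  rep <- region_report(ts$model, ts$reference,
                       regions = list(helix = 1:30,
                                      binding_site = seq(3, 30, 3)))
  # post-fit Calpha RMSD should sit near sigma * sqrt(3)
  expect_equal(rep$ca_rmsd[rep$region == "helix"], sigma * sqrt(3),
               tolerance = 0.25)
  expect_gt(rep$n_ca[rep$region == "helix"], 25)
})

test_that("missing residues shrink counts without breaking the report", {
  ts <- sim_toy_structures(9, noise_sd = 0, seed = 12)
  ref_del <- ts$reference[ts$reference$resno != 3, ]
  rep_full <- region_report(ts$model, ts$reference,
                            regions = list(binding_site = c(3, 6, 9),
                                           rest = c(1, 2, 4, 5)))
  rep_del <- region_report(ts$model, ref_del,
                           regions = list(binding_site = c(3, 6, 9),
                                          rest = c(1, 2, 4, 5)))
  expect_lt(rep_del$n_ca[1], rep_full$n_ca[1])
  expect_equal(rep_del$ca_rmsd[rep_del$region == "rest"],
               rep_full$ca_rmsd[rep_full$region == "rest"],
               tolerance = 1e-10)
  # below 3 pairs: not computable, flagged
  rep_tiny <- region_report(ts$model, ts$reference,
                            regions = list(tiny = c(1, 2)))
  expect_false(rep_tiny$computable)
})

test_that("region YAML reading expands ranges", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("binding_site:", "  - 103", "  - 184",
               "loops:", "  - '160-163'", "  - 201"), path)
  rg <- read_regions(path)
  expect_equal(rg$binding_site, c(103L, 184L))
  expect_equal(rg$loops, c(160L, 161L, 162L, 163L, 201L))
})

test_that("RMSD is invariant under global rigid motion of either input", {
  ts <- sim_toy_structures(8, noise_sd = 0.3, seed = 13)
  base <- region_report(ts$model, ts$reference,
                        regions = list(all = 1:8))
  R <- random_rotation(14)
  moved <- ts$model
  xyz <- as.matrix(moved[, c("x", "y", "z")]) %*% t(R)
  moved[, c("x", "y", "z")] <- sweep(xyz, 2, c(11, -7, 2), `+`)
  rep2 <- region_report(moved, ts$reference,
                        regions = list(all = 1:8))
  expect_equal(rep2$ca_rmsd, base$ca_rmsd, tolerance = 1e-8)
})
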