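# brute-force ROC oracle: enumerate every threshold over the pooled
# scores and count rates directly
oracle_roc <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  thr <- c(-Inf, sort(unique(scores)))
  pts <- t(vapply(thr, function(t) {
    sel <- scores <= t
    c(fpr = sum(sel & labels == "decoy") / sum(labels == "decoy"),
      tpr = sum(sel & labels == "active") / sum(labels == "active"))
  }, c(fpr = 0, tpr = 0)))
  as.data.frame(pts)
}

test_that("ROC matches exhaustive threshold enumeration", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 40
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- sample(rep(c("active", "decoy"), c(12, n - 12)))
    roc <- compute_roc(scores, labels)
    expect_equal(roc, oracle_roc(scores, labels),
                 ignore_attr = TRUE)
  }
  # the spec's interleaved micro-case
  s <- c(1, 2, 3, 4, 5, 6)
  l <- c("active", "decoy", "active", "decoy", "active", "decoy")
  expect_equal(compute_roc(s, l), oracle_roc(s, l), ignore_attr = TRUE)
})

test_that("ROC endpoints and degenerate inputs behave", {
  # perfect separation: straight to TPR 1 at FPR 0
  roc <- compute_roc(c(1, 2, 10, 11), rep(c("active", "decoy"), each = 2))
  expect_equal(roc$tpr[roc$fpr == 0], c(0, 0.5, 1))
  expect_equal(roc[nrow(roc), ], data.frame(fpr = 1, tpr = 1),
               ignore_attr = TRUE)
  # missing scores excluded from the ranking
  roc2 <- compute_roc(c(1, NA, 2, NA), c("active", "active",
                                         "decoy", "decoy"))
  expect_equal(nrow(roc2), 3)
  expect_error(compute_roc(c(NA, 1), c("active", "decoy")), "active")
  expect_error(compute_roc(c(1, NA), c("active", "decoy")), "decoy")
})

test_that("random labels give a near-diagonal ROC", {
  set.seed(7)
  scores <- rnorm(20000)
  labels <- rep(c("active", "decoy"), 10000)
  roc <- compute_roc(scores, labels)
  at <- approx(roc$fpr, roc$tpr, xout = c(0.1, 0.3, 0.5, 0.8),
               ties = max)$y
  expect_equal(at, c(0.1, 0.3, 0.5, 0.8), tolerance = 0.05)
})

test_that("adjusted LogAUC closed forms hold at lambda = 0.001", {
  expect_equal(adjusted_logauc(data.frame(fpr = c(0, 1),
                                          tpr = c(0, 1))), 0)
  perfect <- data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  expect_equal(adjusted_logauc(perfect), 100 - 100 * 0.999 / (3 * log(10)),
               tolerance = 1e-12)
  expect_equal(adjusted_logauc(perfect), 85.538, tolerance = 1e-3)
  expect_error(adjusted_logauc(perfect, lambda_low = 0), "lambda")
  expect_error(adjusted_logauc(perfect, lambda_low = 1), "lambda")
})

test_that("adjusted LogAUC equals dense-grid quadrature", {
  # oracle: 1e6-point trapezoid on the log10 axis of the same polyline
  dense_oracle <- function(roc, lambda = 0.001) {
    tpr_l <- max(approx(roc$fpr, roc$tpr, xout = lambda, ties = max)$y,
                 roc$tpr[roc$fpr <= lambda])
    keep <- roc$fpr > lambda
    x <- c(lambda, roc$fpr[keep]); y <- c(tpr_l, roc$tpr[keep])
    if (x[length(x)] < 1) { x <- c(x, 1); y <- c(y, y[length(y)]) }
    grid <- exp(seq(log(lambda), 0, length.out = 1e6))
    yy <- approx(x, y, xout = grid, ties = max)$y
    u <- log10(grid)
    area <- sum(diff(u) * (yy[-1] + yy[-length(yy)]) / 2)
    100 * (area - (1 - lambda) / log(10)) / log10(1 / lambda)
  }
  set.seed(3)
  for (rep in 1:3) {
    fpr <- sort(c(0, runif(8), 1))
    tpr <- sort(c(0, runif(8), 1))
    roc <- data.frame(fpr = fpr, tpr = pmax(tpr, fpr * 0))
    expect_equal(adjusted_logauc(roc), dense_oracle(roc),
                 tolerance = 1e-6)
  }
})

test_that("adjusted LogAUC is invariant under monotone score transforms", {
  set.seed(5)
  scores <- rnorm(500)
  labels <- rep(c("active", "decoy"), c(100, 400))
  scores[labels == "active"] <- scores[labels == "active"] - 1
  base <- adjusted_logauc(compute_roc(scores, labels))
  for (f in list(function(x) 3 * x + 7, function(x) exp(x),
                 function(x) x^3)) {
    expect_equal(adjusted_logauc(compute_roc(f(scores), labels)), base)
  }
})

test_that("enrichment factor matches a brute-force count oracle", {
  oracle_ef <- function(scores, labels, fraction, ids) {
    keep <- !is.na(scores)
    scores <- scores[keep]; labels <- labels[keep]; ids <- ids[keep]
    n_top <- ceiling(fraction * length(scores))
    top <- order(scores, ids)[seq_len(n_top)]
    (sum(labels[top] == "active") / sum(labels == "active")) / fraction
  }
  # maximal enrichment: all actives first
  expect_equal(enrichment_factor(c(1:10, 101:1090) / 10,
                                 rep(c("active", "decoy"), c(10, 990)),
                                 0.01), 100)
  # spec micro-case: 5 actives among 200 compounds at fraction 0.05
  set.seed(9)
  s <- rnorm(200)
  l <- sample(rep(c("active", "decoy"), c(5, 195)))
  ids <- sprintf("c%03d", 1:200)
  expect_equal(enrichment_factor(s, l, 0.05, ids),
               oracle_ef(s, l, 0.05, ids))
  # with ties and missing values
  s2 <- round(rnorm(200), 1); s2[sample(200, 30)] <- NA
  l2 <- sample(rep(c("active", "decoy"), c(40, 160)))
  if (sum(!is.na(s2) & l2 == "active") > 0)
    expect_equal(enrichment_factor(s2, l2, 0.1, ids),
                 oracle_ef(s2, l2, 0.1, ids))
  expect_error(enrichment_factor(s, l, 0), "fraction")
})

test_that("random-ranking EF averages to 1", {
  set.seed(21)
  efs <- replicate(400, {
    s <- rnorm(200)
    l <- rep(c("active", "decoy"), c(20, 180))
    enrichment_factor(s, l, 0.05)
  })
  expect_equal(mean(efs), 1, tolerance = 0.08)
})

test_that("EF and LogAUC bounds always hold", {
  set.seed(13)
  for (rep in 1:20) {
    n_act <- sample(5:50, 1)
    m <- sim_score_matrix(1, n_act, sample(100:500, 1),
                          separation = runif(1, -1, 3),
                          seed = sample.int(1e6, 1))
    ens <- evaluate_ensemble(m)
    expect_gte(ens$logauc, -14.462)
    expect_lte(ens$logauc, 85.539)
    expect_gte(ens$ef_0.01, 0)
    expect_lte(ens$ef_0.01, 100)
  }
})

test_that("identical model columns give identical results", {
  set.seed(2)
  col <- rnorm(300)
  m <- score_matrix(cbind(a = col, b = col, c = col),
                    rep(c("active", "decoy"), c(50, 250)))
  ens <- evaluate_ensemble(m)
  expect_equal(length(unique(ens$logauc)), 1)
  expect_equal(length(unique(ens$ef_0.01)), 1)
})

test_that("percentile subset uses the nearest-rank convention", {
  ens <- structure(data.frame(model_id = sprintf("m%04d", 1:1000),
                              logauc = seq(0, 50, length.out = 1000)),
                   class = c("enrichment_ensemble", "data.frame"),
                   lambda_low = 0.001, fractions = 0.01)
  top <- percentile_subset(ens, 98)
  expect_equal(nrow(top), 20)   # 98th percentile of 1000 = top 20
  expect_equal(top$model_id[1], "m1000")
  expect_equal(nrow(percentile_subset(ens, 50)), 500)
})

test_that("model selection: top-k, max-min, and exhaustive oracle", {
  set.seed(4)
  n <- 20
  ens <- structure(data.frame(model_id = sprintf("m%02d", 1:n),
                              logauc = seq(40, 2, length.out = n)),
                   class = c("enrichment_ensemble", "data.frame"),
                   lambda_low = 0.001, fractions = 0.01)
  # k = 1: the single best model
  expect_equal(select_models(ens, percentile = 0, k = 1), "m01")
  expect_error(select_models(ens, percentile = 98, k = 5), "percentile")
  # duplicate of the seed is never chosen while distinct models remain
  d <- matrix(runif(n * n, 1, 2), n, n,
              dimnames = list(ens$model_id, ens$model_id))
  d <- (d + t(d)) / 2; diag(d) <- 0
  d["m01", "m02"] <- d["m02", "m01"] <- 0   # m02 == seed m01
  sel <- select_models(ens, percentile = 0, k = n - 1, diversity = d)
  expect_false("m02" %in% sel)
  # greedy selection is deterministic
  expect_identical(select_models(ens, percentile = 0, k = 5,
                                 diversity = d),
                   select_models(ens, percentile = 0, k = 5,
                                 diversity = d))
  # greedy max-min agrees with exhaustive search over all 1140 triples
  # on the greedy objective (seeded at the best model, then two adds)
  greedy <- select_models(ens, percentile = 0, k = 3, diversity = d)
  second <- names(which.max(d["m01", setdiff(ens$model_id, "m01")]))
  rest <- setdiff(ens$model_id, c("m01", second))
  third <- rest[which.max(vapply(rest, function(mm)
    min(d[mm, c("m01", second)]), 0))]
  expect_identical(greedy, c("m01", second, third))
})

test_that("graded separation is recovered in LogAUC order", {
  delta <- seq(0, 2, length.out = 12)
  m <- sim_score_matrix(12, 150, 2000, separation = delta, seed = 31)
  ens <- evaluate_ensemble(m)
  rho <- cor(delta, ens$logauc, method = "spearman")
  expect_gte(rho, 0.95)
})
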