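# Every statistic is checked against an independent oracle: closed forms,
# brute-force enumeration, or the corresponding base-R test function
# (never used inside the package itself).

test_that("cohens_kappa matches closed forms and a contingency oracle", {
  # perfect agreement / balanced perfect disagreement
  set.seed(1)
  for (i in 1:5) {
    x <- sample(letters[1:3], 30, replace = TRUE)
    expect_equal(cohens_kappa(x, x), 1)
    y <- sample(x)
    expect_equal(cohens_kappa(x, y), cohens_kappa(y, x))  # symmetry
  }
  expect_equal(cohens_kappa(c("G", "G", "L", "L"), c("L", "L", "G", "G")),
               -1)

  # 50-item 3-class table: diag (20,15,5), off-diag (3,2,1,1,2,1);
  # oracle: p_o and p_e computed from the integer margins directly
  counts <- matrix(c(20, 1, 2, 3, 15, 1, 2, 1, 5), 3, 3)  # [a, b]
  a <- rep(rep(1:3, 3), times = as.vector(counts))
  b <- rep(rep(1:3, each = 3), times = as.vector(counts))
  po <- sum(diag(counts)) / 50
  pe <- sum(rowSums(counts) * colSums(counts)) / 50^2
  expect_equal(cohens_kappa(a, b), (po - pe) / (1 - pe), tolerance = 1e-12)

  # degenerate conventions and contract errors
  expect_equal(cohens_kappa(rep("x", 4), rep("x", 4)), 1)
  expect_equal(cohens_kappa(rep("x", 4), rep("y", 4)), 0)
  expect_error(cohens_kappa(character(), character()), "empty")
  expect_error(cohens_kappa(1:3, 1:4), "mismatch")
})

test_that("sign_test reproduces exact binomial tails", {
  expect_equal(sign_test(rep(2, 10), 1, "greater"), 0.5^10)
  # n = 10, k = 5: sum_{i=5..10} C(10,i) / 2^10 = 638/1024
  v <- c(rep(2, 5), rep(0, 5))
  expect_equal(sign_test(v, 1, "greater"), 638 / 1024, tolerance = 1e-12)
  expect_equal(sign_test(v, 1, "less"), 638 / 1024, tolerance = 1e-12)
  # whole-tail: no value in the stated direction
  expect_equal(sign_test(rep(2, 8), 1, "less"), 1)
  expect_error(sign_test(rep(1, 5), 1, "greater"), "tied")
  # ties removed before counting
  expect_equal(sign_test(c(1, 1, 2, 2, 2), 1, "greater"), 0.5^3)
  # oracle: binom.test on random instances
  set.seed(7)
  for (i in 1:5) {
    x <- stats::rnorm(25, 0.3)
    k <- sum(x > 0); n <- sum(x != 0)
    expect_equal(sign_test(x, 0, "greater"),
                 stats::binom.test(k, n, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("sign_test null p-values are super-uniform", {
  set.seed(11)
  p <- replicate(2000, sign_test(stats::rnorm(21), 0, "greater"))
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(p <= alpha), alpha + 0.02)
})

test_that("bh_fdr matches the step-up formula and p.adjust", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:10) {
    p <- stats::runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))                       # adjusted >= raw
    expect_true(!is.unsorted(q[order(p)]))         # monotone step-up
  }
  expect_equal(bh_fdr(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
})

test_that("cmh_test matches mantelhaen.test and the K = 1 reduction", {
  # no association: identical row distributions in every stratum
  t0 <- matrix(c(10, 10, 20, 20, 5, 5), 2, 3)
  r0 <- cmh_test(list(t0, t0 * 2))
  expect_lt(r0$statistic, 1e-10)
  expect_equal(r0$p.value, 1, tolerance = 1e-6)

  # 2x2xK against the continuity-uncorrected Mantel-Haenszel oracle
  tabs22 <- list(matrix(c(12, 5, 7, 14), 2, 2),
                 matrix(c(8, 9, 11, 4), 2, 2))
  arr <- array(unlist(tabs22), dim = c(2, 2, 2))
  o <- stats::mantelhaen.test(arr, correct = FALSE)
  r <- cmh_test(tabs22)
  expect_equal(r$statistic, unname(o$statistic), tolerance = 1e-8)
  expect_equal(r$p.value, o$p.value, tolerance = 1e-8)

  # 2xJxK general association against mantelhaen.test
  set.seed(5)
  for (i in 1:3) {
    tabs <- lapply(1:3, function(k)
      matrix(stats::rpois(8, 15) + 1, 2, 4))
    arr <- array(unlist(tabs), dim = c(2, 4, 3))
    o <- stats::mantelhaen.test(arr)
    r <- cmh_test(tabs)
    expect_equal(r$statistic, unname(o$statistic), tolerance = 1e-8)
    expect_equal(r$df, unname(o$parameter))
    # stratum order invariance
    expect_equal(cmh_test(rev(tabs))$statistic, r$statistic,
                 tolerance = 1e-10)
  }

  # single stratum: (n-1)/n times the Pearson chi-square statistic
  t1 <- matrix(c(30, 10, 12, 28, 9, 11), 2, 3)
  n <- sum(t1)
  chi <- suppressWarnings(stats::chisq.test(t1, correct = FALSE))$statistic
  expect_equal(cmh_test(list(t1))$statistic, unname(chi) * (n - 1) / n,
               tolerance = 1e-8)
})

test_that("pearson_cor matches cor.test", {
  x <- 1:6
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  xf <- c(1.2, 3.4, 2.2, 5.9, 4.4, 7.1, 6.3, 8.8)
  yf <- c(2.1, 2.9, 3.8, 4.2, 6.0, 5.1, 7.7, 7.2)
  o <- stats::cor.test(xf, yf)
  r <- pearson_cor(xf, yf)
  expect_equal(r$r, unname(o$estimate), tolerance = 1e-10)
  expect_equal(r$p.value, o$p.value, tolerance = 1e-10)
  expect_error(pearson_cor(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("nmi: conventions, hand cases, and permutation invariance", {
  a <- c(0, 0, 1, 1)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, rep(1, 4)), 0)            # zero-entropy convention
  expect_equal(nmi(a, c(0, 1, 0, 1)), 0)        # independent partitions
  set.seed(9)
  for (i in 1:5) {
    x <- sample(1:4, 60, replace = TRUE)
    y <- sample(1:3, 60, replace = TRUE)
    v <- nmi(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
    relab <- c(9, 7, 8)[y]                      # label permutation
    expect_equal(nmi(x, relab), v, tolerance = 1e-12)
    expect_equal(nmi(x, x), 1)
  }
})

test_that("ari: brute-force pair enumeration oracle", {
  # independent 4-item case: every contingency cell is 1
  # pairs: same-same 0, adjustment by hand gives -1/2
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(ari(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)

  # brute-force oracle: count agreeing pairs over all C(n,2) pairs
  ari_brute <- function(a, b) {
    n <- length(a)
    ss <- sd <- ds <- dd <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) ss <- ss + 1
      else if (sa) sd <- sd + 1
      else if (sb) ds <- ds + 1
      else dd <- dd + 1
    }
    tot <- choose(n, 2)
    exp_ss <- (ss + sd) * (ss + ds) / tot
    mx <- ((ss + sd) + (ss + ds)) / 2
    if (mx == exp_ss) return(1)
    (ss - exp_ss) / (mx - exp_ss)
  }
  set.seed(13)
  for (i in 1:6) {
    x <- sample(1:3, 25, replace = TRUE)
    y <- sample(1:4, 25, replace = TRUE)
    expect_equal(ari(x, y), ari_brute(x, y), tolerance = 1e-12)
    expect_equal(ari(x, c(5, 9, 7)[x]), 1)      # relabeling invariance
  }
})

test_that("batch_asw: limits, undefined marker, and silhouette oracle", {
  set.seed(21)
  # perfectly mixed: both batches drawn from one tight cluster per group
  emb <- matrix(stats::rnorm(200 * 2, sd = 0.1), 200, 2)
  batch <- rep(c("F", "Z"), 100)
  group <- rep(c("g1", "g2"), each = 100)
  emb[group == "g2", ] <- emb[group == "g2", ] + 50
  v <- batch_asw(emb, batch, group)
  expect_lt(as.numeric(v), 0.2)
  expect_equal(as.numeric(v), 1 - attr(v, "raw"), tolerance = 1e-12)

  # no mixing: batches in far-apart clusters within one group
  emb2 <- rbind(matrix(stats::rnorm(100, sd = 0.1), 50, 2),
                matrix(stats::rnorm(100, sd = 0.1) + 100, 50, 2))
  v2 <- batch_asw(emb2, rep(c("F", "Z"), each = 50), rep("g", 100))
  expect_gt(as.numeric(v2), 0.95)

  # undefined when no group spans both batches
  v3 <- batch_asw(emb, rep(c("F", "Z"), each = 100), group)
  expect_true(is.na(v3))

  # internal silhouette against cluster::silhouette
  x <- matrix(stats::rnorm(60 * 3), 60, 3)
  lab <- sample(1:3, 60, replace = TRUE)
  d <- as.matrix(stats::dist(x))
  mine <- matchedsc:::.silhouette_widths(d, lab)
  ref <- cluster::silhouette(lab, stats::dist(x))[, "sil_width"]
  expect_equal(mine, unname(ref), tolerance = 1e-10)
})

test_that("pc_regression: closed form, limits, rotation invariance", {
  # axis-aligned case: PCA eigenvectors are the features themselves,
  # feature 1 is exactly the covariate, feature 2 is orthogonal to it
  f1 <- c(-1, -1, 1, 1)
  f2 <- c(-0.1, 0.1, -0.1, 0.1)
  cov <- c("A", "A", "B", "B")
  expected <- stats::var(f1) / (stats::var(f1) + stats::var(f2))
  expect_equal(pc_regression(cbind(f1, f2), cov, n_pcs = 2), expected,
               tolerance = 1e-8)

  set.seed(31)
  X <- matrix(stats::rnorm(400 * 6), 400, 6)
  lab <- sample(c("a", "b"), 400, replace = TRUE)
  expect_lt(pc_regression(X, lab, n_pcs = 5), 0.05)        # null limit
  Xb <- X * 0.01
  Xb[, 1] <- as.numeric(lab == "a") * 10
  expect_gt(pc_regression(Xb, lab, n_pcs = 5), 0.95)       # batch-driven
  expect_equal(pc_regression(X, rep("a", 400), n_pcs = 5), 0)  # constant

  # orthogonal rotation leaves the score unchanged
  Q <- qr.Q(qr(matrix(stats::rnorm(36), 6, 6)))
  v1 <- pc_regression(X, lab, n_pcs = 4)
  v2 <- pc_regression(X %*% Q, lab, n_pcs = 4)
  expect_equal(v1, v2, tolerance = 1e-8)
})
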