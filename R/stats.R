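## From-scratch implementations of every statistic used by the analysis.
## Nothing here delegates to stats::cor.test, stats::p.adjust,
## stats::mantelhaen.test or cluster::silhouette -- those serve as
## independent oracles in the test suite.

#' Cohen's kappa between two categorical label sequences
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` where `p_o`
#' is the observed agreement rate and `p_e` the expected agreement under
#' independence of the marginal label distributions. The category universe
#' is the union of observed labels. Degenerate cases (`p_e = 1`, both raters
#' constant): kappa is 1 when the constants agree and 0 when they differ,
#' avoiding 0/0.
#'
#' @param a,b equal-length label vectors (character/factor/integer).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) == 0) stop("empty input", call. = FALSE)
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  lev <- union(unique(a), unique(b))
  fa <- factor(a, levels = lev)
  fb <- factor(b, levels = lev)
  n <- length(a)
  tab <- table(fa, fb)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps * 4)
    return(if (p_o >= 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Exact one-sample sign test
#'
#' Tests whether values fall above (`alternative = "greater"`) or below
#' (`"less"`) a stated center. Ties at the center are removed; with `n`
#' remaining values and `k` in the stated direction, the p-value is the
#' exact binomial tail `P(X >= k)` for `X ~ Binomial(n, 1/2)`.
#'
#' @param values numeric vector.
#' @param null_center the hypothesized center.
#' @param alternative `"greater"` or `"less"`.
#' @return the exact p-value.
#' @export
sign_test <- function(values, null_center = 0,
                      alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  values <- values[!is.na(values)]
  values <- values[values != null_center]
  n <- length(values)
  if (n == 0) stop("all values tied at the null center", call. = FALSE)
  k <- if (alternative == "greater") sum(values > null_center)
       else sum(values < null_center)
  ## P(X >= k) with X ~ Bin(n, 1/2)
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: for sorted p-values, `q_(i) = min_{j >= i}
#' (m / j) p_(j)` clipped at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA` passed through.
#' @return adjusted p-values in input order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  x <- p[ok]
  if (length(x) && (min(x) < 0 || max(x) > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  m <- length(x)
  if (m) {
    o <- order(x)
    q <- pmin(1, rev(cummin(rev(x[o] * m / seq_len(m)))))
    adj <- numeric(m)
    adj[o] <- q
    out[ok] <- adj
  }
  out
}

#' Generalized Cochran-Mantel-Haenszel test (2 x J x K)
#'
#' General-association CMH statistic for a set of K strata, each a 2 x J
#' contingency table with common column categories (here: platform rows,
#' cell-type columns, matched-sample strata). No continuity correction.
#' Strata with total < 2 or an empty row margin carry no information and
#' are excluded (with a message); columns empty in every retained stratum
#' are dropped before inversion. Degrees of freedom are J' - 1 for the J'
#' retained columns.
#'
#' @param tables a list of 2 x J non-negative integer matrices with
#'   identical column order.
#' @return list with `statistic`, `df`, `p.value`, `n_strata_used`.
#' @export
cmh_test <- function(tables) {
  if (!length(tables)) stop("no strata", call. = FALSE)
  J <- ncol(tables[[1]])
  for (t in tables)
    if (nrow(t) != 2 || ncol(t) != J || any(t < 0))
      stop("each stratum must be a non-negative 2 x J table", call. = FALSE)
  usable <- vapply(tables, function(t)
    sum(t) >= 2 && all(rowSums(t) > 0), logical(1))
  if (!all(usable))
    message("cmh_test: excluding ", sum(!usable),
            " degenerate strata (empty margin or total < 2)")
  tables <- tables[usable]
  if (!length(tables)) stop("no informative strata", call. = FALSE)
  keep <- which(Reduce(`+`, lapply(tables, colSums)) > 0)
  if (length(keep) < 2)
    stop("fewer than 2 cell-type categories with counts", call. = FALSE)
  Jp <- length(keep)
  d <- numeric(Jp - 1)
  V <- matrix(0, Jp - 1, Jp - 1)
  for (t in tables) {
    t <- t[, keep, drop = FALSE]
    n <- sum(t)
    r1 <- sum(t[1, ]); r2 <- sum(t[2, ])
    cs <- colSums(t)
    u <- t[1, -Jp]
    e <- r1 * cs[-Jp] / n
    cv <- (r1 * r2 / (n^2 * (n - 1))) *
      (n * diag(cs[-Jp], nrow = Jp - 1) - outer(cs[-Jp], cs[-Jp]))
    d <- d + (u - e)
    V <- V + cv
  }
  stat <- tryCatch(drop(t(d) %*% solve(V, d)),
                   error = function(e) stop(
                     "singular covariance in CMH statistic", call. = FALSE))
  df <- Jp - 1
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_strata_used = length(tables))
}

#' Pearson correlation with two-sided t-test
#'
#' Product-moment correlation; the p-value comes from
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return list with `r` and `p.value`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) stop("zero variance", call. = FALSE)
  r <- sum(xc * yc) / (sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) return(list(r = r, p.value = 0))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p.value = 2 * stats::pt(-abs(tval), n - 2))
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Normalized mutual information between two partitions
#'
#' `I(a; b)` divided by the arithmetic mean of the two entropies (the scIB
#' default normalization). If either partition has zero entropy (a single
#' cluster) the score is 0 by convention.
#'
#' @param a,b equal-length label vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (!length(a)) stop("empty partitions", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  ha <- .entropy(rowSums(tab))
  hb <- .entropy(colSums(tab))
  if (ha == 0 || hb == 0) return(0)
  p <- tab / n
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  ex <- outer(pa, pb)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / ex[nz]))
  v <- mi / mean(c(ha, hb))
  max(0, min(1, v))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting Rand index adjusted for chance via the hypergeometric
#' expectation: `(RI - E[RI]) / (max RI - E[RI])`.
#'
#' @param a,b equal-length label vectors (n >= 2).
#' @return ARI (<= 1; 1 iff the partitions match up to relabeling).
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  tot <- ch2(n)
  expected <- sum_a * sum_b / tot
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)  # both partitions trivial (all-one-cluster
                                 # or all-singletons): perfect agreement
  (sum_ij - expected) / (mx - expected)
}

.silhouette_widths <- function(d, labels) {
  ## d: dist-style full matrix; labels: factor; returns s_i per item
  labels <- as.factor(labels)
  n <- length(labels)
  s <- numeric(n)
  lev <- levels(labels)
  idx <- split(seq_len(n), labels)
  for (i in seq_len(n)) {
    own <- labels[i]
    own_idx <- setdiff(idx[[own]], i)
    if (!length(own_idx)) { s[i] <- 0; next }
    a <- mean(d[i, own_idx])
    b <- Inf
    for (l in lev) {
      if (l == own || !length(idx[[l]])) next
      b <- min(b, mean(d[i, idx[[l]]]))
    }
    if (!is.finite(b)) { s[i] <- 0; next }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

#' Batch average silhouette width (platform-mixing score)
#'
#' scIB-style batch ASW: within each biological group (cell type), compute
#' silhouette widths of the batch (platform) labels on the embedding with
#' Euclidean distance, transform each as `1 - |s|`, average within the
#' group, then average the group scores. The raw scIB orientation (1 =
#' perfectly mixed) is returned as attribute `"raw"`; the primary value is
#' the complement ("mixing badness", 0 = good mixing, 1 = none) so that
#' lower = better mixing. Groups without at least 2 batches of at least 2
#' cells each are skipped; if every group is skipped the result is the
#' undefined marker `NA`.
#'
#' @param embedding numeric matrix, items x dims.
#' @param batch batch (platform) label per item.
#' @param group biological group (cell type) label per item.
#' @return mixing badness in `[0, 1]`, or `NA` if undefined; attributes
#'   `raw` (scIB orientation) and `groups_used`.
#' @export
batch_asw <- function(embedding, batch, group) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  if (length(batch) != n || length(group) != n)
    stop("label length mismatch", call. = FALSE)
  scores <- c()
  used <- character()
  for (g in unique(as.character(group))) {
    sel <- which(group == g)
    bt <- table(batch[sel])
    bt <- bt[bt > 0]
    if (length(bt) < 2 || min(bt) < 2) next
    d <- as.matrix(stats::dist(embedding[sel, , drop = FALSE]))
    s <- .silhouette_widths(d, batch[sel])
    scores <- c(scores, mean(1 - abs(s)))
    used <- c(used, g)
  }
  if (!length(scores))
    return(structure(NA_real_, raw = NA_real_, groups_used = character()))
  raw <- mean(scores)
  structure(1 - raw, raw = raw, groups_used = used)
}

#' Principal-component regression score for a covariate
#'
#' Fraction of retained principal-component variance attributable to a
#' covariate: PCA on the data, per-component R-squared from an ordinary
#' least-squares fit of the scores on the covariate (one-hot encoded if
#' categorical), combined as `sum(R2_i Var_i) / sum(Var_i)` over the top
#' `n_pcs` components. 0 = the covariate explains nothing (good mixing for
#' a batch covariate), 1 = fully covariate-driven.
#'
#' @param data numeric matrix, items x features (an embedding or expression
#'   matrix).
#' @param covariate per-item labels (categorical) or a numeric vector.
#' @param n_pcs number of components (default `min(50, n - 2)`).
#' @return score in `[0, 1]`; 0 if the covariate is constant.
#' @export
pc_regression <- function(data, covariate, n_pcs = NULL) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (is.null(n_pcs)) n_pcs <- min(50L, n - 2L)
  if (n < n_pcs + 2) stop("need at least n_pcs + 2 items", call. = FALSE)
  if (length(covariate) != n) stop("covariate length mismatch", call. = FALSE)
  if (length(unique(covariate)) < 2) return(0)
  X <- if (is.numeric(covariate)) cbind(1, covariate)
       else stats::model.matrix(~f, data.frame(f = factor(covariate)))
  pc <- stats::prcomp(data, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  vars <- pc$sdev[seq_len(k)]^2
  r2 <- vapply(seq_len(k), function(i) {
    y <- pc$x[, i]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(0)
    fit <- stats::lm.fit(X, y)
    1 - sum(fit$residuals^2) / tss
  }, numeric(1))
  v <- sum(r2 * vars) / sum(vars)
  max(0, min(1, v))
}
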