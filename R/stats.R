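# The raw statistics behind the per-frame feature battery. These are used
# as signal features — magnitudes tracked over time — not as hypothesis
# tests, so every function returns the test statistic itself, never a
# p-value. Tie handling follows the standard conventions (midranks;
# Wilcoxon drops zero differences).

#' Jonckheere-Terpstra trend statistic
#'
#' For groups in a fixed a-priori order, counts cross-group pairs that
#' increase with the ordering, ties counted one half:
#' `J = sum over ordered group pairs (g < h) of #\{x in g, y in h : x < y\}
#' + 0.5 * #\{x = y\}`.
#'
#' @param groups ordered list of numeric vectors, each non-empty.
#' @return The statistic `J` (a single number).
#' @examples
#' jonckheere_stat(list(c(1, 2), c(3, 4)))  # 4: all cross-pairs increase
#' jonckheere_stat(list(c(1, 1), c(1, 1)))  # 2: four tied pairs x 1/2
#' @export
jonckheere_stat <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_input("'groups' must be an ordered list of at least two vectors")
  }
  if (any(lengths(groups) == 0L)) stop_input("empty group")
  k <- length(groups)
  J <- 0
  for (g in seq_len(k - 1L)) {
    sg <- sort(groups[[g]])
    for (h in seq(g + 1L, k)) {
      y <- groups[[h]]
      n_le <- findInterval(y, sg)                    # #\{x <= y\}
      n_lt <- findInterval(y, sg, left.open = TRUE)  # #\{x <  y\}
      J <- J + sum(n_lt) + 0.5 * sum(n_le - n_lt)
    }
  }
  J
}

# Wilcoxon signed-rank statistic W: zero differences dropped, midranks of
# |d|, W = sum of ranks where d > 0 (the V of stats::wilcox.test).
wilcoxon_signed_rank_stat <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) return(0)
  r <- rank(abs(d))
  sum(r[d > 0])
}

# Mann-Whitney U for the first sample, midranks for ties (the W of
# stats::wilcox.test(x, y)).
mann_whitney_u <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

# Two-sample Kolmogorov-Smirnov distance D = sup |F1 - F2| over the pooled
# sample, ties handled by evaluating only at distinct pooled values.
ks_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  ord <- order(z)
  steps <- cumsum(ifelse(ord <= n1, 1 / n1, -1 / n2))
  zs <- z[ord]
  keep <- c(diff(zs) != 0, TRUE)
  max(abs(steps[keep]))
}

# Kruskal-Wallis H with the usual tie correction; 0 when every pooled value
# is tied (the statistic is then a 0/0 form and the signal content is nil).
kruskal_wallis_stat <- function(groups) {
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(unlist(groups, use.names = FALSE))
  Rj <- vapply(split(r, rep(seq_along(groups), n)), sum, numeric(1))
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / n) - 3 * (N + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(0)
  H / C
}

# Friedman chi-square with pixels as blocks and the k frames of the window
# as treatments; midranks within blocks and the standard tie correction
# (denominator n*k*(k+1) - sum(t^3 - t)/(k - 1)). 0 when fully degenerate.
friedman_stat <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  L <- matrix(0, n, k)   # count of entries in the row strictly less
  T_ <- matrix(0, n, k)  # count of entries in the row tied (incl. self)
  for (j in seq_len(k)) {
    for (l in seq_len(k)) {
      L[, j] <- L[, j] + (mat[, l] < mat[, j])
      T_[, j] <- T_[, j] + (mat[, l] == mat[, j])
    }
  }
  r <- L + (T_ + 1) / 2
  tie_term <- sum(T_^2 - 1)          # == sum over blocks of sum(t^3 - t)
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom == 0) return(0)
  12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
}

# Two-sample chi-square distance on paired 16-bin histograms over [0, 255].
# Expected count per bin is the mean of the two observed counts; bins empty
# in both histograms are excluded.
chi_square_hist_stat <- function(x, y, nbins = 16L) {
  bx <- pmin(floor(x / (256 / nbins)) + 1L, nbins)
  by <- pmin(floor(y / (256 / nbins)) + 1L, nbins)
  o1 <- tabulate(bx, nbins)
  o2 <- tabulate(by, nbins)
  e <- (o1 + o2) / 2
  keep <- e > 0
  sum((o1[keep] - e[keep])^2 / e[keep] + (o2[keep] - e[keep])^2 / e[keep])
}

# Least-squares slope of y regressed on x; 0 when x is constant (no trend
# information), consistent with the Pearson degenerate-case convention.
regression_slope <- function(x, y) {
  vx <- stats::var(x)
  if (vx == 0) return(0)
  stats::cov(x, y) / vx
}

# Pearson correlation with the degenerate-case convention 0 when either
# sample is constant.
safe_cor <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)
}

rmse_stat <- function(x, y) sqrt(mean((x - y)^2))
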