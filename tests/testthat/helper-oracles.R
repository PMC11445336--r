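# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and vectorized shortcuts): explicit formulas and loops
# only, so they can arbitrate the implementation.

# Pearson correlation from the explicit sum formula
bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# two-sided p for a correlation via the t CDF
bf_cor_p <- function(r, df) {
  t <- abs(r) * sqrt(df / (1 - r^2))
  2 * (1 - pt(t, df))
}

# per-edge loop over a ROI x frame matrix: r and p matrices
bf_subject_connectivity <- function(values) {
  R <- nrow(values); n <- ncol(values)
  r <- diag(R) * 0; p <- matrix(1, R, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i == j) next
    r[i, j] <- bf_pearson(values[i, ], values[j, ])
    p[i, j] <- bf_cor_p(r[i, j], n - 2)
  }
  list(r = r, p = p)
}

# one-sample t test of z-values against zero, per edge, explicit formula
bf_group_mean <- function(z_list) {
  n <- length(z_list)
  R <- nrow(z_list[[1]])
  zbar <- matrix(0, R, R); p <- matrix(1, R, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i == j) next
    zs <- sapply(z_list, function(z) z[i, j])
    zbar[i, j] <- mean(zs)
    s <- sqrt(sum((zs - mean(zs))^2) / (n - 1))
    t <- mean(zs) / (s / sqrt(n))
    p[i, j] <- 2 * (1 - pt(abs(t), n - 1))
  }
  list(zbar = zbar, p = p)
}

# Holm step-down by hand: sort, scale by (m - rank + 1), running max, cap
bf_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, (m - k + 1) * p[o[k]])
    adj[o[k]] <- min(1, running)
  }
  adj
}

# row-wise count of nonzero off-diagonal entries
bf_degree <- function(a) {
  R <- nrow(a)
  d <- integer(R)
  for (i in seq_len(R)) for (j in seq_len(R))
    if (i != j && a[i, j] != 0) d[i] <- d[i] + 1L
  d
}

# Mann-Whitney U, first-sample orientation: count of pairs x_i > y_j
# (+ 0.5 per tie)
bf_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# all n! permutations of 1..n, one per row (exact permutation null)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# greedy component matching (for comparison with the optimal assignment)
greedy_match_total <- function(R) {
  total <- 0
  A <- abs(R)
  for (k in seq_len(nrow(R))) {
    ij <- which(A == max(A), arr.ind = TRUE)[1, ]
    total <- total + A[ij[1], ij[2]]
    A[ij[1], ] <- -Inf; A[, ij[2]] <- -Inf
  }
  total
}
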