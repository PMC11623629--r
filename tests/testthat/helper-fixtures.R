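# Small fixtures built in code, shared across test files.

random_rdm <- function(n, seed = NULL, labels = sprintf("c%02d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  m <- as.matrix(dist(pts))
  rownames(m) <- colnames(m) <- labels
  rdm(m)
}

random_patterns_pair <- function(n_cond, n_units, seed = 1,
                                 subject = "sub01") {
  set.seed(seed)
  mk <- function(ses) {
    m <- matrix(rnorm(n_cond * n_units), n_cond)
    rownames(m) <- sprintf("c%02d", seq_len(n_cond))
    zscore_profiles(response_patterns(m, subject_id = subject,
                                      session_id = ses))
  }
  list(session1 = mk(1), session2 = mk(2))
}

# Brute-force oracles, written independently of the implementation paths.

oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

oracle_splitdata <- function(m1, m2) {
  n <- nrow(m1)
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    M[i, j] <- oracle_pearson(m1[i, ], m2[j, ])
  d <- 1 - (M + t(M)) / 2
  diag(d) <- 0
  d
}

# multiple regression R^2 via explicit normal equations
oracle_r2 <- function(y, X) {
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  res <- y - Xd %*% beta
  1 - sum(res^2) / sum((y - mean(y))^2)
}

oracle_rank_std <- function(v) {
  r <- rank(v)
  (r - mean(r)) / sd(r)
}

# Benjamini-Hochberg step-up, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}
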