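test_that("spearman fit matches a rank-then-Pearson oracle and rank invariances", {
  n8 <- random_rdm(8, seed = 1)
  m8 <- random_rdm(8, seed = 2)
  expect_equal(spearman_fit(n8, m8),
               oracle_spearman(rdm_vec(n8), rdm_vec(m8)),
               tolerance = 1e-12)
  expect_equal(spearman_fit(n8, n8), 1)
  # monotone transforms preserve (or reverse) the fit exactly
  inc <- rdm(exp(as.matrix(n8)) - 1 + as.matrix(n8), n8$labels)
  expect_equal(spearman_fit(n8, inc), 1)
  dec_m <- max(as.matrix(n8)) - as.matrix(n8)
  diag(dec_m) <- 0
  expect_equal(spearman_fit(n8, rdm(dec_m, n8$labels)), -1)
  flat <- rdm(matrix(1, 8, 8) - diag(8), n8$labels)
  expect_error(spearman_fit(n8, flat), "constant")
})

test_that("joint fit equals a normal-equations oracle on rank-standardized vectors", {
  neural <- random_rdm(20, seed = 3)
  models <- lapply(1:3, function(i) random_rdm(20, seed = 10 + i))
  r2 <- joint_fit(neural, models)
  y <- oracle_rank_std(rdm_vec(neural))
  X <- sapply(models, function(m) oracle_rank_std(rdm_vec(m)))
  expect_equal(r2, oracle_r2(y, X), tolerance = 1e-10)
  # single model identical to neural -> R^2 = 1
  expect_equal(joint_fit(neural, list(neural)), 1, tolerance = 1e-12)
  # single-model consistency with the Spearman fit
  for (i in 1:3)
    expect_equal(joint_fit(neural, models[i]),
                 spearman_fit(neural, models[[i]])^2, tolerance = 1e-10)
  # collinear models raise a rank-deficiency error naming the culprit
  expect_error(joint_fit(neural, c(models, models[1])), "collinear")
})

# a permutation of 1..15 with exactly zero correlation to 1..15: starting
# from the identity (sum of i*s(i) = 1240), disjoint swaps at distances
# 14, 8, 4, 2 reduce the sum by 196 + 64 + 16 + 4 = 280, hitting the
# zero-covariance value 960 = (sum 1..15)^2 / 15 exactly.
rank_orthogonal_perm <- function() {
  s <- 1:15
  for (sw in list(c(1, 15), c(2, 10), c(3, 7), c(4, 6)))
    s[sw] <- s[rev(sw)]
  s
}

test_that("a model rank-orthogonal to the neural vector explains nothing", {
  v <- 1:15
  w <- rank_orthogonal_perm()
  expect_equal(cor(rank(v), rank(w)), 0)
  mk <- function(x) {
    m <- matrix(0, 6, 6); m[lower.tri(m)] <- x; rdm(m + t(m))
  }
  expect_equal(joint_fit(mk(v), list(mk(w))), 0, tolerance = 1e-12)
})

test_that("variance partitioning obeys full-minus-nested exactly", {
  neural <- random_rdm(15, seed = 5)
  models <- setNames(lapply(1:4, function(i) random_rdm(15, seed = 20 + i)),
                     c("a", "b", "c", "d"))
  pt <- variance_partition(neural, models)
  full <- joint_fit(neural, models)
  for (r in seq_len(nrow(pt))) {
    nested <- joint_fit(neural, models[setdiff(names(models),
                                               pt$partition[r])])
    expect_equal(pt$full_r2[r], full, tolerance = 1e-12)
    expect_equal(pt$nested_r2[r], nested, tolerance = 1e-12)
    expect_equal(pt$unique_r2[r], full - nested, tolerance = 1e-12)
    expect_gte(pt$unique_r2[r], -1e-12)
  }
  # grouped partition
  pg <- variance_partition(neural, models, partitions = list(c("a", "b")))
  expect_equal(pg$unique_r2,
               full - joint_fit(neural, models[c("c", "d")]),
               tolerance = 1e-12)
  # duplicated model contributes zero unique variance
  dup <- c(models, list(a2 = models$a))
  pd <- variance_partition(neural, dup, partitions = list("a2"))
  expect_equal(pd$unique_r2, 0, tolerance = 1e-10)
  expect_error(variance_partition(neural, models, partitions = list("zz")),
               "unknown")
})

test_that("orthogonal ranked predictors decompose the full R^2 additively", {
  v <- 1:15
  w <- rank_orthogonal_perm()
  mk <- function(x) {
    m <- matrix(0, 6, 6); m[lower.tri(m)] <- x; rdm(m + t(m))
  }
  models <- list(a = mk(v), b = mk(w))
  set.seed(6)
  neural <- mk(v + w + rnorm(15, sd = .1))
  pt <- variance_partition(neural, models)
  expect_equal(sum(pt$unique_r2), pt$full_r2[1], tolerance = 1e-10)
})

test_that("leave-one-out intersubject ceiling matches an explicit loop oracle", {
  subs <- lapply(1:5, function(i) random_rdm(8, seed = 30 + i))
  isc <- isc_noise_ceiling(subs)
  for (i in 1:5) {
    others <- Reduce(`+`, lapply(subs[-i], as.matrix)) / 4
    expect_equal(isc$per_subject[i],
                 oracle_spearman(rdm_vec(subs[[i]]), others[lower.tri(others)]),
                 tolerance = 1e-12)
  }
  expect_equal(isc$mean, tanh(mean(atanh(isc$per_subject))),
               tolerance = 1e-12)
  # identical subjects -> ISC 1; rank-reversed pair -> -1 each
  same <- isc_noise_ceiling(list(subs[[1]], subs[[1]], subs[[1]]))
  expect_equal(same$per_subject, rep(1, 3))
  rev_m <- max(as.matrix(subs[[1]])) - as.matrix(subs[[1]])
  diag(rev_m) <- 0
  two <- isc_noise_ceiling(list(subs[[1]], rdm(rev_m, subs[[1]]$labels)))
  expect_equal(two$per_subject, c(-1, -1))
  expect_error(isc_noise_ceiling(subs[1]), "2 subjects")
})

test_that("ceiling fractions reproduce the printed percentages", {
  expect_equal(round(ceiling_fraction(0.22, 0.75), 1), 39.1)
  expect_lte(ceiling_fraction(0.22, 0.75), 40)
  expect_equal(round(ceiling_fraction(0.118, 0.75)), 21)
  expect_equal(round(ceiling_fraction(0.068, 0.75)), 12)
  expect_equal(ceiling_fraction(0, 0.5), 0)
  set.seed(7)
  for (x in runif(5)) expect_equal(ceiling_fraction(x, 1), 100 * x)
  expect_error(ceiling_fraction(0.5, 0), "ceiling_r")
  expect_error(ceiling_fraction(1.2, 0.5), "model_r2")
})

test_that("rsa_fit bundles per-subject fits with group summaries and methods", {
  set.seed(8)
  models <- setNames(lapply(1:3, function(i) random_rdm(10, seed = 40 + i)),
                     c("m1", "m2", "m3"))
  subs <- lapply(1:4, function(s) {
    base <- as.matrix(models$m1) + matrix(rnorm(100, sd = .2), 10)
    base <- (base + t(base)) / 2; diag(base) <- 0
    rdm(pmax(base, 0), models$m1$labels)
  })
  fit <- rsa_fit(subs, models)
  expect_s3_class(fit, "rsa_fit")
  expect_equal(dim(fit$spearman), c(4, 3))
  expect_equal(unname(fit$spearman_group["m1"]),
               tanh(mean(atanh(fit$spearman[, "m1"]))), tolerance = 1e-12)
  expect_equal(unname(fit$joint_r2[1]), joint_fit(subs[[1]], models),
               tolerance = 1e-12)
  expect_equal(names(which.max(fit$spearman_group)), "m1")
  expect_output(print(fit), "RSA fit")
  expect_output(print(summary(fit)), "noise ceiling")
  expect_equal(coef(fit), fit$spearman_group)
})
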