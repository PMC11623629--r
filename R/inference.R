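#' Fisher z-transform
#'
#' `fisher_z` maps correlations to the variance-stabilized arctanh scale on
#' which correlations are averaged and tested; `fisher_z_inverse` maps back.
#'
#' @param r correlations with `|r| < 1`.
#' @param z values on the Fisher-z scale.
#' @return transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    stop_input("fisher_z undefined for |r| >= 1")
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

test_result <- function(observed, null, n_resamples, method, seed) {
  p <- (1 + sum(null >= observed)) / (n_resamples + 1)
  structure(list(
    observed = observed, p = p,
    null_summary = list(n = length(null), mean = mean(null),
                        quantiles = quantile(null, c(.025, .5, .975))),
    method = method, seed = seed, n_resamples = n_resamples
  ), class = "rsa_test")
}

#' @export
print.rsa_test <- function(x, ...) {
  cat(sprintf("%s: observed = %.4f, p = %.4g (%d resamples)\n",
              x$method, x$observed, x$p, x$n_resamples))
  invisible(x)
}

#' Sign-flip permutation test for group-level correlations
#'
#' Under the null hypothesis that subject-level correlations come from a
#' distribution symmetric around zero, each subject's Fisher-z value is
#' randomly negated at every permutation and the flipped values averaged.
#' The observed statistic is the back-transformed mean of the Fisher-z
#' values. The one-tailed p-value uses the add-one convention,
#' `p = (1 + #{null >= observed}) / (n_perms + 1)`, with ties counting
#' against rejection; p is never 0 and never below `1 / (n_perms + 1)`.
#'
#' @param values per-subject correlations in `(-1, 1)`, length >= 2.
#' @param n_perms number of permutations.
#' @param seed optional integer seed.
#' @return an `rsa_test` (observed statistic on the correlation scale).
#' @export
signflip_permutation_test <- function(values, n_perms = 10000, seed = NULL) {
  if (length(values) < 2L) stop_input("need at least 2 subjects")
  if (any(abs(values) >= 1))
    stop_input("infinite Fisher-z: |correlation| = 1")
  if (!is_count(n_perms)) stop_input("n_perms must be a positive count")
  set_seed_if(seed)
  z <- atanh(values)
  n <- length(z)
  signs <- matrix(sample(c(-1, 1), n * n_perms, replace = TRUE), n_perms, n)
  null_z <- as.vector(signs %*% z) / n
  obs_z <- mean(z)
  out <- test_result(obs_z, null_z, n_perms, "sign-flip permutation", seed)
  out$observed <- tanh(obs_z)
  out$null_summary$mean <- tanh(out$null_summary$mean)
  out$null_summary$quantiles <- tanh(out$null_summary$quantiles)
  out
}

#' Re-centered bootstrap test for group-level R-squared
#'
#' In-sample R^2 values are positively biased, so a permutation distribution
#' around zero would be too permissive. Instead, subject-level values are
#' resampled with replacement, the mean recomputed at each iteration, and
#' the observed mean subtracted from the bootstrap distribution, re-centering
#' it around zero; the one-tailed add-one p-value compares the observed mean
#' against this re-centered null.
#'
#' @param values per-subject statistics (e.g. R^2), length >= 2.
#' @param n_boot number of bootstrap iterations.
#' @param seed optional integer seed.
#' @return an `rsa_test`.
#' @export
recentered_bootstrap_test <- function(values, n_boot = 10000, seed = NULL) {
  if (length(values) < 2L) stop_input("need at least 2 subjects")
  if (!is_count(n_boot)) stop_input("n_boot must be a positive count")
  set_seed_if(seed)
  n <- length(values)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  boot_means <- rowMeans(matrix(values[idx], n_boot, n))
  observed <- mean(values)
  null <- boot_means - observed
  test_result(observed, null, n_boot, "re-centered bootstrap", seed)
}

#' Condition-label permutation null for an RDM fit
#'
#' Builds a null distribution for any RDM fit statistic by permuting the
#' condition labels of the model RDM -- one random permutation applied
#' simultaneously to its rows and columns per iteration -- and recomputing
#' the statistic. The identity permutation reproduces the observed statistic
#' exactly.
#'
#' @param neural,model `rdm`s with matched labels.
#' @param statistic function `(neural, model) -> scalar`; defaults to
#'   [spearman_fit()].
#' @param n_perms number of permutations.
#' @param seed optional integer seed.
#' @return an `rsa_test`.
#' @export
label_permutation_null <- function(neural, model, statistic = spearman_fit,
                                   n_perms = 10000, seed = NULL) {
  neural <- as_rdm(neural); model <- as_rdm(model)
  if (!identical(neural$labels, model$labels))
    stop_input("RDM labels do not match")
  if (!is_count(n_perms)) stop_input("n_perms must be a positive count")
  set_seed_if(seed)
  observed <- statistic(neural, model)
  n <- length(model$labels)
  m <- as.matrix(model)
  null <- vapply(seq_len(n_perms), function(i) {
    perm <- sample.int(n)
    statistic(neural, rdm(m[perm, perm], model$labels))
  }, numeric(1))
  test_result(observed, null, n_perms, "condition-label permutation", seed)
}

#' Bootstrap confidence intervals over subjects (and stimuli)
#'
#' Percentile bootstrap intervals under two resampling schemes: resampling
#' subjects (typical population inference) or resampling both subjects and
#' stimuli (generalizability across stimuli). Under the stimulus scheme,
#' condition indices are drawn with replacement, each subject's RDM is
#' rebuilt on the resampled index set, and pairs formed by a condition with
#' its own duplicate (whose dissimilarity is degenerately zero) are excluded
#' from the vectorization; resamples in which no valid pairs remain are
#' redrawn a bounded number of times.
#'
#' @param subject_values per-subject statistics (scheme `"subjects"`), or
#'   NULL when `subject_rdms` is given.
#' @param subject_rdms list of per-subject `rdm`s (scheme
#'   `"subjects+stimuli"`).
#' @param model model `rdm` used with `subject_rdms`.
#' @param statistic for the stimulus scheme, a function
#'   `(neural_vec, model_vec) -> scalar` applied per subject; defaults to
#'   Spearman correlation. Per-subject values are Fisher-z averaged when
#'   `fisher_average = TRUE`.
#' @param scheme `"subjects"` or `"subjects+stimuli"`.
#' @param n_boot bootstrap iterations.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @param fisher_average average per-subject statistics on the Fisher-z
#'   scale (appropriate for correlations).
#' @return an `interval_result`: list with `estimate`, `lower`, `upper`,
#'   `level`, `scheme`, `n_boot`.
#' @export
bootstrap_ci <- function(subject_values = NULL, subject_rdms = NULL,
                         model = NULL,
                         statistic = function(nv, mv)
                           cor(nv, mv, method = "spearman"),
                         scheme = c("subjects", "subjects+stimuli"),
                         n_boot = 10000, level = 0.95, seed = NULL,
                         fisher_average = TRUE) {
  scheme <- match.arg(scheme)
  if (!is_count(n_boot)) stop_input("n_boot must be a positive count")
  set_seed_if(seed)
  alpha <- (1 - level) / 2

  if (scheme == "subjects") {
    if (is.null(subject_values)) {
      if (is.null(subject_rdms) || is.null(model))
        stop_input("provide subject_values, or subject_rdms and model")
      mv <- rdm_vec(model)
      subject_values <- vapply(subject_rdms, function(r)
        statistic(rdm_vec(r), mv), numeric(1))
    }
    n <- length(subject_values)
    if (n < 2L) stop_input("need at least 2 subjects")
    agg <- if (fisher_average) fisher_mean else mean
    estimate <- agg(subject_values)
    boot <- vapply(seq_len(n_boot), function(b)
      agg(subject_values[sample.int(n, n, replace = TRUE)]), numeric(1))
  } else {
    if (is.null(subject_rdms) || is.null(model))
      stop_input("subjects+stimuli scheme needs subject_rdms and model")
    n <- length(subject_rdms)
    if (n < 2L) stop_input("need at least 2 subjects")
    model <- as_rdm(model)
    mats <- lapply(subject_rdms, function(r) as.matrix(as_rdm(r)))
    mm <- as.matrix(model)
    nc <- nrow(mm)
    agg <- if (fisher_average) fisher_mean else mean
    estimate <- agg(vapply(mats, function(m)
      statistic(m[lower.tri(m)], mm[lower.tri(mm)]), numeric(1)))
    low <- lower.tri(mm)
    boot <- vapply(seq_len(n_boot), function(b) {
      for (try in 1:10) {
        cond <- sample.int(nc, nc, replace = TRUE)
        keep <- outer(cond, cond, `!=`)[low]
        if (any(keep)) break
        if (try == 10)
          stop_input("all pairs degenerate after bounded retries")
      }
      subs <- sample.int(n, n, replace = TRUE)
      mvb <- mm[cond, cond][low][keep]
      agg(vapply(subs, function(s) {
        statistic(mats[[s]][cond, cond][low][keep], mvb)
      }, numeric(1)))
    }, numeric(1))
  }
  qs <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(list(estimate = estimate, lower = qs[1L], upper = qs[2L],
                 level = level, scheme = scheme, n_boot = n_boot,
                 seed = seed),
            class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("%.0f%% CI (%s, %d resamples): %.4f [%.4f, %.4f]\n",
              100 * x$level, x$scheme, x$n_boot, x$estimate, x$lower,
              x$upper))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment of a vector of p-values, with rejection flags at
#' level `q`.
#'
#' @param p_values p-values in `(0, 1]`.
#' @param q FDR level (default .001, the map-wise threshold used for
#'   searchlight statistical maps).
#' @return list with `q_values` (monotone adjusted values) and `reject`
#'   (logical flags, `q_values <= q`).
#' @export
fdr_bh <- function(p_values, q = 0.001) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop_input("p-values must lie in (0, 1]")
  qv <- p.adjust(p_values, method = "BH")
  list(q_values = qv, reject = qv <= q)
}
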