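#' Spearman fit of a model RDM to a neural RDM
#'
#' Spearman rank correlation (average ranks for ties) between the two RDMs'
#' shared lower-triangle vectorizations.
#'
#' @param neural,model `rdm` objects with matched labels.
#' @return scalar rho.
#' @export
spearman_fit <- function(neural, model) {
  neural <- as_rdm(neural); model <- as_rdm(model)
  if (!identical(neural$labels, model$labels))
    stop_input("RDM labels do not match")
  x <- rdm_vec(neural); y <- rdm_vec(model)
  if (sd(x) == 0 || sd(y) == 0)
    stop_input("undefined correlation: constant RDM vector")
  cor(x, y, method = "spearman")
}

rank_standardize <- function(v) {
  r <- rank(v)  # average ranks for ties
  s <- sd(r)
  if (s == 0) stop_input("undefined: constant vector after ranking")
  (r - mean(r)) / s
}

#' Joint model fit by rank-standardized multiple regression
#'
#' All model RDM vectors and the neural RDM vector are rank-transformed
#' (average ranks) and standardized, then the neural vector is predicted by
#' ordinary least squares with an intercept. Returns the in-sample
#' coefficient of determination R^2. Rank-standardizing the response keeps
#' the single-model case consistent with [spearman_fit()]: with one model,
#' `R^2 = rho^2`.
#'
#' @param neural an `rdm`.
#' @param models list of `rdm` objects (labels matching `neural`).
#' @param rank_response rank-transform the neural vector too (default TRUE);
#'   set FALSE to regress the raw neural dissimilarities on ranked models.
#' @param allow_collinear if TRUE, perfectly collinear predictors are
#'   handled by the pivoted least-squares fit (aliased models add nothing to
#'   R^2) instead of raising a rank-deficiency error. Used by
#'   [variance_partition()], where a duplicated model must simply contribute
#'   zero unique variance.
#' @return scalar R^2 in `[0, 1]`.
#' @export
joint_fit <- function(neural, models, rank_response = TRUE,
                      allow_collinear = FALSE) {
  fit_ols(neural, models, rank_response, allow_collinear)$r2
}

fit_ols <- function(neural, models, rank_response = TRUE,
                    allow_collinear = FALSE) {
  neural <- as_rdm(neural)
  if (inherits(models, "rdm")) models <- list(models)
  stopifnot(length(models) >= 1L)
  models <- lapply(models, as_rdm)
  for (m in models)
    if (!identical(m$labels, neural$labels))
      stop_input("RDM labels do not match")
  y <- rdm_vec(neural)
  y <- if (rank_response) rank_standardize(y) else (y - mean(y)) / sd(y)
  X <- vapply(models, function(m) rank_standardize(rdm_vec(m)),
              numeric(length(y)))
  Xd <- cbind(`(intercept)` = 1, X)
  q <- qr(Xd)
  if (q$rank < ncol(Xd) && !allow_collinear) {
    nm <- names(models) %||% sprintf("model%d", seq_along(models))
    dep <- q$pivot[seq(q$rank + 1L, ncol(Xd))] - 1L
    stop_input(sprintf("rank-deficiency: collinear model RDM(s): %s",
                       paste(nm[dep], collapse = ", ")))
  }
  fit <- lm.fit(Xd, y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(r2 = max(0, min(1, r2)), coefficients = fit$coefficients)
}

#' Variance partitioning by full-versus-nested regression
#'
#' Quantifies the variance in a neural RDM uniquely explained by each
#' partition (a set of model RDMs): `unique R^2 = full R^2 - nested R^2`,
#' where the full fit uses all models and the nested fit excludes the
#' partition's models. In-sample OLS monotonicity guarantees unique R^2 is
#' nonnegative up to floating point; tiny negative values are kept in the
#' table (clamping, where desired, is a reporting choice).
#'
#' @param neural an `rdm`.
#' @param models *named* list of `rdm` objects.
#' @param partitions list of character vectors of model names; defaults to
#'   one partition per model.
#' @param rank_response see [joint_fit()].
#' @return a `partition_table` data frame with columns `partition`,
#'   `unique_r2`, `full_r2`, `nested_r2`.
#' @export
variance_partition <- function(neural, models, partitions = NULL,
                               rank_response = TRUE) {
  if (is.null(names(models)) || anyDuplicated(names(models)))
    stop_input("models must be a uniquely named list")
  if (is.null(partitions)) partitions <- as.list(names(models))
  full <- joint_fit(neural, models, rank_response, allow_collinear = TRUE)
  rows <- lapply(partitions, function(part) {
    if (!all(part %in% names(models)))
      stop_input(sprintf("unknown model label: %s",
                         setdiff(part, names(models))[1L]))
    rest <- models[setdiff(names(models), part)]
    nested <- if (length(rest) == 0L) 0 else
      joint_fit(neural, rest, rank_response, allow_collinear = TRUE)
    data.frame(partition = paste(part, collapse = "+"),
               unique_r2 = full - nested, full_r2 = full,
               nested_r2 = nested, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("partition_table", "data.frame")
  out
}

#' Intersubject-correlation noise ceiling
#'
#' Leave-one-out intersubject correlation of RDMs: for each subject, the
#' Spearman correlation between that subject's RDM and the elementwise mean
#' of all other subjects' RDMs. Per-subject values are Fisher-z averaged
#' and back-transformed into the group ceiling.
#'
#' @param subject_rdms list of >= 2 `rdm`s with matched labels.
#' @return list with `per_subject` correlations and the group `mean`.
#' @export
isc_noise_ceiling <- function(subject_rdms) {
  if (length(subject_rdms) < 2L) stop_input("need at least 2 subjects")
  subject_rdms <- lapply(subject_rdms, as_rdm)
  mats <- lapply(subject_rdms, as.matrix)
  total <- Reduce(`+`, mats)
  per <- vapply(seq_along(mats), function(i) {
    others <- (total - mats[[i]]) / (length(mats) - 1L)
    spearman_fit(subject_rdms[[i]],
                 rdm(others, subject_rdms[[i]]$labels))
  }, numeric(1))
  list(per_subject = per, mean = fisher_mean(per))
}

#' Fraction of the noise ceiling explained by a model
#'
#' Expresses a model's R^2 as a percentage of the meaningful (reliable)
#' variance indexed by the intersubject-correlation noise ceiling:
#' `100 * model_r2 / ceiling_r^2`.
#'
#' @param model_r2 model R^2 in `[0, 1]`.
#' @param ceiling_r noise-ceiling correlation in `(0, 1]`.
#' @return percentage.
#' @examples
#' ceiling_fraction(0.22, 0.75)  # ~39.1
#' @export
ceiling_fraction <- function(model_r2, ceiling_r) {
  if (!is.numeric(model_r2) || model_r2 < 0 || model_r2 > 1)
    stop_input("model_r2 must be in [0, 1]")
  if (!is.numeric(ceiling_r) || ceiling_r <= 0 || ceiling_r > 1)
    stop_input("ceiling_r must be in (0, 1]")
  100 * model_r2 / ceiling_r^2
}

#' Fit candidate model RDMs to a cohort of neural RDMs
#'
#' The central model-comparison fit: for each subject's neural RDM, the
#' Spearman correlation with every candidate model RDM, the joint
#' (rank-standardized multiple regression) R^2 over all models, the
#' variance partition of unique R^2, and the leave-one-out intersubject
#' noise ceiling. Group means of correlations are computed on the Fisher-z
#' scale and back-transformed; R^2 values are averaged on their native
#' scale.
#'
#' @param neural_rdms list of per-subject `rdm`s (one neural RDM each).
#' @param models named list of model `rdm`s.
#' @param partitions list of model-name sets for [variance_partition()];
#'   defaults to one partition per model.
#' @param rank_response see [joint_fit()].
#' @return an object of class `rsa_fit` with components `spearman`
#'   (subjects x models matrix), `joint_r2` (per subject), `partitions`
#'   (per-subject list of `partition_table`s), `isc`, and group summaries.
#' @seealso [signflip_permutation_test()], [recentered_bootstrap_test()]
#'   for group inference on the per-subject values.
#' @export
rsa_fit <- function(neural_rdms, models, partitions = NULL,
                    rank_response = TRUE) {
  stopifnot(length(neural_rdms) >= 1L, length(models) >= 1L)
  if (is.null(names(models)))
    names(models) <- sprintf("model%d", seq_along(models))
  subjects <- names(neural_rdms) %||%
    sprintf("sub%02d", seq_along(neural_rdms))
  if (is.null(partitions)) partitions <- as.list(names(models))

  spearman <- t(vapply(neural_rdms, function(nr)
    vapply(models, function(m) spearman_fit(nr, m), numeric(1)),
    numeric(length(models))))
  dimnames(spearman) <- list(subjects, names(models))
  joint_r2 <- vapply(neural_rdms, joint_fit, numeric(1), models = models,
                     rank_response = rank_response)
  names(joint_r2) <- subjects
  parts <- lapply(neural_rdms, variance_partition, models = models,
                  partitions = partitions, rank_response = rank_response)
  names(parts) <- subjects
  isc <- if (length(neural_rdms) >= 2L) isc_noise_ceiling(neural_rdms)
         else NULL

  unique_r2 <- vapply(parts, function(p) p$unique_r2,
                      numeric(nrow(parts[[1L]])))
  unique_r2 <- matrix(unique_r2, ncol = length(neural_rdms),
                      dimnames = list(parts[[1L]]$partition, subjects))
  structure(list(
    spearman = spearman,
    spearman_group = apply(spearman, 2L, fisher_mean),
    joint_r2 = joint_r2,
    joint_r2_group = mean(joint_r2),
    partitions = parts,
    unique_r2_group = rowMeans(unique_r2),
    unique_r2 = t(unique_r2),
    isc = isc,
    n_subjects = length(neural_rdms),
    models = names(models)
  ), class = "rsa_fit")
}

#' @export
print.rsa_fit <- function(x, ...) {
  cat(sprintf("RSA fit: %d subject(s), %d model(s)\n", x$n_subjects,
              length(x$models)))
  cat("group Spearman rho (Fisher-z averaged):\n")
  print(round(x$spearman_group, 4))
  cat(sprintf("joint R^2 (all models): %.4f\n", x$joint_r2_group))
  if (!is.null(x$isc))
    cat(sprintf("noise ceiling (leave-one-out ISC): %.4f\n", x$isc$mean))
  invisible(x)
}

#' @export
summary.rsa_fit <- function(object, ...) {
  out <- list(
    models = data.frame(
      model = x_or(names(object$spearman_group), object$models),
      rho_group = unname(object$spearman_group),
      rho_min = apply(object$spearman, 2L, min),
      rho_max = apply(object$spearman, 2L, max)),
    joint_r2_group = object$joint_r2_group,
    unique_r2_group = object$unique_r2_group,
    isc = object$isc,
    ceiling_fraction =
      if (!is.null(object$isc) && object$isc$mean > 0)
        ceiling_fraction(min(1, max(0, object$joint_r2_group)),
                         min(1, object$isc$mean))
      else NA_real_
  )
  class(out) <- "summary.rsa_fit"
  out
}

x_or <- function(a, b) if (is.null(a)) b else a

#' @export
print.summary.rsa_fit <- function(x, ...) {
  cat("Model fits (group):\n")
  print(x$models, row.names = FALSE, digits = 4)
  cat(sprintf("\njoint R^2: %.4f", x$joint_r2_group))
  if (!is.null(x$isc))
    cat(sprintf("  |  noise ceiling r: %.4f  |  %% of ceiling: %.1f",
                x$isc$mean, x$ceiling_fraction))
  cat("\nunique R^2 by partition:\n")
  print(round(x$unique_r2_group, 4))
  invisible(x)
}

#' @export
coef.rsa_fit <- function(object, ...) {
  object$spearman_group
}
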