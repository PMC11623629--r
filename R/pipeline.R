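#' Neighborhood map for searchlight-style analysis
#'
#' Maps center labels to member unit indices (e.g. the vertices within a
#' 10 mm surface disc around each center). Geometry construction is
#' upstream of this package: the map is an explicit input, decoupling the
#' statistical machinery from neuroimaging format handling. Geometry
#' metadata (such as the stated radius) is carried opaquely.
#'
#' @param centers named list of integer vectors of member unit indices.
#' @param geometry optional opaque metadata list.
#' @return a `neighborhood_map`.
#' @export
neighborhood_map <- function(centers, geometry = list()) {
  stopifnot(length(centers) >= 1L)
  if (is.null(names(centers)))
    names(centers) <- sprintf("center%04d", seq_along(centers))
  for (nm in names(centers)) {
    idx <- centers[[nm]]
    if (length(idx) == 0L || any(idx != round(idx)) || any(idx < 1L))
      stop_input(sprintf("center %s: member indices must be positive", nm))
  }
  structure(list(centers = centers, geometry = geometry),
            class = "neighborhood_map")
}

#' Split-data RDMs for every neighborhood
#'
#' For each center in the map, computes the split-data RDM restricted to
#' that center's member units. Centers are processed independently, so any
#' execution order yields identical output; centers whose indices exceed
#' the available units are skipped with a warning.
#'
#' @param s1,s2 z-scored `response_patterns` for the two sessions.
#' @param map a `neighborhood_map`.
#' @return named list of `rdm`s, one per retained center.
#' @export
neighborhood_rdms <- function(s1, s2, map) {
  stopifnot(inherits(map, "neighborhood_map"))
  n_units <- ncol(s1$matrix)
  out <- list()
  for (nm in names(map$centers)) {
    idx <- map$centers[[nm]]
    if (max(idx) > n_units) {
      warning(sprintf("center %s skipped: unit index out of range", nm),
              call. = FALSE)
      next
    }
    p1 <- s1; p1$matrix <- s1$matrix[, idx, drop = FALSE]
    p2 <- s2; p2$matrix <- s2$matrix[, idx, drop = FALSE]
    out[[nm]] <- splitdata_rdm(p1, p2)
  }
  out
}

#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analysis with the canonical
#' defaults: 10,000 permutations and bootstrap iterations, FDR at .001,
#' gaze reliability threshold .1, 84 ms median filter, 60 output gaze
#' samples, and a 90-stimulus / 12-subset / 30-per-subset / 1,000-candidate
#' arrangement design. The configuration is serialized into every result
#' bundle's provenance block.
#'
#' @param n_perms,n_boot resampling iteration counts.
#' @param fdr_q FDR level.
#' @param gaze_threshold inter-block gaze reliability cutoff.
#' @param window_ms gaze median-filter width.
#' @param out_samples decimated gaze samples per trial.
#' @param subset_design sizes `(n_stimuli, n_subsets, subset_size,
#'   n_candidates)` for [design_subsets()].
#' @param partitions list of model-name sets for variance partitioning
#'   (NULL = one per model).
#' @param seed root seed.
#' @return an `analysis_config`.
#' @export
analysis_config <- function(n_perms = 10000, n_boot = 10000, fdr_q = 0.001,
                            gaze_threshold = 0.1, window_ms = 84,
                            out_samples = 60L,
                            subset_design = c(n_stimuli = 90, n_subsets = 12,
                                              subset_size = 30,
                                              n_candidates = 1000),
                            partitions = NULL, seed = 1L) {
  if (!is_count(n_perms) || !is_count(n_boot))
    stop_input("n_perms and n_boot must be positive counts")
  if (fdr_q <= 0 || fdr_q > 1) stop_input("fdr_q must be in (0, 1]")
  structure(list(n_perms = n_perms, n_boot = n_boot, fdr_q = fdr_q,
                 gaze_threshold = gaze_threshold, window_ms = window_ms,
                 out_samples = out_samples, subset_design = subset_design,
                 partitions = partitions, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the neighborhood-wise model-comparison pipeline
#'
#' End-to-end orchestration over neighborhoods (searchlight centers or
#' ROIs): per center, per-subject split-data RDMs, per-model Spearman fits
#' with sign-flip permutation p-values, joint R^2 with re-centered bootstrap
#' p-values, the variance partition of unique R^2, and the leave-one-out
#' intersubject noise ceiling with the joint model's ceiling fraction; FDR
#' is applied across centers within each model's map and within the joint
#' map. Everything is a pure function of `(config, data)`: rerunning with
#' identical inputs reproduces the bundle exactly.
#'
#' @param config an `analysis_config`.
#' @param patterns list per subject of `list(session1, session2)` z-scored
#'   `response_patterns` (as produced by [simulate_subject_patterns()]).
#' @param models named list of model `rdm`s.
#' @param map a `neighborhood_map`; by default one whole-pattern center,
#'   which makes ROI mode and a single-neighborhood searchlight identical.
#' @return a `result_bundle`: list of data frames `model_fits`, `joint`,
#'   `partitions`, plus `config` and `provenance`.
#' @export
run_pipeline <- function(config, patterns, models, map = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (length(patterns) < 2L) stop_input("need at least 2 subjects")
  if (is.null(names(models)))
    names(models) <- sprintf("model%d", seq_along(models))
  if (is.null(map))
    map <- neighborhood_map(list(
      roi = seq_len(ncol(patterns[[1L]]$session1$matrix))))

  centers <- names(map$centers)
  fits <- list()
  for (ct in centers) {
    sub_map <- neighborhood_map(map$centers[ct])
    neural <- lapply(patterns, function(p)
      neighborhood_rdms(p$session1, p$session2, sub_map)[[1L]])
    neural <- neural[!vapply(neural, is.null, logical(1))]
    if (length(neural) < 2L) {
      warning(sprintf("center %s skipped: fewer than 2 usable subjects",
                      ct), call. = FALSE)
      next
    }
    fits[[ct]] <- rsa_fit(neural, models, partitions = config$partitions)
  }
  if (length(fits) == 0L) stop_input("no analyzable centers")

  model_rows <- list()
  joint_rows <- list()
  part_rows <- list()
  for (ct in names(fits)) {
    f <- fits[[ct]]
    for (m in f$models) {
      tst <- signflip_permutation_test(
        f$spearman[, m], n_perms = config$n_perms,
        seed = substream_seed(config$seed, paste0("signflip/", ct, "/", m)))
      model_rows[[length(model_rows) + 1L]] <- data.frame(
        center = ct, model = m, rho_group = f$spearman_group[[m]],
        p = tst$p, stringsAsFactors = FALSE)
    }
    jt <- recentered_bootstrap_test(
      f$joint_r2, n_boot = config$n_boot,
      seed = substream_seed(config$seed, paste0("boot/", ct)))
    joint_rows[[length(joint_rows) + 1L]] <- data.frame(
      center = ct, r2_group = f$joint_r2_group, p = jt$p,
      isc = f$isc$mean,
      pct_ceiling = if (f$isc$mean > 0)
        ceiling_fraction(min(1, max(0, f$joint_r2_group)),
                         min(1, f$isc$mean)) else NA_real_,
      stringsAsFactors = FALSE)
    for (prt in names(f$unique_r2_group)) {
      pt <- recentered_bootstrap_test(
        f$unique_r2[, prt], n_boot = config$n_boot,
        seed = substream_seed(config$seed, paste0("boot/", ct, "/", prt)))
      part_rows[[length(part_rows) + 1L]] <- data.frame(
        center = ct, partition = prt,
        unique_r2_group = f$unique_r2_group[[prt]], p = pt$p,
        stringsAsFactors = FALSE)
    }
  }
  model_fits <- do.call(rbind, model_rows)
  joint <- do.call(rbind, joint_rows)
  partitions <- do.call(rbind, part_rows)

  # map-wise FDR: across centers within one model's map
  model_fits$q <- NA_real_
  for (m in unique(model_fits$model)) {
    sel <- model_fits$model == m
    model_fits$q[sel] <- fdr_bh(model_fits$p[sel], config$fdr_q)$q_values
  }
  joint$q <- fdr_bh(joint$p, config$fdr_q)$q_values
  partitions$q <- NA_real_
  for (prt in unique(partitions$partition)) {
    sel <- partitions$partition == prt
    partitions$q[sel] <- fdr_bh(partitions$p[sel], config$fdr_q)$q_values
  }

  structure(list(
    model_fits = model_fits, joint = joint, partitions = partitions,
    fits = fits, config = config,
    provenance = list(
      package_version = as.character(utils::packageVersion("repgeom")),
      seed = config$seed, n_perms = config$n_perms, n_boot = config$n_boot,
      fdr_q = config$fdr_q, n_subjects = length(patterns),
      n_centers = length(fits))
  ), class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("result bundle: %d center(s), %d subject(s)\n",
              x$provenance$n_centers, x$provenance$n_subjects))
  cat("\nper-model group fits:\n")
  print(head(x$model_fits, 20), row.names = FALSE, digits = 4)
  cat("\njoint fits:\n")
  print(head(x$joint, 10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a result bundle to disk
#'
#' One TSV per result table plus a JSON provenance sidecar (config, seeds,
#' package version). The per-center joint map is additionally exported as a
#' flat `center<TAB>value` table for downstream surface rendering.
#'
#' @param bundle a `result_bundle`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("model_fits", "joint", "partitions"))
    write.table(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$joint[, c("center", "r2_group")],
              file.path(dir, "joint_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
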