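#' Ground truth for synthetic datasets
#'
#' Collects everything the synthetic generators need so that the whole
#' dataset is a pure function of one root seed: the planted candidate model
#' RDMs, per-neighborhood nonnegative mixture weights over those models,
#' the session noise standard deviation (unitless, relative to the
#' unit-variance signal), and the cohort/geometry counts.
#'
#' @param model_rdms named list of planted model `rdm`s.
#' @param mixture_weights named list (one entry per neighborhood) of
#'   nonnegative numeric weight vectors over the models, or a single
#'   numeric vector (treated as one neighborhood named `"nb01"`).
#' @param noise_sd session noise standard deviation.
#' @param n_subjects,n_units cohort size and units per neighborhood.
#' @param stimuli a `stimulus_set` consistent with the model RDM labels.
#' @param seed root integer seed; all generator randomness flows from it
#'   through named substreams.
#' @return a `ground_truth` object.
#' @export
ground_truth <- function(model_rdms, mixture_weights, noise_sd = 0.5,
                         n_subjects = 23L, n_units = 500L, stimuli = NULL,
                         seed = 1L) {
  stopifnot(length(model_rdms) >= 1L)
  model_rdms <- lapply(model_rdms, as_rdm)
  if (is.null(names(model_rdms)))
    names(model_rdms) <- sprintf("model%d", seq_along(model_rdms))
  if (is.numeric(mixture_weights))
    mixture_weights <- list(nb01 = mixture_weights)
  for (nb in names(mixture_weights)) {
    w <- mixture_weights[[nb]]
    if (length(w) != length(model_rdms) || any(w < 0) || any(!is.finite(w)))
      stop_input(sprintf(
        "neighborhood %s: weights must be %d nonnegative numbers", nb,
        length(model_rdms)))
  }
  if (!is_count(n_subjects) || !is_count(n_units) ||
      !is.numeric(noise_sd) || noise_sd < 0)
    stop_input("invalid cohort/noise parameters")
  structure(list(model_rdms = model_rdms, mixture_weights = mixture_weights,
                 noise_sd = noise_sd, n_subjects = as.integer(n_subjects),
                 n_units = as.integer(n_units), stimuli = stimuli,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate candidate model RDMs
#'
#' Generates a set of mutually distinguishable model RDMs over a stimulus
#' set: `"category"` structures have stochastically smaller within-category
#' than between-category distances; `"random"` structures are unstructured
#' (Euclidean distances between random points, min-max scaled). The set is
#' regenerated until every pair of RDMs has absolute Spearman correlation
#' at most `max_spearman`; if the bound cannot be met within `retries`
#' attempts (e.g. two near-identical structures were requested) generation
#' fails.
#'
#' @param stimuli a `stimulus_set`.
#' @param n_models number of models (used when `structures` is NULL).
#' @param structures character vector of `"category"` / `"random"`;
#'   defaults to one category-structured model followed by random ones.
#' @param rdm_noise standard deviation of the symmetric noise added to the
#'   category structure.
#' @param max_spearman pairwise distinguishability bound.
#' @param retries regeneration budget.
#' @param seed optional integer seed.
#' @return named list of `rdm`s (`category1 ..., random1 ...`).
#' @export
simulate_model_rdms <- function(stimuli, n_models = 4L, structures = NULL,
                                rdm_noise = 0.1, max_spearman = 0.8,
                                retries = 20L, seed = NULL) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (is.null(structures))
    structures <- c("category", rep("random", max(0L, n_models - 1L)))
  if (!all(structures %in% c("category", "random")))
    stop_input("structures must be 'category' or 'random'")
  set_seed_if(seed)
  n <- nrow(stimuli)
  labels <- stimuli$stimulus_id
  same_cat <- outer(stimuli$category, stimuli$category, `==`)

  gen_one <- function(kind) {
    if (kind == "category") {
      noise <- matrix(rnorm(n * n, sd = rdm_noise), n)
      m <- ifelse(same_cat, 0.3, 0.7) + (noise + t(noise)) / 2
      m <- pmax(m, 0)
    } else {
      pts <- matrix(rnorm(n * 3L), n)
      m <- as.matrix(stats::dist(pts))
      m <- m / max(m)
    }
    diag(m) <- 0
    rdm(m, labels, meta = list(source = paste0("simulated_", kind)))
  }

  nm <- character(length(structures))
  for (k in c("category", "random")) {
    idx <- which(structures == k)
    nm[idx] <- sprintf("%s%d", k, seq_along(idx))
  }
  models <- lapply(structures, gen_one)
  names(models) <- nm
  for (attempt in seq_len(retries)) {
    vecs <- vapply(models, rdm_vec, numeric(n * (n - 1) / 2))
    cors <- abs(cor(vecs, method = "spearman"))
    diag(cors) <- 0
    bad <- which(apply(cors, 2L, max) > max_spearman)
    if (length(bad) == 0L) return(models)
    # regenerate the later member of each offending pair
    redo <- unique(bad[-1L])
    if (length(redo) == 0L) redo <- bad[length(bad)]
    for (i in redo) models[[i]] <- gen_one(structures[i])
  }
  stop_input(sprintf(
    "generation-failure: could not make model RDMs pairwise distinguishable (|rho| <= %.2f) within %d retries",
    max_spearman, retries))
}

# Blend rescaled model RDMs into the target similarity (correlation)
# matrix: B = sum_k w_k (1 - Dhat_k) with unit diagonal. Because response
# profiles are z-scored across conditions downstream, only the
# double-centered component of the similarity structure is identifiable;
# the planted target is therefore H B H (H the centering projector),
# projected to the nearest valid correlation matrix by eigenvalue clipping
# with the diagonal renormalized to 1. With all weights zero (B = I) the
# target has off-diagonal -1/(n-1), the exact geometry that z-scoring
# induces on independent units.
target_similarity <- function(model_rdms, weights) {
  n <- length(model_rdms[[1L]]$labels)
  B <- matrix(0, n, n)
  for (k in seq_along(model_rdms)) {
    m <- as.matrix(model_rdms[[k]])
    off <- m[lower.tri(m) | upper.tri(m)]
    rng <- range(off)
    dhat <- if (diff(rng) > 0) (m - rng[1L]) / diff(rng) else m * 0
    diag(dhat) <- 0
    B <- B + weights[k] * (1 - dhat)
  }
  diag(B) <- 1
  H <- diag(n) - matrix(1 / n, n, n)
  S <- H %*% B %*% H
  e <- eigen(S, symmetric = TRUE)
  S <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  d <- sqrt(diag(S))
  if (any(d <= 0))
    stop_input("generation-failure: similarity not repairable to a valid correlation matrix")
  S <- S / tcrossprod(d)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Simulate split-session response patterns for one neighborhood
#'
#' Construction: (i) the blend `B = sum_k w_k (1 - Dhat_k)` mixes the
#' planted model RDMs, each min-max rescaled to `[0, 1]` on its
#' off-diagonal entries; (ii) the target similarity `S` is the
#' double-centered blend projected to the nearest valid correlation matrix
#' (negative eigenvalues clipped, unit diagonal restored) -- z-scoring
#' response profiles across conditions removes each unit's profile mean, so
#' only the centered component of the similarity structure is identifiable
#' and the centered blend is the geometry the data can actually realize;
#' (iii) each unit's condition profile is an independent draw from a
#' zero-mean multivariate normal with covariance `S`; (iv) independent
#' Gaussian noise of standard deviation `noise_sd` is added per session;
#' (v) profiles are z-scored per unit across conditions. The expected
#' cross-session Pearson correlation between conditions `i != j` is
#' `S_ij / (1 + noise_sd^2)`, so split-data RDMs converge to
#' `1 - S / (1 + sigma^2)` as the unit count grows.
#'
#' @param truth a `ground_truth`.
#' @param neighborhood name of the mixture-weight entry to use.
#' @param n_units,n_subjects optional overrides of the truth's counts.
#' @return list with one element per subject, each a list of two
#'   `response_patterns` (`session1`, `session2`); the repaired target
#'   similarity matrix is attached as attribute `"target"`.
#' @export
simulate_subject_patterns <- function(truth, neighborhood = NULL,
                                      n_units = truth$n_units,
                                      n_subjects = truth$n_subjects) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(neighborhood)) neighborhood <- names(truth$mixture_weights)[1L]
  w <- truth$mixture_weights[[neighborhood]]
  if (is.null(w))
    stop_input(sprintf("no mixture weights for neighborhood %s",
                       neighborhood))
  S <- target_similarity(truth$model_rdms, w)
  e <- eigen(S, symmetric = TRUE)
  A <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  n <- nrow(S)
  labels <- truth$model_rdms[[1L]]$labels
  sigma <- truth$noise_sd

  subjects <- lapply(seq_len(n_subjects), function(s) {
    set.seed(substream_seed(truth$seed,
                            sprintf("patterns/%s/sub%03d", neighborhood, s)))
    signal <- A %*% matrix(rnorm(n * n_units), n)
    sess <- lapply(1:2, function(ses) {
      m <- signal + matrix(rnorm(n * n_units, sd = sigma), n)
      m <- scale(m)
      attr(m, "scaled:center") <- NULL
      attr(m, "scaled:scale") <- NULL
      rownames(m) <- labels
      response_patterns(m, subject_id = sprintf("sub%03d", s),
                        session_id = ses, conditions = labels,
                        zscored = TRUE)
    })
    names(sess) <- c("session1", "session2")
    sess
  })
  names(subjects) <- sprintf("sub%03d", seq_len(n_subjects))
  attr(subjects, "target") <- S
  subjects
}

#' Simulate one multiple-arrangement session
#'
#' Emulates a participant performing the arrangement task on a planted
#' dissimilarity structure: the first record covers all stimuli and each
#' subsequent record one subset; coordinates are the classical 2D metric MDS
#' embedding of the (sub-)RDM plus isotropic Gaussian jitter of standard
#' deviation `jitter_sd` in the embedded coordinates.
#'
#' @param x the planted `rdm`.
#' @param subsets a `subset_design` whose stimulus IDs all occur in `x`.
#' @param jitter_sd placement noise in screen units.
#' @param seed optional integer seed.
#' @param participant_id,task identifiers stamped on the records.
#' @return list of `arrangement_record`s (1 full set + one per subset).
#' @export
simulate_arrangement_session <- function(x, subsets, jitter_sd = 0,
                                         seed = NULL,
                                         participant_id = "sim01",
                                         task = "sociality") {
  x <- as_rdm(x)
  stopifnot(inherits(subsets, "subset_design"))
  unknown <- setdiff(unlist(subsets$subsets), x$labels)
  if (length(unknown) > 0L)
    stop_input(sprintf("subset references unknown stimulus: %s",
                       unknown[1L]))
  set_seed_if(seed)
  m <- as.matrix(x)
  embed_one <- function(ids, set_index) {
    idx <- match(ids, x$labels)
    coords <- if (length(ids) == length(x$labels) && set_index == 0L)
      mds_embed(x, 2L) else mds_embed(rdm(m[idx, idx], ids), 2L)
    coords <- coords + matrix(rnorm(length(ids) * 2L, sd = jitter_sd),
                              ncol = 2L)
    arrangement_record(participant_id, task, set_index, ids, coords)
  }
  c(list(embed_one(x$labels, 0L)),
    lapply(seq_along(subsets$subsets), function(j)
      embed_one(subsets$subsets[[j]], j)))
}

#' Simulate an eye-tracking session
#'
#' Per stimulus, gaze follows a smooth 2D random walk pulled toward
#' stimulus-specific attractor points (three per stimulus, switching every
#' ~800 ms), sampled at `sample_rate` Hz for `duration_ms` (the defaults
#' give 2500 samples over 2.5 s). The attractors are shared across blocks
#' while the walk noise is block-specific, so trajectories for the same
#' stimulus correlate more strongly across blocks than across stimuli.
#' With probability `blink_rate` a trial contains one blink episode
#' (50-300 ms) flagged invalid.
#'
#' @param stimuli a `stimulus_set`.
#' @param n_blocks number of blocks (each stimulus once per block).
#' @param blink_rate per-trial blink probability.
#' @param seed root integer seed.
#' @param participant_id identifier stamped on the trajectories.
#' @param sample_rate sampling rate in Hz.
#' @param duration_ms trial duration in milliseconds.
#' @param walk_sd per-sample random-walk noise in pixels.
#' @param screen_px screen size (width, height) in pixels.
#' @return list of `gaze_trajectory` objects (blocks x stimuli).
#' @export
simulate_gaze_session <- function(stimuli, n_blocks = 4L, blink_rate = 0.05,
                                  seed = 1L, participant_id = "p01",
                                  sample_rate = 1000, duration_ms = 2500,
                                  walk_sd = 3, screen_px = c(1280, 720)) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (!is_count(n_blocks)) stop_input("n_blocks must be >= 1")
  if (blink_rate < 0 || blink_rate > 1)
    stop_input("blink_rate must be a probability")
  n_samp <- round(duration_ms * sample_rate / 1000)
  t_ms <- seq_len(n_samp) * (1000 / sample_rate)
  pull <- 0.01
  switch_ms <- 800

  trials <- list()
  for (s in seq_len(nrow(stimuli))) {
    sid <- stimuli$stimulus_id[s]
    set.seed(substream_seed(seed, paste0("gaze/attract/", sid)))
    attract <- cbind(runif(3, 0.2, 0.8) * screen_px[1L],
                     runif(3, 0.2, 0.8) * screen_px[2L])
    seg <- pmin(3L, 1L + (t_ms - 1) %/% switch_ms)
    tx <- attract[seg, 1L]
    ty <- attract[seg, 2L]
    for (b in seq_len(n_blocks)) {
      set.seed(substream_seed(seed, sprintf("gaze/walk/%s/b%d/%s",
                                            participant_id, b, sid)))
      ex <- rnorm(n_samp, sd = walk_sd)
      ey <- rnorm(n_samp, sd = walk_sd)
      x <- stats::filter(pull * tx + ex, 1 - pull, "recursive",
                         init = screen_px[1L] / 2)
      y <- stats::filter(pull * ty + ey, 1 - pull, "recursive",
                         init = screen_px[2L] / 2)
      valid <- rep(TRUE, n_samp)
      if (runif(1) < blink_rate) {
        len <- min(n_samp, round(runif(1, 50, 300) * sample_rate / 1000))
        start <- sample.int(max(1L, n_samp - len + 1L), 1L)
        valid[start:min(n_samp, start + len - 1L)] <- FALSE
      }
      trials[[length(trials) + 1L]] <- gaze_trajectory(
        data.frame(t_ms = t_ms, x_px = as.numeric(x), y_px = as.numeric(y),
                   valid = valid),
        participant_id = participant_id, block = b, stimulus_id = sid)
    }
  }
  trials
}

#' Simulate word annotations from two synthetic annotators
#'
#' Per stimulus, 2-5 verb-class and 3-6 nonverb-class embedding vectors are
#' drawn from category-level Gaussians (so stimuli of one category have
#' related annotations); annotator 2's vectors are noisy copies of
#' annotator 1's with noise standard deviation `annotator_noise`.
#'
#' @param stimuli a `stimulus_set`.
#' @param dim embedding dimension (>= 2; 300 matches common pretrained
#'   word embeddings).
#' @param seed optional integer seed.
#' @param annotator_noise standard deviation of annotator 2's perturbation.
#' @return list of two `annotation_table`s.
#' @export
simulate_annotations <- function(stimuli, dim = 300L, seed = NULL,
                                 annotator_noise = 0.1) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (!is_count(dim, 2L)) stop_input("dim must be >= 2")
  set_seed_if(seed)
  cats <- unique(stimuli$category)
  cat_mean <- list(
    verb = matrix(rnorm(length(cats) * dim), length(cats),
                  dimnames = list(cats, NULL)),
    nonverb = matrix(rnorm(length(cats) * dim), length(cats),
                     dimnames = list(cats, NULL)))
  rows1 <- list()
  for (s in seq_len(nrow(stimuli))) {
    sid <- stimuli$stimulus_id[s]
    cat <- stimuli$category[s]
    counts <- c(verb = sample(2:5, 1L), nonverb = sample(3:6, 1L))
    for (cls in c("verb", "nonverb")) {
      stim_mean <- cat_mean[[cls]][cat, ] + rnorm(dim, sd = 0.3)
      for (wi in seq_len(counts[[cls]])) {
        vec <- stim_mean + rnorm(dim, sd = 0.2)
        rows1[[length(rows1) + 1L]] <- c(
          list(stimulus_id = sid, word = sprintf("%s_%s%d", sid, cls, wi),
               class = cls), as.list(vec))
      }
    }
  }
  to_table <- function(rows) {
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE, col.names =
                      c("stimulus_id", "word", "class",
                        sprintf("V%d", seq_len(dim))))))
    annotation_table(df)
  }
  a1 <- to_table(rows1)
  a2 <- a1
  vcols <- sprintf("V%d", seq_len(dim))
  noise <- matrix(rnorm(nrow(a2) * dim, sd = annotator_noise), nrow(a2))
  a2[vcols] <- a2[vcols] + noise
  list(annotator1 = a1, annotator2 = a2)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates and writes every input the pipeline reads -- per
#' subject-session pattern tables, arrangement CSV, gaze CSV, annotation
#' TSVs, the planted model RDMs -- plus a ground-truth JSON sidecar
#' recording weights, noise and seeds.
#'
#' @param truth a `ground_truth` (with `stimuli`).
#' @param dir output directory.
#' @param n_subsets,subset_size,n_blocks sizes for the behavioral tasks.
#' @return the directory, invisibly.
#' @export
simulate_dataset <- function(truth, dir, n_subsets = 4L, subset_size = 10L,
                             n_blocks = 2L) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(truth$stimuli, "stimulus_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(truth$model_rdms))
    write_rdm(truth$model_rdms[[nm]],
              file.path(dir, sprintf("model_%s.tsv", nm)))
  for (nb in names(truth$mixture_weights)) {
    subs <- simulate_subject_patterns(truth, nb)
    for (s in names(subs)) for (ses in 1:2)
      write_patterns(subs[[s]][[ses]],
                     file.path(dir, sprintf("%s_%s_ses-%d.tsv", nb, s, ses)))
  }
  sd_ <- design_subsets(nrow(truth$stimuli), n_subsets, subset_size,
                        n_candidates = 20,
                        seed = substream_seed(truth$seed, "subsets"),
                        stimulus_ids = truth$stimuli$stimulus_id)
  recs <- simulate_arrangement_session(
    truth$model_rdms[[1L]], sd_, jitter_sd = 1,
    seed = substream_seed(truth$seed, "arrangement"))
  write_arrangements(recs, file.path(dir, "arrangements.csv"))
  gaze <- simulate_gaze_session(truth$stimuli, n_blocks = n_blocks,
                                blink_rate = 0.05, seed = truth$seed)
  write_gaze(gaze, file.path(dir, "gaze.csv"))
  ann <- simulate_annotations(truth$stimuli, dim = 10L,
                              seed = substream_seed(truth$seed, "annot"))
  write_annotations(ann$annotator1, file.path(dir, "annotations_a1.tsv"))
  write_annotations(ann$annotator2, file.path(dir, "annotations_a2.tsv"))
  sidecar <- list(seed = truth$seed, noise_sd = truth$noise_sd,
                  n_subjects = truth$n_subjects, n_units = truth$n_units,
                  mixture_weights = truth$mixture_weights,
                  models = names(truth$model_rdms))
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
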