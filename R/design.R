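#' Generate a serially counterbalanced trial-type sequence
#'
#' Produces a cyclic sequence of exactly `n_types^2` trials in which every
#' ordered pair of trial types -- self-pairs included -- occurs exactly once
#' among the `n_types^2` cyclic adjacencies, so that each trial type precedes
#' and follows every other trial type. This first-order counterbalancing
#' neutralizes carry-over effects in rapid event-related designs.
#'
#' With `blocked = FALSE` (default) the sequence is a uniform random
#' Eulerian circuit on the complete directed graph with self-loops,
#' constructed by Hierholzer's algorithm; this exists for every
#' `n_types >= 2`. With `blocked = TRUE` the sequence is additionally
#' organized into `n_types` consecutive blocks each containing every trial
#' type exactly once (the structure required for run-wise exemplar and probe
#' balance when the sequence is split into scanning runs); block junctions
#' then carry the self-pairs. Such block-balanced sequences do not exist for
#' `n_types` of 3, 4 or 5; they are found by a randomized backtracking
#' search for other sizes.
#'
#' @param n_types number of trial types (>= 2).
#' @param seed optional integer seed.
#' @param labels optional character vector of type labels (length
#'   `n_types`); defaults to `t01 ... tNN`.
#' @param blocked logical; require block balance (see Details).
#' @param max_backtracks,max_restarts search budgets for the blocked search.
#' @return character vector of `n_types^2` trial-type labels.
#' @examples
#' s <- generate_type1_sequence(20, seed = 1)
#' length(s)  # 400
#' @export
generate_type1_sequence <- function(n_types, seed = NULL, labels = NULL,
                                    blocked = FALSE, max_backtracks = 50000,
                                    max_restarts = 400) {
  if (!is_count(n_types, 2L)) stop_input("n_types must be a count >= 2")
  if (is.null(labels)) labels <- sprintf("t%02d", seq_len(n_types))
  if (length(labels) != n_types || anyDuplicated(labels))
    stop_input("labels must be n_types distinct values")
  set_seed_if(seed)
  if (blocked) {
    s <- .type1_blocked_search(as.integer(n_types),
                               as.integer(max_backtracks),
                               as.integer(max_restarts))
    if (length(s) == 0L)
      stop_input(sprintf(
        "generation-failure: no block-balanced serially counterbalanced %s",
        sprintf("sequence found for n_types = %d", n_types)))
  } else {
    s <- eulerian_circuit(n_types)
  }
  labels[s]
}

# Random Eulerian circuit on the complete digraph with self-loops
# (Hierholzer, iterative). Returns the n^2 visited nodes of the circuit.
eulerian_circuit <- function(n) {
  targets <- lapply(seq_len(n), function(v) sample.int(n))
  ptr <- rep(1L, n)
  stack <- integer(n * n + 1L)
  stack[1L] <- 1L
  top <- 1L
  circuit <- integer(n * n + 1L)
  ci <- 0L
  while (top > 0L) {
    v <- stack[top]
    if (ptr[v] <= n) {
      w <- targets[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      top <- top + 1L
      stack[top] <- w
    } else {
      ci <- ci + 1L
      circuit[ci] <- v
      top <- top - 1L
    }
  }
  rev(circuit[seq_len(ci)])[seq_len(n * n)]
}

#' Repair probe-trial adjacency violations
#'
#' Whenever a probe trial immediately follows a fixation trial or another
#' probe trial, the trailing probe is replaced with a fixation trial. The
#' scan is left to right, so cascades resolve correctly and the operation is
#' idempotent. All other trials are untouched.
#'
#' @param seq character vector of trial-type labels.
#' @param probe,fixation the labels of the probe and fixation types.
#' @return the repaired sequence.
#' @export
repair_probe_constraints <- function(seq, probe = "probe",
                                     fixation = "fixation") {
  if (length(seq) < 2L) return(seq)
  for (i in 2:length(seq)) {
    if (seq[i] == probe && (seq[i - 1L] == fixation || seq[i - 1L] == probe))
      seq[i] <- fixation
  }
  seq
}

#' Assemble scanning runs from a counterbalanced sequence
#'
#' Splits a (block-balanced) trial-type sequence into `n_runs` runs, assigns
#' exemplars so that within each run every exemplar of every stimulus
#' category occurs exactly once (sampled without replacement per category
#' per run), prepends to each run the last three trials of the previous run
#' (the first run receives the last three of the final run) to reinstate the
#' sequence's temporal context, and assigns onsets with jittered
#' interstimulus intervals. Prepended trials draw their stimuli from a
#' separate preparatory exemplar pool (one clip per category, never used in
#' the main set), so no exemplar repeats within a run.
#'
#' @param seq character vector of trial-type labels whose non-fixation,
#'   non-probe types are the stimulus categories; its length must be
#'   divisible by `n_runs` and each category must occur exactly
#'   `n_exemplars` times per run (use
#'   `generate_type1_sequence(blocked = TRUE)`).
#' @param n_exemplars exemplars per category.
#' @param n_runs number of runs.
#' @param seed optional integer seed.
#' @param session_id session index stored on each run.
#' @param stim_s stimulus duration in seconds.
#' @param mean_isi_s,min_isi_s mean and minimum interstimulus interval in
#'   seconds; ISIs per run are jittered but sum-constrained so the mean is
#'   exact.
#' @param n_candidates number of candidate onset schedules evaluated for
#'   efficiency per run (see [generate_onsets()]).
#' @param lead_fix_s,trail_fix_s fixation appended before and after each run.
#' @param probe,fixation labels of the probe and fixation types.
#' @return list of `trial_sequence` data frames, one per run, with columns
#'   `trial_type`, `exemplar_id`, `onset_s`, `stim_duration_s`, `isi_s` and
#'   attributes `session_id`, `run_id`, `n_prepended`, `lead_fix_s`,
#'   `trail_fix_s`.
#' @export
build_session <- function(seq, n_exemplars, n_runs, seed = NULL,
                          session_id = 1L, stim_s = 2.5, mean_isi_s = 2.5,
                          min_isi_s = 2, n_candidates = 1L, lead_fix_s = 5,
                          trail_fix_s = 15, probe = "probe",
                          fixation = "fixation") {
  if (!is_count(n_exemplars) || !is_count(n_runs))
    stop_input("n_exemplars and n_runs must be positive counts")
  if (length(seq) %% n_runs != 0L)
    stop_input("sequence length must be divisible by n_runs")
  set_seed_if(seed)
  per_run <- length(seq) / n_runs
  categories <- setdiff(unique(seq), c(probe, fixation))
  run_types <- split(seq, rep(seq_len(n_runs), each = per_run))

  # exemplar assignment: each exemplar of each category once per run
  run_frames <- lapply(seq_len(n_runs), function(r) {
    tt <- run_types[[r]]
    ex <- rep(NA_character_, per_run)
    for (cat in categories) {
      idx <- which(tt == cat)
      if (length(idx) != n_exemplars)
        stop_input(sprintf(
          "category %s occurs %d times in run %d; exemplar pool of %d %s",
          cat, length(idx), r, n_exemplars,
          "cannot cover it exactly once each (is the sequence blocked?)"))
      ex[idx] <- sprintf("%s_e%d", cat, sample.int(n_exemplars))
    }
    data.frame(trial_type = tt, exemplar_id = ex, stringsAsFactors = FALSE)
  })

  # prepend last three trials of the previous run (cyclically), stimuli
  # drawn from the separate preparatory pool
  n_pre <- 3L
  runs <- lapply(seq_len(n_runs), function(r) {
    prev <- if (r == 1L) n_runs else r - 1L
    ctx <- utils::tail(run_frames[[prev]], n_pre)
    ctx$exemplar_id <- ifelse(ctx$trial_type %in% categories,
                              sprintf("%s_prep", ctx$trial_type),
                              NA_character_)
    main <- run_frames[[r]]
    out <- rbind(ctx, main)
    rownames(out) <- NULL
    n_tr <- nrow(out)
    ons <- generate_onsets(n_tr, mean_isi_s = mean_isi_s,
                           min_isi_s = min_isi_s,
                           total_null_s = n_tr * mean_isi_s,
                           n_candidates = n_candidates,
                           trial_types = out$trial_type, stim_s = stim_s)
    out$onset_s <- lead_fix_s + ons$onsets_s
    out$stim_duration_s <- stim_s
    out$isi_s <- ons$isi_s
    structure(out, session_id = session_id, run_id = r, n_prepended = n_pre,
              lead_fix_s = lead_fix_s, trail_fix_s = trail_fix_s,
              class = c("trial_sequence", "data.frame"))
  })
  runs
}

#' Jittered onset generation with efficiency selection
#'
#' Generates `n_candidates` candidate onset schedules whose interstimulus
#' intervals are `min_isi_s` plus draws from a truncated exponential
#' distribution, rescaled so that the ISIs sum exactly to `total_null_s`
#' (fixing the run duration), and returns the candidate whose design matrix
#' maximizes estimation efficiency.
#'
#' @param n_trials number of trials.
#' @param mean_isi_s mean ISI implied by `total_null_s / n_trials` (used for
#'   the exponential rate).
#' @param min_isi_s minimum ISI in seconds (no fixation interval is briefer).
#' @param total_null_s total fixation time to distribute across ISIs.
#' @param n_candidates number of candidate schedules (>= 1).
#' @param trial_types optional trial-type vector used to build the
#'   efficiency design matrix; defaults to a single regressor.
#' @param contrasts optional contrast matrix for [design_efficiency()];
#'   defaults to the identity over modeled types.
#' @param seed optional integer seed.
#' @param stim_s stimulus duration in seconds.
#' @param tr_s sampling interval of the efficiency design matrix in seconds.
#' @return list with `onsets_s`, `isi_s`, `candidate_index` (1-based),
#'   `efficiency` (all candidates' scores).
#' @export
generate_onsets <- function(n_trials, mean_isi_s, min_isi_s, total_null_s,
                            n_candidates = 1L, trial_types = NULL,
                            contrasts = NULL, seed = NULL, stim_s = 2.5,
                            tr_s = 1) {
  if (!is_count(n_trials)) stop_input("n_trials must be a positive count")
  if (!is_count(n_candidates)) stop_input("n_candidates must be >= 1")
  if (mean_isi_s < min_isi_s) stop_input("mean_isi_s must be >= min_isi_s")
  if (total_null_s < n_trials * min_isi_s)
    stop_input("total_null_s too small for the minimum ISI")
  set_seed_if(seed)
  if (is.null(trial_types)) trial_types <- rep("stim", n_trials)
  extra_total <- total_null_s - n_trials * min_isi_s
  rate <- if (mean_isi_s > min_isi_s) 1 / (mean_isi_s - min_isi_s) else 1
  upper <- 6 / rate  # truncation point of the exponential

  cands <- lapply(seq_len(n_candidates), function(i) {
    u <- runif(n_trials, 0, pexp(upper, rate))
    extra <- qexp(u, rate)
    if (extra_total > 0 && sum(extra) > 0)
      extra <- extra * (extra_total / sum(extra))
    else extra <- rep(extra_total / n_trials, n_trials)
    isi <- min_isi_s + extra
    onsets <- cumsum(c(0, (stim_s + isi)[-n_trials]))
    list(onsets = onsets, isi = isi)
  })
  eff <- vapply(cands, function(cd) {
    X <- design_matrix(cd$onsets, stim_s, trial_types,
                       total_s = n_trials * stim_s + total_null_s,
                       tr_s = tr_s)
    design_efficiency(X, contrasts)
  }, numeric(1))
  best <- which.max(eff)
  list(onsets_s = cands[[best]]$onsets, isi_s = cands[[best]]$isi,
       candidate_index = best, efficiency = eff)
}

# Canonical double-gamma hemodynamic response function (peak 6 s,
# undershoot 16 s, undershoot ratio 1/6), unit-free amplitude.
hrf_double_gamma <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

#' HRF-convolved indicator design matrix
#'
#' One column per trial type: boxcar indicators of duration `durations_s`
#' convolved with the canonical double-gamma HRF and sampled every `tr_s`
#' seconds. Used to score candidate onset schedules for efficiency.
#'
#' @param onsets_s trial onsets in seconds (run-relative).
#' @param durations_s scalar or per-trial stimulus durations.
#' @param trial_types per-trial type labels (columns in label order of
#'   `unique(trial_types)`).
#' @param total_s run duration in seconds.
#' @param tr_s sampling interval in seconds.
#' @return numeric matrix (timepoints x types).
#' @export
design_matrix <- function(onsets_s, durations_s, trial_types, total_s,
                          tr_s = 1) {
  stopifnot(length(onsets_s) == length(trial_types))
  durations_s <- rep_len(durations_s, length(onsets_s))
  dt <- 0.1
  grid <- seq(0, total_s + 32, by = dt)
  h <- hrf_double_gamma(grid - 0)[grid <= 32]
  types <- unique(trial_types)
  sample_t <- seq(0, total_s - tr_s / 2, by = tr_s)
  X <- matrix(0, length(sample_t), length(types),
              dimnames = list(NULL, types))
  for (k in seq_along(types)) {
    ind <- numeric(length(grid))
    sel <- which(trial_types == types[k])
    for (i in sel) {
      on <- pmin(length(grid), floor(onsets_s[i] / dt) + 1L)
      off <- pmin(length(grid), floor((onsets_s[i] + durations_s[i]) / dt))
      ind[on:off] <- 1
    }
    conv <- stats::convolve(ind, rev(h), type = "open")[seq_along(grid)] * dt
    X[, k] <- approx(grid, conv, xout = sample_t, rule = 2)$y
  }
  X
}

#' Estimation efficiency of a design
#'
#' Computes `e = 1 / trace(C (X'X)^-1 C')`, the standard estimation
#' efficiency of the contrasts `C` under the design matrix `X`; larger is
#' more efficient. The score is invariant to the row order of `C`.
#'
#' @param X design matrix (full column rank).
#' @param contrasts contrast matrix with `ncol(X)` columns; defaults to the
#'   identity.
#' @return scalar efficiency.
#' @export
design_efficiency <- function(X, contrasts = NULL) {
  X <- as.matrix(X)
  if (is.null(contrasts)) contrasts <- diag(ncol(X))
  contrasts <- as.matrix(contrasts)
  if (ncol(contrasts) != ncol(X))
    stop_input("contrast columns must match design columns")
  if (qr(X)$rank < ncol(X))
    stop_input(sprintf(
      "numerical-failure: design matrix is rank-deficient (rank %d < %d)",
      qr(X)$rank, ncol(X)))
  xtx_inv <- solve(crossprod(X))
  1 / sum(diag(contrasts %*% xtx_inv %*% t(contrasts)))
}

#' Total run duration
#'
#' Duration = lead-in fixation + all trials (stimulus + ISI, prepended
#' context trials included) + trailing fixation.
#'
#' @param run a `trial_sequence` from [build_session()].
#' @param lead_fix_s,trail_fix_s override the run's stored lead/trail
#'   fixation durations.
#' @return duration in seconds.
#' @export
run_duration <- function(run, lead_fix_s = attr(run, "lead_fix_s"),
                         trail_fix_s = attr(run, "trail_fix_s")) {
  lead_fix_s + sum(run$stim_duration_s + run$isi_s) + trail_fix_s
}

#' Write per-run timing files
#'
#' One tab-separated file per run with columns `onset_s`, `duration_s`,
#' `trial_type`, `exemplar_id` (0-based run-relative onsets in seconds).
#'
#' @param runs list of `trial_sequence` objects.
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_timing <- function(runs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(runs, function(run) {
    path <- file.path(dir, sprintf("ses-%02d_run-%02d_events.tsv",
                                   attr(run, "session_id"),
                                   attr(run, "run_id")))
    out <- data.frame(onset_s = fmt_full(run$onset_s),
                      duration_s = fmt_full(run$stim_duration_s),
                      trial_type = run$trial_type,
                      exemplar_id = ifelse(is.na(run$exemplar_id), "n/a",
                                           run$exemplar_id))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}
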