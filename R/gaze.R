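#' Gaze trajectory for one trial
#'
#' Time-stamped 2D gaze samples with validity flags (eye-tracker blink
#' censoring), nominally 2500 samples at 1000 Hz over a 2.5 s stimulus.
#'
#' @param samples data frame with columns `t_ms`, `x_px`, `y_px`, `valid`
#'   (logical or 0/1); timestamps strictly increasing.
#' @param participant_id,block,stimulus_id identifiers.
#' @return a `gaze_trajectory`.
#' @export
gaze_trajectory <- function(samples, participant_id = "p01", block = 1L,
                            stimulus_id = "s001") {
  need <- c("t_ms", "x_px", "y_px", "valid")
  if (!all(need %in% names(samples)))
    stop_input("samples need t_ms, x_px, y_px, valid columns")
  if (any(diff(samples$t_ms) <= 0))
    stop_input("timestamps must be strictly increasing")
  samples$valid <- as.logical(samples$valid)
  structure(list(samples = samples, participant_id = participant_id,
                 block = as.integer(block), stimulus_id = stimulus_id),
            class = "gaze_trajectory")
}

rolling_median <- function(x, width) {
  n <- length(x)
  half_l <- (width - 1L) %/% 2L
  half_r <- width - 1L - half_l
  vapply(seq_len(n), function(i) {
    median(x[max(1L, i - half_l):min(n, i + half_r)])
  }, numeric(1))
}

#' Preprocess a gaze trajectory
#'
#' Three steps: (i) invalid (blink) spans are censored and linearly
#' interpolated from flanking valid samples, with edge spans extended from
#' the nearest valid sample; (ii) x and y are independently smoothed with a
#' rolling median whose width is `window_ms` (84 ms at 1000 Hz gives an
#' 84-sample window; the window shrinks at the boundaries); (iii) the
#' trajectory is decimated to `out_samples` by taking the sample nearest
#' each output frame time (one sample per video frame at 24 Hz gives 60
#' samples over 2.5 s).
#'
#' @param traj a `gaze_trajectory` with at least one valid sample.
#' @param window_ms median filter width in milliseconds.
#' @param out_samples number of output samples.
#' @return the preprocessed `gaze_trajectory` (all samples valid).
#' @export
gaze_preprocess <- function(traj, window_ms = 84, out_samples = 60L) {
  stopifnot(inherits(traj, "gaze_trajectory"))
  s <- traj$samples
  if (!any(s$valid))
    stop(errorCondition(
      sprintf("trial excluded: no valid samples (%s, block %d, %s)",
              traj$participant_id, traj$block, traj$stimulus_id),
      class = c("trial_excluded", "error")))
  t <- s$t_ms
  interp <- function(v) {
    if (all(s$valid)) return(v)
    approx(t[s$valid], v[s$valid], xout = t, rule = 2)$y
  }
  x <- interp(s$x_px)
  y <- interp(s$y_px)
  dt <- median(diff(t))
  width <- max(1L, round(window_ms / dt))
  x <- rolling_median(x, width)
  y <- rolling_median(y, width)
  dur <- t[length(t)] - t[1L] + dt
  frame_t <- t[1L] + (seq_len(out_samples) - 0.5) * dur / out_samples
  pick <- vapply(frame_t, function(ft) which.min(abs(t - ft)), integer(1))
  out <- traj
  out$samples <- data.frame(t_ms = t[pick], x_px = x[pick], y_px = y[pick],
                            valid = TRUE)
  out
}

#' Gaze RDM for one block
#'
#' Dissimilarity between two stimuli is the Euclidean distance between the
#' two gaze positions at each sample, summed over the stimulus presentation:
#' `D[i, j] = sum_f || g_i(f) - g_j(f) ||`.
#'
#' @param trials list of preprocessed `gaze_trajectory` objects, one per
#'   stimulus, all with the same sample count.
#' @return an `rdm` over the trials' stimulus IDs.
#' @export
gaze_rdm <- function(trials) {
  stopifnot(length(trials) >= 2L)
  ns <- vapply(trials, function(tr) nrow(tr$samples), integer(1))
  if (length(unique(ns)) != 1L)
    stop_input("trajectories differ in sample count")
  labels <- vapply(trials, `[[`, character(1), "stimulus_id")
  if (anyDuplicated(labels)) stop_input("duplicate stimulus in block")
  X <- vapply(trials, function(tr) tr$samples$x_px, numeric(ns[1L]))
  Y <- vapply(trials, function(tr) tr$samples$y_px, numeric(ns[1L]))
  n <- length(trials)
  d <- matrix(0, n, n)
  for (f in seq_len(ns[1L])) {
    d <- d + sqrt(outer(X[f, ], X[f, ], `-`)^2 +
                    outer(Y[f, ], Y[f, ], `-`)^2)
  }
  rdm(d, labels, meta = list(source = "gaze",
                             participant = trials[[1L]]$participant_id,
                             block = trials[[1L]]$block))
}

#' Reliability screening and averaging of gaze RDMs
#'
#' For each participant, the mean pairwise Pearson correlation between the
#' vectorized block RDMs indexes the within-participant reliability of gaze
#' allocation; participants below `threshold` are excluded. Surviving
#' participants' RDMs are averaged across blocks within participant, then
#' across participants, yielding a single gaze model RDM.
#'
#' @param block_rdms named list: per participant, a list of >= 2 block
#'   `rdm`s.
#' @param threshold minimum mean inter-block correlation (default .1).
#' @return list with `reliability` (named per-participant means),
#'   `retained` (participant names), and `rdm` (the averaged gaze RDM).
#' @export
gaze_reliability_screen <- function(block_rdms, threshold = 0.1) {
  stopifnot(length(block_rdms) >= 1L)
  reliability <- vapply(block_rdms, function(blocks) {
    if (length(blocks) < 2L)
      stop_input("each participant needs at least 2 blocks")
    vecs <- vapply(blocks, rdm_vec, numeric(length(rdm_vec(blocks[[1L]]))))
    cors <- cor(vecs)
    mean(cors[lower.tri(cors)])
  }, numeric(1))
  retained <- names(block_rdms)[reliability >= threshold]
  if (length(retained) == 0L)
    stop_input("empty cohort: all participants below reliability threshold")
  per_participant <- lapply(block_rdms[retained], average_rdms)
  list(reliability = reliability, retained = retained,
       rdm = average_rdms(per_participant))
}

#' Read and write gaze sample logs
#'
#' CSV schema: `participant_id`, `block`, `stimulus_id`, `t_ms`, `x_px`,
#' `y_px`, `valid` (0/1), one row per sample.
#'
#' @param trials list of `gaze_trajectory` objects.
#' @param path file path.
#' @return `read_gaze` returns a list of `gaze_trajectory` objects.
#' @export
write_gaze <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    data.frame(participant_id = tr$participant_id, block = tr$block,
               stimulus_id = tr$stimulus_id, t_ms = tr$samples$t_ms,
               x_px = fmt_full(tr$samples$x_px),
               y_px = fmt_full(tr$samples$y_px),
               valid = as.integer(tr$samples$valid))
  })
  write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  tab <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  key <- paste(tab$participant_id, tab$block, tab$stimulus_id, sep = "\r")
  lapply(split(tab, factor(key, levels = unique(key))), function(d) {
    gaze_trajectory(data.frame(t_ms = d$t_ms, x_px = d$x_px, y_px = d$y_px,
                               valid = d$valid == 1L),
                    participant_id = d$participant_id[1L],
                    block = d$block[1L], stimulus_id = d$stimulus_id[1L])
  })
}
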