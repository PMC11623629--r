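#' Design stimulus subsets for a multiple-arrangement task
#'
#' The multiple-arrangement paradigm presents a first set containing all
#' stimuli, then `n_subsets` pseudo-random subsets of `subset_size` stimuli.
#' Candidate designs draw each subset from a fresh random permutation of the
#' stimulus list; among `n_candidates` candidates the design covering the
#' greatest number of distinct unordered stimulus pairs is selected (ties
#' broken by first occurrence).
#'
#' @param n_stimuli number of stimuli.
#' @param n_subsets number of subsets per design.
#' @param subset_size stimuli per subset (<= `n_stimuli`).
#' @param n_candidates candidate designs to evaluate.
#' @param seed optional integer seed.
#' @param stimulus_ids optional stimulus ID labels (default `s001 ...`).
#' @return a `subset_design`: list with `subsets` (list of ID vectors),
#'   `n_stimuli`, `subset_size`, `n_subsets`, `unique_pair_count`,
#'   `candidate_index`.
#' @examples
#' d <- design_subsets(90, 12, 30, n_candidates = 50, seed = 1)
#' d$unique_pair_count
#' @export
design_subsets <- function(n_stimuli, n_subsets, subset_size,
                           n_candidates = 1000, seed = NULL,
                           stimulus_ids = NULL) {
  if (!is_count(n_stimuli) || !is_count(n_subsets) || !is_count(subset_size))
    stop_input("sizes must be positive counts")
  if (subset_size > n_stimuli)
    stop_input("subset_size must not exceed n_stimuli")
  if (subset_size < 2L) stop_input("subset_size must be at least 2")
  if (!is_count(n_candidates)) stop_input("n_candidates must be >= 1")
  if (is.null(stimulus_ids))
    stimulus_ids <- sprintf("s%03d", seq_len(n_stimuli))
  if (length(stimulus_ids) != n_stimuli || anyDuplicated(stimulus_ids))
    stop_input("stimulus_ids must be n_stimuli distinct labels")
  set_seed_if(seed)

  pair_template <- combn(subset_size, 2L)
  best <- NULL
  best_count <- -1L
  best_idx <- NA_integer_
  for (cand in seq_len(n_candidates)) {
    subsets <- lapply(seq_len(n_subsets), function(j)
      sample.int(n_stimuli)[seq_len(subset_size)])
    covered <- logical(n_stimuli * n_stimuli)
    for (ss in subsets) {
      a <- ss[pair_template[1L, ]]
      b <- ss[pair_template[2L, ]]
      covered[(pmin(a, b) - 1L) * n_stimuli + pmax(a, b)] <- TRUE
    }
    count <- sum(covered)
    if (count > best_count) {
      best <- subsets
      best_count <- count
      best_idx <- cand
    }
  }
  structure(list(
    subsets = lapply(best, function(ss) stimulus_ids[ss]),
    stimulus_ids = stimulus_ids,
    n_stimuli = n_stimuli, subset_size = subset_size,
    n_subsets = n_subsets, unique_pair_count = best_count,
    candidate_index = best_idx
  ), class = "subset_design")
}

#' @export
print.subset_design <- function(x, ...) {
  cat(sprintf(
    "subset design: %d subsets of %d / %d stimuli; %d unique pairs (%.1f%%)\n",
    x$n_subsets, x$subset_size, x$n_stimuli, x$unique_pair_count,
    100 * x$unique_pair_count / choose(x$n_stimuli, 2)))
  invisible(x)
}

#' One arrangement of stimuli on the screen
#'
#' Records the final 2D screen positions (pixels, origin top-left, y
#' increasing downward) of the stimuli in one arrangement set.
#'
#' @param participant_id participant label.
#' @param task arrangement task label (e.g. sociality, transitivity,
#'   person, object, scene).
#' @param set_index 0 for the full set, 1.. for subsets.
#' @param stimulus_ids distinct stimulus labels.
#' @param coords numeric matrix (stimuli x 2) of screen coordinates.
#' @return an `arrangement_record`.
#' @export
arrangement_record <- function(participant_id, task, set_index, stimulus_ids,
                               coords) {
  coords <- as.matrix(coords)
  if (anyDuplicated(stimulus_ids))
    stop_input(sprintf("duplicate stimulus ID in set %d: %s", set_index,
                       stimulus_ids[duplicated(stimulus_ids)][1L]))
  if (nrow(coords) != length(stimulus_ids) || ncol(coords) != 2L)
    stop_input("coords must be a (stimuli x 2) matrix")
  structure(list(participant_id = participant_id, task = task,
                 set_index = as.integer(set_index),
                 stimulus_ids = as.character(stimulus_ids), coords = coords),
            class = "arrangement_record")
}

#' Pairwise screen distances within one arrangement
#'
#' Euclidean distances between all stimulus pairs in screen coordinates.
#'
#' @param record an `arrangement_record` with at least two stimuli.
#' @return data frame with columns `a`, `b` (stimulus IDs) and `distance`,
#'   one row per unordered pair.
#' @export
arrangement_distances <- function(record) {
  k <- length(record$stimulus_ids)
  if (k < 2L) stop_input("at least 2 stimuli required")
  d <- as.matrix(stats::dist(record$coords))
  idx <- which(lower.tri(d), arr.ind = TRUE)
  data.frame(a = record$stimulus_ids[idx[, 2L]],
             b = record$stimulus_ids[idx[, 1L]],
             distance = d[idx], stringsAsFactors = FALSE)
}

#' Aggregate arrangements into a behavioral RDM
#'
#' Per stimulus pair, the plain mean over all observations of that pair
#' across records (each observation equally weighted). Every pair must be
#' observed at least once -- guaranteed when a full-set record is present.
#' An optional per-record RMS-distance normalization is available for
#' arrangements performed at different zoom levels; it is off by default,
#' matching direct averaging of raw screen distances.
#'
#' @param records list of `arrangement_record` objects.
#' @param normalize divide each record's distances by their root mean square
#'   before averaging.
#' @return an `rdm` over the union of stimulus IDs (ordered as in the
#'   record with the most stimuli, typically the full set).
#' @export
aggregate_arrangements <- function(records, normalize = FALSE) {
  stopifnot(length(records) >= 1L)
  sizes <- vapply(records, function(r) length(r$stimulus_ids), integer(1))
  labels <- records[[which.max(sizes)]]$stimulus_ids
  extra <- setdiff(unique(unlist(lapply(records, `[[`, "stimulus_ids"))),
                   labels)
  labels <- c(labels, extra)
  n <- length(labels)
  sums <- matrix(0, n, n)
  counts <- matrix(0L, n, n)
  for (rec in records) {
    idx <- match(rec$stimulus_ids, labels)
    d <- as.matrix(stats::dist(rec$coords))
    if (normalize) {
      rms <- sqrt(mean(d[lower.tri(d)]^2))
      if (rms > 0) d <- d / rms
    }
    sums[idx, idx] <- sums[idx, idx] + d
    counts[idx, idx] <- counts[idx, idx] + 1L
  }
  low <- which(lower.tri(counts) & counts == 0L, arr.ind = TRUE)
  if (nrow(low) > 0L)
    stop_input(sprintf("incomplete coverage: pair (%s, %s) never observed",
                       labels[low[1L, 2L]], labels[low[1L, 1L]]))
  m <- sums / pmax(counts, 1L)
  diag(m) <- 0
  rdm(m, labels, meta = list(source = "arrangements",
                             n_records = length(records),
                             normalized = normalize))
}

#' Read and write arrangement logs
#'
#' CSV schema: `participant_id`, `task`, `set_index`, `stimulus_id`,
#' `x_px`, `y_px` -- one row per placed stimulus. The reader rejects
#' duplicated stimuli within a set, naming the set.
#'
#' @param records list of `arrangement_record`s.
#' @param path file path.
#' @return `read_arrangements` returns a list of `arrangement_record`s.
#' @export
write_arrangements <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(participant_id = r$participant_id, task = r$task,
               set_index = r$set_index, stimulus_id = r$stimulus_ids,
               x_px = fmt_full(r$coords[, 1L]),
               y_px = fmt_full(r$coords[, 2L]))
  })
  write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_arrangements
#' @export
read_arrangements <- function(path) {
  tab <- read.table(path, sep = ",", header = TRUE,
                    stringsAsFactors = FALSE)
  key <- paste(tab$participant_id, tab$task, tab$set_index, sep = "\r")
  lapply(split(tab, factor(key, levels = unique(key))), function(d) {
    if (anyDuplicated(d$stimulus_id))
      stop_input(sprintf(
        "parse error: duplicated stimulus %s in set %d (participant %s)",
        d$stimulus_id[duplicated(d$stimulus_id)][1L], d$set_index[1L],
        d$participant_id[1L]))
    arrangement_record(d$participant_id[1L], d$task[1L], d$set_index[1L],
                       d$stimulus_id, cbind(d$x_px, d$y_px))
  })
}
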