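#' Feature-space RDM
#'
#' Pairwise distances between per-stimulus feature vectors (e.g. motion
#' energy, any precomputed embedding) under a named metric.
#'
#' @param features numeric matrix (stimuli x features) with labeled rows,
#'   or a named list of equal-length vectors.
#' @param metric one of `"correlation"` (1 - Pearson), `"cosine"`
#'   (1 - cosine similarity) or `"euclidean"`.
#' @return an `rdm`.
#' @export
feature_rdm <- function(features,
                        metric = c("correlation", "cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (is.list(features)) {
    lens <- lengths(features)
    if (length(unique(lens)) != 1L) stop_input("vectors differ in length")
    features <- do.call(rbind, features)
  }
  features <- as.matrix(features)
  labels <- rownames(features) %||% sprintf("s%03d", seq_len(nrow(features)))
  d <- switch(metric,
    correlation = {
      sds <- apply(features, 1L, sd)
      if (any(sds == 0))
        stop_input(sprintf(
          "undefined-distance: stimulus %s has a constant feature vector",
          labels[which(sds == 0)[1L]]))
      1 - cor(t(features))
    },
    cosine = {
      nrm <- sqrt(rowSums(features^2))
      if (any(nrm == 0))
        stop_input(sprintf(
          "undefined-distance: stimulus %s has a zero-norm vector",
          labels[which(nrm == 0)[1L]]))
      1 - tcrossprod(features / nrm)
    },
    euclidean = as.matrix(stats::dist(features))
  )
  diag(d) <- 0
  rdm(d, labels, meta = list(source = paste0("feature_", metric)))
}

#' Annotation tables
#'
#' Per-stimulus word annotations with pretrained embedding vectors: a data
#' frame with columns `stimulus_id`, `word`, `class` (`"verb"` or
#' `"nonverb"`) followed by the embedding dimensions `V1 ... Vd`.
#'
#' @param df a data frame in the schema above.
#' @return an `annotation_table`.
#' @export
annotation_table <- function(df) {
  need <- c("stimulus_id", "word", "class")
  if (!all(need %in% names(df)))
    stop_input("annotation table needs stimulus_id, word, class columns")
  if (!all(df$class %in% c("verb", "nonverb")))
    stop_input("word class must be 'verb' or 'nonverb'")
  vcols <- setdiff(names(df), need)
  if (length(vcols) < 2L) stop_input("embedding dimension must be >= 2")
  structure(df, class = c("annotation_table", "data.frame"))
}

annotation_vectors <- function(annotations, word_class = NULL) {
  vcols <- setdiff(names(annotations), c("stimulus_id", "word", "class"))
  rows <- if (is.null(word_class)) rep(TRUE, nrow(annotations))
          else annotations$class == word_class
  list(sub = annotations[rows, , drop = FALSE], vcols = vcols)
}

#' Semantic embedding RDM
#'
#' For each stimulus, the embedding vectors of all words of the requested
#' class are averaged; entries are pairwise cosine distances between the
#' per-stimulus mean vectors.
#'
#' @param annotations an `annotation_table`.
#' @param word_class `"verb"` or `"nonverb"`.
#' @return an `rdm`.
#' @export
semantic_rdm <- function(annotations, word_class = c("verb", "nonverb")) {
  word_class <- match.arg(word_class)
  av <- annotation_vectors(annotations, word_class)
  stimuli <- unique(annotations$stimulus_id)
  missing <- setdiff(stimuli, unique(av$sub$stimulus_id))
  if (length(missing) > 0L)
    stop_input(sprintf("stimulus %s has no %s-class words", missing[1L],
                       word_class))
  means <- t(vapply(stimuli, function(s) {
    colMeans(as.matrix(av$sub[av$sub$stimulus_id == s, av$vcols,
                              drop = FALSE]))
  }, numeric(length(av$vcols))))
  rownames(means) <- stimuli
  out <- feature_rdm(means, "cosine")
  out$meta$source <- paste0("semantic_", word_class)
  out
}

#' Inter-annotator agreement
#'
#' For each shared stimulus, each annotator's word vectors are averaged and
#' the Pearson correlation between the two mean vectors computed.
#'
#' @param a,b `annotation_table`s from two annotators over shared stimuli.
#' @return list with `per_stimulus` (named correlations), `mean` and `sd`.
#' @export
annotator_agreement <- function(a, b) {
  stimuli <- intersect(unique(a$stimulus_id), unique(b$stimulus_id))
  if (length(stimuli) == 0L) stop_input("no shared stimuli")
  ava <- annotation_vectors(a)
  avb <- annotation_vectors(b)
  if (!identical(ava$vcols, avb$vcols))
    stop_input("embedding dimensions differ between annotators")
  r <- vapply(stimuli, function(s) {
    va <- colMeans(as.matrix(ava$sub[ava$sub$stimulus_id == s, ava$vcols,
                                     drop = FALSE]))
    vb <- colMeans(as.matrix(avb$sub[avb$sub$stimulus_id == s, avb$vcols,
                                     drop = FALSE]))
    if (sd(va) == 0 || sd(vb) == 0)
      stop_input(sprintf(
        "undefined correlation: constant mean vector for stimulus %s", s))
    cor(va, vb)
  }, numeric(1))
  list(per_stimulus = r, mean = mean(r), sd = sd(r))
}

#' Read and write annotation TSV files
#'
#' Schema: `stimulus_id`, `word`, `class`, then the embedding columns.
#'
#' @param x an `annotation_table`.
#' @param path file path.
#' @export
write_annotations <- function(x, path) {
  av <- annotation_vectors(x)
  out <- x
  for (cc in av$vcols) out[[cc]] <- fmt_full(x[[cc]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  annotation_table(read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}
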