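#' Condition x unit response patterns
#'
#' One subject-session's matrix of responses, conditions in rows and
#' measurement units (voxels, vertices, simulated units) in columns.
#'
#' @param mat numeric matrix (conditions x units); finite entries only.
#' @param subject_id,session_id identifiers stored with the patterns.
#' @param conditions condition labels; default `rownames(mat)`.
#' @param zscored logical flag recording whether profiles are z-scored.
#' @return a `response_patterns` object.
#' @export
response_patterns <- function(mat, subject_id = "sub01", session_id = 1L,
                              conditions = rownames(mat), zscored = FALSE) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stop_input("non-finite entries in patterns")
  if (is.null(conditions)) conditions <- sprintf("cond%03d", seq_len(nrow(mat)))
  if (length(conditions) != nrow(mat)) stop_input("condition label mismatch")
  rownames(mat) <- conditions
  structure(list(matrix = mat, subject_id = subject_id,
                 session_id = session_id,
                 conditions = as.character(conditions), zscored = zscored),
            class = "response_patterns")
}

#' @export
print.response_patterns <- function(x, ...) {
  cat(sprintf("response patterns: subject %s, session %s, %d conditions x %d units%s\n",
              x$subject_id, x$session_id, nrow(x$matrix), ncol(x$matrix),
              if (isTRUE(x$zscored)) " (z-scored)" else ""))
  invisible(x)
}

#' Z-score response profiles across conditions
#'
#' Each unit's response profile (its column) is standardized to mean 0 and
#' standard deviation 1 across conditions prior to any RDM construction.
#' Units with constant profiles have no defined z-score; they are dropped
#' with a warning.
#'
#' @param patterns a `response_patterns` object.
#' @return the z-scored `response_patterns`.
#' @export
zscore_profiles <- function(patterns) {
  stopifnot(inherits(patterns, "response_patterns"))
  m <- patterns$matrix
  if (nrow(m) < 2L) stop_input("need at least 2 conditions to z-score")
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant-profile unit(s)", sum(sds == 0)),
            call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  m <- scale(m)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  out <- patterns
  out$matrix <- m
  out$zscored <- TRUE
  out
}

#' Split-data (cross-session) neural RDM
#'
#' Computes the matrix `M` of pairwise Pearson correlations between
#' condition response patterns *across* two scanning sessions
#' (`M[i, j] = cor(session-1 pattern of condition i, session-2 pattern of
#' condition j)` over units), separating signal geometry from within-session
#' noise. The returned RDM is `1 - (M + t(M)) / 2` with the diagonal forced
#' to zero; the raw diagonal correlations (split-half pattern reliability,
#' excluded from model comparisons) are kept in `meta$reliability`.
#'
#' @param s1,s2 `response_patterns` for the same subject and conditions with
#'   matching unit counts (z-score first; see [zscore_profiles()]).
#' @return an `rdm` with `meta$reliability` and, if any diagonal correlation
#'   is negative, `meta$negative_reliability = TRUE`.
#' @export
splitdata_rdm <- function(s1, s2) {
  stopifnot(inherits(s1, "response_patterns"),
            inherits(s2, "response_patterns"))
  if (!identical(s1$conditions, s2$conditions))
    stop_input("sessions have different conditions")
  if (ncol(s1$matrix) != ncol(s2$matrix))
    stop_input("unit-count mismatch between sessions")
  for (s in list(s1, s2)) {
    sds <- apply(s$matrix, 1L, sd)
    if (any(sds == 0))
      stop_input(sprintf(
        "undefined correlation: condition %s has a zero-variance pattern",
        s$conditions[which(sds == 0)[1L]]))
  }
  m <- cor(t(s1$matrix), t(s2$matrix))
  rel <- diag(m)
  d <- 1 - (m + t(m)) / 2
  diag(d) <- 0
  rdm(d, s1$conditions,
      meta = c(list(source = "splitdata", subject = s1$subject_id,
                    reliability = rel),
               if (any(rel < 0)) list(negative_reliability = TRUE)))
}

#' Read and write response-pattern tables
#'
#' Plain tab-separated tables, conditions in rows (first column
#' `condition`), units in columns, with `#`-prefixed header lines recording
#' subject, session and z-scoring. Values use 17 significant digits so the
#' round trip is exact.
#'
#' @param x a `response_patterns` object.
#' @param path file path.
#' @export
write_patterns <- function(x, path) {
  stopifnot(inherits(x, "response_patterns"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id=%s", x$subject_id),
               sprintf("# session_id=%s", x$session_id),
               sprintf("# zscored=%d", as.integer(isTRUE(x$zscored)))), con)
  tab <- data.frame(condition = x$conditions,
                    matrix(fmt_full(x$matrix), nrow = nrow(x$matrix)))
  colnames(tab) <- c("condition", colnames(x$matrix) %||%
                       sprintf("u%04d", seq_len(ncol(x$matrix))))
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  hdr <- readLines(path, n = 3L)
  if (!all(startsWith(hdr, "# ")))
    stop_input(sprintf("malformed patterns header in %s", path))
  kv <- sub("^# ", "", hdr)
  get <- function(key) sub(paste0(key, "="), "", kv[startsWith(kv, key)])
  tab <- read.table(path, sep = "\t", header = TRUE, skip = 3L,
                    check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!all(is.finite(m))) stop_input(sprintf("non-finite entry in %s", path))
  rownames(m) <- tab[[1L]]
  response_patterns(m, subject_id = get("subject_id"),
                    session_id = get("session_id"), conditions = tab[[1L]],
                    zscored = get("zscored") == "1")
}
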