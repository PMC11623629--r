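#' Representational dissimilarity matrices
#'
#' An `rdm` is the universal currency of the package: a labeled, square,
#' symmetric, zero-diagonal matrix of pairwise dissimilarities between
#' experimental conditions, with free-form provenance metadata (`meta`)
#' recording how it was built (source kind, participant/block, dissimilarity
#' convention).
#'
#' @param mat square numeric matrix of dissimilarities.
#' @param labels character vector of condition labels; defaults to
#'   `rownames(mat)`.
#' @param meta named list of provenance metadata.
#' @param tol tolerance for the symmetry and zero-diagonal checks. The matrix
#'   is symmetrized as `(m + t(m)) / 2` and the diagonal forced to exactly 0.
#' @return an object of class `rdm`.
#' @export
rdm <- function(mat, labels = rownames(mat), meta = list(), tol = 1e-8) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop_input("RDM must be square")
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop_input(sprintf("non-finite RDM entry at row %d, column %d",
                       bad[1L], bad[2L]))
  }
  if (max(abs(mat - t(mat))) > tol) {
    bad <- which(abs(mat - t(mat)) > tol, arr.ind = TRUE)[1L, ]
    stop_input(sprintf("RDM asymmetric beyond tolerance at row %d, column %d",
                       bad[1L], bad[2L]))
  }
  if (max(abs(diag(mat))) > tol)
    stop_input("RDM diagonal must be zero")
  if (is.null(labels)) labels <- sprintf("cond%03d", seq_len(nrow(mat)))
  if (length(labels) != nrow(mat)) stop_input("label length mismatch")
  if (anyDuplicated(labels)) stop_input("duplicate condition labels")
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  dimnames(mat) <- list(labels, labels)
  structure(list(matrix = mat, labels = as.character(labels), meta = meta),
            class = "rdm")
}

#' @export
as.matrix.rdm <- function(x, ...) x$matrix

#' Coerce to an RDM
#' @param x an `rdm` or square matrix.
#' @param ... passed to [rdm()].
#' @export
as_rdm <- function(x, ...) {
  if (inherits(x, "rdm")) x else rdm(x, ...)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d x %d conditions", length(x$labels), length(x$labels)))
  if (!is.null(x$meta$source)) cat(sprintf(" [%s]", x$meta$source))
  cat("\n")
  v <- rdm_vec(x)
  cat(sprintf("  dissimilarities: min %.4g, median %.4g, max %.4g\n",
              min(v), median(v), max(v)))
  invisible(x)
}

#' @export
plot.rdm <- function(x, main = x$meta$source, ...) {
  n <- length(x$labels)
  graphics::image(seq_len(n), seq_len(n), t(x$matrix[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = if (is.null(main)) "RDM" else main, ...)
  invisible(x)
}

#' Vectorize an RDM
#'
#' The single shared vectorization routine used throughout the package for
#' every comparison between RDMs: the lower triangle excluding the diagonal.
#' Using one routine everywhere guarantees that neural and model vectors are
#' always in the same pair order.
#'
#' @param x an `rdm` or square symmetric matrix.
#' @return numeric vector of length `n (n - 1) / 2`.
#' @export
rdm_vec <- function(x) {
  m <- if (inherits(x, "rdm")) x$matrix else as.matrix(x)
  m[lower.tri(m)]
}

#' Average RDMs elementwise
#'
#' Used, e.g., to average behavioral RDMs across participants. All RDMs must
#' share one stimulus ordering.
#'
#' @param rdms list of `rdm` objects with identical labels.
#' @return an `rdm` whose entries are the elementwise means.
#' @export
average_rdms <- function(rdms) {
  stopifnot(length(rdms) >= 1L)
  rdms <- lapply(rdms, as_rdm)
  labs <- rdms[[1L]]$labels
  for (i in seq_along(rdms)) {
    if (!identical(rdms[[i]]$labels, labs))
      stop_input(sprintf("RDM %d has mismatching labels", i))
  }
  m <- Reduce(`+`, lapply(rdms, as.matrix)) / length(rdms)
  rdm(m, labs, meta = list(source = "average", n = length(rdms)))
}

#' Classical multidimensional scaling of an RDM
#'
#' Embeds conditions in `n_dims` dimensions by classical (Torgerson) metric
#' MDS: double-centering of squared dissimilarities followed by a truncated
#' eigendecomposition, the strain-optimal rank-`n_dims` embedding.
#'
#' @param x an `rdm`.
#' @param n_dims embedding dimension, at most `n - 1`.
#' @return numeric matrix (conditions x `n_dims`) with labeled rows.
#' @export
mds_embed <- function(x, n_dims = 2L) {
  x <- as_rdm(x)
  n <- length(x$labels)
  if (!is_count(n_dims) || n_dims > n - 1L)
    stop_input("n_dims must be a count of at most n - 1")
  y <- stats::cmdscale(x$matrix, k = n_dims)
  # cmdscale drops columns with non-positive eigenvalues (e.g. all-zero RDM);
  # pad so the contract "n_dims columns" always holds
  if (ncol(y) < n_dims)
    y <- cbind(y, matrix(0, n, n_dims - ncol(y)))
  rownames(y) <- x$labels
  y
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Read and write RDM files
#'
#' RDMs are stored as tab-separated square tables with a leading header row
#' and column of stimulus IDs. Numeric values are written with 17 significant
#' digits so the write-read round trip is exact. The reader validates
#' symmetry and the zero diagonal.
#'
#' @param x an `rdm`.
#' @param path file path.
#' @return `read_rdm` returns an `rdm`; `write_rdm` returns `path`
#'   invisibly.
#' @export
write_rdm <- function(x, path) {
  x <- as_rdm(x)
  m <- x$matrix
  chr <- matrix(fmt_full(m), nrow(m))
  tab <- cbind(x$labels, chr)
  colnames(tab) <- c("stimulus_id", x$labels)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
  labels <- tab[[1L]]
  m <- matrix(as.numeric(as.matrix(tab[, -1L, drop = FALSE])),
              nrow = length(labels))
  if (!identical(colnames(tab)[-1L], labels))
    stop_input(sprintf("RDM file %s: row and column labels disagree", path))
  rdm(m, labels)
}
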