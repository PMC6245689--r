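#' Copula-transform an expression matrix
#'
#' Replaces each transcript's values by their normalized ranks
#' `rank / (n_samples + 1)` (average ranks for ties), so downstream mutual
#' information estimation is invariant to any strictly monotone per-transcript
#' transformation of the raw data. Output values lie strictly inside (0, 1).
#' Constant rows become all `0.5` and raise a warning.
#'
#' @param mat expression matrix (transcripts x samples).
#' @return matrix of the same shape and dimnames with values in (0, 1).
#' @export
copula_transform <- function(mat) {
  mat <- as_expression_matrix(mat)
  if (anyNA(mat)) stop("missing values in expression matrix", call. = FALSE)
  rng <- apply(mat, 1L, function(x) max(x) - min(x))
  if (any(rng == 0))
    warning("constant transcript row(s): ", paste(rownames(mat)[rng == 0], collapse = ", "),
            "; mapped to 0.5", call. = FALSE)
  n <- ncol(mat)
  out <- t(apply(mat, 1L, rank, ties.method = "average")) / (n + 1)
  dimnames(out) <- dimnames(mat)
  out
}

# large finite stand-in for +Inf when |C| collapses (perfect collinearity),
# so downstream ranking by MI still works
.MI_CAP <- 1e6

#' Gaussian mutual information between two vectors
#'
#' Parametric estimator `0.5 * log(var(x) * var(y) / det(C))` in nats, where
#' `C` is the 2x2 sample covariance matrix; algebraically equal to
#' `-0.5 * log(1 - rho^2)` for the Pearson correlation `rho`. Perfect
#' collinearity (`det(C) <= 0` or underflowed) is mapped to a large finite
#' cap with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @param cap finite value returned on collinearity (default `1e6`).
#' @return mutual information in nats (>= 0).
#' @export
gaussian_mi <- function(x, y, cap = .MI_CAP) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("constant vector", call. = FALSE)
  detC <- vx * vy - stats::cov(x, y)^2
  # relative threshold: exact collinearity leaves float residue in detC
  if (detC <= 0 || detC / (vx * vy) < 1e-12) {
    warning("collinear pair: mutual information capped", call. = FALSE)
    return(cap)
  }
  max(0.5 * log(vx * vy / detC), 0)
}

#' Pairwise mutual-information matrix
#'
#' Applies the Gaussian estimator to every transcript pair (via the
#' correlation matrix, `-0.5 * log(1 - rho^2)`); the diagonal is set to 0.
#'
#' @param mat expression matrix (transcripts x samples), typically already
#'   copula-transformed; >= 2 transcripts, no constant rows.
#' @param cap finite value standing in for infinite MI on collinear pairs.
#' @return an object of class `mi_matrix`: list with `ids`, `M` (symmetric
#'   matrix of MI in nats), `significant` (`NULL` until
#'   [significance_mask()] is applied) and `threshold`.
#' @export
mi_matrix <- function(mat, cap = .MI_CAP) {
  mat <- as_expression_matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 transcripts", call. = FALSE)
  if (ncol(mat) < 3L) stop("need at least 3 samples", call. = FALSE)
  rng <- apply(mat, 1L, function(x) max(x) - min(x))
  if (any(rng == 0))
    stop("constant transcript row(s): mutual information undefined", call. = FALSE)
  M <- .mi_from_data(mat, cap)
  structure(list(ids = rownames(mat), M = M, significant = NULL,
                 threshold = NA_real_),
            class = "mi_matrix")
}

.mi_from_data <- function(mat, cap = .MI_CAP) {
  R <- stats::cor(t(mat))
  omr <- 1 - R^2
  M <- matrix(cap, nrow(R), ncol(R), dimnames = dimnames(R))
  ok <- omr > 0 & omr >= 1e-12
  M[ok] <- -0.5 * log(omr[ok])
  M[M < 0] <- 0
  diag(M) <- 0
  M
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat("mi_matrix:", length(x$ids), "transcripts")
  if (!is.null(x$significant))
    cat("; significance threshold", format(x$threshold, digits = 4),
        "nats;", sum(x$significant[upper.tri(x$significant)]),
        "significant pairs")
  cat("\n")
  invisible(x)
}

#' Resampling significance mask for a mutual-information matrix
#'
#' Builds a pooled null distribution by recomputing the full MI matrix on
#' row-permuted data (each permutation shuffles every transcript's sample
#' order independently) and pooling all off-diagonal null values. An entry is
#' significant iff the observed MI exceeds the `(1 - alpha)` quantile of the
#' pooled null; non-significant entries are treated as 0 by network
#' inference (see [masked_mi()]).
#'
#' @param mi `mi_matrix` object.
#' @param data the expression matrix the MI was computed from (same row
#'   order).
#' @param n_perm number of full-matrix permutations (default 30).
#' @param alpha significance level in (0, 1), default 0.05.
#' @param seed optional integer seed; given the seed the mask is
#'   deterministic.
#' @return the `mi_matrix` with `significant` and `threshold` filled in.
#' @export
significance_mask <- function(mi, data, n_perm = 30L, alpha = 0.05,
                              seed = NULL) {
  stopifnot(inherits(mi, "mi_matrix"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  data <- as_expression_matrix(data)
  if (!identical(rownames(data), mi$ids))
    stop("data rows do not match the MI matrix ids", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(data)
  ut <- upper.tri(mi$M)
  null_pool <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    perm <- data
    for (i in seq_len(nrow(perm))) perm[i, ] <- perm[i, sample.int(p)]
    null_pool[[b]] <- .mi_from_data(perm)[ut]
  }
  thr <- stats::quantile(unlist(null_pool), probs = 1 - alpha, names = FALSE)
  sig <- mi$M > thr
  diag(sig) <- FALSE
  mi$significant <- sig
  mi$threshold <- thr
  mi
}

#' Significance-masked MI values
#'
#' @param mi `mi_matrix`, after [significance_mask()].
#' @return matrix equal to `M` with non-significant entries set to 0.
#' @export
masked_mi <- function(mi) {
  stopifnot(inherits(mi, "mi_matrix"))
  if (is.null(mi$significant))
    stop("MI matrix has no significance mask; run significance_mask() first",
         call. = FALSE)
  mi$M * mi$significant
}

#' Read / write a square MI (or adjacency) matrix as TSV
#'
#' Square tab-delimited matrix with an identifier header row and first
#' column.
#'
#' @param m square matrix with dimnames.
#' @param path file path.
#' @return `read_square_tsv()` returns the matrix.
#' @export
write_square_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_square_tsv
#' @export
read_square_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}
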