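#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of normalized log2 intensities
#' with transcripts as rows (rownames are transcript identifiers, see
#' [antisense_id()]) and samples as columns (colnames are sample labels).
#'
#' @param mat matrix-like object.
#' @return the validated numeric matrix.
#' @keywords internal
as_expression_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("expression matrix must be numeric", call. = FALSE)
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  if (anyDuplicated(rownames(mat)))
    stop("duplicated transcript identifiers", call. = FALSE)
  mat
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' target distribution is the vector of per-rank means across columns, and
#' each value is replaced by the target value at its within-column rank.
#' Tied input values receive the mean of the target values at their tied
#' ranks. Rank order within each column is preserved, and after
#' normalization every column holds the identical multiset of values.
#'
#' @param mat expression matrix (transcripts x samples), no missing values,
#'   at least two samples.
#' @return matrix of the same shape and dimnames.
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
#' quantile_normalize(m)
quantile_normalize <- function(mat) {
  mat <- as_expression_matrix(mat)
  if (ncol(mat) < 2L)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  if (anyNA(mat)) stop("missing values in expression matrix", call. = FALSE)
  target <- rowMeans(apply(mat, 2L, sort))
  out <- apply(mat, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    (target[floor(r)] + target[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Paired differential expression between two conditions
#'
#' Computes, per transcript, a paired two-sided t-test across matched
#' samples (columns paired by position, e.g. genotypes measured in both
#' conditions) and the mean log2 fold change (`mat_b` minus `mat_a`). A
#' transcript is flagged differentially expressed iff
#' `p_value < alpha` and `|log_fold_change| >= min_lfc`. P-values are raw
#' (no multiple-testing correction at this step).
#'
#' @param mat_a,mat_b expression matrices with identical transcript rows and
#'   paired columns (same count, same order); at least 3 pairs.
#' @param alpha p-value threshold, default `0.01`.
#' @param min_lfc minimal absolute log2 fold change, default `1`.
#' @return data frame with columns `transcript`, `strand`
#'   (`"sense"`/`"antisense"`), `p_value`, `log_fold_change`, `de` (logical).
#' @export
differential_expression <- function(mat_a, mat_b, alpha = 0.01, min_lfc = 1) {
  mat_a <- as_expression_matrix(mat_a)
  mat_b <- as_expression_matrix(mat_b)
  if (!identical(rownames(mat_a), rownames(mat_b)))
    stop("transcript lists differ between conditions", call. = FALSE)
  if (ncol(mat_a) != ncol(mat_b))
    stop("conditions must have the same number of paired samples", call. = FALSE)
  n <- ncol(mat_a)
  if (n < 3L) stop("paired t-test needs at least 3 pairs", call. = FALSE)
  d <- mat_b - mat_a
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1L))
  tt <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(tt), df = n - 1L, lower.tail = FALSE)
  zero <- s == 0
  p[zero] <- ifelse(m[zero] == 0, 1, 0)
  res <- data.frame(
    transcript = rownames(mat_a),
    strand = ifelse(is_antisense(rownames(mat_a)), "antisense", "sense"),
    p_value = unname(p),
    log_fold_change = unname(m),
    stringsAsFactors = FALSE
  )
  res$de <- res$p_value < alpha & abs(res$log_fold_change) >= min_lfc
  res
}

#' Read / write tab-delimited expression matrices
#'
#' The layout is one header row of sample labels, then one row per
#' transcript with the identifier in the first column.
#'
#' @param path file path.
#' @param mat expression matrix.
#' @return `read_expression_tsv()` returns the expression matrix;
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  as_expression_matrix(m)
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(mat, path) {
  mat <- as_expression_matrix(mat)
  df <- data.frame(transcript = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
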