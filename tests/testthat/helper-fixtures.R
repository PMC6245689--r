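# Fixture builders and independent oracles shared across test files.

# mi_matrix object straight from a symmetric MI matrix; by default every
# positive entry is "significant", so network inference can be exercised
# without running the resampling mask.
mi_fixture <- function(M, ids = NULL, significant = NULL) {
  if (is.null(ids)) ids <- rownames(M)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  if (is.null(significant)) significant <- M > 0
  diag(significant) <- FALSE
  structure(list(ids = ids, M = M, significant = significant,
                 threshold = 0),
            class = "mi_matrix")
}

# random symmetric MI matrix with ~frac of entries significant
random_mi <- function(n, frac = 0.4) {
  M <- matrix(0, n, n)
  ut <- upper.tri(M)
  vals <- stats::runif(sum(ut))
  vals[stats::runif(sum(ut)) > frac] <- 0
  M[ut] <- vals
  M <- M + t(M)
  mi_fixture(M)
}

# core_network straight from an edge list (directed arcs)
net_fixture <- function(ids, edges, directed = TRUE, rate = NA_real_) {
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in edges) {
    A[e[1], e[2]] <- TRUE
    if (!directed) A[e[2], e[1]] <- TRUE
  }
  core_network(ids, A, rate = rate, directed = directed)
}

# independent quantile-normalization oracle: explicit rank-then-average,
# one column at a time, no shared code with the implementation
qn_oracle <- function(mat) {
  sorted <- sapply(seq_len(ncol(mat)), function(j) sort(mat[, j]))
  target <- apply(sorted, 1, mean)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    for (i in seq_len(nrow(mat)))
      out[i, j] <- mean(target[c(floor(r[i]), ceiling(r[i]))])
  }
  out
}

# brute-force union-find for connected components
uf_components <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (e in edges) parent[[find(e[1])]] <- find(e[2])
  vapply(ids, find, "")
}

# exhaustive hypergeometric upper tail by enumerating all draws
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  carriers <- seq_len(K)   # wlog the first K items carry the term
  hits <- apply(draws, 2, function(d) sum(d %in% carriers))
  mean(hits >= k)
}

# transitive closure of a parent map by repeated squaring over a matrix
closure_oracle <- function(parents) {
  terms <- unique(c(names(parents), unlist(parents)))
  A <- matrix(FALSE, length(terms), length(terms),
              dimnames = list(terms, terms))
  for (t in names(parents)) A[t, parents[[t]]] <- TRUE
  repeat {
    A2 <- A | ((A %*% A) > 0)
    if (identical(A2, A)) break
    A <- A2
  }
  lapply(stats::setNames(terms, terms), function(t) colnames(A)[A[t, ]])
}

# random connected undirected igraph with unit weights
random_connected_graph <- function(n, p_edge = 0.12) {
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# tiny deterministic expression fixture with correlated pairs
toy_expression <- function(n_genes = 6, p = 20, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * p), n_genes, p,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(p))))
  m
}
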