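#' Core network container
#'
#' A core network is stored as a boolean adjacency matrix over an ordered
#' transcript list. For the extended core network the matrix is asymmetric:
#' `A[g, g']` is `TRUE` when `g'` has been accepted into the neighbourhood
#' of `g` (an out-edge of `g`). The single-best-edge baseline is
#' symmetrized and undirected.
#'
#' @param ids character vector of transcript identifiers.
#' @param A logical adjacency matrix (`length(ids)` square, dimnames `ids`);
#'   the diagonal must be `FALSE`.
#' @param rate the accepting rate the network was inferred with (or `NA`).
#' @param directed whether `A` is to be read as asymmetric out-edges.
#' @return object of class `core_network`.
#' @export
core_network <- function(ids, A, rate = NA_real_, directed = TRUE) {
  A <- as.matrix(A)
  storage.mode(A) <- "logical"
  stopifnot(length(ids) == nrow(A), nrow(A) == ncol(A))
  if (any(diag(A))) stop("self-loops are not allowed", call. = FALSE)
  dimnames(A) <- list(ids, ids)
  structure(list(ids = as.character(ids), A = A, rate = rate,
                 directed = directed),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  ne <- if (x$directed) sum(x$A) else sum(x$A[upper.tri(x$A)] | t(x$A)[upper.tri(x$A)])
  cat("core_network:", length(x$ids), "nodes,", ne,
      if (x$directed) "arcs" else "edges",
      if (!is.na(x$rate)) paste0("(accepting rate ", x$rate, ")") else "",
      "\n")
  invisible(x)
}

#' Extended core network inference
#'
#' For each gene `g` let `m_g` be the maximum significance-masked MI on its
#' row; a partner `g'` is accepted into `g`'s neighbourhood iff its MI is
#' significant (> 0 after masking) and within the accepting rate `r` of the
#' best value: `M[g, g'] >= (1 - r) * m_g`. At `r = 0` only the argmax set
#' is accepted (all ties kept); at `r = 1` every significant partner is
#' accepted. The result is an asymmetric adjacency matrix: acceptance by
#' `g` does not imply acceptance by `g'`.
#'
#' @param mi `mi_matrix` with a significance mask (see [significance_mask()]).
#' @param r accepting rate in \[0, 1\].
#' @return directed [core_network()].
#' @export
ecn_infer <- function(mi, r) {
  stopifnot(inherits(mi, "mi_matrix"))
  if (!(is.numeric(r) && length(r) == 1L && r >= 0 && r <= 1))
    stop("accepting rate r must be a number in [0, 1]", call. = FALSE)
  W <- masked_mi(mi)
  n <- nrow(W)
  rmax <- apply(W, 1L, max)
  thr <- matrix((1 - r) * rmax, n, n)    # per-row threshold, recycled down columns
  A <- W > 0 & W >= thr
  diag(A) <- FALSE
  core_network(mi$ids, A, rate = r, directed = TRUE)
}

#' Single-best-edge core network (C3NET-style baseline)
#'
#' Each gene contributes its single strongest significant interaction
#' (first index on exact ties, or all tied maxima with `ties = "all"`);
#' the contributed arcs are symmetrized into an undirected network.
#'
#' @param mi `mi_matrix` with a significance mask.
#' @param ties `"first"` (original behaviour) or `"all"`.
#' @return undirected [core_network()].
#' @export
c3net_infer <- function(mi, ties = c("first", "all")) {
  stopifnot(inherits(mi, "mi_matrix"))
  ties <- match.arg(ties)
  W <- masked_mi(mi)
  n <- nrow(W)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    m <- max(W[i, ])
    if (m <= 0) next
    j <- if (ties == "first") which.max(W[i, ]) else which(W[i, ] == m)
    A[i, j] <- TRUE
    A[j, i] <- TRUE
  }
  core_network(mi$ids, A, rate = NA_real_, directed = FALSE)
}

#' Symmetrize a core network
#'
#' @param net [core_network()].
#' @param mode `"union"` (edge present if either direction is) or
#'   `"intersection"` (both directions required).
#' @return undirected [core_network()].
#' @export
symmetrize <- function(net, mode = c("union", "intersection")) {
  stopifnot(inherits(net, "core_network"))
  mode <- match.arg(mode)
  A <- if (mode == "union") net$A | t(net$A) else net$A & t(net$A)
  core_network(net$ids, A, rate = net$rate, directed = FALSE)
}

#' Edge list of a core network
#'
#' @param net [core_network()].
#' @return data frame `from`, `to`; for undirected networks each edge is
#'   listed once with `from <= to` in id order.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "core_network"))
  A <- net$A
  if (!net$directed) {
    A <- A | t(A)
    A[lower.tri(A)] <- FALSE
  }
  idx <- which(A, arr.ind = TRUE)
  data.frame(from = net$ids[idx[, 1L]], to = net$ids[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Convert a core network to an igraph graph
#'
#' @param net [core_network()].
#' @return igraph object (directed or undirected to match the network).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "core_network"))
  igraph::graph_from_adjacency_matrix(
    net$A * 1, mode = if (net$directed) "directed" else "undirected")
}
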