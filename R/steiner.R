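#' Steiner trees over core networks
#'
#' A Steiner tree connects a terminal set (here: the genes of an
#' AS-impacted sub-graph) inside a larger undirected graph (here: the
#' union-symmetrized sense+anti-sense network), possibly through
#' non-terminal "Steiner" nodes. Edge weights default to 1 (hop count);
#' pass `weights` (e.g. `1/MI`) for weighted trees.
#'
#' @name steiner
NULL

.as_steiner_graph <- function(graph, weights = NULL) {
  if (inherits(graph, "core_network")) {
    if (graph$directed) graph <- symmetrize(graph, "union")
    g <- as_igraph(graph)
  } else if (igraph::is_igraph(graph)) {
    g <- igraph::as_undirected(graph, mode = "collapse")
  } else stop("graph must be a core_network or an igraph object", call. = FALSE)
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  igraph::E(g)$weight <- if (is.null(weights)) 1 else weights
  g
}

.new_steiner_tree <- function(g_tree, terminals) {
  nodes <- igraph::V(g_tree)$name
  el <- igraph::as_data_frame(g_tree, what = "edges")
  edges <- data.frame(from = el$from, to = el$to,
                      weight = if (nrow(el)) el$weight else numeric(0),
                      stringsAsFactors = FALSE)
  structure(list(terminals = terminals, nodes = nodes, edges = edges,
                 total_weight = sum(edges$weight)),
            class = "steiner_tree")
}

#' @export
print.steiner_tree <- function(x, ...) {
  cat("steiner_tree:", length(x$terminals), "terminals,",
      length(x$nodes) - length(x$terminals), "Steiner nodes,",
      nrow(x$edges), "edges, total weight", format(x$total_weight), "\n")
  invisible(x)
}

# MST of the induced subgraph, then iteratively drop non-terminal leaves
.prune_tree <- function(g, nodes, terminals) {
  sub <- igraph::induced_subgraph(g, nodes)
  tr <- igraph::mst(sub)
  repeat {
    deg <- igraph::degree(tr)
    drop <- names(deg)[deg <= 1 & !(names(deg) %in% terminals)]
    if (!length(drop)) break
    tr <- igraph::delete_vertices(tr, drop)
  }
  tr
}

#' Shortest-path Steiner tree approximation (Takahashi–Matsuyama)
#'
#' Starts from one terminal and repeatedly attaches the terminal closest
#' (by shortest path) to the growing tree via that path; once all terminals
#' are connected, the induced sub-graph is pruned with a minimum spanning
#' tree followed by removal of non-terminal leaves. The approximation ratio
#' is at most `2 * (1 - 1/|terminals|)` times the optimum.
#'
#' @param graph undirected graph: a [core_network()] (symmetrized if
#'   directed) or an igraph object.
#' @param terminals character vector of terminal node names, all present in
#'   the graph.
#' @param seed optional integer; selects the starting terminal and makes
#'   tie-breaks reproducible. Unset, the lexicographically smallest terminal
#'   starts.
#' @param weights optional per-edge weights (default all 1).
#' @return a `steiner_tree` (list with `terminals`, `nodes`, `edges`,
#'   `total_weight`). If the terminals span several connected components a
#'   warning is raised and a list of partial trees (one per component) is
#'   returned instead.
#' @export
steiner_sp_approx <- function(graph, terminals, seed = NULL, weights = NULL) {
  g <- .as_steiner_graph(graph, weights)
  terminals <- unique(as.character(terminals))
  missing <- setdiff(terminals, igraph::V(g)$name)
  if (length(missing))
    stop("terminal(s) absent from graph: ", paste(missing, collapse = ", "),
         call. = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership[terminals]
  if (length(unique(memb)) > 1L) {
    warning("terminals span ", length(unique(memb)),
            " components; returning partial trees", call. = FALSE)
    return(lapply(split(terminals, memb), function(tt)
      steiner_sp_approx(g, tt, seed = seed)))
  }
  if (!is.null(seed)) set.seed(seed)
  start <- if (is.null(seed)) sort(terminals)[1L] else sample(terminals, 1L)
  tree_nodes <- start
  remaining <- setdiff(terminals, start)
  while (length(remaining)) {
    D <- igraph::distances(g, v = remaining, to = tree_nodes)
    best <- which(D == min(D), arr.ind = TRUE)[1L, , drop = TRUE]
    from <- remaining[best[["row"]]]
    to <- tree_nodes[best[["col"]]]
    path <- igraph::shortest_paths(g, from = from, to = to,
                                   output = "vpath")$vpath[[1L]]
    tree_nodes <- union(tree_nodes, names(path))
    remaining <- setdiff(remaining, from)
  }
  .new_steiner_tree(.prune_tree(g, tree_nodes, terminals), terminals)
}

#' Exact minimum Steiner tree (Dreyfus–Wagner)
#'
#' Dynamic program over terminal subsets; exact for any graph but
#' exponential in the number of terminals, so intended for small-instance
#' validation of [steiner_sp_approx()].
#'
#' @inheritParams steiner_sp_approx
#' @param max_terminals guard against oversized instances (default 10).
#' @return a `steiner_tree` of minimal total weight.
#' @export
steiner_exact <- function(graph, terminals, weights = NULL,
                          max_terminals = 10L) {
  g <- .as_steiner_graph(graph, weights)
  terminals <- unique(as.character(terminals))
  vn <- igraph::V(g)$name
  missing <- setdiff(terminals, vn)
  if (length(missing))
    stop("terminal(s) absent from graph: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(terminals) > max_terminals)
    stop("instance too large for the exact solver; use steiner_sp_approx()",
         call. = FALSE)
  comp <- igraph::components(g)
  if (length(unique(comp$membership[terminals])) > 1L)
    stop("terminals are not in a single connected component", call. = FALSE)
  if (length(terminals) == 1L) {
    tr <- igraph::induced_subgraph(g, terminals)
    return(.new_steiner_tree(tr, terminals))
  }
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  t0 <- terminals[1L]
  rest <- terminals[-1L]
  m <- length(rest)
  nS <- bitwShiftL(1L, m) - 1L
  f <- matrix(Inf, nS, n, dimnames = list(NULL, vn))
  walk_ptr <- matrix(NA_integer_, nS, n)   # node the path to v starts from
  part_ptr <- matrix(NA_integer_, nS, n)   # subset split at the merge node
  singles <- bitwShiftL(1L, seq_len(m) - 1L)
  for (i in seq_len(m)) f[singles[i], ] <- d[rest[i], ]
  popcount <- vapply(seq_len(nS), function(s) sum(bitwAnd(s, singles) > 0), 0L)
  for (S in order(popcount)) {
    if (popcount[S] < 2L) next
    fm <- rep(Inf, n)
    pp <- rep(NA_integer_, n)
    sub <- bitwAnd(S - 1L, S)
    while (sub > 0L) {
      if (sub < S - sub) {               # each split once
        cand <- f[sub, ] + f[S - sub, ]
        upd <- cand < fm
        fm[upd] <- cand[upd]
        pp[upd] <- sub
      }
      sub <- bitwAnd(sub - 1L, S)
    }
    M <- d + fm                          # M[u, v] = fm[u] + d[u, v]
    f[S, ] <- apply(M, 2L, min)
    walk_ptr[S, ] <- apply(M, 2L, which.min)
    part_ptr[S, ] <- pp
  }
  # collect edges by backtracking
  edges <- list()
  add_path <- function(a, b) {
    if (a == b) return()
    p <- names(igraph::shortest_paths(g, from = a, to = b,
                                      output = "vpath")$vpath[[1L]])
    for (i in seq_len(length(p) - 1L))
      edges[[length(edges) + 1L]] <<- c(p[i], p[i + 1L])
  }
  expand <- function(S, v) {
    if (popcount[S] == 1L) {
      i <- which(singles == S)
      add_path(rest[i], vn[v])
      return()
    }
    u <- walk_ptr[S, v]
    add_path(vn[u], vn[v])
    T1 <- part_ptr[S, u]
    expand(T1, u)
    expand(S - T1, u)
  }
  expand(nS, match(t0, vn))
  nodes <- unique(c(terminals, unlist(edges)))
  tr <- .prune_tree(g, nodes, terminals)
  out <- .new_steiner_tree(tr, terminals)
  if (out$total_weight > f[nS, t0] + 1e-9)
    stop("internal error: reconstructed tree heavier than DP optimum")
  out
}

#' Summarize the composition of a Steiner tree
#'
#' @param tree a `steiner_tree`.
#' @param net_S optional sense [core_network()]; when given, the S-network
#'   edges among terminals that are absent from the tree are reported (the
#'   impacted "red links").
#' @return list with counts `n_terminals`, `n_steiner`,
#'   `n_steiner_sense`, `n_steiner_antisense` and, when `net_S` is given,
#'   a data frame `red_links`.
#' @export
tree_composition <- function(tree, net_S = NULL) {
  stopifnot(inherits(tree, "steiner_tree"))
  steiner_nodes <- setdiff(tree$nodes, tree$terminals)
  out <- list(
    n_terminals = length(tree$terminals),
    n_steiner = length(steiner_nodes),
    n_steiner_sense = sum(!is_antisense(steiner_nodes)),
    n_steiner_antisense = sum(is_antisense(steiner_nodes))
  )
  if (!is.null(net_S)) {
    sym <- if (net_S$directed) symmetrize(net_S, "union") else net_S
    terms <- intersect(tree$terminals, sym$ids)
    B <- sym$A[terms, terms, drop = FALSE]
    B[lower.tri(B, diag = TRUE)] <- FALSE
    idx <- which(B, arr.ind = TRUE)
    sl <- data.frame(from = terms[idx[, 1L]], to = terms[idx[, 2L]],
                     stringsAsFactors = FALSE)
    in_tree <- function(a, b) any((tree$edges$from == a & tree$edges$to == b) |
                                  (tree$edges$from == b & tree$edges$to == a))
    keep <- !mapply(in_tree, sl$from, sl$to)
    out$red_links <- sl[as.logical(keep), , drop = FALSE]
  }
  out
}

#' Export a Steiner tree as SIF plus a node attribute table
#'
#' @param tree a `steiner_tree`.
#' @param prefix file-path prefix; writes `<prefix>.sif` and
#'   `<prefix>_nodes.tsv` (columns `id`, `role`, `strand`).
#' @return the SIF path, invisibly.
#' @export
write_steiner_tree <- function(tree, prefix) {
  stopifnot(inherits(tree, "steiner_tree"))
  ed <- tree$edges
  ed$interaction <- "steiner"
  write_sif(ed[, c("from", "to", "interaction")], paste0(prefix, ".sif"))
  nodes <- data.frame(
    id = tree$nodes,
    role = ifelse(tree$nodes %in% tree$terminals, "terminal", "steiner"),
    strand = ifelse(is_antisense(tree$nodes), "antisense", "sense"),
    stringsAsFactors = FALSE
  )
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, ".sif"))
}
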