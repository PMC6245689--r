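#' Find anti-sense-impacted genes
#'
#' Compares the extended core network inferred from sense-only data
#' (`net_S`) with the one inferred from sense plus anti-sense data
#' (`net_SAS`). A sense gene is *AS-impacted* when it has at least one
#' neighbour in the sense network but its (non-empty) neighbourhood in the
#' sense+anti-sense network contains no sense transcript — i.e. its strong
#' sense interactions were displaced by anti-sense actors. Neighbourhoods
#' are out-neighbourhoods (rows of the asymmetric adjacency matrix).
#'
#' @param net_S [core_network()] over sense transcripts only.
#' @param net_SAS [core_network()] over sense plus anti-sense transcripts;
#'   must contain every id of `net_S`.
#' @return character vector of AS-impacted gene identifiers.
#' @export
find_as_impacted <- function(net_S, net_SAS) {
  stopifnot(inherits(net_S, "core_network"), inherits(net_SAS, "core_network"))
  if (any(is_antisense(net_S$ids)))
    stop("net_S must be built from sense transcripts only", call. = FALSE)
  if (!all(net_S$ids %in% net_SAS$ids))
    stop("net_SAS is missing ids present in net_S", call. = FALSE)
  anti_sas <- is_antisense(net_SAS$ids)
  impacted <- character(0)
  for (g in net_S$ids) {
    if (!any(net_S$A[g, ])) next               # isolated in S: nothing impacted
    nb <- net_SAS$A[g, ]
    if (any(nb) && all(anti_sas[nb])) impacted <- c(impacted, g)
  }
  impacted
}

#' Build the change motif around an AS-impacted gene
#'
#' The change motif is the sub-graph formed by the AS-impacted gene together
#' with all its direct (out-)neighbours in both the S and the SAS networks;
#' edges are labelled by provenance (`"s_only"`, `"sas_only"`, `"both"`).
#' With `enlarge = TRUE` the motif also gathers the direct SAS-neighbours of
#' its anti-sense actors (edges labelled `"sas_only"`).
#'
#' @param g an AS-impacted sense gene id (see [find_as_impacted()]).
#' @param net_S,net_SAS the two [core_network()]s.
#' @param enlarge also collect the SAS-neighbourhoods of the motif's
#'   anti-sense actors.
#' @return object of class `change_motif`: list with `center`,
#'   `s_neighbors`, `sas_neighbors`, `enlarged`, `edges` (data frame
#'   `from`, `to`, `provenance`) and `members`.
#' @export
build_change_motif <- function(g, net_S, net_SAS, enlarge = FALSE) {
  if (!(g %in% find_as_impacted(net_S, net_SAS)))
    stop("gene ", g, " is not AS-impacted", call. = FALSE)
  s_nb <- net_S$ids[net_S$A[g, ]]
  sas_nb <- net_SAS$ids[net_SAS$A[g, ]]
  as_actors <- sas_nb[is_antisense(sas_nb)]
  edges <- data.frame(from = character(0), to = character(0),
                      provenance = character(0), stringsAsFactors = FALSE)
  for (u in union(s_nb, sas_nb)) {
    prov <- if (u %in% s_nb && u %in% sas_nb) "both"
            else if (u %in% s_nb) "s_only" else "sas_only"
    edges <- rbind(edges, data.frame(from = g, to = u, provenance = prov,
                                     stringsAsFactors = FALSE))
  }
  enlarged <- character(0)
  if (enlarge && length(as_actors)) {
    for (a in as_actors) {
      nb <- net_SAS$ids[net_SAS$A[a, ]]
      nb <- setdiff(nb, c(g, a))
      if (length(nb))
        edges <- rbind(edges, data.frame(from = a, to = nb,
                                         provenance = "sas_only",
                                         stringsAsFactors = FALSE))
      enlarged <- union(enlarged, nb)
    }
    enlarged <- setdiff(enlarged, c(g, as_actors))
  }
  members <- unique(c(g, s_nb, sas_nb, enlarged))
  structure(list(center = g, s_neighbors = s_nb, sas_neighbors = sas_nb,
                 enlarged = enlarged, edges = unique(edges),
                 members = members),
            class = "change_motif")
}

#' @export
print.change_motif <- function(x, ...) {
  cat("change_motif centred on", x$center, "-", length(x$members), "members (",
      length(x$s_neighbors), "S-neighbours,", length(x$sas_neighbors),
      "SAS-neighbours,", length(x$enlarged), "enlarged )\n")
  invisible(x)
}

#' Connected AS-impacted sub-graphs
#'
#' Induces the union-symmetrized sense network on the AS-impacted genes and
#' returns its connected components with at least `min_size` members.
#'
#' @param net_S sense [core_network()].
#' @param impacted character vector of AS-impacted genes (subset of
#'   `net_S$ids`).
#' @param min_size minimal component size kept (default 3).
#' @return list of `as_impacted_subgraph` objects, each a list with
#'   `members` and `s_edges` (data frame `from`, `to`).
#' @export
as_impacted_subgraphs <- function(net_S, impacted, min_size = 3L) {
  stopifnot(inherits(net_S, "core_network"), min_size >= 1L)
  impacted <- intersect(net_S$ids, impacted)
  if (!length(impacted)) return(list())
  sym <- symmetrize(net_S, "union")
  B <- sym$A[impacted, impacted, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(B * 1, mode = "undirected")
  comp <- igraph::components(g)
  out <- list()
  for (k in seq_len(comp$no)) {
    members <- impacted[comp$membership == k]
    if (length(members) < min_size) next
    Bk <- B[members, members, drop = FALSE]
    Bk[lower.tri(Bk, diag = TRUE)] <- FALSE
    idx <- which(Bk, arr.ind = TRUE)
    out[[length(out) + 1L]] <- structure(
      list(members = members,
           s_edges = data.frame(from = members[idx[, 1L]],
                                to = members[idx[, 2L]],
                                stringsAsFactors = FALSE)),
      class = "as_impacted_subgraph")
  }
  out
}

#' Export a change motif as SIF plus node/edge attribute tables
#'
#' @param motif [build_change_motif()] result.
#' @param prefix file-path prefix; writes `<prefix>.sif`,
#'   `<prefix>_nodes.tsv`.
#' @return the SIF path, invisibly.
#' @export
write_motif <- function(motif, prefix) {
  stopifnot(inherits(motif, "change_motif"))
  ed <- motif$edges
  names(ed) <- c("from", "to", "interaction")
  write_sif(ed, paste0(prefix, ".sif"))
  nodes <- data.frame(
    id = motif$members,
    strand = ifelse(is_antisense(motif$members), "antisense", "sense"),
    role = ifelse(motif$members == motif$center, "center",
                  ifelse(motif$members %in% motif$enlarged, "enlarged", "neighbor")),
    stringsAsFactors = FALSE
  )
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, ".sif"))
}
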