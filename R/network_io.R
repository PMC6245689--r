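#' Write / read networks in SIF format
#'
#' SIF lines are `source<TAB>interaction<TAB>target`; isolated nodes are
#' written as a bare node name on its own line, which Cytoscape accepts.
#'
#' @param net [core_network()] or a data frame with columns `from`, `to`
#'   and optionally `interaction`.
#' @param path file path.
#' @param interaction interaction-type string used when `net` carries none.
#' @param keep_isolated write isolated nodes as single-field lines.
#' @return `write_sif()` returns `path` invisibly; `read_sif()` a data frame
#'   with columns `source`, `interaction`, `target` (`NA` interaction and
#'   target for isolated nodes).
#' @export
write_sif <- function(net, path, interaction = "mi", keep_isolated = TRUE) {
  if (inherits(net, "core_network")) {
    ed <- network_edges(net)
    ed$interaction <- interaction
    nodes <- net$ids
  } else {
    ed <- as.data.frame(net)
    if (is.null(ed$interaction)) ed$interaction <- interaction
    nodes <- unique(c(ed$from, ed$to))
  }
  lines <- if (nrow(ed)) paste(ed$from, ed$interaction, ed$to, sep = "\t") else character(0)
  if (keep_isolated) {
    used <- unique(c(ed$from, ed$to))
    lines <- c(lines, setdiff(nodes, used))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(
    source = vapply(parts, `[`, "", 1L),
    interaction = vapply(parts, function(p) if (length(p) >= 3L) p[2L] else NA_character_, ""),
    target = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  out
}

#' Rebuild a core network from a SIF edge table
#'
#' @param sif data frame as returned by [read_sif()].
#' @param directed interpret edges as arcs.
#' @param rate accepting rate to record.
#' @return [core_network()].
#' @export
sif_to_network <- function(sif, directed = TRUE, rate = NA_real_) {
  iso <- is.na(sif$target)
  ids <- unique(c(sif$source, sif$target[!iso]))
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  ed <- sif[!iso, , drop = FALSE]
  if (nrow(ed)) {
    A[cbind(ed$source, ed$target)] <- TRUE
    if (!directed) A[cbind(ed$target, ed$source)] <- TRUE
  }
  core_network(ids, A, rate = rate, directed = directed)
}

#' Write a network as GraphML
#'
#' @param net [core_network()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
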