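#' Annotation map
#'
#' Container tying transcripts to Gene Ontology terms, the term DAG
#' (parent edges), and an optional GO-slim mapping (for apple, a reduced
#' 14-category biological-process vocabulary).
#'
#' @param gene2terms named list: transcript id -> character vector of term
#'   ids.
#' @param parents named list: term id -> character vector of parent term
#'   ids (acyclic).
#' @param slim named character vector: term id -> slim category.
#' @param unknown_term term assigned to transcripts with no annotation when
#'   [annotate_antisense()] fills in missing entries.
#' @return object of class `annotation_map`.
#' @export
annotation_map <- function(gene2terms, parents = list(), slim = character(0),
                           unknown_term = "unknown biological processes") {
  stopifnot(is.list(gene2terms))
  if (length(gene2terms) && is.null(names(gene2terms)))
    stop("gene2terms must be named by transcript id", call. = FALSE)
  structure(list(gene2terms = gene2terms, parents = parents, slim = slim,
                 unknown_term = unknown_term),
            class = "annotation_map")
}

#' Copy sense annotations onto anti-sense transcripts
#'
#' Anti-sense transcripts are not annotated per se; due to sequence
#' complementarity each one receives the annotation of its sense gene.
#' Transcripts (sense or anti-sense) whose gene has no annotation are
#' mapped to the unknown-process term.
#'
#' @param ann [annotation_map()].
#' @param ids transcript ids to cover (sense and/or anti-sense).
#' @return the extended `annotation_map`.
#' @export
annotate_antisense <- function(ann, ids) {
  stopifnot(inherits(ann, "annotation_map"))
  for (id in ids) {
    if (!is.null(ann$gene2terms[[id]])) next
    terms <- ann$gene2terms[[base_id(id)]]
    ann$gene2terms[[id]] <- if (is.null(terms)) ann$unknown_term else terms
  }
  ann
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Every transcript annotated to a term becomes annotated to all of the
#' term's ancestors. Idempotent; errors on a cyclic parent relation.
#'
#' @param ann [annotation_map()].
#' @return propagated `annotation_map`.
#' @export
propagate <- function(ann) {
  stopifnot(inherits(ann, "annotation_map"))
  anc <- term_ancestors(ann$parents)
  ann$gene2terms <- lapply(ann$gene2terms, function(terms)
    unique(c(terms, unlist(anc[terms], use.names = FALSE))))
  ann
}

#' Ancestor sets of every term in a parent map
#'
#' @param parents named list term -> parents.
#' @return named list term -> all (proper) ancestors.
#' @export
term_ancestors <- function(parents) {
  memo <- list()
  state <- new.env(parent = emptyenv())   # visiting marks for cycle detection
  visit <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (isTRUE(state[[t]])) stop("cycle detected in ontology at term ", t,
                                 call. = FALSE)
    assign(t, TRUE, envir = state)
    ps <- parents[[t]]
    res <- if (is.null(ps)) character(0)
           else unique(c(ps, unlist(lapply(ps, visit), use.names = FALSE)))
    assign(t, FALSE, envir = state)
    memo[[t]] <<- res
    res
  }
  for (t in names(parents)) visit(t)
  memo
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` carry the term, the probability of seeing
#' at least `k` carriers. Computed as an explicit sum of exact binomial
#' coefficient ratios.
#'
#' @param k observed carriers in the sample (0 <= k <= min(K, n)).
#' @param K carriers in the universe.
#' @param n sample size.
#' @param N universe size.
#' @return probability in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > n || n > N || K > N || k > K)
    stop("inconsistent hypergeometric counts", call. = FALSE)
  hi <- min(K, n)
  lo <- max(k, n - (N - K))
  if (lo > hi) return(1)  # k below the support: certain event
  x <- lo:hi
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

#' Term over-representation test
#'
#' One upper-tail hypergeometric test per term observed in the gene set
#' (`k >= 1`), against a gene universe, with multiple-testing correction
#' across the tested terms. With `vocabulary = "slim"` terms are first
#' mapped to their GO-slim categories.
#'
#' @param genes character vector of transcripts to test (subset of
#'   `universe`).
#' @param ann [annotation_map()] (propagate first with [propagate()] for
#'   DAG-consistent counting).
#' @param universe character vector of background transcripts.
#' @param vocabulary `"go"` (term ids) or `"slim"` (slim categories).
#' @param correction `"bonferroni"`, `"bh"` or `"none"`.
#' @param alpha significance threshold applied to the corrected p-value.
#' @return data frame sorted by corrected p-value with columns `term`, `k`,
#'   `K`, `n`, `N`, `p_value`, `p_corrected`, `significant`, `members`
#'   (comma-separated gene list).
#' @export
enrich <- function(genes, ann, universe,
                   vocabulary = c("go", "slim"),
                   correction = c("bonferroni", "bh", "none"),
                   alpha = 0.05) {
  stopifnot(inherits(ann, "annotation_map"))
  vocabulary <- match.arg(vocabulary)
  correction <- match.arg(correction)
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  if (!all(genes %in% universe))
    stop("genes must be a subset of the universe", call. = FALSE)
  empty <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      p_corrected = numeric(0), significant = logical(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (!length(genes)) return(empty)
  terms_of <- function(id) {
    tt <- ann$gene2terms[[id]]
    if (is.null(tt)) return(character(0))
    if (vocabulary == "slim") {
      sl <- ann$slim[tt]
      unique(sl[!is.na(sl)])
    } else unique(tt)
  }
  uni_terms <- lapply(stats::setNames(universe, universe), terms_of)
  counts_K <- table(unlist(uni_terms, use.names = FALSE))
  sample_terms <- uni_terms[genes]
  counts_k <- table(unlist(sample_terms, use.names = FALSE))
  if (!length(counts_k)) return(empty)
  terms <- names(counts_k)
  n <- length(genes)
  N <- length(universe)
  p <- vapply(terms, function(tm)
    hypergeom_p(as.integer(counts_k[[tm]]), as.integer(counts_K[[tm]]), n, N),
    0)
  p_corr <- switch(correction,
                   bonferroni = pmin(1, length(p) * p),
                   bh = stats::p.adjust(p, method = "BH"),
                   none = p)
  members <- vapply(terms, function(tm)
    paste(genes[vapply(sample_terms, function(tt) tm %in% tt, TRUE)],
          collapse = ","), "")
  out <- data.frame(term = terms,
                    k = as.integer(counts_k[terms]),
                    K = as.integer(counts_K[terms]),
                    n = n, N = N,
                    p_value = unname(p), p_corrected = unname(p_corr),
                    significant = unname(p_corr < alpha),
                    members = unname(members),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_corrected, out$p_value, out$term), , drop = FALSE]
}

#' Terms revealed by anti-sense data
#'
#' Differential functional analysis: terms significantly over-represented
#' in the sense+anti-sense gene set (`set_SAS`) but not in the sense-only
#' set (`set_S`). The default correction is `"none"` (raw p < alpha), the
#' threshold used for the differential comparison; pass `"bonferroni"` or
#' `"bh"` to match other reporting conventions.
#'
#' @param set_S,set_SAS gene sets (typically `set_SAS = set_S` plus the
#'   anti-sense transcripts).
#' @inheritParams enrich
#' @return the [enrich()] rows of `set_SAS` restricted to revealed terms.
#' @export
revealed_by_as <- function(set_S, set_SAS, ann, universe,
                           vocabulary = "go", correction = "none",
                           alpha = 0.05) {
  e_s <- enrich(set_S, ann, universe, vocabulary, correction, alpha)
  e_sas <- enrich(set_SAS, ann, universe, vocabulary, correction, alpha)
  sig_s <- e_s$term[e_s$significant]
  sig_sas <- e_sas$term[e_sas$significant]
  revealed <- setdiff(sig_sas, sig_s)
  e_sas[e_sas$term %in% revealed, , drop = FALSE]
}

#' Read a tab-delimited gene annotation table
#'
#' Expected columns: transcript id, GO term, optionally GO-slim category
#' (header required: `gene`, `term`, optionally `slim`).
#'
#' @param path file path.
#' @return [annotation_map()] (parents empty; combine with [read_obo()]).
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "term") %in% names(df)))
  g2t <- split(df$term, df$gene)
  slim <- character(0)
  if ("slim" %in% names(df)) {
    keep <- !duplicated(df$term)
    slim <- stats::setNames(df$slim[keep], df$term[keep])
  }
  annotation_map(lapply(g2t, unique), slim = slim)
}

#' Write an enrichment table
#'
#' Column layout: term id, p, corrected p, k, K, n, N, members.
#'
#' @param res data frame from [enrich()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(res, path) {
  cols <- c("term", "p_value", "p_corrected", "k", "K", "n", "N", "members")
  utils::write.table(res[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
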