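#' Generate a connected regulatory network by neighbour addition
#'
#' Starts from a single seed gene and repeatedly attaches a new gene to a
#' randomly chosen existing gene, as its regulator or its target with equal
#' probability; with probability `extra_p` the new gene additionally links
#' to a second existing gene, emulating the multi-regulator/multi-target
#' structure of real transcriptional networks (source-network sub-graphs
#' are denser than trees, roughly 1.5 edges per gene). Edge signs
#' (activation/repression) are random and strengths are Uniform(0.5, 1).
#' The construction yields a weakly connected directed network of `n` genes
#' with at least `n - 1` edges and a right-skewed degree distribution.
#'
#' @param n number of genes (>= 2).
#' @param seed optional integer seed.
#' @param extra_p probability that a new gene receives a second link
#'   (default 0.5).
#' @return object of class `true_network`: list with `genes` and `edges`
#'   (data frame `from`, `to`, `sign` in `{1, -1}`, `strength`).
#' @export
generate_network <- function(n, seed = NULL, extra_p = 0.5) {
  if (n < 2L) stop("need at least 2 genes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  genes <- paste0("g", seq_len(n))
  from <- to <- character(0)
  for (i in 2:n) {
    anchor <- genes[sample.int(i - 1L, 1L)]
    partners <- anchor
    if (i > 2L && stats::runif(1) < extra_p)
      partners <- c(partners, sample(setdiff(genes[1:(i - 1L)], anchor), 1L))
    for (a in partners) {
      if (stats::runif(1) < 0.5) {      # new gene regulates the partner
        from <- c(from, genes[i]); to <- c(to, a)
      } else {                          # new gene is a target of the partner
        from <- c(from, a); to <- c(to, genes[i])
      }
    }
  }
  m <- length(from)
  edges <- data.frame(
    from = from, to = to,
    sign = sample(c(1, -1), m, replace = TRUE),
    strength = stats::runif(m, 0.5, 1),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, edges = edges), class = "true_network")
}

# saturating Hill response, K = 0.5, h = 2
.hill_up <- function(u) u^2 / (u^2 + 0.25)
.hill_down <- function(u) 0.25 / (u^2 + 0.25)

#' Simulate steady-state-like expression from a regulatory network
#'
#' Per sample, root genes (no regulators) draw activities Uniform(0, 1);
#' each regulated gene's activity is a strength-weighted mean of saturating
#' Hill responses to its regulators (activators raise it, repressors lower
#' it), plus Gaussian noise. Genes are evaluated in topological order;
#' should the network contain cycles, a damped fixed-point iteration (at
#' most 50 sweeps) is used instead, with a warning on non-convergence.
#'
#' @param net [generate_network()] result (or any `true_network`).
#' @param p number of samples (>= 2).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (default 0.1).
#' @param seed optional integer seed.
#' @return expression matrix, genes x samples.
#' @export
simulate_expression <- function(net, p, noise_sd = 0.1, seed = NULL) {
  stopifnot(inherits(net, "true_network"))
  if (p < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  genes <- net$genes
  n <- length(genes)
  regs <- split(seq_len(nrow(net$edges)), net$edges$to)
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     vertices = genes)
  topo <- tryCatch(names(igraph::topo_sort(g)), error = function(e) NULL)
  X <- matrix(stats::runif(n * p), n, p,
              dimnames = list(genes, paste0("s", seq_len(p))))
  noise <- matrix(stats::rnorm(n * p, 0, noise_sd), n, p,
                  dimnames = list(genes, NULL))   # drawn once: fixed point stays fixed
  eval_gene <- function(gene, Xcur) {
    idx <- regs[[gene]]
    e <- net$edges[idx, , drop = FALSE]
    resp <- matrix(0, length(idx), p)
    for (k in seq_along(idx)) {
      u <- Xcur[e$from[k], ]
      resp[k, ] <- if (e$sign[k] > 0) .hill_up(u) else .hill_down(u)
    }
    w <- e$strength / sum(e$strength)
    colSums(resp * w) + noise[gene, ]
  }
  targets <- names(regs)
  if (!is.null(topo)) {
    for (gene in topo) if (gene %in% targets) X[gene, ] <- eval_gene(gene, X)
  } else {
    converged <- FALSE
    for (sweep in seq_len(50L)) {
      Xold <- X
      for (gene in targets)
        X[gene, ] <- 0.5 * X[gene, ] + 0.5 * eval_gene(gene, X)
      # tolerance well below the noise floor; residuals that small are
      # immaterial for rank-based MI estimation
      if (max(abs(X - Xold)) < 1e-4) { converged <- TRUE; break }
    }
    if (!converged)
      warning("cyclic network did not converge in 50 sweeps; returning last iterate",
              call. = FALSE)
  }
  X
}

#' Inject anti-sense transcripts coupled to chosen sense genes
#'
#' Appends, per target gene `g`, an anti-sense row
#' `coupling * (-profile of g) + (1 - coupling) * noise`, where the noise is
#' Gaussian with the target profile's standard deviation. `coupling = 1`
#' gives an exact (negated) copy; `coupling = 0` pure noise.
#'
#' @param mat expression matrix (sense genes).
#' @param targets sense gene ids receiving an anti-sense partner.
#' @param coupling coupling strength in \[0, 1\].
#' @param seed optional integer seed.
#' @return expression matrix with the anti-sense rows appended.
#' @export
inject_antisense <- function(mat, targets, coupling, seed = NULL) {
  mat <- as_expression_matrix(mat)
  if (!(coupling >= 0 && coupling <= 1))
    stop("coupling must be in [0, 1]", call. = FALSE)
  targets <- as.character(targets)
  if (any(is_antisense(targets)) || !all(targets %in% rownames(mat)))
    stop("targets must be sense genes present in the matrix", call. = FALSE)
  as_ids <- antisense_id(targets)
  if (any(as_ids %in% rownames(mat)) || anyDuplicated(as_ids))
    stop("duplicate anti-sense transcript for a target", call. = FALSE)
  if (!length(targets)) return(mat)
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(mat)
  rows <- t(vapply(targets, function(g) {
    x <- mat[g, ]
    noise <- stats::rnorm(p, 0, stats::sd(x))
    coupling * (-x) + (1 - coupling) * noise
  }, numeric(p)))
  rownames(rows) <- as_ids
  rbind(mat, rows)
}

#' Precision, recall and F1 of an inferred network
#'
#' Edges are compared undirected: `TP` are inferred edges present in the
#' true network, `FP` inferred-only, `FN` true-only;
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)` (0 when both are 0).
#'
#' @param true_net a `true_network` (or a two-column data frame of edges).
#' @param inferred a [core_network()] (symmetrized internally).
#' @return one-row data frame: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
f1_score <- function(true_net, inferred) {
  ed <- if (inherits(true_net, "true_network")) true_net$edges else as.data.frame(true_net)
  if (!nrow(ed)) stop("true network has no edges", call. = FALSE)
  canon <- function(a, b) paste(pmin(a, b), pmax(a, b))
  true_e <- unique(canon(ed$from, ed$to))
  ie <- network_edges(if (inferred$directed) symmetrize(inferred, "union") else inferred)
  inf_e <- unique(if (nrow(ie)) canon(ie$from, ie$to) else character(0))
  tp <- length(intersect(inf_e, true_e))
  fp <- length(setdiff(inf_e, true_e))
  fn <- length(setdiff(true_e, inf_e))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
             recall = recall, f1 = f1)
}

#' Benchmark study: F1 of the extended core network versus the baseline
#'
#' Generates one ground-truth network of `n` genes and one expression
#' dataset `X` of `p` samples; each of the `S` simulations subsamples
#' `j ~ Uniform{p/2..p}` columns of `X`, estimates the significance-masked
#' MI matrix on copula-transformed data, and scores the single-best-edge
#' baseline (`c3net`) and the extended core network at every accepting rate
#' against the truth. Deterministic given `seed`.
#'
#' @param n number of genes.
#' @param p number of samples in the master dataset.
#' @param S number of simulations.
#' @param rates accepting rates to evaluate.
#' @param seed optional integer seed.
#' @param noise_sd simulator noise (default 0.1).
#' @param n_perm,mi_alpha significance-mask settings.
#' @return tidy data frame: `sim`, `method`, `rate`, `j`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
run_study <- function(n = 200L, p = 100L, S = 500L,
                      rates = c(0, 0.01, 0.05, 0.07, 0.1, 0.2, 0.5, 1),
                      seed = NULL, noise_sd = 0.1,
                      n_perm = 30L, mi_alpha = 0.05) {
  stopifnot(S >= 1L, all(rates >= 0 & rates <= 1))
  if (!is.null(seed)) set.seed(seed)
  net <- generate_network(n)
  X <- simulate_expression(net, p, noise_sd = noise_sd)
  res <- vector("list", S)
  for (k in seq_len(S)) {
    j <- sample(seq.int(floor(p / 2), p), 1L)
    Xk <- X[, sample.int(p, j), drop = FALSE]
    mi <- mi_matrix(copula_transform(Xk))
    mi <- significance_mask(mi, copula_transform(Xk), n_perm = n_perm,
                            alpha = mi_alpha)
    rows <- list()
    sc <- f1_score(net, c3net_infer(mi))
    rows[[1L]] <- cbind(sim = k, method = "c3net", rate = NA_real_, j = j, sc)
    for (r in rates) {
      sc <- f1_score(net, symmetrize(ecn_infer(mi, r), "union"))
      rows[[length(rows) + 1L]] <-
        cbind(sim = k, method = paste0("ecn_", r), rate = r, j = j, sc)
    }
    res[[k]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
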