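#' Pipeline configuration
#'
#' Bundles every tunable of the differential network workflow with its
#' default: accepting rate 0.05, differential-expression threshold
#' p < 0.01 with |log2 FC| >= 1, 30 MI permutations at alpha 0.05, minimal
#' AS-impacted sub-graph size 3.
#'
#' @param accepting_rate ECN accepting rate in \[0, 1\].
#' @param alpha_de differential-expression p-value threshold.
#' @param min_lfc minimal absolute log2 fold change.
#' @param mi_perm number of MI permutations.
#' @param mi_alpha MI significance level.
#' @param min_subgraph minimal AS-impacted sub-graph size.
#' @param correction multiple-testing correction for enrichment.
#' @param enlarge build enlarged change motifs.
#' @param seed integer seed driving every stochastic stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(accepting_rate = 0.05, alpha_de = 0.01, min_lfc = 1,
                       mi_perm = 30L, mi_alpha = 0.05, min_subgraph = 3L,
                       correction = c("none", "bonferroni", "bh"),
                       enlarge = TRUE, seed = 1L) {
  correction <- match.arg(correction)
  stopifnot(accepting_rate >= 0, accepting_rate <= 1,
            alpha_de > 0, alpha_de < 1, min_lfc >= 0,
            mi_perm >= 1, mi_alpha > 0, mi_alpha < 1, min_subgraph >= 1)
  structure(list(accepting_rate = accepting_rate, alpha_de = alpha_de,
                 min_lfc = min_lfc, mi_perm = as.integer(mi_perm),
                 mi_alpha = mi_alpha, min_subgraph = as.integer(min_subgraph),
                 correction = correction, enlarge = enlarge,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read the reproducibility manifest
#'
#' The manifest is the JSON-serialized configuration; together with the
#' input files and the seed it suffices to re-run the workflow
#' bit-for-bit.
#'
#' @param config [run_config()].
#' @param path file path.
#' @return `read_manifest()` returns the `run_config`.
#' @export
write_manifest <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run the full differential network analysis
#'
#' Workflow: quantile-normalize each condition, select differentially
#' expressed transcripts (paired t-test), infer the sense-only (S) and
#' sense+anti-sense (SAS) extended core networks from the second-condition
#' data of the selected transcripts, detect AS-impacted genes, build change
#' motifs and AS-impacted sub-graphs, connect each sub-graph with a Steiner
#' tree in the SAS network, and (when annotations are supplied) compute the
#' revealed-by-AS enrichment.
#'
#' @param config [run_config()].
#' @param expr_a,expr_b expression matrices of the two conditions
#'   (transcripts x paired samples); networks are inferred from `expr_b`
#'   (the "after" condition).
#' @param annotations optional [annotation_map()].
#' @param universe background gene set for enrichment (default: all
#'   transcripts in the matrices).
#' @param outdir optional directory; when given, networks (SIF), motif
#'   files, Steiner trees, enrichment tables and the manifest are written
#'   there.
#' @return list with elements `de`, `net_S`, `net_SAS`, `impacted`,
#'   `motifs`, `subgraphs`, `steiner_trees`, `revealed`, `counts` (named
#'   integer vector of per-stage counts) and `config`.
#' @export
run_pipeline <- function(config, expr_a, expr_b, annotations = NULL,
                         universe = NULL, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  norm_a <- quantile_normalize(expr_a)
  norm_b <- quantile_normalize(expr_b)
  de <- differential_expression(norm_a, norm_b,
                                alpha = config$alpha_de,
                                min_lfc = config$min_lfc)
  de_hits <- de[de$de, , drop = FALSE]
  sense_ids <- de_hits$transcript[de_hits$strand == "sense"]
  as_ids <- de_hits$transcript[de_hits$strand == "antisense"]
  if (length(sense_ids) < 2L)
    stop("pipeline stage 'de': fewer than 2 DE sense transcripts [ECN_DE_EMPTY]",
         call. = FALSE)

  infer_net <- function(ids) {
    dat <- copula_transform(norm_b[ids, , drop = FALSE])
    mi <- mi_matrix(dat)
    mi <- significance_mask(mi, dat, n_perm = config$mi_perm,
                            alpha = config$mi_alpha, seed = config$seed)
    ecn_infer(mi, config$accepting_rate)
  }
  net_S <- infer_net(sense_ids)
  net_SAS <- infer_net(c(sense_ids, as_ids))

  impacted <- find_as_impacted(net_S, net_SAS)
  motifs <- lapply(impacted, build_change_motif, net_S = net_S,
                   net_SAS = net_SAS, enlarge = config$enlarge)
  names(motifs) <- impacted
  subgraphs <- as_impacted_subgraphs(net_S, impacted,
                                     min_size = config$min_subgraph)
  sas_sym <- symmetrize(net_SAS, "union")
  trees <- lapply(subgraphs, function(sg)
    tryCatch(steiner_sp_approx(sas_sym, sg$members, seed = config$seed),
             warning = function(w) NULL))
  trees <- Filter(function(x) inherits(x, "steiner_tree"), trees)

  revealed <- NULL
  if (!is.null(annotations)) {
    if (is.null(universe)) universe <- rownames(norm_b)
    ann <- annotate_antisense(annotations, unique(c(universe, sense_ids, as_ids)))
    universe <- unique(c(universe, sense_ids, as_ids))
    revealed <- revealed_by_as(sense_ids, c(sense_ids, as_ids), ann, universe,
                               correction = config$correction)
  }

  counts <- c(de_sense = length(sense_ids),
              de_antisense = length(as_ids),
              couples = count_couples(de_hits),
              de_total = nrow(de_hits),
              as_impacted = length(impacted),
              change_motifs = length(motifs),
              subgraphs = length(subgraphs),
              steiner_trees = length(trees))
  message("pipeline counts: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_sif(net_S, file.path(outdir, "net_S.sif"), interaction = "s")
    write_sif(net_SAS, file.path(outdir, "net_SAS.sif"), interaction = "sas")
    writeLines(impacted, file.path(outdir, "as_impacted.txt"))
    if (length(motifs)) {
      summary <- data.frame(
        center = impacted,
        n_s_neighbors = vapply(motifs, function(m) length(m$s_neighbors), 0L),
        n_sas_neighbors = vapply(motifs, function(m) length(m$sas_neighbors), 0L),
        n_enlarged = vapply(motifs, function(m) length(m$enlarged), 0L),
        stringsAsFactors = FALSE)
      utils::write.table(summary, file.path(outdir, "motifs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      for (m in motifs)
        write_motif(m, file.path(outdir, paste0("motif_", m$center)))
    }
    for (i in seq_along(trees))
      write_steiner_tree(trees[[i]], file.path(outdir, paste0("steiner_", i)))
    if (!is.null(revealed))
      write_enrichment_tsv(revealed, file.path(outdir, "revealed_by_as.tsv"))
    write_manifest(config, file.path(outdir, "manifest.json"))
  }

  list(de = de, net_S = net_S, net_SAS = net_SAS, impacted = impacted,
       motifs = motifs, subgraphs = subgraphs, steiner_trees = trees,
       revealed = revealed, counts = counts, config = config)
}
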