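#' Run the full splicing-module pipeline on one cohort
#'
#' Executes the six stages end-to-end: (1) event and sample
#' missingness filtering plus kNN imputation, (2) differential
#' splicing selection, (3) correlation-network reconstruction, (4)
#' random-walk module identification with modularity-optimal cut, (5)
#' per-sample module scoring, (6) survival association and retention,
#' plus optional gene-set enrichment. Identical inputs and parameters
#' give identical outputs.
#'
#' @param psi A `psi_matrix` (raw; may contain missing values).
#' @param clinical Optional clinical table for stage 6.
#' @param gene_sets Optional GMT-style gene-set list for enrichment.
#' @param normal_missing_max,tumor_missing_max,sample_missing_max
#'   Missingness thresholds (defaults 0.10, 0.01, 0.001).
#' @param knn_k Imputation neighbors (default 10).
#' @param fdr_max,delta_min Differential thresholds (defaults 0.1, 0.1).
#' @param weight_transform Edge-weight transform (default `"abs"`).
#' @param walk_steps Random-walk length (default 4).
#' @param min_module_size Smallest reported module (default 1).
#' @param aggregate Score aggregation (default `"average"`).
#' @param alpha,near_alpha Retention thresholds (defaults 0.05, 0.1).
#' @param output_dir Optional directory for TSV artifacts.
#' @return A `pipeline_run` list: `psi` (processed), `diff_table`,
#'   `graph`, `tree`, `modules`, `scores`, `survival`, `retained`,
#'   `enrichment`, and `manifest` (tibble of per-stage counts). When
#'   no event passes the differential stage the run stops gracefully
#'   after stage 2 with the stages so far.
#' @export
run_pipeline <- function(psi, clinical = NULL, gene_sets = NULL,
                         normal_missing_max = 0.10, tumor_missing_max = 0.01,
                         sample_missing_max = 0.001, knn_k = 10,
                         fdr_max = 0.1, delta_min = 0.1,
                         weight_transform = "abs", walk_steps = 4,
                         min_module_size = 1, aggregate = "average",
                         alpha = 0.05, near_alpha = 0.1,
                         output_dir = NULL) {
  manifest <- list()
  note <- function(stage, n) {
    manifest[[length(manifest) + 1]] <<- tibble(stage = stage, n = as.integer(n))
  }

  m <- filter_events(psi, normal_missing_max, tumor_missing_max)
  m <- filter_samples(m, sample_missing_max)
  m <- impute_knn(m, k = knn_k)
  note("filter_impute", nrow(m$values))

  diff_table <- select_differential(m, fdr_max = fdr_max, delta_min = delta_min)
  de <- differential_events(diff_table)
  note("differential", length(de))
  res <- list(psi = m, diff_table = diff_table)
  if (length(de) < 2) {
    warn("fewer than 2 differential events; stopping after the differential stage")
    res$manifest <- dplyr::bind_rows(manifest)
    class(res) <- "pipeline_run"
    return(res)
  }

  corr <- pearson_matrix(m, de)
  graph <- build_graph(corr, weight_transform = weight_transform)
  note("network_edges", nrow(graph_edges(graph)))

  tree <- walktrap_dendrogram(graph, t = walk_steps)
  modules <- cut_by_modularity(tree, graph, events = m$events,
                               min_module_size = min_module_size)
  note("modules", nrow(modules$census))

  scores <- score_modules(m, modules, aggregate = aggregate)
  note("scored_samples", ncol(scores$scores))
  res <- c(res, list(graph = graph, tree = tree, modules = modules,
                     scores = scores))

  if (!is.null(clinical)) {
    assoc <- module_survival(scores, clinical)
    retained <- retain_prognostic(assoc, alpha = alpha, near_alpha = near_alpha)
    note("survival_tests", nrow(assoc))
    res$survival <- assoc
    res$retained <- retained
  }
  if (!is.null(gene_sets)) {
    background <- unique(toupper(m$events$gene_symbol))
    res$enrichment <- purrr::map(
      setNames(modules$census$module, modules$census$module),
      function(mod) {
        genes <- unique(toupper(
          m$events$gene_symbol[match(module_events(modules, mod),
                                     m$events$event_id)]))
        fisher_enrich(genes, gene_sets, background)
      })
    note("enrichment_tables", length(res$enrichment))
  }
  res$manifest <- dplyr::bind_rows(manifest)
  class(res) <- "pipeline_run"

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(as.data.frame(res$diff_table),
                file.path(output_dir, "differential_events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$graph)) {
      write_edge_list(res$graph, file.path(output_dir, "network_edges.tsv"))
    }
    if (!is.null(res$modules)) {
      write.table(as.data.frame(res$modules$membership),
                  file.path(output_dir, "module_membership.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(as.data.frame(res$modules$census),
                  file.path(output_dir, "module_census.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_dendrogram_newick(res$tree,
                              file.path(output_dir, "dendrogram.newick"))
    }
    if (!is.null(res$scores)) {
      sc <- data.frame(module = rownames(res$scores$scores),
                       res$scores$scores, check.names = FALSE)
      write.table(sc, file.path(output_dir, "module_scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$survival)) {
      write.table(as.data.frame(res$survival),
                  file.path(output_dir, "survival_association.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(as.data.frame(res$manifest),
                file.path(output_dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$manifest)
  invisible(x)
}
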