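#' Partition a TF's regulated targets into direct and indirect
#'
#' Direct targets are both regulated and bound by the TF
#' (`regulated AND bound`); indirect targets are regulated but not bound
#' (`regulated AND NOT bound`). The two query fragments are composed and
#' evaluated through the query engine, so any bracket filters (e.g.
#' `[EXPERIMENT_TYPE=Expression]`, `[TECHNOLOGY/METHOD=ChIPseq]`) are
#' honoured. It is an error if the TF has no expression experiment.
#'
#' @param tf1 the TF gene id.
#' @param store an `edge_store`.
#' @param regulated_query query fragment selecting the regulation evidence
#'   (default `"<tf1>[EXPERIMENT_TYPE=Expression]"`).
#' @param bound_query query fragment selecting the binding evidence
#'   (default `"<tf1>[TECHNOLOGY/METHOD=ChIPseq]"`).
#' @return List with `direct` and `indirect` gene-id vectors (a partition
#'   of the regulated set).
#' @export
direct_indirect_partition <- function(tf1, store,
                                      regulated_query = NULL,
                                      bound_query = NULL) {
  if (is.null(regulated_query))
    regulated_query <- sprintf("%s[EXPERIMENT_TYPE=Expression]", tf1)
  if (is.null(bound_query))
    bound_query <- sprintf("%s[TECHNOLOGY/METHOD=ChIPseq]", tf1)
  et <- .meta_value(store, "EXPERIMENT_TYPE")
  exp_ids <- store$experiments$analysis_id[store$experiments$tf_id == tf1]
  if (!any(et[exp_ids] %in% "Expression"))
    .stopf("TF %s has no expression experiment", tf1)

  direct_ast <- parse_query(sprintf("(%s) and (%s)",
                                    regulated_query, bound_query))
  indirect_ast <- parse_query(sprintf("(%s) and not (%s)",
                                      regulated_query, bound_query))
  direct <- result_targets(evaluate_query(direct_ast, store), tf1)
  indirect <- result_targets(evaluate_query(indirect_ast, store), tf1)
  list(direct = direct, indirect = indirect)
}

#' Chart a network path TF1 -> direct TF2s -> indirect TF1 targets
#'
#' Network Walking: evaluates a TF2 query (typically over all expression
#' experiments) with the *Filter TFs* constraint set to the direct targets
#' of TF1 and the *Target Genes* constraint set to its indirect targets.
#' The TF2s found are themselves direct TF1 targets with validated edges
#' into the indirect targets; each gets an upper-tail Fisher enrichment of
#' its targets in the indirect set (with specificity and influence), and
#' the result records the coverage: the percent of indirect targets
#' reached by at least one TF2.
#'
#' @param tf1 the TF1 gene id.
#' @param store an `edge_store`.
#' @param tf2_query query for the candidate TF2 experiments (default
#'   `"all_expression"`).
#' @param regulated_query,bound_query passed to
#'   [direct_indirect_partition()].
#' @param background background gene universe for the per-TF2 enrichment.
#' @return A `walk_result`: list with `tf1`, `direct`, `indirect`,
#'   `tf2_set`, `path_edges` (tibble: `source`, `target`, `edge_type`,
#'   `layer`), `enrichment` (per-TF2 tibble) and `coverage` (percent).
#' @export
chart_network_path <- function(tf1, store, tf2_query = "all_expression",
                               regulated_query = NULL, bound_query = NULL,
                               background = NULL) {
  part <- direct_indirect_partition(tf1, store, regulated_query, bound_query)
  if (!length(part$direct) || !length(part$indirect)) {
    .warnf("empty %s target set for %s: empty walk",
           if (!length(part$direct)) "direct" else "indirect", tf1)
    return(structure(list(tf1 = tf1, direct = part$direct,
                          indirect = part$indirect,
                          tf2_set = character(),
                          path_edges = tibble::tibble(
                            source = character(), target = character(),
                            edge_type = character(), layer = character()),
                          enrichment = NULL, coverage = 0),
                     class = "walk_result"))
  }
  res <- evaluate_query(tf2_query, store,
                        filter_tfs = part$direct,
                        target_genes = part$indirect)
  tf2_set <- names(res$targets)
  covered <- unique(unlist(res$targets, use.names = FALSE))
  coverage <- 100 * length(intersect(covered, part$indirect)) /
    length(part$indirect)

  enr <- NULL
  if (length(tf2_set) && !is.null(background)) {
    # full TF2 target sets (not restricted to the indirect list) vs the
    # indirect list, so influence/specificity match the enrichment tab
    full <- evaluate_query(tf2_query, store, filter_tfs = part$direct)
    enr <- target_list_enrichment(
      full, setNames(list(part$indirect), paste0(tf1, "_indirect")),
      background)
  }

  e1 <- tibble::tibble(source = tf1, target = tf2_set,
                       edge_type = "direct", layer = "tf1_tf2")
  e2 <- tibble::tibble(
    source = rep(names(res$targets),
                 vapply(res$targets, length, integer(1))),
    target = unlist(res$targets, use.names = FALSE),
    edge_type = "regulates", layer = "tf2_target")
  structure(list(tf1 = tf1, direct = part$direct, indirect = part$indirect,
                 tf2_set = tf2_set, path_edges = rbind(e1, e2),
                 enrichment = enr, coverage = coverage),
            class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf(
    "<walk_result> %s: %d direct, %d indirect target(s); %d TF2(s) covering %.1f%% of indirect\n",
    x$tf1, length(x$direct), length(x$indirect), length(x$tf2_set),
    x$coverage))
  invisible(x)
}

#' Export a walk result as a layered SIF/JSON network
#'
#' Writes the TF1 -> TF2 and TF2 -> indirect-target edges through
#' [export_network()]; the JSON keeps the `layer` annotation on each edge.
#'
#' @param result a `walk_result`.
#' @param path output path.
#' @param format `"sif"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
export_walk <- function(result, path, format = c("sif", "json")) {
  format <- match.arg(format)
  ed <- result$path_edges
  if (!nrow(ed)) {
    if (format == "sif") writeLines(character(), path)
    else jsonlite::write_json(list(elements = list(nodes = list(),
                                                   edges = list())),
                              path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  names(ed)[names(ed) == "source"] <- "tf"
  export_network(ed, path, format)
  invisible(path)
}
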