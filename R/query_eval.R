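#' Evaluate a parsed query against an edge store
#'
#' A TERM selects every experiment whose TF matches the subject (or all
#' expression experiments for `all_expression`, every experiment for `all`)
#' and whose metadata satisfies the metadata filters; its edges are then
#' restricted by the edge-attribute filters (`log2fc`, `pvalue`,
#' `EDGE_TYPE`). Boolean composition:
#'
#' * `and` over terms of the same TF intersects that TF's target sets;
#'   across distinct TFs each TF's target set is restricted to targets
#'   present for every conjunct.
#' * `X and not Y` subtracts Y's target set from X's (per TF when the TF
#'   occurs on both sides, by target globally otherwise).
#' * bare `not X` complements against the background gene list (an error
#'   when no background is set). `not A and not B` is evaluated as
#'   background minus (A or B).
#' * `or` unions results keeping TFs distinct.
#'
#' Constraints are applied afterwards: `filter_tfs` restricts the TF set,
#' `target_genes` and `background` restrict targets, and `target_network`
#' restricts (tf, target) pairs to the edges of a predicted network.
#'
#' @param ast a `query_ast` from [parse_query()] (a query string is also
#'   accepted and parsed).
#' @param store an `edge_store`.
#' @param target_genes,filter_tfs,background optional gene-id character
#'   vectors (see [load_gene_list()]).
#' @param target_network optional `predicted_network` (see
#'   [read_network()]); restricts results to its (tf, target) pairs.
#' @return A `query_result`: list with `targets` (named list, TF ->
#'   character vector of target genes), `edges` (tibble of supporting
#'   edges), `analyses` (character), `ast` and `constraints`.
#' @export
evaluate_query <- function(ast, store, target_genes = NULL,
                           filter_tfs = NULL, background = NULL,
                           target_network = NULL) {
  if (is.character(ast)) ast <- parse_query(ast)
  stopifnot(inherits(store, "edge_store"))
  val <- .eval_node(ast, store, background)

  tfs <- val$tfs
  edges <- val$edges
  if (!is.null(filter_tfs)) {
    tfs <- tfs[names(tfs) %in% filter_tfs]
    edges <- edges[edges$tf %in% filter_tfs, , drop = FALSE]
  }
  restrict <- function(sets, genes) lapply(sets, function(s) intersect(s, genes))
  if (!is.null(background)) {
    tfs <- restrict(tfs, background)
    edges <- edges[edges$target %in% background, , drop = FALSE]
  }
  if (!is.null(target_genes)) {
    tfs <- restrict(tfs, target_genes)
    edges <- edges[edges$target %in% target_genes, , drop = FALSE]
  }
  if (!is.null(target_network)) {
    netkey <- paste(target_network$tf, target_network$target, sep = "\r")
    tfs <- tfs[names(tfs) %in% target_network$tf]
    tfs <- mapply(function(tf, s) {
      s[paste(tf, s, sep = "\r") %in% netkey]
    }, names(tfs), tfs, SIMPLIFY = FALSE)
    edges <- edges[paste(edges$tf, edges$target, sep = "\r") %in% netkey, ,
                   drop = FALSE]
  }
  tfs <- tfs[vapply(tfs, length, integer(1)) > 0L]
  # keep edges consistent with the surviving (tf, target) pairs
  if (nrow(edges)) {
    pairkey <- unlist(lapply(names(tfs), function(tf)
      paste(tf, tfs[[tf]], sep = "\r")), use.names = FALSE)
    edges <- edges[paste(edges$tf, edges$target, sep = "\r") %in% pairkey, ,
                   drop = FALSE]
  }

  structure(
    list(targets = tfs, edges = edges,
         analyses = unique(edges$analysis_id), ast = ast,
         constraints = list(target_genes = target_genes,
                            filter_tfs = filter_tfs,
                            background = background,
                            target_network = if (!is.null(target_network))
                              attr(target_network, "name") else NULL)),
    class = "query_result"
  )
}

.empty_edges <- function(store) store$edges[0, , drop = FALSE]

.target_union <- function(val) unique(unlist(val$tfs, use.names = FALSE))

.eval_node <- function(node, store, background) {
  switch(node$op,
    term = .eval_term(node, store),
    or = {
      vals <- lapply(node$children, .eval_node, store = store,
                     background = background)
      .union_vals(vals, store)
    },
    and = .eval_and(node$children, store, background),
    not = {
      if (is.null(background))
        .stopf("bare 'not' requires a background gene list")
      val <- .eval_node(node$child, store, background)
      tfs <- lapply(val$tfs, function(s) setdiff(background, s))
      tfs <- tfs[vapply(tfs, length, integer(1)) > 0L]
      list(tfs = tfs, edges = .empty_edges(store))
    },
    .stopf("unknown AST node op '%s'", node$op)
  )
}

.union_vals <- function(vals, store) {
  tfs <- list()
  for (v in vals) {
    for (tf in names(v$tfs)) {
      tfs[[tf]] <- unique(c(tfs[[tf]], v$tfs[[tf]]))
    }
  }
  edges <- do.call(rbind, lapply(vals, `[[`, "edges"))
  if (is.null(edges)) edges <- .empty_edges(store)
  edges <- edges[!duplicated(edges), , drop = FALSE]
  list(tfs = tfs, edges = edges)
}

.eval_and <- function(children, store, background) {
  neg <- vapply(children, function(ch) identical(ch$op, "not"), logical(1))
  if (all(neg)) {
    # De Morgan: not A and not B = background \ (A or B)
    inner <- list(op = "or", children = lapply(children, `[[`, "child"))
    if (length(children) == 1L) inner <- children[[1]]$child
    return(.eval_node(list(op = "not", child = inner), store, background))
  }
  pos <- lapply(children[!neg], .eval_node, store = store,
                background = background)
  negv <- lapply(children[neg], function(ch)
    .eval_node(ch$child, store, background))

  all_tfs <- unique(unlist(lapply(pos, function(v) names(v$tfs))))
  tfs <- list()
  for (tf in all_tfs) {
    s <- NULL
    ok <- TRUE
    for (v in pos) {
      vt <- if (tf %in% names(v$tfs)) v$tfs[[tf]] else .target_union(v)
      s <- if (is.null(s)) vt else intersect(s, vt)
      if (!length(s)) { ok <- FALSE; break }
    }
    if (!ok) next
    for (v in negv) {
      minus <- if (tf %in% names(v$tfs)) v$tfs[[tf]] else .target_union(v)
      s <- setdiff(s, minus)
      if (!length(s)) break
    }
    if (length(s)) tfs[[tf]] <- s
  }
  edges <- do.call(rbind, lapply(pos, `[[`, "edges"))
  if (is.null(edges)) edges <- .empty_edges(store)
  pairkey <- unlist(lapply(names(tfs), function(tf)
    paste(tf, tfs[[tf]], sep = "\r")), use.names = FALSE)
  edges <- edges[paste(edges$tf, edges$target, sep = "\r") %in% pairkey, ,
                 drop = FALSE]
  edges <- edges[!duplicated(edges), , drop = FALSE]
  list(tfs = tfs, edges = edges)
}

# metadata value of one key for all analyses (NA when absent)
.meta_value <- function(store, key) {
  m <- store$metadata[store$metadata$key == key, ]
  setNames(m$value, m$analysis_id)
}

.eval_term <- function(node, store) {
  exps <- store$experiments
  subject <- node$subject
  if (identical(subject, "all")) {
    sel <- exps$analysis_id
  } else if (identical(subject, "all_expression")) {
    et <- .meta_value(store, "EXPERIMENT_TYPE")
    sel <- exps$analysis_id[et[exps$analysis_id] %in% "Expression"]
  } else {
    sel <- exps$analysis_id[exps$tf_id == subject]
  }

  edge_keys <- c("LOG2FC", "PVALUE", "EDGE_TYPE")
  meta_filters <- Filter(function(f) !toupper(f$key) %in% edge_keys,
                         node$filters)
  edge_filters <- Filter(function(f) toupper(f$key) %in% edge_keys,
                         node$filters)

  for (f in meta_filters) {
    mv <- .meta_value(store, toupper(f$key))
    v <- mv[sel]
    keep <- switch(f$op,
      "=" = !is.na(v) & trimws(v) == trimws(f$value),
      "!=" = is.na(v) | trimws(v) != trimws(f$value),
      .stopf("operator '%s' not valid for metadata key '%s'", f$op, f$key))
    sel <- sel[keep]
  }

  if (!length(sel)) {
    .warnf("query term '%s' matches no experiment", subject)
    return(list(tfs = list(), edges = .empty_edges(store)))
  }

  ed <- store$edges[store$edges$analysis_id %in% sel, , drop = FALSE]
  for (f in edge_filters) {
    key <- toupper(f$key)
    if (key == "EDGE_TYPE") {
      keep <- switch(f$op,
        "=" = ed$edge_type == f$value,
        "!=" = ed$edge_type != f$value,
        .stopf("operator '%s' not valid for EDGE_TYPE", f$op))
    } else {
      x <- if (key == "LOG2FC") ed$log2fc else ed$pvalue
      num <- suppressWarnings(as.numeric(f$value))
      if (is.na(num)) .stopf("non-numeric value for %s filter", key)
      keep <- switch(f$op,
        "=" = x == num, "!=" = x != num,
        "<" = x < num, ">" = x > num,
        "<=" = x <= num, ">=" = x >= num)
      keep[is.na(keep)] <- FALSE
    }
    ed <- ed[keep, , drop = FALSE]
  }

  tfs <- lapply(split(ed$target, ed$tf), unique)
  list(tfs = tfs, edges = ed)
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> %d TF(s), %d target gene(s), %d edge(s), %d analysis(es)\n",
              length(x$targets),
              length(unique(unlist(x$targets, use.names = FALSE))),
              nrow(x$edges), length(x$analyses)))
  invisible(x)
}

#' All target genes of a query result
#' @param result a `query_result`.
#' @param tf optional TF id; when given, only that TF's targets.
#' @return Character vector of gene ids.
#' @export
result_targets <- function(result, tf = NULL) {
  if (is.null(tf)) unique(unlist(result$targets, use.names = FALSE))
  else result$targets[[tf]] %||% character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-analysis summary of a query result
#'
#' One row per analysis that contributed edges: its TF, the number of
#' distinct target genes and the number of supporting edges. Sorted by TF
#' then analysis id.
#'
#' @param result a `query_result`.
#' @return Tibble with columns `analysis_id`, `tf`, `n_targets`, `n_edges`.
#' @export
summarize_result <- function(result) {
  ed <- result$edges
  if (!nrow(ed)) {
    return(tibble::tibble(analysis_id = character(), tf = character(),
                          n_targets = integer(), n_edges = integer()))
  }
  sp <- split(ed, ed$analysis_id)
  out <- tibble::tibble(
    analysis_id = names(sp),
    tf = unname(vapply(sp, function(d) d$tf[[1]], character(1))),
    n_targets = unname(vapply(sp, function(d) length(unique(d$target)),
                              integer(1))),
    n_edges = unname(vapply(sp, nrow, integer(1)))
  )
  out[order(out$tf, out$analysis_id), ]
}

#' Export a query result as a long table
#'
#' One row per (tf, target, analysis) edge, with edge attributes, the
#' per-pair edge count (number of analyses validating the pair) and, when
#' gene lists are supplied, one membership column per list holding the list
#' name for member targets and `""` otherwise.
#'
#' @param result a `query_result`.
#' @param gene_lists optional named list of gene-id vectors (or a single
#'   vector with a `name` attribute, as from [load_gene_list()]).
#' @param path optional output path; when given the table is written as CSV.
#' @return The table (tibble), invisibly when `path` is given.
#' @export
export_result_table <- function(result, gene_lists = NULL, path = NULL) {
  ed <- result$edges
  pair <- paste(ed$tf, ed$target, sep = "\r")
  edge_count <- as.integer(table(pair)[pair])
  out <- tibble::tibble(
    tf = ed$tf, target = ed$target, analysis_id = ed$analysis_id,
    edge_type = ed$edge_type, edge_count = edge_count,
    log2fc = ed$log2fc, pvalue = ed$pvalue
  )
  if (!is.null(gene_lists)) {
    if (!is.list(gene_lists)) gene_lists <- list(gene_lists)
    nm <- names(gene_lists)
    if (is.null(nm)) nm <- rep("", length(gene_lists))
    for (i in seq_along(gene_lists)) {
      lname <- if (nzchar(nm[[i]])) nm[[i]]
               else attr(gene_lists[[i]], "name") %||% paste0("list", i)
      out[[lname]] <- ifelse(out$target %in% gene_lists[[i]], lname, "")
    }
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    return(invisible(out))
  }
  out
}
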