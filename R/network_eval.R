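#' Read a ranked predicted network
#'
#' Three tab-separated columns `tf  target  score` (header optional; it is
#' detected when the third field of the first line is not numeric).
#' Duplicate (tf, target) pairs are an error.
#'
#' @param path TSV path.
#' @param name network name (defaults to the file base name).
#' @return A `predicted_network` tibble with columns `tf`, `target`,
#'   `score`.
#' @export
read_network <- function(path, name = NULL) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 3) .stopf("predicted network needs 3 columns (tf, target, score)")
  names(df)[1:3] <- c("tf", "target", "score")
  predicted_network(df$tf, df$target, as.numeric(df$score),
                    name = if (is.null(name)) basename(path) else name)
}

#' Construct a predicted network
#' @param tf,target,score parallel vectors of TF id, target id, rank score.
#' @param name network name.
#' @return A `predicted_network` tibble.
#' @export
predicted_network <- function(tf, target, score, name = NULL) {
  if (anyDuplicated(paste(tf, target, sep = "\r")))
    .stopf("duplicate (tf, target) pairs in predicted network")
  if (any(is.na(score))) .stopf("missing scores in predicted network")
  out <- tibble::tibble(tf = as.character(tf), target = as.character(target),
                        score = as.numeric(score))
  structure(out, class = c("predicted_network", class(out)), name = name)
}

#' Build a gold standard from validated query results
#'
#' Positives are the gene-level validated (tf, target) pairs of the query
#' result, restricted to targets in the background; duplicates across
#' experiments count once. The TFs with any validation data are recorded:
#' only predicted edges from those TFs are evaluable.
#'
#' @param result a `query_result`.
#' @param background background gene universe.
#' @return A `gold_standard`: list with `pairs` (tibble `tf`, `target`),
#'   `tfs` and `background`.
#' @export
make_gold_standard <- function(result, background) {
  ed <- result$edges
  if (!nrow(ed)) .stopf("empty query result")
  n0 <- nrow(unique(ed[, c("tf", "target")]))
  pairs <- unique(ed[ed$target %in% background, c("tf", "target")])
  if (!nrow(pairs)) .stopf("no validated pairs left after background restriction")
  if (nrow(pairs) < n0)
    .warnf("%d validated pair(s) outside the background dropped",
           n0 - nrow(pairs))
  structure(list(pairs = tibble::as_tibble(pairs),
                 tfs = unique(ed$tf),
                 background = unique(background)),
            class = "gold_standard")
}

#' Precision/recall curve of a predicted network against a gold standard
#'
#' Evaluable edges are the predicted edges whose TF has gold-standard data
#' and whose target is in the background. They are ranked by descending
#' score (ties broken lexicographically by (tf, target)); at rank r,
#' precision = TP_r / r and recall = TP_r / P, with P the number of gold
#' positives occurring among the evaluable candidate pairs. Non-evaluable
#' edges are excluded from the curve but retained by
#' [prune_at_precision()].
#'
#' @param network a `predicted_network`.
#' @param gold a `gold_standard`.
#' @return A `pr_curve`: list with `curve` (tibble: `tf`, `target`,
#'   `score`, `label`, `tp`, `precision`, `recall`), `aupr`,
#'   `n_evaluable`, `n_positives`, `network`.
#' @export
precision_recall_curve <- function(network, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  ev <- network[network$tf %in% gold$tfs &
                  network$target %in% gold$background, , drop = FALSE]
  if (!nrow(ev)) .stopf("no evaluable edge (TF with gold data, target in background)")
  ord <- order(-ev$score, ev$tf, ev$target)
  ev <- ev[ord, ]
  goldkey <- paste(gold$pairs$tf, gold$pairs$target, sep = "\r")
  label <- paste(ev$tf, ev$target, sep = "\r") %in% goldkey
  P <- sum(label)
  if (P == 0) .stopf("no gold positive among the evaluable edges")
  tp <- cumsum(label)
  r <- seq_len(nrow(ev))
  curve <- tibble::tibble(tf = ev$tf, target = ev$target, score = ev$score,
                          label = label, tp = tp,
                          precision = tp / r, recall = tp / P)
  structure(list(curve = curve,
                 aupr = sum(curve$precision[label]) / P,
                 n_evaluable = nrow(ev), n_positives = P,
                 network = network),
            class = "pr_curve")
}

#' Area under the precision/recall curve
#'
#' Step (right-continuous) integration: the sum, over ranks where the
#' true-positive count increments, of precision(r) times the recall
#' increment 1/P.
#'
#' @param curve a `pr_curve`.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  curve$aupr
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> AUPR %.4f over %d evaluable edge(s), %d positive(s)\n",
              x$aupr, x$n_evaluable, x$n_positives))
  invisible(x)
}

#' Permutation significance of an observed AUPR
#'
#' The null distribution permutes the scores uniformly among the evaluable
#' edges and recomputes the AUPR (ties re-broken lexicographically). The
#' p-value uses the add-one estimator
#' `(1 + #\{null AUPR >= observed\}) / (1 + n_permutations)`. Also reports
#' the null mean AUPR and the percent improvement of the observed AUPR over
#' it.
#'
#' @param network a `predicted_network`.
#' @param gold a `gold_standard`.
#' @param n_permutations number of permutations (default 999).
#' @param seed optional integer seed.
#' @return List: `p_value`, `observed_aupr`, `null_mean`,
#'   `percent_improvement`, `null_auprs`.
#' @export
randomization_test <- function(network, gold, n_permutations = 999,
                               seed = NULL) {
  if (n_permutations < 1) .stopf("n_permutations must be >= 1")
  obs <- precision_recall_curve(network, gold)
  ev <- obs$curve          # already restricted + sorted
  P <- obs$n_positives
  n <- nrow(ev)
  if (!is.null(seed)) set.seed(seed)
  null_auprs <- vapply(seq_len(n_permutations), function(i) {
    sc <- sample(ev$score)
    ord <- order(-sc, ev$tf, ev$target)
    lab <- ev$label[ord]
    sum((cumsum(lab) / seq_len(n))[lab]) / P
  }, numeric(1))
  null_mean <- mean(null_auprs)
  list(
    p_value = (1 + sum(null_auprs >= obs$aupr)) / (1 + n_permutations),
    observed_aupr = obs$aupr,
    null_mean = null_mean,
    percent_improvement = 100 * (obs$aupr - null_mean) / null_mean,
    null_auprs = null_auprs
  )
}

#' Prune a predicted network at a precision cutoff
#'
#' The score threshold is the score at the deepest rank of the
#' precision/recall curve whose precision still reaches the cutoff; the
#' surviving network is every predicted edge -- evaluable or not -- whose
#' score is greater than or equal to that threshold. When no rank attains
#' the cutoff the result is empty, with a warning.
#'
#' @param network a `predicted_network`.
#' @param curve the `pr_curve` of `network`.
#' @param precision_cutoff required precision, in (0, 1].
#' @return A `prune_result`: list with `edges` (surviving tibble),
#'   `precision_cutoff`, `score_threshold`, `n_edges`, `n_tfs`,
#'   `n_targets`.
#' @export
prune_at_precision <- function(network, curve, precision_cutoff) {
  stopifnot(inherits(curve, "pr_curve"))
  if (precision_cutoff <= 0 || precision_cutoff > 1)
    .stopf("precision_cutoff must lie in (0,1]")
  ok <- which(curve$curve$precision >= precision_cutoff)
  if (!length(ok)) {
    .warnf("no rank attains precision %.3f; pruned network is empty",
           precision_cutoff)
    edges <- network[0, , drop = FALSE]
    thr <- NA_real_
  } else {
    r_star <- max(ok)
    thr <- curve$curve$score[r_star]
    edges <- network[network$score >= thr, , drop = FALSE]
  }
  structure(list(edges = tibble::as_tibble(edges),
                 precision_cutoff = precision_cutoff,
                 score_threshold = thr,
                 n_edges = nrow(edges),
                 n_tfs = length(unique(edges$tf)),
                 n_targets = length(unique(edges$target))),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf(
    "<prune_result> precision >= %.3f (score >= %s): %d interaction(s), %d TF(s), %d target(s)\n",
    x$precision_cutoff,
    if (is.na(x$score_threshold)) "NA" else sprintf("%.4g", x$score_threshold),
    x$n_edges, x$n_tfs, x$n_targets))
  invisible(x)
}

#' Export a network as SIF or Cytoscape-style JSON
#'
#' SIF lines are `tf <edge_type> target` (tab-separated). JSON follows the
#' Cytoscape elements layout: nodes with `data.id`, edges with
#' `data.source`, `data.target`, `data.edge_type` and optional `data.score`
#' and `data.validated`. Use [read_network_json()] to load the JSON back.
#'
#' @param edges data frame with columns `tf`, `target` and optionally
#'   `edge_type`, `score`; extra columns are carried into JSON.
#' @param path output path.
#' @param format `"sif"` or `"json"`.
#' @param validated optional data frame of validated (tf, target) pairs;
#'   matching edges get `validated = TRUE` in the output.
#' @return Invisibly, `path`.
#' @export
export_network <- function(edges, path, format = c("sif", "json"),
                           validated = NULL) {
  format <- match.arg(format)
  if (!nrow(edges)) .stopf("no edges to export")
  if (!"edge_type" %in% names(edges)) edges$edge_type <- "interacts"
  if (!is.null(validated)) {
    vk <- paste(validated$tf, validated$target, sep = "\r")
    edges$validated <- paste(edges$tf, edges$target, sep = "\r") %in% vk
  }
  if (format == "sif") {
    writeLines(paste(edges$tf, edges$edge_type, edges$target, sep = "\t"),
               path)
  } else {
    nodes <- unique(c(edges$tf, edges$target))
    elements <- list(
      nodes = lapply(nodes, function(id) list(data = list(id = id))),
      edges = lapply(seq_len(nrow(edges)), function(i) {
        d <- as.list(edges[i, , drop = FALSE])
        names(d)[names(d) == "tf"] <- "source"
        list(data = d)
      })
    )
    jsonlite::write_json(list(elements = elements), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a Cytoscape-style JSON network written by [export_network()]
#' @param path JSON path.
#' @return Tibble of edges.
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(x$elements$edges, function(e) {
    d <- e$data
    names(d)[names(d) == "source"] <- "tf"
    tibble::as_tibble(d)
  })
  do.call(rbind, rows)
}
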