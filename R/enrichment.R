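#' Fisher's exact test tail probabilities for a 2x2 table
#'
#' The table is `a` (overlap), `b`, `c`, `d` with margins `m1 = a + b`
#' (list 1), `m2 = a + c` (list 2) and universe `N = a + b + c + d`. Under
#' the null, the overlap `X` is hypergeometric with those margins. The
#' upper tail is `P(X >= a)` (enrichment), the lower tail `P(X <= a)`
#' (depletion); `two_sided` sums the probabilities of all tables at most as
#' likely as the observed one (minimum-likelihood method).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param tail `"upper"`, `"lower"` or `"two_sided"`.
#' @return The p-value.
#' @examples
#' fisher_exact(4, 1, 1, 14, "upper")  # 76/15504
#' @export
fisher_exact <- function(a, b, c, d, tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  cnt <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    .stopf("contingency counts must be non-negative integers")
  N <- a + b + c + d
  if (N <= 0) .stopf("empty contingency table")
  m1 <- a + b
  m2 <- a + c
  switch(tail,
    upper = phyper(a - 1, m1, N - m1, m2, lower.tail = FALSE),
    lower = phyper(a, m1, N - m1, m2),
    two_sided = {
      lo <- max(0, m1 + m2 - N)
      hi <- min(m1, m2)
      pm <- dhyper(lo:hi, m1, N - m1, m2)
      obs <- dhyper(a, m1, N - m1, m2)
      min(1, sum(pm[pm <= obs * (1 + 1e-7)]))
    }
  )
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with `m` the declared family size. The family is
#' the full set of tests performed together: all (analysis x list) cells for
#' target-list enrichment, all off-diagonal cells for the gene-set grid,
#' per-group for motif enrichment.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @param m family size (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    .stopf("p-values must lie in [0,1]")
  pmin(1, m * p)
}

# per-analysis target-gene sets from a query_result (or pass-through for a
# named list of gene sets)
.analysis_target_sets <- function(result) {
  if (inherits(result, "query_result")) {
    ed <- result$edges
    lapply(split(ed$target, ed$analysis_id), unique)
  } else if (is.list(result)) {
    result
  } else .stopf("expected a query_result or a named list of gene sets")
}

.analysis_tf_map <- function(result) {
  if (!inherits(result, "query_result")) return(NULL)
  ed <- result$edges
  vapply(split(ed$tf, ed$analysis_id), function(x) x[[1]], character(1))
}

#' Target-list enrichment with specificity and influence
#'
#' Tests, for every (analysis, gene list) pair, whether the analysis'
#' validated target genes overlap the list more than expected by chance
#' (upper-tail Fisher's exact test against the background universe),
#' Bonferroni-corrected over all (analysis x list) cells. Also reports
#' *specificity* (percent of the TF's targets inside the list) and
#' *influence* (percent of the list covered by the TF's targets). Genes
#' outside the background are dropped from both sides with a warning.
#'
#' @param result a `query_result` or named list of per-analysis target sets.
#' @param lists a named list of gene-id vectors (a single vector is
#'   wrapped).
#' @param background character vector: the background gene universe.
#' @return Tibble with columns `analysis_id`, `tf`, `list`, `n_targets`,
#'   `n_list`, `overlap`, `specificity`, `influence`, `p_raw`, `p_adj`.
#' @export
target_list_enrichment <- function(result, lists, background) {
  if (!length(background)) .stopf("empty background")
  background <- unique(background)
  if (!is.list(lists)) {
    nm <- attr(lists, "name") %||% "list1"
    lists <- setNames(list(lists), nm)
  }
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    names(lists) <- paste0("list", seq_along(lists))
  sets <- .analysis_target_sets(result)
  tf_of <- .analysis_tf_map(result)
  N <- length(background)

  dropped <- sum(vapply(sets, function(s) sum(!s %in% background), integer(1))) +
    sum(vapply(lists, function(s) sum(!s %in% background), integer(1)))
  if (dropped > 0)
    .warnf("%d gene(s) outside the background dropped before testing", dropped)

  rows <- list()
  for (aid in names(sets)) {
    targ <- intersect(unique(sets[[aid]]), background)
    for (ln in names(lists)) {
      lst <- intersect(unique(lists[[ln]]), background)
      a <- length(intersect(targ, lst))
      b <- length(targ) - a
      cc <- length(lst) - a
      d <- N - a - b - cc
      p <- fisher_exact(a, b, cc, d, "upper")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        analysis_id = aid,
        tf = if (is.null(tf_of)) NA_character_ else unname(tf_of[aid]),
        list = ln, n_targets = length(targ), n_list = length(lst),
        overlap = a,
        specificity = if (length(targ)) 100 * a / length(targ) else 0,
        influence = if (length(lst)) 100 * a / length(lst) else 0,
        p_raw = p
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, m = nrow(out))
  out
}

#' Pairwise gene-set enrichment grid
#'
#' For every pair of analyses, the overlap of their target-gene sets is
#' tested in both directions against the background: cells above the
#' diagonal hold the Bonferroni-adjusted upper-tail p-value (overlap greater
#' than or equal to observed), cells below the diagonal the lower-tail
#' p-value (less than or equal). The diagonal is `NA`. The Bonferroni family
#' is all `k*(k-1)` off-diagonal cells.
#'
#' @param result a `query_result` or named list of at least two gene sets.
#' @param background background gene universe.
#' @return A list of class `genesect_grid`: `p_adj` and `p_raw` (k x k
#'   matrices), `overlap` (k x k integer matrix), `sets` (the trimmed sets).
#' @export
gene_set_enrichment_grid <- function(result, background) {
  if (!length(background)) .stopf("empty background")
  background <- unique(background)
  sets <- .analysis_target_sets(result)
  k <- length(sets)
  if (k < 2) .stopf("gene-set enrichment needs at least 2 analyses")
  sets <- lapply(sets, function(s) intersect(unique(s), background))
  N <- length(background)
  nm <- names(sets)
  p_raw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  ov <- matrix(NA_integer_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- length(intersect(sets[[i]], sets[[j]]))
      b <- length(sets[[i]]) - a
      cc <- length(sets[[j]]) - a
      d <- N - a - b - cc
      p_raw[i, j] <- fisher_exact(a, b, cc, d, "upper")
      p_raw[j, i] <- fisher_exact(a, b, cc, d, "lower")
      ov[i, j] <- ov[j, i] <- a
    }
  }
  m <- k * (k - 1)
  p_adj <- matrix(pmin(1, m * p_raw), k, k, dimnames = list(nm, nm))
  structure(list(p_adj = p_adj, p_raw = p_raw, overlap = ov, sets = sets,
                 n_background = N),
            class = "genesect_grid")
}

#' @export
print.genesect_grid <- function(x, ...) {
  cat(sprintf("<genesect_grid> %d set(s), background %d genes\n",
              length(x$sets), x$n_background))
  print(signif(x$p_adj, 3))
  invisible(x)
}
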