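#' Sungear analysis of multiple gene lists
#'
#' Partitions the union of n gene lists into exact-membership nodes: the
#' node for a subset S of lists holds the genes found in exactly the lists
#' of S. With x_i the size of list i and x = sum(x_i) (genes counted once
#' per list they occur in), the expected node size is
#' `e_S = x * prod_{i in S}(x_i/x) * prod_{i not in S}(1 - x_i/x)`.
#' Each observed node gets an exact two-sided binomial p-value (x trials,
#' success probability e_S/x, minimum-likelihood method), a direction flag
#' (enriched when observed > e_S, depleted when observed < e_S) and a
#' Bonferroni correction over the observed nodes. Layout places the list
#' anchors at the n-th roots of unity and each node at the centroid of its
#' member anchors, with a deterministic jitter for coincident centroids.
#'
#' @param lists named list of gene-id character vectors (>= 1 non-empty).
#' @return A `sungear` object: list with `nodes` (tibble: `membership`
#'   (comma-joined list indices), `lists` (comma-joined names), `k`
#'   observed, `e` expected, `p_raw`, `p_adj`, `direction`, `x`, `y`),
#'   `vertices` (tibble of anchor coordinates), `genes` (named list of
#'   per-node gene vectors), `x_total` and `sizes`.
#' @examples
#' sungear(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
sungear <- function(lists) {
  if (!is.list(lists) || !length(lists)) .stopf("expected a list of gene lists")
  if (is.null(names(lists))) names(lists) <- paste0("list", seq_along(lists))
  lists <- lapply(lists, unique)
  if (all(vapply(lists, length, integer(1)) == 0L))
    .stopf("all lists are empty")
  n <- length(lists)
  sizes <- vapply(lists, length, integer(1))
  x <- sum(sizes)

  nodes <- compute_nodes(lists)
  memb_idx <- lapply(names(nodes), function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))

  e <- vapply(memb_idx, function(S) node_expectation(sizes, S), numeric(1))
  k_obs <- vapply(nodes, length, integer(1))
  p_raw <- mapply(function(k, eS) binom_twosided(k, x, eS / x), k_obs, e)
  p_adj <- bonferroni(p_raw, m = length(p_raw))
  direction <- ifelse(k_obs > e, "enriched",
                      ifelse(k_obs < e, "depleted", "neutral"))

  lay <- layout_polygon(names(nodes), n)
  tbl <- tibble::tibble(
    membership = names(nodes),
    lists = vapply(memb_idx, function(S)
      paste(names(lists)[S], collapse = ","), character(1)),
    k = unname(k_obs), e = unname(e),
    p_raw = unname(p_raw), p_adj = unname(p_adj),
    direction = unname(direction),
    x = lay$x, y = lay$y
  )
  structure(list(nodes = tbl, genes = nodes, vertices = lay$vertices,
                 x_total = x, sizes = sizes, names = names(lists)),
            class = "sungear")
}

#' Exact-membership node partition of gene lists
#'
#' @param lists named list of gene-id vectors.
#' @return Named list: key = comma-joined sorted list indices, value =
#'   genes exclusively in exactly those lists. Nodes partition the union.
#' @export
compute_nodes <- function(lists) {
  lists <- lapply(lists, unique)
  if (all(vapply(lists, length, integer(1)) == 0L))
    .stopf("all lists are empty")
  genes <- unique(unlist(lists, use.names = FALSE))
  memb <- vapply(genes, function(g)
    paste(which(vapply(lists, function(l) g %in% l, logical(1))),
          collapse = ","), character(1))
  split(genes, memb)
}

#' Expected node size under the Sungear product formula
#'
#' `e_S = x * prod_{i in S}(x_i/x) * prod_{i not in S}(1 - x_i/x)`
#' with `x = sum(x_i)`.
#'
#' @param sizes integer vector of list sizes x_i.
#' @param S integer indices of the member lists (non-empty subset).
#' @return The expectation e_S.
#' @export
node_expectation <- function(sizes, S) {
  x <- sum(sizes)
  if (x == 0) .stopf("total list size x is 0")
  if (!length(S)) .stopf("S must be a non-empty subset of lists")
  p <- sizes / x
  x * prod(p[S]) * prod(1 - p[setdiff(seq_along(sizes), S)])
}

#' Exact two-sided binomial test (minimum-likelihood method)
#'
#' Sums `P(X = j)` over all j whose probability does not exceed that of the
#' observed count (with the conventional `1 + 1e-7` relative tolerance for
#' likelihood ties).
#'
#' @param k observed count.
#' @param n_trials number of trials.
#' @param p_success success probability.
#' @return Two-sided p-value.
#' @export
binom_twosided <- function(k, n_trials, p_success) {
  if (p_success < 0 || p_success > 1)
    .stopf("success probability outside [0,1]")
  if (k < 0 || k > n_trials) .stopf("observed count outside [0, n_trials]")
  d <- dbinom(0:n_trials, n_trials, p_success)
  min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
}

#' Polygon layout for Sungear nodes
#'
#' Anchors (list vertices) sit at the n-th roots of unity on the unit
#' circle; each node sits at the centroid of its member anchors. Nodes
#' whose centroids coincide are jittered deterministically, radially, in
#' an order seeded by the membership key.
#'
#' @param memberships character vector of comma-joined list indices.
#' @param n number of lists.
#' @return List with `x`, `y` (node coordinates) and `vertices` (tibble:
#'   `list_index`, `x`, `y`).
#' @export
layout_polygon <- function(memberships, n) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  vx <- cos(theta)
  vy <- sin(theta)
  xs <- ys <- numeric(length(memberships))
  for (i in seq_along(memberships)) {
    S <- as.integer(strsplit(memberships[[i]], ",", fixed = TRUE)[[1]])
    xs[i] <- mean(vx[S])
    ys[i] <- mean(vy[S])
  }
  key <- paste(round(xs, 9), round(ys, 9))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    for (g in unique(key[dup])) {
      idx <- which(key == g)
      # deterministic jitter: angle from a hash of the membership string
      for (j in seq_along(idx)[-1]) {
        h <- sum(utf8ToInt(memberships[[idx[j]]])) %% 360
        r <- 0.02 * (j - 1)
        xs[idx[j]] <- xs[idx[j]] + r * cos(h * pi / 180)
        ys[idx[j]] <- ys[idx[j]] + r * sin(h * pi / 180)
      }
    }
  }
  list(x = xs, y = ys,
       vertices = tibble::tibble(list_index = seq_len(n), x = vx, y = vy))
}

#' @export
print.sungear <- function(x, ...) {
  cat(sprintf("<sungear> %d list(s), x = %d, %d node(s)\n",
              length(x$sizes), x$x_total, nrow(x$nodes)))
  print(x$nodes)
  invisible(x)
}

#' Write a Sungear result as TSV and/or JSON
#' @param sg a `sungear` object.
#' @param tsv_path,json_path optional output paths.
#' @return Invisibly, `sg`.
#' @export
write_sungear <- function(sg, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(sg$nodes, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(nodes = sg$nodes, vertices = sg$vertices,
           genes = sg$genes, x_total = sg$x_total),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(sg)
}
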