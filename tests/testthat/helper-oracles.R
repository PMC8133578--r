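# Independent oracles, deliberately implemented through different routes
# than the package code (lchoose-based probabilities, word enumeration,
# O(n^2) scans) so they can certify the implementation.

# hypergeometric tail by explicit pmf enumeration over all feasible overlaps
hyper_oracle <- function(a, b, c, d, tail) {
  N <- a + b + c + d
  m1 <- a + b
  m2 <- a + c
  lo <- max(0, m1 + m2 - N)
  hi <- min(m1, m2)
  js <- lo:hi
  pmf <- exp(lchoose(m1, js) + lchoose(N - m1, m2 - js) - lchoose(N, m2))
  if (tail == "upper") sum(pmf[js >= a]) else sum(pmf[js <= a])
}

# binomial pmf via log-gamma route; same minimum-likelihood tie rule as the
# method definition
binom_oracle <- function(k, n, p) {
  js <- 0:n
  if (p == 0) {
    pmf <- as.numeric(js == 0)
  } else if (p == 1) {
    pmf <- as.numeric(js == n)
  } else {
    pmf <- exp(lchoose(n, js) + js * log(p) + (n - js) * log1p(-p))
  }
  min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
}

# exhaustive 4^w word enumeration of P(integer score >= s) under a
# zero-order background, using the same per-column integer scores
pwm_enum_oracle <- function(int_mat, bg) {
  w <- ncol(int_mat)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- integer(nrow(words))
  wts <- rep(1, nrow(words))
  for (j in 1:w) {
    scores <- scores + int_mat[cbind(words[, j], j)]
    wts <- wts * bg[words[, j]]
  }
  function(s) sum(wts[scores >= s])
}

# independent O(n^2) greedy overlap removal in priority order
greedy_overlap_oracle <- function(hits) {
  ord <- order(hits$pvalue, hits$start, hits$strand != "+")
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (k in kept) {
      if (hits$start[i] < hits$end[k] && hits$end[i] > hits$start[k]) {
        clash <- TRUE
        break
      }
    }
    if (!clash) kept <- c(kept, i)
  }
  sort(kept)
}

# cumulative-count precision/recall oracle
pr_oracle <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  r <- seq_along(lab)
  list(precision = tp / r, recall = tp / sum(lab),
       aupr = sum((tp / r)[lab]) / sum(lab))
}

random_pwm <- function(w, id = "R") {
  m <- matrix(runif(4 * w, 0.05, 1), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  pwm(id, m)
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
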