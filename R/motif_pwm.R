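#' Construct a position weight matrix (PWM)
#'
#' @param motif_id motif identifier.
#' @param mat 4 x w probability matrix, rows A, C, G, T; columns must each
#'   sum to 1 (within 1e-6).
#' @param cluster_id optional motif-cluster membership.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, mat, cluster_id = NA_character_) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) .stopf("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 1) .stopf("PWM width must be >= 1")
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(abs(colSums(mat) - 1) > 1e-6))
    .stopf("PWM columns must sum to 1")
  structure(list(motif_id = motif_id, mat = mat, width = ncol(mat),
                 cluster_id = cluster_id),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (width %d%s)\n", x$motif_id, x$width,
              if (!is.na(x$cluster_id)) paste0(", cluster ", x$cluster_id)
              else ""))
  invisible(x)
}

#' Reverse-complement a PWM
#' @param x a `pwm`.
#' @return The reverse-complemented `pwm`.
#' @export
reverse_complement_pwm <- function(x) {
  m <- x$mat[4:1, rev(seq_len(x$width)), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm(x$motif_id, m, x$cluster_id)
}

#' Read motifs from a MEME-format file
#'
#' Supports the minimal MEME text format: optional
#' `Background letter frequencies` block, then one
#' `MOTIF <id> [<name>]` header and `letter-probability matrix:` block per
#' motif.
#'
#' @param path MEME file path.
#' @return Named list of `pwm` objects; the file's background frequencies
#'   (if any) are attached as attribute `"background"`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg <- NULL
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    fl <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(fl[seq(2, length(fl), 2)])
    names(vals) <- fl[seq(1, length(fl), 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  motif_i <- grep("^MOTIF\\s", lines)
  if (!length(motif_i)) .stopf("no MOTIF records in %s", path)
  out <- list()
  for (mi in motif_i) {
    hdr <- strsplit(trimws(lines[mi]), "\\s+")[[1]]
    id <- hdr[2]
    lp <- mi + grep("^letter-probability matrix:",
                    lines[(mi + 1):length(lines)])[1]
    if (is.na(lp)) .stopf("motif %s lacks a letter-probability matrix", id)
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[lp]))
    rows <- lines[(lp + 1):(lp + w)]
    m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                  numeric(4)))
    m <- t(m)
    m <- sweep(m, 2, colSums(m), "/")  # fixed-precision text: renormalise
    dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
    out[[id]] <- pwm(id, m)
  }
  if (!is.null(bg)) attr(out, "background") <- bg
  out
}

#' Write motifs to a MEME-format file
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @param background named background frequencies (A, C, G, T).
#' @return Invisibly, `path`.
#' @export
write_meme <- function(pwms, path, background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[["A"]], background[["C"]],
                       background[["G"]], background[["T"]]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       p$width), con)
    for (j in seq_len(p$width))
      writeLines(paste(sprintf("%.6f", p$mat[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Scanning parameters
#'
#' @param p_threshold report hits with exact p-value strictly below this
#'   (default 1e-4, the conventional genome-scan threshold).
#' @param background zero-order base frequencies (named A, C, G, T); when
#'   `NULL`, computed from the scanned sequences.
#' @param granularity discretisation of the log-likelihood score in bits
#'   used for the exact p-value dynamic programme (default 1e-3).
#' @param pseudocount probability added to every PWM cell before
#'   renormalisation (default 1e-4); 0 is an error if the PWM contains
#'   zero probabilities.
#' @return A `scan_params` list.
#' @export
scan_params <- function(p_threshold = 1e-4, background = NULL,
                        granularity = 1e-3, pseudocount = 1e-4) {
  if (p_threshold <= 0 || p_threshold >= 1)
    .stopf("p_threshold must lie in (0,1)")
  if (!is.null(background)) {
    background <- background[c("A", "C", "G", "T")]
    if (any(is.na(background)) || abs(sum(background) - 1) > 1e-6)
      .stopf("background must be named A,C,G,T frequencies summing to 1")
  }
  structure(list(p_threshold = p_threshold, background = background,
                 granularity = granularity, pseudocount = pseudocount),
            class = "scan_params")
}

# pseudocounted log2 likelihood-ratio matrix and its integer discretisation
.pwm_score_matrices <- function(p, background, granularity, pseudocount) {
  m <- p$mat
  if (pseudocount > 0) m <- sweep(m + pseudocount, 2, colSums(m + pseudocount), "/")
  if (any(m <= 0))
    .stopf("PWM '%s' contains zero probabilities and no pseudocount", p$motif_id)
  s <- log2(m / background)
  list(real = s, int = round(s / granularity))
}

#' Exact score distribution of a PWM under a zero-order background
#'
#' Dynamic programme (convolution over the per-column discretised score
#' distributions) giving the exact null distribution of the integer score,
#' the granularity being that of [scan_params()]. The per-hit p-value
#' reported by [scan_pwm()] is `P(score >= s)` read from this distribution.
#'
#' @param p a `pwm`.
#' @param background named base frequencies.
#' @param granularity score discretisation in bits.
#' @param pseudocount PWM pseudocount.
#' @return Tibble with columns `score_int` (integer score, in units of
#'   `granularity` bits), `prob` and `p_ge` (`P(score >= score_int)`).
#' @export
pwm_score_distribution <- function(p, background = c(A = 0.25, C = 0.25,
                                                     G = 0.25, T = 0.25),
                                   granularity = 1e-3, pseudocount = 1e-4) {
  sm <- .pwm_score_matrices(p, background, granularity, pseudocount)
  I <- sm$int
  w <- ncol(I)
  cur_lo <- min(I[, 1])
  cur <- numeric(max(I[, 1]) - cur_lo + 1L)
  for (b in 1:4) {
    idx <- I[b, 1] - cur_lo + 1L
    cur[idx] <- cur[idx] + background[[b]]
  }
  if (w > 1) {
    for (j in 2:w) {
      col_lo <- min(I[, j])
      new_lo <- cur_lo + col_lo
      new <- numeric(length(cur) + max(I[, j]) - col_lo)
      for (b in 1:4) {
        off <- I[b, j] - col_lo
        rng <- (1 + off):(length(cur) + off)
        new[rng] <- new[rng] + background[[b]] * cur
      }
      cur <- new
      cur_lo <- new_lo
    }
  }
  score_int <- seq.int(cur_lo, cur_lo + length(cur) - 1L)
  p_ge <- rev(cumsum(rev(cur)))
  keep <- cur > 0
  tibble::tibble(score_int = score_int[keep], prob = cur[keep],
                 p_ge = pmin(1, p_ge[keep]))
}

.base_codes <- function(seqchar) {
  code <- integer(128)
  code[c(65L, 97L)] <- 1L   # A a
  code[c(67L, 99L)] <- 2L   # C c
  code[c(71L, 103L)] <- 3L  # G g
  code[c(84L, 116L)] <- 4L  # T t
  out <- code[utf8ToInt(seqchar)]
  out[out == 0L] <- NA_integer_
  out
}

# survival lookup for integer window scores
.lookup_p_ge <- function(dist, s) {
  # dist: full-support tibble from pwm_score_distribution
  lo <- dist$score_int[1]
  hi <- dist$score_int[nrow(dist)]
  sf <- rep(0, hi - lo + 1L)
  sf[dist$score_int - lo + 1L] <- dist$p_ge
  # p_ge at absent scores equals p_ge of the next present (higher) score;
  # p_ge is non-increasing in s, so a right-to-left running max fills gaps
  sf <- rev(cummax(rev(sf)))
  out <- numeric(length(s))
  out[s < lo] <- 1
  out[s > hi] <- 0
  inb <- s >= lo & s <= hi
  out[inb] <- sf[s[inb] - lo + 1L]
  out
}

#' Scan sequences with a PWM, reporting hits with exact p-values
#'
#' Every position on both strands is scored as the sum over columns of
#' `log2(pwm[base] / background[base])`; the exact p-value of a window is
#' the probability, under the zero-order background model, of a score at
#' least as high (computed by [pwm_score_distribution()]). Hits with
#' `p < p_threshold` are reported; reverse-strand hits are reported in
#' forward coordinates (0-based half-open, width = motif width). Windows
#' containing `N` (or any non-ACGT base) are skipped.
#'
#' @param sequences named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @param p a `pwm` or a list of `pwm`s.
#' @param params a [scan_params()] object.
#' @return Tibble of hits: `motif_id`, `chrom`, `start`, `end`, `strand`,
#'   `score` (bits), `pvalue`.
#' @export
scan_pwm <- function(sequences, p, params = scan_params()) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- sub("\\s.*$", "", nm)
  }
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (inherits(p, "pwm")) p <- list(p)

  bg <- params$background
  if (is.null(bg)) {
    tab <- tabulate(unlist(lapply(unname(sequences), .base_codes),
                           use.names = FALSE), nbins = 4L)
    bg <- tab / sum(tab)
    names(bg) <- c("A", "C", "G", "T")
  }

  # per motif x strand: score matrices + exact null distribution
  scorers <- list()
  for (pm in p) {
    for (std in c("+", "-")) {
      m <- if (std == "+") pm else reverse_complement_pwm(pm)
      sm <- .pwm_score_matrices(m, bg, params$granularity, params$pseudocount)
      dist <- pwm_score_distribution(m, bg, params$granularity,
                                     params$pseudocount)
      scorers[[length(scorers) + 1L]] <-
        list(motif_id = pm$motif_id, strand = std, w = pm$width,
             sm = sm, dist = dist)
    }
  }

  out <- list()
  for (chrom in names(sequences)) {
    codes <- .base_codes(sequences[[chrom]])
    nacode <- is.na(codes)
    has_n <- any(nacode)
    codes0 <- codes
    if (has_n) codes0[nacode] <- 1L
    for (sc in scorers) {
      w <- sc$w
      nw <- length(codes) - w + 1L
      if (nw < 1L) next
      si <- integer(nw)
      valid <- if (has_n) rep(TRUE, nw) else TRUE
      Iint <- sc$sm$int
      for (j in seq_len(w)) {
        cj <- codes0[j:(j + nw - 1L)]
        if (has_n) valid <- valid & !nacode[j:(j + nw - 1L)]
        si <- si + Iint[cj + (j - 1L) * 4L]
      }
      pv <- .lookup_p_ge(sc$dist, si)
      hit <- valid & pv < params$p_threshold
      if (!any(hit)) next
      idx <- which(hit)
      # exact real-valued bit score, recomputed on the (few) hits only
      Ireal <- sc$sm$real
      sr <- vapply(idx, function(i)
        sum(Ireal[codes0[i:(i + w - 1L)] + (seq_len(w) - 1L) * 4L]),
        numeric(1))
      out[[length(out) + 1L]] <- tibble::tibble(
        motif_id = sc$motif_id, chrom = chrom,
        start = idx - 1L, end = idx - 1L + w,
        strand = sc$strand, score = sr, pvalue = pv[idx]
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(motif_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), score = numeric(),
                          pvalue = numeric()))
  }
  hits <- do.call(rbind, out)
  hits[order(hits$motif_id, hits$chrom, hits$start, hits$strand), ]
}

#' Remove overlapping hits of the same motif
#'
#' Greedy selection in ascending p-value order (ties broken by ascending
#' start, then forward strand first): a hit is kept iff it does not overlap
#' any previously kept hit of the same motif on the same sequence
#' (strand-agnostic coordinate overlap). Hits of different motifs are never
#' pruned against each other.
#'
#' @param hits hit tibble from [scan_pwm()].
#' @return The non-overlapping subset, in (motif, chrom, start) order.
#' @export
remove_overlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  keep_rows <- logical(nrow(hits))
  grp <- paste(hits$motif_id, hits$chrom, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    h <- hits[idx, ]
    ord <- order(h$pvalue, h$start, h$strand != "+")
    kept_s <- integer(0)
    kept_e <- integer(0)
    for (i in ord) {
      if (!any(h$start[i] < kept_e & h$end[i] > kept_s)) {
        kept_s <- c(kept_s, h$start[i])
        kept_e <- c(kept_e, h$end[i])
        keep_rows[idx[i]] <- TRUE
      }
    }
  }
  out <- hits[keep_rows, ]
  out[order(out$motif_id, out$chrom, out$start), ]
}

#' Write motif hits as BED
#'
#' Columns: `chrom start end motif_id score strand pvalue` (tab-separated,
#' no header; coordinates 0-based half-open as in BED).
#'
#' @param hits hit tibble.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
  df <- data.frame(hits$chrom, hits$start, hits$end, hits$motif_id,
                   signif(hits$score, 6), hits$strand,
                   signif(hits$pvalue, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
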