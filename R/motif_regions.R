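#' Build the per-gene region index used for motif counting
#'
#' Derives, for every gene, the interval lists of the canonical gene
#' regions: `promoter2000`, `promoter1000`, `promoter500` (the k bases
#' immediately 5' of the TSS on the gene's strand, clipped at the
#' chromosome start), `utr5`, `cds`, `intron`, `exon`, `utr3` and `cdna`
#' (the transcribed span). Multi-transcript genes use the union of each
#' region over transcripts; `intron` is the transcribed span minus the exon
#' union. Genes without an annotated transcript contribute only promoters
#' and `cdna` (the gene span), with a warning.
#'
#' @param annotation a `gene_annotation`.
#' @param promoter_sizes upstream window sizes in bp.
#' @return A `region_index`: tibble with columns `gene_id`, `region`,
#'   `chrom`, `start`, `end` (0-based half-open; one row per interval).
#' @export
build_region_index <- function(annotation,
                               promoter_sizes = c(2000, 1000, 500)) {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  rows <- list()
  add <- function(gene_id, region, chrom, start, end) {
    keep <- start < end
    if (!any(keep)) return()
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      gene_id = gene_id[keep], region = region, chrom = chrom[keep],
      start = as.integer(start[keep]), end = as.integer(end[keep]))
  }

  for (k in promoter_sizes) {
    plus <- g$strand == "+"
    add(g$gene_id[plus], paste0("promoter", k), g$chrom[plus],
        pmax(0L, g$tss[plus] - k), g$tss[plus])
    add(g$gene_id[!plus], paste0("promoter", k), g$chrom[!plus],
        g$tss[!plus], g$tss[!plus] + k)
  }

  tx <- annotation$transcripts
  ft <- annotation$features
  has_tx <- g$gene_id %in% tx$gene_id
  if (any(!has_tx))
    .warnf("%d gene(s) without transcripts: only promoters and cdna emitted",
           sum(!has_tx))

  # cdna: union of transcript spans (gene span when no transcript)
  if (nrow(tx)) {
    cdna <- .reduce_by_gene(tx$gene_id, tx$chrom, tx$start, tx$end)
    add(cdna$gene_id, "cdna", cdna$chrom, cdna$start, cdna$end)
  }
  g0 <- g[!has_tx, ]
  add(g0$gene_id, "cdna", g0$chrom, g0$start, g0$end)

  type_map <- c(exon = "exon", CDS = "cds",
                five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  for (ty in names(type_map)) {
    f <- ft[ft$type == ty, ]
    if (!nrow(f)) next
    red <- .reduce_by_gene(f$gene_id, f$chrom, f$start, f$end)
    add(red$gene_id, type_map[[ty]], red$chrom, red$start, red$end)
  }

  # intron = transcribed span minus exon union, per gene
  ex <- ft[ft$type == "exon", ]
  if (nrow(ex) && nrow(tx)) {
    exl <- split(seq_len(nrow(ex)), ex$gene_id)
    spans <- .reduce_by_gene(tx$gene_id, tx$chrom, tx$start, tx$end)
    spl <- split(seq_len(nrow(spans)), spans$gene_id)
    for (gid in intersect(names(exl), names(spl))) {
      ei <- exl[[gid]]
      er <- IRanges::reduce(IRanges::IRanges(ex$start[ei] + 1L, ex$end[ei]))
      si <- spl[[gid]]
      sp <- IRanges::IRanges(spans$start[si] + 1L, spans$end[si])
      intr <- IRanges::setdiff(sp, er)
      if (length(intr))
        add(rep(gid, length(intr)), "intron",
            rep(ex$chrom[ei[1]], length(intr)),
            IRanges::start(intr) - 1L, IRanges::end(intr))
    }
  }

  out <- do.call(rbind, rows)
  structure(out, class = c("region_index", class(out)),
            promoter_sizes = promoter_sizes)
}

# union of 0-based intervals per gene (single chromosome per gene assumed)
.reduce_by_gene <- function(gene_id, chrom, start, end) {
  gr <- GenomicRanges::GRanges(
    seqnames = paste(gene_id, chrom, sep = "\r"),
    ranges = IRanges::IRanges(start + 1L, end))
  red <- GenomicRanges::reduce(gr)
  key <- as.character(GenomicRanges::seqnames(red))
  parts <- do.call(rbind, strsplit(key, "\r", fixed = TRUE))
  tibble::tibble(gene_id = parts[, 1], chrom = parts[, 2],
                 start = GenomicRanges::start(red) - 1L,
                 end = GenomicRanges::end(red))
}

#' Tally motif hits per gene region
#'
#' A hit is counted for a gene x region cell iff its interval overlaps the
#' region by at least one base; a hit overlapping intervals of several
#' genes is counted for all of them, and a hit spanning several intervals
#' of one multi-interval region counts once for that cell. Run
#' [remove_overlaps()] on the hits first.
#'
#' @param hits pruned hit tibble from [scan_pwm()].
#' @param index a `region_index` from [build_region_index()].
#' @return A `motif_counts` tibble: `motif_id`, `gene_id`, `region`,
#'   `count`.
#' @export
count_hits_by_region <- function(hits, index) {
  empty <- tibble::tibble(motif_id = character(), gene_id = character(),
                          region = character(), count = integer())
  if (!nrow(hits) || !nrow(index))
    return(structure(empty, class = c("motif_counts", class(empty))))
  hg <- .as_granges(hits$chrom, hits$start, hits$end)
  ig <- .as_granges(index$chrom, index$start, index$end)
  ov <- GenomicRanges::findOverlaps(hg, ig, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  cell <- tibble::tibble(
    hit = qi,
    motif_id = hits$motif_id[qi],
    gene_id = index$gene_id[si],
    region = index$region[si]
  )
  cell <- cell[!duplicated(cell), ]
  agg <- aggregate(list(count = cell$hit),
                   by = list(motif_id = cell$motif_id,
                             gene_id = cell$gene_id,
                             region = cell$region),
                   FUN = length)
  out <- tibble::as_tibble(agg[order(agg$motif_id, agg$gene_id, agg$region), ])
  structure(out, class = c("motif_counts", class(out)))
}

#' Aggregate motif counts to motif-cluster counts
#'
#' @param counts a `motif_counts` tibble.
#' @param clusters named character vector mapping `motif_id` to cluster id;
#'   motifs without a mapping are dropped.
#' @return A `motif_counts` tibble keyed by cluster id.
#' @export
cluster_counts <- function(counts, clusters) {
  cl <- clusters[counts$motif_id]
  keep <- !is.na(cl)
  if (!any(keep)) .stopf("no motif in the counts has a cluster assignment")
  agg <- aggregate(list(count = counts$count[keep]),
                   by = list(motif_id = unname(cl[keep]),
                             gene_id = counts$gene_id[keep],
                             region = counts$region[keep]),
                   FUN = sum)
  out <- tibble::as_tibble(agg[order(agg$motif_id, agg$gene_id, agg$region), ])
  structure(out, class = c("motif_counts", class(out)))
}

#' Motif (or motif-cluster) enrichment in target-gene sets
#'
#' Occurrence-level Fisher test: for motif m, region r and target set T the
#' 2x2 table is built from the number of occurrences of m in the region r
#' of genes in T, versus occurrences of all other motifs in T, against the
#' same two counts over the rest of the background gene universe. Upper
#' tail (enrichment) only. The Bonferroni family is the full set of
#' (set x motif x region) cells tested in this call; test queried analyses
#' and user gene lists in separate calls so their corrections stay
#' independent. A region with zero total occurrences is flagged untestable
#' (p = 1).
#'
#' @param counts a `motif_counts` tibble (motifs, or clusters via
#'   [cluster_counts()]), built over the background universe.
#' @param target_sets named list of gene-id vectors (per analysis or list).
#' @param background background gene universe.
#' @param regions regions to test (default: all present in `counts`).
#' @param motifs motifs to test (default: all present in `counts`).
#' @return Tibble: `set`, `motif_id`, `region`, `a`, `b`, `c`, `d`,
#'   `p_raw`, `p_adj`, `untestable`.
#' @export
motif_enrichment <- function(counts, target_sets, background,
                             regions = NULL, motifs = NULL) {
  if (!length(background)) .stopf("empty background")
  background <- unique(background)
  if (is.null(regions)) regions <- sort(unique(counts$region))
  if (is.null(motifs)) motifs <- sort(unique(counts$motif_id))
  if (is.null(names(target_sets)))
    names(target_sets) <- paste0("set", seq_along(target_sets))

  counts <- counts[counts$gene_id %in% background &
                     counts$region %in% regions, ]
  rows <- list()
  for (sn in names(target_sets)) {
    T_ <- intersect(unique(target_sets[[sn]]), background)
    in_T <- counts$gene_id %in% T_
    for (r in regions) {
      in_r <- counts$region == r
      tot_T <- sum(counts$count[in_r & in_T])
      tot_B <- sum(counts$count[in_r & !in_T])
      for (m in motifs) {
        is_m <- counts$motif_id == m
        a <- sum(counts$count[in_r & in_T & is_m])
        cc <- sum(counts$count[in_r & !in_T & is_m])
        b <- tot_T - a
        d <- tot_B - cc
        untestable <- (tot_T + tot_B) == 0
        p <- if (untestable) 1 else fisher_exact(a, b, cc, d, "upper")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          set = sn, motif_id = m, region = r,
          a = a, b = b, c = cc, d = d,
          p_raw = p, untestable = untestable)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, m = nrow(out))
  out[, c("set", "motif_id", "region", "a", "b", "c", "d",
          "p_raw", "p_adj", "untestable")]
}
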