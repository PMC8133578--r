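#' Load a TF-target edge table with experiment metadata
#'
#' Reads a compendium of validated TF-target interactions from a tab-separated
#' edge table plus a long-format metadata table, and returns an indexed
#' `edge_store`. The edge table must carry columns `analysis_id`, `tf`,
#' `target` and `edge_type`; optional columns are `log2fc`, `pvalue` and a
#' peak interval (`chrom`, `start`, `end`, 0-based half-open). Metadata is
#' long format (`analysis_id`, `key`, `value`), one record set per analysis;
#' keys are case-normalised to upper case (`EXPERIMENT_TYPE`,
#' `TECHNOLOGY/METHOD`, `TISSUE/SAMPLE`, plus arbitrary extras).
#'
#' Duplicated `(analysis_id, tf, target, edge_type)` rows are collapsed to
#' one edge with a warning. An edge referencing an analysis that has no
#' metadata record is an integrity error.
#'
#' @param edges_path path to the edge TSV.
#' @param metadata_path path to the long-format metadata TSV.
#' @return An object of class `edge_store`: a list with elements
#'   `experiments` (tibble: `analysis_id`, `tf_id`), `metadata` (tibble:
#'   `analysis_id`, `key`, `value`) and `edges` (tibble with the edge
#'   columns above).
#' @seealso [write_edge_table()], [filter_edges_open_chromatin()]
#' @export
load_edge_table <- function(edges_path, metadata_path) {
  if (!file.exists(edges_path)) .stopf("edge table not found: %s", edges_path)
  if (!file.exists(metadata_path)) .stopf("metadata table not found: %s", metadata_path)
  ed <- read.delim(edges_path, stringsAsFactors = FALSE, check.names = FALSE)
  md <- read.delim(metadata_path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("analysis_id", "tf", "target", "edge_type")
  missing <- setdiff(required, names(ed))
  if (length(missing))
    .stopf("edge table is missing required column(s): %s",
           paste(missing, collapse = ", "))
  for (col in c("log2fc", "pvalue", "chrom", "start", "end"))
    if (!col %in% names(ed)) ed[[col]] <- NA
  ed$log2fc <- suppressWarnings(as.numeric(ed$log2fc))
  ed$pvalue <- suppressWarnings(as.numeric(ed$pvalue))
  ed$chrom <- ifelse(is.na(ed$chrom) | ed$chrom == "", NA_character_,
                     as.character(ed$chrom))
  ed$start <- suppressWarnings(as.integer(ed$start))
  ed$end <- suppressWarnings(as.integer(ed$end))

  mreq <- c("analysis_id", "key", "value")
  mmiss <- setdiff(mreq, names(md))
  if (length(mmiss))
    .stopf("metadata table is missing required column(s): %s",
           paste(mmiss, collapse = ", "))
  md$key <- toupper(md$key)

  build_edge_store(edges = ed, metadata = md)
}

#' Assemble an edge store from in-memory tables
#'
#' Lower-level constructor used by [load_edge_table()] and the fixture
#' generator. Performs the same validation: deduplication of edges,
#' integrity check of `analysis_id` references, metadata key normalisation.
#'
#' @param edges data frame with columns `analysis_id`, `tf`, `target`,
#'   `edge_type` and optionally `log2fc`, `pvalue`, `chrom`, `start`, `end`.
#' @param metadata long-format data frame (`analysis_id`, `key`, `value`).
#' @return An `edge_store`.
#' @export
build_edge_store <- function(edges, metadata) {
  edges <- tibble::as_tibble(edges)
  metadata <- tibble::as_tibble(metadata)
  metadata$key <- toupper(metadata$key)
  for (col in c("log2fc", "pvalue")) {
    if (!col %in% names(edges)) edges[[col]] <- NA_real_
  }
  for (col in c("chrom", "start", "end")) {
    if (!col %in% names(edges))
      edges[[col]] <- if (col == "chrom") NA_character_ else NA_integer_
  }

  key <- paste(edges$analysis_id, edges$tf, edges$target, edges$edge_type,
               sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    .warnf("collapsed %d duplicated edge row(s)", n_dup)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }

  known <- unique(metadata$analysis_id)
  unknown <- setdiff(unique(edges$analysis_id), known)
  if (length(unknown))
    .stopf("edge(s) reference analysis_id without metadata: %s",
           paste(unknown, collapse = ", "))

  bad_p <- !is.na(edges$pvalue) & (edges$pvalue < 0 | edges$pvalue > 1)
  if (any(bad_p)) .stopf("edge pvalue outside [0,1]")
  has_peak <- !is.na(edges$chrom)
  if (any(has_peak & (is.na(edges$start) | is.na(edges$end))))
    .stopf("peak interval with missing start/end")
  if (any(has_peak & edges$start >= edges$end, na.rm = TRUE))
    .stopf("peak interval with start >= end")

  tf_of <- vapply(split(edges$tf, edges$analysis_id),
                  function(x) x[[1]], character(1))
  experiments <- tibble::tibble(
    analysis_id = known,
    tf_id = unname(tf_of[known])
  )
  # analyses with metadata but no edges keep their declared TF if present
  decl <- metadata[metadata$key == "TF_ID", c("analysis_id", "value")]
  if (nrow(decl)) {
    idx <- match(experiments$analysis_id, decl$analysis_id)
    experiments$tf_id <- ifelse(is.na(experiments$tf_id) & !is.na(idx),
                                decl$value[idx], experiments$tf_id)
  }

  structure(
    list(experiments = experiments, metadata = metadata, edges = edges),
    class = "edge_store"
  )
}

#' @export
print.edge_store <- function(x, ...) {
  cat(sprintf("<edge_store> %d experiment(s), %d edge(s), %d TF(s)\n",
              nrow(x$experiments), nrow(x$edges),
              length(unique(x$experiments$tf_id))))
  invisible(x)
}

#' Write an edge store back to the tabular exchange format
#'
#' Inverse of [load_edge_table()]: writes the edge TSV and the long-format
#' metadata TSV so that re-loading reproduces the edge multiset
#' field-for-field.
#'
#' @param store an `edge_store`.
#' @param edges_path,metadata_path output paths.
#' @return Invisibly, `store`.
#' @export
write_edge_table <- function(store, edges_path, metadata_path) {
  stopifnot(inherits(store, "edge_store"))
  ed <- store$edges[, c("analysis_id", "tf", "target", "edge_type",
                        "log2fc", "pvalue", "chrom", "start", "end")]
  write.table(ed, edges_path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  write.table(store$metadata, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(store)
}

#' Metadata of one analysis as a named character vector
#' @param store an `edge_store`.
#' @param analysis_id analysis identifier.
#' @return Named character vector of metadata values (names are upper-case
#'   keys).
#' @export
experiment_meta <- function(store, analysis_id) {
  m <- store$metadata[store$metadata$analysis_id == analysis_id, ]
  setNames(m$value, m$key)
}

#' Read a gene list (one identifier per line)
#'
#' Lines starting with `#` and blank lines are skipped; duplicates removed.
#' If `universe` is given, identifiers outside it are retained but flagged
#' in the `"unknown"` attribute.
#'
#' @param path file path.
#' @param name list name (defaults to the file base name).
#' @param universe optional character vector of known gene ids.
#' @return Character vector of gene ids with attributes `name` and
#'   (possibly) `unknown`.
#' @export
load_gene_list <- function(path, name = NULL,
                           universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- unique(lines)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  attr(genes, "name") <- name
  if (!is.null(universe)) {
    unk <- setdiff(genes, universe)
    if (length(unk)) attr(genes, "unknown") <- unk
  }
  genes
}

#' Read genomic intervals (BED) as an interval set
#'
#' Intervals are sorted and merged per chromosome; coordinates are 0-based
#' half-open, matching BED.
#'
#' @param path BED file path.
#' @param name set name.
#' @return An `interval_set`: tibble with columns `chrom`, `start`, `end`.
#' @export
load_bed_intervals <- function(path, name = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  interval_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(name)) basename(path) else name
  )
}

#' Construct an interval set (0-based half-open)
#'
#' @param chrom,start,end parallel vectors.
#' @param name optional set name.
#' @return An `interval_set` tibble, sorted and merged per chromosome.
#' @export
interval_set <- function(chrom, start, end, name = NULL) {
  if (any(start >= end)) .stopf("interval with start >= end")
  gr <- GenomicRanges::reduce(.as_granges(chrom, start, end))
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  out <- out[order(out$chrom, out$start), ]
  structure(out, class = c("interval_set", class(out)), name = name)
}

#' Keep edges whose binding peak falls in open chromatin
#'
#' Binding edges that carry a peak interval are retained iff the peak shares
#' at least one base with an interval of `intervals` (DHS/ATAC open-chromatin
#' regions). Edges without peak coordinates -- typically regulation edges --
#' pass through unchanged; their count is reported in a message. Filtering
#' is idempotent.
#'
#' @param store an `edge_store`.
#' @param intervals an `interval_set` of open-chromatin regions.
#' @return A filtered `edge_store`.
#' @export
filter_edges_open_chromatin <- function(store, intervals) {
  stopifnot(inherits(store, "edge_store"))
  if (!nrow(intervals)) .stopf("empty interval set")
  ed <- store$edges
  has_peak <- !is.na(ed$chrom) & !is.na(ed$start) & !is.na(ed$end)
  if (sum(!has_peak))
    message(sprintf("%d edge(s) without peak coordinates passed through",
                    sum(!has_peak)))
  keep <- rep(TRUE, nrow(ed))
  if (any(has_peak)) {
    peaks <- .as_granges(ed$chrom[has_peak], ed$start[has_peak],
                         ed$end[has_peak])
    dhs <- .as_granges(intervals$chrom, intervals$start, intervals$end)
    hit <- IRanges::overlapsAny(peaks, dhs)
    keep[has_peak] <- hit
  }
  store$edges <- ed[keep, , drop = FALSE]
  store
}

#' Assign peaks to nearby genes (bedtools-closest semantics)
#'
#' A peak is assigned to every gene whose span lies within `max_distance`
#' bases of the peak, distance measured between closest bases (0 when the
#' intervals overlap or are adjacent). The default 2 kb matches the rule
#' used to call bound genes from ChIP peaks.
#'
#' @param peaks an `interval_set` (or data frame with `chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param annotation a `gene_annotation` from [load_gff_annotation()].
#' @param max_distance maximum gap in bp (default 2000).
#' @return Tibble with one row per (peak, gene) assignment: `chrom`,
#'   `start`, `end`, `gene_id`, `distance`.
#' @export
assign_peaks_to_genes <- function(peaks, annotation, max_distance = 2000) {
  stopifnot(inherits(annotation, "gene_annotation"))
  pk <- .as_granges(peaks$chrom, peaks$start, peaks$end)
  g <- annotation$genes
  gn <- .as_granges(g$chrom, g$start, g$end)
  # widen gene spans past max_distance to collect candidates, then exact gap check
  hits <- GenomicRanges::findOverlaps(
    pk, gn + (max_distance + 1L), ignore.strand = TRUE)
  if (!length(hits)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), gene_id = character(),
                          distance = integer()))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(pk[qi], gn[si], ignore.strand = TRUE)
  keep <- !is.na(d) & d <= max_distance
  tibble::tibble(
    chrom = peaks$chrom[qi[keep]],
    start = as.integer(peaks$start[qi[keep]]),
    end = as.integer(peaks$end[qi[keep]]),
    gene_id = g$gene_id[si[keep]],
    distance = as.integer(d[keep])
  )
}
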