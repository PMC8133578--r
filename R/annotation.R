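#' Load a gene annotation from GFF3
#'
#' Parses gene / mRNA / exon / CDS / UTR features and converts the 1-based
#' inclusive GFF coordinates to the internal 0-based half-open convention.
#' The transcription start site (TSS) of each gene is the 5'-most position
#' of its span on the annotated strand: for a `+` strand gene it equals the
#' internal start; for a `-` strand gene it equals the internal (exclusive)
#' end, i.e. one past the 5'-most base.
#'
#' Genes lacking a strand are skipped with a warning; a CDS segment outside
#' its gene span is an integrity error. The gene universe is the set of
#' annotated protein-coding gene ids (all `gene` features by default, or
#' those with `biotype`/`gene_biotype` equal to `protein_coding` when that
#' attribute is present).
#'
#' @param gff3_path path to a GFF3 file.
#' @return A `gene_annotation`: list with `genes` (tibble: `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`), `transcripts` (tibble:
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`),
#'   `features` (tibble: `transcript_id`, `gene_id`, `type`, `chrom`,
#'   `start`, `end`, `strand`) and `universe` (character vector).
#' @export
load_gff_annotation <- function(gff3_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else NA_character_,
    parent = if ("Parent" %in% names(S4Vectors::mcols(gr)))
      vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
             character(1))
    else NA_character_
  )
  biotype <- rep(NA_character_, nrow(df))
  for (col in c("biotype", "gene_biotype"))
    if (col %in% names(S4Vectors::mcols(gr)))
      biotype <- ifelse(is.na(biotype),
                        as.character(S4Vectors::mcols(gr)[[col]]), biotype)

  is_gene <- df$type == "gene"
  genes <- df[is_gene, ]
  gene_bio <- biotype[is_gene]
  no_strand <- !genes$strand %in% c("+", "-")
  if (any(no_strand)) {
    .warnf("skipped %d gene record(s) without strand", sum(no_strand))
    genes <- genes[!no_strand, ]
    gene_bio <- gene_bio[!no_strand]
  }
  genes_tbl <- tibble::tibble(
    gene_id = genes$id,
    chrom = genes$chrom,
    strand = genes$strand,
    start = genes$start,
    end = genes$end,
    tss = ifelse(genes$strand == "+", genes$start, genes$end)
  )

  tx_types <- c("mRNA", "transcript")
  tx <- df[df$type %in% tx_types & df$parent %in% genes_tbl$gene_id, ]
  transcripts <- tibble::tibble(
    transcript_id = tx$id, gene_id = tx$parent, chrom = tx$chrom,
    strand = tx$strand, start = tx$start, end = tx$end
  )

  ft_types <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  ft <- df[df$type %in% ft_types & df$parent %in% transcripts$transcript_id, ]
  gene_of_tx <- setNames(transcripts$gene_id, transcripts$transcript_id)
  features <- tibble::tibble(
    transcript_id = ft$parent,
    gene_id = unname(gene_of_tx[ft$parent]),
    type = ft$type, chrom = ft$chrom,
    start = ft$start, end = ft$end, strand = ft$strand
  )

  cds <- features[features$type == "CDS", ]
  if (nrow(cds)) {
    gi <- match(cds$gene_id, genes_tbl$gene_id)
    bad <- cds$start < genes_tbl$start[gi] | cds$end > genes_tbl$end[gi]
    if (any(bad))
      .stopf("CDS outside gene span for gene(s): %s",
             paste(unique(cds$gene_id[bad]), collapse = ", "))
  }

  universe <- genes_tbl$gene_id
  coding <- !is.na(gene_bio)
  if (any(coding)) universe <- genes_tbl$gene_id[
    is.na(gene_bio) | gene_bio == "protein_coding"]

  structure(
    list(genes = genes_tbl, transcripts = transcripts, features = features,
         universe = universe),
    class = "gene_annotation"
  )
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d gene(s), %d transcript(s) on %d sequence(s)\n",
              nrow(x$genes), nrow(x$transcripts), length(unique(x$genes$chrom))))
  invisible(x)
}
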