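#' Specification for the synthetic compendium generator
#'
#' The defaults describe the regime the generator emulates: a handful of
#' TFs, each with a TF-perturbation (expression) experiment whose targets
#' are largely also bound by the TF, and a binding (ChIP) experiment whose
#' bound genes are mostly *not* regulated — the characteristic asymmetry of
#' TF-regulation versus TF-binding data. A consensus motif is planted in
#' the promoters of the first TF's regulated targets, and a ranked
#' predicted network carries the gold regulation edges at the top ranks
#' plus Gaussian score noise.
#'
#' @param seed integer seed; the same seed yields byte-identical output
#'   files.
#' @param n_genes number of genes in the genome/universe.
#' @param n_tfs number of TFs (the first `n_tfs` genes).
#' @param n_regulated regulated targets per TF.
#' @param frac_induced fraction of regulated targets with positive log2
#'   fold-change.
#' @param beta fraction of regulated targets that are also bound.
#' @param bound_reg_ratio fraction of bound genes that are regulated
#'   (sets the size of the bound-but-not-regulated pool).
#' @param motif_plant_rate probability that a designated target promoter
#'   receives a planted consensus site.
#' @param n_decoys unregulated decoy edges per TF in the predicted
#'   network.
#' @param sigma standard deviation of the Gaussian score noise in the
#'   predicted network (0 ranks all gold edges strictly first).
#' @param dhs_fraction fraction of binding peaks covered by the
#'   open-chromatin interval set.
#' @param n_tf2 number of secondary TFs planted as direct (regulated and
#'   bound) targets of the first TF, enabling Network Walking.
#' @param tf2_indirect_frac fraction of the first TF's indirect targets
#'   each secondary TF regulates.
#' @param gene_length,intergenic gene-slot geometry in bp (the intergenic
#'   gap must exceed the largest promoter window).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 2000L, n_tfs = 5L,
                         n_regulated = 40L, frac_induced = 0.5,
                         beta = 0.75, bound_reg_ratio = 0.25,
                         motif_plant_rate = 0.9, n_decoys = 160L,
                         sigma = 0.1, dhs_fraction = 0.6,
                         n_tf2 = 2L, tf2_indirect_frac = 0.4,
                         gene_length = 600L, intergenic = 2400L) {
  sp <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
             n_tfs = as.integer(n_tfs), n_regulated = as.integer(n_regulated),
             frac_induced = frac_induced, beta = beta,
             bound_reg_ratio = bound_reg_ratio,
             motif_plant_rate = motif_plant_rate,
             n_decoys = as.integer(n_decoys), sigma = sigma,
             dhs_fraction = dhs_fraction,
             n_tf2 = as.integer(min(n_tf2, n_tfs - 1L)),
             tf2_indirect_frac = tf2_indirect_frac,
             gene_length = as.integer(gene_length),
             intergenic = as.integer(intergenic))
  if (sp$n_genes < sp$n_tfs + sp$n_regulated)
    .stopf("n_genes too small for n_tfs + n_regulated")
  for (f in c("frac_induced", "beta", "bound_reg_ratio",
              "motif_plant_rate", "dhs_fraction", "tf2_indirect_frac"))
    if (sp[[f]] < 0 || sp[[f]] > 1) .stopf("%s must lie in [0,1]", f)
  if (sp$intergenic < 2000)
    .stopf("intergenic gap must cover the largest promoter window (2000 bp)")
  structure(sp, class = "fixture_spec")
}

.consensus_to_pwm <- function(id, consensus, major = 0.85) {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - major) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- major
  pwm(id, m)
}

#' Generate a complete synthetic compendium
#'
#' Writes, under `dir`: `genome.fa`, `annotation.gff3`, `edges.tsv`,
#' `metadata.tsv`, `motifs.meme`, `clusters.tsv`, `network.tsv`,
#' `dhs.bed`, `background.txt` and `list_regulated_<tf1>.txt`, all in the
#' exchange formats consumed by the package's readers, plus a
#' `manifest.json` recording the spec. Regulation edges carry signed
#' log2 fold-changes and p-values; binding edges carry peak intervals
#' within 2 kb of their target gene; the consensus site of motif `M1` is
#' planted in promoters of the first TF's regulated targets.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a manifest list: file `paths`, the `spec`, per-TF
#'   `regulated` and `bound` gene sets, the `gold` pair tibble, planted
#'   gene set and motif consensus.
#' @export
generate_compendium <- function(spec = fixture_spec(), dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)

  n <- spec$n_genes
  slot <- spec$gene_length + spec$intergenic
  gene_id <- sprintf("G%05d", seq_len(n))
  strand <- rep(c("+", "-"), length.out = n)
  gstart <- (seq_len(n) - 1L) * slot + spec$intergenic  # 0-based
  gend <- gstart + spec$gene_length
  tss <- ifelse(strand == "+", gstart, gend)
  genome_len <- n * slot + spec$intergenic

  tfs <- gene_id[seq_len(spec$n_tfs)]
  non_tf <- gene_id[-seq_len(spec$n_tfs)]

  ## --- edges + metadata -------------------------------------------------
  n_reg <- spec$n_regulated
  n_bound_reg <- round(spec$beta * n_reg)
  n_bound <- round(n_bound_reg / spec$bound_reg_ratio)
  n_bound_other <- n_bound - n_bound_reg

  regulated <- list()
  bound <- list()
  edge_rows <- list()
  meta_rows <- list()
  add_meta <- function(aid, ...) {
    kv <- list(...)
    meta_rows[[length(meta_rows) + 1L]] <<- tibble::tibble(
      analysis_id = aid, key = names(kv), value = unlist(kv))
  }
  peak_rows <- list()

  tf1 <- tfs[1]
  tf2s <- if (spec$n_tf2 > 0) tfs[1L + seq_len(spec$n_tf2)] else character(0)
  indirect1 <- character(0)

  for (tf in tfs) {
    if (tf == tf1) {
      # TF2s are planted as regulated (and below, bound) targets of TF1
      reg <- sort(c(tf2s, sample(non_tf, n_reg - length(tf2s))))
    } else if (tf %in% tf2s) {
      # each TF2 regulates a slice of TF1's indirect targets
      take <- sort(sample(indirect1,
                          round(spec$tf2_indirect_frac * length(indirect1))))
      reg <- sort(c(take, sample(setdiff(non_tf, take),
                                 n_reg - length(take))))
    } else {
      reg <- sort(sample(non_tf, n_reg))
    }
    regulated[[tf]] <- reg
    n_up <- round(spec$frac_induced * n_reg)
    sign <- rep(c(1, -1), c(n_up, n_reg - n_up))
    l2fc <- sign * abs(rnorm(n_reg, mean = 2, sd = 0.5))
    pv <- 10^-runif(n_reg, 2, 8)
    aid_r <- paste0(tolower(tf), "_target")
    edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
      analysis_id = aid_r, tf = tf, target = reg,
      edge_type = ifelse(sign > 0, "Expression:induced",
                         "Expression:repressed"),
      log2fc = l2fc, pvalue = pv,
      chrom = NA_character_, start = NA_integer_, end = NA_integer_)
    add_meta(aid_r, TF_ID = tf, EXPERIMENT_TYPE = "Expression",
             `TECHNOLOGY/METHOD` = "RNAseq",
             `TISSUE/SAMPLE` = "Root Protoplasts")

    bnd_reg <- if (tf == tf1)
      sort(c(tf2s, sample(setdiff(reg, tf2s), n_bound_reg - length(tf2s))))
    else sort(sample(reg, n_bound_reg))
    bnd_oth <- sort(sample(setdiff(non_tf, reg), n_bound_other))
    bnd <- c(bnd_reg, bnd_oth)
    bound[[tf]] <- bnd
    if (tf == tf1) indirect1 <- setdiff(reg, bnd)
    gi <- match(bnd, gene_id)
    # 200-bp peak on the promoter side of the TSS, within the 2-kb rule
    off <- sample(300:900, length(bnd), replace = TRUE)
    pstart <- ifelse(strand[gi] == "+", tss[gi] - off - 200L, tss[gi] + off)
    pend <- pstart + 200L
    aid_b <- paste0(tolower(tf), "_chip")
    edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
      analysis_id = aid_b, tf = tf, target = bnd,
      edge_type = "in planta:Bound",
      log2fc = NA_real_, pvalue = NA_real_,
      chrom = "chr1", start = as.integer(pstart), end = as.integer(pend))
    add_meta(aid_b, TF_ID = tf, EXPERIMENT_TYPE = "Binding",
             `TECHNOLOGY/METHOD` = "ChIPseq", `TISSUE/SAMPLE` = "Roots")
    peak_rows[[length(peak_rows) + 1L]] <-
      tibble::tibble(chrom = "chr1", start = as.integer(pstart),
                     end = as.integer(pend))
  }
  edges <- do.call(rbind, edge_rows)
  metadata <- do.call(rbind, meta_rows)

  ## --- genome + planted motifs ------------------------------------------
  bases <- c("A", "C", "G", "T")
  genome <- sample(bases, genome_len, replace = TRUE)
  consensus <- "TGACGTCA"
  planted_pool <- regulated[[tfs[1]]]
  planted <- planted_pool[runif(length(planted_pool)) < spec$motif_plant_rate]
  for (g in planted) {
    gi <- match(g, gene_id)
    # centre of the 500-bp promoter window
    pos0 <- if (strand[gi] == "+") tss[gi] - 250L else tss[gi] + 250L
    genome[(pos0 + 1L):(pos0 + nchar(consensus))] <-
      strsplit(consensus, "")[[1]]
  }

  ## --- predicted network -------------------------------------------------
  gold <- tibble::tibble(
    tf = rep(names(regulated), vapply(regulated, length, integer(1))),
    target = unlist(regulated, use.names = FALSE))
  net_rows <- list(gold)
  for (tf in tfs) {
    dec <- sort(sample(setdiff(non_tf, regulated[[tf]]), spec$n_decoys))
    net_rows[[length(net_rows) + 1L]] <- tibble::tibble(tf = tf, target = dec)
  }
  net <- do.call(rbind, net_rows)
  is_gold <- paste(net$tf, net$target, sep = "\r") %in%
    paste(gold$tf, gold$target, sep = "\r")
  net$score <- as.numeric(is_gold) + rnorm(nrow(net), sd = spec$sigma)

  ## --- DHS intervals ------------------------------------------------------
  peaks <- unique(do.call(rbind, peak_rows))
  sel <- sort(sample(nrow(peaks), round(spec$dhs_fraction * nrow(peaks))))
  dhs <- peaks[sel, ]
  dhs$start <- pmax(0L, dhs$start - 50L)
  dhs$end <- dhs$end + 50L

  ## --- write everything ---------------------------------------------------
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gff3"),
    edges = file.path(dir, "edges.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    motifs = file.path(dir, "motifs.meme"),
    clusters = file.path(dir, "clusters.tsv"),
    network = file.path(dir, "network.tsv"),
    dhs = file.path(dir, "dhs.bed"),
    background = file.path(dir, "background.txt"),
    regulated_list = file.path(dir,
                               paste0("list_regulated_", tolower(tfs[1]),
                                      ".txt")),
    manifest = file.path(dir, "manifest.json")
  )

  seq <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(seq) <- "chr1"
  Biostrings::writeXStringSet(seq, paths$genome)

  .write_fixture_gff3(paths$annotation, gene_id, strand, gstart, gend)

  write.table(edges, paths$edges, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.table(metadata, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")

  pwms <- list(.consensus_to_pwm("M1", consensus),
               .consensus_to_pwm("M2", "GATCCGGA"))
  write_meme(pwms, paths$motifs)
  write.table(data.frame(motif_id = c("M1", "M2"),
                         cluster_id = c("C1", "C2")),
              paths$clusters, sep = "\t", quote = FALSE, row.names = FALSE)

  write.table(net, paths$network, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(sprintf("chr1\t%d\t%d", dhs$start, dhs$end), paths$dhs)
  writeLines(gene_id, paths$background)
  writeLines(regulated[[tfs[1]]], paths$regulated_list)

  manifest <- list(spec = unclass(spec), tfs = tfs,
                   consensus = consensus, planted = planted,
                   n_genes = n, files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(paths = paths, spec = spec, gene_id = gene_id, tfs = tfs,
                 regulated = regulated, bound = bound, gold = gold,
                 network = predicted_network(net$tf, net$target, net$score,
                                             name = "fixture"),
                 planted = planted, consensus = consensus,
                 strand = strand, tss = tss))
}

.write_fixture_gff3 <- function(path, gene_id, strand, gstart, gend) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  n <- length(gene_id)
  lines <- character(0)
  for (i in seq_len(n)) {
    g0 <- gstart[i]; g1 <- gend[i]; st <- strand[i]; id <- gene_id[i]
    # internal 0-based half-open -> GFF 1-based inclusive
    gff <- function(type, s0, e0, ident, parent = NULL) {
      attrs <- paste0("ID=", ident,
                      if (!is.null(parent)) paste0(";Parent=", parent) else "",
                      if (type == "gene") ";biotype=protein_coding" else "")
      sprintf("chr1\tfixture\t%s\t%d\t%d\t.\t%s\t.\t%s",
              type, s0 + 1L, e0, st, attrs)
    }
    tid <- paste0(id, ".1")
    len <- g1 - g0
    # two exons with a central intron; 100-bp UTRs at each transcript end
    ex1 <- c(g0, g0 + floor(len * 5 / 12))
    ex2 <- c(g0 + floor(len * 7 / 12), g1)
    utr_left <- c(g0, g0 + 100L)
    utr_right <- c(g1 - 100L, g1)
    cds1 <- c(utr_left[2], ex1[2])
    cds2 <- c(ex2[1], utr_right[1])
    five <- if (st == "+") utr_left else utr_right
    three <- if (st == "+") utr_right else utr_left
    lines <- c(lines,
               gff("gene", g0, g1, id),
               gff("mRNA", g0, g1, tid, id),
               gff("exon", ex1[1], ex1[2], paste0(tid, ".e1"), tid),
               gff("exon", ex2[1], ex2[2], paste0(tid, ".e2"), tid),
               gff("five_prime_UTR", five[1], five[2],
                   paste0(tid, ".u5"), tid),
               gff("CDS", cds1[1], cds1[2], paste0(tid, ".c1"), tid),
               gff("CDS", cds2[1], cds2[2], paste0(tid, ".c2"), tid),
               gff("three_prime_UTR", three[1], three[2],
                   paste0(tid, ".u3"), tid))
  }
  writeLines(lines, con)
}

#' Micro-fixtures for the worked examples
#'
#' Deterministic miniature inputs reused across the documentation and
#' tests: the 6-bp scan sequence with its AC dinucleotide motif, the
#' 4-edge precision/recall example with 2 gold positives, and the two
#' disjoint 5-gene Sungear lists (x = 10).
#'
#' @return List with components `scan` (list: `sequence`, `pwm`,
#'   `background`), `pr` (list: `network`, `gold`) and `sungear_lists`.
#' @export
generate_worked_example <- function() {
  eps <- 1e-3
  acm <- matrix(eps, nrow = 4, ncol = 2,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  acm["A", 1] <- 1 - 3 * eps
  acm["C", 2] <- 1 - 3 * eps
  scan <- list(
    sequence = c(seq1 = "TTACGT"),
    pwm = pwm("AC", acm),
    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  )

  net <- predicted_network(
    tf = rep("TF1", 4),
    target = c("t1", "t2", "t3", "t4"),
    score = c(0.9, 0.8, 0.7, 0.6),
    name = "worked_pr"
  )
  gold <- structure(
    list(pairs = tibble::tibble(tf = c("TF1", "TF1"),
                                target = c("t1", "t3")),
         tfs = "TF1",
         background = c("t1", "t2", "t3", "t4")),
    class = "gold_standard")

  list(
    scan = scan,
    pr = list(network = net, gold = gold),
    sungear_lists = list(A = paste0("a", 1:5), B = paste0("b", 1:5))
  )
}
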