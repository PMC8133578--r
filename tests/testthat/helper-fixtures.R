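# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# full-size compendium at generator defaults (the study conditions)
default_fixture <- function() {
  if (is.null(.fixture_cache$default)) {
    dir <- file.path(tempdir(), "regnet_fixture_default")
    .fixture_cache$default <- generate_compendium(fixture_spec(seed = 101L),
                                                  dir)
  }
  .fixture_cache$default
}

# compact compendium for genome-scale motif work
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    dir <- file.path(tempdir(), "regnet_fixture_small")
    .fixture_cache$small <- generate_compendium(
      fixture_spec(seed = 202L, n_genes = 300L, n_tfs = 3L,
                   n_regulated = 20L, n_decoys = 60L, n_tf2 = 0L),
      dir)
  }
  .fixture_cache$small
}

default_store <- function() {
  if (is.null(.fixture_cache$store)) {
    fx <- default_fixture()
    .fixture_cache$store <- load_edge_table(fx$paths$edges,
                                            fx$paths$metadata)
  }
  .fixture_cache$store
}

# genome-wide scan + per-region counts on the small fixture, cached
small_fixture_counts <- function() {
  if (is.null(.fixture_cache$counts)) {
    fx <- small_fixture()
    pwms <- read_meme(fx$paths$motifs)
    hits <- remove_overlaps(scan_pwm(fx$paths$genome, pwms, scan_params()))
    idx <- build_region_index(load_gff_annotation(fx$paths$annotation))
    .fixture_cache$counts <- list(hits = hits, index = idx,
                                  counts = count_hits_by_region(hits, idx))
  }
  .fixture_cache$counts
}

# tiny handwritten store: one TF, one expression and one ChIP experiment
# (exp targets {g1,g2,g3} with signed log2fc, chip targets {g2,g3,g4})
toy_store <- function() {
  edges <- data.frame(
    analysis_id = c(rep("exp1", 3), rep("chip1", 3)),
    tf = "TF1",
    target = c("g1", "g2", "g3", "g2", "g3", "g4"),
    edge_type = c("Expression:induced", "Expression:repressed",
                  "Expression:induced", rep("in planta:Bound", 3)),
    log2fc = c(2, -1, 1.5, NA, NA, NA),
    pvalue = c(1e-4, 1e-3, 1e-5, NA, NA, NA),
    chrom = c(NA, NA, NA, "chr1", "chr1", "chr1"),
    start = c(NA, NA, NA, 100L, 500L, 900L),
    end = c(NA, NA, NA, 300L, 700L, 1100L)
  )
  metadata <- data.frame(
    analysis_id = rep(c("exp1", "chip1"), each = 3),
    key = rep(c("EXPERIMENT_TYPE", "TECHNOLOGY/METHOD", "TISSUE/SAMPLE"), 2),
    value = c("Expression", "RNAseq", "Root Protoplasts",
              "Binding", "ChIPseq", "Roots")
  )
  build_edge_store(edges, metadata)
}

write_toy_tables <- function(dir = tempfile("store")) {
  dir.create(dir)
  st <- toy_store()
  write_edge_table(st, file.path(dir, "edges.tsv"),
                   file.path(dir, "metadata.tsv"))
  list(edges = file.path(dir, "edges.tsv"),
       metadata = file.path(dir, "metadata.tsv"))
}

# minimal two-gene GFF3 (one per strand) for coordinate-convention tests
write_toy_gff <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1001\t2000\t.\t+\t.\tID=gp;biotype=protein_coding",
    "chr1\ttoy\tmRNA\t1001\t2000\t.\t+\t.\tID=gp.1;Parent=gp",
    "chr1\ttoy\texon\t1001\t1400\t.\t+\t.\tID=gp.1.e1;Parent=gp.1",
    "chr1\ttoy\texon\t1601\t2000\t.\t+\t.\tID=gp.1.e2;Parent=gp.1",
    "chr1\ttoy\tCDS\t1101\t1400\t.\t+\t.\tID=gp.1.c1;Parent=gp.1",
    "chr1\ttoy\tCDS\t1601\t1900\t.\t+\t.\tID=gp.1.c2;Parent=gp.1",
    "chr1\ttoy\tfive_prime_UTR\t1001\t1100\t.\t+\t.\tID=gp.1.u5;Parent=gp.1",
    "chr1\ttoy\tthree_prime_UTR\t1901\t2000\t.\t+\t.\tID=gp.1.u3;Parent=gp.1",
    "chr1\ttoy\tgene\t5001\t6000\t.\t-\t.\tID=gm;biotype=protein_coding",
    "chr1\ttoy\tmRNA\t5001\t6000\t.\t-\t.\tID=gm.1;Parent=gm",
    "chr1\ttoy\texon\t5001\t6000\t.\t-\t.\tID=gm.1.e1;Parent=gm.1"
  ), path)
  path
}
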