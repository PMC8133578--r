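test_that("the dinucleotide worked example scans on both strands with exact p", {
  wx <- generate_worked_example()
  h <- scan_pwm(wx$scan$sequence, wx$scan$pwm,
                scan_params(p_threshold = 0.07,
                            background = wx$scan$background,
                            pseudocount = 0))
  expect_equal(nrow(h), 2L)
  fwd <- h[h$strand == "+", ]
  rev <- h[h$strand == "-", ]
  expect_equal(c(fwd$start, fwd$end), c(2L, 4L))  # "AC" in TTACGT
  expect_equal(c(rev$start, rev$end), c(4L, 6L))  # "GT" = revcomp(AC)
  expect_equal(h$pvalue, c(1 / 16, 1 / 16))

  # at the default genome-scan threshold 1e-4 the same scan yields nothing
  h0 <- scan_pwm(wx$scan$sequence, wx$scan$pwm,
                 scan_params(background = wx$scan$background,
                             pseudocount = 0))
  expect_equal(nrow(h0), 0L)
})

test_that("DP p-values equal exhaustive word enumeration for random PWMs", {
  set.seed(7)
  for (i in 1:12) {
    w <- sample(2:6, 1)
    p <- random_pwm(w)
    bg <- runif(4, 0.5, 1.5)
    bg <- bg / sum(bg)
    names(bg) <- c("A", "C", "G", "T")
    dist <- pwm_score_distribution(p, bg, granularity = 1e-3,
                                   pseudocount = 1e-4)
    sm <- regnet:::.pwm_score_matrices(p, bg, 1e-3, 1e-4)
    oracle <- pwm_enum_oracle(sm$int, unname(bg))
    for (s in sample(dist$score_int, min(10, nrow(dist)))) {
      expect_equal(dist$p_ge[dist$score_int == s], oracle(s),
                   tolerance = 1e-11)
    }
    expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
  }
})

test_that("scanning is strand-symmetric under reverse complementation", {
  set.seed(13)
  for (i in 1:10) {
    L <- sample(50:150, 1)
    s <- random_sequence(L)
    p <- random_pwm(sample(3:6, 1))
    pars <- scan_params(p_threshold = 0.05,
                        background = c(A = 0.25, C = 0.25,
                                       G = 0.25, T = 0.25))
    h1 <- scan_pwm(c(chr = s), p, pars)
    h2 <- scan_pwm(c(chr = revcomp_chr(s)), p, pars)
    # a hit at [s,e) on one strand mirrors to [L-e, L-s) on the other
    mirror <- data.frame(start = L - h2$end, end = L - h2$start,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         pvalue = h2$pvalue)
    o1 <- h1[order(h1$start, h1$strand), c("start", "end", "strand", "pvalue")]
    o2 <- mirror[order(mirror$start, mirror$strand), ]
    expect_equal(as.data.frame(o1), as.data.frame(o2),
                 ignore_attr = TRUE)
  }
})

test_that("overlap removal keeps lowest-p non-overlapping hits per motif", {
  mk <- function(start, end, pvalue, strand = "+", motif = "M") {
    tibble::tibble(motif_id = motif, chrom = "c", start = start, end = end,
                   strand = strand, score = 1, pvalue = pvalue)
  }
  h <- rbind(mk(10, 18, 1e-6), mk(14, 22, 1e-5), mk(30, 38, 1e-7))
  kept <- remove_overlaps(h)
  expect_equal(sort(kept$start), c(10, 30))

  # identical p: leftmost kept
  h2 <- rbind(mk(10, 18, 1e-6), mk(14, 22, 1e-6))
  expect_equal(remove_overlaps(h2)$start, 10)

  # chain A-B-C with p(A) < p(C) < p(B): keep A and C
  h3 <- rbind(mk(0, 10, 1e-8), mk(8, 18, 1e-4), mk(16, 26, 1e-6))
  expect_equal(sort(remove_overlaps(h3)$start), c(0, 16))

  # different motifs are never pruned against each other
  h4 <- rbind(mk(10, 18, 1e-6, motif = "M1"), mk(12, 20, 1e-5, motif = "M2"))
  expect_equal(nrow(remove_overlaps(h4)), 2L)
})

test_that("overlap removal matches the brute-force greedy oracle", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    st <- sample(0:60, n, replace = TRUE)
    h <- tibble::tibble(
      motif_id = "M", chrom = "c",
      start = st, end = st + sample(4:12, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      score = 1, pvalue = signif(10^-runif(n, 1, 8), 3))
    got <- remove_overlaps(h)
    want <- h[greedy_overlap_oracle(h), ]
    expect_setequal(paste(got$start, got$end, got$pvalue),
                    paste(want$start, want$end, want$pvalue))
    # result is pairwise non-overlapping and maximal (no excluded hit fits)
    if (nrow(got) > 1) {
      for (a in 1:(nrow(got) - 1)) for (b in (a + 1):nrow(got))
        expect_true(got$start[a] >= got$end[b] || got$end[a] <= got$start[b])
    }
    excluded <- h[!paste(h$start, h$end, h$pvalue) %in%
                    paste(got$start, got$end, got$pvalue), ]
    if (nrow(excluded)) {
      for (e in seq_len(nrow(excluded)))
        expect_true(any(excluded$start[e] < got$end &
                          excluded$end[e] > got$start))
    }
  }
})

test_that("region index follows promoter, intron and strand conventions", {
  ann <- load_gff_annotation(write_toy_gff())
  idx <- build_region_index(ann)
  # + strand gene: TSS 1000, promoter500 = [500, 1000)
  p5 <- idx[idx$gene_id == "gp" & idx$region == "promoter500", ]
  expect_equal(c(p5$start, p5$end), c(500L, 1000L))
  # - strand gene: TSS 6000 (internal), promoter500 = [6000, 6500)
  m5 <- idx[idx$gene_id == "gm" & idx$region == "promoter500", ]
  expect_equal(c(m5$start, m5$end), c(6000L, 6500L))
  # promoter clipped at chromosome start
  ann2 <- ann
  ann2$genes$start[1] <- 300L
  ann2$genes$tss[1] <- 300L
  idx2 <- build_region_index(ann2)
  p2k <- idx2[idx2$gene_id == "gp" & idx2$region == "promoter2000", ]
  expect_equal(p2k$start, 0L)
  # two-exon transcript: intron is the gap between exon intervals
  intr <- idx[idx$gene_id == "gp" & idx$region == "intron", ]
  expect_equal(c(intr$start, intr$end), c(1400L, 1600L))
  # cdna = transcribed span
  cdna <- idx[idx$gene_id == "gp" & idx$region == "cdna", ]
  expect_equal(c(cdna$start, cdna$end), c(1000L, 2000L))
})

test_that("hit counting honours sharing, multi-interval regions and nesting", {
  ann <- load_gff_annotation(write_toy_gff())
  idx <- build_region_index(ann)
  hits <- tibble::tibble(
    motif_id = "M1", chrom = "c",
    start = 0L, end = 0L, strand = "+", score = 1, pvalue = 1e-6)
  hits$chrom <- "chr1"
  # a hit in promoter500 of gp counts in all three nested promoters
  hits$start <- 700L
  hits$end <- 708L
  cnt <- count_hits_by_region(hits, idx)
  expect_setequal(cnt$region[cnt$gene_id == "gp"],
                  c("promoter500", "promoter1000", "promoter2000"))

  # hit straddling the exon/intron boundary counts in both
  h2 <- hits
  h2$start <- 1396L
  h2$end <- 1404L
  c2 <- count_hits_by_region(h2, idx)
  expect_true(all(c("exon", "intron") %in% c2$region[c2$gene_id == "gp"]))

  # a window shared by two genes counts for both
  gshare <- ann
  gshare$genes <- rbind(gshare$genes, gshare$genes[1, ])
  gshare$genes$gene_id[3] <- "gp2"
  gshare$transcripts <- gshare$transcripts[0, ]
  gshare$features <- gshare$features[0, ]
  idx3 <- suppressWarnings(build_region_index(gshare))
  c3 <- count_hits_by_region(hits, idx3)
  expect_true(all(c("gp", "gp2") %in% c3$gene_id))

  # nested promoter monotonicity on scanned fixture hits
  cg <- small_fixture_counts()$counts
  wide <- function(region) {
    z <- cg[cg$region == region, ]
    setNames(z$count, paste(z$motif_id, z$gene_id))
  }
  p500 <- wide("promoter500")
  p1000 <- wide("promoter1000")
  p2000 <- wide("promoter2000")
  for (k in names(p500)) {
    expect_lte(p500[[k]], if (k %in% names(p1000)) p1000[[k]] else Inf)
  }
  for (k in names(p1000)) {
    expect_lte(p1000[[k]], if (k %in% names(p2000)) p2000[[k]] else Inf)
  }
})

test_that("planted promoter motifs are detected as enriched where planted", {
  fx <- small_fixture()
  cg <- small_fixture_counts()$counts
  me <- motif_enrichment(cg, list(planted = fx$planted), fx$gene_id,
                         regions = c("promoter500", "cds"))
  m1p <- me[me$motif_id == "M1" & me$region == "promoter500", ]
  m1c <- me[me$motif_id == "M1" & me$region == "cds", ]
  expect_lt(m1p$p_adj, 0.05)
  expect_gt(m1c$p_adj, 0.05)
  # the un-planted control motif is not enriched anywhere
  m2 <- me[me$motif_id == "M2", ]
  expect_true(all(m2$p_adj > 0.05))

  # motif absent everywhere inside a region: untestable, p = 1
  cg0 <- cg[cg$region == "never", ]
  me0 <- motif_enrichment(cg0, list(planted = fx$planted), fx$gene_id,
                          regions = "promoter500", motifs = "M1")
  expect_true(me0$untestable)
  expect_equal(me0$p_raw, 1)
})

test_that("MEME round-trip preserves matrices and cluster aggregation sums", {
  p1 <- random_pwm(5, "A1")
  p2 <- random_pwm(7, "B2")
  f <- tempfile(fileext = ".meme")
  write_meme(list(p1, p2), f, background = c(A = 0.3, C = 0.2,
                                             G = 0.2, T = 0.3))
  back <- read_meme(f)
  expect_setequal(names(back), c("A1", "B2"))
  expect_equal(back$A1$mat, p1$mat, tolerance = 1e-5)
  expect_equal(attr(back, "background"),
               c(A = 0.3, C = 0.2, G = 0.2, T = 0.3), tolerance = 1e-5)

  cnt <- tibble::tibble(
    motif_id = c("A1", "B2", "A1"), gene_id = c("g1", "g1", "g2"),
    region = "promoter500", count = c(2L, 3L, 1L))
  cl <- cluster_counts(cnt, c(A1 = "C9", B2 = "C9"))
  expect_equal(cl$count[cl$gene_id == "g1"], 5L)
})
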