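test_that("gold standards deduplicate pairs and respect the background", {
  st <- toy_store()
  r <- evaluate_query("TF1", st)
  gs <- make_gold_standard(r, c("g1", "g2", "g3", "g4"))
  expect_equal(nrow(gs$pairs), 4L)   # g2/g3 validated twice count once
  expect_equal(gs$tfs, "TF1")
  expect_warning(gs2 <- make_gold_standard(r, c("g1", "g2")), "dropped")
  expect_equal(nrow(gs2$pairs), 2L)
  expect_error(make_gold_standard(r, "zz"), "background")
})

test_that("the 4-edge worked curve reproduces the cumulative-count oracle", {
  wx <- generate_worked_example()
  cv <- precision_recall_curve(wx$pr$network, wx$pr$gold)
  expect_equal(cv$curve$precision, c(1, 0.5, 2 / 3, 0.5))
  expect_equal(cv$curve$recall, c(0.5, 0.5, 1, 1))
  expect_equal(aupr(cv), 5 / 6)
  orc <- pr_oracle(wx$pr$network$score,
                   wx$pr$network$target %in% c("t1", "t3"))
  expect_equal(cv$curve$precision, orc$precision)
  expect_equal(aupr(cv), orc$aupr)

  # perfect ranking and the single-positive degenerate case give AUPR 1
  perfect <- predicted_network("TF1", c("t1", "t3", "t2", "t4"),
                               c(4, 3, 2, 1) / 4)
  expect_equal(aupr(precision_recall_curve(perfect, wx$pr$gold)), 1)
  single <- predicted_network("TF1", "t1", 1)
  expect_equal(aupr(precision_recall_curve(single, wx$pr$gold)), 1)

  # edges of TFs without gold data are excluded from the curve but kept
  # for pruning
  net2 <- predicted_network(c(rep("TF1", 4), "TFX"),
                            c("t1", "t2", "t3", "t4", "t1"),
                            c(0.9, 0.8, 0.7, 0.6, 0.95))
  cv2 <- precision_recall_curve(net2, wx$pr$gold)
  expect_equal(cv2$n_evaluable, 4L)
  pr2 <- prune_at_precision(net2, cv2, 2 / 3)
  expect_true("TFX" %in% pr2$edges$tf)

  expect_error(precision_recall_curve(
    predicted_network("TF1", "t2", 1), wx$pr$gold), "positive")
})

test_that("random curves agree with the oracle and keep recall monotone", {
  set.seed(41)
  for (i in 1:15) {
    n <- sample(10:60, 1)
    targets <- paste0("t", 1:n)
    gold_t <- sample(targets, sample(2:(n %/% 2), 1))
    gs <- structure(list(pairs = tibble::tibble(tf = "TF", target = gold_t),
                         tfs = "TF", background = targets),
                    class = "gold_standard")
    net <- predicted_network(rep("TF", n), targets, runif(n))
    cv <- precision_recall_curve(net, gs)
    orc <- pr_oracle(cv$curve$score, cv$curve$label)
    expect_equal(cv$curve$precision, orc$precision, tolerance = 1e-12)
    expect_equal(aupr(cv), orc$aupr, tolerance = 1e-12)
    expect_true(all(diff(cv$curve$recall) >= 0))
    expect_true(all(cv$curve$tp <= seq_len(n)))
    expect_gte(aupr(cv), 0)
    expect_lte(aupr(cv), 1)
    expect_equal(cv$curve$recall[n], 1)
  }
})

test_that("pruning applies the induced threshold to all edges, monotonically", {
  wx <- generate_worked_example()
  cv <- precision_recall_curve(wx$pr$network, wx$pr$gold)
  pr <- prune_at_precision(wx$pr$network, cv, 2 / 3)
  expect_equal(pr$score_threshold, 0.7)
  expect_setequal(pr$edges$target, c("t1", "t2", "t3"))
  expect_equal(c(pr$n_edges, pr$n_tfs, pr$n_targets), c(3L, 1L, 3L))

  # cutoff 1.0 keeps the leading all-positive prefix
  pr1 <- prune_at_precision(wx$pr$network, cv, 1.0)
  expect_equal(pr1$edges$target, "t1")
  # unattainable cutoff: empty with warning
  perfect <- precision_recall_curve(
    predicted_network("TF1", c("t1", "t3"), c(2, 1)), wx$pr$gold)
  expect_warning(
    pr0 <- prune_at_precision(wx$pr$network, cv, 0.99), NA)  # 1.0 attainable
  expect_warning(prx <- prune_at_precision(
    wx$pr$network,
    precision_recall_curve(
      predicted_network("TF1", c("t2", "t1", "t3", "t4"),
                        c(0.9, 0.8, 0.7, 0.6)), wx$pr$gold), 0.9),
    "empty")
  expect_equal(prx$n_edges, 0L)

  # monotone: higher cutoff never enlarges the surviving set
  set.seed(43)
  n <- 40
  targets <- paste0("t", 1:n)
  gs <- structure(list(pairs = tibble::tibble(
    tf = "TF", target = sample(targets, 10)),
    tfs = "TF", background = targets), class = "gold_standard")
  net <- predicted_network(rep("TF", n), targets, runif(n))
  cvn <- precision_recall_curve(net, gs)
  prev <- Inf
  for (cut in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    nr <- suppressWarnings(prune_at_precision(net, cvn, cut))$n_edges
    expect_lte(nr, prev)
    prev <- nr
  }
})

test_that("permutation test is seeded, bounded and detects planted signal", {
  # planted network, all gold edges in the top ranks: observed AUPR 1.0
  # and (at these sizes) no permutation ties it, so p = 1/1000
  targets <- paste0("t", 1:100)
  gold_t <- targets[1:10]
  gs <- structure(list(pairs = tibble::tibble(tf = "TF", target = gold_t),
                       tfs = "TF", background = targets),
                  class = "gold_standard")
  planted <- predicted_network(rep("TF", 100), targets,
                               ifelse(targets %in% gold_t, 1, 0) +
                                 seq(0.001, 0.1, length.out = 100))
  rt <- randomization_test(planted, gs, n_permutations = 999, seed = 7)
  expect_equal(rt$observed_aupr, 1.0)
  expect_equal(rt$p_value, 1 / 1000)
  expect_gt(rt$percent_improvement, 0)

  wx <- generate_worked_example()
  perfect <- predicted_network("TF1", c("t1", "t3", "t2", "t4"),
                               c(4, 3, 2, 1) / 4)

  # seeded runs reproduce exactly
  rt2 <- randomization_test(perfect, wx$pr$gold, n_permutations = 99,
                            seed = 11)
  rt3 <- randomization_test(perfect, wx$pr$gold, n_permutations = 99,
                            seed = 11)
  expect_identical(rt2$null_auprs, rt3$null_auprs)

  # n_permutations = 1 with null >= observed gives the formula bound 1.0
  allsame <- predicted_network("TF1", c("t1", "t3"), c(1, 1))
  rt4 <- randomization_test(allsame, wx$pr$gold, n_permutations = 1,
                            seed = 1)
  expect_equal(rt4$p_value, 1.0)
  expect_error(randomization_test(perfect, wx$pr$gold, n_permutations = 0),
               "n_permutations")
})

test_that("SIF and JSON exports round-trip the edge multiset", {
  ed <- tibble::tibble(tf = c("A", "A", "B"), target = c("x", "y", "x"),
                       edge_type = c("bound", "regulates", "bound"),
                       score = c(0.9, 0.8, 0.7))
  sif <- tempfile(fileext = ".sif")
  export_network(ed, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 3L)
  expect_equal(lines[1], "A\tbound\tx")

  js <- tempfile(fileext = ".json")
  export_network(ed, js, "json")
  back <- read_network_json(js)
  expect_equal(as.data.frame(back[, c("tf", "target", "edge_type", "score")]),
               as.data.frame(ed))

  # validated overlay marks matched pairs
  export_network(ed, js, "json",
                 validated = data.frame(tf = "A", target = "y"))
  back2 <- read_network_json(js)
  expect_equal(back2$validated, c(FALSE, TRUE, FALSE))

  expect_error(export_network(ed, sif, "xml"), "arg")
  expect_error(export_network(ed[0, ], sif, "sif"), "no edges")
})
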