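test_that("queries parse to the expected tree with correct precedence", {
  ast <- parse_query(paste0("AT4G24020[EXPERIMENT_TYPE=Expression] and not ",
                            "AT4G24020[TECHNOLOGY/METHOD=ChIPseq]"))
  expect_equal(ast$op, "and")
  expect_equal(ast$children[[1]]$op, "term")
  expect_equal(ast$children[[2]]$op, "not")
  expect_equal(ast$children[[1]]$filters[[1]],
               list(key = "EXPERIMENT_TYPE", op = "=", value = "Expression"))
  expect_equal(ast$children[[2]]$child$filters[[1]]$key, "TECHNOLOGY/METHOD")

  q <- 'AT2G46680[EDGE_TYPE="in planta:Bound"]'
  ast2 <- parse_query(q)
  expect_equal(ast2$op, "term")
  expect_equal(ast2$filters[[1]]$value, "in planta:Bound")

  # "not" binds tighter than "and", "and" tighter than "or"
  expect_equal(unclass(parse_query("a or (b and c)")),
               unclass(parse_query("a or b and c")))
  expect_equal(unclass(parse_query("(not a) and b")),
               unclass(parse_query("not a and b")))
  # keywords are case-insensitive
  expect_equal(unclass(parse_query("a AND b Or c")),
               unclass(parse_query("a and b or c")))

  expect_error(parse_query("a and"), "syntax error")
  expect_error(parse_query("a["), "syntax error|unterminated")
  expect_error(parse_query(""), "empty")
})

test_that("serialize/parse round-trips hand-written and generated ASTs", {
  for (q in c("AT4G24020[EXPERIMENT_TYPE=Expression] and AT4G24020[TECHNOLOGY/METHOD=ChIPseq]",
              'AT2G46680[EDGE_TYPE="in planta:Bound"]',
              'all_expression[TISSUE/SAMPLE="Root Protoplasts"]',
              "AT2G46680[log2fc < 0] or AT2G46680[log2fc > 0]",
              "a or (b and not c) or not (d and e)")) {
    ast <- parse_query(q)
    expect_equal(unclass(parse_query(serialize_query(ast))), unclass(ast),
                 label = q)
  }

  set.seed(42)
  rand_ast <- function(depth) {
    if (depth <= 0 || runif(1) < 0.4) {
      nf <- sample(0:2, 1)
      filters <- replicate(nf, list(
        key = sample(c("EXPERIMENT_TYPE", "TECHNOLOGY/METHOD", "log2fc"), 1),
        op = sample(c("=", "!=", "<", ">"), 1),
        value = sample(c("Expression", "ChIPseq", "Root Protoplasts", "0"), 1)),
        simplify = FALSE)
      return(list(op = "term",
                  subject = sample(c("TFA", "TFB", "all_expression"), 1),
                  filters = filters))
    }
    op <- sample(c("and", "or", "not"), 1)
    if (op == "not") list(op = "not", child = rand_ast(depth - 1))
    else list(op = op,
              children = replicate(sample(2:3, 1), rand_ast(depth - 1),
                                   simplify = FALSE))
  }
  for (i in 1:60) {
    ast <- rand_ast(3)
    class(ast) <- c("query_ast", "list")
    expect_equal(unclass(parse_query(serialize_query(ast))), unclass(ast))
  }
})

test_that("boolean evaluation implements the documented set algebra", {
  st <- toy_store()
  q_and <- "TF1[EXPERIMENT_TYPE=Expression] and TF1[TECHNOLOGY/METHOD=ChIPseq]"
  q_andnot <- "TF1[EXPERIMENT_TYPE=Expression] and not TF1[TECHNOLOGY/METHOD=ChIPseq]"
  expect_setequal(result_targets(evaluate_query(q_and, st)), c("g2", "g3"))
  expect_setequal(result_targets(evaluate_query(q_andnot, st)), "g1")
  expect_setequal(result_targets(evaluate_query("TF1", st)),
                  c("g1", "g2", "g3", "g4"))

  # log2fc filters separate induced from repressed targets
  expect_setequal(result_targets(evaluate_query("TF1[log2fc > 0]", st)),
                  c("g1", "g3"))
  expect_setequal(result_targets(evaluate_query("TF1[log2fc < 0]", st)), "g2")

  # edge-type filter
  expect_setequal(
    result_targets(evaluate_query('TF1[EDGE_TYPE="in planta:Bound"]', st)),
    c("g2", "g3", "g4"))

  # bare NOT needs a background and complements within it
  expect_error(evaluate_query("not TF1", st), "background")
  bg <- c("g1", "g2", "g3", "g4", "g5")
  r <- evaluate_query(parse_query("not TF1"), st, background = bg)
  expect_setequal(result_targets(r), "g5")

  # unknown subject warns and returns an empty result
  expect_warning(r2 <- evaluate_query("NOSUCH", st), "no experiment")
  expect_length(result_targets(r2), 0)
})

test_that("metadata keyword subjects select the right experiments", {
  fx <- default_fixture()
  st <- default_store()
  r <- evaluate_query('all_expression[TISSUE/SAMPLE="Root Protoplasts"]', st)
  expect_setequal(r$analyses, paste0(tolower(fx$tfs), "_target"))
  r2 <- evaluate_query("all", st)
  expect_equal(length(r2$analyses), nrow(st$experiments))
  # exhaustive metadata scan agrees
  et <- st$metadata[st$metadata$key == "EXPERIMENT_TYPE", ]
  expect_setequal(evaluate_query("all_expression", st)$analyses,
                  et$analysis_id[et$value == "Expression"])
})

test_that("evaluation identities hold: idempotence, annihilation, monotonicity", {
  st <- default_store()
  fx <- default_fixture()
  terms <- c(sprintf("%s[EXPERIMENT_TYPE=Expression]", fx$tfs[1]),
             sprintf("%s[TECHNOLOGY/METHOD=ChIPseq]", fx$tfs[2]),
             sprintf("%s[log2fc > 0]", fx$tfs[3]))
  for (A in terms) {
    tA <- sort(result_targets(evaluate_query(A, st)))
    expect_equal(sort(result_targets(evaluate_query(
      sprintf("(%s) and (%s)", A, A), st))), tA)
    expect_equal(sort(result_targets(evaluate_query(
      sprintf("(%s) or (%s)", A, A), st))), tA)
    expect_length(result_targets(evaluate_query(
      sprintf("(%s) and not (%s)", A, A), st)), 0)
  }

  # adding a filter never enlarges the target set
  base <- result_targets(evaluate_query(fx$tfs[1], st))
  for (f in c("[log2fc > 0]", "[EXPERIMENT_TYPE=Expression]",
              "[pvalue < 0.001]")) {
    expect_true(all(result_targets(
      evaluate_query(paste0(fx$tfs[1], f), st)) %in% base))
  }

  # target-genes constraint commutes with OR
  lists <- fx$regulated[[fx$tfs[2]]][1:20]
  A <- fx$tfs[1]
  B <- fx$tfs[2]
  lhs <- result_targets(evaluate_query(sprintf("%s or %s", A, B), st,
                                       target_genes = lists))
  rhs <- union(
    result_targets(evaluate_query(A, st, target_genes = lists)),
    result_targets(evaluate_query(B, st, target_genes = lists)))
  expect_setequal(lhs, rhs)
})

test_that("constraints restrict TFs, targets and network pairs", {
  st <- default_store()
  fx <- default_fixture()
  r <- evaluate_query("all_expression", st, filter_tfs = fx$tfs[1:2])
  expect_setequal(names(r$targets), fx$tfs[1:2])

  bg <- fx$regulated[[fx$tfs[1]]][1:10]
  r2 <- evaluate_query("all_expression", st, background = bg)
  expect_true(all(result_targets(r2) %in% bg))

  net <- fx$network[1:50, ]
  r3 <- evaluate_query("all_expression", st, target_network = net)
  got <- unlist(lapply(names(r3$targets), function(tf)
    paste(tf, r3$targets[[tf]])), use.names = FALSE)
  expect_true(all(got %in% paste(net$tf, net$target)))
})

test_that("summaries and export tables are consistent with the result", {
  st <- toy_store()
  r <- evaluate_query(
    "TF1[EXPERIMENT_TYPE=Expression] and TF1[TECHNOLOGY/METHOD=ChIPseq]", st)
  s <- summarize_result(r)
  expect_equal(nrow(s), 2L)
  expect_equal(sort(s$n_targets), c(2L, 2L))

  # empty result gives an empty table
  r0 <- suppressWarnings(evaluate_query("NOSUCH", st))
  expect_equal(nrow(summarize_result(r0)), 0L)

  tab <- export_result_table(r, gene_lists = list(L = c("g2", "zzz")))
  expect_true(all(tab$L[tab$target == "g2"] == "L"))
  expect_true(all(tab$L[tab$target != "g2"] == ""))
  tab2 <- export_result_table(r)
  expect_false("L" %in% names(tab2))
  # edge_count counts validating analyses per pair
  expect_true(all(tab$edge_count[tab$target %in% c("g2", "g3")] == 2L))
})
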