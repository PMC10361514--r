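de_stub <- function(mrna, lncrna, mirna) {
  mk <- function(f, cls) tibble::tibble(feature = f, class = cls,
                                        direction = "up", passed = TRUE)
  list(mrna = mk(mrna, "mrna"), lncrna = mk(lncrna, "lncrna"),
       mirna = mk(mirna, "mirna"))
}

edge_stub <- function(mirna, target, class) {
  tibble::tibble(mirna = mirna, target = target, target_class = class,
                 n_sources = 1L, sources = "sourceA")
}

test_that("triple assembly enforces sign and magnitude rules strictly", {
  samples <- paste0("s", 1:8)
  groups <- make_groups(samples, 4)
  cfg <- pipeline_config(correlation_transform = "fpkm")
  strong <- exact_r_profiles(-0.9)

  build_inputs <- function(m_profile) {
    expr <- list(
      mrna = make_expr(rbind(M1 = m_profile), NULL, samples),
      lncrna = make_expr(rbind(L1 = strong$y), NULL, samples),
      mirna = make_expr(rbind(X1 = strong$x), NULL, samples)
    )
    edges <- rbind(edge_stub("X1", "M1", "mRNA"),
                   edge_stub("X1", "L1", "lncRNA"))
    list(expr = expr, edges = edges)
  }

  # strongly negative on both arms: emitted
  ok <- build_inputs(strong$y)
  tr <- assemble_triples(ok$edges, de_stub("M1", "L1", "X1"), ok$expr,
                         groups, cfg)
  expect_identical(nrow(tr), 1L)
  expect_lt(tr$r_mi_m, -0.5)
  expect_gt(tr$r_lnc_m, 0)

  # positive miRNA-mRNA correlation: sign rule rejects
  pos <- build_inputs(strong$x + 1)
  expect_identical(
    nrow(assemble_triples(pos$edges, de_stub("M1", "L1", "X1"), pos$expr,
                          groups, cfg)), 0L)

  # negative but weak (|r| = 0.4): magnitude rule rejects
  weak <- exact_r_profiles(-0.4)
  mix <- build_inputs(weak$y)
  mix$expr$mirna <- make_expr(rbind(X1 = weak$x), NULL, samples)
  mix$expr$lncrna <- make_expr(rbind(L1 = weak$y), NULL, samples)
  expect_identical(
    nrow(assemble_triples(mix$edges, de_stub("M1", "L1", "X1"), mix$expr,
                          groups, cfg)), 0L)
})

test_that("non-DE members and missing expression drop candidates", {
  samples <- paste0("s", 1:8)
  groups <- make_groups(samples, 4)
  cfg <- pipeline_config(correlation_transform = "fpkm")
  strong <- exact_r_profiles(-0.9)
  expr <- list(
    mrna = make_expr(rbind(M1 = strong$y), NULL, samples),
    lncrna = make_expr(rbind(L1 = strong$y), NULL, samples),
    mirna = make_expr(rbind(X1 = strong$x), NULL, samples)
  )
  edges <- rbind(edge_stub("X1", "M1", "mRNA"),
                 edge_stub("X1", "L1", "lncRNA"))
  de <- de_stub("M1", "L1", "X1")
  de$mrna$passed <- FALSE
  expect_identical(nrow(assemble_triples(edges, de, expr, groups, cfg)), 0L)

  de$mrna$passed <- TRUE
  edges2 <- rbind(edges, edge_stub("X1", "M_ghost", "mRNA"))
  de2 <- de_stub(c("M1", "M_ghost"), "L1", "X1")
  expect_warning(
    tr <- assemble_triples(edges2, de2, expr, groups, cfg),
    "without expression"
  )
  expect_identical(tr$mrna, "M1")
})

test_that("network construction yields exact node, edge and degree counts", {
  one <- build_network(tibble::tibble(lncrna = "L1", mirna = "X1",
                                      mrna = "M1"))
  expect_identical(nrow(one$nodes), 3L)
  expect_identical(nrow(one$edges), 2L)
  expect_identical(
    one$nodes$degree[match(c("L1", "X1", "M1"), one$nodes$id)],
    c(1L, 2L, 1L))

  two <- build_network(tibble::tibble(lncrna = c("L1", "L2"),
                                      mirna = "X1",
                                      mrna = c("M1", "M2")))
  expect_identical(nrow(two$nodes), 5L)
  expect_identical(nrow(two$edges), 4L)
  expect_identical(two$nodes$degree[two$nodes$id == "X1"], 4L)
})

test_that("degrees match a brute-force recount on random triple sets", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(50, 1)
    triples <- unique(tibble::tibble(
      lncrna = paste0("L", sample(12, n, TRUE)),
      mirna = paste0("X", sample(8, n, TRUE)),
      mrna = paste0("M", sample(12, n, TRUE))
    ))
    net <- build_network(triples)
    oracle <- recount_degrees(triples)
    expect_setequal(net$nodes$id, oracle$nodes)
    expect_identical(
      net$nodes$degree[order(net$nodes$id)],
      unname(oracle$degree)
    )
    expect_identical(sum(net$nodes$degree), 2L * nrow(net$edges))
    # tripartite: every edge runs from a miRNA to a partner class
    expect_true(all(grepl("^X", net$edges$from)))
    expect_true(all(grepl("^[LM]", net$edges$to)))
  }
})

test_that("hub calling is strict at degree 5 vs 6", {
  star <- function(k) tibble::tibble(
    lncrna = paste0("L", 1:k), mirna = "X1", mrna = paste0("M", 1:k))
  # k lncRNAs + k mRNAs -> miRNA degree 2k; partners have degree 1
  net6 <- build_network(star(3))
  hubs6 <- find_hubs(net6)
  expect_identical(hubs6$hub, "X1")
  expect_identical(hubs6$degree, 6L)

  net5 <- build_network(dplyr::bind_rows(
    star(2), tibble::tibble(lncrna = "L3", mirna = "X1", mrna = "M2")))
  expect_identical(net5$nodes$degree[net5$nodes$id == "X1"], 5L)
  expect_identical(nrow(find_hubs(net5)), 0L)

  expect_identical(nrow(find_hubs(build_network(star(0)))), 0L)
})

test_that("raising the correlation bar never adds triples", {
  sim <- simulate_study(tiny_design(seed = 41L))
  de <- list(
    mrna = run_de(sim$expression$mrna, sim$groups, "mrna"),
    lncrna = run_de(sim$expression$lncrna, sim$groups, "lncrna"),
    mirna = run_de(sim$expression$mirna, sim$groups, "mirna")
  )
  edges <- qualify_mirna_edges(sim$evidence)
  loose <- assemble_triples(edges, de, sim$expression, sim$groups,
                            pipeline_config(cerna_abs_r_min = 0.3))
  tight <- assemble_triples(edges, de, sim$expression, sim$groups,
                            pipeline_config(cerna_abs_r_min = 0.7))
  key <- function(x) paste(x$lncrna, x$mirna, x$mrna)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("network intersection is commutative, idempotent and typed", {
  ta <- tibble::tibble(lncrna = c("L1", "L2"), mirna = c("X1", "X2"),
                       mrna = c("M1", "M2"),
                       lncrna_dir = "down", mirna_dir = "up",
                       mrna_dir = c("down", "up"))
  tb <- tibble::tibble(lncrna = c("L1", "L9"), mirna = c("X1", "X9"),
                       mrna = c("M1", "M9"),
                       lncrna_dir = "down", mirna_dir = "up",
                       mrna_dir = c("up", "down"))
  na <- build_network(ta)
  nb <- build_network(tb)

  self <- intersect_networks(na, na)
  expect_setequal(self$nodes$id, na$nodes$id)
  expect_identical(nrow(self$edges), nrow(na$edges))
  expect_true(all(self$nodes$concordant))

  ab <- intersect_networks(na, nb)
  ba <- intersect_networks(nb, na)
  expect_setequal(paste(ab$nodes$id, ab$nodes$type),
                  paste(ba$nodes$id, ba$nodes$type))
  expect_setequal(paste(ab$edges$from, ab$edges$to),
                  paste(ba$edges$from, ba$edges$to))
  expect_setequal(ab$nodes$id, c("L1", "X1", "M1"))
  # M1 is up in one subtype and down in the other: shared but discordant
  expect_false(ab$nodes$concordant[ab$nodes$id == "M1"])

  disjoint <- intersect_networks(na, build_network(
    tibble::tibble(lncrna = "LZ", mirna = "XZ", mrna = "MZ")))
  expect_identical(nrow(disjoint$nodes), 0L)
  expect_identical(nrow(disjoint$edges), 0L)
})

test_that("id normalization matches transcript-suffixed symbols", {
  na <- build_network(tibble::tibble(lncrna = "SORBS3-203", mirna = "X1",
                                     mrna = "M1"))
  nb <- build_network(tibble::tibble(lncrna = "SORBS3", mirna = "X1",
                                     mrna = "M1"))
  plain <- intersect_networks(na, nb)
  expect_false("SORBS3" %in% plain$nodes$id)
  norm <- intersect_networks(na, nb, normalize_ids = TRUE)
  expect_true("SORBS3" %in% norm$nodes$id)
})

test_that("tidy and glance expose the network as tables", {
  net <- build_network(tibble::tibble(lncrna = c("L1", "L2"), mirna = "X1",
                                      mrna = c("M1", "M1")))
  td <- tidy(net)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$id, c("L1", "L2", "X1", "M1"))
  gl <- glance(net)
  expect_identical(gl$n_nodes, 4L)
  expect_identical(gl$n_edges, 3L)
  expect_identical(gl$triple_memberships, 4L)
})
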