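ann_row <- function(feature, chrom, start, end, strand = "+") {
  tibble::tibble(feature = feature, chrom = chrom, start = start,
                 end = end, strand = strand)
}

test_that("cis pairing follows the symmetric 100-kb boundary-gap rule", {
  cfg <- pipeline_config()
  lnc <- ann_row("L1", "chr1", 150000, 151000)
  gene <- ann_row("G1", "chr1", 200000, 210000)
  hit <- cis_targets(lnc, gene, cfg)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$distance_bp, 49000)

  # symmetric: lncRNA downstream of the gene pairs identically
  hit_rev <- cis_targets(ann_row("L1", "chr1", 260000, 261000), gene, cfg)
  expect_identical(hit_rev$distance_bp, 50000)

  # different chromosome: never a pair
  expect_identical(
    nrow(cis_targets(ann_row("L2", "chr1", 0, 1000),
                     ann_row("G2", "chr2", 0, 1000), cfg)), 0L)

  # overlap counts as distance zero
  ov <- cis_targets(ann_row("L3", "chr3", 500, 1500),
                    ann_row("G3", "chr3", 1000, 5000), cfg)
  expect_identical(ov$distance_bp, 0)
})

test_that("cis pairs agree with a GenomicRanges window oracle", {
  skip_if_not_installed("GenomicRanges")
  set.seed(13)
  n <- 40
  mk <- function(prefix, n) {
    start <- sample.int(5e5, n)
    tibble::tibble(feature = paste0(prefix, seq_len(n)),
                   chrom = sample(c("chr1", "chr2"), n, TRUE),
                   start = start, end = start + sample.int(5e4, n),
                   strand = "+")
  }
  lnc <- mk("L", n)
  gene <- mk("G", n)
  got <- cis_targets(lnc, gene, pipeline_config())

  gr <- function(a) GenomicRanges::GRanges(
    a$chrom, IRanges::IRanges(a$start + 1L, a$end))
  hits <- GenomicRanges::findOverlaps(gr(lnc), gr(gene), maxgap = 100000,
                                      ignore.strand = TRUE)
  want <- paste(lnc$feature[S4Vectors::queryHits(hits)],
                gene$feature[S4Vectors::subjectHits(hits)])
  expect_setequal(paste(got$lncrna, got$gene), want)

  dist <- GenomicRanges::distance(gr(lnc)[S4Vectors::queryHits(hits)],
                                  gr(gene)[S4Vectors::subjectHits(hits)])
  expect_equal(got$distance_bp[match(want, paste(got$lncrna, got$gene))],
               as.numeric(dist))
})

test_that("trans pairing is a signed strict correlation filter", {
  cfg <- pipeline_config(correlation_transform = "fpkm")
  samples <- paste0("s", 1:8)
  groups <- make_groups(samples, 4)
  base <- c(1, 5, 2, 7, 3, 8, 4, 6)
  lnc <- make_expr(rbind(L1 = base), NULL, samples)
  genes <- make_expr(rbind(Gpos = 2 * base,
                           Gneg = max(base) + 1 - base,
                           Gflat = rep(3, 8)), NULL, samples)
  expect_warning(
    hits <- trans_targets(lnc, genes, groups, cfg),
    "constant"
  )
  expect_identical(hits$gene, "Gpos")
  expect_equal(hits$pearson_r, 1)

  # |r| option admits the anti-correlated gene
  cfg_abs <- pipeline_config(correlation_transform = "fpkm",
                             trans_use_abs = TRUE)
  suppressWarnings(hits_abs <- trans_targets(lnc, genes, groups, cfg_abs))
  expect_setequal(hits_abs$gene, c("Gpos", "Gneg"))

  other <- make_expr(rbind(G = base), NULL, paste0("t", 1:8))
  expect_error(
    trans_targets(lnc, other, groups, cfg),
    class = "cernet_input_error"
  )
})

test_that("random profiles essentially never clear the r > 0.95 bar", {
  set.seed(17)
  samples <- paste0("s", 1:16)
  groups <- make_groups(samples, 8)
  lnc <- make_expr(matrix(rlnorm(25 * 16), 25, 16),
                   paste0("L", 1:25), samples)
  genes <- make_expr(matrix(rlnorm(40 * 16), 40, 16),
                     paste0("G", 1:40), samples)
  hits <- trans_targets(lnc, genes, groups, pipeline_config())
  # null tail P(r > 0.95) at n = 16 is ~9e-9: 1,000 pairs give 0 expected
  p_null <- pt(0.95 * sqrt(14) / sqrt(1 - 0.95^2), df = 14,
               lower.tail = FALSE)
  expect_lte(nrow(hits), qbinom(0.999, 1000, p_null))
})

test_that("evidence qualification counts distinct sources per class", {
  ev <- tibble::tibble(
    mirna = c("X1", "X1", "X1", "X1", "X2"),
    target = c("M1", "M1", "M1", "L1", "M2"),
    target_class = c("mRNA", "mRNA", "mRNA", "lncRNA", "mRNA"),
    source = c("sourceA", "sourceB", "sourceA", "sourceA", "sourceA")
  )
  q1 <- qualify_mirna_edges(ev, pipeline_config())
  expect_identical(nrow(q1), 3L)
  q2 <- qualify_mirna_edges(ev, pipeline_config(mrna_sources_required = 2))
  expect_identical(paste(q2$mirna, q2$target), c("X1 L1", "X1 M1"))
  expect_identical(q2$sources[q2$target == "M1"], "sourceA,sourceB")
  # duplicated (mirna, target, source) rows count once
  expect_identical(q1$n_sources[q1$target == "M1"], 2L)

  # raising a requirement never grows the qualified set
  q3 <- qualify_mirna_edges(ev, pipeline_config(mrna_sources_required = 3,
                                                lncrna_sources_required = 2))
  expect_true(all(paste(q3$mirna, q3$target) %in% paste(q2$mirna, q2$target)))

  bad <- ev
  bad$target_class[5] <- "snoRNA"
  expect_error(qualify_mirna_edges(bad), class = "cernet_validation_error")
})

test_that("with no decoys, requirement 1 recovers exactly the planted couplings", {
  d <- tiny_design(decoy_edge_rate = 0)
  sim <- simulate_expression(d)
  ev <- simulate_evidence(d, sim$truth)
  q <- qualify_mirna_edges(ev, pipeline_config())
  tr <- sim$truth$triples
  planted <- c(paste(tr$mirna, tr$mrna), paste(tr$mirna, tr$lncrna))
  expect_setequal(paste(q$mirna, q$target), planted)
})
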