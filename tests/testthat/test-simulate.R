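test_that("a fixed seed reproduces every generator byte for byte", {
  a <- simulate_study(tiny_design(seed = 5L))
  b <- simulate_study(tiny_design(seed = 5L))
  expect_identical(a$expression, b$expression)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$survival, b$survival)
  c <- simulate_study(tiny_design(seed = 6L))
  expect_false(identical(a$expression$mrna, c$expression$mrna))
})

test_that("matrices are dense, non-negative FPKM with labelled samples", {
  sim <- simulate_expression(tiny_design())
  for (cls in names(sim$expression)) {
    e <- sim$expression[[cls]]
    expect_silent(validate_expression(e, sim$groups))
    expect_true(all(as.matrix(e[, -1]) >= 0))
  }
  expect_setequal(unique(sim$groups$group), c("case", "control"))
})

test_that("planted couplings carry the ceRNA correlation signature", {
  # near-noiseless: log-scale |r| must come within 0.15 of corr_strength
  sim <- simulate_expression(tiny_design(noise_sd = 0.005, n_de_per_class = 6,
                                         n_triples = 6, fc_effect = 1.01))
  lg <- lapply(sim$expression, function(e) {
    m <- log(as.matrix(e[, -1]))
    rownames(m) <- e$feature
    m
  })
  tr <- sim$truth$triples
  for (i in seq_len(nrow(tr))) {
    r_ml <- cor(lg$mirna[tr$mirna[i], ], lg$lncrna[tr$lncrna[i], ])
    r_mm <- cor(lg$mirna[tr$mirna[i], ], lg$mrna[tr$mrna[i], ])
    r_lm <- cor(lg$lncrna[tr$lncrna[i], ], lg$mrna[tr$mrna[i], ])
    expect_lt(r_ml, 0)
    expect_lt(r_mm, 0)
    expect_gt(r_lm, 0)
    expect_lt(abs(abs(r_ml) - 0.9), 0.15)
    expect_lt(abs(abs(r_mm) - 0.9), 0.15)
  }
})

test_that("planted DE features shift group means by the designed effect", {
  sim <- simulate_expression(tiny_design(noise_sd = 0.05, fc_effect = 4))
  groups <- sim$groups
  for (cls in c("mrna", "lncrna", "mirna")) {
    e <- sim$expression[[cls]]
    m <- as.matrix(e[, -1])
    rownames(m) <- e$feature
    de <- sim$truth$de[sim$truth$de$class == cls, ]
    ratio <- rowMeans(m[de$feature, groups$group == "case", drop = FALSE]) /
      rowMeans(m[de$feature, groups$group == "control", drop = FALSE])
    up <- ratio[de$direction == "up"]
    down <- ratio[de$direction == "down"]
    # per feature the planted effect clears the 1.5x screening bar; the
    # designed 4x holds in expectation (triple members also carry the
    # shared-factor variance, so individual ratios scatter around it)
    expect_true(all(up > 1.5))
    expect_true(all(down < 1 / 1.5))
    expect_lt(abs(exp(mean(log(up))) - 4), 1.5)
    expect_lt(abs(1 / exp(mean(log(down))) - 4), 1.5)
  }
})

test_that("an empty design yields pure noise and empty truth", {
  sim <- simulate_expression(tiny_design(n_de_per_class = 0, n_triples = 0,
                                         n_prognostic = 0))
  expect_identical(nrow(sim$truth$de), 0L)
  expect_identical(nrow(sim$truth$triples), 0L)
  expect_identical(nrow(sim$truth$prognostic), 0L)
})

test_that("impossible planted structure raises sizing errors", {
  expect_error(simulation_design(n_triples = 50, n_de_per_class = 10),
               class = "cernet_sizing_error")
  expect_error(simulation_design(n_de_per_class = 500, n_mrna = 100),
               class = "cernet_sizing_error")
  expect_error(simulation_design(n_case = 1), class = "cernet_sizing_error")
  expect_error(simulation_design(fc_effect = 1),
               class = "cernet_validation_error")
  expect_error(simulation_design(corr_strength = 1.2),
               class = "cernet_validation_error")
})

test_that("cis_fraction controls planted lncRNA-mRNA genomic placement", {
  gap_of <- function(cis_fraction) {
    d <- tiny_design(cis_fraction = cis_fraction)
    sim <- simulate_expression(d)
    ann <- simulate_annotation(d, sim$truth)
    tr <- sim$truth$triples
    vapply(seq_len(nrow(tr)), function(i) {
      a <- ann[ann$feature == tr$lncrna[i], ]
      b <- ann[ann$feature == tr$mrna[i], ]
      if (a$chrom != b$chrom) return(Inf)
      max(0, max(a$start, b$start) - min(a$end, b$end))
    }, numeric(1))
  }
  expect_true(all(gap_of(1) <= 100000))
  expect_true(all(gap_of(0) > 100000))
  ann <- simulate_annotation(tiny_design(),
                             simulate_expression(tiny_design())$truth)
  expect_true(all(ann$start < ann$end))
  expect_true(all(nzchar(ann$chrom)))
})

test_that("evidence contains every planted coupling plus the decoy share", {
  d0 <- tiny_design(decoy_edge_rate = 0)
  sim <- simulate_expression(d0)
  ev <- simulate_evidence(d0, sim$truth)
  pairs <- unique(ev[, c("mirna", "target")])
  tr <- sim$truth$triples
  planted <- unique(rbind(
    data.frame(mirna = tr$mirna, target = tr$mrna),
    data.frame(mirna = tr$mirna, target = tr$lncrna)
  ))
  expect_setequal(paste(pairs$mirna, pairs$target),
                  paste(planted$mirna, planted$target))

  d3 <- tiny_design(decoy_edge_rate = 0.3, n_triples = 8, n_de_per_class = 8)
  sim3 <- simulate_expression(d3)
  ev3 <- simulate_evidence(d3, sim3$truth)
  pairs3 <- unique(paste(ev3$mirna, ev3$target))
  planted3 <- unique(paste(c(sim3$truth$triples$mirna,
                             sim3$truth$triples$mirna),
                           c(sim3$truth$triples$mrna,
                             sim3$truth$triples$lncrna)))
  decoy_frac <- 1 - length(intersect(pairs3, planted3)) / length(pairs3)
  expect_lt(abs(decoy_frac - 0.3), 0.05)
  # source pools respected
  expect_true(all(ev3$source[ev3$target_class == "mRNA"] %in%
                    c("sourceA", "sourceB", "sourceC")))
  expect_true(all(ev3$source[ev3$target_class == "lncRNA"] %in%
                    c("sourceA", "sourceD")))
})

test_that("survival cohort has positive times, binary events and planted risk", {
  d <- tiny_design(n_prognostic = 1, surv_beta = 2.5, n_survival = 240)
  sim <- simulate_expression(d)
  sv <- simulate_survival(d, sim$truth)
  expect_true(all(sv$survival$time > 0))
  expect_true(all(sv$survival$event %in% c(0, 1)))
  expect_identical(sv$survival$sample, colnames(sv$expression)[-1])

  # planted prognostic miRNA detected in nearly every replicate
  hits <- vapply(1:40, function(s) {
    di <- tiny_design(n_prognostic = 1, surv_beta = 2.5, n_survival = 240,
                      seed = 1000L + s)
    si <- simulate_expression(di)
    svi <- simulate_survival(di, si$truth)
    v <- as.matrix(svi$expression[, -1])[
      match(si$truth$prognostic$mirna, svi$expression$feature), ]
    km_logrank(svi$survival, setNames(v, svi$survival$sample))$p_value
  }, numeric(1))
  expect_gte(mean(hits < 0.05), 0.95)
})

test_that("with no prognostic effect log-rank p-values are uniform", {
  ps <- vapply(1:200, function(s) {
    d <- tiny_design(n_mirna = 2, n_prognostic = 0, n_survival = 50,
                     n_triples = 0, n_de_per_class = 0, seed = 3000L + s)
    sim <- simulate_expression(d)
    sv <- simulate_survival(d, sim$truth)
    v <- as.matrix(sv$expression[, -1])[1, ]
    km_logrank(sv$survival, setNames(v, sv$survival$sample))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
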