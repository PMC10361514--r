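# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the code paths they check: the Mann-Whitney oracle
# enumerates rank assignments directly, the log-rank oracle accumulates the
# O/E table by hand, and the degree oracle recounts adjacency from scratch.

# Exhaustive two-sided Mann-Whitney p by enumeration over all C(n, n1)
# assignments of the pooled ranks to the first group. Assumes no ties.
enum_mw_p <- local({
  cache <- list()
  function(case, control) {
    vals <- c(case, control)
    n1 <- length(case)
    n <- length(vals)
    key <- paste(n1, n)
    if (is.null(cache[[key]])) cache[[key]] <<- utils::combn(n, n1)
    idx <- cache[[key]]
    r <- rank(vals)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  }
})

# Hand O/E/V accumulation for the two-group log-rank test.
logrank_oracle <- function(time, event, high) {
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & high)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & high)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, chi2 = (O - E)^2 / V)
}

# Brute-force degree recount from a triple table: unique undirected edges,
# then per-node incidence scan.
recount_degrees <- function(triples) {
  edges <- unique(rbind(
    data.frame(a = triples$mirna, b = triples$lncrna),
    data.frame(a = triples$mirna, b = triples$mrna)
  ))
  nodes <- unique(c(triples$lncrna, triples$mirna, triples$mrna))
  deg <- vapply(nodes, function(nd) {
    sum(edges$a == nd) + sum(edges$b == nd)
  }, integer(1))
  list(nodes = sort(nodes), edges = edges,
       degree = deg[order(names(deg))])
}

# Two length-8 non-negative profiles whose sample Pearson correlation is
# EXACTLY `target` (searching the ulp neighbourhood of the analytic
# solution), for strict-comparator boundary checks.
exact_r_profiles <- function(target) {
  x <- c(1, -1, 1, -1, 1, -1, 1, -1)
  z <- c(1, 1, -1, -1, 1, 1, -1, -1)
  s <- sign(target)
  b0 <- sqrt(1 / target^2 - 1)
  for (k in -200:200) {
    b <- b0 * (1 + k * .Machine$double.eps)
    y <- s * x + b * z + 4
    if (stats::cor(x + 2, y) == target) return(list(x = x + 2, y = y))
  }
  stop("no floating-point-exact construction found for r = ", target)
}

# Wide expression tibble from a plain matrix.
make_expr <- function(m, features = NULL, samples = NULL) {
  if (!is.null(features)) rownames(m) <- features
  if (!is.null(samples)) colnames(m) <- samples
  tibble::as_tibble(m, rownames = "feature")
}

make_groups <- function(samples, n_case) {
  tibble::tibble(sample = samples,
                 group = rep(c("case", "control"),
                             c(n_case, length(samples) - n_case)))
}

toy_surv <- function(times, events, samples = NULL) {
  if (is.null(samples)) samples <- paste0("p", seq_along(times))
  tibble::tibble(sample = samples, time = times, event = events)
}

# A small, fast study design for structural tests.
tiny_design <- function(...) {
  args <- utils::modifyList(
    list(n_mrna = 60, n_lncrna = 30, n_mirna = 20, n_de_per_class = 8,
         n_triples = 4, n_survival = 40, seed = 101L),
    list(...))
  do.call(simulation_design, args)
}
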