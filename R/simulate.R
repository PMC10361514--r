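#' Define a synthetic study design
#'
#' Fixes every parameter of the synthetic tissue-exosome study: group sizes,
#' feature counts per RNA class, the number and strength of planted
#' differentially expressed features and ceRNA triples, evidence decoy rate,
#' and the survival-cohort model. The defaults mirror the emulated study
#' design: 8 case vs 8 control samples, planted group effects well above the
#' fold-change filter, strong planted couplings (target |r| = 0.9) and a 30%
#' decoy rate among candidate interaction edges.
#'
#' One root `seed` drives four documented child streams (seed + 0 expression,
#' + 1 annotation, + 2 evidence, + 3 survival), so a fixed design yields
#' byte-identical outputs from every generator.
#'
#' @param n_case,n_control Samples per group (each >= 2; default 8 vs 8).
#' @param n_mrna,n_lncrna,n_mirna Feature counts per RNA class.
#' @param n_de_per_class Planted differentially expressed features per class
#'   (split as evenly as possible between up and down; triple members are
#'   drawn from this pool).
#' @param n_triples Planted ceRNA triples (one lncRNA, miRNA and mRNA each;
#'   must not exceed `n_de_per_class`).
#' @param fc_effect Multiplicative case/control effect for planted DE
#'   features (> 1).
#' @param corr_strength Target |Pearson r| (log scale) for planted couplings,
#'   in [0, 1]; the miRNA is anti-correlated with its lncRNA and mRNA
#'   partners, which are positively correlated with each other.
#' @param noise_sd Log-scale (natural log) sd of per-observation noise.
#' @param decoy_edge_rate Fraction of emitted evidence edges that are decoys
#'   (not corresponding to a planted coupling), in [0, 1).
#' @param baseline_log_mean,baseline_log_sd Natural-log FPKM baseline
#'   distribution; the defaults (2, 1) put the median feature near FPKM 7.4
#'   so the FPKM > 5 abundance filter is exercised non-trivially.
#' @param signal_sd Log-scale sd of the shared-factor component of planted
#'   coupled profiles. As `noise_sd` approaches 0 the realized |r| of a
#'   planted pair approaches `corr_strength`; at the defaults it is
#'   `corr_strength * signal_sd^2 / (signal_sd^2 + noise_sd^2)`.
#' @param cis_fraction Fraction of planted lncRNA-mRNA pairs placed within
#'   the 100-kb cis window by [simulate_annotation()].
#' @param n_prognostic Number of planted prognostic miRNAs.
#' @param surv_beta Log-hazard ratio per sd of expression for prognostic
#'   miRNAs (sign set per miRNA by the planted hazard direction).
#' @param surv_baseline_hazard Baseline exponential event rate (per time
#'   unit).
#' @param surv_censor_max Upper bound of the uniform censoring window.
#' @param n_survival Subjects in the simulated survival cohort.
#' @param seed Integer root seed (< 2^31 - 4).
#'
#' @return A validated `simulation_design` object.
#' @seealso [simulate_study()] for the one-call generator.
#' @export
simulation_design <- function(n_case = 8, n_control = 8,
                              n_mrna = 300, n_lncrna = 150, n_mirna = 80,
                              n_de_per_class = 30, n_triples = 10,
                              fc_effect = 4, corr_strength = 0.9,
                              noise_sd = 0.2, decoy_edge_rate = 0.3,
                              baseline_log_mean = 2, baseline_log_sd = 1,
                              signal_sd = 0.5, cis_fraction = 0.5,
                              n_prognostic = 3, surv_beta = 1,
                              surv_baseline_hazard = 0.1,
                              surv_censor_max = 25, n_survival = 100,
                              seed = 1L) {
  d <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
            n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
            n_mirna = as.integer(n_mirna),
            n_de_per_class = as.integer(n_de_per_class),
            n_triples = as.integer(n_triples),
            fc_effect = as.numeric(fc_effect),
            corr_strength = as.numeric(corr_strength),
            noise_sd = as.numeric(noise_sd),
            decoy_edge_rate = as.numeric(decoy_edge_rate),
            baseline_log_mean = as.numeric(baseline_log_mean),
            baseline_log_sd = as.numeric(baseline_log_sd),
            signal_sd = as.numeric(signal_sd),
            cis_fraction = as.numeric(cis_fraction),
            n_prognostic = as.integer(n_prognostic),
            surv_beta = as.numeric(surv_beta),
            surv_baseline_hazard = as.numeric(surv_baseline_hazard),
            surv_censor_max = as.numeric(surv_censor_max),
            n_survival = as.integer(n_survival),
            seed = as.integer(seed))
  if (d$n_case < 2 || d$n_control < 2) {
    rlang::abort("need at least 2 samples per group",
                 class = "cernet_sizing_error")
  }
  if (d$fc_effect <= 1) {
    rlang::abort("`fc_effect` must be > 1", class = "cernet_validation_error")
  }
  if (d$corr_strength < 0 || d$corr_strength > 1) {
    rlang::abort("`corr_strength` must lie in [0, 1]",
                 class = "cernet_validation_error")
  }
  if (d$decoy_edge_rate < 0 || d$decoy_edge_rate >= 1) {
    rlang::abort("`decoy_edge_rate` must lie in [0, 1)",
                 class = "cernet_validation_error")
  }
  if (d$noise_sd < 0 || d$signal_sd <= 0) {
    rlang::abort("`noise_sd` must be >= 0 and `signal_sd` > 0",
                 class = "cernet_validation_error")
  }
  if (d$cis_fraction < 0 || d$cis_fraction > 1) {
    rlang::abort("`cis_fraction` must lie in [0, 1]",
                 class = "cernet_validation_error")
  }
  if (d$n_de_per_class > min(d$n_mrna, d$n_lncrna, d$n_mirna)) {
    rlang::abort("`n_de_per_class` exceeds a class feature count",
                 class = "cernet_sizing_error")
  }
  if (d$n_triples > d$n_de_per_class) {
    rlang::abort("`n_triples` must not exceed `n_de_per_class`",
                 class = "cernet_sizing_error")
  }
  if (d$n_prognostic > d$n_mirna) {
    rlang::abort("`n_prognostic` exceeds `n_mirna`",
                 class = "cernet_sizing_error")
  }
  if (is.na(d$seed) || d$seed > .Machine$integer.max - 4L) {
    rlang::abort("`seed` must be an integer below 2^31 - 4",
                 class = "cernet_validation_error")
  }
  structure(d, class = "simulation_design")
}

with_stream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed + offset)
  force(code)
}

feature_ids <- function(prefix, n) sprintf("%s_%04d", prefix, seq_len(n))

#' Generate three-layer expression matrices with planted truth
#'
#' Simulates FPKM-scale mRNA, lncRNA and miRNA matrices for a two-group
#' design. Log expression is `baseline + group effect + coupling + noise`:
#' baselines are N(`baseline_log_mean`, `baseline_log_sd`); planted DE
#' features gain `+-log(fc_effect)` in the case group (planted baselines are
#' drawn from the upper half of the baseline distribution so planted truth is
#' recoverable above the abundance filter); each planted triple shares a
#' per-sample latent factor entering the miRNA profile with negative sign and
#' the lncRNA/mRNA profiles with positive sign, giving log-scale pairwise
#' correlations of `-corr_strength` (miRNA vs partners) and `+corr_strength`
#' (lncRNA vs mRNA) as `noise_sd` approaches 0. Triple directions are
#' coherent: the miRNA moves opposite to its partners between groups.
#' Everything is exponentiated to FPKM, so values are strictly positive.
#'
#' @param design A [simulation_design()].
#' @return A list with elements `expression` (named list of wide tibbles
#'   `mrna`, `lncrna`, `mirna`), `groups` (sample/group tibble) and `truth`
#'   (list of tibbles `de` (feature, class, direction), `triples` (lncrna,
#'   mirna, mrna) and `prognostic` (mirna, direction)).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  with_stream(d$seed, 0L, {
    samples <- c(sprintf("case_%02d", seq_len(d$n_case)),
                 sprintf("ctrl_%02d", seq_len(d$n_control)))
    groups <- tibble::tibble(
      sample = samples,
      group = rep(c("case", "control"), c(d$n_case, d$n_control))
    )
    n_s <- length(samples)
    is_case <- groups$group == "case"

    classes <- c(mrna = d$n_mrna, lncrna = d$n_lncrna, mirna = d$n_mirna)
    prefixes <- c(mrna = "mRNA", lncrna = "lncRNA", mirna = "miRNA")

    # planted DE ids: the first n_triples per class host the triples
    de <- list(); ids <- list(); logm <- list()
    de_dir <- list()
    triple_flip <- if (d$n_triples > 0) {
      sample(c(1, -1), d$n_triples, replace = TRUE)
    } else numeric(0)
    for (cls in names(classes)) {
      n_f <- classes[[cls]]
      ids[[cls]] <- feature_ids(prefixes[[cls]], n_f)
      mu <- stats::rnorm(n_f, d$baseline_log_mean, d$baseline_log_sd)
      de_idx <- seq_len(d$n_de_per_class)
      # upper-half baseline for planted features: recoverable above FPKM > 5
      mu[de_idx] <- d$baseline_log_mean +
        abs(stats::rnorm(d$n_de_per_class, 0, d$baseline_log_sd))
      dir <- integer(n_f)
      if (d$n_de_per_class > 0) {
        extra <- de_idx[de_idx > d$n_triples]
        if (d$n_triples > 0) {
          tri_dir <- if (cls == "mirna") triple_flip else -triple_flip
          dir[seq_len(d$n_triples)] <- tri_dir
        }
        dir[extra] <- rep_len(c(1, -1), length(extra))
      }
      de_dir[[cls]] <- dir
      m <- matrix(stats::rnorm(n_f * n_s, 0, d$noise_sd), n_f, n_s) + mu
      m <- m + outer(dir * log(d$fc_effect), as.numeric(is_case))
      rownames(m) <- ids[[cls]]
      colnames(m) <- samples
      logm[[cls]] <- m
      de[[cls]] <- tibble::tibble(
        feature = ids[[cls]][de_idx],
        class = cls,
        direction = ifelse(dir[de_idx] > 0, "up", "down")
      )
    }

    # shared latent factor per triple: miRNA loads negative, partners positive
    if (d$n_triples > 0) {
      rho <- d$corr_strength
      for (t in seq_len(d$n_triples)) {
        f <- stats::rnorm(n_s)
        for (cls in names(classes)) {
          load <- if (cls == "mirna") -1 else 1
          g <- stats::rnorm(n_s)
          logm[[cls]][t, ] <- logm[[cls]][t, ] +
            d$signal_sd * (load * sqrt(rho) * f + sqrt(1 - rho) * g)
        }
      }
    }

    expr <- purrr::map(logm, function(m) {
      tibble::as_tibble(exp(m), rownames = "feature")
    })
    truth <- list(
      de = dplyr::bind_rows(de),
      triples = if (d$n_triples > 0) {
        tibble::tibble(lncrna = ids$lncrna[seq_len(d$n_triples)],
                       mirna = ids$mirna[seq_len(d$n_triples)],
                       mrna = ids$mrna[seq_len(d$n_triples)])
      } else {
        tibble::tibble(lncrna = character(), mirna = character(),
                       mrna = character())
      },
      prognostic = if (d$n_prognostic > 0) {
        tibble::tibble(
          mirna = ids$mirna[seq_len(d$n_prognostic)],
          direction = rep_len(c("high-risk", "low-risk"), d$n_prognostic)
        )
      } else {
        tibble::tibble(mirna = character(), direction = character())
      }
    )
    list(expression = expr, groups = groups, truth = truth)
  })
}

#' Generate genomic annotation for mRNAs and lncRNAs
#'
#' Places every mRNA and lncRNA on a small synthetic genome (5 chromosomes,
#' 0-based half-open intervals, random strand). A `cis_fraction` share of the
#' planted lncRNA-mRNA pairs is placed on the same chromosome with a boundary
#' gap drawn uniformly below 90% of the cis window, so they are unambiguously
#' cis-positive; the remaining planted lncRNAs land on a different chromosome
#' than their mRNA partner.
#'
#' @param design A [simulation_design()].
#' @param truth Planted truth from [simulate_expression()].
#' @param cis_window_bp Window used to place cis-positive pairs (default
#'   100,000 bp, matching the pipeline's cis filter).
#' @return Annotation tibble: `feature`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
simulate_annotation <- function(design, truth, cis_window_bp = 100000) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  with_stream(d$seed, 1L, {
    mrna_ids <- feature_ids("mRNA", d$n_mrna)
    lnc_ids <- feature_ids("lncRNA", d$n_lncrna)
    chroms <- paste0("chr", 1:5)
    rand_ann <- function(ids, width_mean) {
      n <- length(ids)
      start <- sample.int(2e8, n)
      width <- pmax(200L, as.integer(stats::rpois(n, width_mean)))
      tibble::tibble(feature = ids,
                     chrom = sample(chroms, n, replace = TRUE),
                     start = start, end = start + width,
                     strand = sample(c("+", "-"), n, replace = TRUE))
    }
    ann_m <- rand_ann(mrna_ids, 20000)
    ann_l <- rand_ann(lnc_ids, 2000)

    tri <- truth$triples
    if (nrow(tri) > 0) {
      n_cis <- round(d$cis_fraction * nrow(tri))
      for (i in seq_len(nrow(tri))) {
        im <- match(tri$mrna[i], ann_m$feature)
        il <- match(tri$lncrna[i], ann_l$feature)
        if (i <= n_cis) {
          gap <- as.integer(stats::runif(1, 0, 0.9 * cis_window_bp))
          ann_l$chrom[il] <- ann_m$chrom[im]
          ann_l$start[il] <- ann_m$end[im] + gap
          ann_l$end[il] <- ann_l$start[il] + 2000L
        } else {
          ann_l$chrom[il] <- setdiff(chroms, ann_m$chrom[im])[1]
        }
      }
    }
    dplyr::arrange(dplyr::bind_rows(ann_m, ann_l), .data$feature)
  })
}

#' Generate candidate miRNA-target evidence with decoys
#'
#' Every planted triple contributes a miRNA->mRNA pair attributed to a random
#' non-empty subset of the mRNA prediction sources (sourceA/B/C) and a
#' miRNA->lncRNA pair attributed to sources from the lncRNA pool (sourceA/D),
#' emulating multi-tool target prediction. Decoy pairs (uniform over
#' non-planted miRNA-target combinations) are added so that a
#' `decoy_edge_rate` fraction of all emitted pairs is false.
#'
#' @param design A [simulation_design()].
#' @param truth Planted truth from [simulate_expression()].
#' @return Evidence tibble with one row per (mirna, target, source):
#'   columns `mirna`, `target`, `target_class` (`"mRNA"`/`"lncRNA"`),
#'   `source`.
#' @export
simulate_evidence <- function(design, truth) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  with_stream(d$seed, 2L, {
    mrna_pool <- c("sourceA", "sourceB", "sourceC")
    lnc_pool <- c("sourceA", "sourceD")
    tri <- truth$triples
    pick <- function(pool) sample(pool, sample.int(length(pool), 1))
    planted <- NULL
    if (nrow(tri) > 0) {
      planted <- dplyr::bind_rows(
        purrr::map_dfr(seq_len(nrow(tri)), function(i) {
          dplyr::bind_rows(
            tibble::tibble(mirna = tri$mirna[i], target = tri$mrna[i],
                           target_class = "mRNA", source = pick(mrna_pool)),
            tibble::tibble(mirna = tri$mirna[i], target = tri$lncrna[i],
                           target_class = "lncRNA", source = pick(lnc_pool))
          )
        })
      )
    } else {
      planted <- tibble::tibble(mirna = character(), target = character(),
                                target_class = character(),
                                source = character())
    }
    n_planted_pairs <- 2L * nrow(tri)
    n_decoy <- round(d$decoy_edge_rate / (1 - d$decoy_edge_rate) *
                       n_planted_pairs)
    decoys <- NULL
    if (n_decoy > 0) {
      mirna_ids <- feature_ids("miRNA", d$n_mirna)
      targets <- c(feature_ids("mRNA", d$n_mrna),
                   feature_ids("lncRNA", d$n_lncrna))
      planted_keys <- paste(planted$mirna, planted$target)
      out <- list(); made <- 0L
      while (made < n_decoy) {
        mi <- sample(mirna_ids, n_decoy, replace = TRUE)
        tg <- sample(targets, n_decoy, replace = TRUE)
        keep <- !(paste(mi, tg) %in% planted_keys) & !duplicated(paste(mi, tg))
        mi <- mi[keep][seq_len(min(sum(keep), n_decoy - made))]
        tg <- tg[keep][seq_len(length(mi))]
        if (length(mi) == 0) next
        cls <- ifelse(startsWith(tg, "mRNA"), "mRNA", "lncRNA")
        src <- purrr::map2(cls, seq_along(cls), function(cl, i) {
          pick(if (cl == "mRNA") mrna_pool else lnc_pool)
        })
        out[[length(out) + 1L]] <- tibble::tibble(
          mirna = rep(mi, lengths(src)), target = rep(tg, lengths(src)),
          target_class = rep(cls, lengths(src)), source = unlist(src))
        made <- made + length(mi)
        planted_keys <- c(planted_keys, paste(mi, tg))
      }
      decoys <- dplyr::bind_rows(out)
    }
    dplyr::distinct(dplyr::bind_rows(planted, decoys))
  })
}

#' Simulate a survival cohort driven by prognostic miRNAs
#'
#' Emulates screening network miRNAs against an independent survival cohort:
#' a fresh cohort of `n_survival` subjects receives per-miRNA log-normal
#' expression; event times are exponential with per-subject rate
#' `surv_baseline_hazard * exp(sum beta_k z_k)` over the planted prognostic
#' miRNAs, where `z` is the standardized log expression and `beta_k` is
#' `+surv_beta` for high-risk and `-surv_beta` for low-risk miRNAs;
#' non-prognostic miRNAs have beta = 0. Censoring is independent uniform on
#' `(0, surv_censor_max)`.
#'
#' @param design A [simulation_design()].
#' @param truth Planted truth from [simulate_expression()].
#' @param expression Optional wide miRNA expression tibble to use as the
#'   cohort (features x subjects, FPKM scale); by default a fresh cohort is
#'   simulated.
#' @return A list with `survival` (tibble `sample`, `time`, `event`) and
#'   `expression` (wide miRNA FPKM tibble for the same subjects).
#' @export
simulate_survival <- function(design, truth, expression = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  with_stream(d$seed, 3L, {
    if (is.null(expression)) {
      subjects <- sprintf("pt_%03d", seq_len(d$n_survival))
      ids <- feature_ids("miRNA", d$n_mirna)
      z <- matrix(stats::rnorm(d$n_mirna * d$n_survival), d$n_mirna,
                  dimnames = list(ids, subjects))
      fpkm <- exp(d$baseline_log_mean + z)
      expression <- tibble::as_tibble(fpkm, rownames = "feature")
    } else {
      validate_expression(expression)
      subjects <- expr_sample_ids(expression)
    }
    zm <- t(scale(t(log(expr_values(expression) + 1e-9))))
    zm[is.na(zm)] <- 0
    beta <- stats::setNames(rep(0, nrow(expression)), expression$feature)
    if (nrow(truth$prognostic) > 0) {
      hit <- intersect(truth$prognostic$mirna, names(beta))
      dirs <- truth$prognostic$direction[match(hit, truth$prognostic$mirna)]
      beta[hit] <- ifelse(dirs == "high-risk", d$surv_beta, -d$surv_beta)
    }
    lp <- as.numeric(crossprod(zm, beta))
    rate <- d$surv_baseline_hazard * exp(lp)
    t_event <- stats::rexp(length(subjects), rate)
    t_cens <- stats::runif(length(subjects), 0, d$surv_censor_max)
    surv <- tibble::tibble(
      sample = subjects,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
    list(survival = surv, expression = expression)
  })
}

#' Simulate a complete synthetic study
#'
#' One call producing everything the pipeline consumes: the three expression
#' matrices with group labels, genomic annotation, candidate interaction
#' evidence, a survival cohort, and the planted truth used to score recovery.
#'
#' @param design A [simulation_design()].
#' @return A `cerna_simulation` list: `expression` (list `mrna`, `lncrna`,
#'   `mirna`), `groups`, `annotation`, `evidence`, `survival` (list
#'   `survival`, `expression`), `truth`, `design`.
#' @examples
#' sim <- simulate_study(simulation_design(n_mrna = 60, n_lncrna = 30,
#'                                         n_mirna = 20, n_de_per_class = 6,
#'                                         n_triples = 3, seed = 7))
#' names(sim)
#' @export
simulate_study <- function(design = simulation_design()) {
  base <- simulate_expression(design)
  ann <- simulate_annotation(design, base$truth)
  ev <- simulate_evidence(design, base$truth)
  surv <- simulate_survival(design, base$truth)
  structure(list(expression = base$expression, groups = base$groups,
                 annotation = ann, evidence = ev, survival = surv,
                 truth = base$truth, design = design),
            class = "cerna_simulation")
}
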