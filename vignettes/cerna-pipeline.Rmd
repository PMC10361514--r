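---
title: "Inferring ceRNA networks from tissue-exosome expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ceRNA networks from tissue-exosome expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cernet)
```

## The screening model

The competing endogenous RNA (ceRNA) hypothesis holds that a lncRNA can
sequester a miRNA and thereby de-repress that miRNA's mRNA targets. In
expression data this predicts a characteristic correlation signature for a
true lncRNA/miRNA/mRNA axis: the miRNA is negatively correlated with both
the lncRNA and the mRNA, while lncRNA and mRNA co-vary positively.

`cernet` implements the screening cascade commonly used on FPKM-scale
case/control profiles of the three RNA classes:

1. **Differential expression** per feature with the two-group Mann-Whitney
   U test plus three strict filters: abundance (group-mean FPKM > 5), raw
   significance (p < 0.05) and effect size (fold change > 1.5, applied
   symmetrically as FC > 1.5 or FC < 1/1.5).
2. **lncRNA target assignment**: *cis* targets lie within a symmetric
   100-kb genomic window (boundary gap, both upstream and downstream);
   *trans* targets require Pearson r > 0.95 between expression profiles.
3. **miRNA-target evidence**: candidate miRNA->mRNA and miRNA->lncRNA
   edges from multiple prediction sources are qualified by a configurable
   distinct-source count (default 1, i.e. the union).
4. **Triple assembly**: a candidate (lncRNA, miRNA, mRNA) whose two edges
   qualified and whose members all passed DE is kept when both
   miRNA-partner correlations are negative with |r| > 0.5.
5. **Network analysis**: triples form a tripartite graph (miRNA-lncRNA and
   miRNA-mRNA edges only, de-duplicated); hubs are nodes with degree > 5;
   two subtype networks can be intersected node- and edge-wise.
6. **Survival screen**: each network miRNA is dichotomized at the cohort
   median and tested with the two-sample log-rank statistic; each
   significant miRNA yields one survival axis aggregating all of its
   network partners.

All comparators are strict, exactly as the thresholds are conventionally
printed: FPKM = 5, FC = 1.5, p = 0.05, r = 0.5, r = 0.95 and a gap of
100,001 bp all *fail* their filters. The test suite pins this behaviour at
floating-point-exact boundary values.

## Parameters that matter

`pipeline_config()` collects every threshold; defaults reproduce the
screening settings above.

| parameter | default | unit / meaning |
|---|---|---|
| `fpkm_min` | 5 | FPKM; abundance floor (strict) |
| `fc_min` | 1.5 | fold change, symmetric (strict) |
| `p_max` | 0.05 | raw Mann-Whitney p; also the survival screen |
| `trans_r_min` | 0.95 | signed Pearson r for trans targets |
| `cerna_abs_r_min` | 0.5 | correlation magnitude for ceRNA couplings |
| `cis_window_bp` | 100,000 | boundary gap for cis pairing |
| `hub_min_degree` | 6 | implements degree > 5 |
| `mrna_sources_required`, `lncrna_sources_required` | 1 | evidence-source agreement |
| `pseudocount` | 0.01 | FPKM offset in the fold change |

Choices the data do not dictate, exposed as options:

- **Abundance rule.** "FPKM > 5" is read as *the larger group mean must
  exceed 5* (`abundance_rule = "max_group_mean"`), which keeps features
  expressed in only one condition — exactly the features a DE screen must
  see. Both-means and overall-mean readings are selectable.
- **Exact vs asymptotic p.** With at most 8 observations per group and no
  ties the U test enumerates exactly (the 8-vs-8 design size makes this
  cheap); otherwise the tie-corrected normal approximation with continuity
  correction is used. The suite checks the exact branch against full
  enumeration over all rank assignments.
- **No multiplicity correction in the filter.** The screen keys on the raw
  p-value; a Benjamini-Hochberg column is emitted for information only.
- **Correlation scale.** Pearson correlations (trans targets and triple
  assembly) are computed on log2(FPKM + 1) by default. On the raw scale a
  lognormal pair whose log-scale correlation is -0.9 shows a raw-scale
  Pearson r of only about -0.3 — the attenuation is severe and asymmetric
  for negative couplings, and would make the "negative with |r| > 0.5"
  rule nearly unsatisfiable at realistic dispersion. The raw scale remains
  available (`correlation_transform = "fpkm"`).
- **Correlation scope.** Correlations pool case and control samples of the
  comparison by default, since ceRNA co-variation is a cross-condition
  property; per-group scopes are available.
- **Evidence combination.** Multi-tool target predictions are combined as
  a union by default (requirement 1), preserving recall; the distinct
  source count is recorded per edge so an intersection policy is one
  config change away.
- **Optional lncRNA-mRNA check.** The canonical assembly rules constrain
  only the two miRNA arms; requiring the positive lncRNA-mRNA correlation
  (r > +0.5) as well is off by default and available as
  `lnc_mrna_check = TRUE`.
- **Survival dichotomization.** Median split with ties assigned to the low
  group. Optimal-cutpoint scanning is deliberately not implemented: it
  would require multiplicity control that a plain screen does not carry.
  Precomputed external per-miRNA p-values drop into `screen_axes()`
  unchanged, mirroring workflows that query a survival database instead of
  holding patient-level data.

## What the synthetic generator emulates

`simulate_study()` produces a complete, fully labelled study:
8 case vs 8 control samples (configurable), three FPKM matrices, genomic
annotation, multi-source interaction evidence with decoys, and an
independent survival cohort.

Log expression is `baseline + group effect + coupling + noise`:

- Baselines are N(2, 1) on the natural-log scale, putting the median
  feature near FPKM 7.4 so the FPKM > 5 filter bites on a non-trivial
  fraction of features. Planted DE features draw baselines from the upper
  half of this distribution so planted truth is recoverable above the
  abundance floor — otherwise exact-recovery checks would be impossible by
  construction; non-planted features keep the full distribution.
- Planted DE features gain ±log(`fc_effect`) (default FC 4) in the case
  group.
- Each planted triple shares a per-sample latent Gaussian factor, loaded
  negatively by the miRNA and positively by the lncRNA and mRNA, scaled so
  log-scale pairwise |r| approaches `corr_strength` (default 0.9) as
  `noise_sd` approaches 0. Triple DE directions are coherent (miRNA
  opposite its partners), as the ceRNA signature implies.
- Evidence edges carry source labels from the class-specific pools
  (sourceA/B/C for mRNA targets, sourceA/D for lncRNA targets); decoy
  pairs are added so a `decoy_edge_rate` fraction (default 0.3) of emitted
  pairs is false.
- Survival times are exponential with per-subject hazard
  `h0 * exp(sum(beta * z))` over planted prognostic miRNAs (standardized
  log expression `z`), censored uniformly. The cohort is simulated fresh
  (default 100 subjects), emulating screens against an external survival
  cohort rather than the small discovery set.

One root seed drives four documented child streams (expression,
annotation, evidence, survival at seed + 0..3), so a design is reproducible
byte for byte.

The generator does **not** emulate read-level sampling noise,
UMI/isoform structure, batch effects, library-size artefacts, or the
heavy-tailed dispersion of real exosome RNA-seq. Passing recovery tests
therefore demonstrate that the pipeline's logic is correct under its own
model assumptions — not that real tissue-exosome data will yield networks
of any particular size.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally (BED convention); GFF3 is
  converted at the file boundary and converted back on write, so both
  dialects round-trip identically.
- Constant expression profiles have undefined correlation: they are
  excluded and counted in a warning, never silently passed.
- A degenerate survival split (all expression values equal, or no events)
  yields a non-evaluable result, not an error, so one flat miRNA cannot
  abort a screen.
- Fold changes use a 0.01 FPKM pseudocount on both group means; direction
  is case-relative ("up" = higher in case).
- Hub ordering breaks degree ties lexicographically by id; triple tables
  are ordered (lncRNA, miRNA, mRNA) so outputs are deterministic.
- Transcript-suffixed ids (`SORBS3-203`) are compared verbatim;
  `intersect_networks(..., normalize_ids = TRUE)` strips `-NNN` suffixes
  for gene-level comparison of mixed id styles.

## Problem sizes used by the checks

The bundled checks run at desk scale, chosen to keep the full suite near a
minute while leaving every statistical property testable: default
simulated studies use 300 mRNAs, 150 lncRNAs, 80 miRNAs, 30 planted DE
features and 10 triples per class-set; the type-I check uses 2,000
null features; enumeration equivalence uses 220 random 5-vs-5 and 8-vs-8
draws; null log-rank behaviour uses 200 replicate cohorts of 50 subjects.
Recovery under the study conditions (|r| = 0.9, FC 4, log-noise 0.2, 30%
decoys) is averaged over 5 seeds.

Two simulated "subtypes" generated with different seeds share their planted
feature positions (ids are allocated deterministically), so their planted
networks intersect heavily — convenient for exercising the intersection
machinery, but not a statement about biological overlap.

## Known limitations

- The Mann-Whitney screen with raw p < 0.05 controls no family-wise or
  false-discovery rate; at 8-vs-8 the smallest exact p is 1/6,435, so
  extreme significance is unattainable and ranking leans on the fold
  change.
- Trans-target assignment at r > 0.95 with n = 16 is a very sharp filter
  (null tail ~1e-8); small sample correlation noise makes it conservative.
- The survival screen assumes proportional-hazards-like separation that a
  median split can see; crossing hazards will be missed.
- Evidence sources are treated as exchangeable labels; no per-source
  reliability weighting is attempted.
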