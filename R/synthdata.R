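#' Configuration of the synthetic study generator
#'
#' Defines a complete synthetic study: a bipartite miRNA-gene regulatory
#' ground truth with planted biomarker miRNAs, log-scale two-group
#' expression matrices for miRNAs and mRNAs, and a clinical table with a
#' planted association and survival difference. The defaults emulate the
#' shape of a two-group microarray biomarker study: a few hundred miRNAs,
#' a few thousand genes, tens of samples per group, and a small set of
#' biomarker miRNAs distinguished by many exclusively regulated targets
#' that are enriched for transcription factors.
#'
#' @param seed master integer seed; every downstream generator derives its
#'   stream from it.
#' @param n_mirnas,n_genes node counts of the regulatory ground truth.
#' @param background_edge_density probability of a background miRNA-gene
#'   edge.
#' @param n_planted number of planted biomarker miRNAs.
#' @param planted_exclusive_targets exclusive targets per planted miRNA
#'   (genes regulated by no other miRNA).
#' @param planted_tf_fraction probability an exclusive target is a
#'   transcription factor.
#' @param tf_background_fraction TF probability for background genes.
#' @param n_de_mirnas total differentially expressed miRNAs (the planted
#'   biomarkers plus ordinary DE miRNAs with no special network role).
#' @param n_samples_per_group samples per group in every expression study.
#' @param de_shift miRNA differential-expression shift, in units of
#'   `noise_sd`, applied uniformly to all disease samples.
#' @param gene_de_shift mRNA shift in units of `noise_sd`, applied in
#'   subgroup mode.
#' @param subgroup_fraction fraction of disease samples carrying the mRNA
#'   shift (outlier-style differential expression).
#' @param noise_sd within-group standard deviation on the log scale.
#' @param missing_rate fraction of mRNA cells set missing (for imputation
#'   exercises).
#' @param n_mrna_studies number of independent mRNA studies generated.
#' @param clinical_n number of clinical cases.
#' @param clinical_effect odds multiplier linking low expression to the
#'   adverse level of the associated clinical variable (1 = no
#'   association).
#' @param survival_hazards length-2 vector, exponential hazard per month
#'   for the high- and low-expression groups.
#' @param censor_time upper bound (months) of the uniform censoring time.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_mirnas = 300, n_genes = 2000,
                         background_edge_density = 0.1,
                         n_planted = 20, planted_exclusive_targets = 25,
                         planted_tf_fraction = 0.4,
                         tf_background_fraction = 0.1,
                         n_de_mirnas = 80,
                         n_samples_per_group = 20,
                         de_shift = 2, gene_de_shift = 3,
                         subgroup_fraction = 0.25,
                         noise_sd = 1, missing_rate = 0,
                         n_mrna_studies = 3,
                         clinical_n = 90, clinical_effect = 3,
                         survival_hazards = c(high = 0.03, low = 0.09),
                         censor_time = 60) {
  stopifnot(n_planted <= n_mirnas, n_de_mirnas >= n_planted,
            n_de_mirnas <= n_mirnas,
            background_edge_density > 0, background_edge_density < 1,
            planted_tf_fraction >= 0, planted_tf_fraction <= 1,
            tf_background_fraction >= 0, tf_background_fraction <= 1,
            subgroup_fraction > 0, subgroup_fraction <= 1,
            missing_rate >= 0, missing_rate < 1,
            noise_sd > 0, length(survival_hazards) == 2,
            all(survival_hazards > 0), censor_time > 0)
  if (n_planted * planted_exclusive_targets >= n_genes) {
    stop("requested exclusive targets exceed the available genes")
  }
  structure(as.list(environment()), class = "synth_config")
}

.synth_ids <- function(config) {
  list(mirnas = sprintf("miR-%03d", seq_len(config$n_mirnas)),
       genes = sprintf("G%04d", seq_len(config$n_genes)))
}

#' Generate interaction evidence with planted network structure
#'
#' Builds the ground-truth bipartite network and emits one evidence table
#' in the format consumed by [load_interactions]. Each planted biomarker
#' miRNA receives its block of exclusive targets (genes targeted by no
#' other miRNA) as low-throughput validated records, so they survive
#' network assembly deterministically. Background edges are sampled at the
#' configured density and dressed with evidence whose scores straddle the
#' prediction-filter thresholds: roughly half are validated (a quarter of
#' those only by high-throughput experiments, which the default filters
#' drop) and half are predicted by the three tools with scores drawn
#' across the cutoffs, so per-tool filtering and tool agreement are both
#' exercised.
#'
#' @param config a [synth_config].
#' @return list with `evidence` (data.frame), `tf_list` (character) and
#'   `truth` (list: planted miRNA ids, their exclusive targets, the DE
#'   miRNA ids and directions, the DE gene ids).
#' @export
generate_network_evidence <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 101L)
  ids <- .synth_ids(config)
  n_excl <- config$n_planted * config$planted_exclusive_targets
  planted <- ids$mirnas[seq_len(config$n_planted)]
  de_only <- if (config$n_de_mirnas > config$n_planted) {
    ids$mirnas[(config$n_planted + 1):config$n_de_mirnas]
  } else character()
  excl_genes <- ids$genes[seq_len(n_excl)]
  bg_genes <- ids$genes[(n_excl + 1):config$n_genes]

  excl_by_mirna <- split(excl_genes,
                         rep(planted, each = config$planted_exclusive_targets))
  tf_flag <- c(stats::runif(n_excl) < config$planted_tf_fraction,
               stats::runif(length(bg_genes)) < config$tf_background_fraction)
  tf_list <- ids$genes[tf_flag]

  # background edges: every non-planted miRNA vs background genes
  bg_mirnas <- setdiff(ids$mirnas, planted)
  hits <- which(matrix(stats::runif(length(bg_mirnas) * length(bg_genes)) <
                         config$background_edge_density,
                       nrow = length(bg_mirnas)), arr.ind = TRUE)
  bg_edges <- data.frame(mirna = bg_mirnas[hits[, 1]],
                         gene = bg_genes[hits[, 2]],
                         stringsAsFactors = FALSE)
  bg_edges <- bg_edges[order(bg_edges$mirna, bg_edges$gene), ]

  blank <- function(n) rep(NA_real_, n)
  ev_excl <- data.frame(
    mirna = rep(planted, each = config$planted_exclusive_targets),
    gene = excl_genes, source = "miRTarBase",
    evidence_class = "validated_low_throughput",
    hoctar_score = blank(n_excl), exprtarget_score = blank(n_excl),
    starbase_readnum = blank(n_excl), starbase_bc = blank(n_excl),
    stringsAsFactors = FALSE)

  n_bg <- nrow(bg_edges)
  kind <- sample(c("validated", "predicted"), n_bg, replace = TRUE)
  ev_bg <- list()
  val <- bg_edges[kind == "validated", ]
  if (nrow(val) > 0) {
    low <- stats::runif(nrow(val)) < 0.75
    ev_bg$validated <- data.frame(
      mirna = val$mirna, gene = val$gene,
      source = sample(c("miRTarBase", "TarBase", "miRecords", "miR2Disease"),
                      nrow(val), replace = TRUE),
      evidence_class = ifelse(low, "validated_low_throughput",
                              "validated_high_throughput"),
      hoctar_score = blank(nrow(val)), exprtarget_score = blank(nrow(val)),
      starbase_readnum = blank(nrow(val)), starbase_bc = blank(nrow(val)),
      stringsAsFactors = FALSE)
  }
  prd <- bg_edges[kind == "predicted", ]
  if (nrow(prd) > 0) {
    np <- nrow(prd)
    ev_bg$hoctar <- data.frame(
      mirna = prd$mirna, gene = prd$gene, source = "HOCTAR",
      evidence_class = "predicted",
      hoctar_score = round(stats::runif(np), 4),
      exprtarget_score = blank(np),
      starbase_readnum = blank(np), starbase_bc = blank(np),
      stringsAsFactors = FALSE)
    ev_bg$exprtarget <- data.frame(
      mirna = prd$mirna, gene = prd$gene, source = "ExprTarget",
      evidence_class = "predicted",
      hoctar_score = blank(np),
      exprtarget_score = round(stats::runif(np, 0, 2), 4),
      starbase_readnum = blank(np), starbase_bc = blank(np),
      stringsAsFactors = FALSE)
    ev_bg$starbase <- data.frame(
      mirna = prd$mirna, gene = prd$gene, source = "starBase",
      evidence_class = "predicted",
      hoctar_score = blank(np), exprtarget_score = blank(np),
      starbase_readnum = stats::rpois(np, 10),
      starbase_bc = sample(0:4, np, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  evidence <- do.call(rbind, c(list(ev_excl), unname(ev_bg)))
  rownames(evidence) <- NULL

  de_dir <- stats::setNames(
    rep_len(c("up", "down"), config$n_de_mirnas),
    c(planted, de_only))
  truth <- list(planted_mirnas = planted,
                exclusive_targets = excl_by_mirna,
                de_mirnas = names(de_dir),
                de_mirna_direction = de_dir,
                de_genes = excl_genes,
                tf_list = tf_list)
  list(evidence = evidence, tf_list = tf_list, truth = truth)
}

.base_matrix <- function(feature_ids, n_samples, noise_sd, prefix) {
  baseline <- stats::rnorm(length(feature_ids), mean = 7, sd = 1)
  values <- baseline + matrix(stats::rnorm(length(feature_ids) * n_samples,
                                           sd = noise_sd),
                              nrow = length(feature_ids))
  dimnames(values) <- list(feature_ids,
                           sprintf("%s%02d", prefix, seq_len(n_samples)))
  values
}

#' Generate miRNA and mRNA expression studies
#'
#' Gaussian log-scale intensity matrices with a disease and a control
#' group. Planted DE miRNAs are shifted by `de_shift * noise_sd` in all
#' disease samples (uniform mode), in the direction recorded in the truth.
#' Planted DE genes are shifted upward by `gene_de_shift * noise_sd` in a
#' random `subgroup_fraction` of disease samples (outlier mode, the regime
#' the cancer-outlier statistics are designed for). Missing values are
#' injected into the mRNA matrices at `missing_rate`.
#'
#' @param config a [synth_config].
#' @param truth the `truth` component from [generate_network_evidence].
#' @return list with `mirna` (an [expression_study]) and `mrna` (list of
#'   `n_mrna_studies` [expression_study] objects).
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 202L)
  ids <- .synth_ids(config)
  n <- config$n_samples_per_group
  groups <- rep(c("disease", "control"), each = n)
  d_idx <- seq_len(n)

  mirna_vals <- .base_matrix(ids$mirnas, 2 * n, config$noise_sd, "S")
  shift <- config$de_shift * config$noise_sd
  for (m in truth$de_mirnas) {
    sgn <- if (truth$de_mirna_direction[[m]] == "up") 1 else -1
    mirna_vals[m, d_idx] <- mirna_vals[m, d_idx] + sgn * shift
  }

  gshift <- config$gene_de_shift * config$noise_sd
  n_sub <- ceiling(config$subgroup_fraction * n)
  mrna <- lapply(seq_len(config$n_mrna_studies), function(s) {
    vals <- .base_matrix(ids$genes, 2 * n, config$noise_sd, "S")
    for (g in truth$de_genes) {
      sub <- sample(d_idx, n_sub)
      vals[g, sub] <- vals[g, sub] + gshift
    }
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(length(vals)) < config$missing_rate,
                     nrow = nrow(vals))
      # never blank a whole feature
      keep <- sample(2 * n, nrow(vals), replace = TRUE)
      miss[cbind(seq_len(nrow(vals)), keep)] <- FALSE
      vals[miss] <- NA_real_
    }
    expression_study(vals, groups)
  })
  list(mirna = expression_study(mirna_vals, groups), mrna = mrna)
}

#' Generate a synthetic clinical / tissue-microarray table
#'
#' Emits `clinical_n` tumor cases with a percent-positive and intensity
#' staining readout (so the weighted scoring rule can be applied), one
#' clinical variable (`tumor_size`) whose adverse level has the configured
#' odds association with low biomarker expression, one null variable
#' (`gender`), and exponential survival with group-specific hazards under
#' uniform censoring.
#'
#' @param config a [synth_config].
#' @return data.frame with columns `case_id`, `tissue`, `percent_positive`,
#'   `intensity`, `expression_class` (implied by the staining scores),
#'   `tumor_size` (`"<=5"`/`">5"`), `gender`, `time`, `event`.
#' @export
generate_clinical <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 303L)
  n <- config$clinical_n
  high <- stats::runif(n) < 1 / 3
  ws <- ifelse(high, sample(4:7, n, replace = TRUE),
               sample(0:3, n, replace = TRUE))
  ps <- pmin(ws, sample(0:4, n, replace = TRUE))
  ps <- pmax(ps, ws - 3L)
  is_ <- ws - ps
  pct_mid <- c(2, 15, 37, 62, 85)[ps + 1L]
  # adverse tumour size: baseline odds 1 for high expression, multiplied
  # by clinical_effect for low expression
  odds <- ifelse(high, 1, config$clinical_effect)
  large <- stats::runif(n) < odds / (1 + odds)
  gender <- sample(c("female", "male"), n, replace = TRUE)
  hz <- ifelse(high, config$survival_hazards[[1]], config$survival_hazards[[2]])
  t_event <- stats::rexp(n, rate = hz)
  t_cens <- stats::runif(n, 0.1, config$censor_time)
  data.frame(case_id = sprintf("case%03d", seq_len(n)),
             tissue = "tumor",
             percent_positive = pct_mid,
             intensity = .intensity_levels[is_ + 1L],
             expression_class = ifelse(high, "high", "low"),
             tumor_size = ifelse(large, ">5", "<=5"),
             gender = gender,
             time = round(pmin(t_event, t_cens), 3),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Write a full synthetic dataset to disk
#'
#' Emits `evidence.tsv`, `mirna_expr.tsv`, `mrna_expr_<i>.tsv`,
#' `groups.tsv`, `tf_list.txt`, `clinical.tsv` and `truth.json` in the
#' text formats the analysis modules consume. Regenerating with the same
#' configuration yields byte-identical files.
#'
#' @param config a [synth_config].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_data <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_network_evidence(config)
  expr <- generate_expression(config, net$truth)
  clin <- generate_clinical(config)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(net$evidence, "evidence.tsv")
  wt(data.frame(feature_id = rownames(expr$mirna$values),
                expr$mirna$values, check.names = FALSE), "mirna_expr.tsv")
  for (i in seq_along(expr$mrna)) {
    wt(data.frame(feature_id = rownames(expr$mrna[[i]]$values),
                  expr$mrna[[i]]$values, check.names = FALSE),
       sprintf("mrna_expr_%d.tsv", i))
  }
  wt(data.frame(sample = colnames(expr$mirna$values),
                group = as.character(expr$mirna$groups)), "groups.tsv")
  writeLines(net$tf_list, file.path(dir, "tf_list.txt"))
  wt(clin, "clinical.tsv")
  jsonlite::write_json(net$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
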