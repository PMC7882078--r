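#' Two-group expression study container
#'
#' Wraps a feature-by-sample matrix of log-scale intensities together with
#' a disease/control label per sample. Missing values are allowed until
#' imputation.
#'
#' @param values numeric matrix, features in rows (rownames are feature
#'   ids), samples in columns.
#' @param groups character or factor per-sample label, values `"disease"`
#'   or `"control"`, recycled against the columns of `values`.
#' @return Object of class `expression_study` with elements `values` and
#'   `groups` (factor with levels control, disease).
#' @export
expression_study <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop("`values` must have feature ids as rownames")
  }
  if (anyDuplicated(rownames(values))) stop("feature ids must be unique")
  groups <- factor(as.character(groups), levels = c("control", "disease"))
  if (length(groups) != ncol(values) || anyNA(groups)) {
    stop("`groups` must label every sample as 'disease' or 'control'")
  }
  if (any(table(groups) < 2)) {
    stop("each group needs at least 2 samples")
  }
  structure(list(values = values, groups = groups),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d features x %d samples (%d disease, %d control), %d missing\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "disease"), sum(x$groups == "control"),
              sum(is.na(x$values))))
  invisible(x)
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' A missing cell (feature f, sample s) is replaced by the mean value at s
#' over the k features nearest to f, where distance is Euclidean over the
#' samples observed in both features, normalized by the number of shared
#' samples. Only neighbours observed at s are eligible. Observed cells are
#' never changed.
#'
#' @param study an [expression_study].
#' @param k number of neighbours (default 10), at most `nrow - 1`.
#' @return The imputed [expression_study].
#' @export
knn_impute <- function(study, k = 10) {
  stopifnot(inherits(study, "expression_study"))
  x <- study$values
  if (!anyNA(x)) return(study)
  k <- as.integer(k)
  stopifnot(k >= 1, k <= nrow(x) - 1)
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stop("feature(s) with no observed values: ",
         paste(utils::head(rownames(x)[all_missing], 5), collapse = ", "))
  }
  need <- which(rowSums(is.na(x)) > 0)
  for (f in need) {
    # mean squared difference over co-observed samples of the *original*
    # matrix, per candidate row: imputed cells are never reused as donors
    diffs <- sweep(study$values, 2, study$values[f, ])
    d2 <- rowMeans(diffs^2, na.rm = TRUE)
    d2[f] <- Inf
    for (s in which(is.na(x[f, ]))) {
      cand <- which(!is.na(study$values[, s]))
      cand <- cand[cand != f & is.finite(d2[cand])]
      if (length(cand) == 0) {
        stop("no donor feature observed at sample ", colnames(x)[s])
      }
      ord <- cand[order(d2[cand], rownames(x)[cand])]
      nn <- ord[seq_len(min(k, length(ord)))]
      x[f, s] <- mean(study$values[nn, s])
    }
  }
  expression_study(x, study$groups)
}

.de_methods <- c("t", "COPA", "OS", "ORT", "MOST", "LSOSS")

#' Quantile with linear interpolation between closest ranks
#' @noRd
.lin_quantile <- function(x, p) {
  unname(stats::quantile(x, p, type = 7, names = FALSE))
}

# Expectation and SD of cumulative sums of descending Gaussian order
# statistics, by fixed-seed Monte Carlo, memoized per sample size.
.most_env <- new.env(parent = emptyenv())

.most_constants <- function(n, reps = 50000L) {
  key <- as.character(n)
  if (!is.null(.most_env[[key]])) return(.most_env[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(19680801L)
  z <- matrix(stats::rnorm(reps * n), nrow = reps)
  cs <- t(apply(z, 1, function(r) cumsum(sort(r, decreasing = TRUE))))
  res <- list(mu = colMeans(cs), sigma = apply(cs, 2, stats::sd))
  .most_env[[key]] <- res
  res
}

#' Cancer outlier differential-expression statistics
#'
#' Computes one of six per-feature two-group statistics. `t` is the Welch
#' two-sample t statistic (disease minus control). The remaining five are
#' outlier statistics sensitive to shifts confined to a subset of disease
#' samples:
#' \describe{
#'   \item{COPA}{the `r`-th percentile of disease values after centering by
#'     the pooled median and scaling by the pooled MAD.}
#'   \item{OS}{sum, over disease values exceeding `q75 + IQR` of the pooled
#'     data, of the pooled-median/MAD standardized values.}
#'   \item{ORT}{as OS but centered/scaled by the control-group median and
#'     MAD, with the outlier threshold `q75 + IQR` from control quartiles.}
#'   \item{MOST}{maximum over k of the standardized sum of the k largest
#'     disease values minus the control mean (scaled by the control SD),
#'     normalized by the Monte-Carlo expectation and SD of the
#'     corresponding sums of Gaussian order statistics.}
#'   \item{LSOSS}{the sorted disease values are split at the change point
#'     minimizing the within-subset sum of squares; the statistic is the
#'     difference between the upper-subset mean and the control mean,
#'     scaled by a pooled within-group variance estimate.}
#' }
#' Percentiles use linear interpolation between closest ranks. All
#' statistics target up-outliers; callers screen for down-outliers by
#' negating the data (see [de_genes]).
#'
#' @param disease,control numeric vectors, at least 2 values each.
#' @param method one of `"t"`, `"COPA"`, `"OS"`, `"ORT"`, `"MOST"`,
#'   `"LSOSS"`.
#' @param r COPA percentile (default 90).
#' @return The scalar statistic.
#' @export
outlier_statistic <- function(disease, control,
                              method = c("t", "COPA", "OS", "ORT", "MOST",
                                         "LSOSS"),
                              r = 90) {
  method <- match.arg(method)
  stopifnot(length(disease) >= 2, length(control) >= 2)
  pooled <- c(disease, control)
  switch(method,
    t = {
      nd <- length(disease); nc <- length(control)
      se <- sqrt(stats::var(disease) / nd + stats::var(control) / nc)
      (mean(disease) - mean(control)) / se
    },
    COPA = {
      med <- stats::median(pooled)
      s <- stats::mad(pooled)
      if (s == 0) stop("degenerate scale: pooled MAD is 0")
      (.lin_quantile(disease, r / 100) - med) / s
    },
    OS = {
      med <- stats::median(pooled)
      s <- stats::mad(pooled)
      if (s == 0) stop("degenerate scale: pooled MAD is 0")
      q <- .lin_quantile(pooled, c(0.25, 0.75))
      thr <- q[2] + (q[2] - q[1])
      out <- disease[disease > thr]
      sum((out - med) / s)
    },
    ORT = {
      med <- stats::median(control)
      s <- stats::mad(control)
      if (s == 0) stop("degenerate scale: control MAD is 0")
      q <- .lin_quantile(control, c(0.25, 0.75))
      thr <- q[2] + (q[2] - q[1])
      out <- disease[disease > thr]
      sum((out - med) / s)
    },
    MOST = {
      sc <- stats::sd(control)
      if (sc == 0) stop("degenerate scale: control SD is 0")
      d <- sort((disease - mean(control)) / sc, decreasing = TRUE)
      const <- .most_constants(length(d))
      max((cumsum(d) - const$mu) / const$sigma)
    },
    LSOSS = {
      d <- sort(disease, decreasing = TRUE)
      nd <- length(d); nc <- length(control)
      ss <- function(v) sum((v - mean(v))^2)
      best_k <- 1L; best_ss <- Inf
      for (k in seq_len(nd - 1)) {
        s2 <- ss(d[seq_len(k)]) + ss(d[(k + 1):nd])
        if (s2 < best_ss) { best_ss <- s2; best_k <- k }
      }
      pooled_var <- (best_ss + ss(control)) / (nd + nc - 3)
      if (pooled_var == 0) stop("degenerate scale: zero pooled variance")
      (mean(d[seq_len(best_k)]) - mean(control)) / sqrt(pooled_var)
    })
}

.study_stat <- function(study, method, r = 90, both_directions = TRUE) {
  d_idx <- study$groups == "disease"
  stats_up <- apply(study$values, 1, function(v) {
    outlier_statistic(v[d_idx], v[!d_idx], method, r = r)
  })
  if (method == "t" || !both_directions) return(stats_up)
  stats_dn <- apply(-study$values, 1, function(v) {
    outlier_statistic(v[d_idx], v[!d_idx], method, r = r)
  })
  ifelse(abs(stats_dn) > abs(stats_up), -stats_dn, stats_up)
}

#' Rank differentially expressed genes per study
#'
#' Computes the chosen statistic for every feature shared by all studies,
#' ranks by decreasing absolute statistic (ties broken by feature id), and
#' truncates each list to `ceiling(top_fraction * n_common)`. For the
#' outlier statistics both orientations are screened (the statistic of the
#' mirrored, negated data is used with a negative sign when it dominates).
#'
#' @param studies list of [expression_study]; the intersection of their
#'   feature universes is used.
#' @param method one of the six methods (see [outlier_statistic]).
#' @param top_fraction fraction of the common features to keep, in (0, 1].
#' @param r COPA percentile.
#' @return A list of character vectors (ranked feature ids), one per study.
#' @export
de_genes <- function(studies, method = .de_methods, top_fraction = 0.4,
                     r = 90) {
  method <- match.arg(method)
  stopifnot(top_fraction > 0, top_fraction <= 1, length(studies) >= 1)
  common <- Reduce(intersect, lapply(studies, function(s) rownames(s$values)))
  if (length(common) == 0) stop("studies share no features")
  n_keep <- ceiling(top_fraction * length(common))
  lapply(studies, function(s) {
    sub <- expression_study(s$values[common, , drop = FALSE], s$groups)
    stat <- .study_stat(sub, method, r = r)
    ord <- order(-abs(stat), common)
    common[ord][seq_len(n_keep)]
  })
}

#' Choose the DE method whose top lists are most consistent across studies
#'
#' For each method, the percentage overlap `100 * |A intersect B| / L` is
#' computed for every unordered pair of per-study top lists (all of common
#' length L) and averaged; the method with the highest mean overlap wins.
#' Ties are broken by the canonical method order (t, COPA, OS, ORT, MOST,
#' LSOSS) with a warning.
#'
#' @param lists_by_method named list (method -> list of per-study ranked
#'   feature id vectors, equal lengths).
#' @return A list with `best` (method name) and `report`, a data.frame with
#'   one row per method and columns `method` and `mean_overlap` (percent).
#' @export
select_method_by_overlap <- function(lists_by_method) {
  stopifnot(length(lists_by_method) >= 1)
  methods <- intersect(.de_methods, names(lists_by_method))
  if (length(methods) != length(lists_by_method)) {
    stop("unknown method name(s): ",
         paste(setdiff(names(lists_by_method), .de_methods), collapse = ", "))
  }
  mean_overlap <- vapply(methods, function(m) {
    lists <- lists_by_method[[m]]
    if (length(lists) < 2) return(100)
    len <- unique(lengths(lists))
    if (length(len) != 1) stop("per-study lists must have equal lengths")
    pairs <- utils::combn(length(lists), 2)
    mean(apply(pairs, 2, function(ij) {
      100 * length(intersect(lists[[ij[1]]], lists[[ij[2]]])) / len
    }))
  }, numeric(1))
  best <- methods[which(mean_overlap == max(mean_overlap))]
  if (length(best) > 1) {
    warning("overlap tie between methods ", paste(best, collapse = ", "),
            "; keeping ", best[1])
  }
  list(best = best[1],
       report = data.frame(method = methods, mean_overlap = mean_overlap,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Screen differentially expressed miRNAs by two-sample t test
#'
#' Welch's unequal-variance t test by default (set `var_equal = TRUE` for
#' the classical pooled-variance version). Features with zero variance in
#' both groups and equal means are untestable and skipped with a warning.
#'
#' @param study an [expression_study].
#' @param alpha two-sided significance threshold, strict (`p < alpha`).
#' @param var_equal assume equal group variances.
#' @return data.frame with columns `feature_id`, `statistic`, `p_value`,
#'   `direction` (`"up"` iff the disease mean exceeds the control mean),
#'   containing the features with `p < alpha`, ordered by p-value.
#' @export
de_mirnas <- function(study, alpha = 0.05, var_equal = FALSE) {
  stopifnot(inherits(study, "expression_study"), alpha > 0, alpha <= 1)
  d_idx <- study$groups == "disease"
  res <- lapply(rownames(study$values), function(f) {
    d <- study$values[f, d_idx]; c0 <- study$values[f, !d_idx]
    if (stats::var(d) == 0 && stats::var(c0) == 0 && mean(d) == mean(c0)) {
      return(NULL)
    }
    tt <- stats::t.test(d, c0, var.equal = var_equal)
    data.frame(feature_id = f, statistic = unname(tt$statistic),
               p_value = tt$p.value,
               direction = if (mean(d) > mean(c0)) "up" else "down",
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped > 0) {
    warning(skipped, " constant feature(s) skipped (untestable)")
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), statistic = numeric(),
                      p_value = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[out$p_value < alpha, , drop = FALSE]
  out[order(out$p_value, out$feature_id), , drop = FALSE]
}
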