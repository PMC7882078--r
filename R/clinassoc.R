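.intensity_levels <- c("negative", "weak", "moderate", "strong")

#' Weighted ISH/IHC staining score
#'
#' Combines the percentage of positive cells and the staining intensity
#' into the standard tissue-microarray weighted score. The percent bins
#' score 0-4 over the cuts 5/25/50/75 (a boundary value falls in the upper
#' bin: 5 scores 1, ..., 75 scores 4) and the intensity scores 0-3
#' (negative/weak/moderate/strong). The weighted score is their sum (0-7),
#' mapped to the category `-` (0-1), `+` (2-3), `++` (4-5), `+++` (6-7);
#' a specimen is classed as high expression when the weighted score is at
#' least 4 (`++` or `+++`).
#'
#' @param percent_positive percentage of positive cells in \[0, 100\]
#'   (vectorized).
#' @param intensity `"negative"`, `"weak"`, `"moderate"` or `"strong"`
#'   (vectorized, recycled).
#' @return data.frame with columns `percent_score` (0-4),
#'   `intensity_score` (0-3), `weighted_score` (0-7), `category`,
#'   `expression_class` (`"high"`/`"low"`).
#' @examples
#' weighted_score(80, "strong")   # 4 + 3 = 7, "+++", high
#' weighted_score(4, "negative")  # 0 + 0 = 0, "-", low
#' @export
weighted_score <- function(percent_positive, intensity) {
  if (any(percent_positive < 0 | percent_positive > 100)) {
    stop("percent_positive must lie in [0, 100]")
  }
  intensity <- match.arg(as.character(intensity), .intensity_levels,
                         several.ok = TRUE)
  n <- max(length(percent_positive), length(intensity))
  percent_positive <- rep_len(percent_positive, n)
  intensity <- rep_len(intensity, n)
  ps <- findInterval(percent_positive, c(5, 25, 50, 75))
  is_ <- match(intensity, .intensity_levels) - 1L
  ws <- ps + is_
  category <- c("-", "-", "+", "+", "++", "++", "+++", "+++")[ws + 1L]
  data.frame(percent_score = ps, intensity_score = is_,
             weighted_score = ws, category = category,
             expression_class = ifelse(ws >= 4, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared association for a 2x2 table
#'
#' Pearson's chi-squared test of independence without continuity
#' correction, with the two-sided p-value from the chi-squared(1) tail.
#'
#' @param table 2x2 matrix of non-negative counts (all margins > 0).
#' @return list with `table`, `chi2`, `p_value`.
#' @export
chi2_association <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  list(table = table, chi2 = unname(ct$statistic),
       p_value = unname(ct$p.value))
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie
#' correction (no continuity correction). The degenerate case of zero
#' rank-sum variance (all values tied) returns p = 1.
#'
#' @param a,b non-empty numeric vectors.
#' @return list with `U` (statistic for sample `a`) and `p_value`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  has_ties <- anyDuplicated(pooled) > 0
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!has_ties && n1 + n2 <= 20) {
    p <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = U, p_value = p)
}

#' Kaplan-Meier curves and log-rank test for a two-group comparison
#'
#' Product-limit survival estimates per group and the standard log-rank
#' chi-squared statistic over the pooled event times, with the two-sided
#' p-value from the chi-squared(1) tail. At coincident event and censoring
#' times, events precede censorings (the usual convention, as implemented
#' in the survival package).
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator (1 = death/event).
#' @param group two-level factor or character vector (e.g. high/low).
#' @return list with `curves` (data.frame: `group`, `time`, `n_risk`,
#'   `n_event`, `survival`), `chi2`, `p_value`, and the underlying
#'   `survival::survfit` object as `fit`.
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0)) {
    stop("exactly two non-empty groups are required")
  }
  if (sum(event) == 0) stop("at least one event is required")
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi2 <- unname(sd_$chisq)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, survival = fit$surv,
                       stringsAsFactors = FALSE)
  list(curves = curves, chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       fit = fit)
}
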