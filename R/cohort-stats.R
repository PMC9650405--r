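#' Gated contingency-table test
#'
#' Computes per-cell expected counts and applies the classical gate: a
#' Pearson chi-square test (without continuity correction) unless any
#' expected count is below 5, in which case Fisher's exact test is used.
#'
#' @param tab A 2 x K matrix of nonnegative integer counts.
#' @param correct Apply Yates continuity correction to the chi-square branch
#'   (default FALSE).
#' @return A `contingency_result`: list with `table`, `expected`,
#'   `test_used` (`"pearson_chi2"` or `"fisher_exact"`), `statistic`, `p_value`.
#' @export
contingency_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    res <- list(table = tab, expected = expected, test_used = "fisher_exact",
                statistic = NA_real_, p_value = ft$p.value)
  } else {
    ct <- stats::chisq.test(tab, correct = correct)
    res <- list(table = tab, expected = expected, test_used = "pearson_chi2",
                statistic = unname(ct$statistic), p_value = ct$p.value)
  }
  structure(res, class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> %s: statistic = %s, p = %.4g\n",
              x$test_used,
              if (is.na(x$statistic)) "-" else sprintf("%.4f", x$statistic),
              x$p_value))
  invisible(x)
}

#' Normality-gated two-sample comparison
#'
#' Shapiro-Wilk is applied to both samples at `alpha`; if both pass, a
#' pooled-variance two-sample t test is used, otherwise a Mann-Whitney U
#' test (exact for two small tie-free samples, normal approximation with tie
#' correction otherwise). Zero-variance samples are reported as untestable.
#'
#' @param x,y Numeric samples, each of length >= 3.
#' @param alpha Normality-gate level. Default 0.05.
#' @return A tibble with `test_used`, `statistic`, `p_value`.
#' @export
compare_continuous <- function(x, y, alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) stop("each sample needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(tibble::tibble(test_used = "none", statistic = NA_real_, p_value = NA_real_))
  sw <- function(v) {
    if (length(v) > 5000) v <- sample(v, 5000)
    stats::shapiro.test(v)$p.value
  }
  normal <- sw(x) > alpha && sw(y) > alpha
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    tibble::tibble(test_used = "t", statistic = unname(tt$statistic),
                   p_value = tt$p.value)
  } else {
    exact <- length(x) <= 20 && length(y) <= 20 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = FALSE))
    tibble::tibble(test_used = "mwu", statistic = unname(wt$statistic),
                   p_value = wt$p.value)
  }
}

#' Spearman rank correlation
#'
#' Tie-aware: the Pearson correlation of mid-ranks.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return The correlation coefficient.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  stats::cor(rank(x), rank(y))
}

#' Multivariable logistic regression with Wald inference
#'
#' Maximum-likelihood fit of a binomial GLM of `outcome` on `terms`; each
#' term is reported as a log-odds coefficient, odds ratio, 95% Wald
#' confidence interval and p value. Non-convergence and quasi-separation are
#' flagged rather than silently returned.
#'
#' @param data A data frame (e.g. from [simulate_cohort()]).
#' @param outcome Name of the binary outcome column.
#' @param terms Character vector of covariate column names.
#' @return A `logistic_fit` object; see [tidy.logistic_fit()].
#' @export
fit_logistic <- function(data, outcome = "complication",
                         terms = c("enlarged", "large_tumor")) {
  miss <- setdiff(c(outcome, terms), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(data) <= length(terms)) stop("more terms than observations", call. = FALSE)
  f <- stats::reformulate(terms, response = outcome)
  fit <- stats::glm(f, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  sm <- summary(fit)$coefficients
  separated <- any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  est <- unname(sm[, "Estimate"])
  se <- unname(sm[, "Std. Error"])
  tb <- tibble::tibble(
    term = rownames(sm),
    estimate = est,
    std_error = se,
    odds_ratio = exp(est),
    conf_low = exp(est - 1.96 * se),
    conf_high = exp(est + 1.96 * se),
    p_value = unname(sm[, "Pr(>|z|)"])
  )
  structure(list(terms = tb, glm = fit, converged = fit$converged,
                 separated = separated, n = stats::nobs(fit)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, converged = %s%s\n", x$n, x$converged,
              if (x$separated) " (possible separation)" else ""))
  print(x$terms)
  invisible(x)
}

#' Logit propensity scores for enlarged-group membership
#'
#' Fits a logistic model of the exposure on the matching covariates and
#' returns the linear predictor (logit of the fitted propensity).
#'
#' @param cohort A cohort data frame.
#' @param covariates Covariate columns. Default `c("age", "cci", "uniportal")`.
#' @param group Exposure column. Default `"enlarged"`.
#' @return Numeric vector of logit scores, one per row of `cohort`.
#' @export
propensity_scores <- function(cohort, covariates = c("age", "cci", "uniportal"),
                              group = "enlarged") {
  fit <- fit_logistic(cohort, outcome = group, terms = covariates)
  unname(stats::predict(fit$glm, type = "link"))
}

#' Greedy 1:k propensity matching with a logit caliper
#'
#' Cases are processed in descending score order; each receives up to `k`
#' unused controls, nearest in logit distance, within the caliper (default
#' 0.1 standard deviations of the pooled logit scores). Matching is without
#' replacement; ties are broken by smallest id; cases with at least one
#' in-caliper control are retained (variable 1..k matching).
#'
#' @param cohort A cohort data frame with an `id` column.
#' @param scores Logit propensity scores aligned with `cohort` rows.
#' @param k Maximum controls per case. Default 4.
#' @param caliper Absolute logit caliper; default `0.1 * sd(scores)`. A
#'   caliper of 0 yields an empty match.
#' @param group Exposure column. Default `"enlarged"`.
#' @return A `match_result`: tibble of `(case_id, control_id, distance)`
#'   pairs plus `caliper`, `k`, `unmatched_cases`.
#' @export
greedy_match <- function(cohort, scores, k = 4, caliper = NULL,
                         group = "enlarged") {
  if (length(scores) != nrow(cohort)) stop("scores must align with cohort rows", call. = FALSE)
  if (is.null(caliper)) caliper <- 0.1 * stats::sd(scores)
  ids <- cohort$id
  is_case <- as.logical(cohort[[group]])
  if (!any(is_case) || !any(!is_case)) stop("need at least one case and one control", call. = FALSE)

  case_ord <- order(-scores[is_case], ids[is_case])
  case_ids <- ids[is_case][case_ord]
  case_sc <- scores[is_case][case_ord]
  ctrl_ids <- ids[!is_case]
  ctrl_sc <- scores[!is_case]
  used <- rep(FALSE, length(ctrl_ids))

  pairs <- vector("list", length(case_ids))
  for (ci in seq_along(case_ids)) {
    if (caliper <= 0) break
    d <- abs(ctrl_sc - case_sc[ci])
    cand <- which(!used & d <= caliper)
    if (!length(cand)) next
    cand <- cand[order(d[cand], ctrl_ids[cand])]
    take <- cand[seq_len(min(k, length(cand)))]
    used[take] <- TRUE
    pairs[[ci]] <- tibble::tibble(case_id = case_ids[ci],
                                  control_id = ctrl_ids[take],
                                  distance = d[take])
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0)
    pairs <- tibble::tibble(case_id = integer(), control_id = integer(),
                            distance = numeric())
  matched_cases <- unique(pairs$case_id)
  structure(list(pairs = pairs, caliper = caliper, k = k,
                 matched_cases = matched_cases,
                 unmatched_cases = setdiff(case_ids, matched_cases)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d cases matched to %d controls (caliper %.4g, 1:%d max); %d cases unmatched\n",
              length(x$matched_cases), nrow(x$pairs), x$caliper, x$k,
              length(x$unmatched_cases)))
  invisible(x)
}

#' Subset a cohort to the matched sample
#'
#' @param cohort The cohort data frame used in [greedy_match()].
#' @param match A `match_result`.
#' @return The rows of `cohort` belonging to matched cases and their controls.
#' @export
matched_cohort <- function(cohort, match) {
  keep <- c(match$matched_cases, match$pairs$control_id)
  dplyr::filter(cohort, .data$id %in% keep)
}

#' Standardized mean differences before and after matching
#'
#' `SMD = (mean_case - mean_control) / sqrt((var_case + var_control) / 2)`,
#' computed on the full cohort and on the matched sample.
#'
#' @param cohort A cohort data frame.
#' @param match A `match_result`.
#' @param covariates Covariate columns (numeric or logical).
#' @param group Exposure column. Default `"enlarged"`.
#' @return A tibble with `covariate`, `smd_before`, `smd_after`
#'   (class `smd_balance`).
#' @export
balance_smd <- function(cohort, match, covariates = c("age", "cci", "uniportal"),
                        group = "enlarged") {
  smd_one <- function(df, cov) {
    g <- as.logical(df[[group]])
    x1 <- as.numeric(df[[cov]][g]); x0 <- as.numeric(df[[cov]][!g])
    pooled <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
    dm <- mean(x1) - mean(x0)
    if (!is.finite(pooled) || pooled == 0) {
      if (abs(dm) < 1e-12) return(0)
      warning("zero pooled variance with unequal means for ", cov, call. = FALSE)
      return(NA_real_)
    }
    dm / pooled
  }
  post <- matched_cohort(cohort, match)
  out <- tibble::tibble(
    covariate = covariates,
    smd_before = vapply(covariates, function(cv) smd_one(cohort, cv), numeric(1),
                        USE.NAMES = FALSE),
    smd_after = vapply(covariates, function(cv) smd_one(post, cv), numeric(1),
                       USE.NAMES = FALSE)
  )
  class(out) <- c("smd_balance", class(out))
  out
}

#' Percentage with half-up rounding
#'
#' Formats `100 * count / total` rounded half-up to `digits` decimals, the
#' convention used in clinical summary tables (e.g. 20/29 -> 69.0).
#'
#' @param count,total Counts.
#' @param digits Decimal places. Default 1.
#' @return Numeric percentage.
#' @export
percent_half_up <- function(count, total, digits = 1) {
  x <- 100 * count / total
  f <- 10^digits
  floor(x * f + 0.5) / f
}

fmt_count_pct <- function(count, total, digits = 1) {
  if (total == 0) return("-")
  sprintf(paste0("%d (%.", digits, "f%%)"), count,
          percent_half_up(count, total, digits))
}

fmt_mean_sd <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))
}

#' Two-group summary table with gated p values
#'
#' Renders the standard clinical baseline table: `n (%)` with one-decimal
#' half-up rounding for categorical variables (with the chi-square / Fisher
#' gate), `mean +/- SD` for continuous variables (with the normality-gated
#' t / Mann-Whitney comparison).
#'
#' @param cohort A cohort data frame.
#' @param vars Columns to summarize.
#' @param group Grouping column (logical). Default `"enlarged"`.
#' @param digits Decimals for percentages and means. Default 1.
#' @return A tibble with one row per variable: formatted overall and
#'   per-group cells, the test used, and the p value.
#' @export
summarize_groups <- function(cohort, vars = c("age", "cci", "uniportal",
                                              "large_tumor", "complication"),
                             group = "enlarged", digits = 1) {
  g <- as.logical(cohort[[group]])
  if (sum(g) == 0 || sum(!g) == 0)
    warning("a group is empty; rows rendered as '-'", call. = FALSE)
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (is.logical(x) || all(x %in% c(0, 1, NA))) {
      x <- as.logical(x)
      cell <- function(sel) if (!any(sel)) "-" else fmt_count_pct(sum(x[sel], na.rm = TRUE), sum(sel), digits)
      tab <- rbind(c(sum(x[!g], na.rm = TRUE), sum(!x[!g], na.rm = TRUE)),
                   c(sum(x[g], na.rm = TRUE), sum(!x[g], na.rm = TRUE)))
      p <- tryCatch({
        ct <- contingency_test(tab)
        c(ct$test_used, ct$p_value)
      }, error = function(e) c("none", NA_real_))
      tibble::tibble(variable = v, type = "categorical",
                     overall = cell(rep(TRUE, length(x))),
                     group0 = cell(!g), group1 = cell(g),
                     test_used = p[1], p_value = as.numeric(p[2]))
    } else {
      cell <- function(sel) if (!any(sel)) "-" else fmt_mean_sd(x[sel], digits)
      p <- tryCatch({
        cc <- compare_continuous(x[g], x[!g])
        c(cc$test_used, cc$p_value)
      }, error = function(e) c("none", NA_real_))
      tibble::tibble(variable = v, type = "continuous",
                     overall = cell(rep(TRUE, length(x))),
                     group0 = cell(!g), group1 = cell(g),
                     test_used = p[1], p_value = as.numeric(p[2]))
    }
  })
  dplyr::bind_rows(rows)
}
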