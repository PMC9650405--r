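test_that("Pearson chi-square equals the closed-form sum over cells", {
  tab <- matrix(c(20, 46, 9, 59), nrow = 2) # complications by group
  res <- contingency_test(tab)
  expect_identical(res$test_used, "pearson_chi2")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected), tolerance = 1e-10)
  # perfect independence
  flat <- contingency_test(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("Fisher's exact branch equals full hypergeometric enumeration", {
  tab <- matrix(c(1, 13, 9, 3), nrow = 2) # min expected count 4.6
  res <- contingency_test(tab)
  expect_identical(res$test_used, "fisher_exact")
  # oracle: enumerate all tables with these margins, sum P(table) <= P(obs)
  rs <- rowSums(tab); cs <- colSums(tab)
  p_obs <- stats::dhyper(tab[1, 1], rs[1], rs[2], cs[1])
  ks <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- stats::dhyper(ks, rs[1], rs[2], cs[1])
  p_oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
})

test_that("the expected<5 gate matches a brute-force expected-count oracle", {
  set.seed(31)
  for (i in 1:50) {
    tab <- matrix(stats::rpois(4, sample(c(2, 8, 25), 1)) + 1, 2, 2)
    res <- contingency_test(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    want <- if (any(expected < 5)) "fisher_exact" else "pearson_chi2"
    expect_identical(res$test_used, want)
  }
})

test_that("normality gating selects t for gaussian and MWU for skewed samples", {
  set.seed(12)
  x <- stats::rnorm(200, 54.4, 9.3)
  y <- stats::rnorm(200, 61.0, 9.7)
  res <- compare_continuous(x, y)
  expect_identical(res$test_used, "t")
  expect_lt(res$p_value, 0.001)
  skew <- compare_continuous(stats::rexp(100), stats::rexp(100))
  expect_identical(skew$test_used, "mwu")
  # identical gaussian-looking samples: t statistic 0, p = 1
  z <- stats::rnorm(50)
  same <- compare_continuous(z, z)
  if (same$test_used == "t") expect_equal(unname(same$statistic), 0)
  expect_gt(same$p_value, 0.99)
  none <- compare_continuous(rep(1, 10), rep(2, 10))
  expect_identical(none$test_used, "none")
})

test_that("spearman_corr is the tie-aware rank correlation", {
  expect_equal(spearman_corr(1:7, (1:7)^3), 1.0)
  expect_equal(spearman_corr(1:7, -(1:7)^3), -1.0)
  # toy with one tie, against the mid-rank Pearson formula assembled by hand
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 3, 5, 4, 6)
  rx <- c(1, 2.5, 2.5, 4, 5, 6)
  ry <- c(2, 1, 3, 5, 4, 6)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_corr(x, y), num / den, tolerance = 1e-12)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("logistic odds ratios equal the 2x2 cross-product for one binary term", {
  set.seed(44)
  n <- 4000
  x <- stats::runif(n) < 0.3
  y <- stats::runif(n) < stats::plogis(-0.5 + 1.1 * x)
  fit <- fit_logistic(data.frame(complication = y, enlarged = x),
                      terms = "enlarged")
  tab <- table(x, y)
  cross <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_equal(tidy(fit)$odds_ratio[2], unname(cross), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("a null generator is covered by the Wald intervals", {
  set.seed(9)
  co <- simulate_cohort(cohort_params(n = 10000, or_enlarged = 1,
                                      or_large_tumor = 1, seed = 77L))
  fit <- fit_logistic(co)
  td <- tidy(fit)[-1, ] # drop intercept
  expect_true(all(td$conf_low <= 1 & 1 <= td$conf_high))
  g <- glance(fit)
  expect_identical(g$n, 10000L)
})

test_that("generative odds ratios are recovered across seeded cohorts", {
  ors <- t(vapply(1:10, function(s) {
    co <- simulate_cohort(default_cohort_params(n = 50000, seed = 1000L + s))
    unname(tidy(fit_logistic(co))$odds_ratio[2:3])
  }, numeric(2)))
  expect_lt(abs(mean(ors[, 1]) - 3.084) / 3.084, 0.05)
  expect_lt(abs(mean(ors[, 2]) - 3.173) / 3.173, 0.05)
})

test_that("propensity scores discriminate exactly when the generator confounds", {
  co <- simulate_cohort(default_cohort_params(n = 20000, seed = 55L))
  sc <- propensity_scores(co)
  expect_length(sc, nrow(co))
  expect_gt(mean(sc[co$enlarged]), mean(sc[!co$enlarged]))
  expect_identical(sc, propensity_scores(co)) # deterministic
  # null cohort: near-zero discrimination (AUC ~ 0.5)
  null <- simulate_cohort(cohort_params(n = 20000, age_shift_enlarged = 0,
                                        cci_shift_enlarged = 0, seed = 56L))
  nsc <- propensity_scores(null)
  auc <- mean(outer(nsc[null$enlarged], nsc[!null$enlarged], ">") +
                0.5 * outer(nsc[null$enlarged], nsc[!null$enlarged], "=="))
  expect_lt(abs(auc - 0.5), 0.03)
})

test_that("greedy matching follows the hand-worked example and tie rules", {
  co <- tibble::tibble(id = 1:5, enlarged = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  scores <- c(0.0, 1.0, 0.05, 0.06, 0.9)
  m <- greedy_match(co, scores, k = 2, caliper = 0.2)
  pairs <- tidy(m)
  expect_setequal(pairs$control_id[pairs$case_id == 2], 5)
  expect_setequal(pairs$control_id[pairs$case_id == 1], c(3, 4))
  # zero caliper: no matches at all
  empty <- greedy_match(co, scores, k = 2, caliper = 0)
  expect_identical(nrow(tidy(empty)), 0L)
  # all-tied scores: k nearest controls by smallest id
  co2 <- tibble::tibble(id = 1:11, enlarged = c(TRUE, rep(FALSE, 10)))
  m2 <- greedy_match(co2, rep(0.3, 11), k = 4, caliper = 0.1)
  expect_identical(sort(tidy(m2)$control_id), 2:5)
})

test_that("matching output always satisfies its structural contract", {
  set.seed(60)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    co <- tibble::tibble(id = seq_len(n),
                         enlarged = stats::runif(n) < stats::runif(1, 0.1, 0.4))
    if (!any(co$enlarged) || all(co$enlarged)) next
    scores <- stats::rnorm(n)
    k <- sample(1:5, 1)
    m <- greedy_match(co, scores, k = k)
    pairs <- tidy(m)
    if (nrow(pairs) == 0) next
    expect_lte(max(table(pairs$case_id)), k)
    expect_false(any(duplicated(pairs$control_id)))
    expect_true(all(pairs$distance <= m$caliper + 1e-12))
    expect_true(all(pairs$control_id %in% co$id[!co$enlarged]))
  }
})

test_that("matching shrinks the generated confounder imbalance", {
  co <- simulate_cohort(default_cohort_params(n = 4000, seed = 70L))
  sc <- propensity_scores(co)
  m <- greedy_match(co, sc)
  bal <- balance_smd(co, m)
  expect_lt(bal$smd_before[bal$covariate == "age"], 0) # enlarged younger
  expect_lt(abs(bal$smd_after[bal$covariate == "age"]),
            abs(bal$smd_before[bal$covariate == "age"]))
  # identical groups give SMD zero
  co_id <- tibble::tibble(id = 1:40, enlarged = rep(c(TRUE, FALSE), 20),
                          age = rep(c(60, 60), 20), cci = 2L,
                          uniportal = rep(c(TRUE, FALSE), 20))
  m_id <- greedy_match(co_id, rep(0, 40), caliper = 1)
  bal_id <- balance_smd(co_id, m_id, covariates = "age")
  expect_equal(bal_id$smd_before, 0)
})

test_that("group summaries format counts and percentages the clinical way", {
  expect_equal(percent_half_up(29, 383, 2), 7.57)
  expect_equal(percent_half_up(20, 29, 1), 69.0)
  expect_equal(percent_half_up(1, 16, 1), 6.3) # 6.25 rounds half-up
  co <- simulate_cohort(default_cohort_params(n = 800, seed = 90L))
  s <- summarize_groups(co)
  expect_identical(nrow(s), 5L)
  expect_true(all(c("overall", "group0", "group1", "p_value") %in% names(s)))
  expect_match(s$overall[s$variable == "uniportal"], "^[0-9]+ \\([0-9.]+%\\)$")
  expect_match(s$overall[s$variable == "age"], "±")
  # empty group renders dashes with a warning
  co0 <- dplyr::mutate(co, enlarged = FALSE)
  expect_warning(s0 <- summarize_groups(co0), "empty")
  expect_true(all(s0$group1 == "-"))
})
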