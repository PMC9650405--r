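#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a logistic fit into a term-level tibble
#'
#' @param x A `logistic_fit` from [fit_logistic()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (log-odds), `std_error`,
#'   `odds_ratio`, `conf_low`, `conf_high` (95% Wald, on the OR scale) and
#'   `p_value`.
#' @export
tidy.logistic_fit <- function(x, ...) x$terms

#' @rdname tidy.logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(n = x$n, converged = x$converged, separated = x$separated,
                 deviance = x$glm$deviance, aic = x$glm$aic)
}

#' Tidy a match result into a case-control pair tibble
#'
#' @param x A `match_result` from [greedy_match()].
#' @param ... Unused.
#' @return The pair tibble `(case_id, control_id, distance)`.
#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @rdname tidy.match_result
#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(n_cases = length(x$matched_cases),
                 n_controls = nrow(x$pairs),
                 n_unmatched = length(x$unmatched_cases),
                 caliper = x$caliper, k = x$k)
}

#' Tidy a contingency test
#'
#' @param x A `contingency_result` from [contingency_test()].
#' @param ... Unused.
#' @return One-row tibble with `test_used`, `statistic`, `p_value`.
#' @export
tidy.contingency_result <- function(x, ...) {
  tibble::tibble(test_used = x$test_used, statistic = x$statistic,
                 p_value = x$p_value)
}
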