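#' Isoform fraction from junction read counts
#'
#' The isoform fraction (psi) of an alternative event is the proportion of
#' exon-exon junction-spanning ("spliced") reads supporting the inclusion
#' isoform: `inc / (inc + exc)`.
#'
#' @param inc,exc Non-negative integer counts of inclusion- and
#'   exclusion-junction reads (vectorized).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' isoform_fraction(30, 10)  # 0.75
#' @export
isoform_fraction <- function(inc, exc) {
  assert_count_vector(inc, "inc")
  assert_count_vector(exc, "exc")
  total <- inc + exc
  if (any(total == 0)) {
    abort("Untestable event: inc + exc must be >= 1.",
          class = "ptbseq_untestable_error")
  }
  inc / total
}

#' Exact binomial test for differential isoform usage
#'
#' Tests, per event, whether the isoform fraction in condition B differs from
#' condition A, using junction-spanning read counts only. The null isoform
#' fraction is the pooled fraction across both conditions,
#' `p_hat = (a_inc + b_inc) / (a_inc + a_exc + b_inc + b_exc)`; the p-value is
#' the exact binomial tail probability of the observed B inclusion count under
#' `Binomial(b_inc + b_exc, p_hat)`. The default two-sided p-value doubles the
#' smaller one-sided tail and caps at 1.
#'
#' The p-value is converted to a log-odds score,
#' `log_base((1 - p) / p)`, used to rank events; `p` is floored at machine
#' epsilon first so the score is finite, and a p-value capped at 1 maps to a
#' log-odds of 0. With the default base 10, a score of 1 corresponds to
#' 10-to-1 odds — the same quorum as a minimum Bayes factor of 10.
#'
#' @param a_inc,a_exc Inclusion/exclusion junction read counts in condition A
#'   (control); vectorized.
#' @param b_inc,b_exc Same for condition B (mutant).
#' @param alternative Sidedness of the test: `"two.sided"` (default),
#'   `"less"` or `"greater"` (B inclusion fraction below/above the pooled
#'   fraction).
#' @param log_base Base of the log-odds transform (default 10).
#' @return A tibble with columns `p_value` and `log_odds`.
#' @examples
#' binomial_isoform_test(20, 0, 0, 20)  # p ~ 1.9e-6
#' @export
binomial_isoform_test <- function(a_inc, a_exc, b_inc, b_exc,
                                  alternative = c("two.sided", "less", "greater"),
                                  log_base = 10) {
  alternative <- match.arg(alternative)
  assert_count_vector(a_inc, "a_inc")
  assert_count_vector(a_exc, "a_exc")
  assert_count_vector(b_inc, "b_inc")
  assert_count_vector(b_exc, "b_exc")
  n_a <- a_inc + a_exc
  n_b <- b_inc + b_exc
  if (any(n_a == 0 | n_b == 0)) {
    abort("Untestable event: both condition totals must be >= 1.",
          class = "ptbseq_untestable_error")
  }
  p_hat <- (a_inc + b_inc) / (n_a + n_b)
  lower <- pbinom(b_inc, n_b, p_hat)
  upper <- pbinom(b_inc - 1, n_b, p_hat, lower.tail = FALSE)
  p <- switch(alternative,
    two.sided = pmin(1, 2 * pmin(lower, upper)),
    less = lower,
    greater = upper
  )
  tibble(p_value = p, log_odds = p_to_log_odds(p, log_base))
}

# Floor p at machine epsilon before the odds transform; a p capped at 1
# (odds <= 0) is reported as log-odds 0.
p_to_log_odds <- function(p, log_base = 10) {
  eps <- .Machine$double.eps
  p_f <- pmin(pmax(p, eps), 1)
  odds <- (1 - p_f) / p_f
  ifelse(odds <= 0, 0, log(odds, base = log_base))
}

#' Unsigned fold-change between two isoform fractions
#'
#' The fold-change reported for differential isoform events is the unsigned
#' ratio of the two isoform fractions, `max(psi_a, psi_b) / min(psi_a,
#' psi_b)`, so it is always `>= 1`; direction is recoverable from the sign of
#' `delta_psi`. When exactly one fraction is zero the ratio is unbounded and
#' the sentinel `Inf` is returned (serialized as `"Large"` by
#' [write_isoform_calls()]); when both are zero the fold-change is 1.
#'
#' @param psi_a,psi_b Isoform fractions in `[0, 1]`; vectorized.
#' @return Numeric vector of fold-changes `>= 1`, possibly `Inf`.
#' @examples
#' isoform_fold_change(0.42, 0.20)  # 2.1
#' isoform_fold_change(0.27, 0)     # Inf ("Large")
#' @export
isoform_fold_change <- function(psi_a, psi_b) {
  assert_fraction(psi_a, "psi_a")
  assert_fraction(psi_b, "psi_b")
  hi <- pmax(psi_a, psi_b)
  lo <- pmin(psi_a, psi_b)
  dplyr::case_when(
    hi == 0 ~ 1,
    lo == 0 ~ Inf,
    TRUE ~ hi / lo
  )
}

#' Convert a Bayes factor to its null probability
#'
#' A minimum Bayes factor of `bf` corresponds to `bf`-to-1 odds that the
#' event call is real, i.e. a probability of `1 / (1 + bf)` that it arose by
#' chance alone. The filter threshold of 10 used for candidate calling maps
#' to 0.0909.
#'
#' @param bf Positive Bayes factor(s).
#' @return Probability in `(0, 1)`.
#' @examples
#' bayes_factor_to_null_probability(10)  # 0.0909...
#' @export
bayes_factor_to_null_probability <- function(bf) {
  if (!is.numeric(bf) || any(is.na(bf)) || any(bf <= 0)) {
    abort("`bf` must be a positive Bayes factor.", class = "ptbseq_input_error")
  }
  1 / (1 + bf)
}

#' Call differential isoform usage across a table of junction events
#'
#' Applies [binomial_isoform_test()] to every event and the two candidate
#' filters used for alternative-splicing calling: a minimum absolute isoform
#' fraction difference (`delta_psi_min`, default 0.2) and a minimum log-odds
#' score (`log_odds_min`, default 1, i.e. 10-to-1 odds). Events with zero
#' total reads in either condition are untestable: they are kept in the
#' output with `status = "untestable"` and `NA` statistics, never silently
#' dropped.
#'
#' @param events Tibble with columns `event_id`, `a_inc`, `a_exc`, `b_inc`,
#'   `b_exc`, and optionally `gene_id` and `event_class` (carried through).
#' @param delta_psi_min Minimum `|psi_b - psi_a|` for significance.
#' @param log_odds_min Minimum log-odds score for significance.
#' @param alternative,log_base Passed to [binomial_isoform_test()].
#' @param adjust If `TRUE`, add a Benjamini-Hochberg adjusted p-value column
#'   `p_adjusted` (the filters themselves are unchanged; no multiple-testing
#'   correction is applied by default).
#' @return A tibble of class `isoform_calls`, one row per event, sorted by
#'   descending `log_odds` (ties broken by `event_id`): `event_id`, carried
#'   annotation columns, `psi_a`, `psi_b`, `delta_psi`, `p_value`,
#'   `log_odds`, `fold_change`, `significant`, `status`.
#' @examples
#' events <- tibble::tibble(event_id = "e1", a_inc = 40, a_exc = 60,
#'                          b_inc = 10, b_exc = 90)
#' call_differential_isoforms(events)
#' @export
call_differential_isoforms <- function(events, delta_psi_min = 0.2,
                                       log_odds_min = 1,
                                       alternative = "two.sided",
                                       log_base = 10, adjust = FALSE) {
  required <- c("event_id", "a_inc", "a_exc", "b_inc", "b_exc")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    abort(sprintf("`events` lacks required columns: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "ptbseq_input_error")
  }
  for (col in c("a_inc", "a_exc", "b_inc", "b_exc")) {
    assert_count_vector(events[[col]], col)
  }
  testable <- (events$a_inc + events$a_exc >= 1) &
    (events$b_inc + events$b_exc >= 1)

  calls <- events |>
    dplyr::mutate(
      psi_a = NA_real_, psi_b = NA_real_, delta_psi = NA_real_,
      p_value = NA_real_, log_odds = NA_real_, fold_change = NA_real_,
      significant = FALSE,
      status = ifelse(testable, "ok", "untestable")
    )
  if (any(testable)) {
    t <- calls[testable, ]
    test <- binomial_isoform_test(t$a_inc, t$a_exc, t$b_inc, t$b_exc,
                                  alternative = alternative,
                                  log_base = log_base)
    calls$psi_a[testable] <- isoform_fraction(t$a_inc, t$a_exc)
    calls$psi_b[testable] <- isoform_fraction(t$b_inc, t$b_exc)
    calls$delta_psi[testable] <- calls$psi_b[testable] - calls$psi_a[testable]
    calls$p_value[testable] <- test$p_value
    calls$log_odds[testable] <- test$log_odds
    calls$fold_change[testable] <-
      isoform_fold_change(calls$psi_a[testable], calls$psi_b[testable])
    calls$significant[testable] <-
      abs(calls$delta_psi[testable]) >= delta_psi_min &
      calls$log_odds[testable] >= log_odds_min
  }
  if (adjust) {
    calls$p_adjusted <- p.adjust(calls$p_value, method = "BH")
  }
  calls <- calls |>
    dplyr::arrange(dplyr::desc(.data$log_odds), .data$event_id)
  class(calls) <- c("isoform_calls", class(calls))
  calls
}

#' Read a junction-event count table
#'
#' Tab-separated with a required header; expected columns `event_id`,
#' `gene_id`, `event_class`, `a_inc`, `a_exc`, `b_inc`, `b_exc` (annotation
#' columns optional).
#'
#' @param path Path to the TSV file.
#' @return A tibble of junction events.
#' @export
read_junction_counts <- function(path) {
  events <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("event_id", "a_inc", "a_exc", "b_inc", "b_exc")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    abort(sprintf("Junction count TSV lacks required columns: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "ptbseq_parse_error")
  }
  events
}

#' Write isoform calls to a TSV file
#'
#' Unbounded fold-changes (`Inf`) are serialized as the literal string
#' `"Large"`.
#'
#' @param calls An `isoform_calls` tibble from [call_differential_isoforms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isoform_calls <- function(calls, path) {
  out <- as_tibble(calls)
  out$fold_change <- ifelse(is.infinite(out$fold_change), "Large",
                            format(out$fold_change, trim = TRUE, digits = 6))
  out$fold_change[is.na(calls$fold_change)] <- NA
  readr::write_tsv(out, path)
  invisible(path)
}
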