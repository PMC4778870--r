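test_that("isoform fractions are simple read ratios with guarded input", {
  expect_equal(isoform_fraction(30, 10), 0.75)
  expect_equal(isoform_fraction(0, 7), 0)
  expect_error(isoform_fraction(0, 0), class = "ptbseq_untestable_error")
  expect_error(isoform_fraction(-1, 5), class = "ptbseq_input_error")
})

test_that("binomial test matches hand-derived tail probabilities", {
  # symmetric observation under the pooled null is uninformative
  res <- binomial_isoform_test(5, 5, 5, 5)
  expect_equal(res$p_value, 1)
  expect_equal(res$log_odds, 0)

  # complete switch at depth 20: doubled lower tail 2 * 2^-20
  res <- binomial_isoform_test(20, 0, 0, 20)
  expect_equal(res$p_value, 1.9073486328125e-06, tolerance = 1e-12)

  # 27% inclusion in control vs none in mutant: doubled lower tail at 0
  # of Binomial(100, 0.135) = 2 * 0.865^100
  res <- binomial_isoform_test(27, 73, 0, 100)
  expect_equal(res$p_value, 1.006099057468432e-06, tolerance = 1e-12)

  expect_error(binomial_isoform_test(0, 0, 5, 5),
               class = "ptbseq_untestable_error")
  expect_error(binomial_isoform_test(-2, 3, 5, 5),
               class = "ptbseq_input_error")
})

test_that("two-sided p-values agree with exhaustive PMF summation", {
  grid <- expand.grid(n_a = c(1, 3, 7, 12), n_b = c(1, 4, 9, 12))
  for (g in seq_len(nrow(grid))) {
    n_a <- grid$n_a[[g]]; n_b <- grid$n_b[[g]]
    combos <- expand.grid(a_inc = 0:n_a, b_inc = 0:n_b)
    got <- binomial_isoform_test(combos$a_inc, n_a - combos$a_inc,
                                 combos$b_inc, n_b - combos$b_inc)$p_value
    want <- mapply(oracle_binom_p, combos$a_inc, n_a - combos$a_inc,
                   combos$b_inc, n_b - combos$b_inc)
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
})

test_that("relabelling isoforms or swapping conditions behaves coherently", {
  events <- withr::with_seed(42, tibble::tibble(
    event_id = sprintf("e%03d", 1:50),
    a_inc = rpois(50, 20), a_exc = rpois(50, 20) + 1,
    b_inc = rpois(50, 35), b_exc = rpois(50, 10) + 1
  ))
  fwd <- dplyr::arrange(tidy(call_differential_isoforms(events)), event_id)

  # exchanging the inclusion/exclusion labels mirrors the null fraction and
  # leaves the two-sided p-value exactly unchanged
  relab <- dplyr::rename(events, a_inc = a_exc, a_exc = a_inc,
                         b_inc = b_exc, b_exc = b_inc)
  mir <- dplyr::arrange(tidy(call_differential_isoforms(relab)), event_id)
  expect_equal(fwd$p_value, mir$p_value, tolerance = 1e-12)
  expect_equal(fwd$delta_psi, -mir$delta_psi, tolerance = 1e-12)

  # swapping the two conditions negates delta_psi; the exact test is
  # anchored on condition B, so its p-value is reproducible but not the
  # identical number — the two orientations must still agree closely
  swapped <- dplyr::rename(events, a_inc = b_inc, a_exc = b_exc,
                           b_inc = a_inc, b_exc = a_exc)
  rev <- dplyr::arrange(tidy(call_differential_isoforms(swapped)), event_id)
  expect_equal(fwd$delta_psi, -rev$delta_psi, tolerance = 1e-12)
  expect_gt(stats::cor(log(fwd$p_value), log(rev$p_value)), 0.9)
})

test_that("fold-change is the unsigned psi ratio with a Large sentinel", {
  expect_equal(isoform_fold_change(0.42, 0.20), 2.1)
  expect_equal(isoform_fold_change(0.27, 0), Inf)
  expect_equal(isoform_fold_change(0, 0.27), Inf)
  expect_equal(isoform_fold_change(0.5, 0.5), 1)
  expect_equal(isoform_fold_change(0, 0), 1)
  expect_error(isoform_fold_change(1.2, 0.5), class = "ptbseq_input_error")

  # fold_change == 1 iff psi_a == psi_b when both are nonzero
  psi <- withr::with_seed(9, tibble::tibble(a = runif(100, 0.01, 1),
                                            b = runif(100, 0.01, 1)))
  fc <- isoform_fold_change(psi$a, psi$b)
  expect_equal(fc == 1, psi$a == psi$b)
  expect_true(all(fc >= 1))
})

test_that("Bayes factors convert to null probabilities via 1/(1+bf)", {
  expect_equal(bayes_factor_to_null_probability(1), 0.5)
  expect_equal(bayes_factor_to_null_probability(1e9), 1e-9,
               tolerance = 1e-6)
  expect_error(bayes_factor_to_null_probability(0),
               class = "ptbseq_input_error")
  expect_error(bayes_factor_to_null_probability(-3),
               class = "ptbseq_input_error")
})

test_that("calling applies both candidate filters and keeps untestable rows", {
  events <- tibble::tibble(
    event_id = c("big_shift", "tiny_shift_deep", "weak", "dead"),
    a_inc = c(40, 2500, 11, 0), a_exc = c(60, 2500, 9, 0),
    b_inc = c(90, 3000, 12, 0), b_exc = c(10, 2000, 8, 0)
  )
  calls <- call_differential_isoforms(events)
  expect_equal(nrow(calls), 4)

  by_id <- function(id) calls[calls$event_id == id, ]
  expect_true(by_id("big_shift")$significant)
  # delta_psi = 0.1 fails the 0.2 filter no matter how extreme the log-odds
  expect_equal(by_id("tiny_shift_deep")$delta_psi, 0.1, tolerance = 1e-12)
  expect_gt(by_id("tiny_shift_deep")$log_odds, 1)
  expect_false(by_id("tiny_shift_deep")$significant)
  expect_false(by_id("weak")$significant)
  expect_equal(by_id("dead")$status, "untestable")
  expect_true(is.na(by_id("dead")$p_value))

  # sorted by descending log-odds, untestable rows last
  lo <- calls$log_odds
  expect_true(all(diff(lo[!is.na(lo)]) <= 0))
  expect_true(is.na(lo[length(lo)]))

  adj <- call_differential_isoforms(events, adjust = TRUE)
  expect_true("p_adjusted" %in% names(adj))
})

test_that("isoform calls serialize with the Large sentinel and read back", {
  events <- tibble::tibble(event_id = c("a", "b"),
                           a_inc = c(27, 30), a_exc = c(73, 70),
                           b_inc = c(0, 20), b_exc = c(100, 80))
  calls <- call_differential_isoforms(events)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_isoform_calls(calls, tsv)
  raw <- readr::read_tsv(tsv, show_col_types = FALSE,
                         col_types = readr::cols(fold_change = "c"))
  expect_equal(raw$fold_change[raw$event_id == "a"], "Large")

  counts_tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(events, counts_tsv)
  expect_equal(read_junction_counts(counts_tsv)$event_id, events$event_id)
  readr::write_tsv(events[, c("event_id", "a_inc")], counts_tsv)
  expect_error(read_junction_counts(counts_tsv),
               class = "ptbseq_parse_error")
})

test_that("tidiers and autoplot work on call tables", {
  sim <- simulate_junction_counts(30, depth = 50,
                                  psi_pairs = tibble::tibble(psi_a = 0.5,
                                                             psi_b = 0.8),
                                  seed = 5)
  calls <- call_differential_isoforms(sim$events)
  g <- glance(calls)
  expect_equal(g$n_events, 30)
  expect_s3_class(autoplot(calls), "ggplot")
  expect_false(inherits(tidy(calls), "isoform_calls"))
})
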