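#' Expected gene-set overlap by chance
#'
#' The mean intersection size of two random sets of fixed sizes drawn
#' uniformly without replacement from a universe: `n_a * n_b / n_universe`
#' (the hypergeometric mean).
#'
#' @param n_a,n_b Set sizes.
#' @param n_universe Universe size (`>= 1`).
#' @return The expected intersection size.
#' @examples
#' expected_overlap(10, 10, 100)  # 1
#' @export
expected_overlap <- function(n_a, n_b, n_universe) {
  if (n_universe < 1) {
    abort("n_universe must be >= 1.", class = "ptbseq_input_error")
  }
  if (any(c(n_a, n_b) < 0) || any(c(n_a, n_b) > n_universe)) {
    abort("Set sizes must lie in [0, n_universe].", class = "ptbseq_input_error")
  }
  n_a * n_b / n_universe
}

#' Gene-set overlap test against a chance baseline
#'
#' Compares the observed intersection of two gene sets with the number
#' expected by chance for random sets of the same sizes drawn from the
#' universe, and attaches a one-sided (enrichment) hypergeometric p-value,
#' `P(X >= observed)`.
#'
#' @param set_a,set_b Character vectors of gene ids; must be duplicate-free
#'   and subsets of `universe`.
#' @param universe Character vector of all eligible gene ids.
#' @return An object of class `overlap_result` with fields `n_a`, `n_b`,
#'   `n_universe`, `observed`, `expected`, `enrichment_ratio`, `p_value`.
#'   Use [tidy()] to get a one-row tibble.
#' @examples
#' u <- paste0("g", 1:200)
#' overlap_test(u[1:30], u[19:58], u)
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  for (nm in c("set_a", "set_b")) {
    s <- get(nm)
    if (anyDuplicated(s)) {
      abort(sprintf("`%s` contains duplicate ids: %s.", nm,
                    paste(unique(s[duplicated(s)]), collapse = ", ")),
            class = "ptbseq_input_error")
    }
    outside <- setdiff(s, universe)
    if (length(outside) > 0) {
      abort(sprintf("`%s` contains ids outside the universe: %s.", nm,
                    paste(utils::head(outside, 10), collapse = ", ")),
            class = "ptbseq_input_error")
    }
  }
  n_a <- length(set_a)
  n_b <- length(set_b)
  n_universe <- length(universe)
  observed <- length(intersect(set_a, set_b))
  expected <- expected_overlap(n_a, n_b, n_universe)
  p_value <- phyper(observed - 1, n_a, n_universe - n_a, n_b,
                    lower.tail = FALSE)
  structure(
    list(n_a = n_a, n_b = n_b, n_universe = n_universe,
         observed = observed, expected = expected,
         enrichment_ratio = if (expected > 0) observed / expected else NA_real_,
         p_value = p_value),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Gene-set overlap: %d observed (%.1f expected by chance; ratio %.2f)\n",
    x$observed, x$expected,
    if (is.na(x$enrichment_ratio)) NA else x$enrichment_ratio))
  cat(sprintf("  |A| = %d, |B| = %d, universe = %d\n", x$n_a, x$n_b, x$n_universe))
  cat(sprintf("  hypergeometric P(X >= observed) = %.3g\n", x$p_value))
  invisible(x)
}

#' @rdname overlap_test
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, n_universe = x$n_universe,
         observed = x$observed, expected = x$expected,
         enrichment_ratio = x$enrichment_ratio, p_value = x$p_value)
}

#' @rdname overlap_test
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) tidy(x)
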