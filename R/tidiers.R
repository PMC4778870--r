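#' Tidy and summarize isoform call tables
#'
#' `tidy()` returns the calls as a plain tibble; `glance()` gives a one-row
#' summary of the screen.
#'
#' @param x An `isoform_calls` tibble from [call_differential_isoforms()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy isoform_calls
#' @export
tidy.isoform_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "isoform_calls")
  as_tibble(out)
}

#' @rdname tidy.isoform_calls
#' @method glance isoform_calls
#' @export
glance.isoform_calls <- function(x, ...) {
  tibble(
    n_events = nrow(x),
    n_testable = sum(x$status == "ok"),
    n_significant = sum(x$significant, na.rm = TRUE),
    min_p_value = suppressWarnings(min(x$p_value, na.rm = TRUE)),
    max_log_odds = suppressWarnings(max(x$log_odds, na.rm = TRUE))
  )
}

#' @rdname estimate_truncation
#' @param x A `truncation_estimate`.
#' @param ... Unused.
#' @method tidy truncation_estimate
#' @export
tidy.truncation_estimate <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "truncation_estimate")
  as_tibble(out)
}

#' @rdname estimate_truncation
#' @method glance truncation_estimate
#' @export
glance.truncation_estimate <- function(x, ...) {
  tibble(full_length_fraction = x$full_length_fraction,
         truncated_fraction = x$truncated_fraction)
}
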