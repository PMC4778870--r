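#' Mean per-base coverage over an interval
#'
#' @param profile A single contiguous coverage profile: tibble with columns
#'   `chrom`, `pos` (0-based) and `depth`, as produced by [read_coverage()]
#'   or [simulate_coverage_pair()].
#' @param start,end 0-based half-open genomic interval; must lie entirely
#'   within the profile.
#' @return The arithmetic mean of the per-base depths over the interval.
#' @examples
#' prof <- tibble::tibble(chrom = "chr1", pos = 0:3, depth = c(0, 0, 10, 10))
#' mean_coverage(prof, 0, 4)  # 5
#' @export
mean_coverage <- function(profile, start, end) {
  if (end <= start) {
    abort("Empty interval: end must exceed start.", class = "ptbseq_input_error")
  }
  sel <- profile$pos >= start & profile$pos < end
  if (sum(sel) != end - start) {
    abort("Interval extends outside the coverage profile.",
          class = "ptbseq_input_error")
  }
  mean(profile$depth[sel])
}

#' Estimate transcript truncation at an insertion breakpoint
#'
#' Quantifies how much of a transcript pool is truncated at a transposon
#' insertion from the coverage drop-off: the fraction of full-length
#' transcripts remaining in the mutant is the mutant downstream/upstream
#' coverage ratio normalized by the same ratio in the control,
#' `(mut_down / mut_up) / (ctl_down / ctl_up)`, clamped to `[0, 1]`. The
#' control normalization cancels 3'/5' coverage bias shared by both
#' genotypes. A P-element insertion that truncates ~96% of transcripts leaves
#' a full-length fraction of ~0.04.
#'
#' Upstream/downstream are taken along the transcript (i.e. swapped for
#' minus-strand genes). `exclusion_nt` bases on each side of the breakpoint
#' can be omitted, since reads spanning the insertion junction are
#' unmappable in a window of unknown width.
#'
#' @param mutant,control Coverage profiles (tibbles with `chrom`, `pos`,
#'   `depth`) covering the breakpoint with at least one base on each side
#'   beyond `exclusion_nt`.
#' @param breakpoint 0-based genomic coordinate of the insertion point.
#' @param strand Transcript strand, `"+"` (default) or `"-"`.
#' @param exclusion_nt Bases excluded on each side of the breakpoint
#'   (default 0).
#' @param gene_id Optional gene label carried into the result.
#' @return A one-row tibble of class `truncation_estimate`: `gene_id`,
#'   `breakpoint`, `upstream_mean`, `downstream_mean`,
#'   `control_upstream_mean`, `control_downstream_mean`,
#'   `full_length_fraction`, `truncated_fraction`.
#' @export
estimate_truncation <- function(mutant, control, breakpoint, strand = "+",
                                exclusion_nt = 0, gene_id = NA_character_) {
  if (!strand %in% c("+", "-")) {
    abort("strand must be '+' or '-'.", class = "ptbseq_input_error")
  }
  side_means <- function(profile) {
    lo <- min(profile$pos); hi <- max(profile$pos) + 1L
    left <- c(lo, breakpoint - exclusion_nt)
    right <- c(breakpoint + exclusion_nt, hi)
    if (left[[2]] <= left[[1]] || right[[2]] <= right[[1]]) {
      abort("Profile must cover >= 1 base on each side of the breakpoint beyond exclusion_nt.",
            class = "ptbseq_input_error")
    }
    m <- c(mean_coverage(profile, left[[1]], left[[2]]),
           mean_coverage(profile, right[[1]], right[[2]]))
    if (strand == "-") rev(m) else m  # upstream first, along the transcript
  }
  mut <- side_means(mutant)
  ctl <- side_means(control)
  if (mut[[1]] == 0) {
    abort("Zero mutant upstream coverage: truncation estimate undefined.",
          class = "ptbseq_estimate_error")
  }
  if (ctl[[1]] == 0 || ctl[[2]] == 0) {
    abort("Zero control coverage ratio: truncation estimate undefined.",
          class = "ptbseq_estimate_error")
  }
  flf <- (mut[[2]] / mut[[1]]) / (ctl[[2]] / ctl[[1]])
  flf <- min(max(flf, 0), 1)
  out <- tibble(
    gene_id = gene_id,
    breakpoint = breakpoint,
    upstream_mean = mut[[1]],
    downstream_mean = mut[[2]],
    control_upstream_mean = ctl[[1]],
    control_downstream_mean = ctl[[2]],
    full_length_fraction = flf,
    truncated_fraction = 1 - flf
  )
  class(out) <- c("truncation_estimate", class(out))
  out
}
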