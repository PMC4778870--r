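#' Read per-base coverage from a bedGraph file
#'
#' Expands a 4-column bedGraph (0-based, half-open; plain or gzip-compressed)
#' into per-base depths. Abutting intervals on the same chromosome are merged
#' into a single contiguous profile; a gap in coverage starts a new profile.
#'
#' @param path Path to a bedGraph file.
#' @return A tibble with columns `profile` (integer id of each contiguous
#'   run), `chrom`, `pos` (0-based base position) and `depth`. Positions
#'   within a profile are consecutive.
#' @seealso [write_coverage()], [mean_coverage()]
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("bedGraph file not found: %s", path), class = "ptbseq_io_error")
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) {
    return(tibble(profile = integer(), chrom = character(),
                  pos = integer(), depth = numeric()))
  }
  if (any(gr$score < 0)) {
    abort("bedGraph contains negative coverage values.",
          class = "ptbseq_parse_error")
  }
  df <- as.data.frame(gr)
  iv <- tibble(
    chrom = as.character(df$seqnames),
    start = df$start - 1L,  # back to 0-based half-open
    end = df$end,
    depth = df$score
  ) |>
    dplyr::arrange(.data$chrom, .data$start)

  iv <- iv |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      overlaps = .data$start < dplyr::lag(cummax(.data$end), default = -1L),
      new_profile = .data$start != dplyr::lag(.data$end, default = -1L)
    ) |>
    dplyr::ungroup()
  if (any(iv$overlaps)) {
    bad <- iv[iv$overlaps, ][1, ]
    abort(sprintf("Overlapping bedGraph intervals on %s near position %d.",
                  bad$chrom, bad$start),
          class = "ptbseq_parse_error")
  }
  iv$profile <- cumsum(iv$new_profile)
  iv |>
    dplyr::reframe(
      chrom = rep(.data$chrom, .data$end - .data$start),
      pos = unlist(purrr::map2(.data$start, .data$end, ~seq.int(.x, .y - 1L))),
      depth = rep(.data$depth, .data$end - .data$start),
      .by = "profile"
    ) |>
    as_tibble()
}

#' Write per-base coverage to a bedGraph file
#'
#' Collapses runs of equal depth back into 0-based half-open intervals.
#'
#' @param coverage Tibble as returned by [read_coverage()] (columns `profile`,
#'   `chrom`, `pos`, `depth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  if (nrow(coverage) == 0L) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  runs <- coverage |>
    dplyr::group_split(.data$profile) |>
    purrr::map(function(df) {
      r <- rle(df$depth)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      tibble(chrom = df$chrom[starts],
             start = df$pos[starts],
             end = df$pos[ends] + 1L,
             depth = r$values)
    }) |>
    dplyr::bind_rows()
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s", runs$chrom, runs$start, runs$end,
            format(runs$depth, trim = TRUE, scientific = FALSE)),
    path
  )
  invisible(path)
}
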