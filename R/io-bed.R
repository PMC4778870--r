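#' Write conserved-site hits to a BED6 file
#'
#' Serializes scanner hits (see [scan_alignment()]) as BED6: 0-based
#' half-open coordinates, the supporting-species count in the score column,
#' and the hit strand.
#'
#' @param hits Tibble with columns `chrom`, `ref_start`, `ref_end`,
#'   `n_support`, `strand`, and optionally `name` (generated from the
#'   coordinates when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_hits <- function(hits, path) {
  if (nrow(hits) == 0L) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(hits)) hits$name else
    sprintf("%s:%d-%d", hits$chrom, hits$ref_start, hits$ref_end)
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s\t%d\t%s",
            hits$chrom, as.integer(hits$ref_start), as.integer(hits$ref_end),
            name, as.integer(hits$n_support), hits$strand),
    path
  )
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One gene id per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @return A character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines[!grepl("^(#|$)", lines)]
}
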