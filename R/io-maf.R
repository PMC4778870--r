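#' Read alignment blocks from a MAF file
#'
#' Parses a multiz-style multiple alignment format (MAF) file (plain or
#' gzip-compressed) into a tidy row-per-species table. MAF coordinates are
#' 0-based; for minus-strand rows the start counts from the 5' end of the
#' reverse-complemented source sequence, per the format standard.
#'
#' Each block is validated: all gapped rows must have equal length, and the
#' ungapped residue count of each row must match the size field declared on
#' its `s` line.
#'
#' @param path Path to a MAF file.
#' @return A tibble with one row per species per block: `block` (1-based
#'   block index in file order), `species`, `chrom`, `start` (0-based),
#'   `size` (ungapped length), `strand`, `src_size` (source sequence length)
#'   and `text` (the gapped row). An empty file yields an empty tibble.
#' @export
read_alignment_blocks <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("MAF file not found: %s", path), class = "ptbseq_io_error")
  }
  lines <- readr::read_lines(path)
  empty <- tibble(block = integer(), species = character(), chrom = character(),
                  start = integer(), size = integer(), strand = character(),
                  src_size = integer(), text = character())
  if (length(lines) == 0L) return(empty)

  block <- 0L
  rows <- list()
  for (ln in lines) {
    if (grepl("^a( |$)", ln) || identical(ln, "a")) {
      block <- block + 1L
    } else if (grepl("^s\\s", ln)) {
      if (block == 0L) {
        abort("MAF s-line before any a-line.", class = "ptbseq_parse_error")
      }
      fields <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(fields) != 7L) {
        abort(sprintf("Malformed MAF s-line in block %d: expected 7 fields.", block),
              class = "ptbseq_parse_error")
      }
      src <- fields[[2]]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0) substr(src, 1, dot - 1) else src
      chrom <- if (dot > 0) substr(src, dot + 1, nchar(src)) else NA_character_
      rows[[length(rows) + 1L]] <- tibble(
        block = block,
        species = species,
        chrom = chrom,
        start = as.integer(fields[[3]]),
        size = as.integer(fields[[4]]),
        strand = fields[[5]],
        src_size = as.integer(fields[[6]]),
        text = toupper(fields[[7]])
      )
    }
    # i/e/q and comment lines are ignored
  }
  if (length(rows) == 0L) return(empty)
  maf <- dplyr::bind_rows(rows)

  for (b in unique(maf$block)) {
    rows_b <- maf[maf$block == b, ]
    widths <- nchar(rows_b$text)
    if (length(unique(widths)) > 1L) {
      abort(sprintf("MAF block %d: rows have unequal gapped lengths.", b),
            class = "ptbseq_parse_error")
    }
    ungapped <- nchar(degap(rows_b$text))
    if (any(ungapped != rows_b$size)) {
      bad <- rows_b$species[ungapped != rows_b$size][[1]]
      abort(sprintf(
        "MAF block %d: declared size disagrees with ungapped residue count for %s.",
        b, bad), class = "ptbseq_parse_error")
    }
  }
  maf
}

#' Write alignment blocks to a MAF file
#'
#' Serializes a block table (as returned by [read_alignment_blocks()] or
#' [simulate_alignment()]) to MAF.
#'
#' @param maf Tibble with columns `block`, `species`, `chrom`, `start`,
#'   `size`, `strand`, `src_size`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_blocks <- function(maf, path) {
  out <- "##maf version=1"
  for (b in unique(maf$block)) {
    rows_b <- maf[maf$block == b, ]
    src <- ifelse(is.na(rows_b$chrom), rows_b$species,
                  paste(rows_b$species, rows_b$chrom, sep = "."))
    out <- c(out, "", "a score=0.000000",
             sprintf("s %s %d %d %s %d %s", src, rows_b$start, rows_b$size,
                     rows_b$strand, rows_b$src_size, rows_b$text))
  }
  readr::write_lines(c(out, ""), path)
  invisible(path)
}
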