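#' Read gene models from a GTF file
#'
#' Parses a GTF annotation (Flybase dialect; plain or gzip-compressed) into a
#' tidy exon table. Coordinates are kept in the native GTF convention:
#' 1-based, both ends inclusive.
#'
#' Exon records are grouped by `gene_id` and `transcript_id`; every exon row
#' must carry both attributes. Within a transcript, exons must be
#' non-overlapping and satisfy `start <= end`; violations raise a parse error
#' that names the offending line.
#'
#' @param path Path to a GTF file (may be gzip-compressed).
#' @return A tibble with one row per exon per transcript and columns
#'   `gene_id`, `transcript_id`, `chrom`, `strand` (`"+"` or `"-"`),
#'   `start`, `end` (1-based inclusive).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0("chr2L\tsrc\texon\t100\t200\t.\t+\t.\t",
#'                   'gene_id "g1"; transcript_id "t1";'), gtf)
#' read_gene_models(gtf)
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GTF file not found: %s", path), class = "ptbseq_io_error")
  }
  lines <- readr::read_lines(path)
  feature_idx <- which(!grepl("^\\s*(#|$)", lines))
  for (i in feature_idx) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9) {
      abort(sprintf("Malformed GTF line %d: expected 9 tab-separated fields, found %d.",
                    i, length(fields)),
            class = "ptbseq_parse_error")
    }
    start <- suppressWarnings(as.numeric(fields[[4]]))
    end <- suppressWarnings(as.numeric(fields[[5]]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("Malformed GTF line %d: non-numeric coordinates.", i),
            class = "ptbseq_parse_error")
    }
    if (end < start) {
      abort(sprintf("Malformed GTF line %d: end (%s) < start (%s).",
                    i, fields[[5]], fields[[4]]),
            class = "ptbseq_parse_error")
    }
    if (identical(fields[[3]], "exon") && !grepl("gene_id", fields[[9]], fixed = TRUE)) {
      abort(sprintf("GTF line %d: exon record lacks a gene_id attribute.", i),
            class = "ptbseq_parse_error")
    }
  }
  if (length(feature_idx) == 0L) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer()))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer()))
  }
  if (any(is.na(gr$gene_id)) ||
      is.null(gr$transcript_id) || any(is.na(gr$transcript_id))) {
    abort("GTF exon records lack gene_id/transcript_id attributes.",
          class = "ptbseq_parse_error")
  }
  df <- as.data.frame(gr)
  strand <- as.character(df$strand)
  if (any(!strand %in% c("+", "-"))) {
    abort("GTF exon records must carry strand '+' or '-'.",
          class = "ptbseq_parse_error")
  }
  exons <- tibble(
    gene_id = df$gene_id,
    transcript_id = df$transcript_id,
    chrom = as.character(df$seqnames),
    strand = strand,
    start = df$start,
    end = df$end
  ) |>
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$start)

  ov <- exons |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(
      overlapping = dplyr::n() > 1 &&
        any(.data$start[-1] <= cummax(.data$end)[-length(.data$end)]),
      .groups = "drop"
    )
  if (any(ov$overlapping)) {
    abort(sprintf("Overlapping exons within transcript %s.",
                  ov$transcript_id[ov$overlapping][[1]]),
          class = "ptbseq_parse_error")
  }
  exons
}

#' Write gene models to a GTF file
#'
#' Serializes an exon table (as returned by [read_gene_models()]) back to GTF,
#' preserving the 1-based inclusive coordinates.
#'
#' @param models Tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- sprintf(
    "%s\tptbseq\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    models$chrom, as.integer(models$start), as.integer(models$end),
    models$strand, models$gene_id, models$transcript_id
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Convert GTF exon coordinates to BED intervals
#'
#' GTF is 1-based with inclusive ends; BED is 0-based half-open. The
#' conversion `start - 1, end` preserves interval length.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return A tibble with 0-based half-open `start` and `end`.
#' @export
gtf_to_bed_coords <- function(start, end) {
  tibble(start = as.integer(start) - 1L, end = as.integer(end))
}
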