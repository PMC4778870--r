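#' Parameters for the conserved pyrimidine-tract scan
#'
#' The binding-site definition used throughout: a stretch of at least
#' `min_length` residues made of C/U allowing at most `max_g` G residues,
#' called conserved when a qualifying tract occurs within `window_nt`
#' ungapped reference nucleotides (indels excluded from the distance) in at
#' least `min_species` of the `total_species` aligned genomes.
#'
#' @param min_length Minimum tract length in nt (default 9).
#' @param max_g Maximum number of G residues tolerated inside a tract
#'   (default 1). A and N always terminate a tract and never count.
#' @param window_nt Conservation window: ungapped reference nucleotides of
#'   flank on each side of the tract (default 25).
#' @param min_species Minimum number of species (reference included) with a
#'   qualifying tract in-window (default 9).
#' @param total_species Number of species in the alignment (default 15);
#'   informational.
#' @return A list of class `tract_params`.
#' @export
tract_params <- function(min_length = 9, max_g = 1, window_nt = 25,
                         min_species = 9, total_species = 15) {
  if (min_length < 1) abort("min_length must be >= 1.", class = "ptbseq_input_error")
  if (max_g < 0 || max_g >= min_length) {
    abort("max_g must satisfy 0 <= max_g < min_length.", class = "ptbseq_input_error")
  }
  if (window_nt < 0) abort("window_nt must be >= 0.", class = "ptbseq_input_error")
  if (min_species < 1 || min_species > total_species) {
    abort("min_species must satisfy 1 <= min_species <= total_species.",
          class = "ptbseq_input_error")
  }
  structure(list(min_length = min_length, max_g = max_g,
                 window_nt = window_nt, min_species = min_species,
                 total_species = total_species),
            class = "tract_params")
}

# Character classes over the mixed DNA/RNA alphabet. T and U are equivalent;
# N is neither a pyrimidine nor a tolerated G.
is_pyrimidine <- function(chars) chars %in% c("C", "T", "U")
is_tract_char <- function(chars) chars %in% c("C", "T", "U", "G")

#' Find maximal pyrimidine tracts in a sequence
#'
#' Returns all maximal substrings of length `>= min_length` composed of C/U
#' (T treated as U) plus at most `max_g` G residues. Maximal means the
#' substring cannot be extended in either direction without violating the
#' composition rule; a tolerated G may sit anywhere, including at a tract
#' boundary.
#'
#' @param sequence A single nucleotide string over `A,C,G,T,U,N` (case
#'   insensitive).
#' @param min_length,max_g See [tract_params()].
#' @return A tibble with 0-based half-open `start`/`end` coordinates and the
#'   tract `seq`, ordered by `start`.
#' @examples
#' find_pyrimidine_tracts("CUCUGCUCU")   # one 9-nt tract with one G
#' find_pyrimidine_tracts("CUCUGGCUCU")  # two Gs: no qualifying tract
#' @export
find_pyrimidine_tracts <- function(sequence, min_length = 9, max_g = 1) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "U", "N"))
  if (length(bad) > 0) {
    abort(sprintf("Invalid residue(s) in sequence: %s.",
                  paste(bad, collapse = ", ")),
          class = "ptbseq_input_error")
  }
  empty <- tibble(start = integer(), end = integer(), seq = character())
  n <- length(chars)
  if (n == 0L) return(empty)

  allowed <- is_tract_char(chars)
  runs <- rle(allowed)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L

  out_start <- integer()
  out_end <- integer()
  for (r in which(runs$values)) {
    a <- run_start[[r]]; b <- run_end[[r]]
    gp <- a - 1L + which(chars[a:b] == "G")
    m <- length(gp)
    if (m <= max_g) {
      wins <- cbind(a, b)
    } else {
      i <- 0:(m - max_g)
      left <- ifelse(i == 0L, a, gp[pmax(i, 1L)] + 1L)
      right <- ifelse(i + max_g == m, b, gp[pmin(i + max_g + 1L, m)] - 1L)
      wins <- cbind(left, right)
    }
    keep <- wins[, 2] - wins[, 1] + 1L >= min_length
    wins <- wins[keep, , drop = FALSE]
    out_start <- c(out_start, wins[, 1])
    out_end <- c(out_end, wins[, 2])
  }
  if (length(out_start) == 0L) return(empty)
  out_start <- as.integer(unname(out_start))
  out_end <- as.integer(unname(out_end))
  ord <- order(out_start)
  tibble(
    start = out_start[ord] - 1L,              # 0-based half-open
    end = out_end[ord],
    seq = substring(sequence, out_start[ord], out_end[ord])
  ) |> dplyr::distinct()
}

#' Extract a species subsequence around a reference interval
#'
#' Maps an ungapped reference-row interval of an alignment block to alignment
#' columns, extends the window by `window_nt` ungapped reference positions on
#' each side (gap columns in the reference row do not consume window budget;
#' the window is truncated at block edges), and returns the species row over
#' those columns with gap characters removed.
#'
#' @param block One alignment block: the rows of a [read_alignment_blocks()]
#'   tibble sharing a single `block` value.
#' @param species Species id whose subsequence to extract.
#' @param ref_species Reference species id.
#' @param ref_interval Ungapped 0-based half-open interval on the reference
#'   row (block-local coordinates).
#' @param window_nt Ungapped reference flank on each side.
#' @return The ungapped species subsequence, or `NA_character_` when the
#'   species is absent from the block.
#' @export
column_window <- function(block, species, ref_species, ref_interval,
                          window_nt = 25) {
  ref_row <- block[block$species == ref_species, ]
  if (nrow(ref_row) == 0L) {
    abort("Reference species absent from block.", class = "ptbseq_input_error")
  }
  sp_row <- block[block$species == species, ]
  if (nrow(sp_row) == 0L) return(NA_character_)

  ref_chars <- strsplit(ref_row$text[[1]], "", fixed = TRUE)[[1]]
  ref_cols <- which(ref_chars != "-")
  n_ref <- length(ref_cols)
  s <- ref_interval[[1]]; e <- ref_interval[[2]]
  if (s < 0 || e > n_ref || e <= s) {
    abort("ref_interval outside the reference row.", class = "ptbseq_input_error")
  }
  w0 <- max(0L, s - window_nt)
  w1 <- min(n_ref, e + window_nt)
  col_lo <- ref_cols[[w0 + 1L]]
  col_hi <- ref_cols[[w1]]
  degap(substr(sp_row$text[[1]], col_lo, col_hi))
}

#' Scan a multi-species alignment for conserved pyrimidine tracts
#'
#' For every maximal pyrimidine tract on the (degapped) reference row of each
#' block, each aligned species supports the site when its [column_window()]
#' subsequence itself contains a qualifying tract under the same
#' `min_length`/`max_g` rule. A hit is emitted when at least
#' `params$min_species` species (the reference trivially among them) support
#' the site. Hit coordinates are reported in reference genome space, 0-based
#' half-open.
#'
#' Blocks are handled independently, so a site spanning a block boundary is
#' not detected. A block lacking the reference species is skipped with a
#' warning. Minus-strand rows (reference or otherwise) are
#' reverse-complemented before tract search, so scanning a
#' reverse-complemented alignment with flipped strand annotations yields the
#' same reference-space hits.
#'
#' @param maf Alignment tibble from [read_alignment_blocks()] or
#'   [simulate_alignment()].
#' @param ref_species Reference species id.
#' @param params A [tract_params()] object.
#' @param regions Optional tibble of reference regions (`chrom`, `start`,
#'   `end`, 0-based half-open) restricting the scan: only tracts overlapping
#'   a region are reported.
#' @return A tibble of class `ptb_site_hits`: `block`, `chrom`, `ref_start`,
#'   `ref_end`, `strand`, `ref_sequence`, `supporting_species` (list column)
#'   and `n_support`.
#' @export
scan_alignment <- function(maf, ref_species, params = tract_params(),
                           regions = NULL) {
  stopifnot(inherits(params, "tract_params"))
  hits <- list()
  for (b in unique(maf$block)) {
    block <- maf[maf$block == b, ]
    if (!ref_species %in% block$species) {
      warn(sprintf("Block %s lacks reference species %s; skipped.", b, ref_species))
      next
    }
    block <- orient_block(block, ref_species)
    ref_row <- block[block$species == ref_species, ]
    ref_seq <- degap(ref_row$text[[1]])
    tracts <- find_pyrimidine_tracts(ref_seq, params$min_length, params$max_g)
    if (nrow(tracts) == 0L) next

    other <- setdiff(block$species, ref_species)
    strands <- setNames(block$strand, block$species)
    for (i in seq_len(nrow(tracts))) {
      supporters <- ref_species
      for (sp in other) {
        w <- column_window(block, sp, ref_species,
                           c(tracts$start[[i]], tracts$end[[i]]),
                           params$window_nt)
        if (is.na(w) || nchar(w) == 0L) next
        if (strands[[sp]] == "-") w <- rev_comp(w)
        if (has_qualifying_tract(w, params$min_length, params$max_g)) {
          supporters <- c(supporters, sp)
        }
      }
      if (length(supporters) >= params$min_species) {
        hits[[length(hits) + 1L]] <- tibble(
          block = b,
          chrom = ref_row$chrom[[1]],
          ref_start = ref_row$start[[1]] + tracts$start[[i]],
          ref_end = ref_row$start[[1]] + tracts$end[[i]],
          strand = ref_row$strand[[1]],
          ref_sequence = tracts$seq[[i]],
          supporting_species = list(sort(supporters)),
          n_support = length(supporters)
        )
      }
    }
  }
  out <- if (length(hits) == 0L) {
    tibble(block = integer(), chrom = character(), ref_start = integer(),
           ref_end = integer(), strand = character(), ref_sequence = character(),
           supporting_species = list(), n_support = integer())
  } else {
    dplyr::bind_rows(hits)
  }
  if (!is.null(regions) && nrow(out) > 0L) {
    keep <- purrr::map_lgl(seq_len(nrow(out)), function(i) {
      any(regions$chrom == out$chrom[[i]] &
            regions$start < out$ref_end[[i]] &
            regions$end > out$ref_start[[i]])
    })
    out <- out[keep, ]
  }
  class(out) <- c("ptb_site_hits", class(out))
  out
}

# Orient a block so the reference row is on the plus strand: when the
# reference is minus-strand, reverse-complement every row, flip strands and
# re-anchor starts on the plus strand (MAF minus-strand starts count from the
# reverse-complemented source).
orient_block <- function(block, ref_species) {
  ref_strand <- block$strand[block$species == ref_species][[1]]
  if (ref_strand == "+") return(block)
  block$text <- rev_comp(block$text)
  block$start <- block$src_size - block$start - block$size
  block$strand <- ifelse(block$strand == "+", "-", "+")
  block
}

has_qualifying_tract <- function(sequence, min_length, max_g) {
  nrow(find_pyrimidine_tracts(sequence, min_length, max_g)) > 0L
}

#' Write scanner hits with supporting-species lists to a TSV file
#'
#' Companion to the BED6 output of [write_site_hits()]: the same hits with
#' the supporting species serialized as a comma-separated list.
#'
#' @param hits A `ptb_site_hits` tibble from [scan_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_hits_tsv <- function(hits, path) {
  out <- as_tibble(hits)
  out$supporting_species <-
    purrr::map_chr(out$supporting_species, paste, collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}
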