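test_that("maximal pyrimidine tracts follow the at-most-one-G rule", {
  expect_equal(find_pyrimidine_tracts("UCUUCUUCUU")[, c("start", "end")],
               tibble::tibble(start = 0L, end = 10L))
  expect_equal(find_pyrimidine_tracts("CUCUGCUCU")[, c("start", "end")],
               tibble::tibble(start = 0L, end = 9L))
  expect_equal(nrow(find_pyrimidine_tracts("CUCUGGCUCU")), 0)
  # T and U are interchangeable; N and A terminate and never count
  expect_equal(find_pyrimidine_tracts("TCTTCTTCTT")$end, 10L)
  expect_equal(nrow(find_pyrimidine_tracts("TCTTNTTCTT")), 0)
  expect_error(find_pyrimidine_tracts("TCTTXTTCTT"),
               class = "ptbseq_input_error")
})

test_that("tract finding matches exhaustive enumeration on random strings", {
  withr::with_seed(271, {
    for (rep in 1:200) {
      n <- sample(1:60, 1)
      s <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                        prob = c(0.1, 0.3, 0.15, 0.4, 0.05)),
                 collapse = "")
      min_len <- sample(3:9, 1)
      max_g <- sample(0:2, 1)
      got <- find_pyrimidine_tracts(s, min_len, max_g)
      want <- oracle_find_tracts(s, min_len, max_g)
      expect_equal(got[, c("start", "end")], want,
                   info = sprintf("seq=%s min=%d g=%d", s, min_len, max_g))
    }
  })
})

# block with a reference gap inside the left flank of the tract
gapped_block <- tibble::tibble(
  block = 1L,
  species = c("ref", "s01"),
  chrom = "chrT",
  start = c(0L, 0L),
  size = c(12L, 15L),
  strand = "+",
  src_size = c(12L, 15L),
  text = c("AAG---TTTTTTTTT",
           "CCCCCCTTTTTTTTT")
)

test_that("column windows count ungapped reference positions only", {
  # identity alignment, window 0: exactly the aligned tract residues
  expect_equal(column_window(gapped_block, "s01", "ref", c(3, 12), 0),
               "TTTTTTTTT")
  # window of 2 reference nt crosses the 3-column reference gap without
  # spending budget on it: species residues over those columns are kept
  expect_equal(column_window(gapped_block, "s01", "ref", c(3, 12), 2),
               "CCCCCTTTTTTTTT")
  # species row all gaps over the tract columns yields an empty string
  blk <- gapped_block
  blk$text[2] <- "CCCCCC---------"
  blk$size[2] <- 6L
  expect_equal(column_window(blk, "s01", "ref", c(3, 12), 0), "")
  # absent species signals NA, not an error
  expect_true(is.na(column_window(gapped_block, "nope", "ref", c(3, 12), 5)))
  expect_error(column_window(gapped_block, "s01", "ref", c(3, 20), 0),
               class = "ptbseq_input_error")
})

make_conserved_block <- function(n_species = 15, n_intact = n_species) {
  tract <- "TCTTCTTCTTCT"
  flank_l <- "GAAGAAGGAAGAAGGAAGAAAGGA"
  flank_r <- "AGGAAGAAAGAAGGAAGGAAAGAA"
  intact <- paste0(flank_l, tract, flank_r)
  ablated <- paste0(flank_l, gsub("[CT]", "A", tract), flank_r)
  species <- c("dm3", sprintf("sp%02d", seq_len(n_species - 1L)))
  text <- c(intact,
            rep(intact, n_intact - 1L),
            rep(ablated, n_species - n_intact))
  tibble::tibble(block = 1L, species = species, chrom = "chr2L",
                 start = 1000L, size = nchar(text), strand = "+",
                 src_size = nchar(text), text = text)
}

test_that("the species quorum gates conserved-site calls", {
  hits <- scan_alignment(make_conserved_block(15, 15), "dm3")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_support, 15)
  expect_equal(hits$ref_start, 1000L + 24L)
  expect_equal(hits$ref_end, 1000L + 36L)
  expect_true("dm3" %in% hits$supporting_species[[1]])

  # 8 intact species miss the 9-species quorum; 9 meet it
  expect_equal(nrow(scan_alignment(make_conserved_block(15, 8), "dm3")), 0)
  hits9 <- scan_alignment(make_conserved_block(15, 9), "dm3")
  expect_equal(hits9$n_support, 9)
})

test_that("scanner output equals the brute-force oracle on random blocks", {
  params <- tract_params(min_length = 5, max_g = 1, window_nt = 6,
                         min_species = 3, total_species = 5)
  withr::with_seed(515, {
    for (rep in 1:50) {
      blk <- random_block(n_species = sample(2:5, 1),
                          width = sample(20:60, 1))
      got <- scan_alignment(blk, "ref", params)
      want <- oracle_scan_block(blk, "ref", params)
      expect_setequal(hit_key(got), hit_key(want))
    }
  })
})

test_that("relaxing quorum, G tolerance or window never removes hits", {
  withr::with_seed(88, {
    for (rep in 1:20) {
      blk <- random_block(n_species = 5, width = 60)
      base <- tract_params(min_length = 5, max_g = 0, window_nt = 4,
                           min_species = 4, total_species = 5)
      h0 <- scan_alignment(blk, "ref", base)
      for (relaxed in list(
        tract_params(5, 0, 4, min_species = 3, total_species = 5),
        tract_params(5, 0, 5, min_species = 4, total_species = 5)
      )) {
        h1 <- scan_alignment(blk, "ref", relaxed)
        expect_true(all(paste(h0$ref_start, h0$ref_end) %in%
                          paste(h1$ref_start, h1$ref_end)))
      }
      # raising max_g keeps every hit interval covered by some hit
      h2 <- scan_alignment(blk, "ref", tract_params(5, 1, 4, 4, 5))
      if (nrow(h0) > 0) {
        covered <- vapply(seq_len(nrow(h0)), function(i) {
          any(h2$ref_start <= h0$ref_start[[i]] & h2$ref_end >= h0$ref_end[[i]])
        }, logical(1))
        expect_true(all(covered))
      }
    }
  })
})

test_that("scanning a reverse-complemented block gives the same hits", {
  params <- tract_params(min_length = 5, max_g = 1, window_nt = 6,
                         min_species = 3, total_species = 5)
  withr::with_seed(99, {
    for (rep in 1:20) {
      blk <- random_block(n_species = 4, width = 50)
      flipped <- blk
      flipped$text <- vapply(blk$text, oracle_revcomp, character(1),
                             USE.NAMES = FALSE)
      flipped$strand <- ifelse(blk$strand == "+", "-", "+")
      flipped$start <- blk$src_size - blk$start - blk$size
      expect_setequal(hit_key(scan_alignment(blk, "ref", params)),
                      hit_key(scan_alignment(flipped, "ref", params)))
    }
  })
})

test_that("blocks lacking the reference are skipped with a warning", {
  blk <- make_conserved_block(5, 5)
  blk2 <- blk
  blk2$block <- 2L
  blk2$species[1] <- "other"
  both <- dplyr::bind_rows(blk, blk2)
  expect_warning(hits <- scan_alignment(both, "dm3",
                                        tract_params(min_species = 5)),
                 "lacks reference")
  expect_equal(unique(hits$block), 1L)
})

test_that("region restriction and TSV serialization work", {
  blk <- make_conserved_block(15, 15)
  hits <- scan_alignment(blk, "dm3",
                         regions = tibble::tibble(chrom = "chr2L",
                                                  start = 1020L, end = 1030L))
  expect_equal(nrow(hits), 1)
  none <- scan_alignment(blk, "dm3",
                         regions = tibble::tibble(chrom = "chr2L",
                                                  start = 0L, end = 10L))
  expect_equal(nrow(none), 0)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_site_hits_tsv(hits, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$n_support, 15)
  expect_match(back$supporting_species, "dm3")
})
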