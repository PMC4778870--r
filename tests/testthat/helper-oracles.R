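# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and stats::pbinom / stats::phyper) so that implementation and
# check stay on separate routes.

# Two-sided pooled-null binomial p-value by explicit log-space summation of
# the probability mass function.
oracle_binom_p <- function(a_inc, a_exc, b_inc, b_exc) {
  n_b <- b_inc + b_exc
  p_hat <- (a_inc + b_inc) / (a_inc + a_exc + n_b)
  k <- 0:n_b
  if (p_hat == 0) {
    pmf <- as.numeric(k == 0)
  } else if (p_hat == 1) {
    pmf <- as.numeric(k == n_b)
  } else {
    pmf <- exp(lchoose(n_b, k) + k * log(p_hat) + (n_b - k) * log1p(-p_hat))
  }
  lower <- sum(pmf[k <= b_inc])
  upper <- sum(pmf[k >= b_inc])
  min(1, 2 * min(lower, upper))
}

# Hypergeometric upper tail P(X >= obs) by explicit summation.
oracle_hyper_upper <- function(obs, n_a, n_b, n_universe) {
  k <- max(0, n_a + n_b - n_universe):min(n_a, n_b)
  pmf <- exp(lchoose(n_a, k) + lchoose(n_universe - n_a, n_b - k) -
               lchoose(n_universe, n_b))
  sum(pmf[k >= obs])
}

oracle_revcomp <- function(s) {
  comp <- chartr("ACGTUN-", "TGCAAN-", toupper(s))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

oracle_qualifies <- function(chars, max_g) {
  all(chars %in% c("C", "T", "U", "G")) && sum(chars == "G") <= max_g
}

# All maximal pyrimidine tracts by exhaustive substring enumeration.
oracle_find_tracts <- function(sequence, min_length = 9, max_g = 1) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  res <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i || j - i + 1 < min_length) next
      if (!oracle_qualifies(chars[i:j], max_g)) next
      ext_left <- i > 1 && oracle_qualifies(chars[(i - 1):j], max_g)
      ext_right <- j < n && oracle_qualifies(chars[i:(j + 1)], max_g)
      if (!ext_left && !ext_right) {
        res[[length(res) + 1L]] <- c(i - 1L, j)
      }
    }
  }
  if (length(res) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- unique(do.call(rbind, res))
  m <- m[order(m[, 1]), , drop = FALSE]
  tibble::tibble(start = m[, 1], end = m[, 2])
}

oracle_has_tract <- function(sequence, min_length, max_g) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < min_length) return(FALSE)
  for (i in seq_len(n - min_length + 1L)) {
    if (oracle_qualifies(chars[i:(i + min_length - 1L)], max_g)) return(TRUE)
  }
  FALSE
}

# Full quadratic re-scan of one alignment block (reference assumed '+').
oracle_scan_block <- function(block, ref_species, params) {
  ref_row <- block[block$species == ref_species, ]
  ref_chars <- strsplit(ref_row$text[[1]], "", fixed = TRUE)[[1]]
  ref_cols <- which(ref_chars != "-")
  ref_seq <- paste(ref_chars[ref_cols], collapse = "")
  tracts <- oracle_find_tracts(ref_seq, params$min_length, params$max_g)
  out <- list()
  for (i in seq_len(nrow(tracts))) {
    s <- tracts$start[[i]]; e <- tracts$end[[i]]
    w0 <- max(0L, s - params$window_nt)
    w1 <- min(length(ref_cols), e + params$window_nt)
    col_lo <- ref_cols[[w0 + 1L]]
    col_hi <- ref_cols[[w1]]
    supporters <- ref_species
    for (sp in setdiff(block$species, ref_species)) {
      row <- block[block$species == sp, ]
      chars <- strsplit(row$text[[1]], "", fixed = TRUE)[[1]][col_lo:col_hi]
      sub <- paste(chars[chars != "-"], collapse = "")
      if (row$strand[[1]] == "-") sub <- oracle_revcomp(sub)
      if (oracle_has_tract(sub, params$min_length, params$max_g)) {
        supporters <- c(supporters, sp)
      }
    }
    if (length(supporters) >= params$min_species) {
      out[[length(out) + 1L]] <- tibble::tibble(
        ref_start = ref_row$start[[1]] + s,
        ref_end = ref_row$start[[1]] + e,
        n_support = length(supporters)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(ref_start = integer(), ref_end = integer(),
                          n_support = integer()))
  }
  dplyr::bind_rows(out)
}

# Small random alignment block in the read_alignment_blocks() layout:
# plus-strand reference, other species' rows randomly gapped and optionally
# minus-strand. Pyrimidine-heavy alphabet so tracts actually occur.
random_block <- function(n_species = 5, width = 60) {
  species <- c("ref", sprintf("s%02d", seq_len(n_species - 1L)))
  alphabet <- c("A", "C", "G", "T", "-")
  probs <- c(0.12, 0.32, 0.10, 0.36, 0.10)
  rows <- lapply(seq_along(species), function(i) {
    chars <- sample(alphabet, width, replace = TRUE, prob = probs)
    if (i == 1L && all(chars == "-")) chars[1] <- "T"
    paste(chars, collapse = "")
  })
  size <- nchar(gsub("-", "", unlist(rows), fixed = TRUE))
  strand <- c("+", sample(c("+", "-"), n_species - 1L, replace = TRUE))
  src_size <- size + sample(0:20, n_species, replace = TRUE)
  start <- vapply(src_size - size, function(m) (0:m)[sample.int(m + 1L, 1L)],
                  integer(1))
  tibble::tibble(block = 1L, species = species, chrom = "chrT",
                 start = start, size = size, strand = strand,
                 src_size = src_size, text = unlist(rows))
}

hit_key <- function(hits) {
  paste(hits$ref_start, hits$ref_end, hits$n_support, sep = ":")
}

# A hit table "recovers" a truth interval when some hit spans it.
recovered <- function(hits, truth_start, truth_end) {
  any(hits$ref_start <= truth_start & hits$ref_end >= truth_end)
}
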