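#' Simulate two-condition junction read counts
#'
#' Emulates exon-exon junction ("spliced") read counts for alternative
#' isoform events in two conditions. Per event and condition, the total
#' junction read count is Poisson around `depth` (optionally
#' negative-binomial for overdispersion) and the inclusion count is
#' `Binomial(total, psi)`, independently per condition — the sampling model
#' the binomial isoform test assumes.
#'
#' @param n_events Number of events.
#' @param depth Mean junction reads per event per condition.
#' @param psi_pairs Tibble (or data frame) with columns `psi_a`, `psi_b`;
#'   rows are recycled over events.
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @param event_class Event class label(s), recycled.
#' @param dispersion Optional negative-binomial size parameter for the
#'   totals; `NULL` (default) keeps Poisson totals.
#' @return A list of tibbles: `events` (columns `event_id`, `gene_id`,
#'   `event_class`, `a_inc`, `a_exc`, `b_inc`, `b_exc`) and `truth`
#'   (`event_id`, `psi_a`, `psi_b`).
#' @examples
#' sim <- simulate_junction_counts(5, depth = 50,
#'   psi_pairs = tibble::tibble(psi_a = 0.5, psi_b = 0.9), seed = 1)
#' sim$events
#' @export
simulate_junction_counts <- function(n_events = 100, depth = 50,
                                     psi_pairs = tibble(psi_a = 0.5, psi_b = 0.5),
                                     seed = 1, event_class = "skipped_exon",
                                     dispersion = NULL) {
  if (depth < 1) abort("depth must be >= 1.", class = "ptbseq_input_error")
  assert_fraction(psi_pairs$psi_a, "psi_a")
  assert_fraction(psi_pairs$psi_b, "psi_b")
  idx <- rep_len(seq_len(nrow(psi_pairs)), n_events)
  psi_a <- psi_pairs$psi_a[idx]
  psi_b <- psi_pairs$psi_b[idx]
  withr::with_seed(seed, {
    draw_total <- function(n) {
      if (is.null(dispersion)) rpois(n, depth)
      else rnbinom(n, size = dispersion, mu = depth)
    }
    n_a <- draw_total(n_events)
    n_b <- draw_total(n_events)
    a_inc <- rbinom(n_events, n_a, psi_a)
    b_inc <- rbinom(n_events, n_b, psi_b)
    event_id <- sprintf("ev%05d", seq_len(n_events))
    list(
      events = tibble(
        event_id = event_id,
        gene_id = sprintf("gene%05d", seq_len(n_events)),
        event_class = rep_len(event_class, n_events),
        a_inc = a_inc, a_exc = n_a - a_inc,
        b_inc = b_inc, b_exc = n_b - b_inc
      ),
      truth = tibble(event_id = event_id, psi_a = psi_a, psi_b = psi_b)
    )
  })
}

#' Simulate a mutant/control coverage-profile pair
#'
#' Emulates the read pileup of a transcript carrying a transposon insertion:
#' the control profile is Poisson around `coverage_depth` along the whole
#' region; the mutant profile is Poisson around `coverage_depth` upstream of
#' the breakpoint and around `coverage_depth * full_length_fraction`
#' downstream (only the full-length transcripts contribute reads there).
#'
#' @param length Region length in bases.
#' @param breakpoint 0-based genomic coordinate of the insertion
#'   (default: region midpoint).
#' @param coverage_depth Mean per-base coverage.
#' @param full_length_fraction Fraction of transcripts escaping truncation,
#'   in `[0, 1]`.
#' @param chrom Chromosome label.
#' @param genomic_start 0-based genomic coordinate of the first base.
#' @param strand Transcript strand; for `"-"` the truncated side is the
#'   lower-coordinate side.
#' @param seed Integer seed.
#' @return A list with tibbles `mutant` and `control`, each a contiguous
#'   coverage profile (`profile`, `chrom`, `pos`, `depth`).
#' @export
simulate_coverage_pair <- function(length = 2000,
                                   breakpoint = genomic_start + length %/% 2,
                                   coverage_depth = 100,
                                   full_length_fraction = 0.04,
                                   chrom = "chr3R", genomic_start = 0,
                                   strand = "+", seed = 1) {
  assert_fraction(full_length_fraction, "full_length_fraction")
  pos <- seq.int(genomic_start, genomic_start + length - 1L)
  downstream <- if (strand == "+") pos >= breakpoint else pos < breakpoint
  mu_mut <- ifelse(downstream, coverage_depth * full_length_fraction,
                   coverage_depth)
  withr::with_seed(seed, {
    list(
      mutant = tibble(profile = 1L, chrom = chrom, pos = pos,
                      depth = as.numeric(rpois(length, mu_mut))),
      control = tibble(profile = 1L, chrom = chrom, pos = pos,
                       depth = as.numeric(rpois(length, coverage_depth)))
    )
  })
}

#' Simulate a multi-species alignment with planted conserved tracts
#'
#' Generates one MAF-style alignment block over `n_species` genomes: a
#' reference sequence drawn from a background composition with a given
#' pyrimidine fraction, per-species rows derived from it by uniform random
#' substitution plus insertions/deletions with geometric lengths (mean 2),
#' and C/U-rich tracts planted at chosen positions in a chosen number of
#' species.
#'
#' For each planted site, the supporting species (the reference plus a
#' random sample) carry the tract with at most `max_subs_per_species`
#' C<->T substitutions (transitions within the pyrimidine class, so a planted
#' tract always remains a qualifying tract) and a per-species placement
#' offset of at most `max_offset_nt` reference positions. In the remaining
#' species the site region — extended by `ablate_window` on each side — is
#' rewritten with purines so those species cannot support the site.
#'
#' @param n_species Number of species including the reference.
#' @param length Reference sequence length (bases).
#' @param pyrimidine_fraction Background C+T fraction (default 0.3,
#'   purine-rich so spurious tracts are rare).
#' @param substitution_rate Per-base substitution probability per species.
#' @param indel_rate Per-base probability of opening an indel per species.
#' @param mean_gap Mean indel length (geometric; default 2).
#' @param planted_sites Tibble with columns `position` (0-based reference
#'   coordinate), `tract` (RNA or DNA alphabet), `n_conserved_species`,
#'   `max_subs_per_species`, `max_offset_nt`. `NULL` plants nothing.
#' @param ref_species,chrom Labels for the reference row.
#' @param ablate_window Flank (reference nt) purine-rewritten around planted
#'   sites in non-supporting species (default 25, the scan window).
#' @param seed Integer seed.
#' @return A list: `alignment` (a block tibble as from
#'   [read_alignment_blocks()]) and `truth` (BED-like tibble of planted
#'   sites: `chrom`, `start`, `end`, `name`, `n_conserved_species`,
#'   `strand`).
#' @export
simulate_alignment <- function(n_species = 15, length = 5000,
                               pyrimidine_fraction = 0.3,
                               substitution_rate = 0.05,
                               indel_rate = 0.01, mean_gap = 2,
                               planted_sites = NULL,
                               ref_species = "dm3", chrom = "chr2L",
                               ablate_window = 25, seed = 1) {
  assert_fraction(pyrimidine_fraction, "pyrimidine_fraction")
  species <- c(ref_species,
               sprintf("sp%02d", seq_len(n_species - 1L)))
  if (!is.null(planted_sites)) {
    planted_sites <- as_tibble(planted_sites)
    planted_sites$position <- as.integer(round(planted_sites$position))
    tract_dna <- chartr("U", "T", toupper(planted_sites$tract))
    starts <- planted_sites$position
    ends <- starts + nchar(tract_dna)
    if (any(starts < 0) || any(ends > length)) {
      abort("Planted site outside sequence bounds.", class = "ptbseq_input_error")
    }
    ord <- order(starts)
    if (any(starts[ord][-1] < ends[ord][-base::length(ord)])) {
      abort("Planted sites overlap.", class = "ptbseq_input_error")
    }
    if (any(planted_sites$n_conserved_species > n_species)) {
      abort("n_conserved_species exceeds n_species.", class = "ptbseq_input_error")
    }
  }

  withr::with_seed(seed, {
    base_probs <- c(A = (1 - pyrimidine_fraction) / 2,
                    C = pyrimidine_fraction / 2,
                    G = (1 - pyrimidine_fraction) / 2,
                    T = pyrimidine_fraction / 2)
    bases <- names(base_probs)
    ref <- sample(bases, length, replace = TRUE, prob = base_probs)

    # Per-species edits relative to the reference. Insertions by one species
    # occupy their own columns, where every other row is gapped.
    edits <- purrr::map(species[-1], function(sp) {
      subs <- which(stats::runif(length) < substitution_rate)
      indel_at <- which(stats::runif(length) < indel_rate)
      is_del <- stats::runif(base::length(indel_at)) < 0.5
      lens <- rgeom(base::length(indel_at), prob = 1 / mean_gap) + 1L
      list(
        subs = subs,
        sub_to = sample(bases, base::length(subs), replace = TRUE),
        del_start = indel_at[is_del], del_len = lens[is_del],
        ins_after = indel_at[!is_del], ins_len = lens[!is_del]
      )
    })
    names(edits) <- species[-1]

    # Column layout: one column per reference base, plus insertion columns.
    ins_tbl <- purrr::imap(edits, function(e, sp) {
      if (base::length(e$ins_after) == 0L) return(NULL)
      tibble(species = sp, after = e$ins_after, len = e$ins_len)
    }) |> dplyr::bind_rows()
    extra_after <- integer(length)
    if (nrow(ins_tbl) > 0) {
      agg <- tapply(ins_tbl$len, ins_tbl$after, sum)
      extra_after[as.integer(names(agg))] <- as.integer(agg)
    }
    total_cols <- length + sum(extra_after)
    # column index of reference base i
    ref_col <- seq_len(length) + c(0L, cumsum(extra_after)[-length])

    mat <- matrix("-", nrow = n_species, ncol = total_cols,
                  dimnames = list(species, NULL))
    mat[1L, ref_col] <- ref
    for (sp in species[-1]) {
      e <- edits[[sp]]
      row <- ref
      row[e$subs] <- e$sub_to
      del_mask <- rep(FALSE, length)
      for (k in seq_along(e$del_start)) {
        d0 <- e$del_start[[k]]
        del_mask[d0:min(length, d0 + e$del_len[[k]] - 1L)] <- TRUE
      }
      row[del_mask] <- "-"
      mat[sp, ref_col] <- row
      if (nrow(ins_tbl) > 0 && any(ins_tbl$species == sp)) {
        ins_sp <- ins_tbl[ins_tbl$species == sp, ]
        for (k in seq_len(nrow(ins_sp))) {
          # insertion columns for ref base `at` span the slots between it and
          # the next ref base; species share slots first-come-first-served
          at <- ins_sp$after[[k]]
          slot_cols <- ref_col[[at]] + seq_len(extra_after[[at]])
          taken <- which(colSums(mat[, slot_cols, drop = FALSE] != "-") > 0)
          free <- setdiff(seq_len(extra_after[[at]]), taken)
          use <- free[seq_len(ins_sp$len[[k]])]
          mat[sp, ref_col[[at]] + use] <-
            sample(bases, ins_sp$len[[k]], replace = TRUE, prob = base_probs)
        }
      }
    }

    # Plant conserved sites.
    truth <- NULL
    if (!is.null(planted_sites)) {
      truth <- purrr::map(seq_len(nrow(planted_sites)), function(i) {
        site <- planted_sites[i, ]
        tract <- strsplit(tract_dna[[i]], "", fixed = TRUE)[[1]]
        len_t <- base::length(tract)
        pos1 <- site$position + 1L  # 1-based reference index
        n_cons <- site$n_conserved_species
        supporters <- c(ref_species,
                        sample_ids(species[-1], n_cons - 1L))
        mat[ref_species, ref_col[pos1:(pos1 + len_t - 1L)]] <<- tract
        for (sp in setdiff(supporters, ref_species)) {
          off <- sample_ids(seq(-site$max_offset_nt, site$max_offset_nt), 1L)
          at <- pmin(pmax(pos1 + off, 1L), length - len_t + 1L)
          sp_tract <- tract
          if (site$max_subs_per_species > 0) {
            n_subs <- sample_ids(0:site$max_subs_per_species, 1L)
            if (n_subs > 0) {
              pyr_pos <- which(sp_tract %in% c("C", "T"))
              swap <- sample_ids(pyr_pos, min(n_subs, base::length(pyr_pos)))
              sp_tract[swap] <- chartr("CT", "TC", sp_tract[swap])
            }
          }
          mat[sp, ref_col[at:(at + len_t - 1L)]] <<- sp_tract
        }
        for (sp in setdiff(species, supporters)) {
          a0 <- max(1L, pos1 - ablate_window - site$max_offset_nt)
          a1 <- min(length, pos1 + len_t - 1L + ablate_window + site$max_offset_nt)
          cols <- ref_col[a0:a1]
          keep_gap <- mat[sp, cols] == "-"
          repl <- sample(c("A", "G"), base::length(cols), replace = TRUE)
          repl[keep_gap] <- "-"
          mat[sp, cols] <- repl
        }
        tibble(chrom = chrom, start = site$position,
               end = site$position + len_t,
               name = sprintf("planted_%02d", i),
               n_conserved_species = n_cons, strand = "+")
      }) |> dplyr::bind_rows()
    }

    text <- apply(mat, 1L, paste, collapse = "")
    size <- nchar(degap(text))
    alignment <- tibble(
      block = 1L,
      species = species,
      chrom = chrom,
      start = 0L,
      size = as.integer(size),
      strand = "+",
      src_size = as.integer(size),
      text = unname(text)
    )
    list(alignment = alignment,
         truth = truth %||% tibble(chrom = character(), start = integer(),
                                   end = integer(), name = character(),
                                   n_conserved_species = integer(),
                                   strand = character()))
  })
}

#' Simulate gene sets with controlled overlap
#'
#' Draws two gene sets from a synthetic universe, either uniformly at random
#' or with a forced intersection size, for testing overlap statistics.
#'
#' @param n_universe Universe size.
#' @param n_a,n_b Set sizes.
#' @param n_overlap Forced intersection size, or `NULL` (default) for
#'   uniform random draws.
#' @param seed Integer seed.
#' @return A list of character vectors: `universe`, `set_a`, `set_b`.
#' @export
simulate_gene_sets <- function(n_universe = 1000, n_a = 200, n_b = 430,
                               n_overlap = NULL, seed = 1) {
  if (any(c(n_a, n_b) > n_universe)) {
    abort("Set sizes cannot exceed the universe size.",
          class = "ptbseq_input_error")
  }
  universe <- sprintf("FBgn%07d", seq_len(n_universe))
  withr::with_seed(seed, {
    set_a <- sample(universe, n_a)
    set_b <- if (is.null(n_overlap)) {
      sample(universe, n_b)
    } else {
      if (n_overlap > min(n_a, n_b) || n_b - n_overlap > n_universe - n_a) {
        abort("Infeasible n_overlap for the given sizes.",
              class = "ptbseq_input_error")
      }
      c(sample_ids(set_a, n_overlap),
        sample_ids(setdiff(universe, set_a), n_b - n_overlap))
    }
    list(universe = universe, set_a = sort(set_a), set_b = sort(set_b))
  })
}
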