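---
title: "ptbseq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ptbseq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptbseq)
```

## The biological setting

The *Drosophila* polypyrimidine tract-binding protein (dmPTB, gene
*hephaestus*) is an hnRNP that binds C/U-rich RNA (UCUU/UUCU-type motifs)
and regulates splicing, stability and translation. A P-element transposon
insertion allele of *heph* abolishes the male-germline transcript and blocks
spermatid individualization, sterilizing males. An RNA-Seq comparison of
mutant versus control flies poses four computational problems that this
package solves: (i) calling differential isoform usage from
junction-spanning read counts, (ii) quantifying how completely the
insertion truncates the host transcript from the coverage drop-off,
(iii) finding PTB binding sites conserved across a multi-species genome
alignment, and (iv) asking whether two gene lists overlap more than chance.

Because such a screen's raw libraries are typically unavailable, the package
ships generators that produce every input with known ground truth; all
statistical guarantees quoted below are demonstrated on those simulations by
the test suite.

## Differential isoform usage from junction reads

An alternative event (skipped exon, alternative 5'/3' splice site,
alternative TSS or 3' end) is summarized by four counts: inclusion- and
exclusion-junction reads in condition A (control) and condition B (mutant).
Only exon–exon spanning ("spliced") reads are used, so the statistic is
insensitive to overall expression level. The isoform fraction is
$\psi = \mathrm{inc}/(\mathrm{inc}+\mathrm{exc})$.

The test treats the pooled fraction
$\hat p = (a_\mathrm{inc}+b_\mathrm{inc})/(n_a+n_b)$ as the null inclusion
probability and asks how surprising the mutant's inclusion count is:
with $n_b = b_\mathrm{inc}+b_\mathrm{exc}$, the two-sided p-value doubles
the smaller tail of $\mathrm{Binomial}(n_b,\hat p)$ at $b_\mathrm{inc}$ and
caps at 1. One-sided variants are available via `alternative`. The p-value
maps to a ranking score $\log_{10}((1-p)/p)$; $p$ is floored at machine
epsilon ($\approx 2.2\times10^{-16}$) before the transform so the score is
finite (capped near 15.7), and a p-value capped at 1 reports a score of 0.
Base 10 is the default so that a score of 1 equals 10-to-1 odds — the same
quorum as the Bayes-factor-10 filter used for candidate calling
(`bayes_factor_to_null_probability(10)` = 0.0909).

Candidates are then filtered exactly as in the screen: `|delta_psi| >= 0.2`
and `log_odds >= 1`. No multiple-testing correction is applied by default
(the log-odds quorum plays that role); `adjust = TRUE` adds a
Benjamini–Hochberg column. Events with zero total reads in either condition
are reported with `status = "untestable"` rather than dropped; events with
zero reads in only one condition remain testable because the other
condition still anchors $\hat p$. Output rows are ordered by descending
log-odds with ties broken lexicographically by `event_id`, so results are
reproducible byte for byte.

Two properties of this statistic deserve note. First, it is exact and
conservative: on simulated null events the fraction of p-values below 0.05
stays at or below the nominal level (binomial discreteness plus tail
doubling). Second, it is anchored on condition B — exchanging the
inclusion/exclusion labels leaves the p-value exactly unchanged, but
exchanging the two *conditions* re-anchors the test on the other sample's
total, giving a close but not bitwise-identical p-value. We kept the
anchored form because it matches the mutant-versus-control framing of the
screen; treat condition B as the perturbed sample.

The unsigned fold-change $\max(\psi_A,\psi_B)/\min(\psi_A,\psi_B)$ is
reported alongside; when exactly one fraction is zero the ratio is
unbounded and serialized as the literal `Large`, and when both are zero it
is 1. Direction is recoverable from the sign of `delta_psi`.

## Truncation at an insertion breakpoint

A transposon inserted in an intron terminates transcription, visible as an
abrupt drop in read pileup downstream of the insertion point. With mean
per-base coverages $m_\mathrm{up}, m_\mathrm{down}$ in the mutant and
$c_\mathrm{up}, c_\mathrm{down}$ in the control (upstream/downstream taken
along the transcript, i.e. swapped on the minus strand), the surviving
full-length fraction is

$$f = \frac{m_\mathrm{down}/m_\mathrm{up}}{c_\mathrm{down}/c_\mathrm{up}},
\qquad \text{clamped to } [0,1].$$

Normalizing by the control ratio cancels the 3'/5' coverage bias shared by
both genotypes, and makes the estimate invariant to rescaling either
library. `exclusion_nt` (default 0) omits bases on each side of the
breakpoint, because reads spanning the insertion junction are unmappable in
a window of unknown width. Degenerate inputs (zero mutant upstream
coverage, zero control ratio, an interval outside the profile) are errors,
not NaNs. A mutant in which ~96% of transcripts are truncated yields
$f \approx 0.04$; the simulation tests recover $f = 0.04$ to within ±0.01
at 200× coverage (mean over 50 replicates, 2 kb regions).

## Conserved pyrimidine-tract scanning

A PTB site is defined combinatorially: a maximal stretch of at least
`min_length = 9` C/U residues tolerating at most `max_g = 1` G anywhere in
the stretch (boundaries included); A and N terminate a tract and never
count. T and U are equivalent throughout, since RNA motifs are searched
over DNA alignments. `find_pyrimidine_tracts()` reports all maximal extents
— overlapping maximal windows that differ in which G they tolerate are
reported separately, never merged, which is the simplest deterministic
rule.

Conservation is assessed on multiz-style MAF blocks against a designated
reference species. For each reference tract, the window extends
`window_nt = 25` *ungapped reference* nucleotides on each flank — gap
columns consume no budget, which is how we read "not including indels" as a
distance measure; a total-window interpretation would be strictly narrower
and can be emulated with a smaller `window_nt`. A species supports the site
when its degapped row over those columns itself contains a qualifying tract
under the same rule (full tract required — no partial-homology credit). A
hit is emitted when at least `min_species = 9` of the species support it,
the reference counting toward the quorum (it trivially contains the
tract), and any species in the block — not only congeneric ones — may
support. Minus-strand rows are reverse-complemented before tract search;
this convention makes scanning a reverse-complemented, strand-flipped
alignment yield identical reference-space hits, and blocks whose reference
row is minus-strand are re-oriented to the plus strand first (MAF
minus-strand starts count from the reverse-complemented source). Blocks are
independent, so a site spanning a block boundary is not detected — a
documented limitation; blocks lacking the reference are skipped with a
warning.

The scanner is validated two ways: against an exhaustive
substring-enumeration oracle on hundreds of randomized small alignments,
and by planted-site recovery (20 of 20 C/U-rich tracts planted in 12 of 15
species across a 50 kb purine-biased background, with ≤ 10 nt offset jitter
and ≤ 1 substitution per species, are recovered at the default parameters;
a site carried by only 8 species is never called).

## Gene-set overlap

For sets of sizes $n_A$, $n_B$ drawn from a universe of size $N$, the
expected intersection is the hypergeometric mean $n_A n_B/N$, and the
attached p-value is the one-sided enrichment tail $P(X \ge \mathrm{obs})$ —
matching the "more overlap than expected by chance" framing such screens
use. The universe must be supplied explicitly (typically the genes
detectably expressed in the comparison); there is no silent default,
because the expectation is meaningless without it. Inputs are validated:
duplicate ids within a set and ids outside the universe are errors that
name the offenders.

## Synthetic data: what it emulates and what it does not

* `simulate_junction_counts()` draws per-event totals Poisson around
  `depth` (negative-binomial via `dispersion` for overdispersion) and
  splits them $\mathrm{Binomial}(\mathrm{total}, \psi)$ independently per
  condition — exactly the sampling model the test assumes. Default depth 50
  reflects the junction coverage at which such screens operate; calibration
  tests use 2,000 events at $\psi = 0.5$, power tests 500 events per
  $\Delta\psi \in \{0.1, 0.2, 0.4\}$ at depth 100.
* `simulate_coverage_pair()` draws independent per-base Poisson pileups,
  control flat and mutant dropping to
  `coverage_depth * full_length_fraction` downstream of the breakpoint.
  Defaults (2 kb, 100–200×, breakpoint at the midpoint) are desk-scale
  stand-ins for a real gene body.
* `simulate_alignment()` builds one alignment block: a reference drawn with
  pyrimidine fraction 0.3 (purine-biased, so spurious tracts are rare but
  not absent), per-species uniform substitutions (rate 0.05) and
  indels with geometric lengths (mean 2) — an arbitrary but fixed choice,
  since nothing here depends on a realistic substitution process. Planted
  tracts are copied into the supporting species with C↔T substitutions
  only, so a plant always remains a qualifying tract (recovery guarantees
  would otherwise be impossible to state); per-species placement offsets
  are realized by shifting the planted columns rather than by dedicated
  indels, which has the same observable effect — a displaced in-window
  tract — with far simpler bookkeeping. In non-supporting species the site
  neighbourhood is rewritten with purines out to the scan window, the
  unambiguous meaning of "ablated".
* `simulate_gene_sets()` draws sets uniformly or with a forced
  intersection size.

All generators are seeded, produce byte-identical output for identical
configurations, emit truth tables alongside the data, and write files that
parse cleanly back through the package's own readers. What the simulations
do *not* emulate: mappability and GC bias, positional read-coverage
autocorrelation, junction-read double counting, phylogenetic correlation
between species, and alignment error. Passing tests therefore demonstrate
correctness of the computations under their stated sampling models, not
robustness to every artifact of real libraries.

## Numerical and interface conventions

* Coordinates: GTF is 1-based inclusive; BED/bedGraph 0-based half-open;
  MAF 0-based with minus-strand starts counted on the reverse-complemented
  source. `gtf_to_bed_coords()` performs the off-by-one conversion.
* p-value floors: machine epsilon before the log-odds transform; log-odds
  capped symmetrically by the floor.
* Clamping: truncation estimates never leave $[0,1]$ even when sampling
  noise pushes the raw ratio above 1.
* Tie-breaks: isoform-call ordering by descending log-odds then
  lexicographic `event_id`; untestable events sort last.
* Degenerate inputs error early with classed conditions
  (`ptbseq_parse_error`, `ptbseq_input_error`, `ptbseq_untestable_error`,
  `ptbseq_estimate_error`) naming the offending line, id or quantity.

## Known limitations

* The isoform test is per-event and single-library; replicate pooling is
  the caller's responsibility, and no hierarchy links events within a gene.
* The scanner's per-species support is all-or-nothing; a
  fractional-identity mode is out of scope.
* Sites spanning MAF block boundaries are invisible.
* The truncation estimator assumes the breakpoint is known; locating
  insertions from split reads is out of scope.
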