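#' Binomial mutation allele-fraction estimate
#'
#' The mutation allele fraction at an SNV is the number of mutation-containing
#' reads divided by all reads overlapping the position, `p = k / n`. The
#' standard error comes from the binomial distribution, stabilized with a
#' +2/+4 pseudocount (`p~ = (k+2)/(n+4)`, `se = sqrt(p~ (1-p~) / (n+4))`) so
#' that it stays positive at k = 0 and k = n; without stabilization those
#' boundary cases would receive infinite weight in replicate averaging.
#'
#' @param mutant_reads Mutant read count k (vectorized).
#' @param total_reads Total read count n >= 1 (vectorized).
#' @return data.frame with columns `estimate` (k/n), `se` and `n_effective`
#'   (= n, the reads used).
#' @export
allele_fraction <- function(mutant_reads, total_reads) {
  if (any(total_reads < 1L))
    stop("allele fraction undefined at zero coverage; filter such loci first")
  if (any(mutant_reads < 0L) || any(mutant_reads > total_reads))
    stop("mutant_reads must satisfy 0 <= k <= n")
  p <- mutant_reads / total_reads
  pt <- (mutant_reads + 2) / (total_reads + 4)
  se <- sqrt(pt * (1 - pt) / (total_reads + 4))
  data.frame(estimate = p, se = se, n_effective = total_reads)
}

#' Combine replicate allele-fraction estimates by inverse-variance weighting
#'
#' Replicate frequencies are combined by error-weighted averaging with weights
#' `w_i = 1 / se_i^2` from the binomial uncertainties, so replicates with more
#' reads receive more weight. The combined standard error is
#' `sqrt(1 / sum(w_i))`.
#'
#' @param estimates data.frame as returned by [allele_fraction()] (one row per
#'   replicate), or a list of such one-row data.frames.
#' @return One-row data.frame with `estimate`, `se`, `n_effective` (summed
#'   reads).
#' @export
combine_replicates <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- do.call(rbind, estimates)
  if (is.null(estimates) || nrow(estimates) == 0L)
    stop("no replicate estimates to combine")
  w <- 1 / estimates$se^2
  est <- sum(w * estimates$estimate) / sum(w)
  data.frame(estimate = est, se = sqrt(1 / sum(w)),
             n_effective = sum(estimates$n_effective))
}

#' Minimum-coverage filter
#'
#' An SNV is analyzed only if at least `min_reads` DNA reads and `min_reads`
#' RNA reads overlap its genomic position. Replicate counts are pooled per
#' position before the comparison; the cutoff is inclusive.
#'
#' @param dna_total_reads Total tumor DNA reads at the position (pooled over
#'   replicates), vectorized.
#' @param rna_total_reads Total tumor RNA reads at the position (pooled),
#'   vectorized.
#' @param min_reads Minimum coverage per analyte (default 10).
#' @return Logical: TRUE = keep.
#' @export
min_read_filter <- function(dna_total_reads, rna_total_reads, min_reads = 10L) {
  dna_total_reads >= min_reads & rna_total_reads >= min_reads
}

#' Germline binomial filter for putative somatic SNVs
#'
#' Guards against coverage artifacts that make a variant look tumor-only. A
#' candidate somatic SNV is kept only when (a) the germline sample is covered
#' well enough that a heterozygous germline variant would almost surely have
#' produced at least one mutant read — `P(0 mutant | het) = 0.5^n_germline`
#' must fall below `alpha` — and (b) the observed germline mutant reads are
#' consistent with sequencing error alone (one-sided exact binomial test of
#' `k_germline` against `error_rate` not significant at `alpha`).
#'
#' @param germline_mutant_reads,germline_total_reads Pooled germline DNA
#'   counts at the position.
#' @param alpha Significance level (default 0.05).
#' @param error_rate Assumed per-read sequencing error rate (default 1e-3).
#' @return Logical: TRUE = keep as somatic.
#' @export
germline_binomial_filter <- function(germline_mutant_reads,
                                     germline_total_reads,
                                     alpha = 0.05, error_rate = 1e-3) {
  stopifnot(length(germline_mutant_reads) == length(germline_total_reads))
  mapply(function(k, n) {
    if (n <= 0L) return(FALSE)
    if (0.5^n >= alpha) return(FALSE)  # too shallow to have seen a het variant
    p_err <- stats::binom.test(k, n, p = error_rate,
                               alternative = "greater")$p.value
    p_err >= alpha
  }, germline_mutant_reads, germline_total_reads)
}

#' Fraction of mutations detectable in RNA
#'
#' A mutation counts as expressed when at least `min_mutant` mutant RNA read
#' is observed (presence definition). Apply after [min_read_filter()] so every
#' SNV has enough RNA coverage for presence/absence to be meaningful.
#'
#' @param rna_mutant_reads Pooled mutant RNA read counts, one per SNV.
#' @param min_mutant Presence threshold (default 1 mutant read).
#' @return Fraction of SNVs with `rna_mutant_reads >= min_mutant`.
#' @export
expressed_fraction <- function(rna_mutant_reads, min_mutant = 1L) {
  if (length(rna_mutant_reads) == 0L)
    stop("expressed_fraction undefined on an empty SNV set")
  mean(rna_mutant_reads >= min_mutant)
}

#' Per-SNV allele-fraction table from a long counts table
#'
#' Pools and combines replicate counts per SNV: DNA and RNA allele fractions
#' are estimated per replicate with [allele_fraction()] and combined with
#' [combine_replicates()]; pooled totals drive [min_read_filter()] and the
#' germline filter.
#'
#' @param counts Long counts data.frame (see [simulate_counts()] /
#'   [read_counts_tsv()]).
#' @param min_reads Minimum pooled DNA and RNA coverage (default 10).
#' @param alpha,error_rate Passed to [germline_binomial_filter()].
#' @return data.frame, one row per SNV: snv_id, p_dna, se_dna, dna_total,
#'   dna_mutant, p_rna, se_rna, rna_total, rna_mutant, germline_total,
#'   germline_mutant, pass_min_reads, pass_germline, pass_filters. SNVs with
#'   zero coverage in an analyte get NA estimates and fail the filter.
#' @export
estimate_allele_fractions <- function(counts, min_reads = 10L, alpha = 0.05,
                                      error_rate = 1e-3) {
  need <- c("snv_id", "sample", "analyte", "mutant_reads", "total_reads")
  stopifnot(all(need %in% names(counts)))
  ids <- unique(counts$snv_id)

  comb <- function(sub) {
    sub <- sub[sub$total_reads >= 1L, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(estimate = NA_real_, se = NA_real_, n_effective = 0L))
    combine_replicates(allele_fraction(sub$mutant_reads, sub$total_reads))
  }

  by_id <- split(counts, counts$snv_id)[ids]
  rows <- lapply(ids, function(id) {
    sub <- by_id[[id]]
    td <- sub[sub$sample == "tumor" & sub$analyte == "DNA", , drop = FALSE]
    tr <- sub[sub$sample == "tumor" & sub$analyte == "RNA", , drop = FALSE]
    gd <- sub[sub$sample == "germline" & sub$analyte == "DNA", , drop = FALSE]
    d <- comb(td); r <- comb(tr)
    data.frame(
      snv_id = id,
      p_dna = d$estimate, se_dna = d$se,
      dna_total = sum(td$total_reads), dna_mutant = sum(td$mutant_reads),
      p_rna = r$estimate, se_rna = r$se,
      rna_total = sum(tr$total_reads), rna_mutant = sum(tr$mutant_reads),
      germline_total = sum(gd$total_reads),
      germline_mutant = sum(gd$mutant_reads),
      stringsAsFactors = FALSE
    )
  })
  af <- do.call(rbind, rows)
  af$pass_min_reads <- min_read_filter(af$dna_total, af$rna_total, min_reads)
  af$pass_germline <- germline_binomial_filter(af$germline_mutant,
                                               af$germline_total,
                                               alpha = alpha,
                                               error_rate = error_rate)
  af$pass_filters <- af$pass_min_reads & af$pass_germline
  af
}
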