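#' RNA-DNA mutation allele-frequency imbalance
#'
#' The imbalance score of an SNV is the RNA mutation allele frequency minus
#' the DNA mutation allele frequency, in percentage points:
#' `I = 100 * (p_rna - p_dna)`. Near zero when the mutant allele is
#' transcribed in proportion to its DNA dosage; strongly negative when the
#' mutant transcript is depleted (e.g. by nonsense-mediated decay).
#'
#' @param p_rna,p_dna Replicate-combined allele fractions in \[0, 1\]
#'   (vectorized).
#' @return Imbalance in percentage points, in \[-100, 100\].
#' @export
imbalance <- function(p_rna, p_dna) {
  if (any(p_rna < 0 | p_rna > 1, na.rm = TRUE) ||
      any(p_dna < 0 | p_dna > 1, na.rm = TRUE))
    stop("allele fractions must lie in [0, 1]")
  100 * (p_rna - p_dna)
}

#' Squared Pearson correlation of DNA and RNA allele fractions
#'
#' @param p_dna,p_rna Paired allele fractions (>= 3 complete pairs).
#' @return r^2 (squared Pearson linear correlation), or NA with a warning if
#'   either vector has zero variance.
#' @export
correlate <- function(p_dna, p_rna) {
  keep <- stats::complete.cases(p_dna, p_rna)
  x <- p_dna[keep]; y <- p_rna[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Summary statistics of an SNV group
#'
#' @param records data.frame with columns `imbalance`, `p_dna`, `p_rna`.
#' @return One-row data.frame: n, mean_imbalance, sd_imbalance, r2 (NA where
#'   undefined: sd needs n >= 2, r2 needs n >= 3 and variance).
#' @export
group_stats <- function(records) {
  n <- nrow(records)
  data.frame(
    n = n,
    mean_imbalance = if (n >= 1L) mean(records$imbalance) else NA_real_,
    sd_imbalance = if (n >= 2L) stats::sd(records$imbalance) else NA_real_,
    r2 = if (n >= 3L && stats::sd(records$p_dna) > 0 &&
             stats::sd(records$p_rna) > 0)
      stats::cor(records$p_dna, records$p_rna)^2 else NA_real_
  )
}

#' High- versus low-coverage imbalance strata
#'
#' Splits SNVs by RNA read coverage into a high stratum (at least
#' `high_cutoff` reads) and a low stratum (fewer than `low_cutoff` reads) and
#' summarizes each. Because the binomial uncertainty of the RNA allele
#' fraction shrinks with coverage, the low stratum is expected to show a
#' larger imbalance spread.
#'
#' @param records data.frame with `imbalance`, `p_dna`, `p_rna`,
#'   `rna_total`.
#' @param high_cutoff,low_cutoff Coverage cutoffs (defaults 65 and 15 reads).
#' @return list with elements `high` and `low` ([group_stats()] rows); an
#'   empty stratum is flagged with a warning and n = 0.
#' @export
coverage_strata <- function(records, high_cutoff = 65L, low_cutoff = 15L) {
  hi <- records[records$rna_total >= high_cutoff, , drop = FALSE]
  lo <- records[records$rna_total < low_cutoff, , drop = FALSE]
  if (nrow(hi) == 0L) warning("high-coverage stratum is empty")
  if (nrow(lo) == 0L) warning("low-coverage stratum is empty")
  list(high = group_stats(hi), low = group_stats(lo))
}

#' Two-sample t-test on imbalance scores of two SNV groups
#'
#' Tests whether the two groups of imbalance scores come from the same normal
#' distribution. The default is the classic pooled-variance (equal-variance)
#' two-sample t-test; set `welch = TRUE` for the unequal-variance variant.
#'
#' @param a,b Numeric vectors of imbalance scores (each n >= 2).
#' @param welch Use the Welch test instead of pooled variance.
#' @return The p-value.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  stats::t.test(a, b, var.equal = !welch)$p.value
}

#' Assemble per-SNV imbalance records
#'
#' Joins the allele-fraction table, copy-number assignments and consequence
#' classes into one record per SNV passing the coverage filters, with the
#' imbalance score and the PTC/coding strata attached.
#'
#' @param af Output of [estimate_allele_fractions()].
#' @param cn_fit Optional data.frame with snv_id, cn, m (e.g. from
#'   [assign_cn()] bound to the snv_ids it was run on).
#' @param consequences Optional output of [classify_consequence()].
#' @param filtered_only Keep only SNVs with `pass_filters` (default TRUE).
#' @return data.frame of imbalance records.
#' @export
imbalance_table <- function(af, cn_fit = NULL, consequences = NULL,
                            filtered_only = TRUE) {
  rec <- af
  if (filtered_only) rec <- rec[rec$pass_filters, , drop = FALSE]
  rec$imbalance <- imbalance(rec$p_rna, rec$p_dna)
  if (!is.null(cn_fit))
    rec <- merge(rec, cn_fit[, c("snv_id", "cn", "m")], by = "snv_id",
                 all.x = TRUE, sort = FALSE)
  if (!is.null(consequences)) {
    rec <- merge(rec, consequences[, c("snv_id", "class")], by = "snv_id",
                 all.x = TRUE, sort = FALSE)
    st <- strata(rec$class)
    rec$ptc_stratum <- st$ptc_stratum
    rec$coding_stratum <- st$coding_stratum
  }
  rec[order(rec$snv_id), , drop = FALSE]
}

#' Summarize an imbalance analysis
#'
#' Computes the headline quantities of the RNA-versus-DNA analysis: the
#' expressed fraction (SNVs with at least one mutant RNA read), the overall
#' DNA-RNA r^2, high/low coverage strata, the count of SNVs with absolute
#' imbalance above `imbalance_cutoff`, per-stratum group statistics and the
#' pooled-variance t-test p-values between the no-PTC group and each PTC
#' group and between silent and non-synonymous SNVs.
#'
#' @param records Output of [imbalance_table()] (with consequence strata for
#'   the group comparisons to be included).
#' @param high_cutoff,low_cutoff RNA coverage cutoffs for the strata.
#' @param imbalance_cutoff Absolute-imbalance flag threshold, percentage
#'   points (default 25).
#' @return A nested list (JSON-ready) of summary statistics.
#' @export
summarize_imbalance <- function(records, high_cutoff = 65L, low_cutoff = 15L,
                                imbalance_cutoff = 25) {
  out <- list(
    n = nrow(records),
    expressed_fraction = expressed_fraction(records$rna_mutant),
    r2 = correlate(records$p_dna, records$p_rna),
    n_extreme_imbalance = sum(abs(records$imbalance) > imbalance_cutoff),
    imbalance_cutoff = imbalance_cutoff,
    coverage = coverage_strata(records, high_cutoff, low_cutoff)
  )
  if (!is.null(records$ptc_stratum)) {
    by_ptc <- split(records, records$ptc_stratum)
    out$ptc_groups <- lapply(by_ptc, group_stats)
    ii <- function(g) records$imbalance[records$ptc_stratum == g]
    if (nrow(by_ptc$no_PTC) >= 2L) {
      if (nrow(by_ptc$PTC_not_last_exon) >= 2L)
        out$p_no_ptc_vs_ptc_not_last <- compare_groups(ii("no_PTC"),
                                                       ii("PTC_not_last_exon"))
      if (nrow(by_ptc$PTC_last_exon) >= 2L)
        out$p_no_ptc_vs_ptc_last <- compare_groups(ii("no_PTC"),
                                                   ii("PTC_last_exon"))
    }
  }
  if (!is.null(records$coding_stratum)) {
    sil <- records$imbalance[records$coding_stratum %in% "silent"]
    nsy <- records$imbalance[records$coding_stratum %in% "nonsynonymous"]
    out$coding_groups <- list(
      silent = group_stats(records[records$coding_stratum %in% "silent", ]),
      nonsynonymous = group_stats(
        records[records$coding_stratum %in% "nonsynonymous", ]))
    if (length(sil) >= 2L && length(nsy) >= 2L)
      out$p_silent_vs_nonsynonymous <- compare_groups(sil, nsy)
  }
  out
}

#' Write the imbalance report: table, summary JSON and figures
#'
#' Emits `imbalance.tsv` (the record table), `summary.json`
#' ([summarize_imbalance()] output) and, when ggplot2 is available,
#' `scatter_cn.png` (DNA vs RNA allele fraction colored by copy number),
#' `scatter_coverage.png` (colored by RNA coverage) and
#' `imbalance_hist.png` (imbalance histograms by PTC stratum). Rerunning on
#' the same records reproduces the same files.
#'
#' @param records Output of [imbalance_table()].
#' @param out_dir Output directory.
#' @param ... Passed to [summarize_imbalance()].
#' @return Invisibly, the summary list.
#' @export
report <- function(records, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(records, file.path(out_dir, "imbalance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  smry <- summarize_imbalance(records, ...)
  jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- ggplot2::ggplot(records,
            ggplot2::aes(x = p_dna, y = p_rna)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           color = "grey60") +
      ggplot2::labs(x = "DNA mutation allele fraction",
                    y = "RNA mutation allele fraction") +
      ggplot2::theme_bw()
    if (!is.null(records$cn))
      ggplot2::ggsave(file.path(out_dir, "scatter_cn.png"),
        gg + ggplot2::geom_point(ggplot2::aes(color = factor(cn)), size = 1) +
          ggplot2::labs(color = "copy number"),
        width = 5, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "scatter_coverage.png"),
      gg + ggplot2::geom_point(ggplot2::aes(color = rna_total,
                                            size = rna_total), alpha = 0.7) +
        ggplot2::scale_color_viridis_c(trans = "log10") +
        ggplot2::scale_size_continuous(range = c(0.3, 2.5), guide = "none") +
        ggplot2::labs(color = "RNA reads"),
      width = 5, height = 4, dpi = 150)
    if (!is.null(records$ptc_stratum))
      ggplot2::ggsave(file.path(out_dir, "imbalance_hist.png"),
        ggplot2::ggplot(records, ggplot2::aes(x = imbalance,
                                              fill = ptc_stratum)) +
          ggplot2::geom_histogram(binwidth = 5, boundary = 0) +
          ggplot2::facet_wrap(~ptc_stratum, ncol = 1, scales = "free_y") +
          ggplot2::labs(x = "imbalance (RNA - DNA, percentage points)") +
          ggplot2::theme_bw() + ggplot2::theme(legend.position = "none"),
        width = 5, height = 6, dpi = 150)
  }
  invisible(smry)
}
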