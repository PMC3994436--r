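#' Discrete allele-fraction lattice
#'
#' A somatic mutation present on m of CN allelic copies can only be observed
#' at discrete DNA allele fractions: at purity 1 these are m/CN (100% in
#' haploid regions; 50/100% diploid; 33/66/100% triploid; 25/50/75/100%
#' tetraploid). With tumor purity rho the fractions shift to
#' `m*rho / (CN*rho + 2*(1-rho))`. Duplicated fractions (e.g. 1/2 and 2/4)
#' are retained with their distinct (CN, m) identities.
#'
#' @param cn_max Maximum copy number to enumerate (default 5).
#' @param purity Tumor purity rho in (0, 1].
#' @return data.frame with columns `cn`, `m`, `af`, ordered by cn then m.
#' @export
af_lattice <- function(cn_max = 5L, purity = 1) {
  stopifnot(cn_max >= 1L)
  cn <- rep(seq_len(cn_max), seq_len(cn_max))
  m <- unlist(lapply(seq_len(cn_max), seq_len))
  data.frame(cn = cn, m = m, af = true_dna_af(m, cn, purity))
}

#' Tumor:germline coverage ratio at a locus
#'
#' Under equal library sizes, the ratio of tumor to germline exome reads
#' mapping to a locus is proportional to the locus copy number. Replicate
#' totals are summed before taking the ratio.
#'
#' @param tumor_total_reads Tumor DNA total reads, one value per replicate.
#' @param germline_total_reads Germline DNA total reads per replicate.
#' @return The ratio of summed tumor to summed germline reads.
#' @export
coverage_ratio <- function(tumor_total_reads, germline_total_reads) {
  g <- sum(germline_total_reads)
  if (g <= 0) stop("zero germline coverage: locus belongs in the germline filter, not here")
  sum(tumor_total_reads) / g
}

#' Standard error of the log coverage ratio
#'
#' Delta-method standard error of the log of the ratio of two Poisson read
#' totals: `sqrt(1/tumor_total + 1/germline_total)`.
#'
#' @param tumor_total,germline_total Pooled read totals (vectorized).
#' @return Standard error(s) of the log ratio.
#' @export
log_ratio_se <- function(tumor_total, germline_total) {
  sqrt(1 / pmax(tumor_total, 1) + 1 / pmax(germline_total, 1))
}

# Binomial log-likelihood matrix: SNVs x lattice points, fractions clamped
# away from 0/1 so boundary lattice points stay comparable under rare
# error reads.
.bin_ll_matrix <- function(mutant, total, af) {
  af <- pmin(pmax(af, 1e-6), 1 - 1e-6)
  out <- vapply(af, function(a) stats::dbinom(mutant, total, a, log = TRUE),
                numeric(length(mutant)))
  matrix(out, nrow = length(mutant), ncol = length(af))
}

#' Jointly fit tumor purity and coverage scaling from all SNVs
#'
#' Grid search over purity rho and a sample-wide coverage scale c. For each
#' candidate (rho, c), every SNV is assigned its best lattice point (CN, m)
#' by combining the binomial log-likelihood of its mutant DNA read count at
#' the lattice allele fraction with a Gaussian log-likelihood of its log
#' tumor:germline coverage ratio around `log((rho*CN + 2*(1-rho)) / c)`; the
#' candidate maximizing the total log-likelihood wins. The scale c absorbs
#' the mean DNA content per cell (rho*psi + 2*(1-rho)): at purity 1 the
#' expected coverage ratio is simply CN / c. Mean ploidy psi is reported as
#' the unweighted mean of the fitted copy numbers over loci.
#'
#' @param mutant_reads,total_reads Pooled tumor DNA counts per SNV.
#' @param ratio Tumor:germline coverage ratio per SNV ([coverage_ratio()]).
#' @param ratio_se Standard error of `log(ratio)` per SNV (default from
#'   [log_ratio_se] applied to the pooled totals via `ratio_totals`).
#' @param cn_max Maximum copy number (default 5).
#' @param rho_grid Candidate purities (default 0.10 to 1.00 in steps of 0.05).
#' @param ratio_weight Relative weight of the coverage-ratio log-likelihood
#'   against the allele-fraction log-likelihood (default 1: equal weighting).
#' @return A list of class `sample_model`: `purity`, `psi`, `coverage_scale`,
#'   `loglik`, `rho_profile` (per-rho profile log-likelihood),
#'   `rho_identifiable` (FALSE when several purities fit equally well, e.g.
#'   an all-diploid genome) and `assignments` (the per-SNV [assign_cn()]
#'   table at the fitted model).
#' @export
fit_sample_model <- function(mutant_reads, total_reads, ratio,
                             ratio_se = NULL,
                             cn_max = 5L,
                             rho_grid = seq(0.10, 1.00, by = 0.05),
                             ratio_weight = 1) {
  n <- length(mutant_reads)
  stopifnot(length(total_reads) == n, length(ratio) == n)
  if (n < 20L)
    warning("fewer than 20 SNVs: purity and scale estimates may be unstable")
  if (is.null(ratio_se)) ratio_se <- rep(0.1, n)
  lr <- log(ratio)

  best <- list(ll = -Inf)
  rho_profile <- stats::setNames(numeric(length(rho_grid)),
                                 formatC(rho_grid, format = "f", digits = 2))
  sdm <- NULL

  for (ri in seq_along(rho_grid)) {
    rho <- rho_grid[ri]
    lat <- af_lattice(cn_max, rho)
    binm <- .bin_ll_matrix(mutant_reads, total_reads, lat$af)  # n x nL
    if (is.null(sdm) || !identical(dim(sdm), dim(binm)))
      sdm <- matrix(ratio_se, n, nrow(lat))
    b <- log(rho * lat$cn + 2 * (1 - rho))
    d0 <- outer(lr, b, "-")                                     # lr_i - b_j
    gauss_const <- -log(sdm) - 0.5 * log(2 * pi)

    eval_c <- function(log_c) {
      z <- (d0 + log_c) / sdm
      m <- binm + ratio_weight * (-0.5 * z^2 + gauss_const)
      sum(do.call(pmax, as.data.frame(m)))
    }
    coarse <- seq(log(0.5), log(2 * cn_max + 2), length.out = 40L)
    ll_c <- vapply(coarse, eval_c, numeric(1))
    j <- which.max(ll_c)
    lo <- coarse[max(1L, j - 1L)]; hi <- coarse[min(length(coarse), j + 1L)]
    fine <- seq(lo, hi, length.out = 41L)
    ll_f <- vapply(fine, eval_c, numeric(1))
    k <- which.max(ll_f)
    rho_profile[ri] <- ll_f[k]
    if (ll_f[k] > best$ll)
      best <- list(ll = ll_f[k], rho = rho, log_c = fine[k])
  }

  identifiable <- sum(rho_profile >= max(rho_profile) - 1e-6) == 1L
  if (!identifiable)
    warning("purity is not identifiable from these SNVs (several purities fit equally well)")

  model <- structure(list(
    purity = best$rho,
    coverage_scale = exp(best$log_c),
    psi = NA_real_,
    loglik = best$ll,
    rho_profile = rho_profile,
    rho_identifiable = identifiable,
    cn_max = cn_max,
    ratio_weight = ratio_weight
  ), class = "sample_model")

  asg <- assign_cn(mutant_reads, total_reads, ratio, model,
                   ratio_se = ratio_se, cn_max = cn_max,
                   ratio_weight = ratio_weight)
  model$psi <- mean(asg$cn)
  model$assignments <- asg
  model
}

#' Maximum-likelihood copy number and multiplicity for each SNV
#'
#' Scores every lattice point (CN, m) with CN up to `cn_max` by the binomial
#' log-likelihood of the pooled mutant DNA reads at the lattice allele
#' fraction plus (when a coverage ratio is supplied) the Gaussian
#' log-likelihood of the log coverage ratio under the sample model, and
#' returns the best. Fractions shared by several lattice points (1/2 = 2/4)
#' are usually separated by the coverage-ratio term; exact ties are broken
#' toward the smaller copy number, then the smaller multiplicity.
#'
#' @param mutant_reads,total_reads Pooled tumor DNA counts per SNV
#'   (vectorized).
#' @param ratio Per-SNV tumor:germline coverage ratio, or NULL to use the
#'   allele-fraction likelihood alone.
#' @param model A `sample_model` (or a list with `purity` and
#'   `coverage_scale`).
#' @param ratio_se Standard error of log(ratio) per SNV (default 0.1).
#' @param cn_max,ratio_weight See [fit_sample_model()].
#' @return data.frame per SNV: `cn`, `m`, `loglik` (best lattice score) and
#'   `runner_up_margin` (best minus second-best score; small margins flag
#'   ambiguous assignments).
#' @export
assign_cn <- function(mutant_reads, total_reads, ratio = NULL, model,
                      ratio_se = NULL, cn_max = model$cn_max %||% 5L,
                      ratio_weight = model$ratio_weight %||% 1) {
  n <- length(mutant_reads)
  rho <- model$purity
  lat <- af_lattice(cn_max, rho)
  score <- .bin_ll_matrix(mutant_reads, total_reads, lat$af)
  if (!is.null(ratio)) {
    if (is.null(ratio_se)) ratio_se <- rep(0.1, n)
    sdm <- matrix(ratio_se, n, nrow(lat))
    mu <- log((rho * lat$cn + 2 * (1 - rho)) / model$coverage_scale)
    z <- (outer(log(ratio), mu, "-")) / sdm
    score <- score + ratio_weight * (-0.5 * z^2 - log(sdm) - 0.5 * log(2 * pi))
  }
  # Lattice rows are ordered by (cn, m); which.max takes the first of exact
  # ties, implementing the parsimony tie-break.
  pick <- apply(score, 1L, which.max)
  best <- score[cbind(seq_len(n), pick)]
  second <- vapply(seq_len(n), function(i) max(score[i, -pick[i]], -Inf),
                   numeric(1))
  data.frame(cn = lat$cn[pick], m = lat$m[pick], loglik = best,
             runner_up_margin = best - second)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map SNVs to copy-number segments
#'
#' Interval lookup of SNV positions (0-based) against a segment table
#' (0-based half-open), as read by [read_segments_bed()].
#'
#' @param snvs data.frame with `chrom` and `pos`.
#' @param segments data.frame with `chrom`, `start`, `end`.
#' @return Integer vector of row indices into `segments` (NA when an SNV
#'   falls in no segment).
#' @export
snv_segment_index <- function(snvs, segments) {
  vapply(seq_len(nrow(snvs)), function(i) {
    j <- which(segments$chrom == snvs$chrom[i] &
               segments$start <= snvs$pos[i] &
               segments$end > snvs$pos[i])
    if (length(j) == 0L) NA_integer_ else j[1L]
  }, integer(1))
}

#' Segment-pooled coverage ratios
#'
#' Copy number is a property of a genomic segment, not of a single base, and
#' exome coverage supporting it accumulates over the whole locus. Pooling the
#' tumor and germline read totals of all SNVs sharing a segment before taking
#' the ratio shrinks the log-ratio standard error by roughly the square root
#' of the number of pooled loci, which is usually what separates adjacent
#' copy numbers for homozygous mutations (whose allele fraction is
#' uninformative). SNVs with `segment = NA` keep their per-SNV ratio.
#'
#' @param tumor_total,germline_total Pooled per-SNV read totals.
#' @param segment Segment index per SNV (e.g. [snv_segment_index()]).
#' @return data.frame with per-SNV `ratio` and `ratio_se` (se of the log
#'   ratio) computed from the segment-pooled totals.
#' @export
pool_segment_ratios <- function(tumor_total, germline_total, segment) {
  n <- length(tumor_total)
  stopifnot(length(germline_total) == n, length(segment) == n)
  key <- as.character(segment)
  pt <- tapply(tumor_total, key, sum)
  pg <- tapply(germline_total, key, sum)
  ratio <- ifelse(is.na(segment), tumor_total / germline_total,
                  (pt / pg)[key])
  se <- ifelse(is.na(segment),
               log_ratio_se(tumor_total, germline_total),
               log_ratio_se(pt, pg)[key])
  data.frame(ratio = as.numeric(ratio), ratio_se = as.numeric(se))
}
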