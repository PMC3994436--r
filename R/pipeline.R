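#' Pipeline configuration
#'
#' Bundles the simulator configuration with all analysis thresholds. Every
#' threshold that matters to the analysis is a default here, not a constant
#' in code: the 10-read coverage floor, the 65/15-read coverage strata, the
#' |I| > 25 extreme-imbalance flag, the copy-number cap of 5, the germline
#' filter's significance level and error rate, and the relative weight of
#' coverage versus allele-fraction evidence in the copy-number fit.
#'
#' @param sim A [sim_config()].
#' @param min_reads Minimum pooled DNA and RNA reads per SNV.
#' @param cn_max Maximum copy number in the lattice.
#' @param high_cutoff,low_cutoff RNA coverage strata cutoffs (reads).
#' @param alpha Germline-filter significance level.
#' @param error_rate Germline sequencing error rate for the filter.
#' @param imbalance_cutoff Extreme-imbalance threshold (percentage points).
#' @param ratio_weight Coverage-ratio log-likelihood weight in the fit.
#' @param nmd_50nt_rule Apply the 50-nt NMD boundary rule in annotation.
#' @param seed Overrides the simulator seed when not NULL.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), min_reads = 10L, cn_max = 5L,
                            high_cutoff = 65L, low_cutoff = 15L,
                            alpha = 0.05, error_rate = 1e-3,
                            imbalance_cutoff = 25, ratio_weight = 1,
                            nmd_50nt_rule = FALSE, seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  stopifnot(min_reads > 0L, cn_max >= 1L, high_cutoff > 0L, low_cutoff > 0L,
            alpha > 0, alpha < 1, imbalance_cutoff > 0, ratio_weight >= 0)
  structure(list(sim = sim, min_reads = as.integer(min_reads),
                 cn_max = as.integer(cn_max),
                 high_cutoff = as.integer(high_cutoff),
                 low_cutoff = as.integer(low_cutoff), alpha = alpha,
                 error_rate = error_rate,
                 imbalance_cutoff = imbalance_cutoff,
                 ratio_weight = ratio_weight,
                 nmd_50nt_rule = isTRUE(nmd_50nt_rule)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any [pipeline_config()] argument at the top level and
#' a `sim:` mapping with [sim_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (genome, counts, fixture files),
#' allele fractions, copy-number fit, consequence annotation, imbalance
#' report — reading each stage's input back from the files the previous stage
#' wrote, and finishes with a manifest of MD5 hashes of every artifact. The
#' run is a pure function of the configuration (including its seed): the same
#' configuration reproduces byte-identical fixtures and manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `truth`, `af`, `model`, `consequences`,
#'   `records`, `summary` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx_dir <- file.path(out_dir, "fixtures")

  res <- list()
  .stage("simulate", {
    res$truth <- simulate_genome(config$sim)
    counts <- simulate_counts(res$truth, config$sim)
    res$fixture_paths <- write_fixtures(res$truth, counts, fx_dir)
  })

  .stage("af", {
    counts_path <- file.path(fx_dir, "counts.tsv")
    if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
    counts <- read_counts_tsv(counts_path)
    res$af <- estimate_allele_fractions(counts, min_reads = config$min_reads,
                                        alpha = config$alpha,
                                        error_rate = config$error_rate)
    utils::write.table(res$af, file.path(out_dir, "af.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  .stage("cn", {
    af <- res$af
    usable <- af$dna_total >= config$min_reads & af$germline_total > 0
    sub <- af[usable, , drop = FALSE]
    segs <- read_segments_bed(file.path(fx_dir, "segments.bed"))
    snv_pos <- read_mutations_vcf(file.path(fx_dir, "mutations.vcf"))
    pos <- snv_pos[match(sub$snv_id, snv_pos$snv_id), c("chrom", "pos")]
    pooled <- pool_segment_ratios(sub$dna_total, sub$germline_total,
                                  snv_segment_index(pos, segs))
    ratio <- pooled$ratio
    rse <- pooled$ratio_se
    res$model <- fit_sample_model(sub$dna_mutant, sub$dna_total, ratio,
                                  ratio_se = rse, cn_max = config$cn_max,
                                  ratio_weight = config$ratio_weight)
    cn_tab <- cbind(snv_id = sub$snv_id, res$model$assignments)
    res$cn <- cn_tab
    utils::write.table(cn_tab, file.path(out_dir, "cn.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(rho = res$model$purity, psi = res$model$psi,
           c = res$model$coverage_scale, loglik = res$model$loglik,
           rho_identifiable = res$model$rho_identifiable),
      file.path(out_dir, "sample_model.json"), auto_unbox = TRUE, digits = NA)
  })

  .stage("annot", {
    snvs <- read_mutations_vcf(file.path(fx_dir, "mutations.vcf"))
    tx <- read_transcripts_tsv(file.path(fx_dir, "transcripts.tsv"))
    res$consequences <- classify_consequence(
      snvs, tx, file.path(fx_dir, "ref.fa"),
      nmd_50nt_rule = config$nmd_50nt_rule)
    utils::write.table(res$consequences,
                       file.path(out_dir, "consequences.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  .stage("imbalance", {
    res$records <- imbalance_table(res$af, cn_fit = res$cn,
                                   consequences = res$consequences)
    res$summary <- report(res$records, file.path(out_dir, "report"),
                          high_cutoff = config$high_cutoff,
                          low_cutoff = config$low_cutoff,
                          imbalance_cutoff = config$imbalance_cutoff)
  })

  .stage("manifest", {
    files <- sort(setdiff(
      list.files(out_dir, recursive = TRUE, full.names = FALSE),
      "manifest.json"))
    files <- files[!grepl("\\.png$", files)]  # rendered rasters are not hashed
    hashes <- tools::md5sum(file.path(out_dir, files))
    res$manifest <- list(
      package = "allelecho",
      version = as.character(utils::packageVersion("allelecho")),
      seed = config$sim$seed,
      files = as.list(stats::setNames(unname(hashes), files))
    )
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(res)
}
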