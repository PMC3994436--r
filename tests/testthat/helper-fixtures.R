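# Shared simulated fixtures, built once per test run and cached.
.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# Full pipeline-style fixture: simulated truth, counts and allele fractions.
fx_analysis <- function(name, cfg) {
  fx_get(name, function() {
    truth <- simulate_genome(cfg)
    counts <- simulate_counts(truth, cfg)
    af <- estimate_allele_fractions(counts)
    list(cfg = cfg, truth = truth, counts = counts, af = af)
  })
}

# Main fixture: 500 SNVs, depth 100, pure tumor, NMD on (default 0.8).
fx_main <- function() fx_analysis("main", sim_config(
  n_snvs = 500, dna_depth_mean = 100, rna_depth_mean = 100,
  seed = 20140422L))

# NMD-free fixture: same scale, nmd_efficiency = 0.
fx_nmd_free <- function() fx_analysis("nmd_free", sim_config(
  n_snvs = 500, dna_depth_mean = 100, rna_depth_mean = 100,
  nmd_efficiency = 0, seed = 20140422L))

# NMD contrast fixture: ~20 PTC-not-last and ~6 PTC-last among ~950 SNVs.
fx_nmd_contrast <- function() fx_analysis("nmd_contrast", sim_config(
  n_snvs = 950, dna_depth_mean = 100, rna_depth_mean = 100,
  nmd_efficiency = 0.8, frac_ptc_not_last = 20 / 950,
  frac_ptc_last = 6 / 950, seed = 20140422L))

# Segment-pooled copy-number fit of a fixture.
fx_fit <- function(fx) {
  af <- fx$af
  pooled <- pool_segment_ratios(af$dna_total, af$germline_total,
                                snv_segment_index(fx$truth$snvs,
                                                  fx$truth$segments))
  fit_sample_model(af$dna_mutant, af$dna_total, pooled$ratio,
                   ratio_se = pooled$ratio_se)
}

# Imbalance record table of a fixture, using true consequence labels from the
# generator (annotation correctness is tested separately in test-annot.R).
fx_records <- function(fx) {
  cons <- data.frame(snv_id = fx$truth$snvs$snv_id,
                     class = fx$truth$snvs$consequence)
  imbalance_table(fx$af, consequences = cons)
}
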