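test_that("true_dna_af follows the purity-adjusted lattice formula", {
  expect_equal(true_dna_af(1, 3), 1 / 3)
  expect_equal(true_dna_af(2, 3), 2 / 3)
  # m = CN is homozygous at purity 1, whatever the copy number
  expect_equal(true_dna_af(1:5, 1:5), rep(1, 5))
  # hand-evaluated with normal-cell dilution: 0.5 * 1 / (2*0.5 + 2*0.5)
  expect_equal(true_dna_af(1, 2, purity = 0.5), 0.25)
  expect_error(true_dna_af(1, 2, purity = 0), "purity")
  expect_error(true_dna_af(1, 2, purity = 1.2), "purity")
  expect_error(true_dna_af(3, 2), "m <= cn")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(segment_cn_weights = c(1, 1, 1, 1, 1)), "summing to 1")
  expect_error(sim_config(frac_silent = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(purity = 0), "purity")
  expect_error(sim_config(dna_depth_mean = 0), "positive")
  expect_error(sim_config(frac_silent = 0.6, frac_ptc_not_last = 0.5),
               "at most 1")
})

test_that("simulate_genome honours the configuration and is deterministic", {
  cfg <- sim_config(n_snvs = 80, n_segments = 8, seed = 42)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(t1, t2)

  expect_equal(nrow(t1$snvs), 80L)
  expect_true(all(t1$snvs$m >= 1 & t1$snvs$m <= t1$snvs$segment_cn))
  expect_true(all(t1$snvs$ref != t1$snvs$alt))
  # psi is the length-weighted mean segment copy number
  seg <- t1$segments
  expect_equal(t1$psi, sum((seg$end - seg$start) * seg$cn) /
                 sum(seg$end - seg$start))
  # segments per chromosome do not overlap
  by_chrom <- split(seg, seg$chrom)
  for (s in by_chrom) {
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})

test_that("an all-diploid genome restricts the lattice to 1/2 and 1", {
  cfg <- sim_config(n_snvs = 60, segment_cn_weights = c(0, 1, 0, 0, 0),
                    seed = 3)
  tr <- simulate_genome(cfg)
  expect_true(all(tr$snvs$segment_cn == 2))
  expect_true(all(tr$snvs$m %in% 1:2))
  expect_true(all(true_dna_af(tr$snvs$m, tr$snvs$segment_cn) %in% c(0.5, 1)))
})

test_that("a pure tumor puts every true allele fraction on the m/CN lattice", {
  tr <- fx_main()$truth
  lattice <- unique(af_lattice(5, 1)$af)
  afs <- true_dna_af(tr$snvs$m, tr$snvs$segment_cn)
  expect_true(all(vapply(afs, function(a) any(abs(a - lattice) < 1e-12),
                         logical(1))))
})

test_that("the requested number of SNVs is generated exactly", {
  cfg <- sim_config(n_snvs = 3023, n_segments = 40, seed = 9)
  tr <- simulate_genome(cfg)
  expect_equal(nrow(tr$snvs), 3023L)
})

test_that("simulated counts conserve reads and are deterministic", {
  fx <- fx_main()
  expect_true(all(fx$counts$mutant_reads <= fx$counts$total_reads))
  expect_true(all(fx$counts$total_reads >= 0))
  expect_identical(simulate_counts(fx$truth, fx$cfg), fx$counts)
  # germline has (at error rate 0) no mutant reads
  g <- fx$counts[fx$counts$sample == "germline", ]
  expect_true(all(g$mutant_reads == 0))
})

test_that("empirical DNA allele fractions converge to the lattice truth", {
  cfg <- sim_config(n_snvs = 200, dna_depth_mean = 1e4, seed = 5)
  tr <- simulate_genome(cfg)
  ct <- simulate_counts(tr, cfg)
  td <- ct[ct$sample == "tumor" & ct$analyte == "DNA", ]
  k <- tapply(td$mutant_reads, td$snv_id, sum)[tr$snvs$snv_id]
  n <- tapply(td$total_reads, td$snv_id, sum)[tr$snvs$snv_id]
  p_true <- true_dna_af(tr$snvs$m, tr$snvs$segment_cn)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(k / n - p_true) <= 3 * se + 1e-12))
})

test_that("NMD scales the RNA mutant pool as (1-e)p / ((1-e)p + (1-p))", {
  # e = 0: expected RNA fraction equals the DNA fraction for every class
  cfg0 <- sim_config(n_snvs = 300, rna_depth_mean = 3000, rna_dispersion = 0.1,
                     nmd_efficiency = 0, frac_ptc_not_last = 0.3,
                     frac_ptc_last = 0.1, seed = 8)
  tr0 <- simulate_genome(cfg0)
  ct0 <- simulate_counts(tr0, cfg0)
  rn <- ct0[ct0$sample == "tumor" & ct0$analyte == "RNA", ]
  k <- tapply(rn$mutant_reads, rn$snv_id, sum)[tr0$snvs$snv_id]
  n <- tapply(rn$total_reads, rn$snv_id, sum)[tr0$snvs$snv_id]
  p <- true_dna_af(tr0$snvs$m, tr0$snvs$segment_cn)
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(k / n - p) <= 4 * se + 1e-12))

  # e = 1: a heterozygous PTC before the last exon leaves no mutant RNA
  cfg1 <- sim_config(n_snvs = 200, nmd_efficiency = 1,
                     frac_ptc_not_last = 0.5, frac_ptc_last = 0.2, seed = 8)
  tr1 <- simulate_genome(cfg1)
  ct1 <- simulate_counts(tr1, cfg1)
  rn1 <- ct1[ct1$sample == "tumor" & ct1$analyte == "RNA", ]
  k1 <- tapply(rn1$mutant_reads, rn1$snv_id, sum)[tr1$snvs$snv_id]
  not_last <- tr1$snvs$consequence == "PTC_not_last_exon"
  expect_true(all(k1[not_last] == 0))

  # PTC in the last exon is expressed at the DNA-predicted fraction even at
  # full NMD efficiency
  cfg2 <- sim_config(n_snvs = 300, rna_depth_mean = 3000, rna_dispersion = 0.1,
                     nmd_efficiency = 1, frac_ptc_last = 0.5,
                     frac_ptc_not_last = 0, seed = 8)
  tr2 <- simulate_genome(cfg2)
  ct2 <- simulate_counts(tr2, cfg2)
  rn2 <- ct2[ct2$sample == "tumor" & ct2$analyte == "RNA", ]
  last <- tr2$snvs$consequence == "PTC_last_exon"
  k2 <- tapply(rn2$mutant_reads, rn2$snv_id, sum)[tr2$snvs$snv_id][last]
  n2 <- tapply(rn2$total_reads, rn2$snv_id, sum)[tr2$snvs$snv_id][last]
  p2 <- true_dna_af(tr2$snvs$m, tr2$snvs$segment_cn)[last]
  se2 <- sqrt(p2 * (1 - p2) / n2)
  expect_true(all(abs(k2 / n2 - p2) <= 4 * se2 + 1e-12))
})

test_that("fixtures round-trip through the standard formats", {
  cfg <- sim_config(n_snvs = 40, n_segments = 6, seed = 77)
  tr <- simulate_genome(cfg)
  ct <- simulate_counts(tr, cfg)
  dir1 <- withr::local_tempdir()
  paths <- write_fixtures(tr, ct, dir1)

  expect_identical(read_counts_tsv(paths[["counts"]])$mutant_reads,
                   ct$mutant_reads)
  expect_identical(read_counts_tsv(paths[["counts"]])$total_reads,
                   ct$total_reads)

  seg <- read_segments_bed(paths[["bed"]])
  expect_equal(seg$start, tr$segments$start)
  expect_equal(seg$end, tr$segments$end)
  expect_equal(seg$cn, tr$segments$cn)

  vcf <- read_mutations_vcf(paths[["vcf"]])
  expect_equal(vcf$pos, tr$snvs$pos)      # reader restores 0-based
  expect_equal(vcf$ref, tr$snvs$ref)
  expect_equal(vcf$m, tr$snvs$m)
  raw_pos <- as.integer(sapply(strsplit(grep("^[^#]",
    readLines(paths[["vcf"]]), value = TRUE), "\t"), `[`, 2))
  expect_equal(raw_pos, tr$snvs$pos + 1L)  # VCF itself is 1-based

  tx <- read_transcripts_tsv(paths[["transcripts"]])
  expect_equal(tx$exon_start, tr$transcripts$exon_start)

  # byte-identical regeneration under the same config + seed
  dir2 <- withr::local_tempdir()
  write_fixtures(simulate_genome(cfg), simulate_counts(simulate_genome(cfg),
                                                       cfg), dir2)
  for (f in basename(paths))
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = paste("md5 of", f))
})

test_that("emitted VCF and BED parse with independent readers", {
  skip_if_not_installed("vcfR")
  skip_if_not_installed("rtracklayer")
  cfg <- sim_config(n_snvs = 25, n_segments = 4, seed = 13)
  tr <- simulate_genome(cfg)
  ct <- simulate_counts(tr, cfg)
  paths <- write_fixtures(tr, ct, withr::local_tempdir())

  v <- suppressWarnings(vcfR::read.vcfR(paths[["vcf"]], verbose = FALSE))
  expect_equal(as.integer(v@fix[, "POS"]), tr$snvs$pos + 1L)
  expect_equal(unname(v@fix[, "REF"]), tr$snvs$ref)
  expect_equal(unname(v@fix[, "ALT"]), tr$snvs$alt)

  gr <- rtracklayer::import(paths[["bed"]], format = "bed")
  expect_equal(GenomicRanges::start(gr) - 1L, tr$segments$start) # BED is 0-based
  expect_equal(GenomicRanges::end(gr), tr$segments$end)
})
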