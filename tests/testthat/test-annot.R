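# Build a single-transcript genome for annotation tests: the CDS occupies all
# exons, introns/pads are filler. Returns the genome, the exon table and a map
# from 1-based CDS position to 0-based genomic position.
make_test_tx <- function(cds, exon_len, strand = "+", intron = 8L, pad = 10L,
                         chrom = "chrT") {
  stopifnot(nchar(cds) == sum(exon_len))
  ends <- cumsum(exon_len)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ex_seq <- substring(cds, starts, ends)
  filler <- function(k) paste(rep("T", k), collapse = "")
  layout <- paste0(filler(pad),
                   paste(ex_seq, collapse = filler(intron)),
                   filler(pad))
  ex_off <- pad + (starts - 1L) + (seq_along(exon_len) - 1L) * intron
  cds2layout <- unlist(lapply(seq_along(exon_len),
                              function(i) ex_off[i] + 0:(exon_len[i] - 1L)))
  L <- nchar(layout)
  if (strand == "+") {
    genome_seq <- layout
    exon_start <- ex_off
    cds2gen <- cds2layout
  } else {
    genome_seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(layout)))
    exon_start <- L - (ex_off + exon_len)
    cds2gen <- L - 1L - cds2layout
  }
  tx <- data.frame(transcript_id = "txT", gene_id = "geneT", chrom = chrom,
                   strand = strand, exon_index = seq_along(exon_len),
                   exon_start = exon_start, exon_end = exon_start + exon_len,
                   cds_start = min(exon_start),
                   cds_end = max(exon_start + exon_len))
  genome <- stats::setNames(genome_seq, chrom)
  list(genome = genome, tx = tx, cds2gen = cds2gen, layout = layout)
}

# SNV record at a given CDS position (1-based), with transcript-strand alleles.
snv_at <- function(f, cds_pos, ref_tx, alt_tx) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  minus <- f$tx$strand[1] == "-"
  data.frame(snv_id = "s1", chrom = f$tx$chrom[1], pos = f$cds2gen[cds_pos],
             ref = if (minus) comp[[ref_tx]] else ref_tx,
             alt = if (minus) comp[[alt_tx]] else alt_tx,
             transcript_id = "txT")
}

test_that("silent, missense and stop-gained changes are classified", {
  f <- make_test_tx("ATGGAATGGTAA", exon_len = c(7L, 5L))
  # GAA -> GAG at the third codon position: synonymous (Glu)
  res <- classify_consequence(snv_at(f, 6L, "A", "G"), f$tx, f$genome)
  expect_equal(res$class, "silent")
  expect_equal(res$codon_ref, "GAA")
  expect_equal(res$codon_alt, "GAG")
  # GAA -> GTA: missense
  res2 <- classify_consequence(snv_at(f, 5L, "A", "T"), f$tx, f$genome)
  expect_equal(res2$class, "nonsynonymous")
  expect_equal(res2$aa_alt, "V")
})

test_that("PTC classes split on last-exon membership", {
  f <- make_test_tx("ATGTGGTGGTAA", exon_len = c(3L, 3L, 6L))
  # TGG -> TGA in exon 2 of 3
  res <- classify_consequence(snv_at(f, 6L, "G", "A"), f$tx, f$genome)
  expect_equal(res$class, "PTC_not_last_exon")
  expect_equal(res$exon_index, 2L)
  expect_equal(res$n_exons, 3L)
  # TGG -> TGA in exon 3 of 3
  res2 <- classify_consequence(snv_at(f, 9L, "G", "A"), f$tx, f$genome)
  expect_equal(res2$class, "PTC_last_exon")
  expect_equal(res2$exon_index, 3L)
})

test_that("codons spanning exon junctions are translated correctly", {
  # exon lengths 4/8: codon 2 (positions 4-6) spans the junction
  f <- make_test_tx("ATGTGGGAATAA", exon_len = c(4L, 8L))
  res <- classify_consequence(snv_at(f, 6L, "G", "A"), f$tx, f$genome)
  expect_equal(res$codon_ref, "TGG")
  expect_equal(res$class, "PTC_last_exon")  # 2-exon transcript, SNV in exon 2
  expect_equal(res$exon_index, 2L)
})

test_that("minus-strand transcripts mirror plus-strand classification", {
  cds <- "ATGTGGTGGTAA"
  for (case in list(list(pos = 6L, ref = "G", alt = "A"),
                    list(pos = 9L, ref = "G", alt = "A"),
                    list(pos = 5L, ref = "G", alt = "C"))) {
    fp <- make_test_tx(cds, exon_len = c(3L, 3L, 6L), strand = "+")
    fm <- make_test_tx(cds, exon_len = c(3L, 3L, 6L), strand = "-")
    rp <- classify_consequence(snv_at(fp, case$pos, case$ref, case$alt),
                               fp$tx, fp$genome)
    rm_ <- classify_consequence(snv_at(fm, case$pos, case$ref, case$alt),
                                fm$tx, fm$genome)
    expect_equal(rm_$class, rp$class)
    expect_equal(rm_$codon_ref, rp$codon_ref)
    expect_equal(rm_$codon_alt, rp$codon_alt)
    expect_equal(rm_$exon_index, rp$exon_index)
  }
})

test_that("intronic positions are noncoding; start/stop hits are flagged", {
  f <- make_test_tx("ATGTGGTGGTAA", exon_len = c(3L, 3L, 6L))
  intronic <- data.frame(snv_id = "s1", chrom = "chrT",
                         pos = f$cds2gen[3L] + 1L,  # first intron base
                         ref = "T", alt = "C", transcript_id = "txT")
  expect_equal(classify_consequence(intronic, f$tx, f$genome)$class,
               "noncoding")
  start_hit <- classify_consequence(snv_at(f, 2L, "T", "C"), f$tx, f$genome)
  expect_equal(start_hit$class, "nonsynonymous")
  expect_equal(start_hit$flag, "start_codon")
  stop_hit <- classify_consequence(snv_at(f, 12L, "A", "C"), f$tx, f$genome)
  expect_equal(stop_hit$class, "nonsynonymous")
  expect_equal(stop_hit$flag, "ref_stop")
})

test_that("annotation errors name the offending transcript", {
  f <- make_test_tx("ATGTGGTGGTAA", exon_len = c(3L, 3L, 6L))
  wrong_ref <- snv_at(f, 6L, "C", "A")
  expect_error(classify_consequence(wrong_ref, f$tx, f$genome),
               "reference base mismatch.*txT")
  bad_alt <- snv_at(f, 6L, "G", "G")
  expect_error(classify_consequence(bad_alt, f$tx, f$genome), "identical")
  non_acgt <- snv_at(f, 6L, "G", "N")
  expect_error(classify_consequence(non_acgt, f$tx, f$genome), "non-ACGT")
  # frame inconsistency: truncate the CDS to a non-multiple of 3
  f2 <- f
  f2$tx$cds_end <- f2$tx$cds_end - 1L
  expect_error(classify_consequence(snv_at(f, 6L, "G", "A"), f2$tx, f$genome),
               "txT.*not divisible by 3")
})

test_that("the optional 50-nt rule reclassifies junction-proximal PTCs", {
  # 2 exons of 90 + 60 nt; last junction at spliced position 90
  set.seed(1)
  internal <- c("TGG", "GAA", "GCA", "CTG")
  cds <- paste0("ATG", paste(sample(internal, 48, TRUE), collapse = ""), "TAA")
  f <- make_test_tx(cds, exon_len = c(90L, 60L))
  # place a TGG codon by hand: codon 15 starts at CDS position 43 (> 90 - 50)
  substr(cds, 43, 45) <- "TGG"
  f <- make_test_tx(cds, exon_len = c(90L, 60L))
  s <- snv_at(f, 45L, "G", "A")
  expect_equal(classify_consequence(s, f$tx, f$genome)$class,
               "PTC_not_last_exon")
  expect_equal(classify_consequence(s, f$tx, f$genome,
                                    nmd_50nt_rule = TRUE)$class,
               "PTC_last_exon")
  # a PTC well upstream of the boundary stays NMD-sensitive under the rule
  cds2 <- cds
  substr(cds2, 10, 12) <- "TGG"
  f2 <- make_test_tx(cds2, exon_len = c(90L, 60L))
  s2 <- snv_at(f2, 12L, "G", "A")
  expect_equal(classify_consequence(s2, f2$tx, f2$genome,
                                    nmd_50nt_rule = TRUE)$class,
               "PTC_not_last_exon")
})

test_that("annotation recovers the generator's consequence labels", {
  fx <- fx_main()
  tr <- fx$truth
  res <- classify_consequence(tr$snvs, tr$transcripts, tr$sequences)
  expect_identical(res$class[match(tr$snvs$snv_id, res$snv_id)],
                   tr$snvs$consequence)
})

test_that("strata partition conserves counts", {
  cls <- c(rep("nonsynonymous", 600), rep("silent", 300),
           rep("PTC_not_last_exon", 19), rep("PTC_last_exon", 6),
           rep("noncoding", 55))
  st <- strata(cls)
  tab <- table(st$ptc_stratum)
  expect_equal(sum(tab), length(cls))
  expect_equal(unname(tab[["no_PTC"]]), 955)
  expect_equal(unname(tab[["PTC_not_last_exon"]]), 19)
  expect_equal(unname(tab[["PTC_last_exon"]]), 6)
  expect_equal(sum(st$coding_stratum == "silent", na.rm = TRUE), 300)

  all_silent <- strata(rep("silent", 10))
  expect_equal(sum(all_silent$coding_stratum == "nonsynonymous",
                   na.rm = TRUE), 0)
})
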