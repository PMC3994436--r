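#' Simulation configuration
#'
#' Builds and validates the configuration for the tumor-genome and read-count
#' simulator. The simulator emulates a homogeneous tumor cell line sequenced
#' in replicate: a genome partitioned into segments of integer copy number
#' 1-5, heterozygous-to-homozygous somatic SNVs whose DNA allele fractions sit
#' on the discrete lattice m/CN (purity-adjusted), and replicate tumor DNA,
#' germline DNA and tumor RNA read counts drawn binomially at those fractions.
#' Transcripts carrying a premature termination codon (PTC) upstream of the
#' last exon are depleted by nonsense-mediated decay (NMD) before RNA
#' sampling.
#'
#' @param n_segments Number of copy-number segments.
#' @param segment_cn_weights Probability weights for copy numbers 1..5, summing
#'   to 1. The default puts most mass on CN 2-4, reflecting a hyperdiploid
#'   genome with substantial triploid, tetraploid and pentaploid regions.
#' @param n_snvs Number of somatic SNVs (one per simulated gene).
#' @param dna_depth_mean Mean exome read depth per replicate at a diploid
#'   germline locus (reads).
#' @param rna_depth_mean Mean RNA-seq depth per replicate for a gene of average
#'   expression (reads).
#' @param rna_dispersion Log-normal sdlog of per-gene relative expression.
#' @param n_replicates Sequencing replicates per sample/analyte.
#' @param purity Tumor cell fraction rho in (0, 1]. Cell lines are pure (1.0).
#' @param nmd_efficiency Fraction in \[0, 1\] of mutant PTC transcripts degraded
#'   by NMD when the PTC lies before the last exon.
#' @param frac_ptc_not_last,frac_ptc_last,frac_silent Expected fractions of
#'   SNVs that are PTC-causing in a non-last exon, PTC-causing in the last
#'   exon, and silent; the remainder are non-synonymous.
#' @param germline_error_rate Per-read sequencing error rate at the mutant base
#'   in germline reads (0 disables errors).
#' @param seed Integer seed; all simulator output is deterministic given the
#'   configuration including this seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_segments = 20,
                       segment_cn_weights = c(0.10, 0.30, 0.25, 0.25, 0.10),
                       n_snvs = 500,
                       dna_depth_mean = 100,
                       rna_depth_mean = 100,
                       rna_dispersion = 1,
                       n_replicates = 2,
                       purity = 1.0,
                       nmd_efficiency = 0.8,
                       frac_ptc_not_last = 0.02,
                       frac_ptc_last = 0.006,
                       frac_silent = 0.29,
                       germline_error_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_segments = as.integer(n_segments),
    segment_cn_weights = as.numeric(segment_cn_weights),
    n_snvs = as.integer(n_snvs),
    dna_depth_mean = dna_depth_mean,
    rna_depth_mean = rna_depth_mean,
    rna_dispersion = rna_dispersion,
    n_replicates = as.integer(n_replicates),
    purity = purity,
    nmd_efficiency = nmd_efficiency,
    frac_ptc_not_last = frac_ptc_not_last,
    frac_ptc_last = frac_ptc_last,
    frac_silent = frac_silent,
    germline_error_rate = germline_error_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_segments < 1L || cfg$n_snvs < 1L || cfg$n_replicates < 1L)
    stop("n_segments, n_snvs and n_replicates must be positive integers")
  w <- cfg$segment_cn_weights
  if (length(w) != 5L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("segment_cn_weights must be 5 non-negative weights (CN 1..5) summing to 1")
  if (cfg$dna_depth_mean <= 0 || cfg$rna_depth_mean <= 0)
    stop("sequencing depths must be positive")
  fr <- c(cfg$purity, cfg$nmd_efficiency, cfg$frac_ptc_not_last,
          cfg$frac_ptc_last, cfg$frac_silent, cfg$germline_error_rate)
  if (any(fr < 0) || any(fr > 1))
    stop("purity, nmd_efficiency, consequence fractions and error rate must lie in [0, 1]")
  if (cfg$purity <= 0) stop("purity must be in (0, 1]")
  if (cfg$frac_ptc_not_last + cfg$frac_ptc_last + cfg$frac_silent > 1)
    stop("consequence fractions must sum to at most 1")
  invisible(cfg)
}

# Gene locus layout (transcript orientation), in bases. Exon lengths are
# deliberately not multiples of 3 so that codons span exon junctions.
.locus_layout <- list(
  pad5 = 50L, exon_len = c(299L, 301L, 300L), intron_len = 100L, pad3 = 50L
)
.locus_span <- function() {
  with(.locus_layout, pad5 + sum(exon_len) + 2L * intron_len + pad3)
}

.stop_codons <- c("TAA", "TAG", "TGA")

# Random CDS of n_codons: ATG start, non-stop internal codons, TAA stop.
.random_cds_codons <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  internal <- setdiff(all_codons, .stop_codons)
  c("ATG", sample(internal, n_codons - 2L, replace = TRUE), "TAA")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
.comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Expected DNA mutation allele fraction on the copy-number lattice
#'
#' In a tumor of purity `rho`, a mutation present on `m` of `cn` allelic
#' copies is observed in DNA reads at the discrete fraction
#' `m * rho / (cn * rho + 2 * (1 - rho))`; contaminating normal cells
#' contribute two wild-type copies. At purity 1 this reduces to `m / cn`
#' (e.g. 1/3, 2/3 or 1 in triploid regions).
#'
#' @param m Mutant multiplicity (integer, `1 <= m <= cn`), vectorized.
#' @param cn Locus absolute copy number (integer >= 1), vectorized.
#' @param purity Tumor purity rho in (0, 1].
#' @return Expected mutant allele fraction(s).
#' @export
true_dna_af <- function(m, cn, purity = 1) {
  if (length(purity) != 1L || is.na(purity) || purity <= 0 || purity > 1)
    stop("purity must be a single value in (0, 1]")
  if (any(m < 1L) || any(cn < 1L) || any(m > cn))
    stop("multiplicity must satisfy 1 <= m <= cn")
  m * purity / (cn * purity + 2 * (1 - purity))
}

#' Simulate a tumor genome with copy-number segments and somatic SNVs
#'
#' Draws `n_segments` genomic segments with integer copy numbers sampled from
#' `segment_cn_weights`, places one gene (one transcript of three exons, CDS
#' spanning all exons) per SNV inside those segments, and assigns each SNV a
#' mutant multiplicity `m` drawn uniformly from `1..CN` plus a coding
#' consequence (silent, non-synonymous, PTC in a non-last exon, PTC in the
#' last exon) realized in the reference sequence so that downstream annotation
#' can recover it. Mean ploidy psi is the length-weighted mean segment copy
#' number.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with elements `segments` (data.frame:
#'   chrom, start, end, cn; 0-based half-open), `snvs` (data.frame: snv_id,
#'   chrom, pos, ref, alt, gene_id, transcript_id, segment_cn, m,
#'   consequence, expression), `transcripts` (exon table), `sequences`
#'   (named character vector of chromosome sequences), `psi` (mean ploidy)
#'   and `config`.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  span <- .locus_span()
  seg_of_snv <- sort(sample.int(config$n_segments, config$n_snvs, replace = TRUE))
  genes_per_seg <- tabulate(seg_of_snv, nbins = config$n_segments)
  seg_cn <- sample(1:5, config$n_segments, replace = TRUE,
                   prob = config$segment_cn_weights)

  # Lay segments end-to-end, four per chromosome.
  seg_len <- pmax(genes_per_seg, 1L) * span
  seg_chrom <- sprintf("chr%d", (seq_len(config$n_segments) - 1L) %/% 4L + 1L)
  seg_start <- integer(config$n_segments)
  for (ch in unique(seg_chrom)) {
    idx <- which(seg_chrom == ch)
    seg_start[idx] <- cumsum(c(0L, seg_len[idx][-length(idx)]))
  }
  segments <- data.frame(
    chrom = seg_chrom, start = seg_start, end = seg_start + seg_len,
    cn = seg_cn, stringsAsFactors = FALSE
  )
  psi <- sum(as.numeric(seg_len) * seg_cn) / sum(as.numeric(seg_len))

  n <- config$n_snvs
  cons_levels <- c("PTC_not_last_exon", "PTC_last_exon", "silent", "nonsynonymous")
  probs <- c(config$frac_ptc_not_last, config$frac_ptc_last, config$frac_silent,
             1 - config$frac_ptc_not_last - config$frac_ptc_last - config$frac_silent)
  consequence <- sample(cons_levels, n, replace = TRUE, prob = probs)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  expression <- stats::rlnorm(n, meanlog = -config$rna_dispersion^2 / 2,
                              sdlog = config$rna_dispersion)
  cn_of_snv <- seg_cn[seg_of_snv]
  m <- vapply(cn_of_snv, function(cn) sample.int(cn, 1L), integer(1))

  # Slot index of each gene inside its segment.
  slot <- stats::ave(seq_len(n), seg_of_snv, FUN = seq_along) - 1L

  ex_len <- .locus_layout$exon_len
  n_codons <- sum(ex_len) %/% 3L
  # Codon index ranges fully inside each exon (CDS positions, 1-based):
  # exon1 = 1..299, exon2 = 300..600, exon3 = 601..900.
  codon_pool <- list(
    exon1 = 5:99,    # codons wholly within exon 1
    exon2 = 102:199, # wholly within exon 2
    exon3 = 205:295  # wholly within exon 3 (before the stop)
  )

  snv_rows <- vector("list", n)
  tx_rows <- vector("list", n)
  chrom_parts <- list()

  for (i in seq_len(n)) {
    cons <- consequence[i]
    target <- switch(cons,
      silent            = list(codon = "GGA", pos = 3L, alt = "G"),  # GGA>GGG, Gly>Gly
      nonsynonymous     = list(codon = "GCA", pos = 2L, alt = "A"),  # GCA>GAA, Ala>Glu
      PTC_not_last_exon = list(codon = "TGG", pos = 3L, alt = "A"),  # TGG>TGA, Trp>stop
      PTC_last_exon     = list(codon = "TGG", pos = 3L, alt = "A")
    )
    codon_idx <- switch(cons,
      PTC_not_last_exon = sample(c(codon_pool$exon1, codon_pool$exon2), 1L),
      PTC_last_exon     = sample(codon_pool$exon3, 1L),
      sample(c(codon_pool$exon1, codon_pool$exon2, codon_pool$exon3), 1L)
    )

    codons <- .random_cds_codons(n_codons)
    codons[codon_idx] <- target$codon
    cds <- paste(codons, collapse = "")

    lay <- .locus_layout
    intr <- function() paste(sample(c("A", "C", "G", "T"), lay$intron_len,
                                    replace = TRUE), collapse = "")
    pad <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                             collapse = "")
    ex_seq <- substring(cds, c(1L, cumsum(ex_len)[-3] + 1L), cumsum(ex_len))
    layout_seq <- paste0(pad(lay$pad5), ex_seq[1], intr(), ex_seq[2], intr(),
                         ex_seq[3], pad(lay$pad3))

    # Transcript-orientation offsets of exons within the locus (0-based).
    ex_off <- lay$pad5 + c(0L, ex_len[1] + lay$intron_len,
                           ex_len[1] + ex_len[2] + 2L * lay$intron_len)
    cds_pos0 <- (codon_idx - 1L) * 3L + target$pos - 1L   # 0-based CDS offset
    exon_of <- findInterval(cds_pos0, c(0L, cumsum(ex_len)))
    within_exon <- cds_pos0 - c(0L, cumsum(ex_len))[exon_of]
    layout_off <- ex_off[exon_of] + within_exon

    seg <- seg_of_snv[i]
    locus_start <- segments$start[seg] + slot[i] * span
    chrom <- segments$chrom[seg]

    if (strand[i] == "+") {
      genome_locus <- layout_seq
      exon_start <- locus_start + ex_off
      exon_end <- exon_start + ex_len
      pos <- locus_start + layout_off
      ref <- substr(layout_seq, layout_off + 1L, layout_off + 1L)
      alt <- target$alt
    } else {
      genome_locus <- .revcomp(layout_seq)
      exon_start <- locus_start + span - (ex_off + ex_len)
      exon_end <- exon_start + ex_len
      pos <- locus_start + span - 1L - layout_off
      ref <- .comp_base(substr(layout_seq, layout_off + 1L, layout_off + 1L))
      alt <- .comp_base(target$alt)
    }
    cds_start <- min(exon_start)
    cds_end <- max(exon_end)

    gene_id <- sprintf("gene%05d", i)
    tx_id <- sprintf("tx%05d", i)
    snv_rows[[i]] <- data.frame(
      snv_id = sprintf("snv%05d", i), chrom = chrom, pos = pos,
      ref = ref, alt = alt, gene_id = gene_id, transcript_id = tx_id,
      segment_cn = cn_of_snv[i], m = m[i], consequence = cons,
      expression = expression[i], stringsAsFactors = FALSE
    )
    tx_rows[[i]] <- data.frame(
      transcript_id = tx_id, gene_id = gene_id, chrom = chrom,
      strand = strand[i], exon_index = 1:3,
      exon_start = exon_start, exon_end = exon_end,
      cds_start = cds_start, cds_end = cds_end, stringsAsFactors = FALSE
    )
    chrom_parts[[length(chrom_parts) + 1L]] <-
      list(chrom = chrom, start = locus_start, seq = genome_locus)
  }

  snvs <- do.call(rbind, snv_rows)
  transcripts <- do.call(rbind, tx_rows)

  # Assemble chromosome sequences; loci are contiguous within segments and
  # segments contiguous within chromosomes, so concatenation in order works.
  sequences <- character(0)
  for (ch in unique(segments$chrom)) {
    parts <- Filter(function(p) p$chrom == ch, chrom_parts)
    parts <- parts[order(vapply(parts, `[[`, numeric(1), "start"))]
    seqs <- vapply(parts, `[[`, character(1), "seq")
    chrom_len <- max(segments$end[segments$chrom == ch])
    assembled <- paste(seqs, collapse = "")
    if (nchar(assembled) < chrom_len)  # segments with no genes: pad with N? use random
      assembled <- paste0(assembled,
        paste(sample(c("A", "C", "G", "T"), chrom_len - nchar(assembled),
                     replace = TRUE), collapse = ""))
    sequences[ch] <- assembled
  }

  structure(list(segments = segments, snvs = snvs, transcripts = transcripts,
                 sequences = sequences, psi = psi, config = config),
            class = "sim_truth")
}

#' Simulate replicate read counts for a simulated tumor genome
#'
#' Draws, for every SNV, `n_replicates` germline DNA, tumor DNA and tumor RNA
#' read-count pairs (mutant reads, total reads). Depths are Poisson around the
#' configured means. The germline is diploid everywhere with mutant reads only
#' from the configured error rate. Tumor DNA depth at a locus of copy number
#' CN is scaled by `(rho*CN + 2*(1-rho)) / (rho*psi + 2*(1-rho))` relative to
#' the germline (library-size normalization: equal-size libraries spread over
#' genomes of different total content), so the expected tumor:germline
#' coverage ratio is proportional to copy number. Mutant tumor DNA reads are
#' binomial at the lattice fraction [true_dna_af()]. RNA depth is proportional
#' to the gene's expression level; the RNA mutant fraction equals the DNA
#' fraction except for PTC-in-non-last-exon SNVs, where NMD degrades the
#' mutant transcript pool: with DNA fraction p and efficiency e, the RNA
#' depth is scaled by `(1-e)*p + (1-p)` and the mutant fraction becomes
#' `(1-e)*p / ((1-e)*p + (1-p))`.
#'
#' @param truth A `sim_truth` from [simulate_genome()].
#' @param config The same [sim_config()] used to generate `truth` (defaults to
#'   the one stored in `truth`).
#' @return A data.frame with one row per SNV x sample x analyte x replicate:
#'   snv_id, sample (tumor/germline), analyte (DNA/RNA), replicate,
#'   mutant_reads, total_reads.
#' @export
simulate_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  validate_sim_config(config)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 1L)

  snvs <- truth$snvs
  n <- nrow(snvs)
  reps <- config$n_replicates
  rho <- config$purity
  e <- config$nmd_efficiency
  p_dna <- true_dna_af(snvs$m, snvs$segment_cn, rho)
  tumor_scale <- (rho * snvs$segment_cn + 2 * (1 - rho)) /
                 (rho * truth$psi + 2 * (1 - rho))

  nmd <- snvs$consequence == "PTC_not_last_exon"
  pool <- ifelse(nmd, (1 - e) * p_dna + (1 - p_dna), 1)
  p_rna <- ifelse(nmd, (1 - e) * p_dna / pool, p_dna)
  p_rna[nmd & pool == 0] <- 0  # e = 1 at a homozygous PTC: no transcript left

  draw <- function(mean_depth, p) {
    tot <- stats::rpois(n, mean_depth)
    mut <- stats::rbinom(n, tot, p)
    list(mut = mut, tot = tot)
  }

  out <- vector("list", 3L * reps)
  k <- 0L
  for (r in seq_len(reps)) {
    g <- draw(rep(config$dna_depth_mean, n), config$germline_error_rate)
    t_dna <- draw(config$dna_depth_mean * tumor_scale, p_dna)
    t_rna <- draw(config$rna_depth_mean * snvs$expression * pool, p_rna)
    out[[k <- k + 1L]] <- data.frame(snv_id = snvs$snv_id, sample = "germline",
      analyte = "DNA", replicate = r, mutant_reads = g$mut,
      total_reads = g$tot, stringsAsFactors = FALSE)
    out[[k <- k + 1L]] <- data.frame(snv_id = snvs$snv_id, sample = "tumor",
      analyte = "DNA", replicate = r, mutant_reads = t_dna$mut,
      total_reads = t_dna$tot, stringsAsFactors = FALSE)
    out[[k <- k + 1L]] <- data.frame(snv_id = snvs$snv_id, sample = "tumor",
      analyte = "RNA", replicate = r, mutant_reads = t_rna$mut,
      total_reads = t_rna$tot, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, out)
  counts <- counts[order(counts$snv_id, counts$sample, counts$analyte,
                         counts$replicate), , drop = FALSE]
  rownames(counts) <- NULL
  counts
}

#' Write simulator output as standard-format fixture files
#'
#' Emits `ref.fa` (chromosome FASTA), `mutations.vcf` (VCF 4.2, 1-based, with
#' INFO keys GENE/TX/CN/M/CSQ carrying the simulation truth), `segments.bed`
#' (BED3+1, 0-based half-open, 4th column the integer copy number),
#' `counts.tsv`, `transcripts.tsv` (exon table) and `truth.json`.
#'
#' @param truth A `sim_truth`.
#' @param counts Output of [simulate_counts()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_fixtures <- function(truth, counts, out_dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(out_dir, "ref.fa"),
    vcf = file.path(out_dir, "mutations.vcf"),
    bed = file.path(out_dir, "segments.bed"),
    counts = file.path(out_dir, "counts.tsv"),
    transcripts = file.path(out_dir, "transcripts.tsv"),
    truth = file.path(out_dir, "truth.json")
  )

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(truth$sequences), paths[["fasta"]])

  s <- truth$snvs
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=allelecho-sim",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene identifier\">",
    "##INFO=<ID=TX,Number=1,Type=String,Description=\"Transcript identifier\">",
    "##INFO=<ID=CN,Number=1,Type=Integer,Description=\"True segment copy number\">",
    "##INFO=<ID=M,Number=1,Type=Integer,Description=\"True mutant multiplicity\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"True coding consequence\">",
    sprintf("##contig=<ID=%s,length=%d>", names(truth$sequences),
            nchar(truth$sequences)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tGENE=%s;TX=%s;CN=%d;M=%d;CSQ=%s",
                  s$chrom, s$pos + 1L, s$snv_id, s$ref, s$alt,
                  s$gene_id, s$transcript_id, s$segment_cn, s$m, s$consequence)
  writeLines(c(header, body), paths[["vcf"]])

  seg <- truth$segments
  writeLines(sprintf("%s\t%d\t%d\t%d", seg$chrom, seg$start, seg$end, seg$cn),
             paths[["bed"]])

  utils::write.table(counts, paths[["counts"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$transcripts, paths[["transcripts"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  jsonlite::write_json(
    list(psi = truth$psi,
         config = unclass(truth$config),
         snvs = s[, c("snv_id", "chrom", "pos", "ref", "alt", "gene_id",
                      "transcript_id", "segment_cn", "m", "consequence",
                      "expression")]),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a counts.tsv fixture
#' @param path Path to a tab-separated counts table with columns snv_id,
#'   sample, analyte, replicate, mutant_reads, total_reads.
#' @return data.frame in the same layout as [simulate_counts()].
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snv_id", "sample", "analyte", "replicate", "mutant_reads",
            "total_reads")
  if (!all(need %in% names(df)))
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  if (any(df$mutant_reads > df$total_reads))
    stop("corrupt counts table: mutant_reads > total_reads")
  df
}

#' Read a segments BED3+1 file (4th column = integer copy number)
#' @param path Path to a BED file, 0-based half-open.
#' @return data.frame with chrom, start, end, cn.
#' @export
read_segments_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("segments BED must have 4 columns (chrom start end cn)")
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "cn")
  if (any(df$start >= df$end)) stop("BED intervals must satisfy start < end")
  df
}

#' Read a transcripts.tsv exon table
#' @param path Path to the tab-separated exon table written by
#'   [write_fixtures()].
#' @return data.frame with one row per exon.
#' @export
read_transcripts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "chrom", "strand", "exon_index", "exon_start",
            "exon_end", "cds_start", "cds_end")
  if (!all(need %in% names(df)))
    stop("transcript table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a mutations VCF written by [write_fixtures()]
#' @param path Path to the VCF (plain text).
#' @return data.frame with snv_id, chrom, pos (0-based), ref, alt and any
#'   GENE/TX/CN/M/CSQ INFO fields present.
#' @export
read_mutations_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }
  info <- vapply(f, `[[`, character(1), 8L)
  data.frame(
    snv_id = vapply(f, `[[`, character(1), 3L),
    chrom = vapply(f, `[[`, character(1), 1L),
    pos = as.integer(vapply(f, `[[`, character(1), 2L)) - 1L,
    ref = vapply(f, `[[`, character(1), 4L),
    alt = vapply(f, `[[`, character(1), 5L),
    gene_id = vapply(info, info_get, character(1), "GENE", USE.NAMES = FALSE),
    transcript_id = vapply(info, info_get, character(1), "TX", USE.NAMES = FALSE),
    segment_cn = as.integer(vapply(info, info_get, character(1), "CN",
                                   USE.NAMES = FALSE)),
    m = as.integer(vapply(info, info_get, character(1), "M", USE.NAMES = FALSE)),
    consequence = vapply(info, info_get, character(1), "CSQ", USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
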