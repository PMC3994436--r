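#' @importFrom Biostrings GENETIC_CODE
NULL

# Normalize a genome argument to a named character vector of chromosome
# sequences. Accepts a named character vector, a DNAStringSet, or a FASTA
# file path.
.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("genome must be a named character vector, a DNAStringSet, or a FASTA path")
}

# Spliced CDS of one transcript: genomic positions (0-based) of CDS bases in
# translation order, plus the CDS sequence in transcript orientation.
.transcript_cds <- function(exons, genome) {
  tx_id <- exons$transcript_id[1]
  strand <- exons$strand[1]
  chrom <- exons$chrom[1]
  if (!chrom %in% names(genome))
    stop("transcript ", tx_id, ": chromosome ", chrom, " absent from genome")
  chrom_seq <- genome[[chrom]]

  ord <- order(exons$exon_start)
  ex <- exons[ord, , drop = FALSE]
  if (any(ex$exon_end[-nrow(ex)] > ex$exon_start[-1]))
    stop("transcript ", tx_id, ": overlapping exons")
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]

  cds_lo <- ex$cds_start[1]; cds_hi <- ex$cds_end[1]
  pos_list <- vector("list", nrow(ex))
  exon_of <- integer(0)
  for (i in seq_len(nrow(ex))) {
    lo <- max(ex$exon_start[i], cds_lo)
    hi <- min(ex$exon_end[i], cds_hi)
    if (lo >= hi) { pos_list[[i]] <- integer(0); next }
    p <- lo:(hi - 1L)
    if (strand == "-") p <- rev(p)
    pos_list[[i]] <- p
    exon_of <- c(exon_of, rep(i, length(p)))
  }
  cds_pos <- unlist(pos_list)
  bases <- substring(chrom_seq, cds_pos + 1L, cds_pos + 1L)
  if (strand == "-")
    bases <- c(A = "T", C = "G", G = "C", T = "A")[bases]
  if (anyNA(bases) || !all(bases %in% c("A", "C", "G", "T")))
    stop("transcript ", tx_id, ": non-ACGT base in CDS")
  if (length(cds_pos) %% 3L != 0L)
    stop("transcript ", tx_id, ": CDS length ", length(cds_pos),
         " not divisible by 3")
  list(tx_id = tx_id, strand = strand, chrom = chrom,
       cds_pos = cds_pos, cds_seq = paste(bases, collapse = ""),
       exon_of = exon_of, n_exons = nrow(ex),
       span = c(min(exons$exon_start), max(exons$exon_end)))
}

#' Coding consequence of SNVs against transcript models
#'
#' Maps each SNV onto its transcript's spliced CDS (strand-aware: positions
#' and bases are reverse-complemented on the minus strand, and codons may
#' span exon junctions), translates the reference and mutant codons with the
#' standard genetic code, and classifies the change:
#' * `silent` — amino acid unchanged;
#' * `nonsynonymous` — amino acid changed (including, with a warning flag,
#'   SNVs hitting the reference start or stop codon);
#' * `PTC_not_last_exon` / `PTC_last_exon` — stop gained, split by whether
#'   the SNV's exon is the transcript's last exon. PTCs before the last exon
#'   are the canonical trigger of nonsense-mediated decay;
#' * `noncoding` — position inside the transcript span but outside the CDS.
#'
#' By default last-exon membership alone decides the PTC split. With
#' `nmd_50nt_rule = TRUE` a stop codon starting within 50 nt upstream of the
#' final exon-exon junction (in spliced CDS coordinates) is also classified
#' `PTC_last_exon`, the classic NMD-escape boundary.
#'
#' @param snvs data.frame with chrom, pos (0-based), ref, alt and
#'   transcript_id (plus snv_id if available).
#' @param transcripts Exon table (see [read_transcripts_tsv()]).
#' @param genome Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param nmd_50nt_rule Apply the 50-nt junction rule (default FALSE).
#' @return data.frame per SNV: snv_id, transcript_id, class, codon_ref,
#'   codon_alt, aa_ref, aa_alt, exon_index, n_exons, flag.
#' @export
classify_consequence <- function(snvs, transcripts, genome,
                                 nmd_50nt_rule = FALSE) {
  genome <- .as_genome(genome)
  need <- c("chrom", "pos", "ref", "alt", "transcript_id")
  stopifnot(all(need %in% names(snvs)))
  if (is.null(snvs$snv_id)) snvs$snv_id <- sprintf("snv%05d", seq_len(nrow(snvs)))

  models <- lapply(split(transcripts, transcripts$transcript_id),
                   .transcript_cds, genome = genome)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- lapply(seq_len(nrow(snvs)), function(i) {
    s <- snvs[i, ]
    out <- data.frame(snv_id = s$snv_id, transcript_id = s$transcript_id,
                      class = NA_character_, codon_ref = NA_character_,
                      codon_alt = NA_character_, aa_ref = NA_character_,
                      aa_alt = NA_character_, exon_index = NA_integer_,
                      n_exons = NA_integer_, flag = "",
                      stringsAsFactors = FALSE)
    mod <- models[[s$transcript_id]]
    if (is.null(mod)) stop("SNV ", s$snv_id, ": unknown transcript ",
                           s$transcript_id)
    out$n_exons <- mod$n_exons
    if (!(s$ref %in% names(comp)) || !(s$alt %in% names(comp)))
      stop("SNV ", s$snv_id, ": non-ACGT allele")
    if (s$ref == s$alt) stop("SNV ", s$snv_id, ": ref and alt are identical")

    idx <- match(s$pos, mod$cds_pos)
    if (is.na(idx)) {
      out$class <- "noncoding"
      if (s$pos < mod$span[1] || s$pos >= mod$span[2])
        out$flag <- "outside_transcript"
      return(out)
    }
    ref_tx <- if (mod$strand == "+") s$ref else comp[[s$ref]]
    alt_tx <- if (mod$strand == "+") s$alt else comp[[s$alt]]
    if (substr(mod$cds_seq, idx, idx) != ref_tx)
      stop("SNV ", s$snv_id, ": reference base mismatch in transcript ",
           mod$tx_id)

    ci <- (idx - 1L) %/% 3L            # 0-based codon index
    codon_ref <- substr(mod$cds_seq, 3L * ci + 1L, 3L * ci + 3L)
    codon_alt <- codon_ref
    substr(codon_alt, (idx - 1L) %% 3L + 1L, (idx - 1L) %% 3L + 1L) <- alt_tx
    aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
    aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
    out$codon_ref <- codon_ref; out$codon_alt <- codon_alt
    out$aa_ref <- aa_ref; out$aa_alt <- aa_alt
    out$exon_index <- mod$exon_of[idx]

    n_cds <- nchar(mod$cds_seq)
    if (ci == 0L) {                     # reference start codon hit
      out$class <- "nonsynonymous"; out$flag <- "start_codon"
    } else if (aa_ref == "*") {         # reference stop codon hit
      out$class <- "nonsynonymous"; out$flag <- "ref_stop"
    } else if (aa_alt == "*") {
      last_exon <- out$exon_index == mod$n_exons
      if (!last_exon && nmd_50nt_rule) {
        last_junction <- max(which(mod$exon_of < mod$n_exons))  # spliced pos
        last_exon <- (3L * ci + 1L) >= (last_junction - 50L)
      }
      out$class <- if (last_exon) "PTC_last_exon" else "PTC_not_last_exon"
    } else if (aa_ref == aa_alt) {
      out$class <- "silent"
    } else {
      out$class <- "nonsynonymous"
    }
    out
  })
  do.call(rbind, rows)
}

#' Stratify classified SNVs for the imbalance analysis
#'
#' Partitions SNVs into the three PTC groups used in the group comparisons —
#' `no_PTC`, `PTC_not_last_exon`, `PTC_last_exon` — and, orthogonally, labels
#' the silent versus non-synonymous subsets (PTC and noncoding SNVs get NA in
#' the coding stratum). The PTC strata are a full partition: their sizes sum
#' to the input size.
#'
#' @param class Character vector of consequence classes from
#'   [classify_consequence()].
#' @return data.frame with factors `ptc_stratum` and `coding_stratum`.
#' @export
strata <- function(class) {
  ptc <- ifelse(class == "PTC_not_last_exon", "PTC_not_last_exon",
         ifelse(class == "PTC_last_exon", "PTC_last_exon", "no_PTC"))
  coding <- ifelse(class == "silent", "silent",
            ifelse(class == "nonsynonymous", "nonsynonymous", NA_character_))
  data.frame(
    ptc_stratum = factor(ptc, levels = c("no_PTC", "PTC_not_last_exon",
                                         "PTC_last_exon")),
    coding_stratum = factor(coding, levels = c("silent", "nonsynonymous"))
  )
}
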