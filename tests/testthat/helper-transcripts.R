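# Deterministic transcript builders for consequence tests: a transcript is
# specified by its CDS sequence (transcript sense), the strand, and the CDS
# positions after which introns are inserted.

make_tx <- function(cds, strand = "+", cuts = integer(), intron_len = 80L,
                    flank = 30L, chrom = "chrT", gene = "TSTG") {
  stopifnot(nchar(cds) %% 3L == 0L)
  bounds <- c(0L, cuts, nchar(cds))
  chunks <- substring(cds, head(bounds, -1L) + 1L, bounds[-1L])
  intron_seq <- function(n) paste(rep(c("G", "T", "C", "A"), length.out = n),
                                  collapse = "")
  flank_seq <- paste(rep("A", flank), collapse = "")
  if (strand == "+") {
    ordered <- chunks
  } else {
    ordered <- rev(vapply(chunks, function(x)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
      character(1L)))
  }
  pieces <- character(0); starts <- integer(0); ends <- integer(0)
  posn <- flank
  for (i in seq_along(ordered)) {
    starts <- c(starts, posn + 1L)
    ends <- c(ends, posn + nchar(ordered[i]))
    posn <- posn + nchar(ordered[i])
    pieces <- c(pieces, ordered[i])
    if (i < length(ordered)) {
      pieces <- c(pieces, intron_seq(intron_len))
      posn <- posn + intron_len
    }
  }
  contig <- paste0(flank_seq, paste(pieces, collapse = ""), flank_seq)
  t <- transcript_model(gene = gene, transcript_id = paste0("TX_", gene),
                        strand = strand,
                        exons = data.frame(start = starts, end = ends),
                        cds_start = min(starts), cds_end = max(ends))
  attr(t, "chrom") <- chrom
  list(t = t, win = list(start = 1L, seq = contig, chrom = chrom), cds = cds)
}

# shift all genomic coordinates so a chosen CDS position lands on a chosen
# genomic coordinate (keeps the reference window aligned)
shift_tx <- function(txo, c_pos, g_target) {
  delta <- as.integer(g_target - cds_to_genomic(txo$t, c_pos))
  t <- txo$t
  t$exons$start <- t$exons$start + delta
  t$exons$end <- t$exons$end + delta
  t$cds_start <- t$cds_start + delta
  t$cds_end <- t$cds_end + delta
  txo$t <- t
  txo$win$start <- txo$win$start + delta
  txo
}

tx_base <- function(txo, gpos) substr(txo$win$seq, gpos - txo$win$start + 1L,
                                      gpos - txo$win$start + 1L)

comp1 <- function(b) chartr("ACGT", "TGCA", b)

# genomic SNV realising a transcript-sense substitution at CDS position c_pos
snv_from_c <- function(txo, c_pos, t_alt, chrom = txo$win$chrom) {
  g <- cds_to_genomic(txo$t, c_pos)
  g_ref <- tx_base(txo, g)
  g_alt <- if (txo$t$strand == "+") t_alt else comp1(t_alt)
  genomic_variant(chrom, g, g_ref, g_alt)
}

# genomic deletion of transcript-sense CDS positions a..b (VCF anchored)
del_from_c <- function(txo, a, b, chrom = txo$win$chrom) {
  gs <- sort(c(cds_to_genomic(txo$t, a), cds_to_genomic(txo$t, b)))
  pos <- gs[1L] - 1L
  ref <- substr(txo$win$seq, pos - txo$win$start + 1L,
                gs[2L] - txo$win$start + 1L)
  genomic_variant(chrom, pos, ref, substr(ref, 1L, 1L))
}

# insertion of genomic-sense bases right after genomic position of CDS c_pos
ins_after_c <- function(txo, c_pos, ins, chrom = txo$win$chrom) {
  g <- cds_to_genomic(txo$t, c_pos)
  anchor <- tx_base(txo, g)
  genomic_variant(chrom, g, anchor, paste0(anchor, ins))
}

# build a CDS of n_codons gly codons with specific transcript-sense bases
# planted at given CDS positions; start ATG, terminal TAA
planted_cds <- function(n_codons, plant = list()) {
  codons <- c("ATG", rep("GGA", n_codons - 2L), "TAA")
  cds <- paste(codons, collapse = "")
  for (p in plant) {   # p = list(at = cds position, bases = string)
    stopifnot(p$at + nchar(p$bases) - 1L <= nchar(cds))
    substr(cds, p$at, p$at + nchar(p$bases) - 1L) <- p$bases
  }
  # the plants must not create an internal stop codon
  for (k in 2:(n_codons - 1L)) {
    cd <- substr(cds, 3L * k - 2L, 3L * k)
    if (cd %in% c("TAA", "TAG", "TGA"))
      stop(sprintf("planted bases create internal stop at codon %d", k))
  }
  cds
}

# search the codon table for a reference codon translating to ref_aa (three
# letter) whose base at `offset` is ref_base, and which becomes a stop codon
# when that base is replaced by alt_base
find_stop_codon_plant <- function(ref_aa3, offset, ref_base, alt_base) {
  b <- c("A", "C", "G", "T")
  for (c1 in b) for (c2 in b) for (c3 in b) {
    codon <- paste0(c1, c2, c3)
    if (substr(codon, offset, offset) != ref_base) next
    aa <- unname(Biostrings::GENETIC_CODE[codon])
    if (aa == "*") next
    if (germtriage:::AA3[[aa]] != ref_aa3) next
    mut <- codon
    substr(mut, offset, offset) <- alt_base
    if (unname(Biostrings::GENETIC_CODE[mut]) == "*") return(codon)
  }
  stop("no codon satisfies the constraints")
}
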