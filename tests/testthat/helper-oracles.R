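# Independent oracles used by the tests. Each deliberately takes a
# different algorithmic route than the package implementation.

# --- variant normalization oracle -------------------------------------------
# Applies the variant to the whole window, then reads the minimal
# left-aligned representation off the global sequence diff: maximal common
# suffix first, then maximal common prefix, then a left anchor base for
# indels. The implementation instead shifts the allele pair iteratively.
oracle_normalize <- function(v, win) {
  W <- toupper(win$seq)
  i <- v$pos - win$start + 1L
  stopifnot(substr(W, i, i + nchar(v$ref) - 1L) == v$ref)
  M <- paste0(substr(W, 1L, i - 1L), v$alt,
              substr(W, i + nchar(v$ref), nchar(W)))
  # maximal common suffix
  s <- 0L
  while (s < min(nchar(W), nchar(M)) &&
         substr(W, nchar(W) - s, nchar(W) - s) ==
         substr(M, nchar(M) - s, nchar(M) - s)) s <- s + 1L
  Wc <- substr(W, 1L, nchar(W) - s); Mc <- substr(M, 1L, nchar(M) - s)
  # maximal common prefix of the remainder
  p <- 0L
  while (p < min(nchar(Wc), nchar(Mc)) &&
         substr(Wc, p + 1L, p + 1L) == substr(Mc, p + 1L, p + 1L)) p <- p + 1L
  ref <- substr(Wc, p + 1L, nchar(Wc)); alt <- substr(Mc, p + 1L, nchar(Mc))
  pos <- win$start + p
  if (!nzchar(ref) || !nzchar(alt)) {   # indel: anchor on the previous base
    stopifnot(p >= 1L)
    pos <- pos - 1L
    anchor <- substr(W, p, p)
    ref <- paste0(anchor, ref); alt <- paste0(anchor, alt)
  }
  genomic_variant(v$chrom, pos, ref, alt)
}

# --- full-translation consequence oracle for SNVs ---------------------------
# Rebuilds the complete mutant CDS by splicing the mutated contig and
# translating it with Biostrings, then classifies by comparing the two
# protein sequences position by position.
oracle_snv_consequence <- function(v, t, refwin) {
  splice_cds <- function(seqchar) {
    ci <- coding_intervals(t)
    chunks <- substring(seqchar, ci$start - refwin$start + 1L,
                        ci$end - refwin$start + 1L)
    cds <- paste(chunks, collapse = "")
    if (t$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    cds
  }
  W <- toupper(refwin$seq)
  i <- v$pos - refwin$start + 1L
  M <- W
  substr(M, i, i) <- v$alt
  ref_cds <- splice_cds(W); alt_cds <- splice_cds(M)
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), if.fuzzy.codon = "error",
    no.init.codon = TRUE))
  pr <- tr(ref_cds); pa <- tr(alt_cds)
  if (pr == pa) return("synonymous")
  k <- which(strsplit(pr, "")[[1L]] != strsplit(pa, "")[[1L]])[1L]
  ref_aa <- substr(pr, k, k); alt_aa <- substr(pa, k, k)
  if (alt_aa == "*") return("stop_gained")
  if (ref_aa == "*") return("stop_lost")
  if (k == 1L && ref_aa == "M") return("start_lost")
  "missense"
}

# last coding exon membership computed straight from the exon table
oracle_in_last_coding_exon <- function(gpos, t) {
  ci <- coding_intervals(t)
  last <- if (t$strand == "+") nrow(ci) else 1L
  gpos >= ci$start[last] && gpos <= ci$end[last]
}

# --- exact-test oracles ------------------------------------------------------
# 2x2 Fisher p by direct factorial enumeration (choose(), no dhyper)
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  prob_of <- function(a) choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  probs <- vapply(lo:hi, prob_of, numeric(1))
  p_obs <- prob_of(m[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# 2x3 Freeman-Halton p by explicit double loop over the first row
oracle_fisher_2x3 <- function(m) {
  cs <- colSums(m); r1 <- sum(m[1, ]); n <- sum(m)
  denom <- lchoose(n, r1)
  lp_of <- function(a) sum(lchoose(cs, a)) - denom
  p_obs <- exp(lp_of(m[1, ]))
  tot <- 0
  for (a1 in 0:min(cs[1], r1))
    for (a2 in 0:min(cs[2], r1 - a1)) {
      a3 <- r1 - a1 - a2
      if (a3 < 0 || a3 > cs[3]) next
      p <- exp(lp_of(c(a1, a2, a3)))
      if (p <= p_obs * (1 + 1e-7)) tot <- tot + p
    }
  tot
}

# --- triage decision-table oracle -------------------------------------------
# Flat re-statement of the rule cascade as one lookup, coded independently
# of classify_variant().
oracle_classify <- function(kind, in_last_exon, clinvar, maf, esm1b, am,
                            splice_ref, splice_alt,
                            maf_thr = 0.005, esm_thr = -10, am_thr = 0.8) {
  if (!is.na(maf) && maf >= maf_thr) return("excluded_common")
  cv <- parse_clinvar_assertion(clinvar)
  if (cv == "PATHOGENIC") return("pathogenic")
  if (cv == "BENIGN") return("benign")
  if (kind %in% c("stop_gained", "frameshift"))
    return(if (isTRUE(in_last_exon)) "likely_benign" else "pathogenic")
  if (kind == "splice_region") {
    if (is.na(splice_ref) || is.na(splice_alt)) return("ambiguous")
    bad <- splice_alt < 0 ||
      (splice_ref > 0 && (splice_ref - splice_alt) / splice_ref >= 0.5) ||
      (splice_ref <= 0)
    return(if (bad) "likely_pathogenic" else "likely_benign")
  }
  if (kind %in% c("missense", "inframe_deletion", "inframe_insertion",
                  "stop_lost", "start_lost")) {
    e <- if (is.na(esm1b)) NA else esm1b <= esm_thr
    a <- if (is.na(am)) NA else am > am_thr
    votes <- c(e, a)[!is.na(c(e, a))]
    if (!length(votes)) return("ambiguous")
    if (all(votes)) return("likely_pathogenic")
    if (all(!votes)) return("likely_benign")
    return("ambiguous")
  }
  "likely_benign"
}

severity_rank <- function(k) match(k, CLASS_LEVELS)
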