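# Consequence projection: map a genomic variant onto its canonical
# transcript, derive the molecular consequence, and flag truncating events
# that fall in the final coding exon (which escape the auto-pathogenic rule).

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

.revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

.complement <- function(s) chartr("ACGT", "TGCA", s)

# single-codon translation against the standard genetic code
.translate_codon <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (is.na(aa)) stop(sprintf("cannot translate codon '%s'", codon))
  aa
}

.window_base <- function(refwin, gpos, len = 1L) {
  i <- gpos - as.integer(refwin$start) + 1L
  if (i < 1L || i + len - 1L > nchar(refwin$seq))
    stop("reference window does not cover the requested position")
  substr(toupper(refwin$seq), i, i + len - 1L)
}

# splice placement for one genomic position: donor window = intronic +1..+6
# downstream of an exon in transcription direction, acceptor = intronic
# -1..-2 upstream of the next exon. Exonic splice-region bases keep their
# coding consequence instead.
.splice_placement <- function(maps, gpos) {
  ex <- maps$exons_tx
  n <- nrow(ex)
  if (n < 2L) return(NULL)
  for (i in seq_len(n - 1L)) {
    if (maps$strand == "+") {
      donor_anchor <- ex$end[i]        # intron is [end_i + 1, start_{i+1} - 1]
      acceptor_anchor <- ex$start[i + 1L]
      d_off <- gpos - donor_anchor     # +1..+6 = donor window
      a_off <- gpos - acceptor_anchor  # -1..-2 = acceptor window
    } else {
      donor_anchor <- ex$start[i]      # transcription runs high -> low
      acceptor_anchor <- ex$end[i + 1L]
      d_off <- donor_anchor - gpos
      a_off <- acceptor_anchor - gpos
    }
    if (d_off >= 1L && d_off <= 6L)
      return(list(site = "donor", offset = d_off, intron = i))
    if (a_off <= -1L && a_off >= -2L)
      return(list(site = "acceptor", offset = a_off, intron = i))
  }
  NULL
}

#' Project a genomic variant onto cDNA coordinates
#'
#' Maps the (first affected) genomic position of a variant onto its
#' transcript: coding positions receive a 1-based CDS coordinate and codon
#' context (with alleles read in transcript orientation for minus-strand
#' genes); positions within the donor window (intronic +1..+6) or acceptor
#' window (intronic -1..-2) are reported as splice placements with their
#' offset; other positions are intronic or non-coding exonic.
#'
#' @param v A [genomic_variant()].
#' @param t A [transcript_model()].
#' @return A list of class \code{cds_projection} with fields \code{region}
#'   (\code{"cds"}, \code{"splice"}, \code{"noncoding_exon"} or
#'   \code{"intronic"}), and for coding positions \code{cds_pos},
#'   \code{codon_index}, \code{codon_offset}, \code{coding_exon}; for splice
#'   placements \code{site} and \code{offset}.
#' @export
project_to_cds <- function(v, t) {
  stopifnot(inherits(v, "genomic_variant"), inherits(t, "transcript_model"))
  span <- range(c(t$exons$start, t$exons$end))
  gpos <- .first_affected_gpos(v)
  if (v$pos < span[1L] - 6L || v$pos > span[2L] + 6L)
    stop(sprintf("variant %s:%d outside transcript span of %s",
                 v$chrom, v$pos, t$transcript_id))
  maps <- .tx_maps(t)
  hit <- .genomic_to_cds(maps, gpos)
  if (!is.null(hit)) {
    cp <- hit$cds_pos
    return(structure(list(region = "cds", cds_pos = cp,
                          codon_index = (cp - 1L) %/% 3L + 1L,
                          codon_offset = (cp - 1L) %% 3L + 1L,
                          coding_exon = hit$coding_exon,
                          n_coding_exons = maps$n_coding),
                     class = "cds_projection"))
  }
  sp <- .splice_placement(maps, gpos)
  if (!is.null(sp))
    return(structure(list(region = "splice", site = sp$site,
                          offset = sp$offset, intron = sp$intron),
                     class = "cds_projection"))
  in_exon <- any(gpos >= t$exons$start & gpos <= t$exons$end)
  structure(list(region = if (in_exon) "noncoding_exon" else "intronic"),
            class = "cds_projection")
}

# first changed genomic base after trimming shared prefix between alleles;
# for pure insertions this is the base right of the insertion point
.first_affected_gpos <- function(v) {
  p <- 0L
  nmin <- min(nchar(v$ref), nchar(v$alt))
  while (p < nmin &&
         substr(v$ref, p + 1L, p + 1L) == substr(v$alt, p + 1L, p + 1L))
    p <- p + 1L
  v$pos + p  # for pure insertions this lands on the base after the anchor
}

.trim_alleles <- function(ref, alt) {
  p <- 0L
  while (p < min(nchar(ref), nchar(alt)) &&
         substr(ref, p + 1L, p + 1L) == substr(alt, p + 1L, p + 1L))
    p <- p + 1L
  r <- substr(ref, p + 1L, nchar(ref))
  a <- substr(alt, p + 1L, nchar(alt))
  s <- 0L
  while (s < min(nchar(r), nchar(a)) &&
         substr(r, nchar(r) - s, nchar(r) - s) == substr(a, nchar(a) - s, nchar(a) - s))
    s <- s + 1L
  list(prefix = p,
       ref_core = substr(r, 1L, nchar(r) - s),
       alt_core = substr(a, 1L, nchar(a) - s))
}

.codon_at <- function(t, maps, refwin, codon_index) {
  bases <- character(3L)
  for (j in 1:3) {
    cp <- (codon_index - 1L) * 3L + j
    gp <- cds_to_genomic(t, cp)
    b <- .window_base(refwin, gp)
    bases[j] <- if (t$strand == "+") b else .complement(b)
  }
  paste(bases, collapse = "")
}

.consequence <- function(kind, in_last_exon = NA, protein_change = NA_character_,
                         cds_position = NA_integer_, splice_offset = NA_integer_) {
  structure(list(kind = kind, in_last_exon = in_last_exon,
                 protein_change = protein_change,
                 cds_position = cds_position, splice_offset = splice_offset),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  extra <- if (!is.na(x$protein_change)) paste0(" p.", x$protein_change) else ""
  le <- if (isTRUE(x$in_last_exon)) " [last exon]" else ""
  cat(sprintf("<consequence> %s%s%s\n", x$kind, extra, le))
  invisible(x)
}

#' Derive the molecular consequence of a variant on a transcript
#'
#' Rebuilds the affected codon(s) from the local reference sequence (read in
#' transcript orientation for minus-strand genes) and derives the
#' consequence kind: \code{stop_gained}, \code{stop_lost}, \code{start_lost},
#' \code{missense} or \code{synonymous} for coding SNVs; \code{frameshift}
#' when an indel's net length change is not a multiple of 3, else
#' \code{inframe_deletion}/\code{inframe_insertion}; \code{splice_region}
#' for variants in the donor/acceptor intronic windows; \code{intronic}
#' otherwise. For truncating kinds (\code{stop_gained}, \code{frameshift})
#' the \code{in_last_exon} flag is \code{TRUE} iff the first affected codon
#' lies within the final coding exon; such variants often escape
#' nonsense-mediated decay and are exempted from the auto-pathogenic
#' truncation rule downstream.
#'
#' @param v A [genomic_variant()].
#' @param t A [transcript_model()].
#' @param reference Reference window (list with \code{start}, \code{seq})
#'   covering the transcript locus on the plus strand.
#' @return An object of class \code{consequence} with fields \code{kind},
#'   \code{in_last_exon}, \code{protein_change}, \code{cds_position},
#'   \code{splice_offset}.
#' @export
call_consequence <- function(v, t, reference) {
  stopifnot(inherits(v, "genomic_variant"), inherits(t, "transcript_model"))
  obs <- .window_base(reference, v$pos, nchar(v$ref))
  if (obs != v$ref)
    stop(sprintf("integrity error: reference at %s:%d is %s, variant ref is %s",
                 v$chrom, v$pos, obs, v$ref))
  maps <- .tx_maps(t)
  pr <- project_to_cds(v, t)
  if (pr$region == "splice")
    return(.consequence("splice_region", splice_offset = pr$offset))
  if (pr$region %in% c("intronic", "noncoding_exon"))
    return(.consequence("intronic"))

  if (v$variant_class == "SNV") {
    ref_codon <- .codon_at(t, maps, reference, pr$codon_index)
    alt_base <- if (t$strand == "+") v$alt else .complement(v$alt)
    alt_codon <- ref_codon
    substr(alt_codon, pr$codon_offset, pr$codon_offset) <- alt_base
    ref_aa <- .translate_codon(ref_codon)
    alt_aa <- .translate_codon(alt_codon)
    pchange <- paste0(AA3[[ref_aa]], pr$codon_index, AA3[[alt_aa]])
    if (ref_aa == alt_aa)
      return(.consequence("synonymous", protein_change = pchange,
                          cds_position = pr$cds_pos))
    if (alt_aa == "*")
      return(.consequence("stop_gained",
                          in_last_exon = pr$coding_exon == pr$n_coding_exons,
                          protein_change = pchange,
                          cds_position = pr$cds_pos))
    if (ref_aa == "*")
      return(.consequence("stop_lost", protein_change = pchange,
                          cds_position = pr$cds_pos))
    if (pr$codon_index == 1L && ref_codon == "ATG")
      return(.consequence("start_lost", protein_change = pchange,
                          cds_position = pr$cds_pos))
    return(.consequence("missense", protein_change = pchange,
                        cds_position = pr$cds_pos))
  }

  # indel / delins: frame determination by net length change
  tr <- .trim_alleles(v$ref, v$alt)
  net <- nchar(tr$alt_core) - nchar(tr$ref_core)
  first_g <- v$pos + tr$prefix
  # first transcribed affected base: for deletions/delins the changed ref
  # interval, read in transcription direction; insertions affect downstream
  changed <- if (nchar(tr$ref_core) > 0L)
    c(first_g, first_g + nchar(tr$ref_core) - 1L) else c(first_g, first_g)
  gpos_first <- if (t$strand == "+") changed[1L] else changed[2L]
  hit <- .genomic_to_cds(maps, gpos_first)
  if (is.null(hit)) {
    # first affected base outside CDS: fall back to splice/intron placement
    sp <- .splice_placement(maps, gpos_first)
    if (!is.null(sp))
      return(.consequence("splice_region", splice_offset = sp$offset))
    return(.consequence("intronic"))
  }
  codon_index <- (hit$cds_pos - 1L) %/% 3L + 1L
  ref_codon <- .codon_at(t, maps, reference, codon_index)
  ref_aa3 <- AA3[[.translate_codon(ref_codon)]]
  last <- hit$coding_exon == maps$n_coding
  if (net %% 3L != 0L) {
    return(.consequence("frameshift", in_last_exon = last,
                        protein_change = paste0(ref_aa3, codon_index, "fs"),
                        cds_position = hit$cds_pos))
  }
  if (net < 0L)
    return(.consequence("inframe_deletion",
                        protein_change = paste0(ref_aa3, codon_index, "del"),
                        cds_position = hit$cds_pos))
  if (net > 0L)
    return(.consequence("inframe_insertion",
                        protein_change = paste0(ref_aa3, codon_index, "ins"),
                        cds_position = hit$cds_pos))
  # balanced multi-base substitution: report as missense at the first codon
  .consequence("missense",
               protein_change = paste0(ref_aa3, codon_index, "delins"),
               cds_position = hit$cds_pos)
}
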