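#' Construct a transcript model
#'
#' A stranded exon/CDS structure for one canonical transcript per gene, used
#' to project genomic variants onto cDNA coordinates. All intervals are
#' 1-based inclusive genomic coordinates; for minus-strand transcripts the
#' exon list is still stored in ascending genomic order and transcription
#' order is derived from the strand.
#'
#' @param gene Gene symbol.
#' @param transcript_id Accession-like label (e.g. an NM identifier).
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons Data.frame with columns \code{start}, \code{end}:
#'   non-overlapping exon intervals sorted by genomic position.
#' @param cds_start,cds_end Genomic bounds of the coding region (both inside
#'   exons; total coding length must be divisible by 3).
#' @return An object of class \code{transcript_model}.
#' @export
transcript_model <- function(gene, transcript_id, strand, exons,
                             cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"))
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (is.unsorted(exons$start, strictly = TRUE))
    stop("exons must be sorted by genomic position")
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_end < cds_start) stop("cds_end before cds_start")
  in_exon <- function(p) any(p >= exons$start & p <= exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end))
    stop("cds bounds must fall inside exons")
  t <- structure(
    list(gene = gene, transcript_id = transcript_id, strand = strand,
         exons = exons, cds_start = cds_start, cds_end = cds_end),
    class = "transcript_model")
  if (cds_length(t) %% 3L != 0L)
    stop(sprintf("total CDS length (%d) must be divisible by 3", cds_length(t)))
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s, strand %s): %d exon(s), CDS %d..%d (%d bp)\n",
              x$gene, x$transcript_id, x$strand, nrow(x$exons),
              x$cds_start, x$cds_end, cds_length(x)))
  invisible(x)
}

#' Coding intervals of a transcript
#'
#' Exon intervals intersected with the CDS bounds, in ascending genomic
#' order.
#'
#' @param t A [transcript_model()].
#' @return Data.frame with columns \code{start}, \code{end}.
#' @export
coding_intervals <- function(t) {
  s <- pmax(t$exons$start, t$cds_start)
  e <- pmin(t$exons$end, t$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

#' Total coding length of a transcript in bases
#' @param t A [transcript_model()].
#' @return Integer length.
#' @export
cds_length <- function(t) {
  ci <- coding_intervals(t)
  sum(ci$end - ci$start + 1L)
}

# Precomputed projection maps: coding intervals in transcription order with
# cumulative cDNA offsets, plus intron bookkeeping for splice windows.
.tx_maps <- function(t) {
  ci <- coding_intervals(t)
  n <- nrow(ci)
  ord <- if (t$strand == "+") seq_len(n) else rev(seq_len(n))
  ci <- ci[ord, , drop = FALSE]
  w <- ci$end - ci$start + 1L
  ci$cds_offset <- cumsum(c(0L, w[-n]))  # cDNA bases before each interval
  ex <- t$exons
  ex <- ex[if (t$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex))), ,
           drop = FALSE]
  list(coding = ci, exons_tx = ex, strand = t$strand, n_coding = n,
       cds_len = sum(w))
}

.genomic_to_cds <- function(maps, gpos) {
  ci <- maps$coding
  for (i in seq_len(nrow(ci))) {
    if (gpos >= ci$start[i] && gpos <= ci$end[i]) {
      off <- if (maps$strand == "+") gpos - ci$start[i] else ci$end[i] - gpos
      return(list(cds_pos = ci$cds_offset[i] + off + 1L, coding_exon = i))
    }
  }
  NULL
}

#' Map a cDNA (CDS) coordinate back to its genomic position
#'
#' @param t A [transcript_model()].
#' @param cds_pos 1-based coding position.
#' @return Integer genomic position.
#' @export
cds_to_genomic <- function(t, cds_pos) {
  maps <- .tx_maps(t)
  ci <- maps$coding
  cds_pos <- as.integer(cds_pos)
  if (cds_pos < 1L || cds_pos > maps$cds_len)
    stop("cds position outside the coding region")
  i <- max(which(ci$cds_offset < cds_pos))
  off <- cds_pos - ci$cds_offset[i] - 1L
  if (maps$strand == "+") ci$start[i] + off else ci$end[i] - off
}
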