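#' germtriage: germline panel variant triage and carrier-burden analysis
#'
#' Tiered pathogenicity triage of rare germline variants from a targeted
#' DNA-repair gene panel (12 homology-directed repair genes and 5
#' mismatch-repair-related genes), patient-level carrier aggregation, and
#' exact association statistics across histology, HPV type and external
#' control cohorts. A seeded synthetic-cohort simulator with planted effect
#' sizes makes every pipeline stage testable without access to patient data.
#'
#' @section Pipeline stages:
#' \itemize{
#'   \item variant model and file readers: [read_vcf()], [read_annotation_table()],
#'     [read_transcripts()], [read_phenotypes()], [read_control_summary()],
#'     [normalize_variant()]
#'   \item transcript consequence projection: [project_to_cds()], [call_consequence()]
#'   \item rule-based triage: [triage_config()], [classify_variant()], [classify_cohort()]
#'   \item association statistics: [aggregate_carriers()], [fisher_exact_2x2()],
#'     [fisher_exact_2xk()], [odds_ratio()], [median_test()], [group_mean_ci()]
#'   \item synthetic cohorts: [simulation_config()], [simulate_cohort()]
#'   \item orchestration: [run_simulate()], [run_classify()], [run_associate()]
#' }
#'
#' @keywords internal
#' @aliases germtriage-package
#' @importFrom stats dhyper qnorm median chisq.test sd qt plogis rbinom
#'   rnorm runif uniroot setNames rhyper
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom tools md5sum
#' @importFrom jsonlite write_json
#' @importFrom vcfR read.vcfR extract.gt getFIX
#' @importFrom Biostrings DNAStringSet writeXStringSet readDNAStringSet
#'   GENETIC_CODE
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a genomic variant
#'
#' A single allele substitution or small indel with 1-based coordinates on
#' the GRCh37 build (or on a synthetic contig). Alleles follow the VCF
#' convention: indels carry one anchor base, so a deletion of \code{A} after
#' position 100 is written \code{pos = 100, ref = "CA", alt = "C"}.
#'
#' @param chrom Chromosome or contig label.
#' @param pos 1-based position of the first reference base.
#' @param ref,alt Reference and alternate allele strings over \code{ACGT}.
#' @return An object of class \code{genomic_variant} with fields
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt} and a derived
#'   \code{variant_class} in \code{SNV}, \code{insertion}, \code{deletion},
#'   \code{delins}.
#' @examples
#' genomic_variant("17", 41245583, "G", "T")
#' @export
genomic_variant <- function(chrom, pos, ref, alt) {
  stopifnot(length(chrom) == 1L, length(pos) == 1L, length(ref) == 1L,
            length(alt) == 1L)
  pos <- as.integer(pos)
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (is.na(pos) || pos < 1L) stop("variant position must be >= 1")
  if (!nzchar(ref) || !nzchar(alt)) stop("ref and alt must be non-empty")
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stop("alleles must be strings over {A,C,G,T}")
  if (ref == alt) stop("ref and alt must differ")
  v <- structure(
    list(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
         variant_class = variant_class(ref, alt)),
    class = "genomic_variant")
  v
}

#' @export
print.genomic_variant <- function(x, ...) {
  cat(sprintf("<genomic_variant> %s:%d %s>%s (%s)\n",
              x$chrom, x$pos, x$ref, x$alt, x$variant_class))
  invisible(x)
}

#' Classify an allele pair as SNV, insertion, deletion or delins
#'
#' @param ref,alt Allele strings (vectorised).
#' @return Character vector with values in
#'   \code{c("SNV", "insertion", "deletion", "delins")}.
#' @export
variant_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  out <- ifelse(nr == 1L & na == 1L, "SNV",
         ifelse(nr <  na & substr(alt, 1L, nr) == ref, "insertion",
         ifelse(nr >  na & substr(ref, 1L, na) == alt, "deletion",
                "delins")))
  out
}

#' Join key for a variant
#'
#' Variants are joined across files by \code{chrom:pos:ref:alt} of the
#' normalized representation, because rsIDs are absent for novel variants.
#'
#' @param chrom,pos,ref,alt Variant fields (vectorised), or a
#'   \code{genomic_variant} as the single first argument.
#' @return Character key(s).
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (inherits(chrom, "genomic_variant")) {
    v <- chrom
    return(sprintf("%s:%d:%s:%s", v$chrom, v$pos, v$ref, v$alt))
  }
  sprintf("%s:%d:%s:%s", as.character(chrom), as.integer(pos),
          as.character(ref), as.character(alt))
}

#' Left-align and trim a variant to its minimal representation
#'
#' Standard indel normalization: shared suffix bases are trimmed, the variant
#' is shifted left through repeat context, and shared prefix bases beyond the
#' single VCF anchor are removed. The operation is idempotent and never moves
#' a variant to the right, so descriptions from different callers (or from
#' HGVS genomic notation) compare equal afterwards.
#'
#' @param v A [genomic_variant()].
#' @param reference_window A list with fields \code{start} (1-based genomic
#'   position of the first base of \code{seq}) and \code{seq} (local
#'   reference sequence covering the variant and enough left context to
#'   shift through).
#' @return The normalized \code{genomic_variant}.
#' @export
normalize_variant <- function(v, reference_window) {
  stopifnot(inherits(v, "genomic_variant"))
  win <- reference_window
  stopifnot(is.list(win), !is.null(win$start), !is.null(win$seq))
  wstart <- as.integer(win$start)
  wseq <- toupper(win$seq)
  ref_at <- function(pos, len) {
    i <- pos - wstart + 1L
    if (i < 1L || i + len - 1L > nchar(wseq))
      stop("reference_window does not cover the variant locus")
    substr(wseq, i, i + len - 1L)
  }
  if (ref_at(v$pos, nchar(v$ref)) != v$ref)
    stop(sprintf("reference mismatch at %s:%d: expected %s, window has %s",
                 v$chrom, v$pos, v$ref, ref_at(v$pos, nchar(v$ref))))

  pos <- v$pos; ref <- v$ref; alt <- v$alt
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    # trim common suffix base unless it would empty both alleles
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        !(nr == 1L && na == 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      # an emptied allele is re-anchored by extending left
      if (!nzchar(ref) || !nzchar(alt)) {
        if (pos - 1L < wstart)
          stop("reference_window has insufficient left context for left-alignment")
        b <- ref_at(pos - 1L, 1L)
        pos <- pos - 1L
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
      next
    }
    # strip common prefix beyond the anchor
    nr <- nchar(ref); na <- nchar(alt)
    if (nr >= 2L && na >= 2L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nr)
      alt <- substr(alt, 2L, na)
      pos <- pos + 1L
      next
    }
    break
  }
  genomic_variant(v$chrom, pos, ref, alt)
}

#' Fixed gene-to-pathway vocabulary of the panel
#'
#' The 12 homology-directed repair (HDR) genes and the 5 mismatch-repair
#' (-related) genes of the sequencing panel.
#'
#' @format Character vectors of gene symbols.
#' @export
HDR_GENES <- c("BARD1", "BRCA1", "BRCA2", "BRIP1", "ERCC4", "FANCM",
               "PALB2", "RAD51", "RAD51B", "RAD51C", "RAD51D", "SLX4")

#' @rdname HDR_GENES
#' @export
MMR_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2", "MUTYH")

#' Map a gene symbol to its repair pathway
#'
#' @param gene Character vector of gene symbols.
#' @return Factor-like character vector: \code{"HDR"}, \code{"MMR"} or
#'   \code{NA} for genes outside the panel vocabulary.
#' @export
gene_pathway <- function(gene) {
  out <- rep(NA_character_, length(gene))
  out[gene %in% HDR_GENES] <- "HDR"
  out[gene %in% MMR_GENES] <- "MMR"
  out
}
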