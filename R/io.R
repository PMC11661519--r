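# TSV dialects used across the pipeline. All tables are tab-separated with a
# header row; empty cells mean "absent". Numeric parse failures are reported
# with their row index so corrupt inputs fail loudly, never silently.

.read_tsv_checked <- function(path, required, numeric_cols = character(),
                              what = "table") {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("schema error in %s '%s': missing required column(s) %s",
                 what, path, paste(missing, collapse = ", ")))
  for (cn in numeric_cols) {
    raw <- df[[cn]]
    blank <- is.na(raw) | raw == ""
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(val))
    if (length(bad))
      stop(sprintf("value error in %s '%s': column '%s' unparseable at row %d (got '%s')",
                   what, path, cn, bad[1L], raw[bad[1L]]))
    val[blank] <- NA_real_
    df[[cn]] <- val
  }
  df
}

#' Read per-patient variant calls from a VCF file
#'
#' Parses a VCF v4.x file (via the \pkg{vcfR} reader) and emits one row per
#' patient-allele whose genotype contains the alternate allele. Multi-allelic
#' records are split by allele; homozygous-reference and missing genotypes
#' produce no rows. Coordinates stay 1-based as in the file.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param sample_map Optional named character vector mapping VCF sample names
#'   to patient identifiers. Names not present among the VCF samples raise a
#'   mapping error. Default: sample names are used as patient ids.
#' @return A data.frame with columns \code{patient_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{variant_class}, \code{key}.
#' @export
read_vcf <- function(path, sample_map = NULL) {
  if (!file.exists(path)) stop(sprintf("VCF file not found: %s", path))
  .validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  samples <- colnames(vcf@gt)[-1L]
  if (!is.null(sample_map)) {
    unknown <- setdiff(names(sample_map), samples)
    if (length(unknown))
      stop(sprintf("mapping error: sample(s) not in VCF: %s",
                   paste(unknown, collapse = ", ")))
  }
  out <- list(); k <- 0L
  if (n_rec > 0L && length(samples) > 0L) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_rec,
                                       dimnames = list(NULL, samples))
    for (i in seq_len(n_rec)) {
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
      for (s in samples) {
        g <- gt[i, s]
        if (is.na(g) || g == ".") next
        alleles <- strsplit(g, "[/|]")[[1L]]
        alleles <- suppressWarnings(as.integer(alleles))
        carried <- unique(alleles[!is.na(alleles) & alleles > 0L])
        for (a in carried) {
          if (a > length(alts))
            stop(sprintf("parse error in VCF record %d: genotype allele %d exceeds ALT count",
                         i, a))
          pid <- if (!is.null(sample_map) && s %in% names(sample_map))
            unname(sample_map[[s]]) else s
          k <- k + 1L
          out[[k]] <- data.frame(
            patient_id = pid, chrom = fix[i, "CHROM"],
            pos = as.integer(fix[i, "POS"]),
            ref = fix[i, "REF"], alt = alts[a],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- if (k) do.call(rbind, out) else
    data.frame(patient_id = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               stringsAsFactors = FALSE)
  df$variant_class <- variant_class(df$ref, df$alt)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  rownames(df) <- NULL
  df
}

# cheap structural pre-check so malformed files fail with a line number
.validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], "##fileformat=VCF"))
    stop(sprintf("parse error in '%s' at line 1: missing ##fileformat header", path))
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr))
    stop(sprintf("parse error in '%s': no #CHROM column header line", path))
  hdr <- hdr[1L]
  body <- lines[seq_along(lines) > hdr & nzchar(lines)]
  nf_hdr <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
  for (j in seq_along(body)) {
    nf <- length(strsplit(body[j], "\t", fixed = TRUE)[[1L]])
    if (nf < 8L || nf != nf_hdr)
      stop(sprintf("parse error in '%s' at line %d: expected %d tab-separated fields, found %d",
                   path, hdr + j, nf_hdr, nf))
  }
  invisible(TRUE)
}

#' Write a minimal multi-sample VCF v4.2 file
#'
#' Emits GT-only records for a variant table and a per-patient carriage
#' matrix; carried variants are written as heterozygous \code{0/1}.
#' Used by the synthetic-cohort generator so that its output can be read
#' back through [read_vcf()].
#'
#' @param variants Data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (one row per variant).
#' @param carriage Logical matrix, variants in rows, samples (patients) in
#'   columns; \code{TRUE} means the sample carries the alternate allele.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(variants, carriage, path) {
  stopifnot(nrow(variants) == nrow(carriage))
  samples <- colnames(carriage)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    gts <- ifelse(carriage[i, ], "0/1", "0/0")
    rows[i] <- paste(c(variants$chrom[i], variants$pos[i], ".",
                       variants$ref[i], variants$alt[i], ".", "PASS", ".",
                       "GT", gts), collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read the per-variant evidence (annotation) table
#'
#' @param path TSV with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{clinvar}, \code{maf}, \code{esm1b},
#'   \code{alphamissense}, \code{splice_ref}, \code{splice_alt}; empty
#'   numeric cells mean "score absent", an empty \code{clinvar} cell means
#'   "not listed".
#' @return Data.frame keyed by \code{key} (see [variant_key()]) with the
#'   evidence columns as numerics (NA = absent).
#' @export
read_annotation_table <- function(path) {
  df <- .read_tsv_checked(
    path,
    required = c("chrom", "pos", "ref", "alt", "clinvar", "maf", "esm1b",
                 "alphamissense", "splice_ref", "splice_alt"),
    numeric_cols = c("pos", "maf", "esm1b", "alphamissense", "splice_ref",
                     "splice_alt"),
    what = "annotation table")
  bad_maf <- which(!is.na(df$maf) & (df$maf < 0 | df$maf > 1))
  if (length(bad_maf))
    stop(sprintf("value error in annotation table: maf outside [0,1] at row %d",
                 bad_maf[1L]))
  bad_am <- which(!is.na(df$alphamissense) &
                  (df$alphamissense < 0 | df$alphamissense > 1))
  if (length(bad_am))
    stop(sprintf("value error in annotation table: alphamissense outside [0,1] at row %d",
                 bad_am[1L]))
  df$pos <- as.integer(df$pos)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' Read transcript models from a flat TSV
#'
#' One row per exon; transcript-level fields are repeated on every row.
#' Intervals are 1-based inclusive genomic coordinates.
#'
#' @param path TSV with columns \code{gene}, \code{transcript_id},
#'   \code{strand}, \code{exon_start}, \code{exon_end}, \code{cds_start},
#'   \code{cds_end}.
#' @return A named list of [transcript_model()] objects, keyed by gene.
#' @export
read_transcripts <- function(path) {
  df <- .read_tsv_checked(
    path,
    required = c("gene", "transcript_id", "strand", "exon_start", "exon_end",
                 "cds_start", "cds_end"),
    numeric_cols = c("exon_start", "exon_end", "cds_start", "cds_end"),
    what = "transcript table")
  out <- list()
  for (g in unique(df$gene)) {
    rows <- df[df$gene == g, , drop = FALSE]
    out[[g]] <- transcript_model(
      gene = g,
      transcript_id = rows$transcript_id[1L],
      strand = rows$strand[1L],
      exons = data.frame(start = as.integer(rows$exon_start),
                         end = as.integer(rows$exon_end)),
      cds_start = as.integer(rows$cds_start[1L]),
      cds_end = as.integer(rows$cds_end[1L]))
  }
  out
}

#' Write transcript models to the flat TSV dialect read by [read_transcripts()]
#'
#' @param transcripts Named list of [transcript_model()] objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  rows <- lapply(transcripts, function(t) {
    data.frame(gene = t$gene, transcript_id = t$transcript_id,
               strand = t$strand, exon_start = t$exons$start,
               exon_end = t$exons$end, cds_start = t$cds_start,
               cds_end = t$cds_end, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

HISTOLOGY_LEVELS <- c("squamous", "adenocarcinoma", "other")
HPV_LEVELS <- c("HPV16", "HPV18", "other_positive", "negative")
STAGE_LEVELS <- c("dysplasia", "invasive")

#' Read the patient phenotype table
#'
#' @param path TSV with columns \code{patient_id}, \code{age},
#'   \code{histology} (squamous/adenocarcinoma/other), \code{hpv}
#'   (HPV16/HPV18/other_positive/negative), \code{stage}
#'   (dysplasia/invasive).
#' @return Data.frame of patient records.
#' @export
read_phenotypes <- function(path) {
  df <- .read_tsv_checked(
    path,
    required = c("patient_id", "age", "histology", "hpv", "stage"),
    numeric_cols = "age", what = "phenotype table")
  bad_age <- which(!is.na(df$age) & df$age <= 0)
  if (length(bad_age))
    stop(sprintf("value error in phenotype table: non-positive age at row %d",
                 bad_age[1L]))
  for (col_lv in list(c("histology", "HISTOLOGY"), c("hpv", "HPV"),
                      c("stage", "STAGE"))) {
    col <- col_lv[1L]
    levels <- get(paste0(col_lv[2L], "_LEVELS"))
    bad <- which(!(df[[col]] %in% levels))
    if (length(bad))
      stop(sprintf("value error in phenotype table: unknown %s '%s' at row %d",
                   col, df[[col]][bad[1L]], bad[1L]))
  }
  if (anyDuplicated(df$patient_id))
    stop("value error in phenotype table: duplicated patient_id")
  df
}

#' Read a per-gene control carrier-count summary
#'
#' Emulates biobank-style summary statistics: for each gene, the number of
#' carriers of qualifying variants and the total number of genotyped
#' controls.
#'
#' @param path TSV with columns \code{gene}, \code{carriers}, \code{total}.
#' @return Data.frame with integer \code{carriers} and \code{total}.
#' @export
read_control_summary <- function(path) {
  df <- .read_tsv_checked(path, required = c("gene", "carriers", "total"),
                          numeric_cols = c("carriers", "total"),
                          what = "control summary")
  bad <- which(is.na(df$carriers) | is.na(df$total) | df$carriers < 0 |
               df$total <= 0 | df$carriers > df$total)
  if (length(bad))
    stop(sprintf("value error in control summary: invalid counts at row %d",
                 bad[1L]))
  df$carriers <- as.integer(df$carriers)
  df$total <- as.integer(df$total)
  df
}

#' Write / read the classified variant table
#'
#' The classified-output dialect extends the variant columns with
#' \code{gene}, \code{consequence}, \code{in_last_exon},
#' \code{classification}, \code{rule_trace} (rule ids joined by \code{>})
#' and \code{evidence_used} (joined by \code{,}). Writing then reading
#' reproduces the records exactly.
#'
#' @param records Data.frame as produced by [classify_cohort()]
#'   (\code{$classified}).
#' @param path Output TSV path.
#' @return \code{path} invisibly for the writer; a data.frame for the reader.
#' @export
write_classified_table <- function(records, path) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
           "in_last_exon", "classification", "rule_trace", "evidence_used")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop(sprintf("classified table missing column(s): %s",
                 paste(missing, collapse = ", ")))
  utils::write.table(records[, union(req, names(records))], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_classified_table
#' @export
read_classified_table <- function(path) {
  df <- .read_tsv_checked(
    path,
    required = c("chrom", "pos", "ref", "alt", "gene", "consequence",
                 "in_last_exon", "classification", "rule_trace",
                 "evidence_used"),
    numeric_cols = "pos", what = "classified table")
  df$pos <- as.integer(df$pos)
  df$in_last_exon <- ifelse(df$in_last_exon == "", NA, df$in_last_exon == "TRUE")
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}
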