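# Packaged rare-variant panel table: the published per-variant summary of
# the 728-patient cervical cancer cohort (gene, GRCh37 position, HGVS
# descriptions, rsID, patient count, molecular consequence, ClinVar
# assertion, and the concordance-category section label). The section label
# is bookkeeping for tests and for synthesising threshold-consistent
# prediction scores; the classifier itself never sees it.

#' Load the packaged rare-variant panel table
#'
#' @param path Path to the fixture TSV (default: the copy shipped with the
#'   package).
#' @return Data.frame with one row per reported variant: \code{block}
#'   (HDR/MMR), \code{section} (the table's concordance-category label),
#'   \code{gene}, \code{chrom}, \code{pos} (position as printed),
#'   \code{vcf_pos}, \code{ref}, \code{alt} (VCF-style join alleles; indel
#'   anchor bases are synthetic placeholders), HGVS descriptions,
#'   \code{rsid}, \code{n_patients}, \code{consequence} and \code{clinvar}.
#' @export
load_panel_variants <- function(path = system.file("extdata",
                                                   "panel_variants.tsv",
                                                   package = "germtriage")) {
  df <- .read_tsv_checked(
    path,
    required = c("block", "section", "gene", "chrom", "pos", "vcf_pos",
                 "ref", "alt", "hgvs_g", "hgvs_c", "hgvs_p", "rsid",
                 "n_patients", "consequence", "clinvar"),
    numeric_cols = c("pos", "vcf_pos", "n_patients"),
    what = "panel fixture")
  df$pos <- as.integer(df$pos)
  df$vcf_pos <- as.integer(df$vcf_pos)
  df$n_patients <- as.integer(df$n_patients)
  df$key <- variant_key(df$chrom, df$vcf_pos, df$ref, df$alt)
  df
}

.CONSEQUENCE_MAP <- c(
  "Stop gained" = "stop_gained",
  "Frameshift" = "frameshift",
  "Frameshift (last exon)" = "frameshift",
  "Missense" = "missense",
  "In frame deletion" = "inframe_deletion",
  "Donor splice-site variant" = "splice_region")

#' Build the classifier-ready variant table from the panel fixture
#'
#' Maps the printed molecular-consequence labels onto consequence kinds
#' (with the last-exon flag taken from the "(last exon)" annotation) and
#' synthesises in-silico scores consistent with each variant's published
#' concordance category: concordant-pathogenic rows receive an ESM1b score
#' below the -10 threshold and an AlphaMissense score above 0.8, discordant
#' rows a pathogenic ESM1b with a benign AlphaMissense, concordant-benign
#' rows benign scores on both (in-frame deletions get only an ESM1b score,
#' since AlphaMissense covers substitutions only), and the donor
#' splice-site variant its published MaxEntScan scores (10.57 reference,
#' 8.38 alternate). MAF is left unknown throughout: every tabulated variant
#' already passed the rarity filter.
#'
#' @param fixture Data.frame from [load_panel_variants()].
#' @return Data.frame accepted by [classify_cohort()].
#' @export
panel_variant_table <- function(fixture = load_panel_variants()) {
  kind <- unname(.CONSEQUENCE_MAP[fixture$consequence])
  if (anyNA(kind))
    stop(sprintf("unknown consequence label '%s'",
                 fixture$consequence[which(is.na(kind))[1L]]))
  df <- data.frame(
    chrom = fixture$chrom, pos = fixture$vcf_pos, ref = fixture$ref,
    alt = fixture$alt, gene = fixture$gene, consequence = kind,
    in_last_exon = grepl("last exon", fixture$consequence, fixed = TRUE),
    clinvar = fixture$clinvar, maf = NA_real_, esm1b = NA_real_,
    alphamissense = NA_real_, splice_ref = NA_real_, splice_alt = NA_real_,
    section = fixture$section, block = fixture$block,
    n_patients = fixture$n_patients, key = fixture$key,
    stringsAsFactors = FALSE)
  df$in_last_exon[!(kind %in% c("stop_gained", "frameshift"))] <- NA
  insilico <- kind %in% c("missense", "inframe_deletion")
  sec <- fixture$section
  path_rows <- insilico & sec == "Alpha missense/ESM1b pathogenic"
  amb_rows <- insilico & sec == "Alpha missense/ESM1b ambiguous"
  ben_rows <- insilico & sec == "Alpha missense/ESM1b benign"
  df$esm1b[path_rows] <- -15; df$alphamissense[path_rows] <- 0.95
  df$esm1b[amb_rows] <- -12; df$alphamissense[amb_rows] <- 0.30
  df$esm1b[ben_rows] <- -4; df$alphamissense[ben_rows] <- 0.15
  df$alphamissense[kind == "inframe_deletion"] <- NA_real_
  splice <- kind == "splice_region"
  df$splice_ref[splice] <- 10.57
  df$splice_alt[splice] <- 8.38
  df
}

#' Wire the panel fixture to a synthetic patient cohort
#'
#' Builds a cohort of \code{n_patients} patient records and assigns each
#' fixture variant to as many distinct patients as its published carrier
#' count; no patient receives more than one variant, matching the per-row
#' patient counts of the source table. Phenotypes are drawn from the
#' default cohort distributions; they carry no planted association.
#'
#' @param fixture Data.frame from [load_panel_variants()].
#' @param n_patients Cohort size (default 728).
#' @param seed Integer seed for phenotype draws and carrier placement.
#' @return List with \code{patients} (phenotype data.frame) and
#'   \code{carriage} (patient_id/key links).
#' @export
panel_cohort <- function(fixture = load_panel_variants(), n_patients = 728L,
                         seed = 1L) {
  total_assign <- sum(fixture$n_patients)
  if (total_assign > n_patients)
    stop("cohort smaller than the number of variant carriers to place")
  rs <- .seeded_rng(seed, "panel_cohort")
  patients <- .draw_phenotypes(n_patients, simulation_config(seed = seed), rs)
  slots <- sample(patients$patient_id, total_assign)
  carriage <- data.frame(
    patient_id = slots,
    key = rep(fixture$key, fixture$n_patients),
    stringsAsFactors = FALSE)
  list(patients = patients, carriage = carriage)
}
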