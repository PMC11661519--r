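# Tiered rule-based classification: rarity filter -> ClinVar precedence ->
# truncation rule (with last-exon exemption) -> splice-score rule ->
# ESM1b/AlphaMissense concordance rule. Every decision leaves an auditable
# rule trace.

#' Triage classes in increasing severity order
#' @export
CLASS_LEVELS <- c("excluded_common", "benign", "likely_benign", "ambiguous",
                  "likely_pathogenic", "pathogenic")

#' Compare a triage class against a severity floor
#'
#' @param klass Character vector of class labels.
#' @param floor Single class label; the minimum severity to count.
#' @return Logical vector: is \code{klass} at least as severe as
#'   \code{floor}? Severity order is
#'   excluded_common < benign < likely_benign < ambiguous <
#'   likely_pathogenic < pathogenic.
#' @export
class_at_least <- function(klass, floor) {
  match(klass, CLASS_LEVELS) >= match(floor, CLASS_LEVELS)
}

#' Evidence bundle for one variant
#'
#' Collects the external evidence the triage rules consume: the ClinVar
#' assertion string, the population minor allele frequency, the ESM1b score
#' (more negative = more damaging), the AlphaMissense score in [0,1], and
#' reference/alternate splice-model (MaxEntScan-style) scores. \code{NA}
#' means absent; an unknown MAF is treated as rare downstream because novel
#' variants have no population record.
#'
#' @param clinvar Assertion string (free text) or \code{"Not listed"}.
#' @param maf Minor allele frequency in [0,1] or \code{NA}.
#' @param esm1b ESM1b score or \code{NA}.
#' @param alphamissense AlphaMissense score in [0,1] or \code{NA}.
#' @param splice_ref,splice_alt Splice-model scores of the reference and
#'   alternate allele, or \code{NA}.
#' @return A list of class \code{evidence_bundle}.
#' @export
evidence_bundle <- function(clinvar = "Not listed", maf = NA_real_,
                            esm1b = NA_real_, alphamissense = NA_real_,
                            splice_ref = NA_real_, splice_alt = NA_real_) {
  if (!is.na(maf) && (maf < 0 || maf > 1)) stop("maf must lie in [0,1]")
  if (!is.na(alphamissense) && (alphamissense < 0 || alphamissense > 1))
    stop("alphamissense must lie in [0,1]")
  structure(list(clinvar = as.character(clinvar), maf = maf, esm1b = esm1b,
                 alphamissense = alphamissense, splice_ref = splice_ref,
                 splice_alt = splice_alt),
            class = "evidence_bundle")
}

#' Triage configuration
#'
#' Thresholds of the tiered classifier. Defaults follow the study design:
#' variants at MAF >= 0.005 are excluded as polymorphic; ESM1b scores at or
#' below -10 and AlphaMissense scores above 0.8 count as pathogenic
#' predictions; a splice variant is called damaging when its alternate
#' splice score drops below \code{splice_abs_floor} or loses at least
#' \code{splice_rel_drop} of the reference score; truncating variants in the
#' final coding exon are exempted from the auto-pathogenic rule.
#'
#' @param maf_threshold Rarity filter on minor allele frequency (default
#'   0.005).
#' @param esm1b_threshold ESM1b pathogenicity threshold (default -10; at or
#'   below is a pathogenic prediction).
#' @param alphamissense_threshold AlphaMissense pathogenicity threshold
#'   (default 0.8; strictly above is a pathogenic prediction).
#' @param splice_abs_floor Alternate splice score below this is damaging
#'   (default 0).
#' @param splice_rel_drop Relative score loss at or above this fraction is
#'   damaging (default 0.5).
#' @param last_exon_exemption Exempt last-exon truncations from the
#'   auto-pathogenic rule (default TRUE).
#' @return A list of class \code{triage_config}.
#' @export
triage_config <- function(maf_threshold = 0.005, esm1b_threshold = -10,
                          alphamissense_threshold = 0.8,
                          splice_abs_floor = 0, splice_rel_drop = 0.5,
                          last_exon_exemption = TRUE) {
  stopifnot(is.finite(maf_threshold), maf_threshold > 0, maf_threshold < 1,
            is.finite(esm1b_threshold), is.finite(alphamissense_threshold),
            is.finite(splice_abs_floor), is.finite(splice_rel_drop),
            is.logical(last_exon_exemption))
  structure(list(maf_threshold = maf_threshold,
                 esm1b_threshold = esm1b_threshold,
                 alphamissense_threshold = alphamissense_threshold,
                 splice_abs_floor = splice_abs_floor,
                 splice_rel_drop = splice_rel_drop,
                 last_exon_exemption = last_exon_exemption),
            class = "triage_config")
}

#' Parse a ClinVar assertion string
#'
#' Reduces a free-text, slash-joined ClinVar assertion to one of four
#' summary categories. Components all within \{Pathogenic, Likely
#' pathogenic\} parse as \code{PATHOGENIC}; all within \{Benign, Likely
#' benign\} as \code{BENIGN}; any "Uncertain significance" component or a
#' mixture of pathogenic and benign components as
#' \code{VUS_OR_CONFLICTING}; anything else (including an empty string or
#' "Not listed") as \code{NOT_LISTED}. Matching is case-insensitive; the
#' function is total.
#'
#' @param s Character vector of assertion strings.
#' @return Character vector over \code{PATHOGENIC}, \code{BENIGN},
#'   \code{VUS_OR_CONFLICTING}, \code{NOT_LISTED}.
#' @export
parse_clinvar_assertion <- function(s) {
  vapply(s, function(x) {
    if (is.na(x)) return("NOT_LISTED")
    x <- tolower(trimws(x))
    if (!nzchar(x) || x == "not listed") return("NOT_LISTED")
    parts <- trimws(strsplit(x, "/", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    if (!length(parts)) return("NOT_LISTED")
    is_path <- parts %in% c("pathogenic", "likely pathogenic")
    is_ben <- parts %in% c("benign", "likely benign")
    is_vus <- parts %in% c("uncertain significance",
                           "conflicting interpretations of pathogenicity",
                           "conflicting classifications of pathogenicity")
    if (any(is_vus)) return("VUS_OR_CONFLICTING")
    if (any(!(is_path | is_ben))) return("NOT_LISTED")
    if (all(is_path)) return("PATHOGENIC")
    if (all(is_ben)) return("BENIGN")
    "VUS_OR_CONFLICTING"
  }, character(1L), USE.NAMES = FALSE)
}

#' Classify a single variant through the tiered rules
#'
#' Decision sequence (first matching tier wins):
#' \enumerate{
#'   \item MAF known and >= \code{maf_threshold}: \code{excluded_common}.
#'   \item ClinVar parses \code{PATHOGENIC}: \code{pathogenic};
#'     \code{BENIGN}: \code{benign}. Uncertain/conflicting assertions fall
#'     through to the evidence tiers.
#'   \item Truncating kinds (\code{stop_gained}, \code{frameshift}):
#'     \code{pathogenic} unless the first affected codon lies in the final
#'     coding exon, which yields \code{likely_benign}.
#'   \item \code{splice_region}: the splice-score rule decides
#'     \code{likely_pathogenic} vs \code{likely_benign}; absent scores yield
#'     \code{ambiguous}.
#'   \item Missense / in-frame indels (and stop/start-loss): the
#'     ESM1b-AlphaMissense concordance rule; a lone available predictor
#'     decides by itself (flagged in the trace); discordant or fully absent
#'     predictions yield \code{ambiguous}.
#'   \item \code{synonymous}/\code{intronic}: \code{likely_benign}.
#' }
#'
#' @param consequence A [call_consequence()] result, or any list with
#'   \code{kind} and \code{in_last_exon}.
#' @param evidence An [evidence_bundle()] (or compatible list).
#' @param cfg A [triage_config()].
#' @return A list of class \code{classification} with \code{klass},
#'   \code{rule_trace} (ordered rule identifiers) and \code{evidence_used}.
#' @export
classify_variant <- function(consequence, evidence, cfg = triage_config()) {
  kind <- consequence$kind
  ev <- evidence
  trace <- character()
  used <- character()
  done <- function(klass) {
    structure(list(klass = klass, rule_trace = trace,
                   evidence_used = unique(used)),
              class = "classification")
  }
  # (1) rarity filter dominates everything
  if (!is.na(ev$maf) && ev$maf >= cfg$maf_threshold) {
    trace <- c(trace, "MAF_EXCLUDE"); used <- c(used, "MAF")
    return(done("excluded_common"))
  }
  trace <- c(trace, "MAF_PASS")
  # (2) ClinVar precedence for confident assertions
  cv <- parse_clinvar_assertion(ev$clinvar)
  if (cv == "PATHOGENIC") {
    trace <- c(trace, "CLINVAR_PATHOGENIC"); used <- c(used, "CLINVAR")
    return(done("pathogenic"))
  }
  if (cv == "BENIGN") {
    trace <- c(trace, "CLINVAR_BENIGN"); used <- c(used, "CLINVAR")
    return(done("benign"))
  }
  trace <- c(trace, paste0("CLINVAR_", cv))
  # (3) truncation rule with last-exon exemption
  if (kind %in% c("stop_gained", "frameshift")) {
    used <- c(used, "TRUNCATION")
    if (cfg$last_exon_exemption && isTRUE(consequence$in_last_exon)) {
      trace <- c(trace, "TRUNCATING_LAST_EXON")
      return(done("likely_benign"))
    }
    trace <- c(trace, "TRUNCATING")
    return(done("pathogenic"))
  }
  # (4) splice-score rule
  if (kind == "splice_region") {
    used <- c(used, "SPLICE")
    if (is.na(ev$splice_ref) || is.na(ev$splice_alt)) {
      trace <- c(trace, "SPLICE_NO_SCORE")
      return(done("ambiguous"))
    }
    rel_drop <- if (ev$splice_ref > 0)
      (ev$splice_ref - ev$splice_alt) / ev$splice_ref else Inf
    damaging <- ev$splice_alt < cfg$splice_abs_floor ||
      rel_drop >= cfg$splice_rel_drop
    trace <- c(trace, if (damaging) "SPLICE_DAMAGING" else "SPLICE_TOLERATED")
    return(done(if (damaging) "likely_pathogenic" else "likely_benign"))
  }
  # (5) in-silico concordance tier
  if (kind %in% c("missense", "inframe_deletion", "inframe_insertion",
                  "stop_lost", "start_lost")) {
    used <- c(used, "INSILICO")
    e_has <- !is.na(ev$esm1b); a_has <- !is.na(ev$alphamissense)
    e_path <- e_has && ev$esm1b <= cfg$esm1b_threshold
    a_path <- a_has && ev$alphamissense > cfg$alphamissense_threshold
    if (e_has && a_has) {
      if (e_path && a_path) {
        trace <- c(trace, "INSILICO_CONCORDANT_PATHOGENIC")
        return(done("likely_pathogenic"))
      }
      if (!e_path && !a_path) {
        trace <- c(trace, "INSILICO_CONCORDANT_BENIGN")
        return(done("likely_benign"))
      }
      trace <- c(trace, "INSILICO_DISCORDANT")
      return(done("ambiguous"))
    }
    if (e_has) {
      trace <- c(trace, "INSILICO_SINGLE_ESM1B")
      return(done(if (e_path) "likely_pathogenic" else "likely_benign"))
    }
    if (a_has) {
      trace <- c(trace, "INSILICO_SINGLE_ALPHAMISSENSE")
      return(done(if (a_path) "likely_pathogenic" else "likely_benign"))
    }
    trace <- c(trace, "INSILICO_ABSENT")
    return(done("ambiguous"))
  }
  # (6) remaining kinds carry no damage signal
  trace <- c(trace, "NONCODING_OR_SILENT")
  done("likely_benign")
}

#' Classify a table of variants and tally the results
#'
#' Applies [classify_variant()] row-wise to a joined variant/evidence table
#' and emits per-class, per-gene and per-pathway counts. Rows without a
#' consequence are reported in a skipped-records section, never silently
#' dropped.
#'
#' @param variants Data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{gene}, \code{consequence} (kind string),
#'   \code{in_last_exon} (logical, may be NA), \code{clinvar}, \code{maf},
#'   \code{esm1b}, \code{alphamissense}, \code{splice_ref},
#'   \code{splice_alt}. Extra columns are carried through.
#' @param cfg A [triage_config()].
#' @return A list of class \code{triage_result}: \code{classified} (input
#'   rows plus \code{classification}, \code{rule_trace},
#'   \code{evidence_used}), \code{class_counts}, \code{gene_counts} (per
#'   gene x class), \code{pathway_counts} (HDR/MMR x class), and
#'   \code{skipped}.
#' @export
classify_cohort <- function(variants, cfg = triage_config()) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
           "in_last_exon", "clinvar", "maf", "esm1b", "alphamissense",
           "splice_ref", "splice_alt")
  missing <- setdiff(req, names(variants))
  if (length(missing))
    stop(sprintf("classify_cohort: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  n <- nrow(variants)
  skip <- is.na(variants$consequence) | variants$consequence == ""
  keep <- variants[!skip, , drop = FALSE]
  classification <- character(nrow(keep))
  rule_trace <- character(nrow(keep))
  evidence_used <- character(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    cls <- classify_variant(
      list(kind = keep$consequence[i], in_last_exon = keep$in_last_exon[i]),
      evidence_bundle(clinvar = keep$clinvar[i], maf = keep$maf[i],
                      esm1b = keep$esm1b[i],
                      alphamissense = keep$alphamissense[i],
                      splice_ref = keep$splice_ref[i],
                      splice_alt = keep$splice_alt[i]),
      cfg)
    classification[i] <- cls$klass
    rule_trace[i] <- paste(cls$rule_trace, collapse = ">")
    evidence_used[i] <- paste(cls$evidence_used, collapse = ",")
  }
  keep$classification <- classification
  keep$rule_trace <- rule_trace
  keep$evidence_used <- evidence_used
  if (!"key" %in% names(keep) && nrow(keep))
    keep$key <- variant_key(keep$chrom, keep$pos, keep$ref, keep$alt)

  class_counts <- stats::setNames(integer(length(CLASS_LEVELS)), CLASS_LEVELS)
  tab <- table(factor(classification, levels = CLASS_LEVELS))
  class_counts[names(tab)] <- as.integer(tab)
  pathway <- gene_pathway(keep$gene)
  gene_counts <- if (nrow(keep))
    as.data.frame(table(gene = keep$gene,
                        classification = factor(classification,
                                                levels = CLASS_LEVELS)),
                  responseName = "n", stringsAsFactors = FALSE)
  else data.frame(gene = character(), classification = character(),
                  n = integer())
  pathway_counts <- if (nrow(keep))
    as.data.frame(table(pathway = factor(pathway, levels = c("HDR", "MMR")),
                        classification = factor(classification,
                                                levels = CLASS_LEVELS)),
                  responseName = "n", stringsAsFactors = FALSE)
  else data.frame(pathway = character(), classification = character(),
                  n = integer())
  structure(list(classified = keep, class_counts = class_counts,
                 gene_counts = gene_counts, pathway_counts = pathway_counts,
                 skipped = variants[skip, , drop = FALSE], n_input = n,
                 config = cfg),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> %d variant(s) classified, %d skipped\n",
              nrow(x$classified), nrow(x$skipped)))
  cc <- x$class_counts[x$class_counts > 0]
  for (k in names(cc)) cat(sprintf("  %-18s %d\n", k, cc[[k]]))
  invisible(x)
}
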