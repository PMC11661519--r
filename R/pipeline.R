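# Orchestration: tie the stages into reproducible runs with manifests.
# classify and associate are pure functions of their inputs and
# configuration; randomness enters only through the simulator's seed.

.write_manifest <- function(out_dir, stage, inputs, seed = NULL, counts = list()) {
  digests <- lapply(inputs, function(p)
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else NULL)
  manifest <- list(tool = "germtriage",
                   version = as.character(utils::packageVersion("germtriage")),
                   stage = stage, timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed, inputs = digests, counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Write a simulated cohort bundle to disk
#'
#' Emits the exact file dialects the readers consume: a multi-sample VCF of
#' per-patient genotypes, the annotation TSV, the transcript TSV, a
#' reference FASTA (one contig per gene), the phenotype TSV, the control
#' summary TSV, a hidden-truth JSON for validation, and a run manifest.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
run_simulate <- function(cfg = simulation_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(cfg)
  paths <- list(
    vcf = file.path(out_dir, "cohort.vcf"),
    annotations = file.path(out_dir, "annotations.tsv"),
    transcripts = file.path(out_dir, "transcripts.tsv"),
    reference = file.path(out_dir, "reference.fa"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    controls = file.path(out_dir, "controls.tsv"),
    truth = file.path(out_dir, "truth.json"))

  v <- sim$variants
  carr <- matrix(FALSE, nrow = nrow(v), ncol = nrow(sim$patients),
                 dimnames = list(NULL, sim$patients$patient_id))
  if (nrow(sim$carriage))
    for (i in seq_len(nrow(sim$carriage))) {
      r <- match(sim$carriage$key[i], v$key)
      carr[r, sim$carriage$patient_id[i]] <- TRUE
    }
  write_vcf(v, carr, paths$vcf)

  ann <- v[, c("chrom", "pos", "ref", "alt", "clinvar", "maf", "esm1b",
               "alphamissense", "splice_ref", "splice_alt")]
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  tx <- sim$transcripts
  for (g in names(tx)) tx[[g]]$gene <- g
  write_transcripts(tx, paths$transcripts)
  seqs <- Biostrings::DNAStringSet(
    vapply(sim$reference, function(r) r$seq, character(1L)))
  names(seqs) <- names(sim$reference)
  Biostrings::writeXStringSet(seqs, paths$reference)
  utils::write.table(sim$patients[, c("patient_id", "age", "histology",
                                      "hpv", "stage")],
                     paths$phenotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$controls, paths$controls, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       pretty = TRUE)
  .write_manifest(out_dir, "simulate", paths, seed = cfg$seed,
                  counts = list(patients = nrow(sim$patients),
                                variants = nrow(v),
                                carriers = sum(sim$patients$carrier)))
  invisible(paths)
}

#' Read a reference FASTA into per-contig reference windows
#'
#' @param path FASTA file (one contig per gene, as written by
#'   [run_simulate()]).
#' @return Named list of windows (\code{start = 1}, \code{seq}).
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i)
    list(start = 1L, seq = as.character(seqs[[i]])))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Classify a cohort's variants from files
#'
#' Reads variant calls, annotations, transcript models and the reference;
#' normalizes each variant; projects it onto its gene's canonical
#' transcript to call the molecular consequence; joins the evidence by
#' normalized variant key; and runs the tiered classifier. Variants that
#' project onto no known transcript are reported as skipped, never
#' dropped silently.
#'
#' @param vcf,annotations,transcripts,reference Input file paths (reference
#'   is the FASTA of contigs named as in the VCF).
#' @param out_dir Output directory for the classified TSV, summary JSON
#'   and manifest.
#' @param cfg A [triage_config()].
#' @return A list: \code{result} (the [classify_cohort()] output),
#'   \code{carriage} (patient/variant links from the VCF), \code{paths}.
#' @export
run_classify <- function(vcf, annotations, transcripts, reference, out_dir,
                         cfg = triage_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  calls <- read_vcf(vcf)
  ann <- read_annotation_table(annotations)
  tx <- read_transcripts(transcripts)
  ref <- read_reference(reference)
  tx_by_chrom <- list()
  for (g in names(tx)) {
    chrom <- attr(tx[[g]], "chrom")
    if (is.null(chrom)) {
      # contigs are named after their gene; fall back to span coverage
      chrom <- if (g %in% names(ref)) g else
        names(ref)[vapply(ref, function(r)
          nchar(r$seq) >= max(tx[[g]]$exons$end), logical(1L))][1L]
      attr(tx[[g]], "chrom") <- chrom
    }
    tx_by_chrom[[chrom]] <- c(tx_by_chrom[[chrom]], list(tx[[g]]))
  }
  uniq <- calls[!duplicated(calls$key),
                c("chrom", "pos", "ref", "alt", "key"), drop = FALSE]
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(uniq))) {
    chrom <- uniq$chrom[i]
    refwin <- ref[[chrom]]
    v <- genomic_variant(chrom, uniq$pos[i], uniq$ref[i], uniq$alt[i])
    if (!is.null(refwin)) v <- normalize_variant(v, refwin)
    cand <- tx_by_chrom[[chrom]]
    cons <- NULL; gene <- NA_character_
    for (t in cand) {
      cons <- tryCatch(call_consequence(v, t, refwin), error = function(e) NULL)
      if (!is.null(cons)) { gene <- t$gene; break }
    }
    if (is.null(cons)) {
      skipped[[length(skipped) + 1L]] <- cbind(uniq[i, , drop = FALSE],
                                               reason = "no transcript")
      next
    }
    erow <- ann[match(variant_key(v), ann$key), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, gene = gene,
      consequence = cons$kind, in_last_exon = cons$in_last_exon,
      protein_change = cons$protein_change,
      clinvar = if (nrow(erow) && !is.na(erow$clinvar)) erow$clinvar else "Not listed",
      maf = if (nrow(erow)) erow$maf else NA_real_,
      esm1b = if (nrow(erow)) erow$esm1b else NA_real_,
      alphamissense = if (nrow(erow)) erow$alphamissense else NA_real_,
      splice_ref = if (nrow(erow)) erow$splice_ref else NA_real_,
      splice_alt = if (nrow(erow)) erow$splice_alt else NA_real_,
      stringsAsFactors = FALSE)
  }
  vt <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene = character(),
               consequence = character(), in_last_exon = logical(),
               protein_change = character(), clinvar = character(),
               maf = numeric(), esm1b = numeric(), alphamissense = numeric(),
               splice_ref = numeric(), splice_alt = numeric(),
               stringsAsFactors = FALSE)
  result <- classify_cohort(vt, cfg)
  if (length(skipped))
    result$skipped <- rbind(result$skipped, do.call(rbind, skipped))

  paths <- list(classified = file.path(out_dir, "classified.tsv"),
                summary = file.path(out_dir, "classify_summary.json"))
  write_classified_table(result$classified, paths$classified)
  jsonlite::write_json(
    list(n_input = result$n_input,
         n_skipped = nrow(result$skipped),
         class_counts = as.list(result$class_counts),
         pathway_counts = result$pathway_counts,
         gene_counts = result$gene_counts[result$gene_counts$n > 0, ]),
    paths$summary, auto_unbox = TRUE, pretty = TRUE)
  .write_manifest(out_dir, "classify",
                  list(vcf = vcf, annotations = annotations,
                       transcripts = transcripts, reference = reference),
                  counts = list(variants = nrow(result$classified),
                                skipped = nrow(result$skipped)))
  # re-key patient carriage to normalized variant keys
  calls$key <- vapply(seq_len(nrow(calls)), function(i) {
    refwin <- ref[[calls$chrom[i]]]
    v <- genomic_variant(calls$chrom[i], calls$pos[i], calls$ref[i],
                         calls$alt[i])
    if (!is.null(refwin)) v <- normalize_variant(v, refwin)
    variant_key(v)
  }, character(1L))
  list(result = result, carriage = calls[, c("patient_id", "key")],
       paths = paths)
}

#' Run the association battery from files
#'
#' Aggregates carriers over a classified table and phenotype file, then
#' reports the exact tests and odds ratios across the configured strata.
#' If the control summary is absent the control section is omitted with a
#' warning.
#'
#' @param classified Path to a classified TSV (from [run_classify()] or
#'   [write_classified_table()]).
#' @param phenotypes Path to the phenotype TSV.
#' @param carriage Data.frame of patient/variant links (columns
#'   \code{patient_id}, \code{key}), e.g. from [read_vcf()].
#' @param controls Optional path to a control summary TSV.
#' @param out_dir Output directory for the JSON report and manifest.
#' @param gene_set,severity_floor Passed to [aggregate_carriers()].
#' @return The [association_report()] object, invisibly writing
#'   \code{association_report.json}.
#' @export
run_associate <- function(classified, phenotypes, carriage, controls = NULL,
                          out_dir, gene_set = NULL,
                          severity_floor = "likely_pathogenic") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cls <- read_classified_table(classified)
  pats <- read_phenotypes(phenotypes)
  ctl <- if (!is.null(controls) && file.exists(controls))
    read_control_summary(controls) else NULL
  if (is.null(ctl) && !is.null(controls))
    warning("control summary not found; control section omitted")
  if (is.null(ctl) && is.null(controls))
    ctl <- NULL
  agg <- aggregate_carriers(pats, carriage, cls, gene_set = gene_set,
                            severity_floor = severity_floor)
  rep <- association_report(agg, controls = ctl)
  out <- file.path(out_dir, "association_report.json")
  jsonlite::write_json(.report_to_json(rep), out, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  .write_manifest(out_dir, "associate",
                  list(classified = classified, phenotypes = phenotypes,
                       controls = controls),
                  counts = list(patients = nrow(agg),
                                carriers = sum(agg$carrier)))
  invisible(rep)
}

.report_to_json <- function(rep) {
  out <- list()
  for (nm in names(rep)) {
    el <- rep[[nm]]
    if (!is.null(el$table)) {
      el$table <- as.data.frame.matrix(el$table)
    }
    for (f in c("or", "or_hpv18"))
      if (!is.null(el[[f]])) el[[f]] <- unclass(el[[f]])
    out[[nm]] <- el
  }
  out
}
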