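# Seeded generator of transcripts, variants, evidence, patients and control
# summaries with planted statistical structure. One master seed drives
# per-stage substreams (derived from a stage label), so adding a stage never
# perturbs the draws of earlier stages.

.seeded_rng <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  sub <- (as.integer(seed) %% 1000003L) * 2011L + (h %% 65521L)
  set.seed(sub %% 2147483629L)
  invisible(sub)
}

.shuffle <- function(x) x[sample.int(length(x))]

STOP_CODONS <- c("TAA", "TAG", "TGA")
NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  setdiff(apply(expand.grid(b, b, b), 1L, paste, collapse = ""), STOP_CODONS)
})

#' Simulation configuration
#'
#' Study-scale defaults: a cohort of 728 patients enriched for invasive
#' cancer, a baseline pathogenic-carrier rate of 4\%, a planted carrier vs
#' HPV18 odds ratio of 3, and a planted fourfold enrichment of MMR-gene
#' carriers among adenocarcinomas. The variant class mix mirrors the
#' observed rare-variant spectrum (roughly 14:9:10:32 truncating-pathogenic
#' : prediction-pathogenic : ambiguous : likely-benign out of 65).
#'
#' @param n_patients Cohort size.
#' @param histology_probs,hpv_probs,stage_probs Named category
#'   probabilities (must sum to 1).
#' @param carrier_rate Marginal probability that a patient carries a
#'   pathogenic/likely-pathogenic variant.
#' @param planted_or_hpv18 Odds ratio of carrier status given HPV18
#'   positivity.
#' @param planted_or_adeno_mmr Odds multiplier for an MMR-gene (vs HDR)
#'   variant among carriers with adenocarcinoma.
#' @param age_model List with \code{carrier} and \code{non_carrier} each
#'   \code{c(mean=, sd=)} in years.
#' @param class_mix Named proportions of intended triage classes for
#'   generated variants.
#' @param n_variants Number of distinct variants to simulate.
#' @param noncarrier_variant_rate Probability that a non-carrier carries
#'   some non-qualifying (benign/ambiguous) variant.
#' @param seed Master seed; identical configurations reproduce output
#'   byte-for-byte.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(
    n_patients = 728L,
    histology_probs = c(squamous = 0.75, adenocarcinoma = 0.20, other = 0.05),
    hpv_probs = c(HPV16 = 0.50, HPV18 = 0.15, other_positive = 0.25,
                  negative = 0.10),
    stage_probs = c(dysplasia = 0.25, invasive = 0.75),
    carrier_rate = 0.04,
    planted_or_hpv18 = 3.0,
    planted_or_adeno_mmr = 4.0,
    age_model = list(carrier = c(mean = 44, sd = 11),
                     non_carrier = c(mean = 47.3, sd = 11)),
    class_mix = c(pathogenic = 14, likely_pathogenic = 9, ambiguous = 10,
                  likely_benign = 32) / 65,
    n_variants = 65L,
    noncarrier_variant_rate = 0.06,
    seed = 1L) {
  stopifnot(abs(sum(histology_probs) - 1) < 1e-8,
            abs(sum(hpv_probs) - 1) < 1e-8,
            abs(sum(stage_probs) - 1) < 1e-8,
            abs(sum(class_mix) - 1) < 1e-8,
            carrier_rate > 0, carrier_rate < 1,
            planted_or_hpv18 > 0, planted_or_adeno_mmr > 0)
  structure(as.list(environment()), class = "simulation_config")
}

.random_seq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                 collapse = "")

#' Simulate transcript models with consistent reference contigs
#'
#' Generates one canonical transcript per synthetic gene: a CDS of random
#' length (divisible by 3, starting ATG, single terminal stop, no internal
#' stop codon), split across a random number of exons with random introns,
#' on alternating strands, each on its own contig.
#'
#' @param n_genes Number of genes.
#' @param exon_count_range Length-2 integer range of exon counts.
#' @param seed Integer seed.
#' @param codon_range Range of CDS lengths in codons (default 40-120).
#' @return List with \code{transcripts} (named list of
#'   [transcript_model()]) and \code{reference} (named list of reference
#'   windows, keyed by contig name).
#' @export
simulate_transcripts <- function(n_genes = 6L, exon_count_range = c(2L, 5L),
                                 seed = 1L, codon_range = c(40L, 120L)) {
  .seeded_rng(seed, "transcripts")
  transcripts <- list(); reference <- list()
  for (g in seq_len(n_genes)) {
    gene <- sprintf("GENE%d", g)
    contig <- gene  # one contig per gene, named after it
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_codons <- sample(codon_range[1L]:codon_range[2L], 1L)
    cds <- paste0("ATG",
                  paste(sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1L))
    n_ex <- sample(exon_count_range[1L]:exon_count_range[2L], 1L)
    len <- nchar(cds)
    # cut the CDS into n_ex chunks of >= 6 bases each
    repeat {
      cuts <- sort(sample(seq(6L, len - 6L, by = 3L),
                          min(n_ex - 1L, max(0L, len %/% 6L - 1L))))
      widths <- diff(c(0L, cuts, len))
      if (all(widths >= 6L)) break
    }
    chunks <- substring(cds, c(1L, cuts + 1L), c(cuts, len))
    introns <- vapply(seq_len(length(chunks) - 1L),
                      function(i) .random_seq(sample(60:200, 1L)),
                      character(1L))
    flank5 <- .random_seq(50L); flank3 <- .random_seq(50L)
    if (strand == "+") {
      pieces <- character(0)
      starts <- integer(0); ends <- integer(0)
      posn <- nchar(flank5)
      for (i in seq_along(chunks)) {
        starts <- c(starts, posn + 1L)
        ends <- c(ends, posn + nchar(chunks[i]))
        posn <- posn + nchar(chunks[i])
        pieces <- c(pieces, chunks[i])
        if (i < length(chunks)) {
          pieces <- c(pieces, introns[i])
          posn <- posn + nchar(introns[i])
        }
      }
      contig_seq <- paste0(flank5, paste(pieces, collapse = ""), flank3)
      exons <- data.frame(start = starts, end = ends)
    } else {
      # genomic plus strand carries the reverse complement; ascending
      # genomic order corresponds to the chunks in reverse
      rev_chunks <- rev(vapply(chunks, .revcomp, character(1L)))
      pieces <- character(0)
      starts <- integer(0); ends <- integer(0)
      posn <- nchar(flank5)
      for (i in seq_along(rev_chunks)) {
        starts <- c(starts, posn + 1L)
        ends <- c(ends, posn + nchar(rev_chunks[i]))
        posn <- posn + nchar(rev_chunks[i])
        pieces <- c(pieces, rev_chunks[i])
        if (i < length(rev_chunks)) {
          pieces <- c(pieces, introns[i])
          posn <- posn + nchar(introns[i])
        }
      }
      contig_seq <- paste0(flank5, paste(pieces, collapse = ""), flank3)
      exons <- data.frame(start = starts, end = ends)
    }
    transcripts[[gene]] <- transcript_model(
      gene = gene, transcript_id = sprintf("TX_%s", gene), strand = strand,
      exons = exons, cds_start = min(exons$start), cds_end = max(exons$end))
    reference[[contig]] <- list(start = 1L, seq = contig_seq,
                                chrom = contig, gene = gene)
    attr(transcripts[[gene]], "chrom") <- contig
  }
  list(transcripts = transcripts, reference = reference)
}

# allocate counts to classes by largest remainder so they sum to n
.allocate_mix <- function(n, mix) {
  raw <- n * mix / sum(mix)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(mix))
}

.rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1L, mean, sd)
      if (x > lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

# find an SNV in transcript t of the requested protein effect;
# want = "stop" (in a non-final coding exon) or "missense"
.find_snv <- function(t, refwin, want, rng_order = TRUE) {
  maps <- .tx_maps(t)
  n_cod <- maps$cds_len %/% 3L
  # bases of earlier exons only, for non-last-exon stops
  pre_last <- sum(maps$coding$end - maps$coding$start + 1L) -
    (maps$coding$end[maps$n_coding] - maps$coding$start[maps$n_coding] + 1L)
  cand_codons <- 2:(n_cod - 1L)
  if (want == "stop")
    cand_codons <- cand_codons[cand_codons * 3L <= pre_last]
  if (rng_order) cand_codons <- .shuffle(cand_codons)
  for (k in cand_codons) {
    codon <- .codon_at(t, maps, refwin, k)
    offs <- .shuffle(1:3)
    for (o in offs) {
      for (b in .shuffle(DNA_BASES)) {
        if (b == substr(codon, o, o)) next
        alt_codon <- codon
        substr(alt_codon, o, o) <- b
        aa_ref <- .translate_codon(codon); aa_alt <- .translate_codon(alt_codon)
        ok <- if (want == "stop") aa_alt == "*" && aa_ref != "*"
              else aa_alt != aa_ref && aa_alt != "*" && aa_ref != "*"
        if (!ok) next
        cp <- (k - 1L) * 3L + o
        gp <- cds_to_genomic(t, cp)
        gref <- .window_base(refwin, gp)
        galt <- if (t$strand == "+") b else .complement(b)
        return(genomic_variant(attr(t, "chrom"), gp, gref, galt))
      }
    }
  }
  NULL
}

#' Simulate variants whose triage classes match a target mix
#'
#' Draws SNVs on the simulated transcripts and attaches evidence bundles
#' built so that the default [triage_config()] reproduces the intended
#' class: truncating-pathogenic variants are stop-gains outside the final
#' coding exon; prediction-pathogenic missense variants draw ESM1b from a
#' normal truncated below the -10 threshold and AlphaMissense above 0.8;
#' benign missense variants draw both scores on the benign side; ambiguous
#' variants get one pathogenic and one benign prediction; common variants
#' get a MAF at or above the rarity threshold. The intended class is kept
#' as a hidden truth label.
#'
#' @param sim Output of [simulate_transcripts()].
#' @param class_mix Named proportions over \code{pathogenic},
#'   \code{likely_pathogenic}, \code{ambiguous}, \code{likely_benign},
#'   \code{excluded_common} (missing entries allowed).
#' @param n_variants Number of distinct variants.
#' @param seed Integer seed.
#' @return Data.frame accepted by [classify_cohort()], with extra columns
#'   \code{truth_class} and \code{key}.
#' @export
simulate_variants <- function(sim, class_mix = simulation_config()$class_mix,
                              n_variants = 65L, seed = 1L) {
  .seeded_rng(seed, "variants")
  counts <- .allocate_mix(n_variants, class_mix)
  genes <- names(sim$transcripts)
  rows <- list(); used_keys <- character(0); i <- 0L
  for (cls in names(counts)) {
    for (j in seq_len(counts[[cls]])) {
      for (attempt in 1:200) {
        gene <- sample(genes, 1L)
        t <- sim$transcripts[[gene]]
        refwin <- sim$reference[[attr(t, "chrom")]]
        v <- .find_snv(t, refwin, if (cls == "pathogenic") "stop" else "missense")
        if (is.null(v)) next
        key <- variant_key(v)
        if (key %in% used_keys) next
        used_keys <- c(used_keys, key)
        cons <- call_consequence(v, t, refwin)
        ev <- switch(cls,
          pathogenic = list(clinvar = "Not listed", maf = NA_real_,
                            esm1b = NA_real_, am = NA_real_),
          likely_pathogenic = list(
            clinvar = "Uncertain significance", maf = NA_real_,
            esm1b = .rtrunc_norm(1L, -15, 2, upper = -10),
            am = .rtrunc_norm(1L, 0.92, 0.04, lower = 0.8, upper = 1)),
          ambiguous = if (stats::runif(1L) < 0.5)
            list(clinvar = "Uncertain significance", maf = NA_real_,
                 esm1b = .rtrunc_norm(1L, -15, 2, upper = -10),
                 am = .rtrunc_norm(1L, 0.3, 0.15, lower = 0, upper = 0.8))
          else
            list(clinvar = "Uncertain significance", maf = NA_real_,
                 esm1b = .rtrunc_norm(1L, -4, 2, lower = -10),
                 am = .rtrunc_norm(1L, 0.92, 0.04, lower = 0.8, upper = 1)),
          likely_benign = list(
            clinvar = "Uncertain significance", maf = NA_real_,
            esm1b = .rtrunc_norm(1L, -4, 2, lower = -10),
            am = .rtrunc_norm(1L, 0.3, 0.15, lower = 0, upper = 0.8)),
          excluded_common = list(clinvar = "Not listed",
                                 maf = stats::runif(1L, 0.01, 0.2),
                                 esm1b = NA_real_, am = NA_real_))
        i <- i + 1L
        rows[[i]] <- data.frame(
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          gene = gene, consequence = cons$kind,
          in_last_exon = cons$in_last_exon, clinvar = ev$clinvar,
          maf = ev$maf, esm1b = ev$esm1b, alphamissense = ev$am,
          splice_ref = NA_real_, splice_alt = NA_real_,
          truth_class = cls, key = key, stringsAsFactors = FALSE)
        break
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.draw_phenotypes <- function(n, cfg, rng = NULL) {
  if (n == 0L)
    return(data.frame(patient_id = character(), age = numeric(),
                      histology = character(), hpv = character(),
                      stage = character(), stringsAsFactors = FALSE))
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = NA_real_,
    histology = sample(names(cfg$histology_probs), n, replace = TRUE,
                       prob = cfg$histology_probs),
    hpv = sample(names(cfg$hpv_probs), n, replace = TRUE,
                 prob = cfg$hpv_probs),
    stage = sample(names(cfg$stage_probs), n, replace = TRUE,
                   prob = cfg$stage_probs),
    stringsAsFactors = FALSE)
}

# logistic intercept such that the marginal carrier probability over the
# HPV18 mixture equals the target rate
.solve_intercept <- function(carrier_rate, or_hpv18, p_hpv18) {
  f <- function(b0) {
    (1 - p_hpv18) * stats::plogis(b0) +
      p_hpv18 * stats::plogis(b0 + log(or_hpv18)) - carrier_rate
  }
  stats::uniroot(f, c(-30, 10), tol = 1e-10)$root
}

#' Simulate a patient cohort with planted carrier associations
#'
#' Draws phenotypes from the configured category distributions, assigns
#' carrier status through a logistic model in HPV18 positivity (intercept
#' solved numerically so the marginal carrier frequency equals
#' \code{carrier_rate}), gives each carrier one pathogenic/likely-pathogenic
#' variant (MMR-gene odds multiplied by \code{planted_or_adeno_mmr} for
#' adenocarcinomas), sprinkles non-qualifying variants over non-carriers,
#' and draws ages from carrier-dependent normals.
#'
#' @param cfg A [simulation_config()].
#' @param variants Variant table from [simulate_variants()] (needs
#'   \code{truth_class}, \code{gene}, \code{key}).
#' @param seed Integer seed (defaults to \code{cfg$seed}).
#' @return List with \code{patients} (phenotypes + hidden \code{carrier}
#'   truth), \code{carriage} (patient/variant links) and \code{intercept}.
#' @export
simulate_patients <- function(cfg, variants, seed = cfg$seed) {
  .seeded_rng(seed, "patients")
  n <- cfg$n_patients
  patients <- .draw_phenotypes(n, cfg)
  if (n == 0L)
    return(list(patients = cbind(patients, carrier = logical(0)),
                carriage = data.frame(patient_id = character(),
                                      key = character(),
                                      stringsAsFactors = FALSE),
                intercept = NA_real_))
  b0 <- .solve_intercept(cfg$carrier_rate, cfg$planted_or_hpv18,
                         unname(cfg$hpv_probs["HPV18"]))
  eta <- b0 + log(cfg$planted_or_hpv18) * (patients$hpv == "HPV18")
  carrier <- stats::rbinom(n, 1L, stats::plogis(eta)) == 1L
  plp <- variants[variants$truth_class %in%
                    c("pathogenic", "likely_pathogenic"), , drop = FALSE]
  benign_pool <- variants[!(variants$truth_class %in%
                              c("pathogenic", "likely_pathogenic")), ,
                          drop = FALSE]
  links <- list(); k <- 0L
  mmr_like <- gene_pathway(plp$gene) %in% "MMR"
  for (idx in which(carrier)) {
    if (!nrow(plp)) break
    w <- rep(1, nrow(plp))
    if (patients$histology[idx] == "adenocarcinoma" && any(mmr_like))
      w[mmr_like] <- cfg$planted_or_adeno_mmr
    pick <- sample.int(nrow(plp), 1L, prob = w)
    k <- k + 1L
    links[[k]] <- data.frame(patient_id = patients$patient_id[idx],
                             key = plp$key[pick], stringsAsFactors = FALSE)
  }
  for (idx in which(!carrier)) {
    if (!nrow(benign_pool)) break
    if (stats::runif(1L) < cfg$noncarrier_variant_rate) {
      pick <- sample.int(nrow(benign_pool), 1L)
      k <- k + 1L
      links[[k]] <- data.frame(patient_id = patients$patient_id[idx],
                               key = benign_pool$key[pick],
                               stringsAsFactors = FALSE)
    }
  }
  am <- cfg$age_model
  patients$age <- ifelse(
    carrier,
    stats::rnorm(n, am$carrier["mean"], am$carrier["sd"]),
    stats::rnorm(n, am$non_carrier["mean"], am$non_carrier["sd"]))
  patients$age <- round(pmax(patients$age, 18), 1)
  patients$carrier <- carrier
  carriage <- if (k) do.call(rbind, links) else
    data.frame(patient_id = character(), key = character(),
               stringsAsFactors = FALSE)
  list(patients = patients, carriage = carriage, intercept = b0)
}

#' Simulate a biobank-style control carrier summary
#'
#' @param genes Character vector of gene symbols.
#' @param carrier_freqs Per-gene carrier frequencies (recycled).
#' @param n_controls Number of genotyped controls.
#' @param seed Integer seed.
#' @return Data.frame with columns \code{gene}, \code{carriers},
#'   \code{total} (binomial draws).
#' @export
simulate_control_summary <- function(genes, carrier_freqs, n_controls,
                                     seed = 1L) {
  .seeded_rng(seed, "controls")
  freqs <- rep_len(carrier_freqs, length(genes))
  data.frame(gene = genes,
             carriers = stats::rbinom(length(genes), n_controls, freqs),
             total = as.integer(n_controls),
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort bundle
#'
#' Runs all generator stages under one master seed: transcripts with
#' reference contigs, variants with evidence, patients with planted
#' associations, and a control summary.
#'
#' @param cfg A [simulation_config()].
#' @return List with \code{transcripts}, \code{reference},
#'   \code{variants}, \code{patients}, \code{carriage}, \code{controls},
#'   \code{truth}.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  sim <- simulate_transcripts(n_genes = 6L, seed = cfg$seed)
  variants <- simulate_variants(sim, class_mix = cfg$class_mix,
                                n_variants = cfg$n_variants, seed = cfg$seed)
  pat <- simulate_patients(cfg, variants, seed = cfg$seed)
  controls <- simulate_control_summary(names(sim$transcripts),
                                       carrier_freqs = 0.002,
                                       n_controls = 50000L, seed = cfg$seed)
  list(transcripts = sim$transcripts, reference = sim$reference,
       variants = variants, patients = pat$patients,
       carriage = pat$carriage, controls = controls,
       truth = list(intercept = pat$intercept,
                    truth_class = as.list(stats::setNames(
                      variants$truth_class, variants$key)),
                    carrier = as.list(stats::setNames(
                      pat$patients$carrier, pat$patients$patient_id))))
}
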