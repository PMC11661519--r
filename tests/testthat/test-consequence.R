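# Codon-aligned helper: one exon cut after codon `k_cut`
cut_after_codon <- function(k) 3L * k

test_that("minus-strand projection reproduces HGVS cDNA numbering", {
  # BRCA1-style minus-strand gene: codon 655 = TAC (Tyr); the third codon
  # base c.1965 is genomic G on the plus strand, so g.G>T reads c.C>A
  txo <- make_tx(planted_cds(700, plant = list(list(at = 1963, bases = "TAC"))),
                 strand = "-", cuts = c(cut_after_codon(400),
                                        cut_after_codon(660)))
  txo <- shift_tx(txo, 1965, 41245583)
  v <- genomic_variant("chrT", 41245583, tx_base(txo, 41245583), "T")
  expect_equal(v$ref, "G")   # genomic plus-strand base complements c. C
  pr <- project_to_cds(v, txo$t)
  expect_equal(pr$region, "cds")
  expect_equal(pr$cds_pos, 1965L)
  expect_equal(pr$codon_index, 655L)
  cons <- call_consequence(v, txo$t, txo$win)
  expect_equal(cons$kind, "stop_gained")
  expect_equal(cons$protein_change, "Tyr655Ter")
  expect_false(cons$in_last_exon)
  # and it agrees with the full-translation oracle
  expect_equal(oracle_snv_consequence(v, txo$t, txo$win), "stop_gained")
})

test_that("intronic donor-window positions project as splice placements", {
  # donor +5 after the exon ending at c.1036 (RAD51B-style)
  txo <- make_tx(planted_cds(400), strand = "+", cuts = 1036L)
  ex1_end <- txo$t$exons$end[1L]
  gpos <- ex1_end + 5L
  v <- genomic_variant("chrT", gpos, tx_base(txo, gpos), "A")
  pr <- project_to_cds(v, txo$t)
  expect_equal(pr$region, "splice")
  expect_equal(pr$site, "donor")
  expect_equal(pr$offset, 5L)
  cons <- call_consequence(v, txo$t, txo$win)
  expect_equal(cons$kind, "splice_region")
  expect_equal(cons$splice_offset, 5L)
  # acceptor window -1
  ex2_start <- txo$t$exons$start[2L]
  aref <- tx_base(txo, ex2_start - 1L)
  va <- genomic_variant("chrT", ex2_start - 1L, aref,
                        setdiff(c("A", "C", "G", "T"), aref)[1L])
  pra <- project_to_cds(va, txo$t)
  expect_equal(pra$region, "splice")
  expect_equal(pra$site, "acceptor")
  expect_equal(pra$offset, -1L)
  # deep intron is intronic
  iref <- tx_base(txo, ex1_end + 30L)
  vi <- genomic_variant("chrT", ex1_end + 30L, iref,
                        setdiff(c("A", "C", "G", "T"), iref)[1L])
  expect_equal(project_to_cds(vi, txo$t)$region, "intronic")
})

test_that("the first CDS base projects to c.1 and start loss is called", {
  txo <- make_tx(planted_cds(30), strand = "+", cuts = cut_after_codon(15))
  v <- snv_from_c(txo, 1L, "C")
  pr <- project_to_cds(v, txo$t)
  expect_equal(pr$cds_pos, 1L)
  cons <- call_consequence(v, txo$t, txo$win)
  expect_equal(cons$kind, "start_lost")
  # out-of-range variants error
  far <- genomic_variant("chrT", max(txo$t$exons$end) + 500L, "A", "T")
  expect_error(project_to_cds(far, txo$t), "outside transcript span")
  # reference/transcript inconsistency is an integrity error
  wrong <- genomic_variant("chrT", cds_to_genomic(txo$t, 10L),
                           comp1(tx_base(txo, cds_to_genomic(txo$t, 10L))),
                           "A")
  expect_error(call_consequence(wrong, txo$t, txo$win), "integrity error")
})

test_that("published truncating variants are reconstructed on planted transcripts", {
  stops <- data.frame(
    gene = c("BARD1", "BRCA1", "BRIP1", "FANCM", "FANCM", "RAD51D", "SLX4"),
    c_pos = c(1690L, 1965L, 484L, 5101L, 1972L, 757L, 2384L),
    ref_b = c("C", "C", "C", "C", "C", "C", "C"),
    alt_b = c("T", "A", "T", "T", "T", "T", "G"),
    aa = c("Gln", "Tyr", "Arg", "Gln", "Arg", "Arg", "Ser"),
    strand = c("-", "-", "-", "+", "+", "-", "-"),
    stringsAsFactors = FALSE)
  stops$res <- (stops$c_pos - 1L) %/% 3L + 1L
  for (i in seq_len(nrow(stops))) {
    r <- stops[i, ]
    off <- (r$c_pos - 1L) %% 3L + 1L
    codon <- find_stop_codon_plant(r$aa, off, r$ref_b, r$alt_b)
    n_cod <- r$res + 20L
    txo <- make_tx(planted_cds(n_cod, plant = list(
                     list(at = 3L * r$res - 2L, bases = codon))),
                   strand = r$strand,
                   cuts = cut_after_codon(r$res + 5L), gene = r$gene)
    v <- snv_from_c(txo, r$c_pos, r$alt_b)
    cons <- call_consequence(v, txo$t, txo$win)
    expect_equal(cons$kind, "stop_gained", info = r$gene)
    expect_equal(cons$protein_change, sprintf("%s%dTer", r$aa, r$res),
                 info = r$gene)
    expect_false(cons$in_last_exon)
    expect_equal(oracle_snv_consequence(v, txo$t, txo$win), "stop_gained",
                 info = r$gene)
  }

  # frameshifting indels outside the last exon
  fs <- list(
    list(gene = "BRCA1", a = 1953L, b = 1956L),   # 4-base deletion
    list(gene = "BRCA2", a = 6277L, b = 6278L),   # delCA
    list(gene = "BRCA2", a = 4478L, b = 4481L),
    list(gene = "BRIP1", a = 2990L, b = 2993L),
    list(gene = "SLX4", a = 4024L, b = 4024L))    # single-base deletion
  for (f in fs) {
    k <- (f$a - 1L) %/% 3L + 1L
    n_cod <- (f$b - 1L) %/% 3L + 1L + 20L
    txo <- make_tx(planted_cds(n_cod), strand = "+",
                   cuts = cut_after_codon((f$b - 1L) %/% 3L + 6L),
                   gene = f$gene)
    v <- del_from_c(txo, f$a, f$b)
    cons <- call_consequence(v, txo$t, txo$win)
    expect_equal(cons$kind, "frameshift", info = f$gene)
    expect_false(cons$in_last_exon, info = f$gene)
    expect_match(cons$protein_change, "fs$")
  }

  # single-base duplication (BRIP1 c.2273dup)
  txo <- make_tx(planted_cds(780), strand = "+", cuts = cut_after_codon(770))
  g2273 <- cds_to_genomic(txo$t, 2273L)
  vdup <- ins_after_c(txo, 2273L, tx_base(txo, g2273))
  cdup <- call_consequence(vdup, txo$t, txo$win)
  expect_equal(cdup$kind, "frameshift")
  expect_false(cdup$in_last_exon)

  # BRCA2-style last-exon delins (c.10095, net +10) escapes via the flag
  txo <- make_tx(planted_cds(3375), strand = "+",
                 cuts = c(cut_after_codon(2000), cut_after_codon(3000)))
  g <- cds_to_genomic(txo$t, 10095L)
  vdi <- genomic_variant("chrT", g, tx_base(txo, g), "GAATTATATCT")
  cdi <- call_consequence(vdi, txo$t, txo$win)
  expect_equal(cdi$kind, "frameshift")
  expect_true(cdi$in_last_exon)
  expect_match(cdi$protein_change, "fs$")
})

test_that("in-frame deletions are distinguished from frameshifts", {
  txo <- make_tx(planted_cds(120), strand = "+", cuts = cut_after_codon(60))
  v3 <- del_from_c(txo, 150L, 152L)   # 3-base deletion
  c3 <- call_consequence(v3, txo$t, txo$win)
  expect_equal(c3$kind, "inframe_deletion")
  expect_true(is.na(c3$in_last_exon))
  v6 <- del_from_c(txo, 150L, 155L)
  expect_equal(call_consequence(v6, txo$t, txo$win)$kind, "inframe_deletion")
  v4 <- del_from_c(txo, 150L, 153L)
  expect_equal(call_consequence(v4, txo$t, txo$win)$kind, "frameshift")
})

test_that("every exonic SNV matches the full-translation oracle", {
  set.seed(99)
  for (rep in 1:3) {
    cds <- paste0("ATG",
                  paste(sample(germtriage:::NONSTOP_CODONS, 38, replace = TRUE),
                        collapse = ""), "TAA")
    strand <- if (rep %% 2L) "+" else "-"
    txo <- make_tx(cds, strand = strand,
                   cuts = c(cut_after_codon(14), cut_after_codon(28)))
    got <- character(0); want <- character(0); last_ok <- logical(0)
    for (cp in seq_len(nchar(cds))) {
      g <- cds_to_genomic(txo$t, cp)
      refb <- tx_base(txo, g)
      for (altb in setdiff(c("A", "C", "G", "T"), refb)) {
        v <- genomic_variant("chrT", g, refb, altb)
        cons <- call_consequence(v, txo$t, txo$win)
        got <- c(got, cons$kind)
        want <- c(want, oracle_snv_consequence(v, txo$t, txo$win))
        if (cons$kind == "stop_gained")
          last_ok <- c(last_ok, identical(cons$in_last_exon,
                                          oracle_in_last_coding_exon(g, txo$t)))
      }
    }
    expect_true(all(got %in% c("stop_gained", "missense", "synonymous",
                               "stop_lost", "start_lost")))
    expect_identical(got, want, info = sprintf("strand %s", strand))
    expect_true(all(last_ok))
  }
})

test_that("a transcript and its reverse-complement mirror call identical consequences", {
  set.seed(123)
  cds <- paste0("ATG",
                paste(sample(germtriage:::NONSTOP_CODONS, 48, replace = TRUE),
                      collapse = ""), "TGA")
  cuts <- c(cut_after_codon(17), cut_after_codon(33))
  plus <- make_tx(cds, strand = "+", cuts = cuts)
  minus <- make_tx(cds, strand = "-", cuts = cuts)
  kinds_p <- character(0); kinds_m <- character(0)
  prot_p <- character(0); prot_m <- character(0)
  for (cp in sample(seq_len(nchar(cds)), 60L)) {
    t_ref <- substr(cds, cp, cp)
    for (t_alt in setdiff(c("A", "C", "G", "T"), t_ref)) {
      cp_plus <- call_consequence(snv_from_c(plus, cp, t_alt), plus$t, plus$win)
      cp_minus <- call_consequence(snv_from_c(minus, cp, t_alt), minus$t,
                                   minus$win)
      kinds_p <- c(kinds_p, cp_plus$kind); kinds_m <- c(kinds_m, cp_minus$kind)
      prot_p <- c(prot_p, cp_plus$protein_change)
      prot_m <- c(prot_m, cp_minus$protein_change)
    }
  }
  expect_identical(kinds_p, kinds_m)
  expect_identical(prot_p, prot_m)
})
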