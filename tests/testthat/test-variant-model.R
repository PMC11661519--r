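test_that("genomic_variant validates its fields and derives the class", {
  v <- genomic_variant("17", 41245583, "G", "T")
  expect_s3_class(v, "genomic_variant")
  expect_equal(v$variant_class, "SNV")
  expect_equal(variant_class(c("CA", "C", "A", "CT"),
                             c("C", "CA", "T", "AG")),
               c("deletion", "insertion", "SNV", "delins"))
  expect_error(genomic_variant("1", 0, "A", "T"), "position")
  expect_error(genomic_variant("1", 5, "A", "A"), "differ")
  expect_error(genomic_variant("1", 5, "AN", "A"), "A,C,G,T")
  expect_error(genomic_variant("1", 5, "", "A"), "non-empty")
})

test_that("normalize_variant left-aligns and trims to minimal form", {
  # deleting one A of the A5 run anchors on the T before the run:
  # window covers positions 50..62, run AAAAA at 54..58
  win <- list(start = 50L, seq = "GGGTAAAAACGGG")
  v <- genomic_variant("1", 57, "AA", "A")
  nv <- normalize_variant(v, win)
  expect_equal(nv$pos, 53L)
  expect_equal(nv$ref, "TA")
  expect_equal(nv$alt, "T")
  # idempotent
  expect_equal(normalize_variant(nv, win), nv)
  # already-minimal SNV unchanged
  s <- genomic_variant("1", 54, "A", "G")
  expect_equal(normalize_variant(s, win), s)
  # reference mismatch is an error
  expect_error(normalize_variant(genomic_variant("1", 54, "C", "G"), win),
               "reference mismatch")
})

test_that("normalization agrees with the exhaustive global-diff oracle on random indels", {
  set.seed(421)
  for (rep in 1:300) {
    unit <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                         replace = TRUE), collapse = "")
    context <- paste0(paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                            collapse = ""),
                      strrep(unit, sample(2:5, 1)),
                      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                            collapse = ""))
    win <- list(start = 1000L, seq = context)
    # random del or ins somewhere inside the repeat region
    i <- sample(5:(nchar(context) - 6), 1)
    gpos <- 1000L + i - 1L
    if (runif(1) < 0.5) {
      len <- sample(1:3, 1)
      ref <- substr(context, i, i + len)
      v <- genomic_variant("1", gpos, ref, substr(ref, 1, 1))
    } else {
      ref <- substr(context, i, i)
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                          replace = TRUE), collapse = "")
      v <- genomic_variant("1", gpos, ref, paste0(ref, ins))
    }
    nv <- normalize_variant(v, win)
    ov <- oracle_normalize(v, win)
    expect_identical(unclass(nv), unclass(ov),
                     info = sprintf("rep %d: %s:%d %s>%s in %s", rep,
                                    v$chrom, v$pos, v$ref, v$alt, context))
    # position-monotone: never shifts right
    expect_lte(nv$pos, v$pos)
  }
})

test_that("read_vcf extracts per-patient alternate alleles", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "17\t41245583\t.\tG\tT\t.\tPASS\t.\tGT\t0/1\t0/0",
    "2\t100\t.\tA\tC,T\t.\tPASS\t.\tGT\t1/2\t0/0",
    "3\t500\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t1/1"), path)
  calls <- read_vcf(path)
  # het carrier emitted, hom-ref not
  expect_equal(nrow(calls[calls$chrom == "17", ]), 1L)
  expect_equal(calls$patient_id[calls$chrom == "17"], "S1")
  # multi-allelic 1/2 split into two entries
  ma <- calls[calls$chrom == "2", ]
  expect_equal(nrow(ma), 2L)
  expect_setequal(ma$alt, c("C", "T"))
  # missing genotype skipped; hom-alt emitted once
  expect_equal(nrow(calls[calls$chrom == "3", ]), 1L)
  expect_equal(calls$patient_id[calls$chrom == "3"], "S2")
  # sample mapping renames, unknown sample errors
  mapped <- read_vcf(path, sample_map = c(S1 = "P1", S2 = "P2"))
  expect_setequal(unique(mapped$patient_id), c("P1", "P2"))
  expect_error(read_vcf(path, sample_map = c(SX = "P9")), "mapping error")
})

test_that("malformed VCF fails with a line number", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1",
    "1\t200\tbroken-line"), path)
  expect_error(read_vcf(path), "line 4")
  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf"), path2)
  expect_error(read_vcf(path2), "line 1")
})

test_that("VCF write -> read round-trip preserves variants and carriage", {
  path <- withr::local_tempfile(fileext = ".vcf")
  variants <- data.frame(chrom = c("G1", "G1", "G2"),
                         pos = c(120L, 388L, 77L),
                         ref = c("A", "CT", "G"),
                         alt = c("G", "C", "GAA"))
  carr <- matrix(c(TRUE, FALSE, FALSE,
                   TRUE, TRUE, FALSE,
                   FALSE, FALSE, TRUE), nrow = 3L, byrow = FALSE,
                 dimnames = list(NULL, c("P1", "P2", "P3")))
  write_vcf(variants, carr, path)
  back <- read_vcf(path)
  expect_equal(nrow(back), sum(carr))
  for (i in seq_len(nrow(variants)))
    expect_setequal(back$patient_id[back$pos == variants$pos[i]],
                    colnames(carr)[carr[i, ]])
  expect_equal(sort(unique(back$key)),
               sort(variant_key(variants$chrom, variants$pos, variants$ref,
                                variants$alt)))
})

test_that("tabular readers enforce schema and value contracts", {
  # annotation: missing column
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tref\talt\tclinvar", p)
  expect_error(read_annotation_table(p), "missing required column")
  # annotation: unparseable numeric names the row
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("chrom", "pos", "ref", "alt", "clinvar", "maf",
                     "esm1b", "alphamissense", "splice_ref", "splice_alt",
                     sep = "\t"),
               "1\t100\tA\tT\tNot listed\t\t-3.5\t0.2\t\t",
               "1\t200\tG\tC\tNot listed\toops\t\t\t\t"), p2)
  expect_error(read_annotation_table(p2), "row 2")
  # valid file: empty cells come back as NA
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("chrom", "pos", "ref", "alt", "clinvar", "maf",
                     "esm1b", "alphamissense", "splice_ref", "splice_alt",
                     sep = "\t"),
               "1\t100\tA\tT\tUncertain significance\t0.001\t-12\t0.9\t\t"),
             p3)
  ann <- read_annotation_table(p3)
  expect_true(is.na(ann$splice_ref[1]))
  expect_equal(ann$maf[1], 0.001)
  expect_equal(ann$key[1], "1:100:A:T")
  # phenotypes: bad category
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tage\thistology\thpv\tstage",
               "P1\t44\tsquamous\tHPV16\tinvasive",
               "P2\t51\tglandular\tHPV18\tdysplasia"), p4)
  expect_error(read_phenotypes(p4), "row 2")
  # controls: carriers > total
  p5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcarriers\ttotal", "BRCA1\t10\t5"), p5)
  expect_error(read_control_summary(p5), "row 1")
})

test_that("transcript and classified tables round-trip exactly", {
  txo <- make_tx(planted_cds(30), strand = "-", cuts = c(30L, 60L))
  tx2 <- make_tx(planted_cds(20), strand = "+", cuts = 27L, gene = "TSTG2")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_transcripts(list(TSTG = txo$t, TSTG2 = tx2$t), p)
  back <- read_transcripts(p)
  for (nm in c("TSTG", "TSTG2")) {
    orig <- if (nm == "TSTG") txo$t else tx2$t
    expect_equal(back[[nm]]$exons, orig$exons)
    expect_equal(back[[nm]]$strand, orig$strand)
    expect_equal(back[[nm]]$cds_start, orig$cds_start)
    expect_equal(cds_length(back[[nm]]), cds_length(orig))
  }
  # classified table round-trip
  res <- classify_cohort(panel_variant_table())
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_classified_table(res$classified, p2)
  back2 <- read_classified_table(p2)
  expect_equal(nrow(back2), nrow(res$classified))
  expect_equal(back2$classification, res$classified$classification)
  expect_equal(back2$rule_trace, res$classified$rule_trace)
  expect_equal(back2$in_last_exon, res$classified$in_last_exon)
  expect_equal(back2$key, res$classified$key)
})

test_that("transcript model invariants are enforced", {
  expect_error(transcript_model("G", "T1", "+",
                                data.frame(start = c(10, 5), end = c(20, 8)),
                                10, 20), "sorted")
  expect_error(transcript_model("G", "T1", "+",
                                data.frame(start = c(10, 15), end = c(20, 30)),
                                10, 30), "non-overlapping")
  expect_error(transcript_model("G", "T1", "+",
                                data.frame(start = 10, end = 20), 10, 20),
               "divisible by 3")
  expect_error(transcript_model("G", "T1", "+",
                                data.frame(start = 10, end = 21), 5, 21),
               "inside exons")
})

test_that("gene pathway vocabulary is fixed", {
  expect_equal(gene_pathway(c("BRCA1", "MSH6", "TP53")),
               c("HDR", "MMR", NA))
  expect_length(HDR_GENES, 12L)
  expect_length(MMR_GENES, 5L)
})
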