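test_that("annotation construction validates features and coordinates", {
  expect_error(mt_annotation("ACGTN"), "non-ACGT")
  expect_error(
    mt_annotation("ACGTACGTAC",
                  data.frame(name = "x", kind = "protein", start = 1, end = 20,
                             strand = "+")),
    "outside")
  expect_error(
    mt_annotation("ACGTACGTAC",
                  data.frame(name = "x", kind = "exon", start = 1, end = 3,
                             strand = "+")),
    "unknown feature kind")
  # protein span must be codon-sized unless flagged incomplete
  expect_error(
    mt_annotation(strrep("ACGT", 10),
                  data.frame(name = "x", kind = "protein", start = 1, end = 8,
                             strand = "+")),
    "not divisible by 3")
  ok <- mt_annotation(strrep("ACGT", 10),
                      data.frame(name = "x", kind = "protein", start = 1,
                                 end = 8, strand = "+"),
                      incomplete_stop = "x")
  expect_s3_class(ok, "mt_annotation")
})

test_that("load_annotation converts BED to 1-based and keeps GFF3 as-is", {
  ann0 <- toy_annotation()
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrM", ann0$sequence), fa)
  bed <- tempfile(fileext = ".bed")
  writeLines("chrM\t0\t9\tprotein:g1\t0\t+", bed)
  ann <- load_annotation(fa, bed)
  expect_equal(ann$features$start, 1L)
  expect_equal(ann$features$end, 9L)
  expect_equal(ann$features$name, "g1")
  expect_equal(ann$features$kind, "protein")

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrM\tx\tCDS\t3914\t4951\t.\t+\t.\tID=nd2;Name=nd2"), gff)
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">chrM", strrep("ACGTAC", 1000)), fa2)
  ann2 <- load_annotation(fa2, gff)
  expect_equal(ann2$features$start, 3914L)
  expect_equal(ann2$features$end, 4951L)

  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_warning(ann3 <- load_annotation(fa, empty), "empty")
  expect_equal(nrow(ann3$features), 0L)

  fa3 <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa3)
  expect_error(load_annotation(fa3, bed), "exactly one")
})

test_that("classify_region applies the fixed overlap priority", {
  ann <- toy_annotation()
  expect_equal(classify_region(ann, 25), "protein")
  expect_equal(classify_region(ann, 5), "other-noncoding")
  expect_equal(classify_region(ann, 205), "OriL")     # OriL inside tRNA
  expect_equal(classify_region(ann, 196), "tRNA")
  expect_equal(classify_region(ann, 380), "D-loop")
  expect_error(classify_region(ann, 0), "out of range")
  expect_error(classify_region(ann, 401), "out of range")
})

test_that("translate_cds follows the vertebrate mitochondrial code", {
  mk <- function(cds, strand = "+") {
    body <- if (strand == "+") cds else mitosoma:::.revcomp(cds)
    mt_annotation(paste0("AAAA", body, "TTTT"),
                  data.frame(name = "g", kind = "protein", start = 5,
                             end = 4 + nchar(cds), strand = strand))
  }
  expect_equal(translate_cds(mk("ATGTGATAA"), "g"), "MW")   # TGA = Trp
  expect_equal(translate_cds(mk("ATGAGAAAA"), "g"), "M")    # AGA = stop
  # minus-strand gene equals plus-strand translation of the revcomp'd CDS
  cds <- "ATGGGATGCCATTAA"
  expect_equal(translate_cds(mk(cds, "-"), "g"), translate_cds(mk(cds, "+"), "g"))
})

test_that("count_ns_sites matches hand enumeration on single codons", {
  mk <- function(codon) mt_annotation(
    paste0("AA", codon, "TT"),
    data.frame(name = "g", kind = "protein", start = 3, end = 5, strand = "+"))
  expect_equal(count_ns_sites(mk("GGG"), "g"), c(N = 2, S = 1))
  atg <- count_ns_sites(mk("ATG"), "g")
  expect_equal(atg[["S"]], 1 / 3)  # only ATG->ATA (Met) is synonymous
  expect_equal(atg[["N"]], 8 / 3)
})

test_that("count_ns_sites agrees with the brute-force oracle on random genes", {
  for (seed in 1:50) {
    ann <- random_gene_annotation(seed)
    got <- count_ns_sites(ann, "g")
    want <- oracle_ns_sites(ann, "g")
    expect_equal(got, want, tolerance = 1e-12)
    # N + S equals the coding length in bp
    f <- ann$features
    expect_equal(sum(got), f$end - f$start + 1)
  }
})

test_that("classify_substitution handles code, strand and noncoding cases", {
  ann <- toy_annotation()
  # gplus codon 2 is GGA at 24..26; GGA->GGC (position 26 A->C) is synonymous
  expect_equal(classify_substitution(ann, 26, "C")$effect, "synonymous")
  # gplus codon 2 position 1 G->A: GGA->AGA = stop (nonsense)
  expect_equal(classify_substitution(ann, 24, "A")$effect, "nonsense")
  expect_equal(classify_substitution(ann, 380,
                                     setdiff(c("A", "C", "G", "T"),
                                             substr(ann$sequence, 380, 380))[1])$effect,
               "noncoding")
  expect_error(classify_substitution(ann, 26, "A"), "equals the reference")
  expect_error(classify_substitution(ann, 26, "N"), "one of A,C,G,T")
})

test_that("minus-strand classification equals complemented plus-strand classification", {
  for (seed in 1:10) {
    cds_ann <- random_gene_annotation(seed, strand = "+")
    f <- cds_ann$features
    cds <- substr(cds_ann$sequence, f$start, f$end)
    minus_ann <- mt_annotation(
      paste0(substr(cds_ann$sequence, 1, f$start - 1),
             mitosoma:::.revcomp(cds),
             substr(cds_ann$sequence, f$end + 1, cds_ann$length)),
      data.frame(name = "g", kind = "protein", start = f$start, end = f$end,
                 strand = "-"))
    tp <- ns_effect_table(cds_ann)
    tm <- ns_effect_table(minus_ann)
    # position i on plus maps to end-(i-start) on minus with complemented alleles
    tm$mapped_pos <- f$end - (tm$position - f$start)
    tm$mapped_alt <- mitosoma:::.complement(tm$alt)
    key_p <- paste(tp$position, tp$alt)
    key_m <- paste(tm$mapped_pos, tm$mapped_alt)
    expect_setequal(key_p, key_m)
    expect_equal(tp$effect[match(key_m, key_p)], tm$effect)
  }
})

test_that("frameshift_stop_scan applies indels and finds premature stops", {
  # CDS: ATG AAA GGG TAA; deleting the A at CDS position 4 shifts the frame
  # to ATG AAG GGT AA -> no stop before the CDS end (reported, not raised)
  ann <- mt_annotation(
    paste0("CC", "ATGAAAGGGTAA", "GG"),
    data.frame(name = "g", kind = "protein", start = 3, end = 14, strand = "+"))
  res <- frameshift_stop_scan(ann, "g", position = 5, ref = "GA", alt = "G")
  expect_true(res$no_stop)
  # insertion creating an early stop: ATG A(G)AA GGG TAA -> ATG AGA ... AGA=stop
  res2 <- frameshift_stop_scan(ann, "g", position = 6, ref = "A", alt = "AG")
  expect_equal(res2$stop_codon_index, 2L)
  expect_equal(res2$truncation_aa, nchar(translate_cds(ann, "g")) - 1L)
  expect_error(frameshift_stop_scan(ann, "g", position = 3, ref = "ATG", alt = "A"),
               "start codon")
  expect_error(frameshift_stop_scan(ann, "g", position = 5, ref = "G", alt = "T"),
               "pure anchored")
})

test_that("frameshift insertion/deletion round-trip restores the stop index", {
  for (seed in 1:10) {
    ann <- random_gene_annotation(seed, n_codons = 12, strand = "+")
    f <- ann$features
    wt_aa <- nchar(translate_cds(ann, "g"))
    # insert an A mid-gene, then scan the sequence with the insertion removed
    pos <- f$start + 6L
    refb <- substr(ann$sequence, pos, pos)
    ins <- frameshift_stop_scan(ann, "g", pos, refb, paste0(refb, "A"))
    mut_seq <- paste0(substr(ann$sequence, 1, pos), "A",
                      substr(ann$sequence, pos + 1, ann$length))
    # widen the span by two downstream bases to keep it codon-sized; the
    # original stop codon stays intact inside the span
    ann_mut <- mt_annotation(mut_seq,
                             data.frame(name = "g", kind = "protein",
                                        start = f$start, end = f$end + 3L,
                                        strand = "+"))
    del <- frameshift_stop_scan(ann_mut, "g", pos, paste0(refb, "A"), refb)
    expect_equal(del$stop_codon_index, wt_aa + 1L)
  }
})
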