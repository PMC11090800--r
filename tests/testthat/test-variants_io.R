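calls_fixture <- function() {
  data.frame(position = c(10L, 50L, 50L, 200L),
             ref = c("C", "G", "G", "C"),
             alt = c("T", "A", "T", "CA"),
             alt_depth = c(2, 12, 1, 5),
             depth = c(10000, 10000, 10000, 9000),
             sample_id = "s1", stringsAsFactors = FALSE)
}

test_that("TSV round-trip is record-identical", {
  calls <- calls_fixture()
  path <- tempfile(fileext = ".tsv")
  write_calls(calls, path)
  back <- read_calls(path, "tsv")
  expect_equal(back, calls)
})

test_that("validation rejects malformed rows with the row named", {
  calls <- calls_fixture()
  calls$alt_depth[2] <- 0
  p <- tempfile(fileext = ".tsv"); write_calls(calls, p)
  expect_error(read_calls(p), "row\\(s\\): 2")
  calls <- calls_fixture(); calls$alt_depth[3] <- 20000
  write_calls(calls, p)
  expect_error(read_calls(p), "exceeds depth")
  calls <- calls_fixture(); calls$alt[1] <- "C"
  write_calls(calls, p)
  expect_error(read_calls(p), "ref equals alt")
})

test_that("indels are left-anchored and parsimony-trimmed on read", {
  # "C>CAA" and "CC>CCAA" at adjacent anchors describe the same insertion
  raw <- data.frame(position = c(7L, 6L), ref = c("C", "CC"),
                    alt = c("CAA", "CCAA"), alt_depth = c(1, 1),
                    depth = c(100, 100), sample_id = "s",
                    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  utils::write.table(raw, p, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_calls(p)
  expect_equal(got$position, c(7L, 7L))
  expect_equal(got$ref, c("C", "C"))
  expect_equal(got$alt, c("CAA", "CAA"))
})

test_that("VCF dialect maps configured INFO depth fields", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"duplex depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"alt duplex depth\">",
    "##contig=<ID=chrM,length=16299>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrM\t4050\t.\tC\tCA\t.\tPASS\tDP=10000;AD=12",
    "chrM\t77\t.\tG\tT\t.\tPASS\tDP=9000;AD=3"), vcf)
  got <- read_calls(vcf, "vcf", sample_id = "m1")
  expect_setequal(got$position, c(77L, 4050L))  # record order follows the file
  expect_equal(got[got$position == 4050L, ]$alt, "CA")
  expect_equal(got[got$position == 4050L, ]$alt_depth, 12)
  expect_equal(got[got$position == 4050L, ]$depth, 10000)
  expect_equal(unique(got$sample_id), "m1")
  expect_error(read_calls(vcf, "vcf", depth_field = "DPX"), "lacks INFO")
})

test_that("haplotype-site filter splits kept and removed calls", {
  calls <- calls_fixture()
  hap <- data.frame(strain = "NZB", position = c(50L, 300L),
                    b6_allele = c("G", "A"), conplastic_allele = c("A", "C"))
  fh <- filter_haplotype_sites(calls, hap)
  expect_equal(nrow(fh$removed), 2L)  # both alts at position 50
  expect_equal(nrow(fh$kept), 2L)
  expect_false(any(fh$kept$position %in% hap$position))
  # empty haplotype table (B6) is the identity
  fh0 <- filter_haplotype_sites(calls, hap[0, ])
  expect_equal(fh0$kept, calls)
})

test_that("high-frequency filter is strict and commutes with the haplotype filter", {
  calls <- calls_fixture()
  calls$alt_depth <- c(10, 21, 10, 9)   # freqs 1e-3, 2.1e-3, 1e-3, 1e-3
  kept <- filter_high_frequency(calls, 1e-3)
  expect_equal(nrow(kept), 3L)          # exactly-at-threshold calls retained
  expect_false(21 %in% kept$alt_depth)
  hap <- data.frame(strain = "x", position = 10L, b6_allele = "C",
                    conplastic_allele = "T")
  a <- filter_haplotype_sites(filter_high_frequency(calls, 1e-3), hap)$kept
  b <- filter_high_frequency(filter_haplotype_sites(calls, hap)$kept, 1e-3)
  expect_equal(a[order(a$position), ], b[order(b$position), ],
               ignore_attr = TRUE)
})

test_that("de novo selection applies both strict clauses with unit weight", {
  calls <- data.frame(position = 1:3, ref = "G", alt = "A",
                      alt_depth = c(99, 100, 50),
                      depth = c(20000, 20000, 2000),
                      sample_id = "s", stringsAsFactors = FALSE)
  dn <- select_de_novo(calls)
  expect_equal(dn$position, 1L)    # 100 fails depth clause, 0.025 fails freq
  expect_equal(dn$weight, 1)
})

test_that("aggregate_condition sums depths and merges duplicate alleles", {
  depth <- rep(1000, 300)
  meta <- function(i) data.frame(sample_id = paste0("s", i), strain = "AKR",
                                 tissue = "liver", age = "aged", replicate = i)
  c1 <- data.frame(position = c(5L, 9L), ref = c("G", "T"), alt = c("A", "C"),
                   alt_depth = c(2, 1), depth = 1000, sample_id = "s1",
                   stringsAsFactors = FALSE)
  c2 <- data.frame(position = 5L, ref = "G", alt = "A", alt_depth = 3,
                   depth = 2000, sample_id = "s2", stringsAsFactors = FALSE)
  ct <- aggregate_condition(list(mt_sample(c1, depth, meta(1)),
                                 mt_sample(c2, 2 * depth, meta(2))))
  expect_equal(unique(ct$depth), 3000)
  expect_equal(ct$calls$alt_depth[ct$calls$position == 5L], 5)
  expect_equal(nrow(ct$calls), 2L)
  # conservation of totals
  expect_equal(sum(ct$calls$alt_depth), sum(c1$alt_depth) + sum(c2$alt_depth))
  expect_error(aggregate_condition(list()), "empty")
  bad <- mt_sample(c2, depth, data.frame(sample_id = "s3", strain = "B6",
                                         tissue = "liver", age = "aged",
                                         replicate = 1))
  expect_error(aggregate_condition(list(mt_sample(c1, depth, meta(1)), bad)),
               "multiple conditions")
})

test_that("depth normalization thins to the per-position minimum", {
  mkcond <- function(depth, alt) {
    calls <- data.frame(position = 1L, ref = "G", alt = "A", alt_depth = alt,
                        stringsAsFactors = FALSE)
    make_condition(calls, depth)
  }
  deep <- mkcond(rep(2000, 5), 20)
  shallow <- mkcond(rep(1000, 5), 10)
  # identity when depths are equal
  same <- normalize_depth_across_conditions(list(shallow, shallow), "thin-to-min")
  expect_equal(same[[1]]$depth, shallow$depth)
  # expectation of the thinned alt count is alt * min/depth
  thinned <- replicate(400, {
    out <- normalize_depth_across_conditions(list(deep, shallow), "thin-to-min",
                                             seed = sample.int(1e6, 1))
    sum(out[[1]]$calls$alt_depth)
  })
  expect_lt(abs(mean(thinned) - 10), 3 * stats::sd(thinned) / sqrt(400))
  # determinism under a fixed seed
  a <- normalize_depth_across_conditions(list(deep, shallow), "thin-to-min", seed = 9)
  b <- normalize_depth_across_conditions(list(deep, shallow), "thin-to-min", seed = 9)
  expect_identical(a, b)
  # zero-depth positions are masked everywhere
  z <- mkcond(c(0, rep(1000, 4)), 3)
  masked <- normalize_depth_across_conditions(list(z, shallow), "none")
  expect_equal(masked[[2]]$depth[1], 0)
  expect_equal(nrow(masked[[1]]$calls), 0L)
})
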