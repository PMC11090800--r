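test_that("observed_hnhs follows the weighted-count definition", {
  ann <- toy_annotation()
  eff <- ns_effect_table(ann)
  gp <- eff[eff$gene == "gplus", ]
  ns_row <- gp[gp$effect == "non-synonymous", ][1:2, ]
  syn_row <- gp[gp$effect == "synonymous", ][1, ]
  calls <- data.frame(position = c(ns_row$position, syn_row$position),
                      ref = c(ns_row$ref, syn_row$ref),
                      alt = c(ns_row$alt, syn_row$alt),
                      alt_depth = c(3, 2, 5), stringsAsFactors = FALSE)
  cond <- make_condition(calls, rep(10000, ann$length))
  sites <- count_ns_sites(ann, "gplus")
  got <- observed_hnhs(cond, ann, "gplus")
  expect_equal(got$hN, 5 / sites[["N"]])
  expect_equal(got$hS, 5 / sites[["S"]])
  expect_equal(got$ratio, (5 / sites[["N"]]) / (5 / sites[["S"]]))
  # unit weighting scores each site-allele once
  unit <- observed_hnhs(cond, ann, "gplus", weighting = "unit")
  expect_equal(unit$hN, 2 / sites[["N"]])
  # hS of 0 excludes the gene
  cond2 <- make_condition(calls[1:2, ], rep(10000, ann$length))
  expect_true(observed_hnhs(cond2, ann, "gplus")$excluded)
  expect_error(observed_hnhs(cond, ann, "nope"), "unknown")
})

test_that("simulate_null respects proportions, compatibility and seeds", {
  ann <- toy_annotation()
  expect_equal(nrow(simulate_null(ann, 0, c("G>A/C>T" = 1))), 0L)
  seqc <- strsplit(ann$sequence, "")[[1]]
  calls <- simulate_null(ann, 500, c("G>A/C>T" = 1), seed = 4)
  expect_true(all(seqc[calls$position] %in% c("G", "C")))
  expect_true(all(calls$ref == seqc[calls$position]))
  expect_true(all(calls$alt == ifelse(calls$ref == "G", "A", "T")))
  expect_identical(simulate_null(ann, 50, c("T>C/A>G" = 1), seed = 9),
                   simulate_null(ann, 50, c("T>C/A>G" = 1), seed = 9))
  ins <- simulate_null(ann, 20, c("INS" = 1), seed = 2)
  expect_true(all(nchar(ins$alt) == 2L & substr(ins$alt, 2, 2) == "A"))
})

test_that("null draws follow the multinomial law per class", {
  ann <- toy_annotation()
  props <- c("G>A/C>T" = 0.5, "T>C/A>G" = 0.3, "INS" = 0.2)
  n_draws <- 400L; n_mut <- 500L
  counts <- matrix(0, n_draws, 3,
                   dimnames = list(NULL, names(props)))
  for (i in seq_len(n_draws)) {
    s <- simulate_null(ann, n_mut, props, seed = 1000L + i)
    for (k in names(props)) counts[i, k] <- sum(s$class == k)
  }
  for (k in names(props)) {
    mu <- n_mut * props[[k]]
    se <- sqrt(n_mut * props[[k]] * (1 - props[[k]]) / n_draws)
    expect_lt(abs(mean(counts[, k]) - mu), 4 * se)
  }
})

test_that("the fast tally path matches direct tallies of simulate_null draws", {
  ann <- toy_annotation()
  props <- c("G>A/C>T" = 0.6, "T>A/A>T" = 0.3, "DEL" = 0.1)
  n_mut <- 200L; n_sim <- 600L
  fast <- mitosoma:::.simulate_null_tallies(ann, n_mut, props, n_sim, seed = 21)
  eff <- ns_effect_table(ann)
  key <- paste(eff$position, eff$alt)
  slow <- matrix(0, nrow(fast$cat), n_sim)
  for (i in seq_len(n_sim)) {
    s <- simulate_null(ann, n_mut, props, seed = 5000L + i)
    e <- eff[match(paste(s$position, s$alt), key), ]
    e <- e[!is.na(e$gene) & s$class %in% setdiff(mutation_classes(),
                                                 c("INS", "DEL")), ]
    e$eff2 <- ifelse(e$effect == "synonymous", "S", "N")
    cnt <- table(factor(paste(e$gene, e$eff2),
                        levels = paste(fast$cat$gene, fast$cat$effect)))
    slow[, i] <- as.numeric(cnt)
  }
  for (j in seq_len(nrow(fast$cat))) {
    mf <- mean(fast$tallies[j, ]); ms <- mean(slow[j, ])
    pooled_se <- sqrt(stats::var(fast$tallies[j, ]) / n_sim +
                        stats::var(slow[j, ]) / n_sim)
    if (pooled_se == 0) expect_equal(mf, ms)
    else expect_lt(abs(mf - ms), 4 * pooled_se)
  }
})

test_that("empirical p matches exact enumeration on a tiny genome", {
  # one 4-codon gene; with a single SNV class the null (nN, nS) law is a
  # trinomial that can be enumerated exactly, independent of the tally path
  ann <- mt_annotation(paste0("AATT", "ATGGGATGCTAA", "CCGG"),
                       data.frame(name = "g", kind = "protein", start = 5,
                                  end = 16, strand = "+"))
  seqc <- strsplit(ann$sequence, "")[[1]]
  code <- Biostrings::getGeneticCode("SGC1")
  # brute-force per-position effect of the G>A/C>T class (alt A at G, T at C)
  pool <- which(seqc %in% c("G", "C"))
  eff_of <- vapply(pool, function(p) {
    alt <- if (seqc[p] == "G") "A" else "T"
    if (p < 5 || p > 16) return("other")
    j <- p - 4L; ci <- (j - 1) %/% 3 + 1; cp <- (j - 1) %% 3 + 1
    codon <- paste(seqc[5:16][(3 * ci - 2):(3 * ci)], collapse = "")
    mut <- codon; substr(mut, cp, cp) <- alt
    if (code[mut] == code[codon]) "S" else "N"
  }, character(1))
  qN <- mean(eff_of == "N"); qS <- mean(eff_of == "S")
  sites <- count_ns_sites(ann, "g")
  # observed: one non-synonymous and one synonymous G>A/C>T call
  npos <- pool[eff_of == "N"][1]; spos <- pool[eff_of == "S"][1]
  calls <- data.frame(position = c(npos, spos), ref = seqc[c(npos, spos)],
                      alt = ifelse(seqc[c(npos, spos)] == "G", "A", "T"),
                      alt_depth = c(1, 1), stringsAsFactors = FALSE)
  n_mut <- 2L
  outcomes <- expand.grid(nN = 0:n_mut, nS = 0:n_mut)
  outcomes <- outcomes[outcomes$nN + outcomes$nS <= n_mut, ]
  outcomes$prob <- apply(outcomes, 1, function(r)
    stats::dmultinom(c(r[["nN"]], r[["nS"]], n_mut - r[["nN"]] - r[["nS"]]),
                     prob = c(qN, qS, 1 - qN - qS)))
  valid <- outcomes$nN > 0 & outcomes$nS > 0
  ratio <- (outcomes$nN / sites[["N"]]) / (outcomes$nS / sites[["S"]])
  obs_ratio <- (1 / sites[["N"]]) / (1 / sites[["S"]])
  pv <- sum(outcomes$prob[valid])
  p_le <- sum(outcomes$prob[valid & ratio <= obs_ratio]) / pv
  p_ge <- sum(outcomes$prob[valid & ratio >= obs_ratio]) / pv
  p_exact <- min(1, 2 * min(p_le, p_ge))
  cond <- make_condition(calls, rep(1000, ann$length))
  res <- empirical_selection_test(cond, ann, n_sim = 40000L, min_valid = 10L,
                                  seed = 31)
  expect_false(res$excluded)
  expect_equal(res$p, p_exact, tolerance = 0.05)
})

test_that("binned scan is consistent with the aggregate test on a single bin", {
  cfg <- small_sim_config()
  sim <- simulate_genome(cfg)
  ct <- aggregate_condition(
    simulate_condition(cfg, sim$annotation, "B6", "brain", "young",
                       sim$haplotypes)$samples)
  bins <- frequency_bins(c(0, 1))
  lab <- mitosoma:::.bin_labels(c(0, 1))
  suppressMessages(
    scan <- binned_selection_scan(ct, sim$annotation, bins, n_sim = 300L,
                                  seed = 17))
  direct <- empirical_selection_test(
    ct, sim$annotation, n_sim = 300L, high_freq_threshold = NULL,
    exclude_dloop_props = TRUE, exclude_dloop_calls = TRUE,
    seed = derive_seed(17, lab), bin_label = lab)
  expect_equal(scan, direct, ignore_attr = TRUE)
})

test_that("ns_frequency_spectra yields unit-sum vectors per effect", {
  cfg <- small_sim_config()
  sim <- simulate_genome(cfg)
  ct <- aggregate_condition(
    simulate_condition(cfg, sim$annotation, "B6", "liver", "aged",
                       sim$haplotypes)$samples)
  sp <- ns_frequency_spectra(ct, sim$annotation)
  expect_equal(sum(sp$nonsyn), 1, tolerance = 1e-12)
  expect_equal(sum(sp$syn), 1, tolerance = 1e-12)
  expect_equal(nrow(sp), 4L)
})

test_that("null_ns_spectrum matches brute-force enumeration", {
  # toy gene of six Gs: every synonymous potential change is third-position
  ann <- mt_annotation(paste0("AT", "ATGGGGGGGTAA", "CG"),
                       data.frame(name = "g", kind = "protein", start = 3,
                                  end = 14, strand = "+"))
  got <- null_ns_spectrum(ann)
  want <- oracle_null_spectrum(ann)
  expect_equal(got$nonsyn, want$nonsyn, tolerance = 1e-12)
  expect_equal(got$syn, want$syn, tolerance = 1e-12)
  expect_equal(sum(got$nonsyn), 1)
  expect_equal(sum(got$syn), 1)
  for (seed in 1:10) {
    ann2 <- random_gene_annotation(seed + 200)
    expect_equal(null_ns_spectrum(ann2), oracle_null_spectrum(ann2),
                 tolerance = 1e-12)
  }
})
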