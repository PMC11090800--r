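# hN/hS selection statistics with a simulation-calibrated multinomial null:
# observed per-gene statistics, null simulation, empirical p-values with
# Benjamini-Hochberg correction, frequency-binned scans, and the
# non-synonymous/synonymous frequency spectra and their null expectation.

#' Frequency bin edges
#'
#' Half-open bins `[lo, hi)` over mutation frequency. The interior bounds
#' 5e-5 and 1e-3 delimit the intermediate-frequency range where selection is
#' assessed; the remaining edges are package defaults.
#'
#' @param edges Strictly increasing numeric vector.
#' @export
frequency_bins <- function(edges = c(0, 1e-5, 5e-5, 1e-3, 1)) {
  stopifnot(is.numeric(edges), length(edges) >= 2L, all(diff(edges) > 0))
  structure(edges, class = "frequency_bins")
}

.bin_labels <- function(bins) {
  paste0("[", utils::head(bins, -1L), ",", utils::tail(bins, -1L), ")")
}

# effects pooled into the non-synonymous numerator
.nonsyn_effects <- c("non-synonymous", "nonsense")

# per-gene N/S site counts for all protein features
.gene_sites <- function(ann) {
  genes <- ann$features$name[ann$features$kind == "protein"]
  t(vapply(genes, function(g) count_ns_sites(ann, g), numeric(2)))
}

#' Observed hN/hS for one gene
#'
#' hN is the weighted count of non-synonymous calls in the gene divided by
#' its non-synonymous site count; hS analogously. Nonsense calls pool with
#' non-synonymous. With `weighting = "alt-depth"` (the aggregation convention
#' of the source analysis) each call contributes its summed duplex
#' alternative-allele depth; `"unit"` scores each (position, alt) once.
#'
#' @param cond A `condition_table`.
#' @param ann An [mt_annotation()].
#' @param gene Protein feature name.
#' @param weighting `"alt-depth"` or `"unit"`.
#' @return List with `hN`, `hS`, `ratio` (NA and `excluded = TRUE` when
#'   either component is 0).
#' @export
observed_hnhs <- function(cond, ann, gene, weighting = c("alt-depth", "unit")) {
  weighting <- match.arg(weighting)
  sites <- count_ns_sites(ann, gene)
  eff <- ns_effect_table(ann)
  calls <- cond$calls
  snv <- nchar(calls$ref) == 1L & nchar(calls$alt) == 1L
  calls <- calls[snv, , drop = FALSE]
  e <- eff$effect[match(paste(calls$position, calls$alt),
                        paste(eff$position, eff$alt))]
  g <- eff$gene[match(paste(calls$position, calls$alt),
                      paste(eff$position, eff$alt))]
  w <- if (weighting == "alt-depth") calls$alt_depth else rep(1, nrow(calls))
  ing <- !is.na(g) & g == gene
  nw <- sum(w[ing & e %in% .nonsyn_effects])
  sw <- sum(w[ing & e == "synonymous"])
  hN <- nw / sites[["N"]]
  hS <- sw / sites[["S"]]
  excluded <- nw == 0 || sw == 0
  list(hN = hN, hS = hS, ratio = if (excluded) NA_real_ else hN / hS,
       excluded = excluded)
}

# ---- null machinery ---------------------------------------------------------

# class-compatible position pools within the sampling space
.class_pools <- function(ann, space = c("genome", "coding")) {
  space <- match.arg(space)
  refbase <- .seq_chars(ann)
  allowed <- if (space == "coding") {
    sort(unique(ns_effect_table(ann)$position))
  } else seq_len(ann$length)
  pools <- lapply(mutation_classes(), function(k) {
    if (k %in% c("INS", "DEL")) allowed
    else allowed[refbase[allowed] %in% .class_ref_pair[[k]]]
  })
  names(pools) <- mutation_classes()
  pools
}

#' Simulate a null mutation set
#'
#' Each of `n_mut` draws picks a strand-collapsed class from `proportions`
#' (multinomial) and a position uniformly with replacement among positions
#' whose reference base is compatible with the class; the SNV alternative
#' allele is then determined by class and reference base. INS/DEL draws are
#' placed uniformly as single-base A insertions/deletions (they carry no
#' hN/hS information and are simulated for count conservation only).
#'
#' @param ann An [mt_annotation()].
#' @param n_mut Number of mutations to draw.
#' @param proportions Named vector over [mutation_classes()] summing to 1.
#' @param seed Integer seed.
#' @param space `"genome"` (default) or `"coding"` position target space.
#' @return `data.frame` with `position`, `ref`, `alt`, `class`.
#' @export
simulate_null <- function(ann, n_mut, proportions, seed = 1L,
                          space = c("genome", "coding")) {
  space <- match.arg(space)
  classes <- mutation_classes()
  p <- stats::setNames(rep(0, length(classes)), classes)
  p[names(proportions)] <- proportions
  stopifnot(abs(sum(p) - 1) < 1e-8)
  if (n_mut == 0L)
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), class = character(),
                      stringsAsFactors = FALSE))
  pools <- .class_pools(ann, space)
  empty <- vapply(pools, length, integer(1)) == 0L & p > 0
  if (any(empty))
    stop("class(es) with nonzero proportion but no compatible positions: ",
         paste(classes[empty], collapse = ", "))
  set.seed(seed)
  cls <- sample(classes, n_mut, replace = TRUE, prob = p)
  refbase <- .seq_chars(ann)
  out <- lapply(classes, function(k) {
    n <- sum(cls == k)
    if (!n) return(NULL)
    pos <- pools[[k]][sample.int(length(pools[[k]]), n, replace = TRUE)]
    if (k == "INS") {
      ref <- refbase[pos]; alt <- paste0(ref, "A")
    } else if (k == "DEL") {
      ref <- paste0(refbase[pos], refbase[.wrap_pos(pos + 1L, ann$length)])
      alt <- refbase[pos]
    } else {
      ref <- refbase[pos]
      alt <- vapply(ref, function(b) .class_alt_for_ref(k, b), character(1),
                    USE.NAMES = FALSE)
    }
    data.frame(position = pos, ref = ref, alt = alt, class = k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Probability that a single null draw lands in (gene, effect) category.
# Returns list(cat = data.frame(gene, effect), M = matrix[n_cat+1, 8]) where
# column k gives the per-category probability conditional on class k; the
# last row is the "no hN/hS contribution" sink.
.null_category_probs <- function(ann, space = "genome") {
  key <- paste0(".null_cat_", space)
  cache <- attr(ann, key)
  if (!is.null(cache)) return(cache)
  eff <- ns_effect_table(ann)
  pools <- .class_pools(ann, space)
  genes <- ann$features$name[ann$features$kind == "protein"]
  cat <- expand.grid(gene = genes, effect = c("N", "S"),
                     stringsAsFactors = FALSE)
  classes <- mutation_classes()
  M <- matrix(0, nrow(cat) + 1L, length(classes),
              dimnames = list(NULL, classes))
  eff$eff2 <- ifelse(eff$effect == "synonymous", "S", "N")
  eff$class <- classify_mutation(eff$ref, eff$alt)
  for (k in setdiff(classes, c("INS", "DEL"))) {
    npool <- length(pools[[k]])
    if (!npool) next
    sub <- eff[eff$class == k & eff$position %in% pools[[k]], , drop = FALSE]
    cnt <- table(factor(paste(sub$gene, sub$eff2),
                        levels = paste(cat$gene, cat$effect)))
    M[seq_len(nrow(cat)), k] <- as.numeric(cnt) / npool
    M[nrow(cat) + 1L, k] <- 1 - sum(M[seq_len(nrow(cat)), k])
  }
  M[nrow(cat) + 1L, c("INS", "DEL")] <- 1
  out <- list(cat = cat, M = M)
  out
}

# Fast null: n_sim multinomial draws of per-(gene, effect) tallies. The
# marginal law of the tallies is identical to tallying simulate_null() draws.
.simulate_null_tallies <- function(ann, n_mut, proportions, n_sim, seed,
                                   space = "genome") {
  cp <- .null_category_probs(ann, space)
  classes <- mutation_classes()
  p <- stats::setNames(rep(0, length(classes)), classes)
  p[names(proportions)] <- proportions
  empty <- colSums(cp$M) == 0 & p > 0
  if (any(empty))
    stop("class(es) with nonzero proportion but no compatible positions: ",
         paste(classes[empty], collapse = ", "))
  q <- as.vector(cp$M %*% p)
  set.seed(seed)
  tal <- stats::rmultinom(n_sim, n_mut, q)
  list(cat = cp$cat, tallies = tal[seq_len(nrow(cp$cat)), , drop = FALSE])
}

# Weighted per-class proportions observed in a set of calls.
.observed_class_proportions <- function(calls, weighting = "alt-depth") {
  classes <- mutation_classes()
  if (!nrow(calls)) return(stats::setNames(rep(0, length(classes)), classes))
  w <- if (weighting == "alt-depth") calls$alt_depth else rep(1, nrow(calls))
  cl <- classify_mutation(calls$ref, calls$alt)
  cnt <- vapply(classes, function(k) sum(w[cl == k]), numeric(1))
  cnt / sum(cnt)
}

#' Empirical hN/hS selection test
#'
#' Per protein gene, compares the observed hN/hS ratio with `n_sim` null
#' datasets in which the observed number of mutations is resampled across
#' the genome uniformly with replacement under the observed class
#' proportions (multinomial). The empirical p-value is the fraction of valid
#' simulations at least as extreme as the observation in the observed
#' direction, doubled (two-sided) and capped at 1; ties count as extreme.
#' Genes whose observed hN or hS is 0, or with fewer than `min_valid` valid
#' simulations, are excluded. Benjamini-Hochberg correction is applied
#' across genes and a direction is called at adjusted p < `alpha`.
#'
#' @param cond A `condition_table`.
#' @param ann An [mt_annotation()].
#' @param n_sim Number of null simulations (default 10000).
#' @param weighting `"alt-depth"` (default) or `"unit"`.
#' @param high_freq_threshold Calls with frequency strictly above this are
#'   excluded in aggregate mode (default 1e-3; `NULL` disables).
#' @param exclude_dloop_props Drop D-loop calls when estimating the class
#'   proportions fed to the null (default TRUE).
#' @param exclude_dloop_calls Drop D-loop calls everywhere (used by the
#'   binned scan).
#' @param space Position target space for the null (`"genome"`/`"coding"`).
#' @param min_valid Minimum valid simulations per gene.
#' @param alpha Adjusted-p cutoff for a direction call (default 0.01).
#' @param seed Integer seed.
#' @param bin_label Label stored on the result rows.
#' @return `data.frame`: `gene`, `bin`, `hN`, `hS`, `ratio`, `n_valid`,
#'   `p`, `p_floor` (2 / valid simulations), `p_adj`, `direction`
#'   (`positive`/`negative`/`none`), `excluded`.
#' @export
empirical_selection_test <- function(cond, ann, n_sim = 10000L,
                                     weighting = c("alt-depth", "unit"),
                                     high_freq_threshold = 1e-3,
                                     exclude_dloop_props = TRUE,
                                     exclude_dloop_calls = FALSE,
                                     space = c("genome", "coding"),
                                     min_valid = 100L, alpha = 0.01,
                                     seed = 1L, bin_label = "aggregate") {
  weighting <- match.arg(weighting)
  space <- match.arg(space)
  if (!is.null(high_freq_threshold))
    cond <- filter_high_frequency(cond, high_freq_threshold)
  calls <- cond$calls
  dloop <- ann$features[ann$features$kind == "D-loop", , drop = FALSE]
  in_dloop <- rep(FALSE, nrow(calls))
  if (nrow(dloop) && nrow(calls)) {
    kinds <- .region_kind_track(ann)
    in_dloop <- kinds[calls$position] == "D-loop"
  }
  if (exclude_dloop_calls) {
    calls <- calls[!in_dloop, , drop = FALSE]
    in_dloop <- rep(FALSE, nrow(calls))
  }
  cond$calls <- calls
  prop_calls <- if (exclude_dloop_props) calls[!in_dloop, , drop = FALSE] else calls
  props <- .observed_class_proportions(prop_calls, weighting)
  w <- if (weighting == "alt-depth") calls$alt_depth else rep(1, nrow(calls))
  n_mut <- round(sum(w))
  genes <- ann$features$name[ann$features$kind == "protein"]
  sites <- .gene_sites(ann)
  obs <- lapply(genes, function(g) observed_hnhs(cond, ann, g, weighting))
  if (n_mut == 0L || all(props == 0)) {
    return(data.frame(gene = genes, bin = bin_label,
                      hN = vapply(obs, `[[`, numeric(1), "hN"),
                      hS = vapply(obs, `[[`, numeric(1), "hS"),
                      ratio = NA_real_, n_valid = 0L, p = NA_real_,
                      p_floor = NA_real_, p_adj = NA_real_,
                      direction = "none", excluded = TRUE,
                      stringsAsFactors = FALSE))
  }
  sim <- .simulate_null_tallies(ann, n_mut, props, n_sim, seed, space)
  res <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    o <- obs[[i]]
    iN <- which(sim$cat$gene == g & sim$cat$effect == "N")
    iS <- which(sim$cat$gene == g & sim$cat$effect == "S")
    simN <- sim$tallies[iN, ]; simS <- sim$tallies[iS, ]
    valid <- simN > 0 & simS > 0
    n_valid <- sum(valid)
    row <- data.frame(gene = g, bin = bin_label, hN = o$hN, hS = o$hS,
                      ratio = o$ratio, n_valid = n_valid, p = NA_real_,
                      p_floor = if (n_valid) 2 / n_valid else NA_real_,
                      p_adj = NA_real_, direction = "none",
                      excluded = TRUE, stringsAsFactors = FALSE)
    if (o$excluded || n_valid < min_valid) return(row)
    rsim <- (simN[valid] / sites[g, "N"]) / (simS[valid] / sites[g, "S"])
    n_le <- sum(rsim <= o$ratio); n_ge <- sum(rsim >= o$ratio)
    row$p <- min(1, 2 * min(n_le, n_ge) / n_valid)
    row$excluded <- FALSE
    row
  })
  out <- do.call(rbind, res)
  ok <- !out$excluded
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$direction <- ifelse(!out$excluded & out$p_adj < alpha,
                          ifelse(out$ratio > 1, "positive",
                                 ifelse(out$ratio < 1, "negative", "none")),
                          "none")
  out
}

#' Frequency-binned hN/hS scan
#'
#' Runs the empirical selection test independently within each frequency
#' bin: class proportions and mutation counts are recomputed from the bin's
#' calls, high-frequency calls are included, D-loop calls are excluded, and
#' Benjamini-Hochberg correction is applied within each bin. Empty bins are
#' skipped with a message.
#'
#' @inheritParams empirical_selection_test
#' @param bins A [frequency_bins()] object.
#' @return Row-bound `data.frame` of per-gene results with `bin` labels.
#' @export
binned_selection_scan <- function(cond, ann, bins = frequency_bins(),
                                  n_sim = 10000L,
                                  weighting = c("alt-depth", "unit"),
                                  space = c("genome", "coding"),
                                  min_valid = 100L, alpha = 0.01, seed = 1L) {
  weighting <- match.arg(weighting)
  space <- match.arg(space)
  edges <- unclass(bins)
  labels <- .bin_labels(edges)
  freq <- .cond_call_freq(cond)
  out <- list()
  for (b in seq_len(length(edges) - 1L)) {
    sel <- freq >= edges[b] & freq < edges[b + 1L]
    sub <- cond
    sub$calls <- cond$calls[sel, , drop = FALSE]
    if (!nrow(sub$calls)) {
      message("bin ", labels[b], " is empty; skipped")
      next
    }
    out[[labels[b]]] <- empirical_selection_test(
      sub, ann, n_sim = n_sim, weighting = weighting,
      high_freq_threshold = NULL, exclude_dloop_props = TRUE,
      exclude_dloop_calls = TRUE, space = space, min_valid = min_valid,
      alpha = alpha, seed = derive_seed(seed, labels[b]),
      bin_label = labels[b])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Non-synonymous and synonymous frequency spectra
#'
#' For protein-coding SNV calls, the proportion of non-synonymous (resp.
#' synonymous) mutations falling in each frequency bin relative to the total
#' across bins; both vectors sum to 1.
#'
#' @inheritParams empirical_selection_test
#' @param bins A [frequency_bins()] object.
#' @return `data.frame` with `bin`, `nonsyn`, `syn` proportions.
#' @export
ns_frequency_spectra <- function(cond, ann, bins = frequency_bins(),
                                 weighting = c("alt-depth", "unit")) {
  weighting <- match.arg(weighting)
  eff <- ns_effect_table(ann)
  calls <- cond$calls
  snv <- nchar(calls$ref) == 1L & nchar(calls$alt) == 1L
  calls <- calls[snv, , drop = FALSE]
  e <- eff$effect[match(paste(calls$position, calls$alt),
                        paste(eff$position, eff$alt))]
  keep <- !is.na(e)
  calls <- calls[keep, , drop = FALSE]; e <- e[keep]
  if (!nrow(calls)) stop("no protein-coding calls")
  freq <- calls$alt_depth / cond$depth[calls$position]
  w <- if (weighting == "alt-depth") calls$alt_depth else rep(1, nrow(calls))
  edges <- unclass(bins)
  bin <- cut(freq, edges, right = FALSE, labels = .bin_labels(edges))
  ns <- e %in% .nonsyn_effects
  nsw <- tapply(w[ns], bin[ns], sum, default = 0)
  sw <- tapply(w[!ns], bin[!ns], sum, default = 0)
  if (sum(nsw) == 0 || sum(sw) == 0)
    stop("zero non-synonymous or synonymous calls overall")
  data.frame(bin = .bin_labels(edges),
             nonsyn = as.numeric(nsw / sum(nsw)),
             syn = as.numeric(sw / sum(sw)),
             stringsAsFactors = FALSE)
}

#' Null per-class proportions of potential mutations by coding effect
#'
#' Enumerates every coding position x substitution, tallies its
#' strand-collapsed class and effect, and reports the class proportions of
#' all possible non-synonymous (resp. synonymous) changes genome-wide.
#'
#' @param ann An [mt_annotation()].
#' @return `data.frame` with `class`, `nonsyn`, `syn`; each column sums to 1.
#' @export
null_ns_spectrum <- function(ann) {
  eff <- ns_effect_table(ann)
  if (!nrow(eff)) stop("annotation has no protein features")
  cls <- classify_mutation(eff$ref, eff$alt)
  ns <- eff$effect %in% .nonsyn_effects
  classes <- setdiff(mutation_classes(), c("INS", "DEL"))
  n_cnt <- vapply(classes, function(k) sum(ns & cls == k), numeric(1))
  s_cnt <- vapply(classes, function(k) sum(!ns & cls == k), numeric(1))
  data.frame(class = classes,
             nonsyn = n_cnt / sum(n_cnt),
             syn = s_cnt / sum(s_cnt),
             stringsAsFactors = FALSE)
}
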