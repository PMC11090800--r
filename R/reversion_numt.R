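# NUMT-contamination estimation and correction, and the reversion-mutation
# enrichment, identity and age-delta tests at conplastic haplotype sites.

#' Estimate NUMT contamination from junction read counts
#'
#' Per-junction contamination fraction is the chr1 junction read count
#' divided by the average duplex depth of the mt-genome (computed with the
#' NUMT-homologous span masked). The adopted fraction is the maximum over
#' junctions (conservative). When SNV-cluster counts are supplied their
#' median fraction is reported for validation against the adopted value.
#'
#' @param junction_chr1_reads Numeric vector of chr1 read counts, one per
#'   junction region (10 bp up/downstream of the NUMT span).
#' @param avg_mt_depth Average mt duplex depth (NUMT span masked).
#' @param cluster_chr1_reads Optional chr1 read counts at SNV clusters.
#' @return A `numt_estimate`: list with `junction_fractions`, `adopted`,
#'   `chr1_depth` (= `avg_mt_depth * adopted`), `cluster_fractions`,
#'   `cluster_median`, `avg_mt_depth`.
#' @export
estimate_contamination <- function(junction_chr1_reads, avg_mt_depth,
                                   cluster_chr1_reads = NULL) {
  if (avg_mt_depth <= 0) stop("average mt depth must be positive")
  jf <- junction_chr1_reads / avg_mt_depth
  cf <- if (!is.null(cluster_chr1_reads)) cluster_chr1_reads / avg_mt_depth
  adopted <- max(jf)
  structure(list(junction_fractions = jf,
                 adopted = adopted,
                 chr1_depth = avg_mt_depth * adopted,
                 cluster_fractions = cf,
                 cluster_median = if (!is.null(cf)) stats::median(cf) else NA_real_,
                 avg_mt_depth = avg_mt_depth),
            class = "numt_estimate")
}

#' @export
print.numt_estimate <- function(x, ...) {
  cat(sprintf("numt_estimate: adopted fraction %.4g (chr1 depth %.1f reads)\n",
              x$adopted, x$chr1_depth))
  invisible(x)
}

#' Correct reversion counts and depths for NUMT contamination
#'
#' Inside the NUMT-homologous span, the estimated chr1 read depth
#' (`avg mt depth x adopted fraction`) is subtracted from the duplex depth
#' and from the reversion-allele counts (all chr1 reads are assumed to carry
#' the B6 allele); corrected counts clamp at 0. Sites outside the span are
#' unchanged.
#'
#' @param cond A `condition_table`.
#' @param est A [estimate_contamination()] result.
#' @param span `c(start, end)` NUMT-homologous mt span.
#' @param hap Optional haplotype table; when given, only calls whose
#'   alternative allele is the B6 allele at a haplotype site are treated as
#'   reversions and corrected. When `NULL`, every call in the span is.
#' @return The corrected `condition_table`.
#' @export
correct_reversion_counts <- function(cond, est, span, hap = NULL) {
  chr1 <- est$chr1_depth
  if (chr1 == 0) return(cond)
  in_span <- seq_len(cond$genome_length) >= span[1] &
    seq_len(cond$genome_length) <= span[2]
  cond$depth[in_span] <- pmax(cond$depth[in_span] - chr1, 0)
  if (nrow(cond$calls)) {
    target <- in_span[cond$calls$position]
    if (!is.null(hap)) {
      key <- paste(hap$position, hap$b6_allele)
      target <- target & paste(cond$calls$position, cond$calls$alt) %in% key
    }
    cond$calls$alt_depth[target] <- pmax(cond$calls$alt_depth[target] - chr1, 0)
    cond$calls <- cond$calls[cond$calls$alt_depth > 0, , drop = FALSE]
  }
  cond
}

#' Reversion-mutation enrichment at haplotype sites
#'
#' For strains with few haplotype sites (at most `site_threshold`), each
#' site gets a one-sided empirical p-value: the count of non-haplotype
#' (background) sites with a frequency at least as high as the haplotype
#' site divided by the background size (ties counted as extreme),
#' Benjamini-Hochberg adjusted across the strain's sites. For many-site strains the two frequency distributions are
#' compared with a one-sided Wilcoxon rank-sum test. Frequencies must be
#' NUMT-corrected upstream; the background includes all mutations, including
#' frequency > 1e-3 ones.
#'
#' @param hap_site_freqs Numeric vector of haplotype-site frequencies.
#' @param background_freqs Numeric vector of non-haplotype-site frequencies.
#' @param site_threshold Switch between per-site and distribution modes.
#' @return For the per-site mode, `data.frame` with `frequency`, `p`,
#'   `p_adj`; for the distribution mode, list with `mode`, `p`,
#'   `fold` (ratio of mean frequencies).
#' @export
reversion_enrichment_test <- function(hap_site_freqs, background_freqs,
                                      site_threshold = 10L) {
  if (!length(background_freqs)) stop("empty background")
  if (length(hap_site_freqs) <= site_threshold) {
    # ties count as extreme (conservative for the discrete frequencies of
    # shallow data)
    p <- vapply(hap_site_freqs,
                function(f) mean(background_freqs >= f), numeric(1))
    data.frame(frequency = hap_site_freqs, p = p,
               p_adj = stats::p.adjust(p, method = "BH"))
  } else {
    wt <- stats::wilcox.test(hap_site_freqs, background_freqs,
                             alternative = "greater", exact = FALSE)
    list(mode = "rank-sum", p = wt$p.value,
         fold = mean(hap_site_freqs) / mean(background_freqs))
  }
}

#' Are mutations at haplotype sites reversions to the B6 allele?
#'
#' Per haplotype site, the fraction of alternative reads matching the B6
#' base, with an exact binomial test against the null that each of the three
#' possible alternative bases is equally likely (success probability 1/3,
#' upper tail).
#'
#' @param calls_at_hap_sites Call `data.frame` restricted to haplotype-site
#'   positions (multi-allelic: one row per observed alt).
#' @param hap Haplotype table for the strain.
#' @return `data.frame` with `position`, `b6_reads`, `total_reads`,
#'   `fraction_b6`, `p`.
#' @export
reversion_identity_test <- function(calls_at_hap_sites, hap) {
  res <- lapply(seq_len(nrow(hap)), function(i) {
    at <- calls_at_hap_sites[calls_at_hap_sites$position == hap$position[i], ,
                             drop = FALSE]
    total <- sum(at$alt_depth)
    b6 <- sum(at$alt_depth[at$alt == hap$b6_allele[i]])
    p <- if (total > 0)
      stats::binom.test(b6, total, p = 1 / 3, alternative = "greater")$p.value
    else NA_real_
    data.frame(position = hap$position[i], b6_reads = b6, total_reads = total,
               fraction_b6 = if (total > 0) b6 / total else NA_real_, p = p)
  })
  do.call(rbind, res)
}

#' Age-delta test for reversion alleles
#'
#' Per haplotype site, a direction-conditional one-sided empirical p-value:
#' for a site whose reversion frequency increases with age, the count of
#' background deltas at least as large as the site's delta over the
#' background size (symmetrically for decreasing sites; ties count as
#' extreme).
#' Benjamini-Hochberg correction is applied within the strain and
#' significance flagged at adjusted p < `alpha`. Deltas must be computed on
#' depth-normalized, NUMT-corrected frequencies.
#'
#' @param hap_site_deltas Named or plain numeric vector of per-site
#'   aged-minus-young frequency deltas.
#' @param background_deltas Numeric vector of non-haplotype-site deltas
#'   (same tissue).
#' @param alpha Significance cutoff on the adjusted p (default 0.02).
#' @return `data.frame` with `delta`, `direction`, `p`, `p_adj`,
#'   `significant`.
#' @export
reversion_age_delta_test <- function(hap_site_deltas, background_deltas,
                                     alpha = 0.02) {
  if (length(background_deltas) < 20L)
    warning("fewer than 20 background deltas: empirical p resolution is coarse")
  p <- vapply(hap_site_deltas, function(d) {
    # ties count as extreme, keeping the empirical p conservative when the
    # delta distribution is discrete
    if (d >= 0) mean(background_deltas >= d) else mean(background_deltas <= d)
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(delta = as.numeric(hap_site_deltas),
             direction = ifelse(hap_site_deltas >= 0, "increase", "decrease"),
             p = as.numeric(p), p_adj = p_adj,
             significant = p_adj < alpha)
}
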