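# Mutation-burden summaries: per-site frequency tracks, exact Poisson
# intervals, region probabilities, sliding-window hotspot scans,
# homopolymer-tract frequencies, and age/strain rate tests.

#' Per-position mutation frequency track
#'
#' Frequency at a position is the summed alternative-allele depth over all
#' alts at that position divided by the condition's duplex depth there.
#' Positions with zero depth are masked (`NA`) and excluded downstream.
#'
#' @param cond A `condition_table`.
#' @return `data.frame` with `position`, `depth`, `alt_sum`, `frequency`.
#' @export
site_frequencies <- function(cond) {
  L <- cond$genome_length
  alt_sum <- numeric(L)
  if (nrow(cond$calls)) {
    agg <- rowsum(cond$calls$alt_depth, cond$calls$position)
    alt_sum[as.integer(rownames(agg))] <- agg[, 1L]
  }
  frequency <- ifelse(cond$depth > 0, alt_sum / cond$depth, NA_real_)
  data.frame(position = seq_len(L), depth = cond$depth,
             alt_sum = alt_sum, frequency = frequency)
}

#' Exact Poisson confidence interval for a rate
#'
#' Chi-square-quantile interval on a count `k` with exposure `E`:
#' lower `qchisq(alpha/2, 2k)/2 / E` (0 when `k = 0`), upper
#' `qchisq(1 - alpha/2, 2k + 2)/2 / E`.
#'
#' @param k Event count.
#' @param exposure Exposure (e.g. total duplex depth).
#' @param alpha Two-sided error rate.
#' @return Named vector `c(lower, upper)`.
#' @export
poisson_ci <- function(k, exposure = 1, alpha = 0.05) {
  lower <- if (k == 0) 0 else stats::qchisq(alpha / 2, 2 * k) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2
  c(lower = lower / exposure, upper = upper / exposure)
}

#' Average mutation frequency with a 95 percent Poisson interval
#'
#' Reports both the mean of per-position frequencies and the pooled
#' frequency (total alternative depth / total depth); the exact Poisson
#' interval is computed on the total mutation count with total depth as
#' exposure, scaled to the frequency axis.
#'
#' @param cond A `condition_table`.
#' @param alpha Two-sided error rate (default 0.05 for a 95 percent CI).
#' @return List with `condition`, `mean`, `pooled`, `ci` (lower/upper),
#'   `count`, `exposure`.
#' @export
mean_frequency_with_ci <- function(cond, alpha = 0.05) {
  sf <- site_frequencies(cond)
  ok <- !is.na(sf$frequency)
  if (!any(ok)) stop("all positions are masked")
  k <- sum(sf$alt_sum[ok])
  E <- sum(sf$depth[ok])
  list(condition = paste(cond$strain, cond$tissue, cond$age, sep = "_"),
       mean = mean(sf$frequency[ok]),
       pooled = k / E,
       ci = poisson_ci(k, E, alpha),
       count = k, exposure = E)
}

#' Region mutation probability
#'
#' Total mutation count in a region kind normalized by the region length in
#' bp multiplied by the average duplex depth across the region: mutations
#' per bp per duplex read.
#'
#' @param cond A `condition_table`.
#' @param ann An [mt_annotation()].
#' @param kind Region kind (see [classify_region()]).
#' @export
region_mutation_probability <- function(cond, ann, kind) {
  kinds <- .region_kind_track(ann)
  pos <- which(kinds == kind)
  if (!length(pos)) stop("region '", kind, "' is empty")
  mean_depth <- mean(cond$depth[pos])
  if (mean_depth == 0) stop("zero mean depth in region '", kind, "'")
  count <- sum(cond$calls$alt_depth[cond$calls$position %in% pos])
  count / (length(pos) * mean_depth)
}

#' Pooled mutation frequency over a (possibly wrapping) span
#'
#' Sum of mutations across the span divided by the sum of the duplex depth
#' across its positions; used for homopolymer tracts where per-position
#' placement of indels is ambiguous.
#'
#' @param cond A `condition_table`.
#' @param span `c(start, end)`; `start > end` wraps the circular origin.
#' @export
homopolymer_region_frequency <- function(cond, span) {
  L <- cond$genome_length
  pos <- if (span[1] <= span[2]) seq.int(span[1], span[2])
         else c(seq.int(span[1], L), seq.int(1L, span[2]))
  d <- sum(cond$depth[pos])
  if (d == 0) return(0)
  sum(cond$calls$alt_depth[cond$calls$position %in% pos]) / d
}

#' Sliding-window mutation-frequency scan
#'
#' Mean of per-position frequencies in windows of `width` bp advanced by
#' `step` bp; windows wrap the circular origin so the whole genome is tiled.
#' High-frequency filtering is expected upstream.
#'
#' @param cond A `condition_table`.
#' @param width Window width in bp (default 150).
#' @param step Step in bp (default 1, i.e. maximally sliding).
#' @return `data.frame` with `start`, `end`, `mean_frequency`, plus the
#'   condition labels.
#' @export
sliding_window_scan <- function(cond, width = 150L, step = 1L) {
  L <- cond$genome_length
  if (width > L) stop("window width exceeds genome length")
  sf <- site_frequencies(cond)
  f <- sf$frequency
  ok <- as.numeric(!is.na(f))
  f[is.na(f)] <- 0
  # circular rolling mean via cumulative sums over the doubled track
  f2 <- cumsum(c(0, f, f))
  ok2 <- cumsum(c(0, ok, ok))
  starts <- seq.int(1L, L, by = step)
  ends <- starts + width - 1L
  num <- f2[ends + 1L] - f2[starts]
  den <- ok2[ends + 1L] - ok2[starts]
  data.frame(start = starts, end = .wrap_pos(ends, L),
             mean_frequency = ifelse(den > 0, num / den, NA_real_),
             strain = cond$strain, tissue = cond$tissue, age = cond$age,
             stringsAsFactors = FALSE)
}

# total retained mutation count and total-depth exposure of a condition
.cond_count_exposure <- function(cond) {
  c(count = sum(cond$calls$alt_depth), exposure = sum(cond$depth))
}

#' Age-associated mutation-rate test
#'
#' Poisson generalized linear model with logarithmic link on the total
#' mutation counts of the young and aged tables, with log total depth as the
#' exposure offset and age as covariate. With two groups the model is
#' saturated, so the estimate equals the closed-form rate ratio
#' `(k_aged/E_aged) / (k_young/E_young)`.
#'
#' @param young,aged `condition_table`s sharing strain and tissue.
#' @return List with `rate_ratio`, `p` (Wald), `ci` (95 percent, Wald scale).
#' @export
age_rate_test <- function(young, aged) {
  if (young$strain != aged$strain || young$tissue != aged$tissue)
    stop("young and aged tables must share strain and tissue")
  ky <- .cond_count_exposure(young); ka <- .cond_count_exposure(aged)
  if (ky[["count"]] == 0 && ka[["count"]] == 0)
    stop("zero mutation counts in both age groups")
  df <- data.frame(count = c(ky[["count"]], ka[["count"]]),
                   exposure = c(ky[["exposure"]], ka[["exposure"]]),
                   age = factor(c("young", "aged"), levels = c("young", "aged")))
  fit <- stats::glm(count ~ age + offset(log(exposure)),
                    family = stats::poisson(link = "log"), data = df)
  co <- summary(fit)$coefficients["ageaged", ]
  list(rate_ratio = exp(unname(co["Estimate"])),
       p = unname(co["Pr(>|z|)"]),
       ci = exp(unname(co["Estimate"]) + c(-1, 1) * 1.96 * unname(co["Std. Error"])))
}

#' Strain-specific mutation-rate contrasts versus B6
#'
#' Log-link Poisson regression of per-condition mutation counts on strain
#' indicators with log-depth offsets; every non-baseline strain is
#' contrasted against B6.
#'
#' @param conditions List of `condition_table`s (one or more per strain).
#' @param baseline Baseline strain (default `"B6"`).
#' @return `data.frame` with `strain`, `rate_ratio`, `p`.
#' @export
strain_rate_test <- function(conditions, baseline = "B6") {
  strains <- vapply(conditions, function(x) x$strain, character(1))
  if (!baseline %in% strains) stop("baseline strain '", baseline, "' missing")
  if (length(unique(strains)) < 2L) stop("need at least two strains")
  ce <- t(vapply(conditions, .cond_count_exposure, numeric(2)))
  df <- data.frame(count = ce[, "count"], exposure = ce[, "exposure"],
                   strain = stats::relevel(factor(strains), ref = baseline))
  fit <- stats::glm(count ~ strain + offset(log(exposure)),
                    family = stats::poisson(link = "log"), data = df)
  co <- summary(fit)$coefficients
  rows <- grep("^strain", rownames(co), value = TRUE)
  data.frame(strain = sub("^strain", "", rows),
             rate_ratio = exp(unname(co[rows, "Estimate"])),
             p = unname(co[rows, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}

#' Percentage of genome positions carrying a retained mutation
#'
#' @param cond A `condition_table` (depth-normalized upstream if comparing
#'   across conditions).
#' @return Percentage in `[0, 100]`.
#' @export
percent_bp_mutated <- function(cond) {
  100 * length(unique(cond$calls$position)) / cond$genome_length
}

#' Young-to-aged difference in percent bp mutated
#' @param young,aged `condition_table`s.
#' @return `aged - young` difference in percentage points.
#' @export
percent_bp_delta <- function(young, aged) {
  percent_bp_mutated(aged) - percent_bp_mutated(young)
}
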