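# Reading, validation, filtering and aggregation of per-site duplex
# variant calls.
#
# A call table is a data.frame with columns:
#   position (1-based), ref, alt (VCF-style anchored alleles),
#   alt_depth, depth (duplex read counts), sample_id
# A sample couples a call table with a dense per-position depth track and
# its metadata row (strain, tissue, age, replicate).

.call_cols <- c("position", "ref", "alt", "alt_depth", "depth", "sample_id")

.validate_calls <- function(calls) {
  miss <- setdiff(.call_cols, names(calls))
  if (length(miss)) stop("call table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(calls) == 0L) return(invisible(calls))
  bad <- which(calls$alt_depth <= 0)
  if (length(bad))
    stop("alt_depth must be positive; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(calls$alt_depth > calls$depth)
  if (length(bad))
    stop("alt_depth exceeds depth; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(calls$ref == calls$alt)
  if (length(bad))
    stop("ref equals alt; offending row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  if (any(calls$position < 1))
    stop("malformed coordinates: positions must be >= 1")
  invisible(calls)
}

# Left-anchor and parsimony-trim a ref/alt pair; returns new (position, ref, alt).
.trim_alleles <- function(position, ref, alt) {
  # drop shared suffix (keep at least one base each)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # drop shared prefix, advancing the anchor
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    position <- position + 1L
  }
  list(position = position, ref = ref, alt = alt)
}

#' Read per-site duplex variant calls
#'
#' @param path File path.
#' @param dialect `"tsv"` (columns `position`, `ref`, `alt`, `alt_depth`,
#'   `depth`, `sample_id`) or `"vcf"` (VCF 4.x; one sample per file).
#' @param depth_field,alt_depth_field INFO field names carrying the total and
#'   alternative duplex depths for the VCF dialect.
#' @param sample_id Overrides the sample identifier (defaults to the VCF
#'   sample name or the file base name).
#' @return Normalized call `data.frame`; indels are left-anchored and
#'   parsimony-trimmed.
#' @export
read_calls <- function(path, dialect = c("tsv", "vcf"),
                       depth_field = "DP", alt_depth_field = "AD",
                       sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    calls <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    vcf <- VariantAnnotation::readVcf(path)
    info <- VariantAnnotation::info(vcf)
    if (!all(c(depth_field, alt_depth_field) %in% names(info)))
      stop("VCF lacks INFO field(s): ",
           paste(setdiff(c(depth_field, alt_depth_field), names(info)), collapse = ", "))
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- as.character(unlist(rr$ALT))
    if (length(alt) != length(rr))
      stop("multi-allelic VCF records are not supported; split them first")
    if (is.null(sample_id)) {
      sn <- colnames(vcf)
      sample_id <- if (length(sn)) sn[1] else sub("\\.vcf$", "", basename(path))
    }
    calls <- data.frame(
      position = BiocGenerics::start(rr),
      ref = as.character(rr$REF),
      alt = alt,
      alt_depth = as.numeric(info[[alt_depth_field]]),
      depth = as.numeric(info[[depth_field]]),
      sample_id = sample_id,
      stringsAsFactors = FALSE)
  }
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  calls$position <- as.integer(calls$position)
  .validate_calls(calls)
  # normalize indel representation
  multi <- which(nchar(calls$ref) > 1L | nchar(calls$alt) > 1L)
  for (i in multi) {
    t <- .trim_alleles(calls$position[i], calls$ref[i], calls$alt[i])
    calls$position[i] <- t$position
    calls$ref[i] <- t$ref
    calls$alt[i] <- t$alt
  }
  rownames(calls) <- NULL
  calls
}

#' Write a call table as TSV
#' @param calls Call `data.frame`.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls[, .call_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense per-position depth track
#'
#' TSV with columns `position`, `depth` covering every genome position.
#' @param path File path.
#' @return Numeric vector indexed by position.
#' @export
read_depth_track <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "depth") %in% names(d)))
    stop("depth track must have columns position, depth")
  out <- numeric(max(d$position))
  out[d$position] <- d$depth
  out
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `strain`, `tissue`, `age`, `replicate`.
#' @param path File path.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "strain", "tissue", "age", "replicate")
  miss <- setdiff(req, names(ss))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  key <- paste(ss$strain, ss$tissue, ss$age, ss$replicate)
  if (anyDuplicated(key)) stop("(strain, tissue, age, replicate) must be unique")
  ss
}

#' Read a per-strain haplotype-site table
#'
#' TSV with columns `strain`, `position`, `b6_allele`, `conplastic_allele`
#' and optionally `annotation`.
#' @param path File path.
#' @export
read_haplotypes <- function(path) {
  hap <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain", "position", "b6_allele", "conplastic_allele")
  miss <- setdiff(req, names(hap))
  if (length(miss)) stop("haplotype table missing columns: ", paste(miss, collapse = ", "))
  if (any(duplicated(hap[, c("strain", "position")])))
    stop("haplotype positions must be unique within a strain")
  hap
}

#' Remove calls at conplastic haplotype sites
#'
#' @param calls Call `data.frame`.
#' @param hap Haplotype table for one strain (see [read_haplotypes()]).
#' @return List with `kept` and `removed` call tables; the removed set feeds
#'   the reversion analysis.
#' @export
filter_haplotype_sites <- function(calls, hap) {
  at <- calls$position %in% hap$position
  list(kept = calls[!at, , drop = FALSE], removed = calls[at, , drop = FALSE])
}

#' Remove calls above a mutation-frequency threshold
#'
#' The comparison is strict (`frequency > threshold` is removed), so a call at
#' exactly the threshold is retained.
#'
#' @param x Call `data.frame` (with `depth`) or [condition_table].
#' @param threshold Frequency cutoff, default `1e-3`.
#' @export
filter_high_frequency <- function(x, threshold = 1e-3) {
  stopifnot(threshold > 0)
  UseMethod("filter_high_frequency")
}

#' @export
filter_high_frequency.data.frame <- function(x, threshold = 1e-3) {
  if (!nrow(x)) return(x)
  x[x$alt_depth / x$depth <= threshold, , drop = FALSE]
}

#' @export
filter_high_frequency.condition_table <- function(x, threshold = 1e-3) {
  if (nrow(x$calls)) {
    freq <- x$calls$alt_depth / x$depth[x$calls$position]
    x$calls <- x$calls[freq <= threshold, , drop = FALSE]
  }
  x
}

#' Select de novo mutations
#'
#' Operational proxy for newly arisen mutations: keeps calls with
#' `alt_depth < 100` and sample-level frequency `< 0.01`; each surviving
#' (position, alt) contributes unit weight regardless of its depth.
#'
#' @param calls Call `data.frame`.
#' @param max_alt_depth,max_frequency Clause cutoffs (strict `<`).
#' @return The surviving calls with a `weight` column of 1s.
#' @export
select_de_novo <- function(calls, max_alt_depth = 100, max_frequency = 0.01) {
  keep <- calls$alt_depth < max_alt_depth &
    (calls$alt_depth / calls$depth) < max_frequency
  out <- calls[keep, , drop = FALSE]
  out$weight <- rep(1, nrow(out))
  out
}

#' Bundle one sample's calls, depth track and metadata
#'
#' @param calls Call `data.frame` for the sample.
#' @param depth Dense numeric vector of per-position duplex depth
#'   (length = genome length).
#' @param meta One-row `data.frame` with `sample_id`, `strain`, `tissue`,
#'   `age`, `replicate`.
#' @export
mt_sample <- function(calls, depth, meta) {
  .validate_calls(calls)
  stopifnot(is.numeric(depth), nrow(meta) == 1L)
  if (nrow(calls) && any(calls$position > length(depth)))
    stop("call position beyond depth track")
  structure(list(calls = calls, depth = as.numeric(depth), meta = meta),
            class = "mt_sample")
}

#' Aggregate replicate samples into a condition table
#'
#' Depths and alternative-allele depths are summed per position and per
#' (position, ref, alt) across the replicates of one strain x tissue x age
#' cell; sample provenance is retained.
#'
#' @param samples List of [mt_sample()] objects sharing one condition.
#' @return A `condition_table`: list with `strain`, `tissue`, `age`,
#'   `depth` (dense per-position vector), `calls` (summed per
#'   position/ref/alt), `sample_ids`, `genome_length`.
#' @export
aggregate_condition <- function(samples) {
  if (!length(samples)) stop("empty sample list")
  metas <- do.call(rbind, lapply(samples, function(s) s$meta))
  key <- unique(metas[, c("strain", "tissue", "age")])
  if (nrow(key) != 1L) stop("samples span multiple conditions")
  lens <- vapply(samples, function(s) length(s$depth), integer(1))
  if (length(unique(lens)) != 1L) stop("depth tracks differ in length")
  depth <- Reduce(`+`, lapply(samples, function(s) s$depth))
  allcalls <- data.table::rbindlist(lapply(samples, function(s) s$calls))
  if (nrow(allcalls)) {
    position <- ref <- alt <- alt_depth <- NULL  # NSE bindings
    calls <- allcalls[, list(alt_depth = sum(alt_depth)),
                      by = list(position, ref, alt)]
    data.table::setorder(calls, position, alt)
    calls <- as.data.frame(calls)
  } else {
    calls <- data.frame(position = integer(), ref = character(),
                        alt = character(), alt_depth = numeric(),
                        stringsAsFactors = FALSE)
  }
  structure(list(strain = key$strain, tissue = key$tissue, age = key$age,
                 depth = depth, calls = calls,
                 sample_ids = metas$sample_id, genome_length = lens[1]),
            class = "condition_table")
}

#' @export
print.condition_table <- function(x, ...) {
  cat("condition_table:", x$strain, x$tissue, x$age, "|",
      length(x$sample_ids), "sample(s),", nrow(x$calls), "call record(s)\n")
  invisible(x)
}

# Per-call mutation frequency within a condition table.
.cond_call_freq <- function(cond) {
  if (!nrow(cond$calls)) return(numeric(0))
  cond$calls$alt_depth / cond$depth[cond$calls$position]
}

#' Normalize sequencing depth across condition tables
#'
#' `mode = "thin-to-min"` rescales every condition to the per-position
#' minimum depth across conditions by hypergeometric thinning (sampling the
#' retained reads without replacement), which leaves the expected frequency
#' unchanged. `mode = "none"` returns the input (frequencies are already
#' self-normalizing as alt/depth). Positions with zero depth in any condition
#' are masked (depth 0, calls dropped) in all conditions.
#'
#' @param tables List of `condition_table`s over the same genome.
#' @param mode `"none"` or `"thin-to-min"`.
#' @param seed Integer seed making the thinning reproducible.
#' @export
normalize_depth_across_conditions <- function(tables, mode = c("none", "thin-to-min"),
                                              seed = 1L) {
  mode <- match.arg(mode)
  lens <- vapply(tables, function(t) t$genome_length, numeric(1))
  if (length(unique(lens)) != 1L) stop("condition tables differ in genome length")
  depths <- do.call(cbind, lapply(tables, function(t) t$depth))
  masked <- apply(depths == 0, 1L, any)
  if (mode == "none" && !any(masked)) return(tables)
  min_depth <- apply(depths, 1L, min)
  out <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    if (any(masked)) {
      t$depth[masked] <- 0
      if (nrow(t$calls)) t$calls <- t$calls[!masked[t$calls$position], , drop = FALSE]
    }
    t
  })
  if (mode == "none") return(out)
  set.seed(seed)
  lapply(out, function(t) {
    if (nrow(t$calls)) {
      d <- t$depth[t$calls$position]
      k <- min_depth[t$calls$position]
      newalt <- stats::rhyper(nrow(t$calls), m = t$calls$alt_depth,
                              n = d - t$calls$alt_depth, k = k)
      t$calls$alt_depth <- newalt
      t$calls <- t$calls[t$calls$alt_depth > 0, , drop = FALSE]
    }
    t$depth <- ifelse(t$depth > 0, min_depth, 0)
    t
  })
}
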