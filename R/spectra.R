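# Strand-collapsed mutation classes, per-class frequencies, trinucleotide
# spectra of de novo calls, and age-association tests.

#' The eight strand-collapsed mutation classes
#'
#' Six substitution classes keyed by their purine-reference representation
#' (each pools a substitution with its reverse complement, e.g. `G>T` with
#' `C>A`) plus `INS` and `DEL`.
#' @export
mutation_classes <- function() {
  c("G>A/C>T", "G>T/C>A", "G>C/C>G", "T>C/A>G", "T>A/A>T", "T>G/A>C",
    "INS", "DEL")
}

# reference bases compatible with each SNV class (plus-strand)
.class_ref_pair <- list(
  "G>A/C>T" = c("G", "C"), "G>T/C>A" = c("G", "C"), "G>C/C>G" = c("G", "C"),
  "T>C/A>G" = c("T", "A"), "T>A/A>T" = c("T", "A"), "T>G/A>C" = c("T", "A"))

# for an SNV class and a reference base, the alt base it implies
.class_alt_for_ref <- function(class, ref) {
  parts <- strsplit(sub("/.*", "", class), ">")[[1]]  # purine-ref representation
  if (ref == parts[1]) parts[2] else .complement(parts[2])
}

#' Classify a mutation into one of the eight strand-collapsed classes
#'
#' @param ref,alt Allele strings (VCF-anchored for indels). Vectorized.
#' @return Character vector of classes (see [mutation_classes()]).
#' @export
classify_mutation <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  lr <- nchar(ref); la <- nchar(alt)
  out <- character(n)
  out[la > lr] <- "INS"
  out[la < lr] <- "DEL"
  snv <- la == lr & lr == 1L
  if (any(la == lr & lr > 1L))
    stop("equal-length multi-base substitutions (MNVs) are not supported")
  if (any(snv)) {
    r <- ref[snv]; a <- alt[snv]
    if (any(r == a)) stop("ref equals alt")
    pyr <- r %in% c("C", "A")
    r[pyr] <- .complement(r[pyr]); a[pyr] <- .complement(a[pyr])
    out[snv] <- paste0(r, ">", a, "/", .complement(r), ">", .complement(a))
  }
  bad <- !out %in% mutation_classes()
  if (any(bad)) stop("invalid alleles: ", paste(ref[bad], alt[bad], collapse = "; "))
  out
}

#' Convert purine-reference class keys to the pyrimidine (COSMIC) convention
#' @param class Character vector of class keys from [mutation_classes()].
#' @export
to_pyrimidine_key <- function(class) {
  map <- c("G>A/C>T" = "C>T", "G>T/C>A" = "C>A", "G>C/C>G" = "C>G",
           "T>C/A>G" = "T>C", "T>A/A>T" = "T>A", "T>G/A>C" = "T>G",
           "INS" = "INS", "DEL" = "DEL")
  unname(map[class])
}

#' Per-class mutation frequencies for a condition
#'
#' SNV classes are normalized by the duplex depth summed over positions whose
#' reference base belongs to the class's strand-collapsed base pair; INS and
#' DEL are normalized by the total duplex depth.
#'
#' @param cond A `condition_table`.
#' @param ann An [mt_annotation()].
#' @param weighting `"alt-depth"` counts each call by its summed alternative
#'   allele depth (the aggregation convention of the burden analyses);
#'   `"unit"` scores each (position, alt) once.
#' @return `data.frame` with `class`, `count`, `exposure`, `frequency`.
#' @export
class_frequencies <- function(cond, ann, weighting = c("alt-depth", "unit")) {
  weighting <- match.arg(weighting)
  classes <- mutation_classes()
  refbase <- .seq_chars(ann)
  total_depth <- sum(cond$depth)
  pair_depth <- c(
    GC = sum(cond$depth[refbase %in% c("G", "C")]),
    TA = sum(cond$depth[refbase %in% c("T", "A")]))
  calls <- cond$calls
  w <- if (nrow(calls) == 0L) numeric(0)
       else if (weighting == "alt-depth") calls$alt_depth else rep(1, nrow(calls))
  cl <- if (nrow(calls)) classify_mutation(calls$ref, calls$alt) else character(0)
  count <- vapply(classes, function(k) sum(w[cl == k]), numeric(1))
  exposure <- vapply(classes, function(k) {
    if (k %in% c("INS", "DEL")) total_depth
    else if (all(.class_ref_pair[[k]] %in% c("G", "C"))) pair_depth[["GC"]]
    else pair_depth[["TA"]]
  }, numeric(1))
  if (any(count > 0 & exposure == 0))
    stop("class with calls but zero compatible reference-base depth")
  data.frame(class = classes, count = unname(count), exposure = unname(exposure),
             frequency = ifelse(exposure > 0, count / exposure, NA_real_),
             stringsAsFactors = FALSE)
}

#' Trinucleotide spectrum of de novo SNVs
#'
#' Context is read from the reference sequence at positions -1, 0, +1
#' (circular). Purine-reference calls are reverse-complemented into the
#' pyrimidine-centred facet, so e.g. a `G>A` at context `CGT` is pooled into
#' the `ACG` cell of the `G>A/C>T` class. Each mutation is scored once.
#'
#' @param de_novo_calls Calls that passed [select_de_novo()]; SNVs only.
#' @param ann An [mt_annotation()].
#' @return List with `spectrum` (`data.frame`: `class`, `context`,
#'   `count`, `fraction`) and `total` (de novo SNV count). Fractions sum to 1
#'   over all cells when `total > 0`.
#' @export
trinucleotide_spectrum <- function(de_novo_calls, ann) {
  snv <- de_novo_calls[nchar(de_novo_calls$ref) == 1L &
                       nchar(de_novo_calls$alt) == 1L, , drop = FALSE]
  if (nrow(snv) == 0L) {
    return(list(spectrum = data.frame(class = character(), context = character(),
                                      count = numeric(), fraction = numeric(),
                                      stringsAsFactors = FALSE),
                total = 0L))
  }
  chars <- .seq_chars(ann)
  len <- ann$length
  up <- chars[.wrap_pos(snv$position - 1L, len)]
  mid <- chars[.wrap_pos(snv$position, len)]
  down <- chars[.wrap_pos(snv$position + 1L, len)]
  ctx <- paste0(up, mid, down)
  pur <- mid %in% c("G", "A")
  ctx[pur] <- .revcomp(ctx[pur])
  cls <- classify_mutation(snv$ref, snv$alt)
  tab <- data.table::data.table(class = cls, context = ctx)
  class <- context <- NULL
  agg <- tab[, list(count = .N), by = list(class, context)]
  data.table::setorder(agg, class, context)
  agg <- as.data.frame(agg)
  agg$fraction <- agg$count / nrow(snv)
  list(spectrum = agg, total = nrow(snv))
}

#' Test each mutation class for an age association
#'
#' Per class, a 2x2 Fisher exact test of (class count vs all-other count) x
#' (young vs aged), Benjamini-Hochberg corrected across the eight classes.
#'
#' @param young_counts,aged_counts Named numeric vectors of per-class counts
#'   (names from [mutation_classes()]).
#' @return `data.frame` with `class`, `odds_ratio`, `p`, `p_adj`.
#' @export
age_spectrum_test <- function(young_counts, aged_counts) {
  classes <- mutation_classes()
  y <- young_counts[classes]; a <- aged_counts[classes]
  y[is.na(y)] <- 0; a[is.na(a)] <- 0
  res <- lapply(classes, function(k) {
    m <- matrix(c(a[[k]], sum(a) - a[[k]], y[[k]], sum(y) - y[[k]]), nrow = 2)
    ft <- stats::fisher.test(m)
    data.frame(class = k, odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Export the condition x class mutation-type count matrix
#'
#' The matrix consumed by external mutational-signature extraction. Counts
#' follow the alt-depth aggregation convention; the caller is expected to
#' have removed high-frequency calls (frequency > 1e-3) upstream.
#'
#' @param conditions List of `condition_table`s.
#' @param path Optional TSV output path.
#' @param weighting See [class_frequencies()].
#' @return Numeric matrix (conditions x 8 classes) with row names
#'   `strain_tissue_age`, invisibly written to `path` when given.
#' @export
export_signature_matrix <- function(conditions, path = NULL,
                                    weighting = c("alt-depth", "unit")) {
  weighting <- match.arg(weighting)
  classes <- mutation_classes()
  rows <- lapply(conditions, function(cond) {
    calls <- cond$calls
    if (nrow(calls) == 0L) {
      warning("condition ", cond$strain, "_", cond$tissue, "_", cond$age,
              " has no calls; emitting a zero row")
      return(stats::setNames(rep(0, length(classes)), classes))
    }
    w <- if (weighting == "alt-depth") calls$alt_depth else rep(1, nrow(calls))
    cl <- classify_mutation(calls$ref, calls$alt)
    vapply(classes, function(k) sum(w[cl == k]), numeric(1))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(conditions, function(cond)
    paste(cond$strain, cond$tissue, cond$age, sep = "_"), character(1))
  if (!is.null(path)) {
    df <- data.frame(condition = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  m
}
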