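# Circular mitochondrial genome model: sequence, typed features, vertebrate
# mitochondrial translation, and synonymous/non-synonymous classification.

.mt_kinds <- c("protein", "tRNA", "rRNA", "D-loop", "OriL", "other-noncoding")

# Region priority used when features overlap (highest wins).
.mt_region_priority <- c("OriL" = 1, "D-loop" = 2, "tRNA" = 3, "rRNA" = 4,
                         "protein" = 5, "other-noncoding" = 6)

.mito_code <- function() Biostrings::getGeneticCode("SGC1")

.revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Construct a mitochondrial genome annotation
#'
#' Bundles a single circular reference sequence with typed features and the
#' vertebrate mitochondrial genetic code (NCBI table 2: `TGA` = Trp,
#' `ATA` = Met, `AGA`/`AGG` = stop).
#'
#' @param sequence Upper-case nucleotide string over `{A,C,G,T}`.
#' @param features `data.frame` with columns `name`, `kind`, `start`, `end`,
#'   `strand`. Coordinates are 1-based inclusive. A feature with
#'   `start > end` wraps through the circular origin (position `length` to 1)
#'   and is flagged in the `wraps` column of the stored table.
#' @param incomplete_stop Character vector of protein feature names whose
#'   annotated span ends in a partial, polyadenylation-completed stop codon;
#'   the trailing partial codon is dropped from translation and site counting.
#' @return An object of class `mt_annotation`.
#' @export
mt_annotation <- function(sequence, features = NULL, incomplete_stop = character()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("sequence contains non-ACGT symbols")
  len <- nchar(sequence)
  if (is.null(features)) {
    features <- data.frame(name = character(), kind = character(),
                           start = integer(), end = integer(),
                           strand = character(), stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  req <- c("name", "kind", "start", "end", "strand")
  if (!all(req %in% names(features)))
    stop("features must have columns: ", paste(req, collapse = ", "))
  if (nrow(features)) {
    if (anyDuplicated(features$name))
      stop("feature names must be unique")
    bad <- setdiff(unique(features$kind), .mt_kinds)
    if (length(bad))
      stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
    if (any(features$start < 1L) || any(features$start > len) ||
        any(features$end < 1L) || any(features$end > len))
      stop("feature coordinates outside [1, genome length]")
    if (!all(features$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  features$wraps <- if (nrow(features)) features$start > features$end else logical()
  ann <- structure(
    list(length = len, sequence = sequence, features = features,
         code = .mito_code(), incomplete_stop = incomplete_stop),
    class = "mt_annotation")
  # check protein spans are codon-sized up front
  prot <- features[features$kind == "protein", , drop = FALSE]
  if (nrow(prot)) {
    for (g in prot$name) {
      n <- length(.feature_positions(ann, g))
      if (n %% 3L != 0L && !(g %in% incomplete_stop))
        stop("protein feature '", g, "' span (", n,
             " bp) not divisible by 3 and not flagged incomplete_stop")
    }
  }
  ann
}

#' @export
print.mt_annotation <- function(x, ...) {
  cat("mt_annotation:", x$length, "bp circular genome\n")
  if (nrow(x$features)) {
    tab <- table(x$features$kind)
    cat("features:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else cat("features: none\n")
  invisible(x)
}

# Wrap positions onto the circle (1-based).
.wrap_pos <- function(pos, len) ((pos - 1L) %% len) + 1L

# Genomic positions (5'->3' on the plus strand of the annotated span) for a
# named feature, honouring circular wrap-around.
.feature_positions <- function(ann, gene) {
  f <- ann$features[ann$features$name == gene, , drop = FALSE]
  if (!nrow(f)) stop("unknown feature: ", gene)
  if (f$wraps) c(seq.int(f$start, ann$length), seq.int(1L, f$end))
  else seq.int(f$start, f$end)
}

.seq_at <- function(ann, positions) {
  positions <- .wrap_pos(positions, ann$length)
  vapply(positions, function(p) substr(ann$sequence, p, p), character(1))
}

# Fast single-character access for vectors of positions.
.seq_chars <- function(ann) strsplit(ann$sequence, "")[[1]]

#' Load an annotated mitochondrial genome from files
#'
#' Reads a single-record FASTA plus a feature file. The feature dialect is
#' auto-detected from the extension: `.bed` is BED (0-based half-open,
#' converted to 1-based inclusive on read), anything `.gff`/`.gff3` is GFF3
#' (1-based inclusive, used as-is). BED feature names carry the kind as
#' `kind:name` (e.g. `protein:MT-ND2`); GFF3 uses the `type` column (standard
#' types `CDS`/`gene` map to `protein`, `D_loop`/`rep_origin` to
#' `D-loop`/`OriL`) and the `Name`/`ID` attribute.
#'
#' @param fasta_path Path to a FASTA file with exactly one sequence.
#' @param features_path Path to a BED or GFF3 feature file.
#' @param incomplete_stop Protein names with polyadenylation-completed stops.
#' @return An [mt_annotation()] object. Feature counts per kind are reported
#'   via `message()`.
#' @export
load_annotation <- function(fasta_path, features_path, incomplete_stop = character()) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L)
    stop("FASTA must hold exactly one sequence, found ", length(seqs))
  sequence <- as.character(seqs[[1]])

  ext <- tolower(tools::file_ext(features_path))
  info <- file.info(features_path)
  empty <- is.na(info$size) || info$size == 0 ||
    !nzchar(paste(readLines(features_path, warn = FALSE), collapse = ""))
  if (empty) {
    warning("features file is empty; annotation has zero features")
    return(mt_annotation(sequence))
  }
  if (ext == "bed") {
    gr <- rtracklayer::import(features_path, format = "BED")
    nm <- if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
    kind <- sub(":.*$", "", nm)
    name <- ifelse(grepl(":", nm), sub("^[^:]*:", "", nm), nm)
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "+"
    features <- data.frame(
      name = name, kind = kind,
      start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
      strand = strand, stringsAsFactors = FALSE)
  } else if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(features_path, format = "GFF3")
    type <- as.character(gr$type)
    map <- c(CDS = "protein", gene = "protein", protein = "protein",
             tRNA = "tRNA", rRNA = "rRNA",
             D_loop = "D-loop", "D-loop" = "D-loop",
             rep_origin = "OriL", OriL = "OriL",
             "other-noncoding" = "other-noncoding")
    if (any(!type %in% names(map)))
      stop("unknown feature kind(s): ",
           paste(setdiff(type, names(map)), collapse = ", "))
    kind <- unname(map[type])
    name <- if (!is.null(gr$Name)) as.character(gr$Name) else
      if (!is.null(gr$ID)) as.character(gr$ID) else
        paste0(kind, "_", seq_along(gr))
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "+"
    features <- data.frame(
      name = name, kind = kind,
      start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
      strand = strand, stringsAsFactors = FALSE)
  } else {
    stop("unrecognized feature file extension: .", ext)
  }
  ann <- mt_annotation(sequence, features, incomplete_stop = incomplete_stop)
  tab <- table(features$kind)
  message("loaded ", nrow(features), " features (",
          paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  ann
}

#' Classify a genome position into a region kind
#'
#' Overlapping features are resolved by the fixed priority
#' OriL > D-loop > tRNA > rRNA > protein; positions covered by no feature are
#' `other-noncoding`. The OriL-over-protein ordering keeps the replication
#' origin hotspot separate from the coding background it can overlap.
#'
#' @param ann An [mt_annotation()].
#' @param position Vector of 1-based positions.
#' @return Character vector of region kinds.
#' @export
classify_region <- function(ann, position) {
  if (any(position < 1L | position > ann$length))
    stop("position out of range [1, ", ann$length, "]")
  kinds <- .region_kind_track(ann)
  kinds[position]
}

# Per-position region kind for the whole genome (priority-resolved).
.region_kind_track <- function(ann) {
  kinds <- rep("other-noncoding", ann$length)
  prio <- rep(.mt_region_priority["other-noncoding"], ann$length)
  f <- ann$features
  if (nrow(f)) {
    ord <- order(-.mt_region_priority[f$kind])  # lowest priority first
    for (i in ord) {
      pos <- if (f$wraps[i]) c(seq.int(f$start[i], ann$length), seq.int(1L, f$end[i]))
             else seq.int(f$start[i], f$end[i])
      p <- .mt_region_priority[f$kind[i]]
      sel <- pos[p < prio[pos]]
      kinds[sel] <- f$kind[i]
      prio[sel] <- p
    }
  }
  kinds
}

# Strand-oriented CDS (character string) of a protein feature; drops the
# trailing partial codon for incomplete-stop genes.
.cds_string <- function(ann, gene) {
  f <- ann$features[ann$features$name == gene, , drop = FALSE]
  if (!nrow(f)) stop("unknown gene: ", gene)
  if (f$kind != "protein") stop("feature '", gene, "' is not a protein feature")
  pos <- .feature_positions(ann, gene)
  s <- paste(.seq_chars(ann)[.wrap_pos(pos, ann$length)], collapse = "")
  if (f$strand == "-") s <- .revcomp(s)
  if (gene %in% ann$incomplete_stop) {
    keep <- 3L * (nchar(s) %/% 3L)
    s <- substr(s, 1L, keep)
  }
  s
}

.codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a protein-coding feature
#'
#' Uses the vertebrate mitochondrial code; translation stops at (and
#' excludes) the first stop codon.
#'
#' @inheritParams classify_region
#' @param gene Name of a protein feature.
#' @return Amino-acid string.
#' @export
translate_cds <- function(ann, gene) {
  cds <- .cds_string(ann, gene)
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT symbols")
  aa <- unname(ann$code[.codons(cds)])
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

#' Count non-synonymous and synonymous sites in a gene
#'
#' Every codon position contributes fractional site counts: each of its three
#' possible point substitutions is classified under the vertebrate
#' mitochondrial code, and the position adds (non-synonymous fraction,
#' synonymous fraction) that sum to 1. Stop-gaining (and stop-losing) changes
#' count as non-synonymous. Consequently `N_sites + S_sites` equals the
#' gene's (codon-complete) coding length in bp.
#'
#' @inheritParams translate_cds
#' @return Named numeric vector `c(N = ..., S = ...)`.
#' @export
count_ns_sites <- function(ann, gene) {
  cds <- .cds_string(ann, gene)
  codons <- .codons(cds)
  code <- ann$code
  bases <- c("A", "C", "G", "T")
  n_syn <- 0
  for (cp in 1:3) {
    orig <- substr(codons, cp, cp)
    aa0 <- code[codons]
    for (b in bases) {
      mut <- codons
      substr(mut, cp, cp) <- b
      hit <- b != orig
      n_syn <- n_syn + sum(hit & code[mut] == aa0)
    }
  }
  s_sites <- n_syn / 3
  n_sites <- length(codons) * 3 - s_sites
  c(N = n_sites, S = s_sites)
}

#' Classify a single-nucleotide substitution
#'
#' Positions outside protein features (by feature membership, not region
#' priority) are `noncoding`; inside a protein feature the effect is
#' determined by the codon change under the feature's strand orientation.
#' Stop-gaining changes are reported as `nonsense` and are pooled with
#' `non-synonymous` by the selection machinery.
#'
#' @inheritParams classify_region
#' @param position 1-based position (scalar).
#' @param alt Alternative base on the plus strand.
#' @return A list with `position`, `gene`, `codon_index`, `effect`.
#' @export
classify_substitution <- function(ann, position, alt) {
  stopifnot(length(position) == 1L, length(alt) == 1L)
  if (!alt %in% c("A", "C", "G", "T")) stop("alt must be one of A,C,G,T")
  ref <- .seq_at(ann, position)
  if (alt == ref) stop("alt equals the reference base at position ", position)
  tab <- ns_effect_table(ann)
  row <- tab[tab$position == position & tab$alt == alt, , drop = FALSE]
  if (!nrow(row))
    return(list(position = position, gene = NA_character_,
                codon_index = NA_integer_, effect = "noncoding"))
  list(position = position, gene = row$gene[1],
       codon_index = row$codon_index[1], effect = row$effect[1])
}

#' Effect lookup table for all coding point substitutions
#'
#' Enumerates every (protein-coding position, alternative base) pair and its
#' effect under the vertebrate mitochondrial code. Positions covered by more
#' than one protein feature are attributed to the first such feature in the
#' annotation's feature order. The table is the vectorized backbone of the
#' selection module.
#'
#' @inheritParams classify_region
#' @return `data.frame` with columns `position`, `ref` (plus-strand), `alt`
#'   (plus-strand), `gene`, `codon_index`, `effect`
#'   (`synonymous`/`non-synonymous`/`nonsense`).
#' @export
ns_effect_table <- function(ann) {
  cache <- attr(ann, ".ns_effect_table")
  if (!is.null(cache)) return(cache)
  prot <- ann$features[ann$features$kind == "protein", , drop = FALSE]
  out <- vector("list", nrow(prot))
  seen <- integer(0)
  bases <- c("A", "C", "G", "T")
  code <- ann$code
  if (nrow(prot)) for (i in seq_len(nrow(prot))) {
    g <- prot$name[i]
    pos <- .wrap_pos(.feature_positions(ann, g), ann$length)
    cds <- .cds_string(ann, g)
    ncod <- nchar(cds) %/% 3L
    pos <- pos[seq_len(3L * ncod)]          # drop incomplete-stop tail
    if (prot$strand[i] == "-") {
      cds_index <- rev(seq_along(pos))      # genomic pos -> CDS coordinate
    } else cds_index <- seq_along(pos)
    new <- pos[!pos %in% seen]
    if (!length(new)) next
    keep <- !pos %in% seen
    codons <- .codons(cds)
    cidx <- (cds_index - 1L) %/% 3L + 1L
    cpos <- (cds_index - 1L) %% 3L + 1L
    cds_chars <- strsplit(cds, "")[[1]]
    # build per-position alt rows in CDS orientation
    ref_cds <- cds_chars[cds_index]
    aa0 <- code[codons[cidx]]
    res <- list()
    for (b in bases) {
      sel <- keep & ref_cds != b
      if (!any(sel)) next
      mut <- codons[cidx[sel]]
      substr(mut, cpos[sel], cpos[sel]) <- b
      aa1 <- code[mut]
      eff <- ifelse(aa1 == aa0[sel], "synonymous",
                    ifelse(aa1 == "*", "nonsense", "non-synonymous"))
      alt_plus <- if (prot$strand[i] == "-") .complement(b) else b
      res[[b]] <- data.frame(
        position = pos[sel],
        ref = if (prot$strand[i] == "-") .complement(ref_cds[sel]) else ref_cds[sel],
        alt = alt_plus, gene = g, codon_index = cidx[sel],
        effect = eff, stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, res)
    seen <- c(seen, new)
  }
  tab <- do.call(rbind, out)
  if (is.null(tab))
    tab <- data.frame(position = integer(), ref = character(),
                      alt = character(), gene = character(),
                      codon_index = integer(), effect = character(),
                      stringsAsFactors = FALSE)
  tab <- tab[order(tab$position, tab$alt), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Attach the coding-effect cache to an annotation
#'
#' Precomputes [ns_effect_table()] once and stores it on the object so the
#' burden/selection stages do not recompute it per call.
#' @inheritParams classify_region
#' @return The annotation with the cache attached.
#' @export
cache_effects <- function(ann) {
  attr(ann, ".ns_effect_table") <- ns_effect_table(ann)
  ann
}

#' Scan a frameshift indel for the first premature stop codon
#'
#' Applies a VCF-anchored insertion or deletion to the strand-oriented CDS,
#' translates the shifted frame, and reports the 1-based codon index of the
#' first stop plus how many amino acids the truncated product loses relative
#' to the unmutated protein.
#'
#' @inheritParams translate_cds
#' @param position 1-based genomic position of the anchor base.
#' @param ref,alt VCF-style anchored alleles on the plus strand; exactly one
#'   of them must be a prefix of the other (pure insertion or deletion).
#' @return List with `stop_codon_index` (NA if no stop before the CDS end),
#'   `truncation_aa`, and `no_stop`.
#' @export
frameshift_stop_scan <- function(ann, gene, position, ref, alt) {
  f <- ann$features[ann$features$name == gene, , drop = FALSE]
  if (!nrow(f) || f$kind != "protein") stop("unknown protein gene: ", gene)
  if (!(startsWith(ref, alt) || startsWith(alt, ref)) || ref == alt)
    stop("ref/alt must encode a pure anchored insertion or deletion")
  pos <- .wrap_pos(.feature_positions(ann, gene), ann$length)
  span <- position:(position + nchar(ref) - 1L)
  if (!all(span %in% pos)) stop("edit span not fully inside gene ", gene)
  cds <- .cds_string(ann, gene)
  # map the genomic edit span into CDS coordinates
  if (f$strand == "+") {
    i1 <- match(position, pos); i2 <- match(span[length(span)], pos)
    ref_c <- ref; alt_c <- alt
  } else {
    i1 <- match(span[length(span)], rev(pos)) # CDS runs 3'->5' on plus strand
    i1 <- i1  # first CDS base of the edited span
    i2 <- match(position, rev(pos))
    ref_c <- .revcomp(ref); alt_c <- .revcomp(alt)
  }
  lo <- min(i1, i2); hi <- max(i1, i2)
  if (substr(cds, lo, hi) != ref_c)
    stop("reference allele mismatch at CDS positions ", lo, "-", hi)
  mutated <- paste0(substr(cds, 1L, lo - 1L), alt_c,
                    substr(cds, hi + 1L, nchar(cds)))
  if (!startsWith(mutated, "ATG") && startsWith(cds, "ATG") && lo <= 3L)
    stop("indel removes the start codon")
  aa <- unname(ann$code[.codons(mutated)])
  stop_at <- which(aa == "*")
  wt_len <- nchar(translate_cds(ann, gene))
  if (!length(stop_at)) {
    return(list(stop_codon_index = NA_integer_,
                truncation_aa = NA_integer_, no_stop = TRUE))
  }
  idx <- stop_at[1]
  list(stop_codon_index = idx,
       truncation_aa = wt_len - (idx - 1L),
       no_stop = FALSE)
}
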