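# Synthetic duplex-sequencing-style data with the statistical structure the
# analysis assumes: negative-binomial duplex depth, position-specific rates
# with region/hotspot folds, 8-class mutation-type proportions, age
# fold-changes, frequency-dependent selection on non-synonymous calls,
# reversion enrichment at haplotype sites, and low-level NUMT read leakage.

# Deterministic 31-bit seed derived from a master seed and a stage/key label.
derive_seed <- function(master, key) {
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Simulation configuration
#'
#' Defaults state the world the analysis expects: a mitochondrial-genome-like
#' layout (13 proteins, 22 tRNAs, 2 rRNAs, one D-loop, one OriL), a
#' replication-error-dominated 8-class spectrum, a D-loop/OriL hotspot
#' structure (6.4x and 40x the coding background), an overall ~2x aged/young
#' fold concentrated in the clock-like classes, overdispersed duplex depth,
#' and conplastic strains whose haplotype-site counts mirror the study design
#' (AKR 1, ALR 3, FVB 2, NZB 91 sites; B6 none).
#'
#' @param genome_length Genome size in bp.
#' @param n_protein,n_trna,n_rrna Feature counts.
#' @param protein_codons Range of protein lengths in codons (span includes
#'   the stop codon).
#' @param trna_length,rrna_length,dloop_length,oril_length Feature sizes (bp);
#'   ranges where length 2.
#' @param base_rate Mutations per bp per duplex read in the coding background.
#' @param region_fold Named rate multipliers per region kind.
#' @param type_proportions Proportions over the 8 strand-collapsed classes
#'   (must sum to 1).
#' @param age_fold Named per-class aged/young rate fold.
#' @param tissue_rate_fold,tissue_age_fold Per-tissue rate multiplier and
#'   extra aged multiplier.
#' @param strain_rate_fold Per-strain rate multiplier (vs B6).
#' @param hotspots `data.frame(start, end, fold)` of extra positional folds.
#' @param ns_selection `NULL` or `list(bins = edges, factor = folds)`:
#'   a non-synonymous call whose sample-level frequency falls in bin `i` is
#'   dropped wholesale with probability `1 - 1/factor[i]` (selection removes
#'   the mutant lineage, not individual reads).
#' @param reversion_fold Rate fold for B6-reversion alleles at haplotype
#'   sites relative to `base_rate`.
#' @param reversion_age_slope Extra aged multiplier on the reversion rate.
#' @param numt_fraction Fraction of mt depth that is NUMT (chr1) leakage,
#'   in `[0, 0.05]`; those reads carry the B6 allele at haplotype sites.
#' @param numt_span `NULL` (middle ~30 percent of the genome) or `c(start, end)`.
#' @param depth_mean,depth_dispersion Negative-binomial per-position duplex
#'   depth mean and size per sample.
#' @param replicates Samples per condition.
#' @param strains Named integer vector of haplotype-site counts per strain.
#' @param seed Master seed; fans out to stage seeds via [derive_seed()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 16299,
                       n_protein = 13, n_trna = 22, n_rrna = 2,
                       protein_codons = c(70, 180),
                       trna_length = 68, rrna_length = c(950, 1550),
                       dloop_length = 880, oril_length = 32,
                       base_rate = 1e-5,
                       region_fold = c("protein" = 1, "tRNA" = 1, "rRNA" = 1,
                                       "D-loop" = 6.4, "OriL" = 40,
                                       "other-noncoding" = 1),
                       type_proportions = c("G>A/C>T" = 0.33, "G>T/C>A" = 0.20,
                                            "G>C/C>G" = 0.05, "T>C/A>G" = 0.12,
                                            "T>A/A>T" = 0.06, "T>G/A>C" = 0.04,
                                            "INS" = 0.08, "DEL" = 0.12),
                       age_fold = c("G>A/C>T" = 2, "G>T/C>A" = 1, "G>C/C>G" = 1,
                                    "T>C/A>G" = 2, "T>A/A>T" = 1.5,
                                    "T>G/A>C" = 2, "INS" = 1, "DEL" = 2),
                       tissue_rate_fold = c(brain = 1, heart = 0.7, liver = 1.1),
                       tissue_age_fold = c(brain = 1, heart = 0.8, liver = 1.25),
                       strain_rate_fold = c(B6 = 1, AKR = 1, ALR = 1,
                                            FVB = 1, NZB = 1),
                       hotspots = NULL,
                       ns_selection = NULL,
                       reversion_fold = 100,
                       reversion_age_slope = 2,
                       numt_fraction = 0.005,
                       numt_span = NULL,
                       depth_mean = 18000, depth_dispersion = 10,
                       replicates = 4,
                       strains = c(B6 = 0L, AKR = 1L, ALR = 3L,
                                   FVB = 2L, NZB = 91L),
                       seed = 1L) {
  stopifnot(genome_length >= 2000, base_rate >= 0,
            abs(sum(type_proportions) - 1) < 1e-8,
            numt_fraction >= 0, numt_fraction <= 0.05,
            all(names(type_proportions) %in% mutation_classes()))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an annotated circular genome and haplotype tables
#'
#' Lays out non-overlapping protein/tRNA/rRNA features plus one D-loop and
#' one OriL over a random sequence. Protein CDSs start with ATG, contain no
#' internal stop on their strand, and end with TAA. Haplotype sites per
#' strain are drawn uniformly with a random non-reference conplastic allele.
#'
#' @param cfg A [sim_config()].
#' @return List with `annotation` ([mt_annotation()]) and `haplotypes`
#'   (`data.frame`: `strain`, `position`, `b6_allele`, `conplastic_allele`,
#'   `annotation`).
#' @export
simulate_genome <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "genome"))
  rng <- function(r) if (length(r) == 2L) sample(seq.int(r[1], r[2]), 1L) else r
  lens <- c(vapply(seq_len(cfg$n_protein), function(i) 3L * rng(cfg$protein_codons),
                   numeric(1)),
            rep(cfg$trna_length, cfg$n_trna),
            vapply(seq_len(cfg$n_rrna), function(i) rng(cfg$rrna_length), numeric(1)),
            cfg$oril_length)
  kinds <- c(rep("protein", cfg$n_protein), rep("tRNA", cfg$n_trna),
             rep("rRNA", cfg$n_rrna), "OriL")
  names_ <- c(sprintf("gene%02d", seq_len(cfg$n_protein)),
              sprintf("trna%02d", seq_len(cfg$n_trna)),
              sprintf("rrna%d", seq_len(cfg$n_rrna)), "OriL")
  # D-loop goes last, as in the real genome
  slack <- cfg$genome_length - sum(lens) - cfg$dloop_length
  if (slack < length(lens) + 1L) stop("infeasible layout: features exceed genome")
  ord <- sample.int(length(lens))
  lens <- lens[ord]; kinds <- kinds[ord]; names_ <- names_[ord]
  gaps <- as.vector(stats::rmultinom(1L, slack, rep(1, length(lens) + 1L)))
  starts <- integer(length(lens)); pos <- 1L
  for (i in seq_along(lens)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  features <- data.frame(
    name = c(names_, "D-loop"),
    kind = c(kinds, "D-loop"),
    start = c(starts, cfg$genome_length - cfg$dloop_length + 1L),
    end = c(starts + lens - 1L, cfg$genome_length),
    strand = c(ifelse(stats::runif(length(lens)) < 0.85, "+", "-"), "+"),
    stringsAsFactors = FALSE)
  seqc <- sample(c("A", "C", "G", "T"), cfg$genome_length, replace = TRUE)
  # write clean CDSs into protein spans
  code <- .mito_code()
  nonstop <- names(code)[code != "*" & names(code) != "ATG"]
  for (i in which(features$kind == "protein")) {
    ncod <- (features$end[i] - features$start[i] + 1L) %/% 3L
    cds <- paste0("ATG", paste(sample(nonstop, ncod - 2L, replace = TRUE),
                               collapse = ""), "TAA")
    if (features$strand[i] == "-") cds <- .revcomp(cds)
    seqc[features$start[i]:features$end[i]] <- strsplit(cds, "")[[1]]
  }
  ann <- mt_annotation(paste(seqc, collapse = ""), features)
  ann <- cache_effects(ann)
  eff <- ns_effect_table(ann)
  haps <- lapply(names(cfg$strains), function(st) {
    n <- cfg$strains[[st]]
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(cfg$genome_length, n))
    b6 <- seqc[pos]
    conp <- vapply(b6, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                   character(1), USE.NAMES = FALSE)
    key <- paste(pos, conp)
    effl <- eff$effect[match(key, paste(eff$position, eff$alt))]
    annot <- ifelse(is.na(effl), "noncoding",
                    ifelse(effl == "synonymous", "synonymous", "non-synonymous"))
    data.frame(strain = st, position = pos, b6_allele = b6,
               conplastic_allele = conp, annotation = annot,
               stringsAsFactors = FALSE)
  })
  list(annotation = ann, haplotypes = do.call(rbind, haps))
}

# default NUMT-homologous span: the middle ~30% of the genome (mirrors the
# real nt6394-nt11042 span relative to 16,299 bp)
.default_numt_span <- function(cfg) {
  c(round(0.392 * cfg$genome_length), round(0.677 * cfg$genome_length))
}

#' Simulate one condition's replicate samples
#'
#' Per position and replicate, duplex depth is negative-binomial; the
#' alternative-allele depth of each (position, class) is Poisson with rate
#' `depth x base_rate x region fold x hotspot fold x strain/tissue folds x
#' class proportion (x age folds when aged)`, with classes placed only at
#' compatible reference bases. Non-synonymous calls are binomially thinned
#' per the configured frequency-binned selection. Haplotype sites receive
#' B6-reversion alleles at `reversion_fold` times the base rate (times
#' `reversion_age_slope` when aged), and a `numt_fraction` of depth inside
#' the NUMT-homologous span leaks chr1 reads carrying the B6 allele.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_genome()].
#' @param strain,tissue,age Condition labels (`age` is `"young"`/`"aged"`).
#' @param haplotypes Haplotype table (all strains) from [simulate_genome()].
#' @return List with `samples` (list of [mt_sample()]), `junctions`
#'   (`data.frame`: `junction`, `chr1_reads`), `avg_mt_depth`, `numt_span`.
#' @export
simulate_condition <- function(cfg, ann, strain, tissue, age, haplotypes = NULL) {
  stopifnot(age %in% c("young", "aged"))
  L <- ann$length
  kinds <- .region_kind_track(ann)
  fold_pos <- unname(cfg$region_fold[kinds])
  if (!is.null(cfg$hotspots)) for (i in seq_len(nrow(cfg$hotspots))) {
    span <- cfg$hotspots$start[i]:cfg$hotspots$end[i]
    fold_pos[.wrap_pos(span, L)] <- fold_pos[.wrap_pos(span, L)] * cfg$hotspots$fold[i]
  }
  srate <- if (strain %in% names(cfg$strain_rate_fold))
    cfg$strain_rate_fold[[strain]] else 1
  trate <- if (tissue %in% names(cfg$tissue_rate_fold))
    cfg$tissue_rate_fold[[tissue]] else 1
  aged_extra <- if (age == "aged" && tissue %in% names(cfg$tissue_age_fold))
    cfg$tissue_age_fold[[tissue]] else 1
  classes <- mutation_classes()
  props <- cfg$type_proportions[classes]
  props[is.na(props)] <- 0
  afold <- if (age == "aged") cfg$age_fold[classes] else
    stats::setNames(rep(1, length(classes)), classes)
  afold[is.na(afold)] <- 1
  refbase <- .seq_chars(ann)
  eff <- ns_effect_table(ann)
  eff_key <- paste(eff$position, eff$alt)
  hap <- if (!is.null(haplotypes))
    haplotypes[haplotypes$strain == strain, , drop = FALSE] else NULL
  numt_span <- if (is.null(cfg$numt_span)) .default_numt_span(cfg) else cfg$numt_span
  samples <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    set.seed(derive_seed(cfg$seed, paste("cond", strain, tissue, age, r)))
    depth <- stats::rnbinom(L, mu = cfg$depth_mean, size = cfg$depth_dispersion)
    depth <- pmax(depth, 1L)  # duplex coverage never fully drops out
    base_lambda <- depth * cfg$base_rate * fold_pos * srate * trate * aged_extra
    rows <- list()
    for (k in classes) {
      lam <- base_lambda * props[[k]] * afold[[k]]
      if (k %in% c("INS", "DEL")) {
        if (k == "DEL") lam[L] <- 0  # avoid wrap-around ref allele
      } else {
        lam[!refbase %in% .class_ref_pair[[k]]] <- 0
      }
      n <- stats::rpois(L, lam)
      at <- which(n > 0L)
      if (!length(at)) next
      if (k == "INS") {
        ref <- refbase[at]; alt <- paste0(ref, "A")
      } else if (k == "DEL") {
        ref <- paste0(refbase[at], refbase[at + 1L]); alt <- refbase[at]
      } else {
        ref <- refbase[at]
        alt <- vapply(ref, function(b) .class_alt_for_ref(k, b), character(1),
                      USE.NAMES = FALSE)
      }
      rows[[k]] <- data.frame(position = at, ref = ref, alt = alt,
                              alt_depth = n[at], stringsAsFactors = FALSE)
    }
    calls <- if (length(rows)) do.call(rbind, rows) else
      data.frame(position = integer(), ref = character(), alt = character(),
                 alt_depth = numeric(), stringsAsFactors = FALSE)
    # frequency-binned selection against non-synonymous calls
    if (!is.null(cfg$ns_selection) && nrow(calls)) {
      e <- eff$effect[match(paste(calls$position, calls$alt), eff_key)]
      nonsyn <- !is.na(e) & e %in% c("non-synonymous", "nonsense") &
        nchar(calls$ref) == 1L & nchar(calls$alt) == 1L
      if (any(nonsyn)) {
        # selection removes the mutant lineage wholesale (Bernoulli per
        # call), so thinning does not migrate calls into lower bins
        fr <- calls$alt_depth / depth[calls$position]
        bin <- findInterval(fr, cfg$ns_selection$bins,
                            rightmost.closed = FALSE)
        keepp <- rep(1, nrow(calls))
        inbin <- nonsyn & bin >= 1 & bin <= length(cfg$ns_selection$factor)
        keepp[inbin] <- 1 / cfg$ns_selection$factor[bin[inbin]]
        calls <- calls[stats::runif(nrow(calls)) < keepp, , drop = FALSE]
      }
    }
    # reversion alleles at haplotype sites (+ NUMT leakage of B6 reads)
    if (!is.null(hap) && nrow(hap)) {
      rev_rate <- cfg$base_rate * cfg$reversion_fold *
        (if (age == "aged") cfg$reversion_age_slope else 1)
      d <- depth[hap$position]
      n <- stats::rpois(nrow(hap), d * rev_rate)
      in_numt <- hap$position >= numt_span[1] & hap$position <= numt_span[2]
      leak <- integer(nrow(hap))
      if (cfg$numt_fraction > 0 && any(in_numt))
        leak[in_numt] <- stats::rbinom(sum(in_numt), d[in_numt], cfg$numt_fraction)
      tot <- n + leak
      at <- which(tot > 0L)
      if (length(at)) {
        calls <- rbind(calls, data.frame(
          position = hap$position[at], ref = hap$conplastic_allele[at],
          alt = hap$b6_allele[at], alt_depth = tot[at],
          stringsAsFactors = FALSE))
      }
    }
    if (nrow(calls)) {
      dt <- data.table::as.data.table(calls)
      position <- ref <- alt <- alt_depth <- NULL
      agg <- dt[, list(alt_depth = sum(alt_depth)),
                by = list(position, ref, alt)]
      data.table::setorder(agg, position, alt)
      calls <- as.data.frame(agg)
      rownames(calls) <- NULL
      calls$alt_depth <- pmin(calls$alt_depth, depth[calls$position])
      calls$depth <- depth[calls$position]
    } else calls$depth <- numeric(0)
    sid <- paste(strain, tissue, age, r, sep = "_")
    calls$sample_id <- rep(sid, nrow(calls))
    meta <- data.frame(sample_id = sid, strain = strain, tissue = tissue,
                       age = age, replicate = r, stringsAsFactors = FALSE)
    samples[[r]] <- mt_sample(calls[, .call_cols], depth, meta)
  }
  avg_depth <- mean(Reduce(`+`, lapply(samples, function(s) s$depth)))
  set.seed(derive_seed(cfg$seed, paste("junction", strain, tissue, age)))
  junctions <- data.frame(
    junction = c("upstream", "downstream"),
    chr1_reads = stats::rbinom(2L, round(avg_depth), cfg$numt_fraction),
    stringsAsFactors = FALSE)
  list(samples = samples, junctions = junctions,
       avg_mt_depth = avg_depth, numt_span = numt_span)
}

#' Write simulated inputs in the dialects the I/O layer reads
#'
#' Emits FASTA + GFF3 for the genome, per-sample call TSVs, a sample sheet
#' and the haplotype TSV under `dir`.
#'
#' @param sim Output of [simulate_genome()].
#' @param conditions Named list of [simulate_condition()] outputs.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_inputs <- function(sim, conditions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- sim$annotation
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(ann$sequence, "chrM_synthetic")),
    file.path(dir, "genome.fa"))
  f <- ann$features
  type_map <- c(protein = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                "D-loop" = "D_loop", OriL = "rep_origin",
                "other-noncoding" = "other-noncoding")
  gff <- sprintf("chrM_synthetic\tmitosoma\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                 type_map[f$kind], f$start, f$end, f$strand, f$name, f$name)
  writeLines(c("##gff-version 3", gff), file.path(dir, "features.gff3"))
  if (!is.null(sim$haplotypes))
    utils::write.table(sim$haplotypes, file.path(dir, "haplotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- list(); junc <- list(); i <- 0L
  for (nm in names(conditions)) {
    cd <- conditions[[nm]]
    for (s in cd$samples) {
      i <- i + 1L
      write_calls(s$calls, file.path(dir, paste0(s$meta$sample_id, ".calls.tsv")))
      utils::write.table(
        data.frame(position = seq_along(s$depth), depth = s$depth),
        file.path(dir, paste0(s$meta$sample_id, ".depth.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      sheet[[i]] <- s$meta
    }
    m <- cd$samples[[1]]$meta
    junc[[nm]] <- data.frame(strain = m$strain, tissue = m$tissue, age = m$age,
                             junction = cd$junctions$junction,
                             chr1_reads = cd$junctions$chr1_reads,
                             stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, sheet), file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, junc), file.path(dir, "junctions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
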