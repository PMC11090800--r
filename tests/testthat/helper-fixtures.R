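# Fixtures and independent oracles shared across test files.

# A small deterministic annotation exercising every region kind, both
# strands, and an OriL-inside-tRNA overlap.
toy_annotation <- function() {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  seqc <- sample(bases, 400, replace = TRUE)
  # plus-strand gene at 21..50 (10 codons), minus-strand gene at 101..130
  plus_cds <- "ATGGGATGCCATAAAGGGCTTACATGGTAA"
  seqc[21:50] <- strsplit(plus_cds, "")[[1]]
  minus_cds <- "ATGCCTTACGGAAGACATTGACTACTGTAA"  # read on the minus strand
  seqc[101:130] <- strsplit(mitosoma:::.revcomp(minus_cds), "")[[1]]
  features <- data.frame(
    name = c("gplus", "gminus", "trnaX", "OriL", "D-loop"),
    kind = c("protein", "protein", "tRNA", "OriL", "D-loop"),
    start = c(21L, 101L, 195L, 200L, 361L),
    end = c(50L, 130L, 230L, 210L, 400L),
    strand = c("+", "-", "+", "+", "+"),
    stringsAsFactors = FALSE)
  mt_annotation(paste(seqc, collapse = ""), features)
}

# random single-gene annotation for oracle loops
random_gene_annotation <- function(seed, n_codons = NULL, strand = NULL) {
  set.seed(seed)
  if (is.null(n_codons)) n_codons <- sample(4:20, 1)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  code <- mitosoma:::.mito_code()
  nonstop <- names(code)[code != "*"]
  cds <- paste0("ATG", paste(sample(nonstop, n_codons - 2, replace = TRUE),
                             collapse = ""), "TAA")
  pad1 <- paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")
  pad2 <- paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE), collapse = "")
  body <- if (strand == "+") cds else mitosoma:::.revcomp(cds)
  ann <- mt_annotation(
    paste0(pad1, body, pad2),
    data.frame(name = "g", kind = "protein", start = 18L,
               end = 17L + nchar(cds), strand = strand,
               stringsAsFactors = FALSE))
  ann
}

# Brute-force N/S site oracle: enumerates every (codon, position, alt) triple
# with Biostrings translation, independent of count_ns_sites internals.
oracle_ns_sites <- function(ann, gene) {
  f <- ann$features[ann$features$name == gene, ]
  cds <- substr(ann$sequence, f$start, f$end)
  if (f$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  code <- Biostrings::getGeneticCode("SGC1")
  tr <- function(codon) unname(code[codon])
  n <- 0; s <- 0
  for (i in seq_len(nchar(cds) / 3)) {
    codon <- substr(cds, 3 * i - 2, 3 * i)
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
        mut <- codon
        substr(mut, p, p) <- b
        if (tr(mut) == tr(codon)) s <- s + 1 / 3 else n <- n + 1 / 3
      }
    }
  }
  c(N = n, S = s)
}

# Brute-force null spectrum oracle over every coding (position, alt).
oracle_null_spectrum <- function(ann) {
  prot <- ann$features[ann$features$kind == "protein", ]
  code <- Biostrings::getGeneticCode("SGC1")
  rows <- list()
  seen <- integer(0)
  for (i in seq_len(nrow(prot))) {
    f <- prot[i, ]
    cds <- substr(ann$sequence, f$start, f$end)
    if (f$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    for (j in seq_len(nchar(cds))) {
      gpos <- if (f$strand == "+") f$start + j - 1L else f$end - j + 1L
      if (gpos %in% seen) next
      seen <- c(seen, gpos)
      ci <- (j - 1) %/% 3 + 1; cp <- (j - 1) %% 3 + 1
      codon <- substr(cds, 3 * ci - 2, 3 * ci)
      refc <- substr(cds, j, j)
      for (b in setdiff(c("A", "C", "G", "T"), refc)) {
        mut <- codon; substr(mut, cp, cp) <- b
        eff <- if (code[mut] == code[codon]) "S" else "N"
        ref_plus <- if (f$strand == "-") chartr("ACGT", "TGCA", refc) else refc
        alt_plus <- if (f$strand == "-") chartr("ACGT", "TGCA", b) else b
        rows[[length(rows) + 1L]] <- data.frame(
          class = classify_mutation(ref_plus, alt_plus), eff = eff,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  classes <- setdiff(mutation_classes(), c("INS", "DEL"))
  nn <- vapply(classes, function(k) sum(tab$eff == "N" & tab$class == k), numeric(1))
  ss <- vapply(classes, function(k) sum(tab$eff == "S" & tab$class == k), numeric(1))
  data.frame(class = classes, nonsyn = nn / sum(nn), syn = ss / sum(ss),
             stringsAsFactors = FALSE)
}

# Step-up Benjamini-Hochberg oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Minimal condition table built by hand.
make_condition <- function(calls, depth, strain = "B6", tissue = "brain",
                           age = "young") {
  structure(list(strain = strain, tissue = tissue, age = age,
                 depth = depth, calls = calls,
                 sample_ids = paste0(strain, "_1"),
                 genome_length = length(depth)),
            class = "condition_table")
}

empty_calls <- function() {
  data.frame(position = integer(), ref = character(), alt = character(),
             alt_depth = numeric(), stringsAsFactors = FALSE)
}

# small shared simulation config for module tests
small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 6000, n_protein = 13, n_trna = 8, n_rrna = 1,
         protein_codons = c(60, 110), rrna_length = 400,
         dloop_length = 300, depth_mean = 3000, depth_dispersion = 10,
         replicates = 2, base_rate = 5e-5, seed = 11),
    list(...))
  do.call(sim_config, args)
}
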