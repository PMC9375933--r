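# Shared fixtures, built once per test run. The default synthetic
# data set (seed 7) backs the cross-module manifest checks; a small
# enriched variant backs the planted-enrichment checks.

.fixture_env <- new.env(parent = emptyenv())

sim_default <- function() {
  if (is.null(.fixture_env$sim)) {
    dir <- file.path(tempdir(), "lectinscan-sim7")
    .fixture_env$sim <- generate_synthetic_genome(
      synthetic_config(seed = 7), outdir = dir)
    .fixture_env$sim_dir <- dir
  }
  .fixture_env$sim
}

sim_default_dir <- function() {
  sim_default()
  .fixture_env$sim_dir
}

pipeline_default <- function() {
  if (is.null(.fixture_env$pipe))
    .fixture_env$pipe <- run_lectin_pipeline(sim_default_dir())
  .fixture_env$pipe
}

region_gene_sets <- function(sim = sim_default()) {
  lapply(strsplit(sim$manifest$regions$gene_idx, ","), as.integer)
}

# a minimal hand-written GFF3 with one 3-exon gene
write_toy_gff3 <- function(path, end_lt_start = FALSE) {
  gene_end <- if (end_lt_start) 50L else 1400L
  lines <- c(
    "##gff-version 3",
    sprintf("chr1\ttoy\tgene\t100\t%d\t.\t+\t.\tID=g1", gene_end),
    "chr1\ttoy\tmRNA\t100\t1400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttoy\texon\t100\t300\t.\t+\t.\tParent=g1.t1",
    "chr1\ttoy\texon\t500\t800\t.\t+\t.\tParent=g1.t1",
    "chr1\ttoy\texon\t1000\t1400\t.\t+\t.\tParent=g1.t1",
    "chr1\ttoy\tCDS\t150\t300\t.\t+\t0\tParent=g1.t1",
    "chr1\ttoy\tCDS\t500\t800\t.\t+\t0\tParent=g1.t1",
    "chr1\ttoy\tCDS\t1000\t1200\t.\t+\t0\tParent=g1.t1")
  writeLines(lines, path)
  path
}

# random pre-aligned CDS pair with syn/nonsyn mutations applied through
# codon alternatives (used by Ka/Ks agreement tests)
random_mutated_pair <- function(n_codons = 120, n_syn = 10, n_nonsyn = 5) {
  sense <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]
  codons <- c("ATG", sample(setdiff(sense, "ATG"), n_codons - 2,
                            replace = TRUE), "TAA")
  mutated <- codons
  gc <- Biostrings::GENETIC_CODE
  alt <- function(codon, synonymous) {
    aa <- gc[[codon]]
    sp <- strsplit(codon, "")[[1]]
    out <- character(0)
    for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), sp[pos])) {
      mut <- sp; mut[pos] <- b
      mcd <- paste(mut, collapse = "")
      if (gc[[mcd]] == "*") next
      if (synonymous == (gc[[mcd]] == aa)) out <- c(out, mcd)
    }
    out
  }
  free <- 2:(n_codons - 1)
  free <- free[sample.int(length(free))]
  done_s <- 0; done_n <- 0
  for (i in free) {
    if (done_s < n_syn) {
      a <- alt(mutated[i], TRUE)
      if (length(a)) { mutated[i] <- sample(a, 1); done_s <- done_s + 1
                       next }
    }
    if (done_n < n_nonsyn) {
      a <- alt(mutated[i], FALSE)
      if (length(a)) { mutated[i] <- sample(a, 1); done_n <- done_n + 1 }
    }
    if (done_s >= n_syn && done_n >= n_nonsyn) break
  }
  list(a = paste(codons, collapse = ""),
       b = paste(mutated, collapse = ""))
}
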