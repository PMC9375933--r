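toy_genes <- function(n_per_chr = 30L, chroms = c("c1", "c2")) {
  genes <- list()
  for (ch in chroms) for (i in seq_len(n_per_chr)) {
    id <- sprintf("%s_g%03d", ch, i)
    genes[[id]] <- gene_model(id, ch, i * 1000L, i * 1000L + 500L)
  }
  genes
}

test_that("rank distance drives tandem and proximal calls", {
  genes <- toy_genes()
  ri <- build_gene_rank_index(genes)
  expect_identical(ri$rank[ri$gene_id == "c1_g005"], 5L)

  pairs <- data.frame(gene_a = rep("c1_g010", 4L),
                      gene_b = c("c1_g011", "c1_g015", "c1_g025",
                                 "c2_g010"))
  cls <- classify_pairs(pairs, ri)
  expect_identical(cls$mode,
                   c("tandem", "proximal", "dispersed", "dispersed"))

  # symmetry in (gene_a, gene_b)
  swapped <- classify_pairs(
    data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a), ri)
  expect_identical(swapped$mode, cls$mode)

  # ancestral evidence turns a cross-chromosome pair into transposed
  anc <- classify_pairs(pairs, ri, ancestral_loci = "c1_g010")
  expect_identical(anc$mode[4L], "transposed")
  # ...but both-in-ancestral does not
  anc2 <- classify_pairs(pairs, ri,
                         ancestral_loci = c("c1_g010", "c2_g010"))
  expect_identical(anc2$mode[4L], "dispersed")

  expect_error(classify_pairs(
    data.frame(gene_a = "nope", gene_b = "c1_g001"), ri), "nope")
})

test_that("random pairs match a literal rule-table oracle", {
  genes <- toy_genes(40L)
  ri <- build_gene_rank_index(genes)
  set.seed(17)
  ids <- ri$gene_id
  pairs <- data.frame(gene_a = sample(ids, 100, TRUE),
                      gene_b = sample(ids, 100, TRUE))
  pairs <- pairs[pairs$gene_a != pairs$gene_b, ]
  anc <- sample(ids, 10)
  cls <- classify_pairs(pairs, ri, ancestral_loci = anc)
  for (i in seq_len(nrow(cls))) {
    ia <- match(cls$gene_a[i], ri$gene_id)
    ib <- match(cls$gene_b[i], ri$gene_id)
    expect_identical(cls$mode[i], oracle_classify(
      ri$chromosome[ia], ri$rank[ia], ri$chromosome[ib], ri$rank[ib],
      character(0), cls$gene_a[i] %in% anc, cls$gene_b[i] %in% anc))
  }
})

test_that("collinear blocks need enough monotone anchors", {
  genes <- toy_genes(30L)
  ri <- build_gene_rank_index(genes)
  mk <- function(ra, rb) data.frame(
    gene_a = sprintf("c1_g%03d", ra), gene_b = sprintf("c2_g%03d", rb))

  six <- mk(c(3, 5, 8, 10, 13, 15), c(2, 4, 7, 9, 12, 14))
  blocks <- detect_collinear_blocks(six, ri, min_anchors = 5L)
  expect_length(blocks, 1L)
  expect_identical(nrow(blocks[[1L]]$anchors), 6L)

  four <- mk(c(3, 5, 8, 10), c(2, 4, 7, 9))
  expect_length(detect_collinear_blocks(four, ri, min_anchors = 5L), 0L)

  # reversed orientation also chains
  rev6 <- mk(c(3, 5, 8, 10, 13, 15), c(20, 18, 15, 13, 10, 8))
  blocks_rev <- detect_collinear_blocks(rev6, ri, min_anchors = 5L)
  expect_length(blocks_rev, 1L)
  expect_identical(blocks_rev[[1L]]$orientation, -1L)

  # anchor pairs in a detected block classify as wgd
  cls <- classify_pairs(six, ri, blocks = blocks)
  expect_true(all(cls$mode == "wgd"))
})

test_that("NG86 Ka/Ks has the expected fixed points and edge behavior", {
  cds <- "ATGGCTGCTAAGGCTTAA"
  same <- compute_ka_ks(cds, cds)
  expect_identical(same$ka, 0)
  expect_identical(same$ks, 0)
  expect_true(same$retained)

  expect_error(compute_ka_ks("ATGGCT", "ATG"), "length mismatch")
  expect_error(compute_ka_ks("ATGGC", "ATGGC"), "multiple of 3")
  expect_error(compute_ka_ks("ATGTAAGCTTAA", "ATGTAAGCTTAA"),
               "internal stop")

  # ambiguity codes: codon skipped and counted
  amb <- compute_ka_ks("ATGGCTNNNAAGTAA", "ATGGCTGCTAAGTAA")
  expect_identical(amb$skipped_codons, 1L)

  # symmetry
  p <- random_mutated_pair(60, 6, 3)
  ab <- compute_ka_ks(p$a, p$b)
  ba <- compute_ka_ks(p$b, p$a)
  expect_equal(ab$ks, ba$ks, tolerance = 1e-12)
  expect_equal(ab$ka, ba$ka, tolerance = 1e-12)
})

test_that("a hand-built two-difference pair matches the codon oracle", {
  set.seed(8)
  # 100 codons, exactly two synonymous third-position differences
  sense <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]
  fourfold <- c("GCT", "GGT", "CCT", "ACT", "GTT", "TCT", "CGT", "CTT")
  codons <- c("ATG", sample(sense[!sense %in% "ATG"], 97, TRUE),
              "GCT", "TAA")
  codons[50] <- "GGT"
  mut <- codons
  mut[50] <- "GGC"   # Gly, synonymous
  mut[99] <- "GCC"   # Ala, synonymous
  a <- paste(codons, collapse = ""); b <- paste(mut, collapse = "")
  mine <- compute_ka_ks(a, b)
  orac <- oracle_ng86(a, b)
  expect_identical(mine$nonsyn_diffs, 0)
  expect_identical(mine$syn_diffs, 2)
  expect_equal(mine$ks, orac$ks, tolerance = 1e-12)
  expect_equal(mine$ka, 0, tolerance = 1e-12)
})

test_that("NG86 agrees with the independent oracle on mutated pairs", {
  set.seed(31)
  for (rep in 1:25) {
    p <- random_mutated_pair(n_codons = sample(40:120, 1L),
                             n_syn = sample(0:12, 1L),
                             n_nonsyn = sample(0:8, 1L))
    mine <- compute_ka_ks(p$a, p$b)
    orac <- oracle_ng86(p$a, p$b)
    expect_equal(mine$syn_sites, orac$S, tolerance = 1e-9)
    expect_equal(mine$ps, orac$ps, tolerance = 1e-9)
    expect_equal(mine$pn, orac$pn, tolerance = 1e-9)
    if (is.na(orac$ks)) expect_true(is.na(mine$ks))
    else expect_equal(mine$ks, orac$ks, tolerance = 1e-9)
  }
})

test_that("saturated synonymous divergence hits the Jukes-Cantor edge", {
  # two-codon sequences where all synonymous sites differ maximally are
  # easiest built directly on the proportion: ps >= 3/4 must yield NA
  jc_edge <- compute_ka_ks("ATGTTATAA", "ATGCTGTAA")
  # Leu TTA vs CTG: same amino acid through 2 changes; tiny S makes ps
  # large; whatever the exact value, retention requires a finite ks <= 1
  if (is.na(jc_edge$ks)) expect_false(jc_edge$retained)
  else expect_identical(jc_edge$retained, jc_edge$ks <= 1)
})

test_that("third-position-only mutation recovers the generator's target ks", {
  set.seed(77)
  sense <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]
  for (rep in 1:20) {
    n <- 150L
    codons <- c("ATG", sample(setdiff(sense, "ATG"), n - 2L, TRUE),
                "TAA")
    base <- paste(codons, collapse = "")
    target <- stats::runif(1, 0.2, 0.8)
    # package generator path
    ka_t <- 0.05
    mut <- lectinscan:::.mutate_to_targets(base, target, ka_t)
    rec <- compute_ka_ks(base, mut$cds)
    expect_lt(abs(rec$ks - target) / target, 0.15)
  }
})

test_that("expansion summaries tabulate modes over retained pairs", {
  pairs <- data.frame(gene_a = c("a", "b", "c", "d"),
                      gene_b = c("x", "y", "z", "w"),
                      mode = c("tandem", "tandem", "dispersed", "wgd"),
                      retained = c(TRUE, TRUE, TRUE, FALSE))
  fam <- c(a = "JRL", b = "JRL", c = "JRL", d = "Legume")
  summ <- expansion_summary(pairs, fam)
  expect_identical(sort(unique(summ$family)), "JRL")  # wgd pair filtered
  expect_identical(summ$pct_pairs[summ$mode == "tandem"], 66.7)
  expect_identical(nrow(expansion_summary(pairs[0L, ])), 0L)

  all_tandem <- expansion_summary(
    data.frame(gene_a = "a", gene_b = "b", mode = "tandem",
               retained = TRUE))
  expect_identical(all_tandem$pct_pairs, 100)
})
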