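qtl_row <- function(id, trait, sub, cat, chrom, start, end) {
  data.frame(qtl_id = id, trait = trait, subcategory = sub,
             category = cat, chromosome = chrom, start = start,
             end = end)
}

simple_qtls <- function(intervals, trait = "t1", sub = "s1",
                        cat = "abiotic", chrom = "chr1") {
  do.call(rbind, lapply(seq_len(nrow(intervals)), function(i)
    qtl_row(sprintf("Q%02d", i), trait, sub, cat, chrom,
            intervals[i, 1L], intervals[i, 2L])))
}

test_that("overlapping QTLs merge; adjacent and disjoint ones do not", {
  merged <- merge_qtls(simple_qtls(rbind(c(1, 100), c(50, 150))))
  expect_identical(nrow(merged), 1L)
  expect_identical(c(merged$start, merged$end), c(1L, 150L))
  expect_identical(merged$source_qtl_ids, "Q01,Q02")

  two <- merge_qtls(simple_qtls(rbind(c(1, 100), c(150, 200))))
  expect_identical(nrow(two), 2L)

  # closed-coordinate adjacency (end + 1 == start) is not overlap
  touching <- merge_qtls(simple_qtls(rbind(c(1, 100), c(101, 200))))
  expect_identical(nrow(touching), 2L)

  # exact duplicate interval+trait rows collapse, keeping both ids
  dup <- merge_qtls(simple_qtls(rbind(c(1, 100), c(1, 100))))
  expect_identical(nrow(dup), 1L)
  expect_identical(dup$source_qtl_ids, "Q01,Q02")

  expect_error(merge_qtls(simple_qtls(rbind(c(100, 1)))), "start")
  expect_error(merge_qtls(qtl_row("Q1", "t", "s", "weird", "chr1", 1, 5)),
               "category")
})

test_that("merged coverage equals a per-base union oracle on random inputs", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(2:12, 1L)
    starts <- sample.int(400, n, replace = TRUE)
    ends <- starts + sample.int(80, n, replace = TRUE)
    q <- simple_qtls(cbind(starts, ends))
    merged <- merge_qtls(q)
    covered <- oracle_union_coverage(starts, ends)
    expect_identical(sum(merged$end - merged$start + 1L), sum(covered))
    # each merged region is fully covered, and regions are pairwise
    # disjoint (adjacent regions may touch: strict-overlap semantics)
    for (i in seq_len(nrow(merged)))
      expect_true(all(covered[merged$start[i]:merged$end[i]]))
    if (nrow(merged) > 1L) {
      m <- merged[order(merged$start), ]
      expect_true(all(m$start[-1L] > m$end[-nrow(m)]))
    }
    # idempotence and input-order invariance
    remerge <- merge_qtls(data.frame(
      qtl_id = merged$region_id, trait = "t1", subcategory = "s1",
      category = "abiotic", chromosome = merged$chromosome,
      start = merged$start, end = merged$end))
    expect_identical(remerge[, c("start", "end")],
                     merged[, c("start", "end")])
    shuffled <- merge_qtls(q[sample.int(nrow(q)), , drop = FALSE])
    expect_identical(shuffled[, c("start", "end")],
                     merged[, c("start", "end")])
  }
})

test_that("coarser grouping levels never yield more regions", {
  sim <- sim_default()
  n_trait <- nrow(merge_qtls(sim$qtl, "trait"))
  n_sub <- nrow(merge_qtls(sim$qtl, "subcategory"))
  n_cat <- nrow(merge_qtls(sim$qtl, "category"))
  expect_lte(n_cat, n_sub)
  expect_lte(n_sub, n_trait)
})

test_that("gene counting applies the any-overlap rule at boundaries", {
  genes <- list(
    gene_model("gin", "chr1", 10, 20),
    gene_model("gout", "chr1", 21, 100) # adjacent only
  )
  names(genes) <- c("gin", "gout")
  regions <- merge_qtls(simple_qtls(rbind(c(15, 100))))
  # region (15,100): gin overlaps by 6 bp; gout overlaps fully
  counted <- count_genes_in_regions(regions, genes, "gin")
  expect_identical(counted$n_genes, 2L)
  expect_identical(counted$k_lectins, 1L)

  tight <- merge_qtls(simple_qtls(rbind(c(21, 100))))
  counted2 <- count_genes_in_regions(tight, genes, "gin")
  expect_identical(counted2$n_genes, 1L)   # gin (10,20) does not touch 21
  expect_identical(counted2$k_lectins, 0L)

  within_ <- count_genes_in_regions(regions, genes, "gin",
                                    rule = "within")
  expect_identical(within_$n_genes, 1L)    # gin straddles the boundary

  expect_error(count_genes_in_regions(regions, genes, "nope"), "nope")
})

test_that("(n, k) equals a quadratic all-pairs oracle on the synthetic genome", {
  sim <- sim_default()
  pipe <- pipeline_default()
  reg <- pipe$colocalization$regions
  tab <- sim$manifest$genes
  for (i in seq_len(nrow(reg))) {
    nk <- oracle_count_region(reg$chromosome[i], reg$start[i],
                              reg$end[i], tab$chromosome, tab$start,
                              tab$end, tab$is_lectin)
    expect_identical(reg$n_genes[i], unname(nk["n"]))
    expect_identical(reg$k_lectins[i], unname(nk["k"]))
  }
  # every lectin flagged in-QTL is recovered by the oracle and vice versa
  in_qtl_oracle <- unique(unlist(lapply(seq_len(nrow(reg)), function(i) {
    sel <- tab$chromosome == reg$chromosome[i] &
      tab$start <= reg$end[i] & tab$end >= reg$start[i] & tab$is_lectin
    tab$gene_id[sel]
  })))
  expect_setequal(pipe$colocalization$report$lectins_in_qtl,
                  in_qtl_oracle)
})

test_that("co-localization report percentages cover edge cases", {
  genes <- setNames(lapply(1:10, function(i)
    gene_model(sprintf("g%02d", i), "chr1", i * 100, i * 100 + 50)),
    sprintf("g%02d", 1:10))
  regions <- merge_qtls(simple_qtls(rbind(c(1, 2000))))
  counted <- count_genes_in_regions(regions, genes, "g01")
  rep1 <- colocalization_report(counted, "g01")
  expect_identical(rep1$per_key$pct_regions_with_lectin, 100)
  expect_identical(rep1$pct_lectins_in_qtl, 100)

  rep0 <- colocalization_report(
    count_genes_in_regions(regions, genes, character(0)), character(0))
  expect_identical(rep0$per_key$pct_regions_with_lectin, 0)
})

test_that("unknown chromosomes are flagged and excluded from counting", {
  q <- rbind(simple_qtls(rbind(c(1, 100))),
             qtl_row("Q99", "t1", "s1", "abiotic", "scaffold_7", 1, 500))
  merged <- merge_qtls(q, known_chromosomes = "chr1")
  expect_identical(merged$chromosome_known,
                   merged$chromosome == "chr1")
  genes <- list(g1 = gene_model("g1", "chr1", 10, 20))
  counted <- count_genes_in_regions(merged, genes, character(0))
  expect_true(is.na(counted$n_genes[counted$chromosome == "scaffold_7"]))
})
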