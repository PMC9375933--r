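test_that("promoter extraction is strand-aware with edge truncation", {
  chrom <- paste(rep(c("A", "C", "G", "T"), length.out = 5000),
                 collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))

  plus <- gene_model("p1", "chr1", 2001, 2500, "+")
  prom <- extract_promoter(genome, plus)
  expect_identical(nchar(prom), 1500L)
  expect_identical(as.character(prom), substr(chrom, 501, 2000))
  expect_false(attr(prom, "truncated"))

  minus <- gene_model("m1", "chr1", 500, 1000, "-")
  promm <- extract_promoter(genome, minus)
  expect_identical(as.character(promm), as.character(
    Biostrings::reverseComplement(
      Biostrings::DNAString(substr(chrom, 1001, 2500)))))

  short <- extract_promoter(genome, gene_model("s1", "chr1", 301, 400, "+"))
  expect_identical(nchar(short), 300L)
  expect_true(attr(short, "truncated"))

  at_start <- extract_promoter(genome, gene_model("e1", "chr1", 1, 50, "+"))
  expect_identical(as.character(at_start), "")
  expect_true(attr(at_start, "truncated"))

  expect_error(extract_promoter(genome, gene_model("x", "chrX", 1, 5)),
               "chrX")
})

test_that("IUPAC scanning reports every overlapping hit on both strands", {
  motifs <- data.frame(name = "m", pattern = "ACGT", category = "test")
  hits <- scan_cis_elements("TTACGTTT", motifs)
  plus <- hits[hits$strand == "+", ]
  expect_identical(plus$offset, 2L)
  # ACGT is its own reverse complement: mirrored hit at same offset
  expect_identical(hits$offset[hits$strand == "-"], 2L)

  amb <- data.frame(name = "r", pattern = "RCGT", category = "test")
  h2 <- scan_cis_elements("ACGTGCGT", amb)
  expect_setequal(h2$offset[h2$strand == "+"], c(0L, 4L))

  expect_error(scan_cis_elements("ACGT",
    data.frame(name = "bad", pattern = "ACZT", category = "t")), "bad")
})

test_that("scanning a promoter and its reverse complement mirror each other", {
  set.seed(19)
  motifs <- data.frame(name = c("a", "b"),
                       pattern = c("ACGTG", "TTGACY"),
                       category = "t")
  for (rep in 1:10) {
    prom <- paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                  collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(prom)))
    h1 <- scan_cis_elements(prom, motifs)
    h2 <- scan_cis_elements(rc, motifs)
    for (i in seq_len(nrow(h1))) {
      w <- nchar(motifs$pattern[motifs$name == h1$motif[i]])
      mirrored_offset <- nchar(prom) - h1$offset[i] - w
      mirrored_strand <- if (h1$strand[i] == "+") "-" else "+"
      expect_true(any(h2$motif == h1$motif[i] &
                      h2$strand == mirrored_strand &
                      h2$offset == mirrored_offset))
    }
    expect_identical(nrow(h1), nrow(h2))
  }
})

test_that("the scanner equals a quadratic brute-force scan on random promoters", {
  set.seed(23)
  motifs <- default_cis_elements()
  for (rep in 1:8) {
    prom <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE),
                  collapse = "")
    hits <- scan_cis_elements(prom, motifs)
    for (i in seq_len(nrow(motifs))) {
      orac <- oracle_scan_iupac(prom, motifs$pattern[i])
      got <- hits[hits$motif == motifs$name[i], ]
      expect_identical(sort(got$offset[got$strand == "+"]),
                       sort(orac$plus))
      expect_identical(sort(got$offset[got$strand == "-"]),
                       sort(orac$minus))
    }
  }
})

test_that("SSR detection enforces thresholds and shortest-unit reporting", {
  set.seed(29)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  seq1 <- paste0("GCGC", strrep("A", 12), "TGCA")
  found <- find_ssrs(seq1)
  mono <- found[found$unit == "A", ]
  expect_identical(nrow(mono), 1L)
  expect_identical(mono$repeat_count, 12L)
  expect_identical(c(mono$start, mono$end), c(5L, 16L))

  # AT x 5 is below the dinucleotide threshold of 6
  expect_identical(nrow(find_ssrs(paste0("GGCC", strrep("AT", 5), "GGCC"))),
                   0L)
  # AT x 7 is a dinucleotide SSR, never a tetra-/hexanucleotide one
  found2 <- find_ssrs(paste0("GGCC", strrep("AT", 7), "GGCC"))
  expect_identical(found2$unit, "AT")
  expect_identical(found2$repeat_count, 7L)
})

test_that("SSR output equals exhaustive enumeration on planted sequences", {
  set.seed(37)
  units <- c("A", "AG", "AT", "AAG", "ACGT", "AACGT", "ACGTAG")
  for (rep in 1:20) {
    pieces <- character(0)
    for (j in 1:3) {
      u <- sample(units, 1L)
      cnt <- sample(5:12, 1L)
      pieces <- c(pieces,
                  paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                        collapse = ""),
                  strrep(u, cnt))
    }
    s <- paste(c(pieces, paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                               collapse = "")), collapse = "")
    mine <- find_ssrs(s)
    orac <- oracle_find_ssrs(s)
    expect_identical(nrow(mine), nrow(orac))
    if (nrow(mine)) {
      expect_identical(mine$start, orac$start)
      expect_identical(mine$end, orac$end)
      expect_identical(mine$unit, orac$unit)
      expect_identical(mine$repeat_count, orac$repeat_count)
    }
    # same-unit loci are non-overlapping and maximal
    for (u in unique(mine$unit_length)) {
      mu <- mine[mine$unit_length == u, ]
      if (nrow(mu) > 1L)
        expect_true(all(mu$start[-1L] > mu$end[-nrow(mu)]))
    }
  }
})

test_that("planted promoter motifs are recovered with full recall", {
  sim <- sim_default()
  pipe <- pipeline_default()
  hits <- pipe$promoter$cis$hits
  pm <- sim$manifest$planted_motifs
  expect_gt(nrow(pm), 0L)
  for (i in seq_len(nrow(pm))) {
    expect_true(any(hits$gene_id == pm$gene_id[i] &
                    hits$motif == pm$motif[i] &
                    hits$strand == "+" &
                    hits$offset == pm$offset[i]))
  }
})

test_that("planted genomic SSRs are recovered at their exact loci", {
  sim <- sim_default()
  pipe <- pipeline_default()
  ss <- pipe$promoter$ssrs
  ps <- sim$manifest$planted_ssrs
  expect_gt(nrow(ps), 0L)
  for (i in seq_len(nrow(ps))) {
    expect_true(any(ss$seq_id == ps$gene_id[i] &
                    ss$unit == ps$unit[i] &
                    ss$start == ps$start[i] &
                    ss$end == ps$end[i]))
  }
})
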