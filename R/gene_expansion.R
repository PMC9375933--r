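# Duplicate-pair classification (tandem / proximal / dispersed /
# transposed / WGD) and Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor
# correction and the Ks <= 1 retention rule.

#' Build a per-chromosome gene rank index
#'
#' Genes are ranked 1..m along each chromosome by start coordinate;
#' rank distance underlies the tandem/proximal rules.
#'
#' @param genes List of [gene_model] objects.
#' @return data.frame with `gene_id`, `chromosome`, `rank`.
#' @export
build_gene_rank_index <- function(genes) {
  df <- data.frame(
    gene_id = vapply(genes, `[[`, character(1L), "gene_id"),
    chromosome = vapply(genes, `[[`, character(1L), "chromosome"),
    start = vapply(genes, `[[`, integer(1L), "start"))
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  df$rank <- as.integer(stats::ave(df$start, df$chromosome,
                                   FUN = function(x)
                                     rank(x, ties.method = "first")))
  rownames(df) <- NULL
  df[, c("gene_id", "chromosome", "rank")]
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Classify homologous gene pairs by duplication mode
#'
#' Rule table, applied with precedence
#' tandem > proximal > wgd > transposed > dispersed:
#' tandem = same chromosome and rank distance <= `tandem_window`
#' (default 1, i.e. adjacent); proximal = same chromosome and rank
#' distance <= `proximal_window` (default 10); wgd = the pair is an
#' anchor of a collinear block; transposed = exactly one gene lies at a
#' caller-supplied ancestral locus and the pair is not block-anchored;
#' dispersed = none of the above. Without an ancestral-locus list,
#' would-be transposed pairs fall to dispersed. Classification is
#' symmetric in the two genes.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param rank_index From [build_gene_rank_index()].
#' @param blocks Optional blocks from [detect_collinear_blocks()].
#' @param ancestral_loci Optional character vector of gene ids.
#' @param tandem_window,proximal_window Rank-distance windows.
#' @return `pairs` with a `mode` column appended.
#' @export
classify_pairs <- function(pairs, rank_index, blocks = NULL,
                           ancestral_loci = NULL,
                           tandem_window = 1L, proximal_window = 10L) {
  idx <- match(pairs$gene_a, rank_index$gene_id)
  jdx <- match(pairs$gene_b, rank_index$gene_id)
  if (anyNA(idx) || anyNA(jdx))
    stop("gene absent from rank index: ",
         paste(unique(c(pairs$gene_a[is.na(idx)],
                        pairs$gene_b[is.na(jdx)])), collapse = ", "))
  anchor_keys <- character(0)
  if (length(blocks))
    anchor_keys <- unlist(lapply(blocks, function(b)
      .pair_key(b$anchors$gene_a, b$anchors$gene_b)))
  same_chr <- rank_index$chromosome[idx] == rank_index$chromosome[jdx]
  rd <- abs(rank_index$rank[idx] - rank_index$rank[jdx])
  in_block <- .pair_key(pairs$gene_a, pairs$gene_b) %in% anchor_keys
  n_anc <- (pairs$gene_a %in% ancestral_loci) +
           (pairs$gene_b %in% ancestral_loci)
  pairs$mode <- ifelse(same_chr & rd <= tandem_window, "tandem",
    ifelse(same_chr & rd <= proximal_window, "proximal",
    ifelse(in_block, "wgd",
    ifelse(n_anc == 1L, "transposed", "dispersed"))))
  pairs
}

#' Detect collinear anchor blocks
#'
#' A deliberately simple synteny-chain detector: homologous pairs are
#' mapped to (rank, rank) anchors per chromosome pair and chained
#' greedily while ranks stay strictly monotone (same or reversed
#' orientation) and the inter-anchor rank gap stays within `max_gap` on
#' both chromosomes. Chains shorter than `min_anchors` are discarded.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param rank_index From [build_gene_rank_index()].
#' @param min_anchors Minimum chain length (default 5).
#' @param max_gap Maximum rank gap between consecutive anchors
#'   (default 25).
#' @return List of blocks; each has `chromosomes` (length-2 character),
#'   `orientation` (+1/-1) and `anchors` (data.frame `gene_a`,
#'   `gene_b`, `rank_a`, `rank_b`).
#' @export
detect_collinear_blocks <- function(pairs, rank_index, min_anchors = 5L,
                                    max_gap = 25L) {
  if (!nrow(pairs)) return(list())
  idx <- match(pairs$gene_a, rank_index$gene_id)
  jdx <- match(pairs$gene_b, rank_index$gene_id)
  an <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                   chr_a = rank_index$chromosome[idx],
                   chr_b = rank_index$chromosome[jdx],
                   rank_a = rank_index$rank[idx],
                   rank_b = rank_index$rank[jdx])
  # canonical chromosome-pair orientation
  flip <- an$chr_a > an$chr_b
  an[flip, c("gene_a", "gene_b", "chr_a", "chr_b", "rank_a", "rank_b")] <-
    an[flip, c("gene_b", "gene_a", "chr_b", "chr_a", "rank_b", "rank_a")]
  blocks <- list()
  for (cp in unique(paste(an$chr_a, an$chr_b, sep = "\r"))) {
    sub <- an[paste(an$chr_a, an$chr_b, sep = "\r") == cp, , drop = FALSE]
    sub <- sub[order(sub$rank_a, sub$rank_b), , drop = FALSE]
    for (orient in c(1L, -1L)) {
      chains <- list()
      for (i in seq_len(nrow(sub))) {
        attached <- FALSE
        best <- NULL; best_gap <- Inf
        for (ci in seq_along(chains)) {
          last <- chains[[ci]][nrow(chains[[ci]]), ]
          ga <- sub$rank_a[i] - last$rank_a
          gb <- orient * (sub$rank_b[i] - last$rank_b)
          if (ga > 0L && gb > 0L && ga <= max_gap && gb <= max_gap &&
              ga + gb < best_gap) {
            best <- ci; best_gap <- ga + gb
          }
        }
        if (!is.null(best)) {
          chains[[best]] <- rbind(chains[[best]], sub[i, ])
          attached <- TRUE
        }
        if (!attached) chains[[length(chains) + 1L]] <- sub[i, ]
      }
      for (ch in chains) {
        if (nrow(ch) >= min_anchors) {
          blocks[[length(blocks) + 1L]] <- list(
            chromosomes = c(ch$chr_a[1L], ch$chr_b[1L]),
            orientation = orient,
            anchors = ch[, c("gene_a", "gene_b", "rank_a", "rank_b")])
        }
      }
    }
  }
  blocks
}

# ---- NG86 Ka/Ks -----------------------------------------------------------

.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.codon_env$syn_sites)) return(.codon_env)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)
  syn <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (gc[[cd]] == "*") next
    f <- 0
    sp <- strsplit(cd, "")[[1L]]
    for (pos in 1:3) for (b in setdiff(bases, sp[pos])) {
      mut <- sp; mut[pos] <- b
      mcd <- paste(mut, collapse = "")
      # mutation to a stop codon counts as nonsynonymous
      if (gc[[mcd]] == gc[[cd]]) f <- f + 1 / 3
    }
    syn[cd] <- f
  }
  .codon_env$code <- gc
  .codon_env$syn_sites <- syn
  .codon_env
}

# average syn/nonsyn differences between two codons over all mutational
# pathways; pathways through stop codons are excluded unless all are
.codon_diffs <- function(ca, cb, code) {
  pos <- which(strsplit(ca, "")[[1L]] != strsplit(cb, "")[[1L]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- .perms(pos)
  tally <- matrix(0, nrow = length(paths), ncol = 2L)
  blocked <- logical(length(paths))
  for (pi in seq_along(paths)) {
    cur <- strsplit(ca, "")[[1L]]
    tgt <- strsplit(cb, "")[[1L]]
    sd <- nd <- 0
    for (p in paths[[pi]]) {
      nxt <- cur; nxt[p] <- tgt[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" || aa1 == "*") blocked[pi] <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    tally[pi, ] <- c(sd, nd)
  }
  ok <- if (all(blocked)) rep(TRUE, length(paths)) else !blocked
  c(sd = mean(tally[ok, 1L]), nd = mean(tally[ok, 2L]))
}

.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Nei-Gojobori (1986) Ka and Ks
#'
#' Proportions of synonymous and nonsynonymous differences per site,
#' with per-codon synonymous-site counting averaged over both
#' sequences, equal-weight pathway averaging for codons differing at
#' more than one position (pathways through stop codons excluded), and
#' the Jukes-Cantor multiple-hit correction
#' `d = -(3/4) log(1 - 4 p / 3)`. Input CDS must be codon-aligned:
#' equal length, a multiple of 3, no internal stops. Codons containing
#' ambiguity codes are skipped and counted. `ks` (or `ka`) is `NA` when
#' its proportion reaches the Jukes-Cantor domain edge `p >= 3/4`.
#'
#' @param cds_a,cds_b Nucleotide strings.
#' @return List with `ka`, `ks`, `ps`, `pn`, `syn_sites`,
#'   `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `skipped_codons`,
#'   and `retained` (TRUE iff ks is defined and <= 1).
#' @export
compute_ka_ks <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("CDS length mismatch (pairs must be codon-aligned)")
  if (nchar(cds_a) %% 3L != 0L)
    stop("CDS length not a multiple of 3")
  env <- .codon_tables()
  nc <- nchar(cds_a) %/% 3L
  ca <- substring(cds_a, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  cb <- substring(cds_b, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  # a shared terminal stop codon is allowed and excluded from counting
  last_a <- env$code[ca[nc]]; last_b <- env$code[cb[nc]]
  if (nc > 1L && !is.na(last_a) && !is.na(last_b) &&
      last_a == "*" && last_b == "*") {
    ca <- ca[-nc]; cb <- cb[-nc]
  }
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  skipped <- sum(!clean)
  ca <- ca[clean]; cb <- cb[clean]
  if (!length(ca)) stop("no unambiguous codons to compare")
  if (any(env$code[ca] == "*") || any(env$code[cb] == "*"))
    stop("internal stop codon in CDS")
  S <- (sum(env$syn_sites[ca]) + sum(env$syn_sites[cb])) / 2
  Nn <- 3 * length(ca) - S
  sd <- nd <- 0
  for (i in which(ca != cb)) {
    d <- .codon_diffs(ca[i], cb[i], env$code)
    sd <- sd + d[["sd"]]; nd <- nd + d[["nd"]]
  }
  ps <- if (S > 0) sd / S else 0
  pn <- if (Nn > 0) nd / Nn else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  list(ka = ka, ks = ks, ps = ps, pn = pn,
       syn_sites = S, nonsyn_sites = Nn,
       syn_diffs = sd, nonsyn_diffs = nd,
       skipped_codons = skipped,
       retained = is.finite(ks) && ks <= 1)
}

#' Classify and Ka/Ks-filter a homolog pair table
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param genes List of [gene_model] objects (for the rank index).
#' @param cds Named character vector (or `DNAStringSet`) of CDS keyed
#'   by gene id.
#' @param ancestral_loci Optional ancestral-locus gene ids.
#' @param min_anchors,max_gap Collinear-block parameters.
#' @param tandem_window,proximal_window Rank-distance windows.
#' @return data.frame of duplicate pairs: mode, ka, ks, retained.
#' @export
analyze_duplicates <- function(pairs, genes, cds, ancestral_loci = NULL,
                               min_anchors = 5L, max_gap = 25L,
                               tandem_window = 1L, proximal_window = 10L) {
  cds <- as.character(cds)
  rank_index <- build_gene_rank_index(genes)
  blocks <- detect_collinear_blocks(pairs, rank_index, min_anchors, max_gap)
  pairs <- classify_pairs(pairs, rank_index, blocks, ancestral_loci,
                          tandem_window, proximal_window)
  kk <- lapply(seq_len(nrow(pairs)), function(i)
    compute_ka_ks(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]]))
  pairs$ka <- vapply(kk, `[[`, numeric(1L), "ka")
  pairs$ks <- vapply(kk, `[[`, numeric(1L), "ks")
  pairs$retained <- vapply(kk, `[[`, logical(1L), "retained")
  pairs
}

#' Per-family duplication-mode summary
#'
#' Tabulates duplication modes over Ks-retained pairs (ks <= 1), per
#' lectin family, reporting both counting bases: pairs and distinct
#' genes. Percentages to one decimal.
#'
#' @param pairs Classified pairs with `mode`, `retained` (see
#'   [analyze_duplicates()]).
#' @param family_of Named character vector mapping gene id to family;
#'   a pair's family is taken from `gene_a`.
#' @return data.frame with `family`, `mode`, `n_pairs`, `pct_pairs`,
#'   `n_genes`, `pct_genes`.
#' @export
expansion_summary <- function(pairs, family_of = NULL) {
  ret <- pairs[pairs$retained, , drop = FALSE]
  if (!nrow(ret))
    return(data.frame(family = character(), mode = character(),
                      n_pairs = integer(), pct_pairs = numeric(),
                      n_genes = integer(), pct_genes = numeric()))
  fam <- if (is.null(family_of)) rep("all", nrow(ret))
         else unname(family_of[ret$gene_a])
  fam[is.na(fam)] <- "unknown"
  out <- list()
  for (f in sort(unique(fam))) {
    r <- ret[fam == f, , drop = FALSE]
    tot_pairs <- nrow(r)
    tot_genes <- length(unique(c(r$gene_a, r$gene_b)))
    for (m in sort(unique(r$mode))) {
      rm_ <- r[r$mode == m, , drop = FALSE]
      ng <- length(unique(c(rm_$gene_a, rm_$gene_b)))
      out[[length(out) + 1L]] <- data.frame(
        family = f, mode = m,
        n_pairs = nrow(rm_),
        pct_pairs = round(100 * nrow(rm_) / tot_pairs, 1L),
        n_genes = ng,
        pct_genes = round(100 * ng / tot_genes, 1L))
    }
  }
  do.call(rbind, out)
}
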