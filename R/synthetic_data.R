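# Deterministic synthetic-genome generator with a planted-truth
# manifest. Every pipeline stage (family assignment, QTL merging and
# co-localization, enrichment, duplication analysis, promoter and SSR
# scanning) can be validated against the manifest, which the generator
# computes with its own plain base-R bookkeeping, independent of the
# GenomicRanges/Biostrings code paths used by the analysis modules.

.default_family_mix <- function(s) {
  # proportions follow the census of a grain-sorghum-like lectin
  # complement (Legume-dominated, then JRL/Nictaba)
  props <- c(Legume = 0.45, JRL = 0.15, Nictaba = 0.13, Hevein = 0.09,
             EUL = 0.07, LysM = 0.05, CRA = 0.03, `Ricin-B` = 0.03)
  mix <- as.integer(round(props * s))
  names(mix) <- names(props)
  mix[1L] <- mix[1L] + (s - sum(mix))
  mix[mix < 0L] <- 0L
  mix
}

.arch_templates <- list(
  Legume = list(c("Legume", "PKinase"), c("Legume")),
  JRL = list(c("Dirigent", "JRL"), c("JRL", "JRL", "PKinase"), c("JRL")),
  Nictaba = list(c("Nictaba"), c("Nictaba", "NB-ARC")),
  Hevein = list(c("Hevein", "GH-19")),
  EUL = list(c("EUL"), c("EUL", "EUL")),
  LysM = list(c("LysM", "PKinase")),
  CRA = list(c("CRA")),
  `Ricin-B` = list(c("RIP", "Ricin-B", "Ricin-B")))

.signal_class_pool <- list(
  Legume = c("SP", "SP", "SP", "TM", "IC", "USP"),
  JRL = c("USP", "IC", "TM"),
  Nictaba = c("USP", "IC", "TM"),
  Hevein = c("SP"),
  EUL = c("USP", "IC", "SP"),
  LysM = c("SP", "TM"),
  CRA = c("SP"),
  `Ricin-B` = c("USP", "SP"))

.subcategory_scheme <- data.frame(
  subcategory = c("cold_tolerance", "drought_tolerance",
                  "disease_resistance", "grain_composition",
                  "stem_composition", "flowering_time",
                  "leaf_morphology", "root_morphology",
                  "panicle_morphology"),
  category = c("abiotic", "abiotic", "biotic", "composition",
               "composition", "maturity", "morphology", "morphology",
               "morphology"))

#' Synthetic genome configuration
#'
#' Defines the study conditions for the generator. Defaults give a
#' desk-scale genome (N = 2000 genes, s = 40 lectins over 5
#' chromosomes) that preserves the lectin fraction s/N of a real
#' grain-sorghum-like genome (order 119/34129) while keeping full
#' pipeline runs fast; merged QTL regions at this scale contain roughly
#' 100-300 genes so the expected lectin count per region stays >= 2,
#' the regime in which the Wald normal approximation is meaningful.
#'
#' @param seed Integer seed; everything downstream is reproducible from
#'   the config alone.
#' @param n_chromosomes Number of chromosomes.
#' @param n_genes Total protein-coding genes N.
#' @param s_lectins Number of lectin genes s.
#' @param family_mix Named integer vector (family -> count) summing to
#'   `s_lectins`; default scales a Legume-dominated census.
#' @param n_qtls_per_subcategory QTLs simulated per trait subcategory
#'   (9 subcategories across 5 categories).
#' @param qtl_span_range QTL length as a fraction of chromosome length
#'   (min, max).
#' @param enrichment_factor Planted enrichment factor lambda: lectin
#'   density inside enriched QTLs is lambda * s / N. `1` plants no
#'   enrichment (null-calibration fixture).
#' @param n_enriched_qtls Number of QTLs that carry the planted
#'   enrichment when `enrichment_factor > 1`.
#' @param duplication Named list: counts of `tandem`, `proximal`,
#'   `dispersed`, `transposed` pairs, and `wgd_anchors` (anchor pairs in
#'   one planted collinear block).
#' @param target_ks Vector of target Ks values recycled across pairs;
#'   values above 1 exercise the retention filter.
#' @param ka_fraction Target Ka as a fraction of target Ks.
#' @param motif_fractions Named vector: fraction of lectin genes in
#'   whose promoters each cis-element is planted.
#' @param n_ssr_plants Number of lectin genes receiving a planted
#'   intron SSR.
#' @param promoter_length Promoter length (bp) used for planting.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 5L,
                             n_genes = 2000L,
                             s_lectins = 40L,
                             family_mix = NULL,
                             n_qtls_per_subcategory = 4L,
                             qtl_span_range = c(0.25, 0.75),
                             enrichment_factor = 1,
                             n_enriched_qtls = 2L,
                             duplication = list(tandem = 3L, proximal = 2L,
                                                dispersed = 3L,
                                                transposed = 2L,
                                                wgd_anchors = 5L),
                             target_ks = c(0.15, 0.3, 0.45, 0.6, 0.8,
                                           1.2, 0.25, 0.5, 0.9, 1.1,
                                           0.2, 0.35, 0.55, 0.7, 0.4),
                             ka_fraction = 0.25,
                             motif_fractions = c(ABRE = 0.89,
                                                 `W-box` = 0.49,
                                                 MBS = 0.47, LTR = 0.39,
                                                 `WUN-motif` = 0.20),
                             n_ssr_plants = 8L,
                             promoter_length = 1500L) {
  if (is.null(family_mix)) family_mix <- .default_family_mix(s_lectins)
  if (sum(family_mix) != s_lectins)
    stop("family_mix must sum to s_lectins")
  if (s_lectins > n_genes) stop("s_lectins must be <= n_genes")
  if (enrichment_factor < 0) stop("enrichment_factor must be >= 0")
  if (enrichment_factor * s_lectins / n_genes > 1)
    stop("infeasible config: lambda * s / N exceeds 1")
  n_pair_genes <- 2L * (duplication$tandem + duplication$proximal +
                        duplication$dispersed + duplication$transposed +
                        duplication$wgd_anchors)
  if (n_pair_genes > s_lectins)
    stop("infeasible config: duplication scenario needs ", n_pair_genes,
         " lectin genes but s_lectins = ", s_lectins)
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 n_genes = n_genes, s_lectins = s_lectins,
                 family_mix = family_mix,
                 n_qtls_per_subcategory = n_qtls_per_subcategory,
                 qtl_span_range = qtl_span_range,
                 enrichment_factor = enrichment_factor,
                 n_enriched_qtls = n_enriched_qtls,
                 duplication = duplication, target_ks = target_ks,
                 ka_fraction = ka_fraction,
                 motif_fractions = motif_fractions,
                 n_ssr_plants = n_ssr_plants,
                 promoter_length = promoter_length),
            class = "synthetic_config")
}

#' Plant lectin labels with optional regional enrichment
#'
#' Assigns `s` lectin labels among `N` genes. Genes inside the enriched
#' set become lectins independently with probability
#' `lambda * s / N`; the remaining labels are placed uniformly among
#' the other genes so exactly `s` genes are labelled. With an empty
#' enriched set (or `lambda = 1`) labels are uniform over all genes.
#'
#' @param N Total genes.
#' @param s Lectin labels to place.
#' @param enriched_idx Integer indices of genes in enriched regions.
#' @param lambda Enrichment factor.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return Sorted integer vector of lectin gene indices (length `s`).
#' @export
plant_lectin_labels <- function(N, s, enriched_idx = integer(),
                                lambda = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!length(enriched_idx) || lambda == 1)
    return(sort(sample.int(N, s)))
  p <- lambda * s / N
  if (p > 1) stop("infeasible: lambda * s / N > 1")
  inside <- enriched_idx[stats::runif(length(enriched_idx)) < p]
  if (length(inside) > s)
    stop("infeasible: planted enrichment requires more than s lectins")
  outside_pool <- setdiff(seq_len(N), enriched_idx)
  if (s - length(inside) > length(outside_pool))
    stop("infeasible: not enough genes outside enriched regions")
  sort(c(inside, sample(outside_pool, s - length(inside))))
}

#' Uniform null resampling of lectin labels
#'
#' Reassigns the `s` lectin labels uniformly at random without
#' replacement among the `N` genes, `n_reps` times. Deterministic per
#' seed.
#'
#' @param N,s Genome totals.
#' @param n_reps Number of resamples.
#' @param seed Integer seed.
#' @return `n_reps x s` integer matrix; each row a label set.
#' @export
null_resample <- function(N, s, n_reps, seed) {
  set.seed(seed)
  t(vapply(seq_len(n_reps), function(i) sample.int(N, s),
           integer(s)))
}

#' Empirical null calibration of the Wald test
#'
#' For a list of regions (gene index sets), resamples lectin labels
#' under the uniform null and reports the fraction of (region,
#' resample) combinations with one-sided Wald P below `alpha`.
#'
#' @param region_gene_idx List of integer vectors (gene indices per
#'   region).
#' @param N,s Genome totals.
#' @param n_reps Resamples (default 10000).
#' @param seed Integer seed.
#' @param alpha Threshold (default 0.05).
#' @return List with `fraction` (scalar) and `n_tests`.
#' @export
null_calibration <- function(region_gene_idx, N, s, n_reps = 10000L,
                             seed = 1L, alpha = 0.05) {
  labels <- null_resample(N, s, n_reps, seed)
  n <- lengths(region_gene_idx)
  p0 <- s / N
  denom <- sqrt(p0 * (1 - p0) / n)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    member <- logical(N)
    member[labels[r, ]] <- TRUE
    k <- vapply(region_gene_idx, function(idx) sum(member[idx]),
                integer(1L))
    p <- stats::pnorm((p0 - k / n) / denom)
    hits <- hits + sum(p < alpha)
  }
  list(fraction = hits / (n_reps * length(region_gene_idx)),
       n_tests = n_reps * length(region_gene_idx))
}

# ---- internal generator helpers ------------------------------------------

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  setdiff(names(gc)[gc != "*"], c())
}

.random_cds <- function(n_codons) {
  sense <- .sense_codons()
  paste(c("ATG", sample(setdiff(sense, "ATG"), n_codons - 2L,
                        replace = TRUE), "TAA"), collapse = "")
}

.iupac_expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG",
                   Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                   B = "CGT", D = "AGT", H = "ACT", V = "ACG",
                   N = "ACGT")

.instantiate_iupac <- function(pattern) {
  paste(vapply(strsplit(toupper(pattern), "")[[1L]], function(cc) {
    opts <- strsplit(.iupac_expand[[cc]], "")[[1L]]
    opts[sample.int(length(opts), 1L)]
  }, character(1L)), collapse = "")
}

# synonymous / nonsynonymous single-base alternatives for one codon
.codon_alternatives <- function(codon, synonymous = TRUE) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  sp <- strsplit(codon, "")[[1L]]
  out <- character(0)
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), sp[pos])) {
    mut <- sp; mut[pos] <- b
    mcd <- paste(mut, collapse = "")
    if (gc[[mcd]] == "*") next
    if (synonymous == (gc[[mcd]] == aa)) out <- c(out, mcd)
  }
  out
}

# mutate a copy of cds codon-wise until NG86+JC ks/ka reach targets
.mutate_to_targets <- function(cds, ks_target, ka_target) {
  codons <- substring(cds, 3L * seq_len(nchar(cds) %/% 3L) - 2L,
                      3L * seq_len(nchar(cds) %/% 3L))
  touched <- logical(length(codons))
  touched[c(1L, length(codons))] <- TRUE  # keep start/stop intact
  apply_muts <- function(n_mut, synonymous) {
    free <- which(!touched)
    free <- free[sample.int(length(free))]
    done <- 0L
    for (i in free) {
      if (done >= n_mut) break
      alts <- .codon_alternatives(codons[i], synonymous)
      if (!length(alts)) next
      codons[i] <<- alts[sample.int(length(alts), 1L)]
      touched[i] <<- TRUE
      done <- done + 1L
    }
    done
  }
  measure <- function() compute_ka_ks(cds, paste(codons, collapse = ""))
  # initial guess from inverted Jukes-Cantor, then fine-tune
  m0 <- measure()
  ps_t <- 3 / 4 * (1 - exp(-4 * ks_target / 3))
  pn_t <- 3 / 4 * (1 - exp(-4 * ka_target / 3))
  apply_muts(round(ps_t * m0$syn_sites), TRUE)
  apply_muts(round(pn_t * m0$nonsyn_sites), FALSE)
  for (step in 1:200) {
    m <- measure()
    if (is.na(m$ks) || m$ks >= 0.98 * ks_target) break
    if (apply_muts(1L, TRUE) == 0L) break
  }
  for (step in 1:200) {
    m <- measure()
    if (is.na(m$ka) || m$ka >= 0.98 * ka_target) break
    if (apply_muts(1L, FALSE) == 0L) break
  }
  m <- measure()
  list(cds = paste(codons, collapse = ""), ka = m$ka, ks = m$ks)
}

# simple independent interval union sweep (1-based closed)
.sweep_merge <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out <- list()
  if (length(starts) > 1L) for (i in 2L:length(starts)) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { out[[length(out) + 1L]] <- c(ms, me); ms <- starts[i]; me <- ends[i] }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  do.call(rbind, out)
}

#' Generate a complete synthetic input set with manifest
#'
#' Produces, deterministically from the config seed, every input the
#' pipeline consumes -- gene annotation (GFF3), genome and CDS FASTA,
#' protein-domain hits, secretion-predictor table, QTL table, homolog
#' pairs and ancestral loci -- plus a manifest of all planted truths:
#' lectin identities and families, per-gene architectures and signal
#' classes, merged-QTL regions with their (n, k) gene counts computed
#' by plain brute-force sweeps, duplicate-pair modes with realized
#' Ka/Ks, and planted promoter-motif and SSR loci.
#'
#' @param config A [synthetic_config()].
#' @param outdir Optional directory; when given, all files are written
#'   there (`genes.gff3`, `genome.fa`, `cds.fa`, `domains.tsv`,
#'   `predictors.tsv`, `qtls.tsv`, `pairs.tsv`, `ancestral_loci.tsv`
#'   and `manifest_*.tsv`).
#' @return Invisible list with all tables, sequences and the `manifest`
#'   list.
#' @export
generate_synthetic_genome <- function(config = synthetic_config(),
                                      outdir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  N <- config$n_genes
  n_chr <- config$n_chromosomes
  per_chr <- rep(N %/% n_chr, n_chr)
  per_chr[seq_len(N %% n_chr)] <- per_chr[seq_len(N %% n_chr)] + 1L
  chrom_names <- sprintf("Chr%02d", seq_len(n_chr))
  slot <- 2200L
  chrom_len <- per_chr * slot + 2000L
  names(chrom_len) <- chrom_names

  # ---- gene placement ----
  genes_df <- do.call(rbind, lapply(seq_len(n_chr), function(ci) {
    m <- per_chr[ci]
    data.frame(chromosome = chrom_names[ci], rank = seq_len(m),
               slot_start = (seq_len(m) - 1L) * slot + 1000L)
  }))
  genes_df$gene_id <- sprintf("SynG%02d%04d",
                              match(genes_df$chromosome, chrom_names),
                              genes_df$rank)
  genes_df$strand <- sample(c("+", "-"), nrow(genes_df), replace = TRUE)
  genes_df$n_codons <- sample(100:300, nrow(genes_df), replace = TRUE)
  genes_df$n_exons <- sample(1:4, nrow(genes_df), replace = TRUE,
                             prob = c(0.3, 0.3, 0.25, 0.15))
  gene_index <- seq_len(nrow(genes_df))

  # exon layout per gene: exons carry the CDS exactly; introns 50-300 bp
  structures <- vector("list", nrow(genes_df))
  for (i in gene_index) {
    len <- 3L * genes_df$n_codons[i]
    ne <- genes_df$n_exons[i]
    cuts <- if (ne > 1L)
      sort(sample(seq(3L, len - 3L, by = 3L), ne - 1L)) else integer()
    piece_len <- diff(c(0L, cuts, len))
    introns <- if (ne > 1L) sample(50:300, ne - 1L, replace = TRUE)
               else integer()
    start <- genes_df$slot_start[i] + sample(0:150, 1L)
    ex <- matrix(0L, nrow = ne, ncol = 2L)
    p <- start
    for (e in seq_len(ne)) {
      ex[e, ] <- c(p, p + piece_len[e] - 1L)
      p <- ex[e, 2L] + 1L + (if (e < ne) introns[e] else 0L)
    }
    structures[[i]] <- ex
  }
  genes_df$start <- vapply(structures, function(m) m[1L, 1L], integer(1L))
  genes_df$end <- vapply(structures, function(m) m[nrow(m), 2L],
                         integer(1L))

  # ---- QTL table ----
  scheme <- .subcategory_scheme
  qtl_rows <- list()
  qid <- 0L
  for (si in seq_len(nrow(scheme))) {
    for (j in seq_len(config$n_qtls_per_subcategory)) {
      ci <- sample.int(n_chr, 1L)
      L <- chrom_len[ci]
      span <- round(stats::runif(1, config$qtl_span_range[1L],
                                 config$qtl_span_range[2L]) * L)
      st <- sample.int(max(L - span, 1L), 1L)
      qid <- qid + 1L
      qtl_rows[[qid]] <- data.frame(
        qtl_id = sprintf("Q%04d", qid),
        trait = sprintf("%s_trait%d", scheme$subcategory[si],
                        1L + (j %% 2L)),
        subcategory = scheme$subcategory[si],
        category = scheme$category[si],
        chromosome = chrom_names[ci],
        start = st, end = min(st + span - 1L, L))
    }
  }
  qtl <- do.call(rbind, qtl_rows)

  # enriched gene set: union of genes overlapping the designated QTLs
  overlaps_gene <- function(chrom, st, en) {
    which(genes_df$chromosome == chrom & genes_df$start <= en &
          genes_df$end >= st)
  }
  enriched_idx <- integer(0)
  enriched_qtls <- character(0)
  if (config$enrichment_factor > 1 && config$n_enriched_qtls > 0L) {
    enriched_qtls <- qtl$qtl_id[seq_len(min(config$n_enriched_qtls,
                                            nrow(qtl)))]
    for (qi in match(enriched_qtls, qtl$qtl_id))
      enriched_idx <- union(enriched_idx,
                            overlaps_gene(qtl$chromosome[qi],
                                          qtl$start[qi], qtl$end[qi]))
  }

  # ---- lectin labels + duplication scenario ----
  lectin_idx <- plant_lectin_labels(N, config$s_lectins, enriched_idx,
                                    config$enrichment_factor)
  used <- logical(N)
  is_lectin <- logical(N); is_lectin[lectin_idx] <- TRUE
  relabel <- function(target) {
    # make gene `target` a lectin by moving a donor label
    if (is_lectin[target]) return(invisible(TRUE))
    donors <- which(is_lectin & !used & !seq_len(N) %in% enriched_idx)
    donors <- setdiff(donors, target)
    if (!length(donors)) donors <- which(is_lectin & !used)
    if (!length(donors)) stop("infeasible duplication scenario")
    d <- donors[sample.int(length(donors), 1L)]
    is_lectin[d] <<- FALSE; is_lectin[target] <<- TRUE
    invisible(TRUE)
  }
  idx_of <- function(chrom, rank)
    which(genes_df$chromosome == chrom & genes_df$rank == rank)
  pick_pair <- function(dist_min, dist_max, same_chr = TRUE) {
    for (try in 1:500) {
      a <- sample.int(N, 1L)
      if (used[a]) next
      if (same_chr) {
        d <- sample(dist_min:dist_max, 1L) * sample(c(-1L, 1L), 1L)
        b <- idx_of(genes_df$chromosome[a], genes_df$rank[a] + d)
        if (!length(b) || used[b]) next
        if (same_chr && dist_min > 10L &&
            abs(genes_df$rank[a] - genes_df$rank[b]) <= 10L) next
      } else {
        b <- sample.int(N, 1L)
        if (used[b] || genes_df$chromosome[b] == genes_df$chromosome[a])
          next
      }
      return(c(a, b))
    }
    stop("could not place duplication pair (scenario too dense)")
  }
  pairs <- list(); ancestral <- character(0)
  add_pair <- function(a, b, mode) {
    used[c(a, b)] <<- TRUE   # lock both before donor selection
    relabel(a); relabel(b)
    pairs[[length(pairs) + 1L]] <<- data.frame(
      gene_a = genes_df$gene_id[a], gene_b = genes_df$gene_id[b],
      mode = mode, idx_a = a, idx_b = b)
  }
  dup <- config$duplication
  for (i in seq_len(dup$tandem)) {
    p <- pick_pair(1L, 1L); add_pair(p[1L], p[2L], "tandem")
  }
  for (i in seq_len(dup$proximal)) {
    p <- pick_pair(2L, 10L); add_pair(p[1L], p[2L], "proximal")
  }
  for (i in seq_len(dup$dispersed)) {
    p <- pick_pair(0L, 0L, same_chr = FALSE)
    add_pair(p[1L], p[2L], "dispersed")
  }
  for (i in seq_len(dup$transposed)) {
    p <- pick_pair(0L, 0L, same_chr = FALSE)
    add_pair(p[1L], p[2L], "transposed")
    ancestral <- c(ancestral, genes_df$gene_id[p[1L]])
  }
  if (dup$wgd_anchors > 0L) {
    # one collinear block: anchors with small monotone rank gaps on two
    # different chromosomes
    for (try in 1:200) {
      cpair <- sample.int(n_chr, 2L)
      ra <- 20L + cumsum(sample(1:4, dup$wgd_anchors, replace = TRUE))
      rb <- 30L + cumsum(sample(1:4, dup$wgd_anchors, replace = TRUE))
      ia <- vapply(ra, function(r) {
        z <- idx_of(chrom_names[cpair[1L]], r)
        if (length(z)) z else NA_integer_ }, integer(1L))
      ib <- vapply(rb, function(r) {
        z <- idx_of(chrom_names[cpair[2L]], r)
        if (length(z)) z else NA_integer_ }, integer(1L))
      if (anyNA(ia) || anyNA(ib) || any(used[c(ia, ib)])) next
      for (ai in seq_len(dup$wgd_anchors))
        add_pair(ia[ai], ib[ai], "wgd")
      break
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(), gene_b = character(),
               mode = character(), idx_a = integer(), idx_b = integer())
  lectin_idx <- which(is_lectin)

  # ---- families / architectures / domains ----
  quota <- config$family_mix
  family <- rep(NA_character_, N)
  # the WGD block is one family; other pairs one family each
  components <- list()
  if (nrow(pairs)) {
    wgd_rows <- pairs$mode == "wgd"
    if (any(wgd_rows))
      components[[length(components) + 1L]] <-
        unique(c(pairs$idx_a[wgd_rows], pairs$idx_b[wgd_rows]))
    for (i in which(!wgd_rows))
      components[[length(components) + 1L]] <-
        c(pairs$idx_a[i], pairs$idx_b[i])
  }
  components <- components[order(-lengths(components))]
  for (comp in components) {
    fit <- names(quota)[quota >= length(comp)]
    if (!length(fit)) stop("family_mix cannot host duplication scenario")
    f <- fit[which.max(quota[fit])]
    family[comp] <- f
    quota[f] <- quota[f] - length(comp)
  }
  singles <- setdiff(lectin_idx, which(!is.na(family)))
  pool <- rep(names(quota), quota)
  pool <- pool[sample.int(length(pool))]
  family[singles] <- pool[seq_along(singles)]

  arch <- vector("list", N)
  for (i in lectin_idx) {
    tpl <- .arch_templates[[family[i]]]
    arch[[i]] <- tpl[[sample.int(length(tpl), 1L)]]
  }
  # a few non-lectin genes carry kinase-only hits (must be excluded by
  # the screen)
  nonlec <- setdiff(gene_index, lectin_idx)
  decoys <- sample(nonlec, min(20L, length(nonlec)))
  catalog <- default_family_catalog()
  acc_of <- function(name) {
    a <- catalog$lectin_domains[[name]]
    if (is.null(a)) a <- catalog$partner_domains[[name]]
    a[1L]
  }
  dom_rows <- list()
  for (i in c(lectin_idx, decoys)) {
    doms <- if (i %in% decoys) "PKinase" else arch[[i]]
    p <- 10L
    for (dn in doms) {
      w <- sample(60:120, 1L)
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        gene_id = genes_df$gene_id[i], accession = acc_of(dn),
        name = dn, start_aa = p, end_aa = p + w - 1L,
        evalue = signif(10^stats::runif(1, -30, -5), 3L))
      p <- p + w + sample(5:25, 1L)
    }
  }
  domains <- do.call(rbind, dom_rows)

  # ---- signal classes + predictor table ----
  signal_class <- rep(NA_character_, N)
  for (i in lectin_idx) {
    pool_sc <- .signal_class_pool[[family[i]]]
    signal_class[i] <- pool_sc[sample.int(length(pool_sc), 1L)]
  }
  loc_for <- function(sc) switch(sc,
    SP = "extracellular", TM = "plasma membrane",
    IC = sample(c("nucleus", "cytoplasm", "chloroplast"), 1L),
    USP = "extracellular")
  predictors <- do.call(rbind, lapply(lectin_idx, function(i) {
    sc <- signal_class[i]
    data.frame(gene_id = genes_df$gene_id[i],
               signal_peptide = ifelse(sc == "SP", "yes", "no"),
               transmembrane = ifelse(sc == "TM", "yes", "no"),
               localization = loc_for(sc))
  }))

  # ---- CDS sequences (pairs mutated to target Ks) ----
  cds <- setNames(vector("list", N), genes_df$gene_id)
  for (i in gene_index) cds[[i]] <- NA_character_
  pair_ka <- pair_ks <- rep(NA_real_, nrow(pairs))
  if (nrow(pairs)) {
    tks <- rep_len(config$target_ks, nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$idx_a[i]; b <- pairs$idx_b[i]
      nc <- max(genes_df$n_codons[a], 200L)
      genes_df$n_codons[a] <- genes_df$n_codons[b] <- nc
      base <- .random_cds(nc)
      mut <- .mutate_to_targets(base, tks[i], tks[i] * config$ka_fraction)
      cds[[a]] <- base
      cds[[b]] <- mut$cds
      pair_ka[i] <- mut$ka; pair_ks[i] <- mut$ks
    }
    pairs$target_ks <- tks
    pairs$planted_ks <- pair_ks
    pairs$planted_ka <- pair_ka
    # re-derive structures for genes whose codon count changed
    for (i in unique(c(pairs$idx_a, pairs$idx_b))) {
      len <- 3L * genes_df$n_codons[i]
      ne <- genes_df$n_exons[i]
      cuts <- if (ne > 1L)
        sort(sample(seq(3L, len - 3L, by = 3L), ne - 1L)) else integer()
      piece_len <- diff(c(0L, cuts, len))
      introns <- if (ne > 1L) sample(50:300, ne - 1L, replace = TRUE)
                 else integer()
      start <- genes_df$slot_start[i] + sample(0:150, 1L)
      ex <- matrix(0L, nrow = ne, ncol = 2L)
      p <- start
      for (e in seq_len(ne)) {
        ex[e, ] <- c(p, p + piece_len[e] - 1L)
        p <- ex[e, 2L] + 1L + (if (e < ne) introns[e] else 0L)
      }
      structures[[i]] <- ex
      genes_df$start[i] <- ex[1L, 1L]
      genes_df$end[i] <- ex[ne, 2L]
    }
  }
  for (i in gene_index)
    if (is.na(cds[[i]])) cds[[i]] <- .random_cds(genes_df$n_codons[i])
  cds <- unlist(cds)

  # ---- chromosome sequences with CDS planted in place ----
  chrom_seq <- lapply(chrom_len, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  cds_mask <- lapply(chrom_len, function(L) logical(L))  # bases locked
  for (i in gene_index) {
    ex <- structures[[i]]
    ci <- genes_df$chromosome[i]
    seq_i <- strsplit(cds[[genes_df$gene_id[i]]], "")[[1L]]
    if (genes_df$strand[i] == "-")
      seq_i <- rev(chartr("ACGT", "TGCA", seq_i))
    p <- 1L
    for (e in seq_len(nrow(ex))) {
      w <- ex[e, 2L] - ex[e, 1L] + 1L
      chrom_seq[[ci]][ex[e, 1L]:ex[e, 2L]] <- seq_i[p:(p + w - 1L)]
      cds_mask[[ci]][ex[e, 1L]:ex[e, 2L]] <- TRUE
      p <- p + w
    }
  }

  # ---- promoter motif planting ----
  motif_table <- default_cis_elements()
  plant_rows <- list()
  promoter_window <- function(i) {
    # genomic interval of the promoter, strand-aware
    if (genes_df$strand[i] == "+")
      c(max(1L, genes_df$start[i] - config$promoter_length),
        genes_df$start[i] - 1L)
    else
      c(genes_df$end[i] + 1L,
        min(chrom_len[[genes_df$chromosome[i]]],
            genes_df$end[i] + config$promoter_length))
  }
  for (mn in names(config$motif_fractions)) {
    mrow <- match(mn, motif_table$name)
    if (is.na(mrow)) stop("motif not in catalog: ", mn)
    n_plant <- round(config$motif_fractions[[mn]] * length(lectin_idx))
    targets <- sample(lectin_idx, n_plant)
    for (i in targets) {
      win <- promoter_window(i)
      if (win[2L] - win[1L] + 1L < config$promoter_length) next
      inst <- .instantiate_iupac(motif_table$pattern[mrow])
      w <- nchar(inst)
      ci <- genes_df$chromosome[i]
      placed <- FALSE
      for (try in 1:25) {
        off <- sample.int(config$promoter_length - w + 1L, 1L) - 1L
        gpos <- if (genes_df$strand[i] == "+") win[1L] + off
                else win[2L] - off - w + 1L
        span <- gpos:(gpos + w - 1L)
        if (any(cds_mask[[ci]][span])) next
        bases <- strsplit(inst, "")[[1L]]
        if (genes_df$strand[i] == "-")
          bases <- rev(chartr("ACGT", "TGCA", bases))
        chrom_seq[[ci]][span] <- bases
        cds_mask[[ci]][span] <- TRUE  # lock against later overwrites
        plant_rows[[length(plant_rows) + 1L]] <- data.frame(
          gene_id = genes_df$gene_id[i], motif = mn,
          offset = off, strand = "+", instance = inst)
        placed <- TRUE
        break
      }
    }
  }
  planted_motifs <- if (length(plant_rows)) do.call(rbind, plant_rows)
    else data.frame(gene_id = character(), motif = character(),
                    offset = integer(), strand = character(),
                    instance = character())

  # ---- SSR planting (introns of multi-exon lectin genes) ----
  ssr_units <- c("AG", "AT", "CT", "AAG", "AGC", "A")
  ssr_rows <- list()
  candidates <- lectin_idx[genes_df$n_exons[lectin_idx] >= 2L]
  for (i in utils::head(candidates, config$n_ssr_plants)) {
    ex <- structures[[i]]
    intr <- c(ex[1L, 2L] + 1L, ex[2L, 1L] - 1L)
    unit <- ssr_units[1L + (length(ssr_rows) %% length(ssr_units))]
    u <- nchar(unit)
    count <- max(.default_ssr_min_repeats[[as.character(u)]], 8L)
    need <- u * count + 2L
    if (intr[2L] - intr[1L] + 1L < need) next
    st <- intr[1L] + 1L
    ci <- genes_df$chromosome[i]
    span <- (st - 1L):(st + u * count)  # repeat plus both break flanks
    if (any(cds_mask[[ci]][span])) next
    span <- st:(st + u * count - 1L)
    chrom_seq[[ci]][span] <- rep(strsplit(unit, "")[[1L]], count)
    # break the repeat at both flanks
    brk <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
    chrom_seq[[ci]][st - 1L] <- brk(chrom_seq[[ci]][st + u - 1L])
    chrom_seq[[ci]][st + u * count] <- brk(chrom_seq[[ci]][st + u * count - u])
    cds_mask[[ci]][(st - 1L):(st + u * count)] <- TRUE
    ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
      gene_id = genes_df$gene_id[i], chromosome = ci, unit = unit,
      unit_length = u, repeat_count = count, start = st,
      end = st + u * count - 1L)
  }
  planted_ssrs <- if (length(ssr_rows)) do.call(rbind, ssr_rows)
    else data.frame(gene_id = character(), chromosome = character(),
                    unit = character(), unit_length = integer(),
                    repeat_count = integer(), start = integer(),
                    end = integer())

  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste,
                                            character(1L), collapse = ""))
  names(genome) <- chrom_names

  # ---- manifest regions: independent merge + counts ----
  region_rows <- list()
  for (sub in scheme$subcategory) {
    q <- qtl[qtl$subcategory == sub, , drop = FALSE]
    for (ci in unique(q$chromosome)) {
      qq <- q[q$chromosome == ci, , drop = FALSE]
      mg <- .sweep_merge(qq$start, qq$end)
      for (ri in seq_len(nrow(mg))) {
        gi <- overlaps_gene(ci, mg[ri, 1L], mg[ri, 2L])
        region_rows[[length(region_rows) + 1L]] <- data.frame(
          grouping_key = sub, chromosome = ci,
          start = mg[ri, 1L], end = mg[ri, 2L],
          n_genes = length(gi), k_lectins = sum(is_lectin[gi]),
          gene_idx = paste(gi, collapse = ","))
      }
    }
  }
  regions <- do.call(rbind, region_rows)
  regions <- regions[order(regions$grouping_key, regions$chromosome,
                           regions$start), , drop = FALSE]
  rownames(regions) <- NULL

  gene_models <- lapply(gene_index, function(i)
    gene_model(genes_df$gene_id[i], genes_df$chromosome[i],
               genes_df$start[i], genes_df$end[i], genes_df$strand[i],
               exons = structures[[i]], cds = structures[[i]],
               transcript_ids = paste0(genes_df$gene_id[i], ".1")))
  names(gene_models) <- genes_df$gene_id

  manifest <- list(
    genes = data.frame(genes_df[, c("gene_id", "chromosome", "rank",
                                    "start", "end", "strand",
                                    "n_exons", "n_codons")],
                       is_lectin = is_lectin,
                       family = ifelse(is.na(family), "", family),
                       signal_class = ifelse(is.na(signal_class), "",
                                             signal_class)),
    regions = regions,
    pairs = pairs,
    enriched_qtls = enriched_qtls,
    planted_motifs = planted_motifs,
    planted_ssrs = planted_ssrs,
    architectures = data.frame(
      gene_id = genes_df$gene_id[lectin_idx],
      architecture = vapply(arch[lectin_idx], paste, character(1L),
                            collapse = "|")))

  out <- list(config = config, genes = gene_models,
              genes_table = genes_df, genome = genome, cds = cds,
              domains = domains, predictors = predictors, qtl = qtl,
              pairs = pairs[, c("gene_a", "gene_b")],
              ancestral_loci = ancestral, manifest = manifest)
  if (!is.null(outdir)) write_synthetic_genome(out, outdir)
  invisible(out)
}

#' Write a generated synthetic data set to disk
#'
#' @param sim Result of [generate_synthetic_genome()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synthetic_genome <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outdir, f)
  write_gff3(sim$genes, fp("genes.gff3"))
  Biostrings::writeXStringSet(sim$genome, fp("genome.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$cds), fp("cds.fa"))
  write_table_tsv(sim$domains, fp("domains.tsv"))
  write_table_tsv(sim$predictors, fp("predictors.tsv"))
  write_table_tsv(sim$qtl, fp("qtls.tsv"))
  write_table_tsv(sim$pairs, fp("pairs.tsv"))
  write_table_tsv(data.frame(gene_id = sim$ancestral_loci),
                  fp("ancestral_loci.tsv"))
  write_table_tsv(sim$manifest$genes, fp("manifest_genes.tsv"))
  write_table_tsv(sim$manifest$regions, fp("manifest_regions.tsv"))
  write_table_tsv(sim$manifest$pairs, fp("manifest_pairs.tsv"))
  write_table_tsv(sim$manifest$planted_motifs, fp("manifest_motifs.tsv"))
  write_table_tsv(sim$manifest$planted_ssrs, fp("manifest_ssrs.tsv"))
  write_table_tsv(sim$manifest$architectures,
                  fp("manifest_architectures.tsv"))
  invisible(outdir)
}
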