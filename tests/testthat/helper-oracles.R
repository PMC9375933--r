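# Independent brute-force oracles. Each is deliberately written as the
# most literal possible computation (per-base boolean arrays, all-pairs
# scans, exhaustive enumeration), separate from the package's
# GenomicRanges/Biostrings/vectorized code paths.

# per-base union coverage of 1-based closed intervals
oracle_union_coverage <- function(starts, ends, max_pos = max(ends)) {
  covered <- logical(max_pos)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  covered
}

# all-pairs overlap counting: (n, k) per region
oracle_count_region <- function(region_chrom, region_start, region_end,
                                gene_chrom, gene_start, gene_end,
                                is_lectin) {
  n <- 0L; k <- 0L
  for (g in seq_along(gene_chrom)) {
    if (gene_chrom[g] == region_chrom &&
        gene_start[g] <= region_end && gene_end[g] >= region_start) {
      n <- n + 1L
      if (is_lectin[g]) k <- k + 1L
    }
  }
  c(n = n, k = k)
}

# hypergeometric upper tail by log-space summation of choose terms
oracle_hyper_tail <- function(N, s, n, k) {
  if (k <= 0) return(1)
  kk <- k:min(n, s)
  terms <- lchoose(s, kk) + lchoose(N - s, n - kk) - lchoose(N, n)
  m <- max(terms)
  exp(m) * sum(exp(terms - m))
}

# ---- independent NG86 oracle ---------------------------------------------
# per-codon enumeration with its own bookkeeping; conventions match the
# documented ones (stop-codon mutations nonsynonymous, stop-passing
# pathways excluded unless all are blocked, JC correction).

.oracle_code <- as.list(Biostrings::GENETIC_CODE)

oracle_syn_sites_codon <- function(codon) {
  aa <- .oracle_code[[codon]]
  if (aa == "*") return(0)
  total <- 0
  chars <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == chars[pos]) next
      mut <- chars; mut[pos] <- b
      maa <- .oracle_code[[paste(mut, collapse = "")]]
      if (maa != "*" && maa == aa) total <- total + 1 / 3
      # stop or different aa: nonsynonymous site fraction
    }
  }
  total
}

oracle_path_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0) return(c(0, 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) res[[length(res) + 1]] <- c(v[i], p)
    res
  }
  good <- list(); blocked <- list()
  for (path in perms(pos)) {
    cur <- a; sd <- 0; nd <- 0; via_stop <- FALSE
    for (p in path) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- .oracle_code[[paste(cur, collapse = "")]]
      aa2 <- .oracle_code[[paste(nxt, collapse = "")]]
      if (aa1 == "*" || aa2 == "*") via_stop <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (via_stop) blocked[[length(blocked) + 1]] <- c(sd, nd)
    else good[[length(good) + 1]] <- c(sd, nd)
  }
  use <- if (length(good)) good else blocked
  Reduce(`+`, use) / length(use)
}

oracle_ng86 <- function(seq1, seq2) {
  n <- nchar(seq1) / 3
  c1 <- substring(seq1, 3 * (1:n) - 2, 3 * (1:n))
  c2 <- substring(seq2, 3 * (1:n) - 2, 3 * (1:n))
  # drop shared terminal stop
  if (.oracle_code[[c1[n]]] == "*" && .oracle_code[[c2[n]]] == "*") {
    c1 <- c1[-n]; c2 <- c2[-n]
  }
  S <- (sum(sapply(c1, oracle_syn_sites_codon)) +
        sum(sapply(c2, oracle_syn_sites_codon))) / 2
  NN <- 3 * length(c1) - S
  sd <- 0; nd <- 0
  for (i in seq_along(c1)) {
    d <- oracle_path_diffs(c1[i], c2[i])
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  ps <- sd / S; pn <- nd / NN
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ks = jc(ps), ka = jc(pn), ps = ps, pn = pn, S = S, N = NN)
}

# ---- brute-force IUPAC motif scanner --------------------------------------

.oracle_iupac <- list(A = "A", C = "C", G = "G", T = "T",
                      R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                      W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x),
                     "")[[1]]), collapse = "")
}

oracle_scan_one_strand <- function(promoter, pattern) {
  p <- strsplit(toupper(promoter), "")[[1]]
  m <- strsplit(toupper(pattern), "")[[1]]
  hits <- integer(0)
  if (length(m) > length(p)) return(hits)
  for (off in 0:(length(p) - length(m))) {
    ok <- TRUE
    for (j in seq_along(m)) {
      if (!(p[off + j] %in% .oracle_iupac[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

oracle_scan_iupac <- function(promoter, pattern) {
  list(plus = oracle_scan_one_strand(promoter, pattern),
       minus = oracle_scan_one_strand(promoter, oracle_revcomp(pattern)))
}

# ---- exhaustive SSR enumerator -------------------------------------------
# every (start, unit length, count) candidate, kept when perfect, above
# threshold, unit primitive, and maximal (not extendable by one unit on
# either side); reported at whole-unit extent.

oracle_find_ssrs <- function(sequence, min_repeats = c(`1` = 10, `2` = 6,
                                                       `3` = 5, `4` = 5,
                                                       `5` = 5, `6` = 5)) {
  s <- strsplit(toupper(sequence), "")[[1]]
  L <- length(s)
  primitive <- function(unit) {
    u <- nchar(unit)
    for (d in seq_len(u - 1)) {
      if (u %% d == 0 &&
          unit == paste(rep(substr(unit, 1, d), u / d), collapse = ""))
        return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (u in 1:6) {
    for (st in seq_len(L - u + 1)) {
      unit <- paste(s[st:(st + u - 1)], collapse = "")
      if (grepl("[^ACGT]", unit) || !primitive(unit)) next
      # count maximal whole-unit extension to the right
      count <- 1
      while (st + (count + 1) * u - 1 <= L &&
             paste(s[(st + count * u):(st + (count + 1) * u - 1)],
                   collapse = "") == unit) count <- count + 1
      if (count < min_repeats[[as.character(u)]]) next
      # maximality: not extendable left by one unit, and the position
      # just left must not continue the period (leftmost phase)
      if (st - 1 >= 1 && s[st - 1] == s[st - 1 + u]) next
      out[[length(out) + 1]] <- data.frame(
        unit = unit, unit_length = as.integer(u),
        repeat_count = as.integer(count), start = as.integer(st),
        end = as.integer(st + count * u - 1))
    }
  }
  if (!length(out))
    return(data.frame(unit = character(), unit_length = integer(),
                      repeat_count = integer(), start = integer(),
                      end = integer()))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# rule-table oracle for duplication-mode classification
oracle_classify <- function(chrom_a, rank_a, chrom_b, rank_b,
                            anchor_keys, anc_a, anc_b,
                            tandem_window = 1, proximal_window = 10,
                            key = NULL) {
  same <- chrom_a == chrom_b
  d <- abs(rank_a - rank_b)
  if (same && d <= tandem_window) return("tandem")
  if (same && d <= proximal_window) return("proximal")
  if (!is.null(key) && key %in% anchor_keys) return("wgd")
  if (sum(c(anc_a, anc_b)) == 1) return("transposed")
  "dispersed"
}
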