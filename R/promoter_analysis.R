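# Strand-aware promoter extraction, IUPAC cis-element scanning on both
# strands (via Biostrings), and perfect SSR detection.

#' Default cis-acting element motif table
#'
#' A small editable catalog of well-known plant promoter elements,
#' grouped into seven functional categories. Shipped as a TSV at
#' `system.file("extdata", "cis_elements.tsv", package = "lectinscan")`;
#' this accessor reads it. The table is configuration, not hard-coded
#' biology: users may pass any (name, IUPAC pattern, category) table.
#'
#' @return data.frame with `name`, `pattern`, `category`.
#' @export
default_cis_elements <- function() {
  path <- system.file("extdata", "cis_elements.tsv",
                      package = "lectinscan")
  read_table_tsv(path, c("name", "pattern", "category"))
}

#' Extract a promoter sequence
#'
#' The promoter is the `length` bp immediately upstream of the gene,
#' strand-aware: for a plus-strand gene the bases ending just before
#' the gene start; for a minus-strand gene the reverse complement of
#' the bases starting just after the gene end. Promoters are truncated
#' at chromosome edges and flagged.
#'
#' @param genome Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param gene A [gene_model].
#' @param length Promoter length in bp (default 1500).
#' @return Character string with attribute `truncated` (logical).
#' @export
extract_promoter <- function(genome, gene, length = 1500L) {
  seqs <- if (methods::is(genome, "DNAStringSet")) genome
          else Biostrings::DNAStringSet(genome)
  if (!gene$chromosome %in% names(seqs))
    stop("chromosome not in genome: ", gene$chromosome)
  chrom <- seqs[[gene$chromosome]]
  clen <- Biostrings::nchar(chrom)
  if (gene$strand == "+") {
    to <- gene$start - 1L
    from <- max(1L, gene$start - length)
    truncated <- (to - from + 1L) < length
    s <- if (to < from) "" else as.character(Biostrings::subseq(
      chrom, from, to))
  } else {
    from <- gene$end + 1L
    to <- min(clen, gene$end + length)
    truncated <- (to - from + 1L) < length
    s <- if (to < from) "" else as.character(
      Biostrings::reverseComplement(Biostrings::subseq(chrom, from, to)))
  }
  structure(s, truncated = truncated)
}

.valid_iupac <- function(pattern) {
  grepl("^[ACGTRYSWKMBDHVN]+$", toupper(pattern))
}

#' Scan a promoter for cis-acting elements
#'
#' Exact IUPAC matching of each motif at every offset on both strands
#' (a minus-strand hit is a match of the motif's reverse complement on
#' the given sequence). Overlapping hits are all reported. Offsets are
#' 0-based from the promoter 5' end.
#'
#' @param promoter Nucleotide string.
#' @param motifs data.frame with `name`, `pattern` (IUPAC), `category`.
#' @return data.frame with `motif`, `category`, `strand`, `offset`.
#' @export
scan_cis_elements <- function(promoter, motifs = default_cis_elements()) {
  bad <- !.valid_iupac(motifs$pattern)
  if (any(bad))
    stop("invalid IUPAC pattern for motif(s): ",
         paste(motifs$name[bad], collapse = ", "))
  out <- list()
  if (!nzchar(promoter))
    return(data.frame(motif = character(), category = character(),
                      strand = character(), offset = integer()))
  subject <- Biostrings::DNAString(toupper(promoter))
  for (i in seq_len(nrow(motifs))) {
    pat <- Biostrings::DNAString(toupper(motifs$pattern[i]))
    if (length(pat) > length(subject)) next
    plus <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    minus <- Biostrings::matchPattern(
      Biostrings::reverseComplement(pat), subject, fixed = FALSE)
    if (length(plus))
      out[[length(out) + 1L]] <- data.frame(
        motif = motifs$name[i], category = motifs$category[i],
        strand = "+", offset = Biostrings::start(plus) - 1L)
    if (length(minus))
      out[[length(out) + 1L]] <- data.frame(
        motif = motifs$name[i], category = motifs$category[i],
        strand = "-", offset = Biostrings::start(minus) - 1L)
  }
  if (!length(out))
    return(data.frame(motif = character(), category = character(),
                      strand = character(), offset = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$motif, res$strand, res$offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-gene cis-element presence table
#'
#' @param promoters Named character vector of promoter sequences.
#' @param motifs Motif table (see [scan_cis_elements()]).
#' @return List with `hits` (long data.frame with `gene_id` prepended),
#'   `presence` (gene x motif logical matrix) and `pct_genes` (named
#'   percentage of genes carrying each motif, one decimal).
#' @export
cis_element_profile <- function(promoters, motifs = default_cis_elements()) {
  hits <- do.call(rbind, lapply(names(promoters), function(gid) {
    h <- scan_cis_elements(promoters[[gid]], motifs)
    if (nrow(h)) cbind(gene_id = gid, h) else NULL
  }))
  if (is.null(hits))
    hits <- data.frame(gene_id = character(), motif = character(),
                       category = character(), strand = character(),
                       offset = integer())
  presence <- matrix(FALSE, nrow = length(promoters),
                     ncol = nrow(motifs),
                     dimnames = list(names(promoters), motifs$name))
  if (nrow(hits))
    presence[cbind(hits$gene_id, hits$motif)] <- TRUE
  pct <- round(100 * colSums(presence) / max(length(promoters), 1L), 1L)
  list(hits = hits, presence = presence, pct_genes = pct)
}

.default_ssr_min_repeats <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L,
                              `5` = 5L, `6` = 5L)

.is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        unit == paste(rep(substr(unit, 1L, d), u %/% d), collapse = ""))
      return(FALSE)
  }
  TRUE
}

#' Find perfect simple sequence repeats
#'
#' Detects maximal perfect tandem repeats of 1-6 bp units, reporting
#' 1-based closed coordinates covering whole repeat units only. A
#' repeat whose unit is itself a repeat of a shorter unit is reported
#' at the shortest unit (so `ATATAT...` is a dinucleotide SSR, never a
#' tetra- or hexanucleotide one). Minimum repeat counts per unit length
#' follow common microsatellite-search defaults and are configurable.
#'
#' @param sequence Nucleotide string.
#' @param min_repeats Named integer vector, names "1".."6".
#' @param seq_id Optional sequence id copied into the output.
#' @return data.frame with `seq_id`, `unit`, `unit_length`,
#'   `repeat_count`, `start`, `end`.
#' @export
find_ssrs <- function(sequence, min_repeats = .default_ssr_min_repeats,
                      seq_id = NA_character_) {
  s <- strsplit(toupper(sequence), "")[[1L]]
  L <- length(s)
  out <- list()
  for (u in 1:6) {
    minrep <- min_repeats[[as.character(u)]]
    if (L < u * minrep) next
    eq <- s[seq_len(L - u)] == s[seq_len(L - u) + u]
    # maximal runs of TRUE in eq: run i..j means period-u repeat i..j+u
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (ri in seq_along(r$lengths)) {
      if (!r$values[ri]) next
      i <- pos[ri]; len <- r$lengths[ri] + u  # repeated region length
      count <- len %/% u
      if (count < minrep) next
      unit <- paste(s[i:(i + u - 1L)], collapse = "")
      if (!.is_primitive_unit(unit)) next
      if (any(!s[i:(i + u - 1L)] %in% c("A", "C", "G", "T"))) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id, unit = unit, unit_length = u,
        repeat_count = count, start = i, end = i + count * u - 1L)
    }
  }
  if (!length(out))
    return(data.frame(seq_id = character(), unit = character(),
                      unit_length = integer(), repeat_count = integer(),
                      start = integer(), end = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}
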