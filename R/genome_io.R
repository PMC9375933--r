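#' @importFrom stats setNames
NULL

# Coordinate conventions: GFF3, QTL tables and all user-facing tables are
# 1-based fully-closed; BED export is 0-based half-open. Internal arithmetic
# on IRanges is 1-based closed (the IRanges convention), converted at the
# BED boundary only.

#' Construct a gene model
#'
#' A `gene_model` holds one gene's genomic coordinates, strand and
#' exon/CDS structure in 1-based closed coordinates. It is the unit of
#' QTL co-localization and promoter extraction.
#'
#' @param gene_id Gene identifier (non-empty string).
#' @param chromosome Chromosome / scaffold name.
#' @param start,end 1-based closed gene span.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of exon intervals, or NULL.
#' @param cds Two-column matrix of CDS intervals, or NULL. Every CDS
#'   interval must lie within some exon.
#' @param transcript_ids Character vector of transcript ids.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, start, end, strand = "+",
                       exons = NULL, cds = NULL,
                       transcript_ids = character()) {
  if (!nzchar(gene_id)) stop("gene_id must be non-empty")
  if (!nzchar(chromosome)) stop("chromosome must be non-empty")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop(sprintf("gene %s: start (%d) must be <= end (%d)",
                 gene_id, start, end))
  if (start < 1L) stop(sprintf("gene %s: coordinates must be >= 1", gene_id))
  if (!strand %in% c("+", "-"))
    stop(sprintf("gene %s: strand must be '+' or '-'", gene_id))
  if (is.null(exons)) exons <- matrix(c(start, end), ncol = 2L)
  exons <- .as_interval_matrix(exons, gene_id, "exon")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop(sprintf("gene %s: exons overlap", gene_id))
  if (is.null(cds)) {
    cds <- matrix(numeric(0), ncol = 2L)
  } else {
    cds <- .as_interval_matrix(cds, gene_id, "CDS")
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    ok <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L])
    }, logical(1L))
    if (!all(ok))
      stop(sprintf("gene %s: CDS interval outside exons", gene_id))
  }
  structure(list(gene_id = gene_id, transcript_ids = transcript_ids,
                 chromosome = chromosome, start = start, end = end,
                 strand = strand, exons = exons, cds = cds),
            class = "gene_model")
}

.as_interval_matrix <- function(x, gene_id, what) {
  x <- matrix(as.integer(as.matrix(x)), ncol = 2L)
  if (any(is.na(x)) || any(x[, 1L] > x[, 2L]) || any(x < 1L))
    stop(sprintf("gene %s: invalid %s intervals", gene_id, what))
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s), %d CDS segment(s)\n",
              x$gene_id, x$chromosome, x$start, x$end, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features and assembles one [gene_model] per
#' gene. Child features are attached through their `Parent` attributes.
#' For multi-transcript genes the gene span is the union of transcript
#' spans and the exon/CDS structure is taken from the primary transcript
#' (longest total CDS; ties broken by lexicographically smallest
#' transcript id), so each gene contributes a single representative row
#' to per-gene tables.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of `gene_model` objects (names are gene ids).
#' @export
read_gff3 <- function(path) {
  .validate_gff3_lines(path)
  gff <- rtracklayer::readGFF(path,
    columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent"))
  gff <- as.data.frame(gff)
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1L))
  gff$type <- as.character(gff$type)
  gff$seqid <- as.character(gff$seqid)
  gff$strand <- as.character(gff$strand)

  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  parts <- gff[gff$type %in% c("exon", "CDS"), , drop = FALSE]
  if (anyDuplicated(genes$ID))
    stop("duplicate gene IDs in GFF3: ",
         paste(unique(genes$ID[duplicated(genes$ID)]), collapse = ", "))
  if (any(is.na(parts$Parent)))
    stop("exon/CDS feature without Parent attribute in ", path)
  unknown <- setdiff(parts$Parent, mrnas$ID)
  if (length(unknown))
    stop("exon/CDS Parent not a known mRNA: ",
         paste(unknown, collapse = ", "))

  mrna_by_gene <- split(seq_len(nrow(mrnas)), mrnas$Parent)
  parts_by_mrna <- split(seq_len(nrow(parts)), parts$Parent)

  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    midx <- mrna_by_gene[[g$ID]]
    tids <- if (length(midx)) mrnas$ID[midx] else character()
    # primary transcript: longest CDS, ties -> smallest id
    pick <- NULL
    if (length(tids)) {
      cds_len <- vapply(tids, function(tid) {
        p <- parts[parts_by_mrna[[tid]], , drop = FALSE]
        p <- p[p$type == "CDS", , drop = FALSE]
        if (nrow(p)) sum(p$end - p$start + 1L) else 0L
      }, numeric(1L))
      ord <- order(-cds_len, tids)
      pick <- tids[ord[1L]]
    }
    exons <- cds <- NULL
    if (!is.null(pick) && !is.null(parts_by_mrna[[pick]])) {
      p <- parts[parts_by_mrna[[pick]], , drop = FALSE]
      pe <- p[p$type == "exon", , drop = FALSE]
      pc <- p[p$type == "CDS", , drop = FALSE]
      if (nrow(pe)) exons <- cbind(pe$start, pe$end)
      if (nrow(pc)) cds <- cbind(pc$start, pc$end)
    }
    out[[i]] <- gene_model(g$ID, g$seqid, g$start, g$end, g$strand,
                           exons = exons, cds = cds,
                           transcript_ids = sort(tids))
  }
  setNames(out, genes$ID)
}

.validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop(sprintf("%s line %d: expected 9 tab-separated fields, got %d",
                   path, i, length(f)))
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e))
      stop(sprintf("%s line %d: non-numeric start/end", path, i))
  }
  invisible(TRUE)
}

#' Write gene models to GFF3
#'
#' Emits one gene, one mRNA (the representative transcript) and its
#' exon/CDS children per gene, in 1-based closed GFF3 coordinates.
#' `read_gff3()` followed by `write_gff3()` preserves all coordinates
#' and strands.
#'
#' @param genes List of [gene_model] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    tid <- if (length(g$transcript_ids)) g$transcript_ids[[1L]]
           else paste0(g$gene_id, ".1")
    lines <- c(
      sprintf("%s\tlectinscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chromosome, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\tlectinscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chromosome, min(g$exons[, 1L]), max(g$exons[, 2L]),
              g$strand, tid, g$gene_id))
    for (i in seq_len(nrow(g$exons)))
      lines <- c(lines, sprintf(
        "%s\tlectinscan\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        g$chromosome, g$exons[i, 1L], g$exons[i, 2L], g$strand, tid))
    for (i in seq_len(nrow(g$cds)))
      lines <- c(lines, sprintf(
        "%s\tlectinscan\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
        g$chromosome, g$cds[i, 1L], g$cds[i, 2L], g$strand, tid))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Summarize exon/intron structure
#'
#' @param genes List of [gene_model] objects.
#' @return A data.frame with `gene_id`, `exon_count`, `intron_count` and a
#'   list-column `intron_lengths` (bp gaps between consecutive exons).
#' @export
gene_structure_summary <- function(genes) {
  if (!length(genes))
    return(data.frame(gene_id = character(), exon_count = integer(),
                      intron_count = integer(),
                      intron_lengths = I(list())))
  rows <- lapply(genes, function(g) {
    ne <- nrow(g$exons)
    il <- if (ne > 1L)
      as.integer(g$exons[-1L, 1L] - g$exons[-ne, 2L] - 1L)
    else integer()
    list(gene_id = g$gene_id, exon_count = ne,
         intron_count = ne - 1L, intron_lengths = il)
  })
  data.frame(
    gene_id = vapply(rows, `[[`, character(1L), "gene_id"),
    exon_count = vapply(rows, `[[`, integer(1L), "exon_count"),
    intron_count = vapply(rows, `[[`, integer(1L), "intron_count"),
    intron_lengths = I(lapply(rows, `[[`, "intron_lengths")),
    row.names = NULL)
}

#' Write intervals as BED
#'
#' Converts 1-based closed intervals to the 0-based half-open BED
#' convention: a closed interval (10, 20) becomes BED (9, 20).
#'
#' @param intervals data.frame with columns `chromosome`, `start`, `end`
#'   and optionally `name`, `score`, `strand` (1-based closed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED: chrom\tchromStart\tchromEnd\tname\tscore\tstrand", con)
  if (nrow(intervals)) {
    if (any(intervals$start < 1L) || any(intervals$end < intervals$start))
      stop("invalid interval coordinates (must be 1-based closed, start>=1)")
    name <- if ("name" %in% names(intervals)) intervals$name else "."
    score <- if ("score" %in% names(intervals)) intervals$score else 0L
    strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       intervals$chromosome,
                       as.integer(intervals$start) - 1L,
                       as.integer(intervals$end),
                       name, score, strand), con)
  }
  invisible(path)
}

#' Read a BED file back into 1-based closed intervals
#'
#' @param path Path to a BED file written by [write_bed()].
#' @return data.frame with `chromosome`, `start`, `end`, `name`, `score`,
#'   `strand` in 1-based closed coordinates.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser|\\s*$)", lines)]
  if (!length(lines))
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), name = character(),
                      score = character(), strand = character()))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (any(as.integer(f[, 2L]) < 0L)) stop("negative BED coordinates")
  data.frame(chromosome = f[, 1L],
             start = as.integer(f[, 2L]) + 1L,
             end = as.integer(f[, 3L]),
             name = if (ncol(f) >= 4L) f[, 4L] else ".",
             score = if (ncol(f) >= 5L) f[, 5L] else "0",
             strand = if (ncol(f) >= 6L) f[, 6L] else ".",
             row.names = NULL)
}

#' Read a header-bearing TSV table with schema validation
#'
#' @param path Path to a tab-separated file with a header row.
#' @param required Character vector of column names that must be present.
#' @return data.frame.
#' @export
read_table_tsv <- function(path, required = character()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  df
}

#' Write a TSV table with a parameter-recording header comment
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param params Optional named list recorded as `# key=value` comments.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params))
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(x)
                         paste(format(x), collapse = ","), character(1L))),
               con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert gene models to a GRanges of gene spans
#'
#' @param genes List of [gene_model] objects.
#' @return A `GRanges` with gene ids as names.
#' @export
genes_as_granges <- function(genes) {
  if (!length(genes))
    return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(genes, `[[`, character(1L), "chromosome"),
    ranges = IRanges::IRanges(
      start = vapply(genes, `[[`, integer(1L), "start"),
      end = vapply(genes, `[[`, integer(1L), "end")),
    strand = vapply(genes, `[[`, character(1L), "strand"))
  names(gr) <- vapply(genes, `[[`, character(1L), "gene_id")
  gr
}
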