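# QTL ingestion, non-redundant merging and gene co-localization by
# physical position. Interval algebra is delegated to GenomicRanges;
# tests re-derive every result with brute-force base-R oracles.

.qtl_categories <- c("abiotic", "biotic", "maturity", "composition",
                     "morphology")

#' Read a QTL table
#'
#' Expects a tab-separated export with columns `qtl_id`, `trait`,
#' `subcategory`, `category`, `chromosome`, `start`, `end` in 1-based
#' closed coordinates (the convention of QTL-atlas-style exports).
#'
#' @param path Path to the TSV file.
#' @return data.frame of validated QTL records.
#' @export
read_qtl_table <- function(path) {
  qtl <- read_table_tsv(path, c("qtl_id", "trait", "subcategory",
                                "category", "chromosome", "start", "end"))
  validate_qtl_records(qtl)
}

#' Validate QTL records
#'
#' @param qtl data.frame of QTL records.
#' @return The validated data.frame (invisibly the same object).
#' @export
validate_qtl_records <- function(qtl) {
  qtl$start <- as.integer(qtl$start)
  qtl$end <- as.integer(qtl$end)
  if (any(qtl$start > qtl$end))
    stop("QTL with start > end: ",
         paste(qtl$qtl_id[qtl$start > qtl$end], collapse = ", "))
  bad <- setdiff(unique(qtl$category), .qtl_categories)
  if (length(bad))
    stop("unknown QTL category(ies): ", paste(bad, collapse = ", "),
         " (expected ", paste(.qtl_categories, collapse = "/"), ")")
  qtl
}

#' Merge overlapping QTLs into non-redundant regions
#'
#' Within each grouping key (trait, subcategory or category) and
#' chromosome, overlapping input intervals are merged into maximal
#' disjoint regions; exact duplicate rows (same interval and trait)
#' collapse before merging. Intervals sharing at least one bp merge;
#' intervals merely adjacent in closed coordinates (end + 1 == start)
#' do not. Merging is idempotent and input-order invariant.
#'
#' @param qtl Validated QTL data.frame.
#' @param level Grouping level: `"trait"`, `"subcategory"` or
#'   `"category"`.
#' @param known_chromosomes Optional character vector; regions on other
#'   chromosomes are kept but flagged (`chromosome_known = FALSE`) and
#'   excluded from gene counting.
#' @return data.frame with `region_id`, `grouping_key`, `chromosome`,
#'   `start`, `end`, `source_qtl_ids` (comma-joined), and
#'   `chromosome_known`.
#' @export
merge_qtls <- function(qtl, level = c("subcategory", "trait", "category"),
                       known_chromosomes = NULL) {
  level <- match.arg(level)
  qtl <- validate_qtl_records(qtl)
  # drop redundant rows: identical interval + trait
  dupkey <- paste(qtl$trait, qtl$chromosome, qtl$start, qtl$end, sep = "\r")
  first <- !duplicated(dupkey)
  ids_by_key <- split(qtl$qtl_id, dupkey)
  qtl$all_ids <- vapply(dupkey, function(k)
    paste(sort(unique(ids_by_key[[k]])), collapse = ","), character(1L))
  qtl <- qtl[first, , drop = FALSE]

  keys <- qtl[[level]]
  out <- list()
  for (key in sort(unique(keys))) {
    q <- qtl[keys == key, , drop = FALSE]
    gr <- GenomicRanges::GRanges(q$chromosome,
                                 IRanges::IRanges(q$start, q$end))
    # min.gapwidth = 0: intervals sharing >= 1 bp merge, intervals that
    # merely touch end-to-start in closed coordinates do not
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    ov <- GenomicRanges::findOverlaps(red, gr)
    src <- vapply(seq_along(red), function(i) {
      ids <- q$all_ids[S4Vectors::subjectHits(ov)[
        S4Vectors::queryHits(ov) == i]]
      paste(sort(unique(unlist(strsplit(ids, ",")))), collapse = ",")
    }, character(1L))
    out[[key]] <- data.frame(
      grouping_key = key,
      chromosome = as.character(GenomicRanges::seqnames(red)),
      start = GenomicRanges::start(red),
      end = GenomicRanges::end(red),
      source_qtl_ids = src)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(grouping_key = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      source_qtl_ids = character())
  res <- res[order(res$grouping_key, res$chromosome, res$start), ,
             drop = FALSE]
  res$region_id <- sprintf("R%04d", seq_len(nrow(res)))
  res$chromosome_known <- if (is.null(known_chromosomes)) TRUE
    else res$chromosome %in% known_chromosomes
  rownames(res) <- NULL
  res[, c("region_id", "grouping_key", "chromosome", "start", "end",
          "source_qtl_ids", "chromosome_known")]
}

#' Count total and lectin genes in merged regions
#'
#' A gene counts toward a region iff its span overlaps the region by at
#' least one bp (`rule = "any"`), or iff its span lies entirely inside
#' it (`rule = "within"`). Regions flagged with an unknown chromosome
#' get `NA` counts.
#'
#' @param regions Merged regions from [merge_qtls()].
#' @param genes List of [gene_model] objects.
#' @param lectin_ids Character vector of lectin gene ids (subset of the
#'   gene ids).
#' @param rule Overlap rule, `"any"` (default) or `"within"`.
#' @return `regions` with columns `n_genes`, `k_lectins` and
#'   `lectin_ids` (comma-joined) appended.
#' @export
count_genes_in_regions <- function(regions, genes, lectin_ids,
                                   rule = c("any", "within")) {
  rule <- match.arg(rule)
  stray <- setdiff(lectin_ids, names(genes))
  if (length(stray))
    stop("lectin_ids not among gene ids: ", paste(stray, collapse = ", "))
  gr <- genes_as_granges(genes)
  reg <- GenomicRanges::GRanges(regions$chromosome,
                                IRanges::IRanges(regions$start, regions$end))
  type <- if (rule == "any") "any" else "within"
  ov <- GenomicRanges::findOverlaps(gr, reg, type = type)
  n <- k <- integer(nrow(regions))
  lids <- character(nrow(regions))
  hit_gene <- names(gr)[S4Vectors::queryHits(ov)]
  hit_reg <- S4Vectors::subjectHits(ov)
  for (i in seq_len(nrow(regions))) {
    g <- hit_gene[hit_reg == i]
    n[i] <- length(g)
    inlec <- sort(intersect(g, lectin_ids))
    k[i] <- length(inlec)
    lids[i] <- paste(inlec, collapse = ",")
  }
  regions$n_genes <- ifelse(regions$chromosome_known, n, NA_integer_)
  regions$k_lectins <- ifelse(regions$chromosome_known, k, NA_integer_)
  regions$lectin_ids <- ifelse(regions$chromosome_known, lids,
                               NA_character_)
  regions
}

#' Co-localization report per grouping key
#'
#' Aggregates counted regions into a per-grouping-key table (number of
#' regions, regions containing at least one lectin, percentage to one
#' decimal) plus genome-wide lectin recovery: the percentage of lectin
#' genes found inside at least one region. A lectin falling in several
#' regions is reported in each (co-localization is many-to-many).
#'
#' @param counted Regions with counts from [count_genes_in_regions()].
#' @param lectin_ids All lectin gene ids (denominator for recovery).
#' @return List with `per_key` (data.frame: `grouping_key`, `n_regions`,
#'   `n_regions_with_lectin`, `pct_regions_with_lectin`), and scalars
#'   `pct_lectins_in_qtl`, `lectins_in_qtl` (ids).
#' @export
colocalization_report <- function(counted, lectin_ids) {
  counted <- counted[counted$chromosome_known, , drop = FALSE]
  keys <- sort(unique(counted$grouping_key))
  per_key <- do.call(rbind, lapply(keys, function(key) {
    r <- counted[counted$grouping_key == key, , drop = FALSE]
    with_lec <- sum(r$k_lectins > 0L)
    data.frame(grouping_key = key, n_regions = nrow(r),
               n_regions_with_lectin = with_lec,
               pct_regions_with_lectin =
                 round(100 * with_lec / max(nrow(r), 1L), 1L))
  }))
  if (is.null(per_key))
    per_key <- data.frame(grouping_key = character(), n_regions = integer(),
                          n_regions_with_lectin = integer(),
                          pct_regions_with_lectin = numeric())
  in_qtl <- sort(unique(unlist(strsplit(
    counted$lectin_ids[nzchar(counted$lectin_ids)], ","))))
  list(per_key = per_key,
       lectins_in_qtl = in_qtl,
       pct_lectins_in_qtl =
         round(100 * length(in_qtl) / max(length(lectin_ids), 1L), 1L))
}
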