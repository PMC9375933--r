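# Stage orchestration. Each stage reads the standard input files,
# runs the corresponding module and (optionally) writes TSV/BED
# outputs whose headers record the parameters that produced them.
# The thin command-line wrapper in inst/scripts/lectinscan.R maps
# subcommands onto these functions.

#' Screen a genome for lectin genes
#'
#' @param gff3 Path to the gene annotation (GFF3).
#' @param domains_tsv Path to the protein-domain hit table.
#' @param predictors_tsv Path to the secretion-predictor table (or
#'   NULL).
#' @param outdir Optional output directory for `lectins.tsv` and
#'   `family_summary.tsv`.
#' @param catalog Family catalog.
#' @return List with `genes`, `annotations`, `lectin_table`,
#'   `family_summary`.
#' @export
screen_lectins <- function(gff3, domains_tsv, predictors_tsv = NULL,
                           outdir = NULL,
                           catalog = default_family_catalog()) {
  genes <- read_gff3(gff3)
  hits <- read_table_tsv(domains_tsv,
                         c("gene_id", "accession", "name",
                           "start_aa", "end_aa"))
  predictors <- if (!is.null(predictors_tsv))
    read_table_tsv(predictors_tsv,
                   c("gene_id", "signal_peptide", "transmembrane",
                     "localization"))
  ann <- annotate_lectins(hits, predictors, genes, catalog)
  lectin_table <- do.call(rbind, lapply(ann, function(a) data.frame(
    gene_id = a$gene_id,
    chromosome = a$chromosome %||% NA_character_,
    start = a$start %||% NA_integer_, end = a$end %||% NA_integer_,
    family = a$dominant_family,
    all_families = paste(a$families, collapse = ","),
    architecture = paste(a$architecture, collapse = "|"),
    arch_class = a$arch_class,
    lectin_domain_count = a$lectin_domain_count,
    signal_class = a$signal_class %||% NA_character_)))
  rownames(lectin_table) <- NULL
  fam_sum <- summarize_families(ann)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_table_tsv(lectin_table, file.path(outdir, "lectins.tsv"),
                    params = list(n_genes = length(genes),
                                  n_lectins = length(ann)))
    write_table_tsv(fam_sum, file.path(outdir, "family_summary.tsv"),
                    params = list(total_lectins = length(ann)))
  }
  list(genes = genes, annotations = ann, lectin_table = lectin_table,
       family_summary = fam_sum)
}

#' Merge QTLs and co-localize genes
#'
#' @param qtl_tsv Path to the QTL table.
#' @param genes Gene models (from [screen_lectins()] or [read_gff3()]).
#' @param lectin_ids Lectin gene ids.
#' @param level Grouping level for the merge.
#' @param rule Gene-overlap rule (`"any"` or `"within"`).
#' @param outdir Optional output directory for `merged_qtls.tsv`,
#'   `merged_qtls.bed` and `colocalization.tsv`.
#' @return List with `regions` (counted) and `report`.
#' @export
colocalize_qtls <- function(qtl_tsv, genes, lectin_ids,
                            level = "subcategory", rule = "any",
                            outdir = NULL) {
  qtl <- read_qtl_table(qtl_tsv)
  chroms <- unique(vapply(genes, `[[`, character(1L), "chromosome"))
  merged <- merge_qtls(qtl, level, known_chromosomes = chroms)
  counted <- count_genes_in_regions(merged, genes, lectin_ids, rule)
  report <- colocalization_report(counted, lectin_ids)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_table_tsv(counted, file.path(outdir, "merged_qtls.tsv"),
                    params = list(level = level, rule = rule))
    bed <- counted[counted$chromosome_known, , drop = FALSE]
    bed$name <- paste(bed$grouping_key, bed$region_id, sep = "|")
    write_bed(bed, file.path(outdir, "merged_qtls.bed"))
    write_table_tsv(report$per_key,
                    file.path(outdir, "colocalization.tsv"),
                    params = list(level = level, rule = rule,
                                  pct_lectins_in_qtl =
                                    report$pct_lectins_in_qtl))
  }
  list(regions = counted, report = report)
}

#' Run the enrichment stage on counted regions
#'
#' @param regions Counted regions (see [count_genes_in_regions()]).
#' @param N,s Genome totals.
#' @param alpha,alpha_bonf Thresholds.
#' @param outdir Optional output directory for `enrichment.tsv`.
#' @return A [lectin_enrichment] object.
#' @export
enrich_regions <- function(regions, N = 34129, s = 119, alpha = 0.05,
                           alpha_bonf = 0.025, outdir = NULL) {
  fit <- lectin_enrichment(regions, N, s, alpha, alpha_bonf)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_table_tsv(as.data.frame(fit),
                    file.path(outdir, "enrichment.tsv"),
                    params = list(N = N, s = s, alpha = alpha,
                                  alpha_bonf = alpha_bonf))
  }
  fit
}

#' Run the duplication stage
#'
#' @param pairs_tsv Path to the homolog-pair table.
#' @param genes Gene models.
#' @param cds_fasta Path to the CDS FASTA keyed by gene id.
#' @param ancestral_tsv Optional ancestral-locus table (column
#'   `gene_id`).
#' @param family_of Named family vector for the summary.
#' @param outdir Optional output directory.
#' @param ... Passed to [analyze_duplicates()].
#' @return List with `pairs` and `summary`.
#' @export
expand_genes <- function(pairs_tsv, genes, cds_fasta,
                         ancestral_tsv = NULL, family_of = NULL,
                         outdir = NULL, ...) {
  pairs <- read_table_tsv(pairs_tsv, c("gene_a", "gene_b"))
  cds <- Biostrings::readDNAStringSet(cds_fasta)
  names(cds) <- sub("\\s.*$", "", names(cds))
  ancestral <- if (!is.null(ancestral_tsv))
    read_table_tsv(ancestral_tsv, "gene_id")$gene_id
  res <- analyze_duplicates(pairs, genes, cds, ancestral, ...)
  summ <- expansion_summary(res, family_of)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_table_tsv(res, file.path(outdir, "duplicates.tsv"),
                    params = list(ks_retention = "ks<=1"))
    write_table_tsv(summ, file.path(outdir, "expansion_summary.tsv"))
  }
  list(pairs = res, summary = summ)
}

#' Run the promoter stage
#'
#' @param genome_fasta Path to the genome FASTA.
#' @param genes Gene models.
#' @param lectin_ids Genes whose promoters are analyzed.
#' @param motifs Motif table.
#' @param promoter_length Promoter length in bp.
#' @param ssr_min_repeats SSR thresholds per unit length.
#' @param outdir Optional output directory.
#' @return List with `promoters`, `cis` (profile) and `ssrs`.
#' @export
promoter_stage <- function(genome_fasta, genes, lectin_ids,
                           motifs = default_cis_elements(),
                           promoter_length = 1500L,
                           ssr_min_repeats = .default_ssr_min_repeats,
                           outdir = NULL) {
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  promoters <- setNames(lapply(lectin_ids, function(gid)
    as.character(extract_promoter(genome, genes[[gid]],
                                  promoter_length))), lectin_ids)
  cis <- cis_element_profile(promoters, motifs)
  ssrs <- do.call(rbind, lapply(lectin_ids, function(gid) {
    g <- genes[[gid]]
    s <- as.character(Biostrings::subseq(genome[[g$chromosome]],
                                         g$start, g$end))
    found <- find_ssrs(s, ssr_min_repeats, seq_id = gid)
    if (nrow(found)) {
      found$start <- found$start + g$start - 1L  # back to chromosome
      found$end <- found$end + g$start - 1L
    }
    found
  }))
  if (is.null(ssrs))
    ssrs <- data.frame(seq_id = character(), unit = character(),
                       unit_length = integer(), repeat_count = integer(),
                       start = integer(), end = integer())
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_table_tsv(cis$hits, file.path(outdir, "cis_elements.tsv"),
                    params = list(promoter_length = promoter_length))
    write_table_tsv(
      data.frame(motif = names(cis$pct_genes),
                 pct_genes = unname(cis$pct_genes)),
      file.path(outdir, "cis_element_pct.tsv"))
    write_table_tsv(ssrs, file.path(outdir, "ssrs.tsv"))
  }
  list(promoters = promoters, cis = cis, ssrs = ssrs)
}

#' Run the full pipeline on a directory of standard inputs
#'
#' Expects the file layout written by [generate_synthetic_genome()]
#' (`genes.gff3`, `genome.fa`, `cds.fa`, `domains.tsv`,
#' `predictors.tsv`, `qtls.tsv`, `pairs.tsv`, `ancestral_loci.tsv`) and
#' runs screen, colocalize, enrich, expand and promoter stages in
#' order, then aggregates a census-style report.
#'
#' @param indir Input directory.
#' @param outdir Optional output directory for all stage TSVs.
#' @param N,s Genome totals for the enrichment test; default to the
#'   actual gene and lectin counts of the input.
#' @param level Grouping level for QTL merging.
#' @param rule Gene-overlap rule.
#' @return List with all stage results plus `report`.
#' @export
run_lectin_pipeline <- function(indir, outdir = NULL, N = NULL, s = NULL,
                                level = "subcategory", rule = "any") {
  fp <- function(f) {
    p <- file.path(indir, f)
    if (!file.exists(p)) stop("missing required input: ", p)
    p
  }
  scr <- screen_lectins(fp("genes.gff3"), fp("domains.tsv"),
                        fp("predictors.tsv"), outdir)
  lectin_ids <- names(scr$annotations)
  if (is.null(N)) N <- length(scr$genes)
  if (is.null(s)) s <- length(lectin_ids)
  col <- colocalize_qtls(fp("qtls.tsv"), scr$genes, lectin_ids,
                         level, rule, outdir)
  enr <- enrich_regions(col$regions, N, s, outdir = outdir)
  fam_of <- setNames(scr$lectin_table$family, scr$lectin_table$gene_id)
  exp_ <- expand_genes(fp("pairs.tsv"), scr$genes, fp("cds.fa"),
                       fp("ancestral_loci.tsv"), fam_of, outdir)
  prom <- promoter_stage(fp("genome.fa"), scr$genes, lectin_ids,
                         outdir = outdir)
  report <- list(
    family_summary = scr$family_summary,
    colocalization = col$report$per_key,
    pct_lectins_in_qtl = col$report$pct_lectins_in_qtl,
    enrichment = enr,
    expansion = exp_$summary,
    cis_element_pct = prom$cis$pct_genes)
  if (!is.null(outdir))
    write_table_tsv(report$colocalization,
                    file.path(outdir, "report_colocalization.tsv"),
                    params = list(N = N, s = s, level = level))
  list(screen = scr, colocalization = col, enrichment = enr,
       expansion = exp_, promoter = prom, report = report,
       N = N, s = s)
}
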