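# Lectin family assignment from protein-domain hit tables, domain
# architecture classification and Table-1-style summaries.

#' The canonical plant lectin domain catalog
#'
#' Twelve lectin domain families (Pfam accessions) plus the partner
#' (non-lectin) domains commonly found fused to them in plant genomes.
#' A protein is a lectin iff it carries at least one domain from the
#' lectin set; partner domains drive the chimerolectin call.
#'
#' @return A list with elements `lectin_domains` and `partner_domains`,
#'   each a named list mapping a domain name to its accession(s).
#' @export
default_family_catalog <- function() {
  list(
    lectin_domains = list(
      ABA        = "PF07367",
      Amaranthin = "PF07468",
      Cyanovirin = "PF08881",
      EUL        = "PF14200",
      GNA        = "PF01453",
      JRL        = "PF01419",
      Legume     = "PF00139",
      LysM       = "PF01476",
      Hevein     = "PF00187",
      CRA        = "PF00704",
      Nictaba    = "PF14299",
      `Ricin-B`  = "PF00652"),
    partner_domains = list(
      RIP          = "PF00161",
      `GH-19`      = "PF00182",
      `F-box/PP2`  = "PF00646",
      `NB-ARC`     = "PF00954",
      Dirigent     = "PF03018",
      Rx_N         = "PF18052",
      PKinase      = c("PF00069", "PF07714")))
}

.catalog_lookup <- function(catalog) {
  lec <- rep(names(catalog$lectin_domains),
             lengths(catalog$lectin_domains))
  names(lec) <- unlist(catalog$lectin_domains, use.names = FALSE)
  if (anyDuplicated(names(lec)))
    stop("catalog: duplicated lectin accessions")
  par <- rep(names(catalog$partner_domains),
             lengths(catalog$partner_domains))
  names(par) <- unlist(catalog$partner_domains, use.names = FALSE)
  list(lectin = lec, partner = par)
}

#' Assign lectin families from a domain-hit table
#'
#' A gene is a lectin iff at least one of its domain hits carries a
#' lectin-family accession; its families are all matching families and
#' its architecture is the N-to-C ordered list of domain names (hits
#' sorted by amino-acid start). Genes with no lectin hit are excluded
#' from the returned set (they still count toward the genome total N of
#' the enrichment test). Hits with accessions absent from the catalog
#' are retained as partner domain `"other"` with a warning. Overlapping
#' hits on one protein are resolved by keeping the lower E-value (if an
#' `evalue` column is present), else the longer hit.
#'
#' @param hits data.frame with columns `gene_id`, `accession`, `name`,
#'   `start_aa`, `end_aa` and optionally `evalue`.
#' @param catalog A catalog as returned by [default_family_catalog()].
#' @return A named list of lectin annotations; each has `gene_id`,
#'   `families`, `dominant_family` (longest aggregate hit coverage),
#'   `architecture`, `arch_class`, `lectin_domain_count`,
#'   `partner_domains`, `multi_family` flag.
#' @export
assign_families <- function(hits, catalog = default_family_catalog()) {
  req <- c("gene_id", "accession", "name", "start_aa", "end_aa")
  missing <- setdiff(req, names(hits))
  if (length(missing))
    stop("hits table missing column(s): ", paste(missing, collapse = ", "))
  if (!nrow(hits)) return(list())
  if (any(hits$start_aa > hits$end_aa) || any(hits$start_aa < 1L))
    stop("invalid hit coordinates (need 1 <= start_aa <= end_aa)")
  lk <- .catalog_lookup(catalog)
  unknown <- setdiff(unique(hits$accession), c(names(lk$lectin), names(lk$partner)))
  if (length(unknown))
    warning("unknown accession(s) kept as partner domain 'other': ",
            paste(unknown, collapse = ", "))
  out <- list()
  for (gid in unique(hits$gene_id)) {
    h <- hits[hits$gene_id == gid, , drop = FALSE]
    h <- .drop_overlapping_hits(h)
    h <- h[order(h$start_aa, h$end_aa), , drop = FALSE]
    fam_per_hit <- unname(lk$lectin[h$accession])
    par_per_hit <- unname(lk$partner[h$accession])
    is_lectin_hit <- !is.na(fam_per_hit)
    if (!any(is_lectin_hit)) next
    par_per_hit[is.na(par_per_hit) & !is_lectin_hit] <- "other"
    dom_names <- ifelse(is_lectin_hit, fam_per_hit, par_per_hit)
    fams <- unique(fam_per_hit[is_lectin_hit])
    cov <- vapply(fams, function(f)
      sum((h$end_aa - h$start_aa + 1L)[is_lectin_hit & fam_per_hit == f]),
      numeric(1L))
    out[[gid]] <- list(
      gene_id = gid,
      families = fams,
      dominant_family = fams[order(-cov, fams)][1L],
      multi_family = length(fams) > 1L,
      architecture = dom_names,
      arch_class = classify_architecture(dom_names, lk),
      lectin_domain_count = sum(is_lectin_hit),
      partner_domains = unique(dom_names[!is_lectin_hit]))
  }
  out
}

.drop_overlapping_hits <- function(h) {
  # keep lower E-value (else longer hit) among mutually overlapping hits
  pref <- if ("evalue" %in% names(h) && !all(is.na(h$evalue)))
    order(h$evalue, -(h$end_aa - h$start_aa)) else
    order(-(h$end_aa - h$start_aa))
  keep <- logical(nrow(h))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in pref) {
    if (!any(h$start_aa[i] <= taken_end & h$end_aa[i] >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, h$start_aa[i])
      taken_end <- c(taken_end, h$end_aa[i])
    }
  }
  h[keep, , drop = FALSE]
}

#' Classify a domain architecture as mero-, holo- or chimerolectin
#'
#' Merolectin: a single lectin domain and nothing else. Hololectin: two
#' or more lectin domains and no other domain. Chimerolectin: at least
#' one lectin domain fused to at least one non-lectin domain.
#'
#' @param architecture Character vector of domain names, N- to C-terminal.
#' @param lookup Internal accession lookup; pass a catalog via
#'   [default_family_catalog()] consumers instead.
#' @return One of `"merolectin"`, `"hololectin"`, `"chimerolectin"`.
#' @export
classify_architecture <- function(architecture,
                                  lookup = .catalog_lookup(default_family_catalog())) {
  lectin_names <- unique(unname(lookup$lectin))
  n_lec <- sum(architecture %in% lectin_names)
  n_other <- length(architecture) - n_lec
  if (n_lec == 0L)
    stop("classify_architecture: architecture has no lectin domain")
  if (n_other >= 1L) "chimerolectin"
  else if (n_lec == 1L) "merolectin"
  else "hololectin"
}

#' Assign secretion signal classes from predictor outputs
#'
#' Combines signal-peptide, transmembrane and subcellular-localization
#' predictions into one of four classes with precedence
#' SP > TM > IC/USP: a protein with a signal peptide is `SP`; otherwise
#' a transmembrane protein is `TM`; otherwise it is `IC` when predicted
#' intracellular and `USP` (unconventionally secreted) when predicted
#' extracellular without SP or TM.
#'
#' @param predictor_table data.frame with columns `gene_id`,
#'   `signal_peptide` (logical or yes/no), `transmembrane` (ditto) and
#'   `localization` (free-text label; `"extracellular"` or `"secreted"`
#'   triggers USP).
#' @param gene_ids Optional gene ids to classify; ids missing from the
#'   table are classified `IC` with a warning.
#' @return Named character vector of classes (`SP`, `TM`, `IC`, `USP`).
#' @export
assign_signal_class <- function(predictor_table, gene_ids = NULL) {
  req <- c("gene_id", "signal_peptide", "transmembrane", "localization")
  missing <- setdiff(req, names(predictor_table))
  if (length(missing))
    stop("predictor table missing column(s): ",
         paste(missing, collapse = ", "))
  tab <- predictor_table
  tab$signal_peptide <- .as_flag(tab$signal_peptide)
  tab$transmembrane <- .as_flag(tab$transmembrane)
  if (is.null(gene_ids)) gene_ids <- tab$gene_id
  idx <- match(gene_ids, tab$gene_id)
  if (anyNA(idx))
    warning("gene(s) absent from predictor table classified IC: ",
            paste(gene_ids[is.na(idx)], collapse = ", "))
  cls <- vapply(idx, function(i) {
    if (is.na(i)) return("IC")
    if (tab$signal_peptide[i]) "SP"
    else if (tab$transmembrane[i]) "TM"
    else if (grepl("extracellular|secreted", tab$localization[i],
                   ignore.case = TRUE)) "USP"
    else "IC"
  }, character(1L))
  setNames(cls, gene_ids)
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("yes", "y", "true", "1")
}

#' Tabulate lectin families
#'
#' Produces a per-family summary in the style of a gene-family census
#' table: gene count, percentage of the lectin complement (one decimal),
#' sorted list of occupied chromosomes and signal-class tallies. A gene
#' hitting lectin domains of two families is counted once, under its
#' dominant (longest-coverage) family, so counts stay disjoint.
#'
#' @param annotations List from [assign_families()], optionally carrying
#'   `$signal_class` and `$chromosome` per gene (see
#'   [annotate_lectins()]).
#' @param total_lectins Denominator for percentages; defaults to the
#'   number of annotations.
#' @return data.frame with `family`, `n_genes`, `pct`, `chromosomes`,
#'   `SP`, `TM`, `IC`, `USP`.
#' @export
summarize_families <- function(annotations,
                               total_lectins = length(annotations)) {
  fams <- vapply(annotations, `[[`, character(1L), "dominant_family")
  ufam <- sort(unique(fams))
  rows <- lapply(ufam, function(f) {
    ann <- annotations[fams == f]
    chroms <- sort(unique(unlist(lapply(ann, function(a)
      a$chromosome %||% NA_character_))))
    chroms <- chroms[!is.na(chroms)]
    sc <- unlist(lapply(ann, function(a) a$signal_class %||% NA_character_))
    data.frame(family = f, n_genes = length(ann),
               pct = round(100 * length(ann) / max(total_lectins, 1L), 1L),
               chromosomes = paste(chroms, collapse = ","),
               SP = sum(sc == "SP", na.rm = TRUE),
               TM = sum(sc == "TM", na.rm = TRUE),
               IC = sum(sc == "IC", na.rm = TRUE),
               USP = sum(sc == "USP", na.rm = TRUE))
  })
  if (!length(rows))
    return(data.frame(family = character(), n_genes = integer(),
                      pct = numeric(), chromosomes = character(),
                      SP = integer(), TM = integer(), IC = integer(),
                      USP = integer()))
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full lectin annotation for a gene set
#'
#' Convenience wrapper combining family assignment, signal classes and
#' genomic placement into one annotation list.
#'
#' @param hits Domain-hit table (see [assign_families()]).
#' @param predictor_table Predictor table (see [assign_signal_class()]).
#' @param genes Optional list of [gene_model] objects to attach
#'   chromosome/position.
#' @param catalog Family catalog.
#' @return Named list of annotations with `signal_class` and
#'   `chromosome` filled in.
#' @export
annotate_lectins <- function(hits, predictor_table = NULL, genes = NULL,
                             catalog = default_family_catalog()) {
  ann <- assign_families(hits, catalog)
  if (!length(ann)) return(ann)
  if (!is.null(predictor_table)) {
    cls <- assign_signal_class(predictor_table, names(ann))
    for (gid in names(ann)) ann[[gid]]$signal_class <- unname(cls[gid])
  }
  if (!is.null(genes)) {
    for (gid in names(ann)) {
      g <- genes[[gid]]
      if (!is.null(g)) {
        ann[[gid]]$chromosome <- g$chromosome
        ann[[gid]]$start <- g$start
        ann[[gid]]$end <- g$end
        ann[[gid]]$strand <- g$strand
      }
    }
  }
  ann
}

# ---- protein pI / Mw ------------------------------------------------------

# average residue masses (Da); protein MW = sum + one water
.aa_masses <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.01524

#' EMBOSS pK values used for isoelectric-point calculation
#'
#' @return Named numeric vector of pK values for the charged side chains
#'   and the termini (`Nterm`, `Cterm`).
#' @export
emboss_pk <- function() {
  c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
    D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
}

.net_charge <- function(counts, ph, pk) {
  pos <- c("Nterm", "K", "R", "H")
  neg <- c("Cterm", "D", "E", "C", "Y")
  sum(counts[pos] / (1 + 10^(ph - pk[pos]))) -
    sum(counts[neg] / (1 + 10^(pk[neg] - ph)))
}

#' Compute protein molecular weight and isoelectric point
#'
#' Molecular weight is the sum of average residue masses plus one water.
#' The isoelectric point is the pH at which the Henderson-Hasselbalch
#' net charge (EMBOSS pK set by default, including both termini)
#' crosses zero, located by bisection to |charge| < 1e-4.
#'
#' @param protein_sequence Single string over the 20 standard amino-acid
#'   one-letter codes.
#' @param pk Named pK vector, see [emboss_pk()].
#' @return Named numeric vector `c(mw = ..., pi = ...)` (Da, pH units).
#' @export
compute_mw_pi <- function(protein_sequence, pk = emboss_pk()) {
  if (!nzchar(protein_sequence)) stop("empty protein sequence")
  aa <- strsplit(toupper(protein_sequence), "")[[1L]]
  bad <- setdiff(unique(aa), names(.aa_masses))
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  mw <- sum(.aa_masses[aa]) + .water_mass
  counts <- c(Nterm = 1, Cterm = 1,
              vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                     function(r) sum(aa == r), numeric(1L)))
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- .net_charge(counts, mid, pk)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-9) break
    if (q > 0) lo <- mid else hi <- mid
  }
  c(mw = mw, pi = mid)
}
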