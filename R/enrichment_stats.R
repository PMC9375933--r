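# Wald overrepresentation test for lectin density in QTL regions, with
# an exact hypergeometric cross-check. Sign convention: z < 0 means the
# region's lectin proportion exceeds the genome-wide proportion
# (overrepresentation), so the one-sided P is the lower normal tail.

.check_enrichment_input <- function(n, k, N, s) {
  if (any(n <= 0)) stop("empty region: n must be > 0")
  if (any(n > N)) stop("region gene count n exceeds genome total N")
  if (any(k < 0) || any(k > pmin(n, s)))
    stop("lectin count k must satisfy 0 <= k <= min(n, s)")
  if (any(s <= 0) || any(s >= N)) stop("need 0 < s < N")
  invisible(TRUE)
}

#' Wald overrepresentation statistic
#'
#' One-sample proportion statistic comparing a region's lectin
#' proportion `k/n` with the genome-wide proportion `p0 = s/N`, using
#' the null variance `p0 (1 - p0) / n`:
#' `z = (p0 - k/n) / sqrt(p0 (1 - p0) / n)`.
#' Negative z denotes overrepresentation.
#'
#' @param n Genes in the region (vectorized).
#' @param k Lectin genes in the region.
#' @param N Protein-coding genes in the genome (default 34129).
#' @param s Lectin genes in the genome (default 119).
#' @return Numeric z (vectorized over `n`, `k`).
#' @export
wald_z <- function(n, k, N = 34129, s = 119) {
  .check_enrichment_input(n, k, N, s)
  p0 <- s / N
  (p0 - k / n) / sqrt(p0 * (1 - p0) / n)
}

#' One-sided P value for the Wald statistic
#'
#' The lower tail of the standard normal at z, so overrepresentation
#' (negative z) yields a small P.
#'
#' @param z Wald statistic (finite, vectorized).
#' @return P = Phi(z).
#' @export
one_sided_p <- function(z) {
  if (any(!is.finite(z))) stop("non-finite z")
  stats::pnorm(z)
}

#' Exact hypergeometric upper tail
#'
#' Finite-population oracle for the Wald approximation:
#' `P[X >= k]` for `X ~ Hypergeometric(N, s, n)` (drawing the region's
#' `n` genes from a genome of `N` genes of which `s` are lectins).
#'
#' @inheritParams wald_z
#' @return Exact tail probability (vectorized).
#' @export
hypergeometric_tail <- function(n, k, N = 34129, s = 119) {
  .check_enrichment_input(n, k, N, s)
  stats::phyper(k - 1, s, N - s, n, lower.tail = FALSE)
}

#' Apply the significance rules
#'
#' A region is significant iff it is overrepresented (z < 0) and its
#' one-sided P falls below the threshold; flags are stored for the
#' nominal level (default 0.05) and the Bonferroni-corrected level
#' (default 0.025, the fixed two-test correction used in this design).
#'
#' @param results data.frame with columns `z` and `p`.
#' @param alpha Nominal level.
#' @param alpha_bonf Bonferroni-corrected level.
#' @return `results` with logical columns `significant_05` and
#'   `significant_bonferroni` appended.
#' @export
apply_significance <- function(results, alpha = 0.05, alpha_bonf = 0.025) {
  results$significant_05 <- results$p < alpha & results$z < 0
  results$significant_bonferroni <- results$p < alpha_bonf & results$z < 0
  results
}

#' Lectin overrepresentation test for QTL regions
#'
#' Fits the Wald overrepresentation test to a set of regions with
#' total-gene and lectin counts, attaching the expected count
#' `n s / N`, the exact hypergeometric tail, and significance flags.
#'
#' @param regions data.frame with columns `n_genes` and `k_lectins`
#'   (rows with `NA` counts are dropped); typically the output of
#'   [count_genes_in_regions()].
#' @param N,s Genome totals (see [wald_z()]).
#' @param alpha,alpha_bonf Significance thresholds.
#' @return An object of class `lectin_enrichment`: the input data.frame
#'   with `expected`, `z`, `p`, `p_exact`, `significant_05`,
#'   `significant_bonferroni` appended, plus attributes `N`, `s`,
#'   `alpha`, `alpha_bonf`.
#' @export
lectin_enrichment <- function(regions, N = 34129, s = 119,
                              alpha = 0.05, alpha_bonf = 0.025) {
  if (!all(c("n_genes", "k_lectins") %in% names(regions)))
    stop("regions must carry n_genes and k_lectins columns")
  res <- regions[!is.na(regions$n_genes), , drop = FALSE]
  res$expected <- res$n_genes * s / N
  res$z <- wald_z(res$n_genes, res$k_lectins, N, s)
  res$p <- one_sided_p(res$z)
  res$p_exact <- hypergeometric_tail(res$n_genes, res$k_lectins, N, s)
  res <- apply_significance(res, alpha, alpha_bonf)
  structure(res, class = c("lectin_enrichment", "data.frame"),
            N = N, s = s, alpha = alpha, alpha_bonf = alpha_bonf)
}

#' @export
print.lectin_enrichment <- function(x, ...) {
  cat(sprintf(
    "Lectin overrepresentation in %d region(s) [N = %d, s = %d]\n",
    nrow(x), attr(x, "N"), attr(x, "s")))
  cols <- intersect(c("region_id", "grouping_key", "n_genes", "k_lectins",
                      "expected", "z", "p", "p_exact",
                      "significant_05", "significant_bonferroni"),
                    names(x))
  df <- as.data.frame(x)[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) signif(v, 5L))
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.lectin_enrichment <- function(object, ...) {
  cat(sprintf("Regions tested:            %d\n", nrow(object)))
  cat(sprintf("Genome totals:             N = %d, s = %d (p0 = %.5f)\n",
              attr(object, "N"), attr(object, "s"),
              attr(object, "s") / attr(object, "N")))
  cat(sprintf("Overrepresented (z < 0):   %d\n", sum(object$z < 0)))
  cat(sprintf("Significant at %.3f:       %d\n", attr(object, "alpha"),
              sum(object$significant_05)))
  cat(sprintf("Significant at Bonferroni %.3f: %d\n",
              attr(object, "alpha_bonf"),
              sum(object$significant_bonferroni)))
  invisible(object)
}
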