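---
title: "Methods: genome-wide lectin family analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide lectin family analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
`lectinscan`, in the spirit of a methods supplement: what each stage
assumes, which parameters matter, and what the synthetic-data tests do
and do not establish about real genomes.

## Coordinates and data model

All user-facing tables (GFF3, QTL tables, SSR loci) are 1-based and
fully closed; BED export converts to 0-based half-open at the boundary
(a closed gene `(10, 20)` becomes BED `(9, 20)`). Internally, interval
algebra is delegated to `IRanges`/`GenomicRanges`, whose native
convention is also 1-based closed, so no silent shifting occurs.

A `gene_model` carries the gene span, strand and exon/CDS structure.
Multi-transcript genes are represented by a primary transcript — the
one with the longest total CDS, ties broken by the lexicographically
smallest transcript id — and the gene span is the union of transcript
spans. This is a choice, not a biological fact: splice-variant
collapsing rules differ between annotation pipelines, and any
deterministic rule that yields one row per gene would serve; ours
favors the transcript with the most coding evidence. Unplaced scaffolds
survive I/O but are flagged and excluded from QTL counting.

## Family screen

A gene is a lectin iff at least one domain hit carries an accession
from the twelve-family lectin catalog; everything else (kinases,
GH-19, RIP, F-box/PP2, NB-ARC, Dirigent, Rx_N and unknown accessions,
which are retained as `"other"` with a warning) is a partner domain.
The architecture, hits ordered by amino-acid start, drives the
three-way classification: merolectin (exactly one lectin domain,
nothing else), hololectin (two or more lectin domains, nothing else),
chimerolectin (lectin plus partner domains). These classes are
mutually exclusive and exhaustive by construction.

Two rules cover situations the classification alone does not decide:

* **Nested/overlapping hits** on one protein keep the hit with the
  lower E-value when present, else the longer hit. Domain scanners
  emit overlapping signatures routinely; without a rule the
  architecture would double-count.
* **Multi-family genes** (lectin domains of two families on one
  protein) keep all families and are flagged, but census tables count
  them once under the dominant family (largest aggregate hit
  coverage), so family counts stay disjoint and sum to the lectin
  total.

Secretion classes apply the precedence SP > TM > (IC | USP): a signal
peptide wins over a transmembrane segment, and proteins with neither
are split by predicted localization into intracellular (IC) versus
unconventionally secreted (USP, extracellular without SP/TM). The
precedence encodes the biological reading that a signal peptide routes
the protein into the secretory pathway regardless of downstream
membrane anchors.

Protein molecular weight is the sum of average residue masses plus one
water; the isoelectric point solves net charge = 0 under
Henderson–Hasselbalch with the EMBOSS pK set (side chains C 8.5, D
3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1; termini 8.6/3.6) by
bisection on pH ∈ [0, 14] to |charge| < 1e−4. The pK table is a
parameter (`pk =` argument): published calculators differ by a few
tenths of a pH unit depending on the table, which is why the tests
assert self-consistency (zero charge at the reported pI) and
monotonicity rather than third-party agreement.

## QTL merging and co-localization

Within one grouping key (trait, subcategory or category — default
subcategory) and chromosome, QTL intervals that share **at least one
bp** merge into maximal disjoint regions; intervals merely touching
end-to-start in closed coordinates (`end + 1 == start`) do *not*
merge (`reduce(min.gapwidth = 0)`). Exact duplicate interval+trait
rows collapse before merging, keeping all source ids. Merging is
idempotent and input-order invariant, and is verified against a
per-base boolean-union oracle in the tests.

A gene co-localizes with a region when its span overlaps it by at
least one bp (`rule = "any"`, the default) — the inclusive reading of
"physical position". Full containment (`rule = "within"`) is also
implemented for sensitivity analysis; boundary-straddling genes are
the only genes on which the two rules disagree. Co-localization is
many-to-many: a lectin inside three regions appears in all three
region reports, while genome-wide recovery percentages count it once.

## The overrepresentation test

For a region with `n` genes of which `k` are lectins, against genome
totals `N` and `s`:

* `z = (p0 − k/n) / sqrt(p0 (1 − p0) / n)` with `p0 = s/N` — a
  one-sample proportion (Wald) statistic under the *null* variance.
  The sign convention puts overrepresentation at negative z.
* `P = Φ(z)`, the lower standard-normal tail, with no continuity
  correction.
* Flags at α = 0.05 and at 0.025 (a fixed two-test Bonferroni
  correction), both requiring z < 0: the test is one-sided for
  overrepresentation, so depleted regions are never "significant".

The binomial null variance treats the region's genes as sampled with
replacement. The exact finite-population answer is hypergeometric, and
`hypergeometric_tail()` (`P[X ≥ k]`, `X ~ Hypergeom(N, s, n)`) is
computed for every region alongside the Wald P. In the regime the test
is meant for — region gene counts in the hundreds, regions a small
fraction of the genome, expected lectin counts of a few or more — the
two agree to well under 20% relative error and the gap closes as `n`
grows; for tiny regions (expected count below ~2) the normal
approximation degrades and `p_exact` is the number to trust. Both are
reported precisely so this comparison is never hidden.

## Duplication modes and Ka/Ks

Pairs are classified by a fixed precedence over a rule table:

| mode | rule |
|---|---|
| tandem | same chromosome, gene-rank distance ≤ 1 (adjacent) |
| proximal | same chromosome, rank distance ≤ 10 |
| wgd | pair is an anchor of a collinear block |
| transposed | exactly one gene at a caller-supplied ancestral locus, pair not block-anchored |
| dispersed | none of the above |

Strict adjacency for tandem and a 10-gene proximal window are common
conventions and both are parameters (`tandem_window`,
`proximal_window`). Transposition calls genuinely require outgroup
evidence; without an ancestral-locus list, would-be transposed pairs
fall to dispersed, which is stated in the output rather than guessed.
The collinear-block detector is deliberately simple — greedy chains of
rank-anchors, strictly monotone in both genomes (either orientation),
inter-anchor gap ≤ 25 ranks, minimum 5 anchors — adequate for calling
planted or well-preserved blocks, not a substitute for e-value-weighted
synteny tools.

Ka/Ks follows Nei–Gojobori (1986) on codon-aligned CDS (equal length,
multiple of 3, no internal stops; codons with ambiguity codes are
skipped and counted): synonymous site fractions per codon averaged
over both sequences; equal-weight pathway averaging for codons
differing at 2–3 positions; Jukes–Cantor correction
`d = −(3/4) ln(1 − 4p/3)`. Two conventions are fixed and mirrored by
the independent test oracle: mutations *to* stop codons count as
nonsynonymous in site counting, and multi-hit pathways passing through
a stop are excluded (unless every pathway is blocked, in which case
all are used). `ks` is undefined at the correction's domain edge
(`p_s ≥ 3/4`), and a pair is **retained** only when `ks` is finite and
≤ 1 — the recent-duplicate filter applied before every expansion
summary. Summaries report percentages on both counting bases (pairs
and distinct genes), because the two differ whenever one gene belongs
to several pairs.

## Promoters and SSRs

The promoter is the 1500 bp immediately upstream of the gene span,
strand-aware: upstream means 5′ of the transcription start, so for
minus-strand genes the reverse complement of the bases after the gene
end. Promoters truncate (flagged) at chromosome edges. Cis-element
scanning is exact IUPAC matching at every offset on both strands, all
overlapping hits reported; the motif catalog ships as an editable TSV
(name, IUPAC pattern, one of seven functional categories: hormone
response, drought, low temperature, wounding/pathogen, light,
development, core promoter) and is configuration, not hard-coded
biology.

SSR detection reports maximal perfect tandem repeats of 1–6 bp units
at MISA-style minimum counts (10/6/5/5/5/5 by unit length,
configurable), covering whole units only, and always at the shortest
unit (`ATATAT…` is a dinucleotide repeat, never a hexanucleotide one —
enforced by requiring a primitive unit). Imperfect and compound
repeats are out of scope.

## The synthetic genome and what it shows

`generate_synthetic_genome()` builds, deterministically from one seed:
non-overlapping genes with exon/intron structure on several
chromosomes, with CDS sequences spliced into the chromosome sequence
at the annotated coordinates; planted lectins with family-specific
domain architectures and secretion classes; a QTL table over 9 trait
subcategories in 5 categories; homologous CDS pairs mutated codon-wise
to target Ks values (synonymous and nonsynonymous changes applied to
disjoint codons, then measured and topped up until the realized NG86
Ks reaches the target, typically within a few percent); and promoter
motifs and intron SSRs written at recorded offsets. Every planted
truth lands in a manifest computed with plain base-R sweeps and
all-pairs loops — independent of the GenomicRanges/Biostrings paths
the analysis modules use — so manifest agreement is a genuine
dual-route check.

Default scale is N = 2000 genes with s = 40 lectins on 5 chromosomes,
preserving the lectin fraction (s/N ≈ 2%) of a real cereal genome
at desk scale; full-pipeline runs take seconds. QTLs span 25–75% of a
chromosome, so merged regions contain roughly 100–300 genes and the
expected lectin count per region stays at or above ~2 — the regime
where the Wald approximation is defensible. The statistical checks run
under these conditions:

* **Null calibration**: lectin labels are reassigned uniformly
  (10,000 resamples) and the fraction of region×resample combinations
  with Wald P < 0.05 must sit in 0.05 ± 0.01.
* **Planted power**: at genome scale (N = 34129, s = 119), a 500-gene
  region whose genes carry lectin labels at five times the background
  density (enrichment factor λ = 5, i.e. density λ·s/N) must reach
  P < 0.025 in at least 90% of 200 independent plantings.

Both are recomputed from scratch by `scripts/acceptance.R`.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: realistic base
composition (GC skew, isochores, repeats), UTRs and non-coding exons,
overlapping or nested genes, imperfect domain-scanner output (the
synthetic domain tables are clean), linkage-map-derived QTL boundary
uncertainty, and imperfect/compound SSRs. One consequence worth
flagging: short cis-elements (4–6 bp) occur by chance every few
hundred bp, so per-motif *presence* percentages saturate near 100% on
1500-bp promoters, in synthetic and real genomes alike; planted-motif
recall is checked at exact offsets, which random background cannot
mimic, and biological signal in real data lives in counts and
positions rather than presence/absence of short motifs.

## Numerical and degenerate-input choices

* pI bisection: tolerance 1e−4 charge units, bracket [0, 14],
  guaranteed to converge since net charge is strictly decreasing in pH.
* `wald_z` refuses empty regions (`n = 0`); `one_sided_p` refuses
  non-finite z.
* Empty annotation sets, empty QTL tables and empty pair tables
  produce empty (zero-row) results, never errors.
* Region ids are assigned after sorting (grouping key, chromosome,
  start), so outputs are stable across input orderings.
* Percentages are rounded to one decimal at the reporting boundary
  only; internal computation is double precision throughout.
* All randomness flows through explicit seeds; no stage consults the
  global RNG state except under a caller-provided seed.

## Known limitations

The Wald variance uses the binomial rather than the hypergeometric
form; for regions that are a large fraction of the genome the reported
P is conservative relative to `p_exact`, and the exact tail should be
preferred. The collinear-block detector can absorb a stray homologous
pair that happens to extend a chain monotonically within the gap
limit. The screen trusts its input domain table — no HMM or alignment
is run — so screen quality on real data is bounded by the upstream
scanner. Promoter extraction is TSS-approximate (gene-span start, not
annotated TSS), which is exact for the synthetic coding-only gene
models and an approximation wherever UTRs exist.
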