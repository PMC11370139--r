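# Cluster-level mutation summaries, bulk VAF, and the closed-form
# heterozygous-fraction expectation.

#' Summarise mutation status per cell cluster
#'
#' For each cluster, reports how many cells have informative coverage at the
#' variant site(s) and what fraction of those covered cells are mutated -
#' the quantity used to argue that a transcriptionally heterogeneous cluster
#' is nonetheless tumor ("mutated fraction among covered cells"). The
#' denominator of `mutated_fraction` is covered cells only
#' (`ALT + REF`); `mutated_fraction_all` (over all cells) is emitted as a
#' separate column to avoid ambiguity. Clusters with no covered cell get
#' `NA` fractions and `undefined = TRUE`.
#'
#' @param genotypes Combined genotype `data.frame`, one row per barcode
#'   (see [combine_sites()] or [classify_cells()] for a single site).
#' @param clusters Cluster assignment `data.frame` from
#'   [read_cluster_assignments()].
#' @param include_unassigned Count barcodes absent from `clusters` under an
#'   `"unassigned"` bucket (default `TRUE`); if `FALSE` they are dropped.
#' @param expected Optional expected mutated fraction among covered cells
#'   (e.g. from [expected_het_fraction()]); adds an exact binomial test
#'   p-value per cluster (`binomial_p`, no multiplicity correction - one
#'   descriptive comparison per cluster).
#' @return A `data.frame`: `cluster`, `n_cells`, `n_covered`, `n_alt_cells`,
#'   `covered_fraction`, `mutated_fraction`, `mutated_fraction_all`,
#'   `undefined`, `evidence`, and `expected_fraction`/`binomial_p` when
#'   `expected` is given.
#' @export
summarize_by_cluster <- function(genotypes, clusters,
                                 include_unassigned = TRUE,
                                 expected = NULL) {
  stopifnot(nrow(genotypes) >= 1L)
  if (anyDuplicated(genotypes$barcode))
    stop("genotypes must have one row per barcode; run combine_sites() first")
  cl <- clusters$cluster[match(genotypes$barcode, clusters$barcode)]
  if (include_unassigned) cl[is.na(cl)] <- "unassigned"
  keep <- !is.na(cl)
  g <- genotypes[keep, , drop = FALSE]
  cl <- cl[keep]
  rows <- lapply(split(seq_along(cl), cl), function(i) {
    lab <- g$label[i]
    n_cells <- length(i)
    n_alt <- sum(lab == "ALT")
    n_cov <- n_alt + sum(lab == "REF")
    data.frame(cluster = cl[i][1],
               n_cells = n_cells,
               n_covered = n_cov,
               n_alt_cells = n_alt,
               covered_fraction = n_cov / n_cells,
               mutated_fraction = if (n_cov > 0) n_alt / n_cov else NA_real_,
               mutated_fraction_all = n_alt / n_cells,
               undefined = n_cov == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$evidence <- g$evidence[1]
  if (!is.null(expected)) {
    stopifnot(expected >= 0, expected <= 1)
    out$expected_fraction <- expected
    out$binomial_p <- vapply(seq_len(nrow(out)), function(i) {
      if (out$n_covered[i] == 0L) return(NA_real_)
      stats::binom.test(out$n_alt_cells[i], out$n_covered[i],
                        p = expected)$p.value
    }, numeric(1))
  }
  out
}

#' Bulk variant allele fraction
#'
#' `VAF = n_alt / (n_alt + n_ref)` from bulk (e.g. whole-exome) read counts
#' at a somatic site; ranges over `[0, 1]` and reflects tumor purity and
#' zygosity.
#'
#' @param n_alt_reads,n_ref_reads Non-negative read counts; their sum must
#'   be at least 1.
#' @return VAF in `[0, 1]`.
#' @examples
#' bulk_vaf(0, 57)   # 0
#' bulk_vaf(53, 72)  # ~0.424
#' @export
bulk_vaf <- function(n_alt_reads, n_ref_reads) {
  if (n_alt_reads < 0 || n_ref_reads < 0)
    stop("read counts must be non-negative")
  depth <- n_alt_reads + n_ref_reads
  if (depth < 1) stop("zero total depth: VAF undefined")
  n_alt_reads / depth
}

#' Expected mutated fraction among covered heterozygous cells
#'
#' A heterozygous cell observed at depth 1 is called mutated with
#' probability 1/2 (one draw of one of two alleles - the origin of the
#' familiar "expected 50% for a heterozygous mutation"); at depth `d` with
#' balanced allele sampling the probability rises to `1 - (1/2)^d`. This
#' function evaluates the exact closed form for an arbitrary depth
#' distribution, allelic imbalance and sequencing error: each informative
#' observation is an alt call with probability `q = p + (1 - p) * epsilon`,
#' and a cell with depth `d` is called mutated when at least
#' `min_alt_evidence` of its `d` observations are alt, i.e. with probability
#' `P(Binom(d, q) >= min_alt_evidence)`. The result is the depth-weighted
#' mean over covered cells. With `p = 0` it gives the false-ALT rate among
#' homozygous-reference cells, `1 - (1 - epsilon)^d` at
#' `min_alt_evidence = 1`.
#'
#' @param depths Integer vector of informative depths, one per covered cell
#'   (all `>= 1`), or a named vector/table mapping depth to cell count.
#' @param p Probability an observation samples the alt allele (default 0.5,
#'   balanced heterozygote; allele-specific expression can skew it).
#' @param epsilon Per-observation miscall-to-alt probability (for a uniform
#'   substitution error rate `e`, `epsilon = e/3`). Default 0.
#' @param min_alt_evidence Alt observations required for an `ALT` call
#'   (default 1).
#' @return Expected mutated fraction among covered cells, in `[0, 1]`.
#' @examples
#' expected_het_fraction(rep(1, 100))              # 0.5
#' expected_het_fraction(rep(3, 100))              # 0.875
#' expected_het_fraction(c(`1` = 50, `3` = 50))    # mixed depths
#' @export
expected_het_fraction <- function(depths, p = 0.5, epsilon = 0,
                                  min_alt_evidence = 1L) {
  stopifnot(p >= 0, p <= 1, epsilon >= 0, epsilon < 1, min_alt_evidence >= 1L)
  if (is.table(depths) || !is.null(names(depths))) {
    d <- as.integer(names(depths))
    w <- as.numeric(depths)
  } else {
    tb <- table(as.integer(depths))
    d <- as.integer(names(tb))
    w <- as.numeric(tb)
  }
  if (!length(d) || sum(w) <= 0) stop("empty depth distribution")
  if (any(d < 1L)) stop("depths must be >= 1 (covered cells only)")
  q <- p + (1 - p) * epsilon
  prob_alt <- stats::pbinom(min_alt_evidence - 1L, d, q, lower.tail = FALSE)
  sum(w * prob_alt) / sum(w)
}

#' Write a cluster summary table
#'
#' Tab-separated output of [summarize_by_cluster()].
#'
#' @param summary Summary `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
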