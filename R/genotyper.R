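# Per-cell mutation-status classification at known SNV sites.

#' Classify cells as mutated / wildtype / unknown at one site
#'
#' Applies the trichotomy used to annotate tumor cells at known driver loci:
#' a cell is `ALT` (mutated) when at least `min_alt_evidence` observations
#' carry the variant allele, `REF` (wildtype) when it has reference
#' observations and fewer than `min_alt_evidence` variant observations, and
#' `UNKNOWN` when it has no informative coverage. Cells whose only
#' observations are a third base (neither ref nor alt) are handled by
#' `other_policy`: `"unknown"` (default - a discordant base carries no
#' information about the known variant) or `"ref"` (no variant allele seen
#' in the aligned reads).
#'
#' @param counts Allele-count `data.frame` from [pileup_site()].
#' @param min_alt_evidence Variant observations required to call `ALT`
#'   (default 1: "at least one read carrying the known variant allele"). A
#'   single variant read is vulnerable to sequencing error; raise to 2 for a
#'   stricter call.
#' @param other_policy `"unknown"` or `"ref"` for other-base-only cells.
#' @param barcodes Optional character vector of all cell barcodes under
#'   consideration; barcodes without counts receive `UNKNOWN` rows with
#'   zero counts so that every cell is labelled.
#' @param strip_suffix Normalize `barcodes` the same way the pileup
#'   normalized `CB` tags (default `TRUE`), see [normalize_barcode()].
#' @return A genotype `data.frame`: `barcode`, `site_id`, `label`, `n_ref`,
#'   `n_alt`, `n_other`, `evidence`.
#' @export
classify_cells <- function(counts, min_alt_evidence = 1L,
                           other_policy = c("unknown", "ref"),
                           barcodes = NULL, strip_suffix = TRUE) {
  other_policy <- match.arg(other_policy)
  if (!is.null(barcodes)) barcodes <- normalize_barcode(barcodes, strip_suffix)
  stopifnot(min_alt_evidence >= 1L)
  label <- rep("UNKNOWN", nrow(counts))
  is_alt <- counts$n_alt >= min_alt_evidence
  is_ref <- !is_alt & (counts$n_ref >= 1L |
                         (other_policy == "ref" & counts$n_other >= 1L))
  label[is_alt] <- "ALT"
  label[is_ref] <- "REF"
  out <- data.frame(barcode = counts$barcode,
                    site_id = counts$site_id,
                    label = label,
                    n_ref = counts$n_ref,
                    n_alt = counts$n_alt,
                    n_other = counts$n_other,
                    evidence = counts$evidence,
                    stringsAsFactors = FALSE)
  if (!is.null(barcodes)) {
    site_ids <- unique(out$site_id)
    if (!length(site_ids)) site_ids <- NA_character_
    ev <- if (nrow(out)) out$evidence[1] else "read"
    for (sid in site_ids) {
      missing <- setdiff(barcodes, out$barcode[out$site_id %in% sid])
      if (length(missing))
        out <- rbind(out, data.frame(
          barcode = missing, site_id = sid, label = "UNKNOWN",
          n_ref = 0L, n_alt = 0L, n_other = 0L, evidence = ev,
          stringsAsFactors = FALSE))
    }
    out <- out[order(out$site_id, out$barcode), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Combine per-site genotypes into one label per cell
#'
#' When a sample carries several candidate driver sites, a cell is mutated
#' if any site is `ALT`, wildtype if no site is `ALT` and at least one is
#' `REF`, and unknown otherwise. Counts are summed across sites.
#'
#' @param genotypes Genotype `data.frame` from [classify_cells()], possibly
#'   spanning several `site_id` values.
#' @param combined_id Label for the combined pseudo-site (default
#'   `"combined"`).
#' @return A genotype `data.frame` with one row per barcode.
#' @export
combine_sites <- function(genotypes, combined_id = "combined") {
  if (nrow(genotypes) == 0L) stop("no genotypes to combine (empty site list)")
  sp <- split(genotypes, genotypes$barcode)
  rows <- lapply(sp, function(g) {
    label <- if (any(g$label == "ALT")) "ALT"
             else if (any(g$label == "REF")) "REF"
             else "UNKNOWN"
    data.frame(barcode = g$barcode[1], site_id = combined_id, label = label,
               n_ref = sum(g$n_ref), n_alt = sum(g$n_alt),
               n_other = sum(g$n_other), evidence = g$evidence[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$barcode), , drop = FALSE]
}
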