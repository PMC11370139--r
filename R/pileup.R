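# Splice-aware CIGAR walk and per-cell allele counting from barcoded BAMs.

.REF_OPS <- c("M", "D", "N", "=", "X")   # consume reference
.QRY_OPS <- c("M", "I", "S", "=", "X")   # consume query

.parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*")
    stop("missing CIGAR")
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

# 1-based query index aligned to reference position `pos`, or NA when the
# site falls in a deletion/skip/clip or outside the aligned span.
.query_index_at <- function(start, cigar, pos, query_len = NA_integer_) {
  cg <- .parse_cigar(cigar)
  if (!is.na(query_len)) {
    qlen <- sum(cg$len[cg$op %in% .QRY_OPS])
    if (qlen != query_len)
      stop("CIGAR (", cigar, ") implies query length ", qlen,
           " but sequence has ", query_len)
  }
  ref_cur <- start
  qry_cur <- 1L
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    ref_c <- op %in% .REF_OPS
    qry_c <- op %in% .QRY_OPS
    if (ref_c && pos < ref_cur + len) {
      if (pos < ref_cur) return(NA_integer_)        # before aligned span
      if (!qry_c) return(NA_integer_)               # D or N spans the site
      return(qry_cur + (pos - ref_cur))
    }
    if (ref_c) ref_cur <- ref_cur + len
    if (qry_c) qry_cur <- qry_cur + len
  }
  NA_integer_                                       # past the aligned end
}

#' Base observed by one aligned read at a reference position
#'
#' Walks the read's CIGAR string to locate the query base aligned to a
#' 1-based reference coordinate. Operations `M`, `D`, `N`, `=`, `X` consume
#' reference; `M`, `I`, `S`, `=`, `X` consume query; `H` and `P` consume
#' neither. Positions falling under a deletion (`D`), intron skip (`N`), in
#' soft clips, or outside the aligned span are reported as `"uncovered"` —
#' this is what makes the walk splice-aware: an exon-exon junction read whose
#' `N` gap spans the variant site contributes no allele observation.
#'
#' @param start 1-based reference position of the first aligned base.
#' @param cigar CIGAR string (operations `MIDNSHP=X`).
#' @param seq Query sequence (character scalar).
#' @param pos 1-based reference coordinate to interrogate.
#' @param qual Optional query base-quality string (Phred+33).
#' @return A list with `base` (single character, or `"uncovered"`) and
#'   `qual` (integer Phred score, `NA` if uncovered or `qual` missing).
#' @examples
#' base_at_position(100, "50M", strrep("A", 50), pos = 120)$base    # "A"
#' base_at_position(100, "10M100N40M", strrep("A", 50), pos = 115)  # uncovered
#' @export
base_at_position <- function(start, cigar, seq, pos, qual = NULL) {
  qi <- .query_index_at(start, cigar, pos, query_len = nchar(seq))
  if (is.na(qi))
    return(list(base = "uncovered", qual = NA_integer_))
  q <- if (!is.null(qual) && !is.na(qual) && nzchar(qual))
    as.integer(charToRaw(substr(qual, qi, qi))) - 33L
  else NA_integer_
  list(base = substr(seq, qi, qi), qual = q)
}

.bam_index_path <- function(bam) {
  for (cand in c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam)))
    if (file.exists(cand)) return(cand)
  NULL
}

# Fetch reads overlapping a site with flag pre-filtering; returns a
# data.frame of raw observations (one per read) before quality filtering.
.fetch_site_reads <- function(bam, site) {
  idx <- .bam_index_path(bam)
  if (is.null(idx))
    stop("missing BAM index: expected ", paste0(bam, ".bai"),
         " (create with Rsamtools::indexBam or samtools index)")
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!site$chrom %in% names(hdr))
    stop("chromosome '", site$chrom, "' absent from BAM header; available: ",
         paste(names(hdr), collapse = ", "))
  which <- GenomicRanges::GRanges(site$chrom,
                                  IRanges::IRanges(site$pos, site$pos))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isNotPassingQualityControls = FALSE)
  param <- Rsamtools::ScanBamParam(
    which = which, flag = flag,
    what = c("qname", "pos", "cigar", "seq", "qual", "mapq"),
    tag = c("CB", "UB"))
  res <- Rsamtools::scanBam(Rsamtools::BamFile(bam, index = idx),
                            param = param)[[1]]
  data.frame(qname = res$qname,
             pos = res$pos,
             cigar = res$cigar,
             seq = as.character(res$seq),
             qual = as.character(res$qual),
             mapq = res$mapq,
             CB = if (is.null(res$tag$CB)) NA_character_ else res$tag$CB,
             UB = if (is.null(res$tag$UB)) NA_character_ else res$tag$UB,
             stringsAsFactors = FALSE)
}

#' Per-cell allele counts at one variant site
#'
#' Extracts the reads overlapping a known SNV locus from a coordinate-sorted,
#' indexed, barcoded BAM, determines the base each read reports at the site
#' via the splice-aware CIGAR walk ([base_at_position()]), applies quality
#' filters, and tallies reference / alternate / other observations per cell
#' barcode.
#'
#' Unmapped, secondary, supplementary and QC-fail reads never contribute.
#' Duplicate-flagged reads are retained: 10x duplicate marking is UMI-based
#' and is handled by `umi_mode` instead. With `umi_mode = "consensus"`,
#' observations sharing `(barcode, UMI)` collapse to a single count by
#' majority base; a tied vote discards that UMI (an evenly split molecule is
#' uninformative). Reads without a `UB` tag each count as their own molecule.
#' With `umi_mode = "auto"` (default), consensus is used when any retained
#' read carries a `UB` tag, read-level counting otherwise.
#'
#' @param bam Path to an indexed, coordinate-sorted BAM with `CB`/`UB` tags.
#' @param site One-row variant-site `data.frame` (see [variant_sites()]).
#' @param min_base_quality Minimum Phred base quality at the site
#'   (default 20).
#' @param min_mapping_quality Minimum mapping quality (default 0; a MAPQ of
#'   255, "unavailable", always passes).
#' @param require_cb Drop reads lacking a `CB` tag (default `TRUE`; such
#'   reads cannot be assigned to a cell).
#' @param umi_mode `"auto"`, `"consensus"` or `"read"`.
#' @param strip_suffix Normalize barcodes by stripping the GEM-well suffix
#'   (default `TRUE`), see [normalize_barcode()].
#' @return A `data.frame` with one row per observed barcode: `barcode`,
#'   `site_id`, `n_ref`, `n_alt`, `n_other`, `depth`, `evidence`
#'   (`"read"` or `"umi"`).
#' @export
pileup_site <- function(bam, site,
                        min_base_quality = 20,
                        min_mapping_quality = 0,
                        require_cb = TRUE,
                        umi_mode = c("auto", "consensus", "read"),
                        strip_suffix = TRUE) {
  umi_mode <- match.arg(umi_mode)
  stopifnot(is.data.frame(site), nrow(site) == 1L)
  reads <- .fetch_site_reads(bam, site)
  evidence_obs <- .site_observations(reads, site$pos,
                                     min_base_quality, min_mapping_quality,
                                     require_cb, umi_mode, strip_suffix)
  .tally_observations(evidence_obs$obs, site, evidence_obs$evidence)
}

# Filter raw reads to informative observations and (optionally) collapse
# UMIs; returns list(obs = data.frame(barcode, base), evidence = "read"|"umi")
.site_observations <- function(reads, pos, min_base_quality,
                               min_mapping_quality, require_cb,
                               umi_mode, strip_suffix) {
  n <- nrow(reads)
  base <- character(n); bq <- integer(n)
  for (i in seq_len(n)) {
    b <- base_at_position(reads$pos[i], reads$cigar[i], reads$seq[i],
                          pos, reads$qual[i])
    base[i] <- b$base; bq[i] <- b$qual
  }
  covered <- base != "uncovered"
  pass_bq <- ifelse(is.na(bq), min_base_quality <= 0, bq >= min_base_quality)
  pass_mq <- is.na(reads$mapq) | reads$mapq == 255L |
    reads$mapq >= min_mapping_quality
  keep <- covered & pass_bq & pass_mq
  if (require_cb) keep <- keep & !is.na(reads$CB)
  obs <- data.frame(barcode = normalize_barcode(reads$CB[keep], strip_suffix),
                    umi = reads$UB[keep],
                    base = base[keep],
                    stringsAsFactors = FALSE)
  obs$barcode[is.na(obs$barcode)] <- "(no-CB)"
  if (umi_mode == "auto")
    umi_mode <- if (any(!is.na(obs$umi))) "consensus" else "read"
  if (umi_mode == "read")
    return(list(obs = obs[, c("barcode", "base")], evidence = "read"))
  # consensus: majority base per (barcode, UMI); ties discarded;
  # missing UMIs get unique pseudo-keys (each read its own molecule)
  no_umi <- is.na(obs$umi)
  obs$umi[no_umi] <- paste0(".read", seq_len(sum(no_umi)))
  key <- paste(obs$barcode, obs$umi, sep = "\r")
  consensus <- function(b) {
    tb <- sort(table(b), decreasing = TRUE)
    if (length(tb) > 1L && tb[1] == tb[2]) NA_character_ else names(tb)[1]
  }
  by_mol <- tapply(obs$base, key, consensus)
  bc <- sub("\r.*$", "", names(by_mol))
  keep_mol <- !is.na(by_mol)
  list(obs = data.frame(barcode = bc[keep_mol],
                        base = unname(by_mol[keep_mol]),
                        stringsAsFactors = FALSE),
       evidence = "umi")
}

.tally_observations <- function(obs, site, evidence) {
  if (nrow(obs) == 0L)
    return(data.frame(barcode = character(), site_id = character(),
                      n_ref = integer(), n_alt = integer(),
                      n_other = integer(), depth = integer(),
                      evidence = character(), stringsAsFactors = FALSE))
  cls <- ifelse(obs$base == site$ref, "ref",
                ifelse(obs$base == site$alt, "alt", "other"))
  tab <- table(factor(obs$barcode), factor(cls, levels = c("ref", "alt", "other")))
  out <- data.frame(barcode = rownames(tab),
                    site_id = site$id,
                    n_ref = as.integer(tab[, "ref"]),
                    n_alt = as.integer(tab[, "alt"]),
                    n_other = as.integer(tab[, "other"]),
                    stringsAsFactors = FALSE)
  out$depth <- out$n_ref + out$n_alt + out$n_other
  out$evidence <- evidence
  out[order(out$barcode), , drop = FALSE]
}

#' Per-cell allele counts at several sites
#'
#' Applies [pileup_site()] to each row of a variant-site table and binds the
#' results.
#'
#' @inheritParams pileup_site
#' @param sites Variant-site `data.frame`, one row per locus.
#' @param ... Passed to [pileup_site()].
#' @return Row-bound counts, one row per (barcode, site) observed.
#' @export
pileup_sites <- function(bam, sites, ...) {
  stopifnot(nrow(sites) >= 1L)
  out <- lapply(seq_len(nrow(sites)),
                function(i) pileup_site(bam, sites[i, , drop = FALSE], ...))
  do.call(rbind, out)
}
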