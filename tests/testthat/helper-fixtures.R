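# In-code fixture builders (no stored binary files).

# Write a minimal sites-only VCF.
write_test_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr3>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    records), path)
  path
}

# Hand-built barcoded BAM from an explicit read table; returns the BAM path.
# `reads` columns: pos, cigar, seq, qual (string or single char to repeat),
# optional flag, mapq, CB, UB.
make_test_bam <- function(reads, chrom = "chr1", chrom_len = 10000,
                          prefix = tempfile()) {
  n <- nrow(reads)
  flag <- if ("flag" %in% names(reads)) reads$flag else rep(0L, n)
  mapq <- if ("mapq" %in% names(reads)) reads$mapq else rep(60L, n)
  qual <- vapply(seq_len(n), function(i) {
    q <- reads$qual[i]
    if (nchar(q) == 1L) strrep(q, nchar(reads$seq[i])) else q
  }, "")
  tags <- vapply(seq_len(n), function(i) {
    t <- character()
    if ("CB" %in% names(reads) && !is.na(reads$CB[i]))
      t <- c(t, paste0("CB:Z:", reads$CB[i]))
    if ("UB" %in% names(reads) && !is.na(reads$UB[i]))
      t <- c(t, paste0("UB:Z:", reads$UB[i]))
    paste(t, collapse = "\t")
  }, "")
  rec <- paste(sprintf("q%03d", seq_len(n)), flag, chrom, reads$pos, mapq,
               reads$cigar, "*", 0L, 0L, reads$seq, qual, sep = "\t")
  rec <- ifelse(nzchar(tags), paste(rec, tags, sep = "\t"), rec)
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len),
               rec), sam)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# Shorthand allele-count row(s) for classifier tests.
make_counts <- function(n_ref, n_alt, n_other = 0L,
                        barcode = sprintf("BC%02d", seq_along(n_ref)),
                        site_id = "s1", evidence = "read") {
  data.frame(barcode = barcode, site_id = site_id,
             n_ref = as.integer(n_ref), n_alt = as.integer(n_alt),
             n_other = as.integer(n_other),
             depth = as.integer(n_ref + n_alt + n_other),
             evidence = evidence, stringsAsFactors = FALSE)
}
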