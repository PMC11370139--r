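#' Construct a table of known SNV sites
#'
#' A variant-site table holds the loci to genotype: one row per single-base
#' substitution, with 1-based coordinates as in VCF.
#'
#' @param chrom Chromosome names, matching the alignment header (character).
#' @param pos 1-based genomic positions (integer-like, `>= 1`).
#' @param ref,alt Single uppercase bases in `A/C/G/T`; `ref != alt` per row.
#' @param id Optional site labels (e.g. `"CTNNB1:S33"`); defaults to
#'   `"{chrom}:{pos}{ref}>{alt}"`.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `id`.
#' @examples
#' variant_sites("chr3", 41224610, "C", "T", id = "CTNNB1:S33")
#' @export
variant_sites <- function(chrom, pos, ref, alt, id = NULL) {
  chrom <- as.character(chrom)
  pos <- suppressWarnings(as.integer(pos))
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- length(chrom)
  if (length(pos) != n || length(ref) != n || length(alt) != n)
    stop("chrom, pos, ref, alt must have equal length")
  if (anyNA(pos) || any(pos < 1L))
    stop("malformed coordinate: positions must be integers >= 1")
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("indel/MNV not supported: REF and ALT must be single bases (",
         paste0(chrom[bad], ":", pos[bad], " ", ref[bad], ">", alt[bad],
                collapse = ", "), ")")
  if (any(ref == alt))
    stop("ref and alt must differ at every site")
  if (is.null(id)) id <- paste0(chrom, ":", pos, ref, ">", alt)
  id <- as.character(id)
  id[is.na(id) | id == "." | id == ""] <-
    paste0(chrom, ":", pos, ref, ">", alt)[is.na(id) | id == "." | id == ""]
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, id = id,
             stringsAsFactors = FALSE)
}

#' Read known SNV sites from a VCF or TSV file
#'
#' Accepts a sites-only VCF 4.x file (INFO/FORMAT ignored) or a tab-separated
#' table with columns `chrom`, `pos`, `ref`, `alt` and an optional fifth `id`
#' column (`#` comment lines skipped; an optional header row is detected).
#' Multi-allelic VCF records are split into one site per ALT allele. Records
#' with multi-base or symbolic alleles are rejected: this tool genotypes
#' point mutations only.
#'
#' @param path Path to the variant file. Files ending in `.vcf`/`.vcf.gz`, or
#'   whose first line starts with `##fileformat`, are parsed as VCF.
#' @param chrom_alias Optional named character vector mapping chromosome
#'   names as written in the file to names used in the alignment header
#'   (e.g. `c("3" = "chr3")`). Without it, names are taken verbatim.
#' @return A variant-site `data.frame` (see [variant_sites()]), input order
#'   preserved.
#' @export
read_variant_sites <- function(path, chrom_alias = NULL) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path) ||
    (length(first) && startsWith(first, "##fileformat"))
  sites <- if (is_vcf) .read_vcf_sites(path) else .read_tsv_sites(path)
  if (!is.null(chrom_alias)) {
    hit <- sites$chrom %in% names(chrom_alias)
    sites$chrom[hit] <- unname(chrom_alias[sites$chrom[hit]])
  }
  sites
}

.read_vcf_sites <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("no variant records in ", path)
  chrom <- fix[, "CHROM"]
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  id <- fix[, "ID"]
  if (anyNA(pos)) stop("malformed coordinate in VCF record ",
                       which(is.na(pos))[1])
  bad_ref <- nchar(ref) != 1L
  if (any(bad_ref))
    stop("indel/MNV not supported at record ", which(bad_ref)[1], " (",
         chrom[bad_ref][1], ":", pos[bad_ref][1], " REF=", ref[bad_ref][1], ")")
  # split multi-allelic records, preserving record order
  alts <- strsplit(alt, ",", fixed = TRUE)
  k <- lengths(alts)
  idx <- rep(seq_along(k), k)
  alt_flat <- unlist(alts, use.names = FALSE)
  bad_alt <- nchar(alt_flat) != 1L | !alt_flat %in% c("A", "C", "G", "T")
  if (any(bad_alt))
    stop("indel/MNV not supported at record ", idx[bad_alt][1], " (",
         chrom[idx][bad_alt][1], ":", pos[idx][bad_alt][1],
         " ALT=", alt_flat[bad_alt][1], ")")
  id_flat <- id[idx]
  # a split record needs distinct ids per allele; default labels provide that
  id_flat[k[idx] > 1L] <- "."
  variant_sites(chrom[idx], pos[idx], ref[idx], alt_flat, id = id_flat)
}

.read_tsv_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop("no variant records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("variant TSV needs at least 4 columns (chrom, pos, ref, alt)")
  # optional header row: second field not a number
  if (is.na(suppressWarnings(as.integer(fields[[1]][2])))) {
    fields <- fields[-1]
    if (!length(fields)) stop("no variant records in ", path)
  }
  chrom <- vapply(fields, `[`, "", 1L)
  pos <- vapply(fields, `[`, "", 2L)
  ref <- vapply(fields, `[`, "", 3L)
  alt <- vapply(fields, `[`, "", 4L)
  id <- vapply(fields, function(f) if (length(f) >= 5L) f[5L] else NA_character_, "")
  pos_i <- suppressWarnings(as.integer(pos))
  if (anyNA(pos_i)) stop("malformed coordinate '", pos[is.na(pos_i)][1], "' in ", path)
  variant_sites(chrom, pos_i, ref, alt, id = id)
}

#' Normalize a cell barcode
#'
#' Strips a trailing GEM-well suffix (`-1`, `-2`, ...) so that barcodes from
#' CellRanger `barcodes.tsv` / BAM `CB` tags match user cluster tables that
#' omit it.
#'
#' @param barcode Character vector of barcodes.
#' @param strip_suffix Strip a trailing `-<integer>`? Default `TRUE`.
#' @return Character vector of normalized barcodes.
#' @export
normalize_barcode <- function(barcode, strip_suffix = TRUE) {
  if (strip_suffix) sub("-[0-9]+$", "", barcode) else barcode
}

#' Read a barcode-to-cluster assignment table
#'
#' Two-column tab-separated file: cell barcode, cluster label. `#` comment
#' lines are skipped and an optional header row is detected. Each barcode may
#' appear at most once.
#'
#' @inheritParams normalize_barcode
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `barcode` (normalized) and `cluster`.
#' @export
read_cluster_assignments <- function(path, strip_suffix = TRUE) {
  if (!file.exists(path)) stop("cluster table not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty cluster table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("cluster table needs 2 tab-separated columns (barcode, cluster)")
  if (identical(tolower(fields[[1]][1]), "barcode")) {
    fields <- fields[-1]
    if (!length(fields)) stop("empty cluster table: ", path)
  }
  barcode <- normalize_barcode(vapply(fields, `[`, "", 1L), strip_suffix)
  cluster <- vapply(fields, `[`, "", 2L)
  dup <- duplicated(barcode)
  if (any(dup))
    stop("duplicate barcode in cluster table: ", barcode[dup][1])
  data.frame(barcode = barcode, cluster = cluster, stringsAsFactors = FALSE)
}

#' Read a barcode list (CellRanger `barcodes.tsv` layout)
#'
#' One barcode per line; gzipped files accepted.
#'
#' @inheritParams normalize_barcode
#' @param path Path to the barcode file (`.tsv` or `.tsv.gz`).
#' @return Character vector of normalized barcodes.
#' @export
read_barcodes <- function(path, strip_suffix = TRUE) {
  if (!file.exists(path)) stop("barcode file not found: ", path)
  bc <- readLines(path)
  bc <- bc[nzchar(bc)]
  normalize_barcode(bc, strip_suffix)
}

.GENOTYPE_COLS <- c("barcode", "site_id", "label",
                    "n_ref", "n_alt", "n_other", "evidence")

#' Write / read a per-cell genotype table
#'
#' Tab-separated, one row per (cell, site): `barcode`, `site_id`, `label`
#' (`ALT`/`REF`/`UNKNOWN`), counts `n_ref`, `n_alt`, `n_other`, and the
#' `evidence` level (`read` or `umi`). `write_genotype_table()` and
#' [read_genotype_table()] round-trip losslessly.
#'
#' @param genotypes A genotype `data.frame` (see [classify_cells()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  stopifnot(all(.GENOTYPE_COLS %in% names(genotypes)))
  utils::write.table(genotypes[, .GENOTYPE_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character", "character",
                                        "integer", "integer", "integer",
                                        "character"),
                         stringsAsFactors = FALSE)
  stopifnot(identical(names(g), .GENOTYPE_COLS))
  g
}
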