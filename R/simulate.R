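# Seeded generators: barcoded alignments over a known SNV with truth
# genotypes, and expression matrices with a planted active gene set.

.BASES <- c("A", "C", "G", "T")

# deterministic fixed-width base-4 encoding of an index as a DNA word
.dna_word <- function(i, width) {
  stopifnot(i >= 1)
  digits <- integer(width)
  v <- i - 1
  for (k in seq_len(width)) {
    digits[k] <- v %% 4
    v <- v %/% 4
  }
  paste(rev(.BASES[digits + 1L]), collapse = "")
}

#' Configuration for the barcoded-alignment simulator
#'
#' Defaults describe a modest 10x-style library over a heterozygous driver
#' SNV: 500 cells, an even mix of homozygous-reference and heterozygous
#' cells, per-cell molecule depth Poisson(2) with an explicit zero class
#' (so uncovered cells exercise the `UNKNOWN` label), per-base substitution
#' error 0.001 (miscalls uniform over the three other bases), on average
#' 0.5 extra PCR/optical reads per molecule, 20% of reads spliced over the
#' site, and balanced allelic sampling.
#'
#' @param n_cells Number of cells.
#' @param het_fraction Fraction of cells heterozygous for the variant; the
#'   rest are homozygous reference.
#' @param depth_lambda Poisson mean of the per-cell molecule count at the
#'   site (the zero class is kept deliberately: depth-0 cells stay).
#' @param error_rate Per-read substitution probability at the site
#'   (`e`; miscall lands on each of the other 3 bases with probability
#'   `e/3`).
#' @param umi_dup_mean Poisson mean of *extra* reads per molecule (each
#'   molecule yields `1 + Pois(umi_dup_mean)` reads sharing one UMI).
#' @param spliced_fraction Probability a read carries an intron skip (`N`)
#'   spanning the site, contributing no allele observation.
#' @param p_alt Probability a heterozygous cell's molecule carries the alt
#'   allele (default 0.5, balanced).
#' @param read_length Read length in bp (default 91, 10x R2-like;
#'   single-end).
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 500L, het_fraction = 0.5,
                       depth_lambda = 2, error_rate = 0.001,
                       umi_dup_mean = 0.5, spliced_fraction = 0.2,
                       p_alt = 0.5, read_length = 91L, seed = 1L) {
  stopifnot(n_cells >= 1L,
            het_fraction >= 0, het_fraction <= 1,
            depth_lambda > 0,
            error_rate >= 0, error_rate < 1,
            umi_dup_mean >= 0,
            spliced_fraction >= 0, spliced_fraction <= 1,
            p_alt >= 0, p_alt <= 1,
            read_length >= 31L)
  structure(list(n_cells = as.integer(n_cells), het_fraction = het_fraction,
                 depth_lambda = depth_lambda, error_rate = error_rate,
                 umi_dup_mean = umi_dup_mean,
                 spliced_fraction = spliced_fraction, p_alt = p_alt,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a barcoded alignment file over one known SNV
#'
#' Emits a coordinate-sorted, indexed BAM whose reads carry `CB` (cell
#' barcode) and `UB` (UMI) tags, together with a truth table, so the whole
#' genotyping path can be tested without controlled-access data. Each
#' cell's molecules draw the alt allele with probability `p_alt` when the
#' cell is heterozygous (never when homozygous reference); every read of a
#' molecule shares its allele; miscalls are applied per read at
#' `error_rate`; spliced reads place an `N` gap over the site and are
#' therefore uninformative.
#'
#' @param config A [sim_config()].
#' @param site One-row variant-site `data.frame` ([variant_sites()]); `pos`
#'   must exceed ~300 so reads fit on the contig.
#' @param out_prefix Output path prefix; writes `<prefix>.bam`,
#'   `<prefix>.bam.bai`, `<prefix>.truth_cells.tsv`,
#'   `<prefix>.truth_reads.tsv`.
#' @return Invisibly, a list: `bam`, `truth` (per-cell `data.frame`:
#'   `barcode`, `genotype` in `het`/`homref`, `n_molecules`,
#'   `n_informative` molecules with at least one unspliced read,
#'   `n_alt_informative` of those carrying alt), `truth_reads` (per-read
#'   `data.frame`), and the two truth paths.
#' @export
simulate_bam <- function(config, site, out_prefix) {
  stopifnot(inherits(config, "sim_config"),
            is.data.frame(site), nrow(site) == 1L)
  if (site$pos < 300L) stop("site pos must be >= 300 for read placement")
  withr::with_seed(config$seed, .simulate_bam_impl(config, site, out_prefix))
}

.simulate_bam_impl <- function(cfg, site, out_prefix) {
  L <- cfg$read_length
  n_het <- round(cfg$n_cells * cfg$het_fraction)
  genotype <- rep(c("het", "homref"), c(n_het, cfg$n_cells - n_het))
  barcode <- paste0(vapply(seq_len(cfg$n_cells), .dna_word, "", width = 14L), "-1")
  n_mol <- stats::rpois(cfg$n_cells, cfg$depth_lambda)

  cell_rows <- vector("list", cfg$n_cells)
  read_rows <- vector("list", cfg$n_cells)
  rid <- 0L
  for (ci in seq_len(cfg$n_cells)) {
    m <- n_mol[ci]
    inf <- 0L; alt_inf <- 0L
    reads <- NULL
    if (m > 0L) {
      allele <- if (genotype[ci] == "het")
        ifelse(stats::runif(m) < cfg$p_alt, "alt", "ref") else rep("ref", m)
      mol_reads <- 1L + stats::rpois(m, cfg$umi_dup_mean)
      per_mol <- vector("list", m)
      for (mi in seq_len(m)) {
        k <- mol_reads[mi]
        spliced <- stats::runif(k) < cfg$spliced_fraction
        if (any(!spliced)) {
          inf <- inf + 1L
          if (allele[mi] == "alt") alt_inf <- alt_inf + 1L
        }
        true_base <- if (allele[mi] == "alt") site$alt else site$ref
        miscall <- stats::runif(k) < cfg$error_rate
        obs <- rep(true_base, k)
        if (any(miscall))
          obs[miscall] <- vapply(which(miscall), function(z)
            sample(setdiff(.BASES, true_base), 1L), "")
        per_mol[[mi]] <- data.frame(
          umi = .dna_word(mi, 10L), allele = allele[mi],
          spliced = spliced, obs_base = obs, stringsAsFactors = FALSE)
      }
      reads <- do.call(rbind, per_mol)
      reads$barcode <- barcode[ci]
    }
    cell_rows[[ci]] <- data.frame(
      barcode = barcode[ci], genotype = genotype[ci], n_molecules = m,
      n_informative = inf, n_alt_informative = alt_inf,
      stringsAsFactors = FALSE)
    read_rows[[ci]] <- reads
  }
  truth <- do.call(rbind, cell_rows)
  truth_reads <- do.call(rbind, read_rows[!vapply(read_rows, is.null, TRUE)])
  if (is.null(truth_reads))
    truth_reads <- data.frame(umi = character(), allele = character(),
                              spliced = logical(), obs_base = character(),
                              barcode = character(), stringsAsFactors = FALSE)

  # geometry and SAM records
  n_reads <- nrow(truth_reads)
  qname <- sprintf("r%07d", seq_len(n_reads))
  start <- integer(n_reads); cigar <- character(n_reads)
  seqs <- character(n_reads)
  filler <- strrep("A", L)
  m1 <- 30L; gap <- 200L; m2 <- L - m1
  if (n_reads > 0L) for (i in seq_len(n_reads)) {
    if (truth_reads$spliced[i]) {
      s <- sample.int(gap, 1L) - 1L
      start[i] <- site$pos - m1 - s
      cigar[i] <- paste0(m1, "M", gap, "N", m2, "M")
      seqs[i] <- filler
    } else {
      o <- sample.int(min(L, site$pos), 1L) - 1L
      start[i] <- site$pos - o
      cigar[i] <- paste0(L, "M")
      seqs[i] <- paste0(substr(filler, 1L, o), truth_reads$obs_base[i],
                        substr(filler, o + 2L, L))
    }
  }
  truth_reads$read_id <- qname
  truth_reads$start <- start
  truth_reads$cigar <- cigar

  sam <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", site$chrom, "\tLN:",
                     site$pos + gap + 10L * L))
  qual <- strrep("F", L)                              # Phred 37 throughout
  records <- if (n_reads > 0L)
    paste(qname, 0L, site$chrom, start, 255L, cigar, "*", 0L, 0L,
          seqs, qual,
          paste0("CB:Z:", truth_reads$barcode),
          paste0("UB:Z:", truth_reads$umi), sep = "\t")
  else character()
  writeLines(c(header, records), sam)
  bam <- Rsamtools::asBam(sam, out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)

  truth_path <- paste0(out_prefix, ".truth_cells.tsv")
  reads_path <- paste0(out_prefix, ".truth_reads.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    truth_reads[, c("read_id", "barcode", "umi", "allele", "spliced",
                    "obs_base", "start", "cigar")],
    reads_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(bam = bam, truth = truth, truth_reads = truth_reads,
                 truth_path = truth_path, truth_reads_path = reads_path))
}

#' Simulate an expression matrix with a planted active gene set
#'
#' Inactive cells draw every gene i.i.d. from a negative-binomial law with
#' gene-specific lognormal means; active cells draw the planted set's genes
#' with means inflated by `2^effect`, shifting those genes toward the top
#' of the active cells' rankings. `effect = 0` is the null (active and
#' inactive cells identically distributed).
#'
#' @param n_genes Gene universe size.
#' @param n_cells_active,n_cells_inactive Cells with / without the planted
#'   activity.
#' @param set_size Planted set size (`<= n_genes`).
#' @param effect Log2 fold inflation of set-gene means in active cells.
#' @param dispersion Negative-binomial `size` parameter (default 2).
#' @param seed Integer seed.
#' @return A list: `counts` (sparse genes x cells `dgCMatrix`), `set`
#'   (planted gene ids), `labels` (`data.frame` with `barcode`, `active`).
#' @export
simulate_expression <- function(n_genes = 200L, n_cells_active = 50L,
                                n_cells_inactive = 50L, set_size = 10L,
                                effect = 2, dispersion = 2, seed = 1L) {
  stopifnot(set_size <= n_genes, set_size >= 1L, effect >= 0,
            n_cells_active >= 1L, n_cells_inactive >= 1L)
  withr::with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    n_cells <- n_cells_active + n_cells_inactive
    cells <- paste0(vapply(seq_len(n_cells), .dna_word, "", width = 14L), "-1")
    active <- rep(c(TRUE, FALSE), c(n_cells_active, n_cells_inactive))
    mu <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    set_genes <- sample(genes, set_size)
    set_i <- match(set_genes, genes)
    counts <- matrix(0L, n_genes, n_cells, dimnames = list(genes, cells))
    for (j in seq_len(n_cells)) {
      mu_j <- mu
      if (active[j]) mu_j[set_i] <- mu_j[set_i] * 2^effect
      counts[, j] <- stats::rnbinom(n_genes, mu = mu_j, size = dispersion)
    }
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         set = set_genes,
         labels = data.frame(barcode = cells, active = active,
                             stringsAsFactors = FALSE))
  })
}
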