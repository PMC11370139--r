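# Rank-based per-cell gene-set activity: recovery-curve AUC (AUCell-style).

# Deterministic per-cell seed so scores depend only on (values, barcode,
# seed), never on column order.
.cell_seed <- function(seed, barcode) {
  h <- 0
  for (v in utf8ToInt(barcode)) h <- (h * 131 + v) %% 2147483563
  as.integer((h + as.numeric(seed)) %% 2147483563) + 1L
}

#' Rank genes within one cell, highest expression first
#'
#' Produces a total order over the gene universe for one cell's expression
#' vector (rank 1 = highest value). Ties - including the dominant zero
#' block of droplet data - are broken by a seeded uniform shuffle, so equal
#' values are ordered randomly but reproducibly; average ranks are avoided
#' because they let a fully unexpressed gene set accrue fractional recovery.
#'
#' @param x Numeric expression vector (one cell, length = gene universe).
#' @param tie_seed Integer seed for the tie-breaking shuffle.
#' @return Integer vector of ranks, same length and names as `x`.
#' @export
rank_genes <- function(x, tie_seed = 1L) {
  n <- length(x)
  shuffle <- withr::with_seed(tie_seed, sample.int(n))
  ord <- order(-x, shuffle)
  r <- integer(n)
  r[ord] <- seq_len(n)
  names(r) <- names(x)
  r
}

#' Recovery-curve AUC of a gene set in one ranked cell
#'
#' The recovery curve counts how many genes of a set `S` appear among the
#' top `k` ranked genes, for `k = 1 .. T` with `T = floor(theta * n_genes)`.
#' The score is the area under this step function normalised by the maximal
#' area achievable if all set genes occupied the very top ranks:
#' `auc = sum_k H(k) / sum_k min(k, |S|)` with
#' `H(k) = |{g in S : rank(g) <= k}|`. A set filling the top `|S|` ranks
#' scores exactly 1 regardless of `|S|` versus `T` (normalisation choice
#' documented because implementations differ here); a set entirely below
#' the threshold scores 0.
#'
#' @param ranks Integer rank vector from [rank_genes()] (named by gene).
#' @param set Character vector of set member genes, or logical/integer
#'   index into the universe.
#' @param top_fraction Fraction of the universe forming the evaluation
#'   window (default 0.05, the usual recovery-AUC convention);
#'   `T = floor(top_fraction * n)` must be `>= 1`.
#' @return AUC in `[0, 1]`.
#' @export
recovery_auc <- function(ranks, set, top_fraction = 0.05) {
  n <- length(ranks)
  stopifnot(top_fraction > 0, top_fraction <= 1)
  T <- floor(top_fraction * n)
  if (T < 1L) stop("top_fraction too small: evaluation window is empty")
  if (is.character(set)) {
    missing <- setdiff(set, names(ranks))
    if (length(missing) == length(set))
      stop("no set gene found in the universe; unmatched: ",
           paste(utils::head(missing, 10), collapse = ", "))
    hit_ranks <- unname(ranks[intersect(set, names(ranks))])
  } else {
    hit_ranks <- unname(ranks[set])
  }
  s <- length(hit_ranks)
  if (s == 0L) stop("empty gene set")
  r <- hit_ranks[hit_ranks <= T]
  num <- sum(T - r + 1)                       # = sum_{k=1..T} H(k)
  k <- seq_len(T)
  den <- sum(pmin(k, s))
  num / den
}

#' Score gene-set activity per cell across an expression matrix
#'
#' Ranks each cell's expression profile ([rank_genes()]) and computes the
#' recovery AUC ([recovery_auc()]) of every gene set. Set genes absent from
#' the matrix are dropped (a message reports how many); a set with no gene
#' in the matrix is scored `NA` with a warning rather than a silent zero.
#' Scores are rank-based, hence invariant under any strictly monotone
#' transform of a cell's values (raw counts and log-normalised data give
#' identical scores), and each cell is scored independently: its tie-break
#' seed derives from `seed` and its barcode, so permuting cell order only
#' permutes output rows.
#'
#' @param mat Genes x cells numeric matrix (dense or `Matrix` sparse) with
#'   gene rownames and cell colnames.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param top_fraction Passed to [recovery_auc()]; default 0.05.
#' @param seed Base integer seed for tie-breaking (recorded in the output).
#' @return A `data.frame`: `barcode`, `set`, `auc`, `threshold_rank`,
#'   `n_set_genes`, `seed`.
#' @export
score_signatures <- function(mat, sets, top_fraction = 0.05, seed = 1L) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  if (anyDuplicated(rownames(mat))) stop("gene identifiers must be unique")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  genes <- rownames(mat)
  n <- length(genes)
  T <- floor(top_fraction * n)
  set_idx <- lapply(sets, function(s) {
    dropped <- sum(!s %in% genes)
    if (dropped > 0)
      message("dropping ", dropped, "/", length(s),
              " set genes absent from the matrix")
    which(genes %in% s)
  })
  empty <- vapply(set_idx, length, 1L) == 0L
  if (any(empty))
    warning("gene set(s) with no gene in the matrix scored as NA: ",
            paste(names(sets)[empty], collapse = ", "))
  cells <- colnames(mat)
  out <- vector("list", length(cells))
  for (j in seq_along(cells)) {
    x <- as.numeric(mat[, j])
    r <- rank_genes(x, tie_seed = .cell_seed(seed, cells[j]))
    auc <- vapply(set_idx, function(idx) {
      if (!length(idx)) return(NA_real_)
      recovery_auc(r, idx, top_fraction = top_fraction)
    }, numeric(1))
    out[[j]] <- data.frame(barcode = cells[j], set = names(sets),
                           auc = unname(auc), threshold_rank = T,
                           n_set_genes = unname(vapply(set_idx, length, 1L)),
                           seed = seed, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited: set name, description, then member genes. Returns a named
#' list of character vectors.
#'
#' @param path Path to the `.gmt` file.
#' @return Named list of gene identifier vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (second GMT column); recycled.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a CellRanger-layout sparse expression matrix
#'
#' Reads the MatrixMarket triplet (`matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`, gzipped variants accepted) into a genes x cells sparse
#' matrix with gene rownames and barcode colnames.
#'
#' @param dir Directory containing the triplet, or `NULL` when the three
#'   paths are given explicitly.
#' @param mtx,barcodes,features Explicit paths (override `dir`).
#' @param feature_column Column of `features.tsv` holding the gene
#'   identifier to use (default 1, the feature id).
#' @param strip_suffix Normalize barcodes (default `TRUE`).
#' @return A `dgCMatrix`, genes x cells.
#' @export
read_mtx_matrix <- function(dir = NULL, mtx = NULL, barcodes = NULL,
                            features = NULL, feature_column = 1L,
                            strip_suffix = TRUE) {
  find1 <- function(names) {
    for (nm in names) {
      p <- file.path(dir, nm)
      if (file.exists(p)) return(p)
    }
    stop("none of ", paste(names, collapse = "/"), " found in ", dir)
  }
  if (!is.null(dir)) {
    if (is.null(mtx)) mtx <- find1(c("matrix.mtx", "matrix.mtx.gz"))
    if (is.null(barcodes)) barcodes <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
    if (is.null(features)) features <- find1(c("features.tsv", "features.tsv.gz",
                                               "genes.tsv", "genes.tsv.gz"))
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  bc <- read_barcodes(barcodes, strip_suffix = strip_suffix)
  ft <- utils::read.table(features, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(m) != nrow(ft) || ncol(m) != length(bc))
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") disagree with features (", nrow(ft), ") / barcodes (",
         length(bc), ")")
  rownames(m) <- ft[[feature_column]]
  colnames(m) <- bc
  m
}

#' Write a CellRanger-layout sparse expression matrix
#'
#' @param mat Genes x cells matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx_matrix <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(mat, "dMatrix"), "TsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  invisible(dir)
}
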